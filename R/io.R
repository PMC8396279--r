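#' Write a configuration or trajectory as extended XYZ
#'
#' One block per frame: bead count, a comment line carrying the box as a
#' `Lattice="..."` record, then `species x y z` lines.  Readable by OVITO,
#' VMD and ASE for visual inspection and cross-validation against external
#' MD codes.
#'
#' @param config an `md_config`
#' @param path output file
#' @param frames optional list of position matrices (defaults to the
#'   configuration's own positions)
#' @return invisibly, the path
#' @export
write_xyz <- function(config, path, frames = NULL) {
  stopifnot(inherits(config, "md_config"))
  if (is.null(frames)) frames <- list(config$positions)
  sp <- names(SPECIES)[config$species]
  L <- config$box$L
  lattice <- sprintf("Lattice=\"%g 0 0 0 %g 0 0 0 %g\" Properties=species:S:1:pos:R:3",
                     L[1], L[2], L[3])
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    writeLines(c(as.character(nrow(f)), lattice), con)
    writeLines(sprintf("%s %.8f %.8f %.8f", sp, f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Write a LAMMPS data file (atoms + bonds)
#'
#' Emits an `atom_style bond` data file (Masses, Atoms, Bonds sections) so a
#' built configuration can be cross-validated in an external MD code.
#'
#' @param config an `md_config`
#' @param path output file
#' @return invisibly, the path
#' @export
write_lammps_data <- function(config, path) {
  stopifnot(inherits(config, "md_config"))
  n <- nrow(config$positions)
  nb <- nrow(config$bonds)
  L <- config$box$L
  lines <- c(
    "LAMMPS data file generated by hairyMD", "",
    sprintf("%d atoms", n),
    sprintf("%d bonds", nb),
    "3 atom types",
    if (nb > 0) "1 bond types" else "0 bond types", "",
    sprintf("0.0 %g xlo xhi", L[1]),
    sprintf("0.0 %g ylo yhi", L[2]),
    sprintf("0.0 %g zlo zhi", L[3]), "",
    "Masses", "", "1 1.0", "2 1.0", "3 1.0", "",
    "Atoms # bond", "",
    sprintf("%d 1 %d %.8f %.8f %.8f", seq_len(n), config$species,
            config$positions[, 1], config$positions[, 2], config$positions[, 3]))
  if (nb > 0)
    lines <- c(lines, "", "Bonds", "",
               sprintf("%d 1 %d %d", seq_len(nb), config$bonds[, 1],
                       config$bonds[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory as LAMMPS dump text
#'
#' One `ITEM: TIMESTEP` block per frame with `id type x y z` atom lines,
#' readable by OVITO and by LAMMPS post-processing tools.
#'
#' @param config an `md_config`
#' @param path output file
#' @param frames list of position matrices (defaults to the configuration's
#'   positions)
#' @param steps integer step labels, one per frame
#' @return invisibly, the path
#' @export
write_lammps_dump <- function(config, path, frames = NULL, steps = NULL) {
  stopifnot(inherits(config, "md_config"))
  if (is.null(frames)) frames <- list(config$positions)
  if (is.null(steps)) steps <- seq_along(frames) - 1L
  n <- nrow(config$positions)
  L <- config$box$L
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    writeLines(c("ITEM: TIMESTEP", as.character(steps[k]),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0.0 %g", L[1]), sprintf("0.0 %g", L[2]),
                 sprintf("0.0 %g", L[3]),
                 "ITEM: ATOMS id type x y z"), con)
    f <- frames[[k]]
    writeLines(sprintf("%d %d %.8f %.8f %.8f", seq_len(n), config$species,
                       f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Serialize an interaction table to run-config keys
#'
#' The table is defined by its build parameters, so provenance round-trips
#' through the key-value config format: `do.call(make_interaction_table,
#' interaction_table_config(tab))` reproduces the table.
#'
#' @param table an [make_interaction_table()] result
#' @return named list of the build parameters
#' @export
interaction_table_config <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  list(variant = table$variant, eps_Ps = table$eps_Ps,
       sigma_c = unname(table$diameters["c"]),
       sigma_P = unname(table$diameters["P"]),
       sigma_s = unname(table$diameters["s"]), kss = table$kss)
}

parse_config_value <- function(v) {
  v <- trimws(v)
  if (grepl("^\\[", v)) {
    inner <- sub("^\\[", "", sub("\\]$", "", v))
    if (trimws(inner) == "") return(numeric())
    parts <- trimws(strsplit(inner, ",")[[1]])
    return(unlist(lapply(parts, parse_config_value)))
  }
  if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
  if (v %in% c("true", "false")) return(v == "true")
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

#' Read / write a run configuration file
#'
#' Flat `key = value` files (a TOML-style dialect: numbers, quoted strings,
#' `true`/`false`, and `[a, b, c]` arrays; `#` comments).  One file
#' describes one isotherm scan; [run_isotherm()] documents the keys.
#' Round-trips losslessly through [write_run_config()].
#'
#' @param path file path
#' @return named list
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line (no '='): ", ln, call. = FALSE)
    key <- trimws(substr(ln, 1, eq - 1))
    out[[key]] <- parse_config_value(substr(ln, eq + 1, nchar(ln)))
  }
  out
}

format_config_value <- function(v) {
  if (is.character(v)) {
    if (length(v) > 1) sprintf("[%s]", paste(sprintf('"%s"', v), collapse = ", "))
    else sprintf('"%s"', v)
  } else if (is.logical(v)) {
    tolower(as.character(v))
  } else if (length(v) > 1) {
    sprintf("[%s]", paste(format(v, digits = 15), collapse = ", "))
  } else {
    format(v, digits = 15)
  }
}

#' @rdname read_run_config
#' @param config named list of scalar / vector values
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, format_config_value(config[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

RUN_CONFIG_DEFAULTS <- list(
  geometry = "sphere", variant = "M1", sigma_c = 4, f = 20, M = 10,
  eps_Ps = 1.5, L = 30, Lz = 40, rho_gr = 0.398, rho0 = 0.01,
  seeds = c(1, 2, 3), equilibration_steps = 1e5, production_steps = 1e5,
  sample_interval = 500, dt = 0.002, T_star = 1, tdamp = 0.1,
  bin_width = 0.05)

validate_run_config <- function(config, quiet = FALSE) {
  required <- c("geometry", "variant", "f", "M", "rho0", "seeds")
  for (k in setdiff(names(RUN_CONFIG_DEFAULTS), names(config))) {
    if (k %in% required)
      stop("missing required config field: '", k, "'", call. = FALSE)
    config[[k]] <- RUN_CONFIG_DEFAULTS[[k]]
    if (!quiet)
      message("config: defaulting ", k, " = ",
              format_config_value(RUN_CONFIG_DEFAULTS[[k]]))
  }
  if (any(config$rho0 < 0 | config$rho0 > 0.3))
    warning("rho0 outside the replication range [0.0001, 0.3]", call. = FALSE)
  if (!all(config$M %in% c(5, 10, 15, 20, 30)))
    warning("M outside the replication set {5, 10, 15, 20, 30}", call. = FALSE)
  if (!all(config$f %in% c(0, 5, 10, 20, 30)))
    warning("f outside the replication set {5, 10, 20, 30}", call. = FALSE)
  config
}

# build, run, and measure one state point; returns a one-row data.frame
run_state_point <- function(config, rho0, seed, method = "cell") {
  sphere <- config$geometry == "sphere"
  cfg <- if (sphere)
    build_hairy_particle(sigma_c = config$sigma_c, f = config$f, M = config$M,
                         variant = config$variant, L = config$L,
                         eps_Ps = config$eps_Ps, seed = seed,
                         T_star = config$T_star)
  else
    build_flat_brush(f = config$f, M = config$M, rho_gr = config$rho_gr,
                     Lz = config$Lz, variant = config$variant,
                     eps_Ps = config$eps_Ps, seed = seed,
                     T_star = config$T_star)
  cfg <- insert_fluid(cfg, rho0, seed = seed + 1000L, T_star = config$T_star)
  proto <- md_protocol(equilibration_steps = config$equilibration_steps,
                       production_steps = config$production_steps,
                       sample_interval = config$sample_interval,
                       dt = config$dt, T_star = config$T_star,
                       tdamp = config$tdamp)
  traj <- run_protocol(cfg, proto, method = method)
  seg <- radial_or_planar_profile(traj, "s", config$bin_width)
  H <- if (sphere) corona_thickness_spherical(seg) else brush_thickness_flat(seg)
  has_fluid <- (cfg$spec$N_P %||% 0) > 0
  if (has_fluid) {
    flu <- radial_or_planar_profile(traj, "P", config$bin_width)
    brush_reach <- if (sphere) config$sigma_c / 2 + config$M else config$M
    # plateau window past the reach of fully stretched chains (the naive
    # "outer 20%" can overlap the corona for long chains in modest boxes)
    window <- if (sphere) {
      Rp <- cfg$box$L[1] / 2
      c(min(brush_reach + 1.5, Rp - 1), Rp)
    } else {
      c(min(brush_reach + 2, 0.85 * cfg$box$L[3]), 0.95 * cfg$box$L[3])
    }
    rho_b <- suppressWarnings(estimate_bulk_density(flu, window = window,
                                                    brush_extent = brush_reach))
    rho0_virtual <- if (sphere)
      virtual_loading_density(cfg$spec$N_P, prod(cfg$box$L), v_prime(cfg), rho_b)
    else rho0
    Gamma_mb <- excess_adsorption_mass_balance(v_prime(cfg), rho0_virtual, rho_b)
    if (sphere) {
      Gamma_int <- excess_adsorption_spherical(flu, rho_b)
      Gamma_star <- normalize_adsorption(Gamma_int, "sphere",
                                         sigma_c = config$sigma_c)
      Gamma_mb_star <- normalize_adsorption(Gamma_mb, "sphere",
                                            sigma_c = config$sigma_c)
    } else {
      area <- prod(cfg$box$L[1:2])
      Gamma_star <- excess_adsorption_flat(flu, rho_b)  # Eq. already per area
      Gamma_int <- Gamma_star * area
      Gamma_mb_star <- Gamma_mb / area
    }
  } else {
    rho_b <- 0; Gamma_int <- 0; Gamma_mb <- 0; Gamma_star <- 0; Gamma_mb_star <- 0
  }
  data.frame(rho0 = rho0, seed = seed, rho_b = as.numeric(rho_b),
             Gamma = Gamma_int, Gamma_mass_balance = Gamma_mb,
             Gamma_star = Gamma_star, Gamma_mass_balance_star = Gamma_mb_star,
             H = H, H_star = relative_thickness(H, config$M),
             mean_Tstar = if (nrow(traj$prod_series))
               mean(traj$prod_series$Tstar) else NA_real_,
             converged = isTRUE(traj$converged))
}

radial_or_planar_profile <- function(traj, species, bin_width) {
  if (traj$config$box$geometry == "cubic")
    radial_profile(traj, species, bin_width)
  else planar_profile(traj, species, bin_width)
}

#' Run an excess-adsorption isotherm scan
#'
#' For every loading density in `config$rho0` and every replicate seed:
#' build the system, insert the fluid, run the anneal/equilibrate/produce
#' protocol, and measure the bulk density, the excess adsorption by both the
#' profile and the mass-balance route, and the layer thickness.  Failures at
#' individual state points are recorded and the scan continues.  The same
#' configuration and seeds always reproduce the same table.
#'
#' Config keys (see `hairyMD:::RUN_CONFIG_DEFAULTS` for defaults):
#' `geometry` ("sphere"/"flat"), `variant`, `sigma_c`, `f`, `M`, `eps_Ps`,
#' `L` (sphere) or `Lz` + `rho_gr` (flat), `rho0` (vector), `seeds`
#' (vector), `equilibration_steps`, `production_steps`, `sample_interval`,
#' `dt`, `T_star`, `tdamp`, `bin_width`.
#'
#' @param config named list (e.g. from [read_run_config()])
#' @param method force algorithm
#' @param quiet suppress per-default messages
#' @return object of class `isotherm_result`: `points` (one row per run),
#'   `isotherm` (per-rho0 means with SEMs), `errors`, and the fully
#'   defaulted `config` for provenance
#' @export
run_isotherm <- function(config, method = "cell", quiet = FALSE) {
  config <- validate_run_config(config, quiet = quiet)
  points <- list()
  errors <- list()
  for (rho0 in config$rho0) {
    for (seed in config$seeds) {
      res <- tryCatch(run_state_point(config, rho0, as.integer(seed), method),
                      error = function(e)
                        structure(conditionMessage(e), class = "sp_error"))
      if (inherits(res, "sp_error")) {
        errors[[length(errors) + 1]] <-
          list(rho0 = rho0, seed = seed, message = unclass(res))
        if (!quiet) message(sprintf("state point rho0=%g seed=%d failed: %s",
                                    rho0, seed, res))
      } else {
        points[[length(points) + 1]] <- res
      }
    }
  }
  points <- if (length(points)) do.call(rbind, points) else data.frame()
  isotherm <- if (nrow(points)) {
    agg <- lapply(split(points, points$rho0), function(d) {
      sem <- function(x) if (nrow(d) > 1) sd(x) / sqrt(length(x)) else 0
      data.frame(rho0 = d$rho0[1], n = nrow(d),
                 rho_b = mean(d$rho_b), rho_b_sem = sem(d$rho_b),
                 Gamma_star = mean(d$Gamma_star),
                 Gamma_star_sem = sem(d$Gamma_star),
                 Gamma = mean(d$Gamma), Gamma_sem = sem(d$Gamma),
                 Gamma_mass_balance = mean(d$Gamma_mass_balance),
                 H_star = mean(d$H_star), H_star_sem = sem(d$H_star))
    })
    out <- do.call(rbind, agg)
    out[order(out$rho0), , drop = FALSE]
  } else data.frame()
  structure(list(points = points, isotherm = isotherm, errors = errors,
                 config = config),
            class = "isotherm_result")
}

#' @export
print.isotherm_result <- function(x, ...) {
  cat("isotherm scan:", nrow(x$points), "state points,",
      length(x$errors), "failures\n")
  if (nrow(x$isotherm)) print(x$isotherm, row.names = FALSE)
  invisible(x)
}

#' Write isotherm results with provenance
#'
#' JSON record carrying the full (defaulted) configuration, the seeds, the
#' package version, and the per-point and aggregated tables, so a result
#' file is self-describing and reproducible.
#'
#' @param result an `isotherm_result`
#' @param path output file
#' @return invisibly, the path
#' @export
write_results_json <- function(result, path) {
  stopifnot(inherits(result, "isotherm_result"))
  payload <- list(
    package = "hairyMD",
    version = as.character(packageVersion("hairyMD")),
    config = result$config,
    points = result$points,
    isotherm = result$isotherm,
    errors = result$errors)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write an isotherm table as CSV with header metadata
#'
#' @param result an `isotherm_result`
#' @param path output file
#' @return invisibly, the path
#' @export
write_isotherm_csv <- function(result, path) {
  stopifnot(inherits(result, "isotherm_result"))
  cfg <- result$config
  hdr <- sprintf("# %s = %s", names(cfg),
                 vapply(cfg, format_config_value, character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(result$isotherm, con, row.names = FALSE)
  invisible(path)
}
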