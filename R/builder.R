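#' Grafting density of a tethered layer
#'
#' \eqn{\rho_{gr} = f/A} with \eqn{A = \pi\sigma_c^2} for a spherical core
#' and \eqn{A = L_x L_y} for a flat substrate.
#'
#' @param f number of tethered chains
#' @param geometry `"sphere"` or `"flat"`
#' @param sigma_c core diameter (sphere)
#' @param area substrate area (flat)
#' @return chains per unit area
#' @examples
#' grafting_density(20, "sphere", sigma_c = 4)  # 0.398
#' grafting_density(5,  "sphere", sigma_c = 2)  # same coverage
#' @export
grafting_density <- function(f, geometry = c("sphere", "flat"),
                             sigma_c = NULL, area = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(f >= 0)
  A <- if (geometry == "sphere") {
    if (is.null(sigma_c)) stop("sigma_c required for spherical geometry", call. = FALSE)
    pi * sigma_c^2
  } else {
    if (is.null(area)) stop("area required for flat geometry", call. = FALSE)
    area
  }
  if (A <= 0) stop("zero or negative substrate area", call. = FALSE)
  f / A
}

random_unit_vectors <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Random anchor layout on a spherical core
#'
#' Draws `f` tethering directions uniformly on the sphere (normalised
#' Gaussian vectors) by rejection, so that anchor beads placed at radius
#' \eqn{\sigma_{cs} = (\sigma_c + \sigma_s)/2} are pairwise at least
#' `min_separation` apart.  The layout is deterministic for a given seed.
#'
#' @param f number of chains (>= 1)
#' @param sigma_c core diameter
#' @param min_separation minimum anchor-anchor distance at radius sigma_cs
#' @param seed integer seed, or NULL to use the current RNG stream
#' @param sigma_s segment diameter
#' @param max_tries rejection budget per anchor
#' @return object of class `grafting_layout`: unit `directions` (f x 3),
#'   `sigma_cs`, and `grafting_density`
#' @export
place_anchors <- function(f, sigma_c, min_separation = 0.8, seed = NULL,
                          sigma_s = 1, max_tries = 20000) {
  stopifnot(f >= 1, sigma_c > 0, min_separation >= 0)
  sigma_cs <- (sigma_c + sigma_s) / 2
  dirs <- with_seed(seed, {
    out <- matrix(NA_real_, f, 3)
    placed <- 0L
    tries <- 0L
    while (placed < f) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("anchor packing failed: cannot place ", f, " anchors with ",
             "min_separation = ", min_separation, " on a sphere of radius ",
             sigma_cs, call. = FALSE)
      cand <- random_unit_vectors(1)
      if (placed > 0L) {
        d <- sqrt(colSums((t(out[seq_len(placed), , drop = FALSE]) - as.vector(cand))^2)) * sigma_cs
        if (any(d < min_separation)) next
      }
      placed <- placed + 1L
      out[placed, ] <- cand
    }
    out
  })
  structure(list(directions = dirs, sigma_cs = sigma_cs, f = f,
                 grafting_density = grafting_density(f, "sphere", sigma_c = sigma_c)),
            class = "grafting_layout")
}

# propose a growth direction biased outward along `u`
biased_direction <- function(u, bias) {
  v <- bias * u + rnorm(3)
  v / sqrt(sum(v^2))
}

#' Grow one tethered chain
#'
#' Flexible mode: outward-biased self-avoiding random growth with fixed bond
#' length \eqn{\sigma_s}, every bead outside the core (radius
#' \eqn{\sigma_{cs}} from its center) and no closer than
#' `0.9 * min_separation_scale` bond lengths to previously placed beads.
#' The growth algorithm only provides a sane, overlap-free starting
#' structure; equilibration erases its bias.  Rigid mode: `M` collinear
#' beads along the anchor direction at radial distances
#' \eqn{\sigma_{cs} + k\sigma_s}, `k = 0..M-1`.
#'
#' @param anchor_dir unit 3-vector from the core center to the anchor
#' @param M number of beads in the chain (>= 1)
#' @param mode `"flexible"` or `"rigid"`
#' @param sigma_c core diameter
#' @param center core center (3-vector)
#' @param existing optional matrix of already-placed bead positions to avoid
#' @param sigma_s segment diameter
#' @param bias outward bias strength of the growth walk
#' @param max_tries proposals per bead before restarting the chain
#' @param max_restarts chain rebuild budget
#' @return M x 3 matrix of bead positions; row 1 is the anchor bead
#' @export
grow_chain <- function(anchor_dir, M, mode = c("flexible", "rigid"),
                       sigma_c, center = c(0, 0, 0), existing = NULL,
                       sigma_s = 1, bias = 1.5, max_tries = 60, max_restarts = 50) {
  mode <- match.arg(mode)
  stopifnot(M >= 1, sigma_c > 0)
  sigma_cs <- (sigma_c + sigma_s) / 2
  anchor <- center + sigma_cs * anchor_dir
  if (mode == "rigid") {
    radii <- sigma_cs + (seq_len(M) - 1) * sigma_s
    return(sweep(outer(radii, anchor_dir), 2, center, "+"))
  }
  # progressively relax the pair criterion at high grafting density; the
  # builder's push-off restores 0.9 sigma afterwards
  for (min_sep in c(0.9, 0.85, 0.8, 0.75, 0.7) * sigma_s) {
    for (restart in seq_len(max_restarts)) {
      pos <- matrix(NA_real_, M, 3)
      pos[1, ] <- anchor
      ok <- TRUE
      if (M > 1) {
        for (k in 2:M) {
          placed <- FALSE
          for (t in seq_len(max_tries)) {
            u <- (pos[k - 1, ] - center) / sqrt(sum((pos[k - 1, ] - center)^2))
            cand <- pos[k - 1, ] + sigma_s * biased_direction(u, bias)
            if (sqrt(sum((cand - center)^2)) < sigma_cs) next
            prev <- pos[seq_len(k - 2), , drop = FALSE]
            if (nrow(prev) > 0 &&
                min(sqrt(colSums((t(prev) - cand)^2))) < min_sep) next
            if (!is.null(existing) && nrow(existing) > 0 &&
                min(sqrt(colSums((t(existing) - cand)^2))) < min_sep) next
            pos[k, ] <- cand
            placed <- TRUE
            break
          }
          if (!placed) { ok <- FALSE; break }
        }
      }
      if (ok) return(pos)
    }
  }
  stop("chain growth dead-end: rebuild budget exhausted", call. = FALSE)
}

# upward-biased self-avoiding growth above a hard wall at z = 0; distances
# are minimum-image in x, y (period Lxy) so dense brushes in small periodic
# footprints start overlap-free
grow_chain_upward <- function(base, M, existing = NULL, sigma_s = 1,
                              Lxy = NULL, bias = 1.5, max_tries = 60,
                              max_restarts = 50) {
  too_close <- function(others, cand, min_sep) {
    if (is.null(others) || nrow(others) == 0) return(FALSE)
    d <- sweep(others, 2, cand)
    if (!is.null(Lxy)) {
      d[, 1] <- d[, 1] - Lxy * round(d[, 1] / Lxy)
      d[, 2] <- d[, 2] - Lxy * round(d[, 2] / Lxy)
    }
    min(rowSums(d^2)) < min_sep^2
  }
  # at high grafting density a hard 0.9 sigma criterion can be ungrowable;
  # progressively relax it (the builder's push-off restores 0.9 afterwards)
  for (min_sep in c(0.9, 0.85, 0.8, 0.75, 0.7) * sigma_s) {
    for (restart in seq_len(max_restarts)) {
      pos <- matrix(NA_real_, M, 3)
      pos[1, ] <- base
      ok <- TRUE
      if (M > 1) {
        for (k in 2:M) {
          placed <- FALSE
          for (t in seq_len(max_tries)) {
            cand <- pos[k - 1, ] + sigma_s * biased_direction(c(0, 0, 1), bias)
            if (cand[3] < sigma_s / 2) next
            if (too_close(pos[seq_len(k - 2), , drop = FALSE], cand, min_sep)) next
            if (too_close(existing, cand, min_sep)) next
            pos[k, ] <- cand
            placed <- TRUE
            break
          }
          if (!placed) { ok <- FALSE; break }
        }
      }
      if (ok) return(pos)
    }
  }
  stop("chain growth dead-end: rebuild budget exhausted", call. = FALSE)
}

# capped-displacement steepest descent until every pair with at least one
# mobile bead is separated by >= target_gap * sigma_ij (overlap push-off
# after dense-brush growth; a no-op on clean configurations)
push_off <- function(config, target_gap = 0.9, max_move = 0.02,
                     max_iter = 600) {
  n <- nrow(config$positions)
  mob <- which(config$mobile)
  if (n < 2 || length(mob) == 0) return(config)
  gap_ok <- function() {
    pos <- config$positions
    s <- config$table$sigma_ij
    for (i in seq_len(n - 1)) {
      js <- (i + 1):n
      if (!config$mobile[i]) js <- js[config$mobile[js]]
      if (length(js) == 0) next
      d <- sweep(pos[js, , drop = FALSE], 2, pos[i, ])
      for (k in 1:3) if (config$box$periodic[k])
        d[, k] <- d[, k] - config$box$L[k] * round(d[, k] / config$box$L[k])
      sij <- s[config$species[i], config$species[js]]
      if (any(rowSums(d^2) < (target_gap * sij)^2)) return(FALSE)
    }
    TRUE
  }
  for (it in seq_len(max_iter)) {
    if ((it - 1) %% 20 == 0 && gap_ok()) return(config)
    f <- compute_forces(config)$forces[mob, , drop = FALSE]
    norm <- sqrt(rowSums(f^2))
    disp <- pmin(max_move, 1e-3 * norm)
    scale <- ifelse(norm > 0, disp / norm, 0)
    config$positions[mob, ] <- config$positions[mob, ] + f * scale
    for (k in 1:3) if (config$box$periodic[k])
      config$positions[, k] <- config$positions[, k] %% config$box$L[k]
    if (isTRUE(config$box$walls)) {
      r <- unname(config$table$diameters[config$species] / 2)
      z <- config$positions[, 3]
      bad <- config$mobile & z < r
      config$positions[bad, 3] <- r[bad]
      bad <- config$mobile & z > config$box$L[3] - r
      config$positions[bad, 3] <- (config$box$L[3] - r)[bad]
    }
  }
  warning("push-off did not fully restore the 0.9 sigma pair criterion",
          call. = FALSE)
  config
}

new_md_config <- function(positions, velocities, species, mobile, bonds, box,
                          table, spec, core_idx = integer(), anchor_idx = integer()) {
  structure(list(positions = positions, velocities = velocities,
                 species = species, mobile = mobile, bonds = bonds, box = box,
                 table = table, spec = spec, core_idx = core_idx,
                 anchor_idx = anchor_idx),
            class = "md_config")
}

#' @export
print.md_config <- function(x, ...) {
  n <- nrow(x$positions)
  cnt <- table(factor(names(SPECIES)[x$species], levels = names(SPECIES)))
  cat("md_config:", n, "beads (",
      paste(names(cnt), cnt, sep = "=", collapse = ", "), "),",
      nrow(x$bonds), "bonds\n")
  cat("box:", x$box$geometry, paste(signif(x$box$L, 4), collapse = " x "), "\n")
  if (!is.null(x$spec$variant))
    cat("model:", x$spec$variant,
        sprintf("sigma_c=%g f=%g M=%g eps_Ps=%g\n",
                x$spec$sigma_c %||% NA, x$spec$f %||% NA,
                x$spec$M %||% NA, x$spec$eps_Ps %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

maxwell_velocities <- function(n, T_star = 1, mass = 1) {
  matrix(rnorm(3 * n, sd = sqrt(T_star / mass)), ncol = 3)
}

cubic_box <- function(L) {
  list(geometry = "cubic", L = c(L, L, L), periodic = c(TRUE, TRUE, TRUE),
       walls = FALSE)
}

slab_box <- function(Lx, Ly, Lz) {
  list(geometry = "slab", L = c(Lx, Ly, Lz), periodic = c(TRUE, TRUE, FALSE),
       walls = TRUE)
}

#' Build a spherical hairy particle
#'
#' Places one immobile core bead at the center of a cubic periodic box,
#' scatters `f` tethering points at radius \eqn{\sigma_{cs}} (frozen, they
#' are the first beads of the chains) and grows the chains: self-avoiding
#' flexible walks for models M1/M1a, rigid radial rods (all beads frozen)
#' for M2/M2a.  Consecutive beads within a chain are bonded
#' (\eqn{f\,(M-1)} bonds; anchors bond to their chain, not to the core).
#' Mobile beads receive Maxwell-Boltzmann velocities at `T_star`.
#'
#' @param sigma_c core diameter (the paper studies 2 and 4)
#' @param f number of chains
#' @param M beads per chain
#' @param variant model variant (`"M1"`, `"M1a"`, `"M2"`, `"M2a"`)
#' @param L cubic box edge; must satisfy
#'   \eqn{\sigma_c/2 + M\sigma_s + r_{cut}^{max} < L/2} so the box can
#'   accommodate fully stretched ligands plus an interaction shell
#' @param eps_Ps particle-segment well depth
#' @param seed integer seed for the anchor layout, chain growth and velocities
#' @param T_star reduced temperature for initial velocities
#' @param min_separation anchor spacing passed to [place_anchors()]
#' @param check_box set FALSE to permit deliberately undersized boxes
#' @return an `md_config`
#' @examples
#' cfg <- build_hairy_particle(sigma_c = 4, f = 5, M = 5, L = 30, seed = 1)
#' nrow(cfg$positions)  # 1 + f*M
#' @export
build_hairy_particle <- function(sigma_c = 4, f = 20, M = 10, variant = "M1",
                                 L = 57, eps_Ps = 1.5, seed = NULL, T_star = 1,
                                 min_separation = 0.8, check_box = TRUE) {
  table <- make_interaction_table(variant, eps_Ps = eps_Ps, sigma_c = sigma_c)
  sigma_s <- unname(table$diameters["s"])
  # relevant interaction shell: the core-core cutoff cannot occur with a
  # single core
  rcut_max <- max(table$rcut_ij[!(row(table$rcut_ij) == 1 & col(table$rcut_ij) == 1)])
  reach <- sigma_c / 2 + M * sigma_s + rcut_max
  if (check_box && reach >= L / 2)
    stop(sprintf(paste0("box too small: sigma_c/2 + M*sigma + rcut_max = %.2f ",
                        ">= L/2 = %.2f; enlarge L or set check_box = FALSE"),
                 reach, L / 2), call. = FALSE)
  with_seed(seed, {
    center <- rep(L / 2, 3)
    layout <- place_anchors(f, sigma_c, min_separation, seed = NULL,
                            sigma_s = sigma_s)
    mode <- if (table$rigid_ligands) "rigid" else "flexible"
    n <- 1L + f * M
    pos <- matrix(NA_real_, n, 3)
    pos[1, ] <- center
    placed <- pos[1, , drop = FALSE]
    for (ch in seq_len(f)) {
      chain <- grow_chain(layout$directions[ch, ], M, mode = mode,
                          sigma_c = sigma_c, center = center,
                          existing = placed, sigma_s = sigma_s)
      rows <- 1L + (ch - 1L) * M + seq_len(M)
      pos[rows, ] <- chain
      placed <- rbind(placed, chain)
    }
    species <- c(SPECIES[["c"]], rep(SPECIES[["s"]], f * M))
    anchor_idx <- 1L + (seq_len(f) - 1L) * M + 1L
    mobile <- rep(TRUE, n)
    mobile[1L] <- FALSE
    mobile[anchor_idx] <- FALSE
    if (table$rigid_ligands) mobile[1L + seq_len(f * M)] <- FALSE
    bonds <- do.call(rbind, lapply(seq_len(f), function(ch) {
      first <- 1L + (ch - 1L) * M + 1L
      if (M > 1) cbind(first + 0:(M - 2), first + 1:(M - 1)) else
        matrix(integer(), 0, 2)
    }))
    if (is.null(bonds)) bonds <- matrix(integer(), 0, 2)
    vel <- matrix(0, n, 3)
    vel[mobile, ] <- maxwell_velocities(sum(mobile), T_star)
    spec <- list(geometry = "sphere", sigma_c = sigma_c, f = f, M = M,
                 variant = variant, eps_Ps = eps_Ps, L = L,
                 rho_gr = layout$grafting_density, rho_0 = 0, seed = seed)
    cfg <- new_md_config(pos, vel, unname(species), mobile, bonds,
                         cubic_box(L), table, spec, core_idx = 1L,
                         anchor_idx = anchor_idx)
    if (!table$rigid_ligands) cfg <- push_off(cfg)
    cfg
  })
}

#' Build a planar brush on a hard wall
#'
#' Chains are end-tethered to the wall at `z = 0` at grafting density
#' `rho_gr`; the box is periodic in x and y with
#' \eqn{L_x = L_y = \sqrt{f/\rho_{gr}}}, and a bare hard wall sits at
#' `z = Lz`.  Anchor beads are frozen at \eqn{z = \sigma_s/2} (a
#' \eqn{\sigma}-bead in contact with the wall) at random (x, y) positions.
#' `f = 0` yields a valid bare-wall system.
#'
#' @param f number of chains (0 allowed)
#' @param M beads per chain
#' @param rho_gr target grafting density (chains per area)
#' @param Lz wall separation
#' @param variant,eps_Ps model variant and particle-segment well depth
#' @param seed integer seed
#' @param T_star reduced temperature for initial velocities
#' @param min_separation minimum anchor-anchor distance in the wall plane
#' @return an `md_config` with slab geometry
#' @export
build_flat_brush <- function(f = 20, M = 10, rho_gr = 0.398, Lz = 40,
                             variant = "M1", eps_Ps = 1.5, seed = NULL,
                             T_star = 1, min_separation = 0.8) {
  stopifnot(f >= 0, M >= 1, Lz > 0)
  table <- make_interaction_table(variant, eps_Ps = eps_Ps, sigma_c = 4)
  sigma_s <- unname(table$diameters["s"])
  if (f > 0) {
    A <- f / rho_gr
    Lx <- sqrt(A)
  } else {
    Lx <- max(8, 4 * max(table$rcut_ij))
  }
  if (Lx < 2 * max(table$rcut_ij["s", "s"], table$rcut_ij["P", "s"], table$rcut_ij["P", "P"]))
    stop("wall area too small: Lx < 2 rcut; reduce rho_gr or raise f", call. = FALSE)
  if (M * sigma_s + max(table$rcut_ij) >= Lz)
    stop("slab too thin: stretched chains plus interaction shell exceed Lz", call. = FALSE)
  with_seed(seed, {
    mode <- if (table$rigid_ligands) "rigid" else "flexible"
    n <- f * M
    pos <- matrix(NA_real_, max(n, 0), 3)
    anchors <- matrix(NA_real_, f, 2)
    placedxy <- 0L
    tries <- 0L
    while (placedxy < f) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop("anchor packing failed on the wall: lower rho_gr or min_separation",
             call. = FALSE)
      cand <- c(runif(1, 0, Lx), runif(1, 0, Lx))
      if (placedxy > 0L) {
        d <- anchors[seq_len(placedxy), , drop = FALSE]
        dx <- abs(d[, 1] - cand[1]); dx <- pmin(dx, Lx - dx)
        dy <- abs(d[, 2] - cand[2]); dy <- pmin(dy, Lx - dy)
        if (any(dx^2 + dy^2 < min_separation^2)) next
      }
      placedxy <- placedxy + 1L
      anchors[placedxy, ] <- cand
    }
    placed <- matrix(numeric(), 0, 3)
    for (ch in seq_len(f)) {
      base <- c(anchors[ch, ], sigma_s / 2)
      if (mode == "rigid") {
        chain <- cbind(matrix(rep(anchors[ch, ], each = M), M, 2),
                       sigma_s / 2 + (seq_len(M) - 1) * sigma_s)
      } else {
        chain <- grow_chain_upward(base, M, existing = placed,
                                   sigma_s = sigma_s, Lxy = Lx)
      }
      rows <- (ch - 1L) * M + seq_len(M)
      pos[rows, ] <- chain
      placed <- rbind(placed, chain)
    }
    if (f > 0) {
      pos[, 1] <- pos[, 1] %% Lx
      pos[, 2] <- pos[, 2] %% Lx
    }
    species <- rep(SPECIES[["s"]], n)
    anchor_idx <- if (f > 0) (seq_len(f) - 1L) * M + 1L else integer()
    mobile <- rep(TRUE, n)
    mobile[anchor_idx] <- FALSE
    if (table$rigid_ligands && n > 0) mobile[] <- FALSE
    bonds <- if (f > 0 && M > 1) {
      do.call(rbind, lapply(seq_len(f), function(ch) {
        first <- (ch - 1L) * M + 1L
        cbind(first + 0:(M - 2), first + 1:(M - 1))
      }))
    } else matrix(integer(), 0, 2)
    vel <- matrix(0, max(n, 0), 3)
    if (any(mobile)) vel[mobile, ] <- maxwell_velocities(sum(mobile), T_star)
    spec <- list(geometry = "flat", f = f, M = M, variant = variant,
                 eps_Ps = eps_Ps, rho_gr = if (f > 0) f / Lx^2 else 0,
                 Lx = Lx, Lz = Lz, rho_0 = 0, seed = seed)
    cfg <- new_md_config(pos, vel, species, mobile, bonds,
                         slab_box(Lx, Lx, Lz), table, spec,
                         anchor_idx = anchor_idx)
    if (f > 0 && !table$rigid_ligands) cfg <- push_off(cfg)
    cfg
  })
}

#' Insert fluid particles at a target density
#'
#' Randomly inserts \eqn{N_P = \mathrm{round}(\rho_0 V)} fluid beads (species
#' `P`) with no pair closer than \eqn{0.9\,\sigma_{ij}} to any existing bead,
#' and draws their velocities from the Maxwell-Boltzmann distribution at
#' `T_star`.  In slab geometry insertion is restricted to
#' \eqn{z \in [\sigma_P/2, L_z - \sigma_P/2]}.
#'
#' @param config an `md_config`
#' @param rho_0 target number density \eqn{N/V} (paper range 0.0001 to 0.3)
#' @param seed integer seed
#' @param T_star reduced temperature
#' @param min_frac overlap criterion as a fraction of \eqn{\sigma_{ij}}
#' @param max_tries total insertion attempts before giving up
#' @return the augmented `md_config`
#' @export
insert_fluid <- function(config, rho_0, seed = NULL, T_star = 1,
                         min_frac = 0.9, max_tries = NULL) {
  stopifnot(inherits(config, "md_config"), rho_0 >= 0)
  V <- prod(config$box$L)
  n_p <- round(rho_0 * V)
  if (n_p == 0) {
    config$spec$rho_0 <- rho_0
    return(config)
  }
  if (is.null(max_tries)) max_tries <- max(200L * n_p, 100000L)
  sigma_P <- unname(config$table$diameters["P"])
  zlim <- if (config$box$geometry == "slab")
    c(sigma_P / 2, config$box$L[3] - sigma_P / 2) else c(0, config$box$L[3])
  new_pos <- with_seed(seed, cpp_insert_fluid(
    config$positions, as.integer(config$species) - 1L, as.integer(n_p),
    SPECIES[["P"]] - 1L, config$table$sigma_ij, config$box$L,
    config$box$periodic, zlim[1], zlim[2], min_frac, as.integer(max_tries)))
  new_vel <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                       maxwell_velocities(n_p, T_star))
  config$positions <- rbind(config$positions, new_pos)
  config$velocities <- rbind(config$velocities, new_vel)
  config$species <- c(config$species, rep(SPECIES[["P"]], n_p))
  config$mobile <- c(config$mobile, rep(TRUE, n_p))
  config$spec$rho_0 <- rho_0
  config$spec$N_P <- n_p
  config
}
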