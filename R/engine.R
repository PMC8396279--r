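# largest cutoff among species pairs that can actually occur; with a single
# core bead the (large) core-core entry is irrelevant and would only waste
# cells
effective_cutoff <- function(config) {
  cnt <- tabulate(config$species, nbins = 3L)
  rc <- config$table$rcut_ij
  best <- 0
  for (a in 1:3) for (b in a:3) {
    present <- if (a == b) cnt[a] >= 2 else cnt[a] >= 1 && cnt[b] >= 1
    if (present) best <- max(best, rc[a, b])
  }
  if (best == 0) best <- max(rc)
  best
}

#' Forces and potential energy of a configuration
#'
#' Sums the shifted-force Lennard-Jones interactions over all non-bonded
#' pairs (minimum image in periodic directions; directly bonded beads are
#' excluded from the non-bonded sum) plus the harmonic bond terms.  The
#' default linked-cell algorithm is exact - it reproduces the brute-force
#' \eqn{O(N^2)} double loop to machine precision - and falls back to the
#' double loop automatically when the box is too small for three cells per
#' periodic direction.
#'
#' @param config an `md_config`
#' @param method `"cell"` (linked cells with automatic fallback) or
#'   `"brute"` (\eqn{O(N^2)} reference)
#' @return list with `forces` (N x 3; reaction forces on frozen beads are
#'   reported even though the integrator never applies them), `epot`, and
#'   `used_cell`
#' @export
compute_forces <- function(config, method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "md_config"))
  t <- config$table
  cpp_compute_forces(config$positions, as.integer(config$species) - 1L,
                     bonds_zero_based(config), t$kss,
                     unname(t$diameters["s"]), t$sigma_ij, t$eps_ij, t$rcut_ij,
                     config$box$L, config$box$periodic,
                     effective_cutoff(config), method)
}

bonds_zero_based <- function(config) {
  b <- config$bonds
  if (nrow(b) == 0) return(matrix(integer(), 0, 2))
  storage.mode(b) <- "integer"
  b - 1L
}

wall_vectors <- function(config) {
  radius <- unname(config$table$diameters[config$species] / 2)
  exempt <- rep(FALSE, nrow(config$positions))
  exempt[config$anchor_idx] <- TRUE
  list(radius = radius, exempt = exempt)
}

#' Integrate a configuration forward in time
#'
#' Velocity-Verlet dynamics, either microcanonical (`ensemble = "nve"`) or
#' canonical via a single Nose-Hoover thermostat (`"nvt"`).  The thermostat
#' couples to mobile beads only (\eqn{g = 3N_{mobile}} degrees of freedom,
#' thermostat mass \eqn{Q = g T^* \tau_{damp}^2}).  Frozen beads (core,
#' tethering beads, rigid ligands) never move.  In slab geometry the hard
#' walls reflect mobile beads specularly at one bead radius from either
#' wall.  The default `dt = 0.002` resolves the stiff
#' \eqn{k_{ss} = 1000} bond (vibration period \eqn{\approx 0.1\tau},
#' so about 50 steps per period).
#'
#' @param config an `md_config`
#' @param nsteps number of steps
#' @param dt timestep in \eqn{\tau}
#' @param ensemble `"nvt"` or `"nve"`
#' @param T_star thermostat target temperature
#' @param tdamp thermostat damping time in \eqn{\tau}
#' @param xi initial thermostat friction variable
#' @param esample record energies/temperature every this many steps (0 = never)
#' @param fsample record position frames every this many steps (0 = never)
#' @param method force algorithm, see [compute_forces()]
#' @return list with the updated `config`, the scalar `series`
#'   (step, epot, ekin, Tstar), `frames` (list of position matrices),
#'   `frame_step`, and the final thermostat variable `xi`
#' @export
run_md <- function(config, nsteps, dt = 0.002, ensemble = c("nvt", "nve"),
                   T_star = 1, tdamp = 0.1, xi = 0, esample = 100,
                   fsample = 0, method = c("cell", "brute")) {
  ensemble <- match.arg(ensemble)
  method <- match.arg(method)
  stopifnot(inherits(config, "md_config"), nsteps >= 0, dt > 0)
  if (nsteps == 0)
    return(list(config = config, series = data.frame(step = integer(),
                epot = numeric(), ekin = numeric(), Tstar = numeric()),
                frames = list(), frame_step = integer(), xi = xi))
  t <- config$table
  w <- wall_vectors(config)
  res <- cpp_run_md(config$positions, config$velocities,
                    as.integer(config$species) - 1L, config$mobile,
                    bonds_zero_based(config), t$kss,
                    unname(t$diameters["s"]), t$sigma_ij, t$eps_ij, t$rcut_ij,
                    config$box$L, config$box$periodic, effective_cutoff(config),
                    isTRUE(config$box$walls), w$radius, w$exempt,
                    dt, as.integer(nsteps), ensemble == "nvt", T_star, tdamp,
                    xi, as.integer(esample), as.integer(fsample), method)
  config$positions <- res$positions
  config$velocities <- res$velocities
  list(config = config, series = as.data.frame(res$series),
       frames = res$frames, frame_step = res$frame_step, xi = res$xi)
}

#' Instantaneous kinetic temperature
#'
#' \eqn{T^* = 2K / (3 N_{mobile})} with the kinetic energy summed over
#' mobile beads only.
#'
#' @param config an `md_config`
#' @return reduced temperature
#' @export
kinetic_temperature <- function(config) {
  v <- config$velocities[config$mobile, , drop = FALSE]
  if (nrow(v) == 0) return(0)
  sum(v^2) / (3 * nrow(v))
}

#' Simulation protocol
#'
#' Bundles the anneal / equilibrate / produce schedule.  The paper-scale
#' protocol (at least 1e8 equilibration and 1e7 production steps) is
#' expressible but the defaults are the desk-scale protocol used throughout
#' the tests: 1e5 + 1e5 steps.
#'
#' @param equilibration_steps steps of NVT equilibration at `T_star`
#' @param production_steps steps of NVT production
#' @param sample_interval save a frame every this many production steps
#'   (must divide `production_steps`)
#' @param dt timestep
#' @param T_star target temperature
#' @param tdamp thermostat damping time
#' @param esample energy sampling cadence (steps)
#' @param anneal optional list of `list(T_star =, steps =)` stages executed
#'   before equilibration (alternating heating/cooling)
#' @return object of class `md_protocol`
#' @export
md_protocol <- function(equilibration_steps = 1e5, production_steps = 1e5,
                        sample_interval = 500, dt = 0.002, T_star = 1,
                        tdamp = 0.1, esample = 100, anneal = NULL) {
  stopifnot(equilibration_steps >= 0, production_steps >= 0,
            sample_interval >= 1)
  if (production_steps > 0 && production_steps %% sample_interval != 0)
    stop("sample_interval must divide production_steps", call. = FALSE)
  structure(list(equilibration_steps = as.integer(equilibration_steps),
                 production_steps = as.integer(production_steps),
                 sample_interval = as.integer(sample_interval), dt = dt,
                 T_star = T_star, tdamp = tdamp, esample = as.integer(esample),
                 anneal = anneal),
            class = "md_protocol")
}

# sliding-window stationarity check on a total-energy series: the drift of
# the fitted linear trend across the window must be small both relative to
# the energy scale and to the residual fluctuation
energy_converged <- function(step, etot, window_frac = 0.5, rel_tol = 0.02) {
  n <- length(etot)
  if (n < 10) return(NA)
  idx <- seq.int(max(1L, floor(n * (1 - window_frac))), n)
  fit <- lm(etot[idx] ~ step[idx])
  drift <- abs(coef(fit)[2]) * (max(step[idx]) - min(step[idx]))
  scale <- max(abs(mean(etot[idx])), sd(etot[idx]) * sqrt(length(idx)), 1e-8)
  unname(drift < rel_tol * scale)
}

#' Run a full anneal / equilibrate / produce protocol
#'
#' Executes the optional anneal stages, the equilibration run, and the
#' production run on a configuration, collecting frames every
#' `sample_interval` production steps.  Equilibration is checked for
#' stationarity of the total energy with a sliding-window drift test; a
#' non-converged equilibration produces a warning and is flagged in the
#' result, never silently accepted.
#'
#' @param config an `md_config`
#' @param protocol an [md_protocol()]
#' @param method force algorithm
#' @return object of class `md_trajectory`: `frames`, `frame_step`,
#'   `equil_series`, `prod_series`, final `config`, `converged` flag and the
#'   originating `protocol`
#' @export
run_protocol <- function(config, protocol = md_protocol(),
                         method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "md_config"), inherits(protocol, "md_protocol"))
  xi <- 0
  for (stage in protocol$anneal %||% list()) {
    st <- run_md(config, stage$steps, dt = protocol$dt, ensemble = "nvt",
                 T_star = stage$T_star, tdamp = protocol$tdamp, xi = 0,
                 esample = 0, fsample = 0, method = method)
    config <- st$config
  }
  equil <- run_md(config, protocol$equilibration_steps, dt = protocol$dt,
                  ensemble = "nvt", T_star = protocol$T_star,
                  tdamp = protocol$tdamp, xi = xi,
                  esample = protocol$esample, fsample = 0, method = method)
  config <- equil$config
  conv <- with(equil$series,
               if (length(step)) energy_converged(step, epot + ekin) else NA)
  if (isFALSE(conv))
    warning("equilibration energy not stationary within budget; ",
            "result flagged converged = FALSE", call. = FALSE)
  prod <- run_md(config, protocol$production_steps, dt = protocol$dt,
                 ensemble = "nvt", T_star = protocol$T_star,
                 tdamp = protocol$tdamp, xi = equil$xi,
                 esample = protocol$esample,
                 fsample = protocol$sample_interval, method = method)
  structure(list(frames = prod$frames, frame_step = prod$frame_step,
                 equil_series = equil$series, prod_series = prod$series,
                 config = prod$config, converged = conv, protocol = protocol),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", length(x$frames), "frames,",
      nrow(x$equil_series), "equil samples,",
      nrow(x$prod_series), "production samples\n")
  if (nrow(x$prod_series))
    cat(sprintf("mean production T* = %.4f\n", mean(x$prod_series$Tstar)))
  cat("equilibration converged:", format(x$converged), "\n")
  invisible(x)
}
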