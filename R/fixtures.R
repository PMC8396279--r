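#' Analytic density profiles with closed-form observables
#'
#' A small library of prescribed density profiles used to validate the
#' adsorption and thickness estimators without running dynamics.  Each
#' profile carries a vectorised density function on a finite support and,
#' where tractable, closed forms for the excess adsorption
#' \eqn{\Gamma(\rho_b)} and the moment-ratio thickness \eqn{H}; the closed
#' forms are themselves validated against adaptive quadrature (see
#' [profile_gamma_quadrature()]).
#'
#' Forms: `"constant"` (`value`), `"shell"` (top-hat: `base` outside
#' `c(r1, r2)`, `value` inside), `"gaussian_bumps"` (`base` plus Gaussians
#' with `centers`, `amplitudes`, `widths`), `"decay_plateau"`
#' (\eqn{\rho = c\,(1 - e^{-(x - lo)/\lambda})}, parameters `plateau`,
#' `lambda`), and `"delta"` (all mass at radius `R0`; density is singular,
#' only sampling and H are defined).
#'
#' @param form one of the forms above
#' @param geometry `"spherical"` (density vs distance from center) or
#'   `"planar"` (density vs z)
#' @param support `c(lo, hi)` of the profile
#' @param Rc core radius entering the thickness moment ratio
#' @param ... form parameters, see Details
#' @return object of class `analytic_profile` with fields `fun`,
#'   `closed_gamma` (function of rho_b, or NULL), `closed_H` (number or
#'   NULL)
#' @export
analytic_profile <- function(form = c("constant", "shell", "gaussian_bumps",
                                      "decay_plateau", "delta"),
                             geometry = c("spherical", "planar"),
                             support = c(0, 10), Rc = 0, ...) {
  form <- match.arg(form)
  geometry <- match.arg(geometry)
  p <- list(...)
  lo <- support[1]; hi <- support[2]
  stopifnot(hi > lo, lo >= 0)
  sph <- geometry == "spherical"
  # moment integrals of x^k over [a, b]
  mom <- function(a, b, k) (b^(k + 1) - a^(k + 1)) / (k + 1)
  fun <- closed_gamma <- NULL
  closed_H <- NULL
  if (form == "constant") {
    v <- p$value
    stopifnot(v >= 0)
    fun <- function(x) ifelse(x >= lo & x <= hi, v, 0)
    closed_gamma <- if (sph) function(rho_b) 4 * pi * (v - rho_b) * mom(lo, hi, 2)
                    else function(rho_b) (v - rho_b) * (hi - lo)
    closed_H <- if (sph) 2 * (mom(lo, hi, 3) / mom(lo, hi, 2) - Rc)
                else 2 * mom(lo, hi, 1) / mom(lo, hi, 0)
  } else if (form == "shell") {
    b <- p$base %||% 0; v <- p$value; r1 <- p$r1; r2 <- p$r2
    stopifnot(r1 >= lo, r2 <= hi, r2 > r1, v >= 0, b >= 0)
    fun <- function(x) ifelse(x >= lo & x <= hi,
                              ifelse(x >= r1 & x <= r2, v, b), 0)
    closed_gamma <- if (sph)
      function(rho_b) 4 * pi * ((b - rho_b) * mom(lo, hi, 2) + (v - b) * mom(r1, r2, 2))
    else function(rho_b) (b - rho_b) * (hi - lo) + (v - b) * (r2 - r1)
    I1 <- b * mom(lo, hi, if (sph) 3 else 1) + (v - b) * mom(r1, r2, if (sph) 3 else 1)
    I0 <- b * mom(lo, hi, if (sph) 2 else 0) + (v - b) * mom(r1, r2, if (sph) 2 else 0)
    closed_H <- if (sph) 2 * (I1 / I0 - Rc) else 2 * I1 / I0
  } else if (form == "gaussian_bumps") {
    b <- p$base %||% 0; mu <- p$centers; a <- p$amplitudes; s <- p$widths
    stopifnot(length(mu) == length(a), length(s) %in% c(1, length(mu)))
    if (length(s) == 1) s <- rep(s, length(mu))
    fun <- function(x) {
      out <- ifelse(x >= lo & x <= hi, b, 0)
      for (k in seq_along(mu))
        out <- out + ifelse(x >= lo & x <= hi,
                            a[k] * exp(-(x - mu[k])^2 / (2 * s[k]^2)), 0)
      out
    }
  } else if (form == "decay_plateau") {
    cc <- p$plateau; lam <- p$lambda
    stopifnot(cc >= 0, lam > 0)
    fun <- function(x) ifelse(x >= lo & x <= hi, cc * (1 - exp(-(x - lo) / lam)), 0)
  } else { # delta
    R0 <- p$R0
    stopifnot(R0 >= lo, R0 <= hi)
    fun <- function(x) stop("delta profile has no pointwise density", call. = FALSE)
    closed_H <- if (sph) 2 * (R0 - Rc) else 2 * R0
  }
  structure(list(form = form, geometry = geometry, support = support, Rc = Rc,
                 params = p, fun = fun, closed_gamma = closed_gamma,
                 closed_H = closed_H),
            class = "analytic_profile")
}

measure_weight <- function(profile) {
  sph <- profile$geometry == "spherical"
  function(x) (if (sph) 4 * pi * x^2 else 1) * profile$fun(x)
}

#' Quadrature cross-checks for analytic profiles
#'
#' Evaluate \eqn{\Gamma(\rho_b)} and \eqn{H} of an [analytic_profile()] by
#' adaptive quadrature of the density function, independent of the closed
#' forms stored on the profile.
#'
#' @param profile an `analytic_profile` (not `"delta"`)
#' @param rho_b bulk density subtracted in the excess integral
#' @return a number
#' @export
profile_gamma_quadrature <- function(profile, rho_b) {
  stopifnot(inherits(profile, "analytic_profile"), profile$form != "delta")
  lo <- profile$support[1]; hi <- profile$support[2]
  sph <- profile$geometry == "spherical"
  f <- function(x) (if (sph) 4 * pi * x^2 else 1) * (profile$fun(x) - rho_b)
  integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = 1e-12,
            subdivisions = 2000L)$value
}

#' @rdname profile_gamma_quadrature
#' @export
profile_H_quadrature <- function(profile) {
  stopifnot(inherits(profile, "analytic_profile"), profile$form != "delta")
  lo <- profile$support[1]; hi <- profile$support[2]
  sph <- profile$geometry == "spherical"
  k <- if (sph) 2 else 0
  num <- integrate(function(x) x^(k + 1) * profile$fun(x), lo, hi,
                   rel.tol = 1e-12, subdivisions = 2000L)$value
  den <- integrate(function(x) x^k * profile$fun(x), lo, hi,
                   rel.tol = 1e-12, subdivisions = 2000L)$value
  if (sph) 2 * (num / den - profile$Rc) else 2 * num / den
}

#' Sample particle positions from a prescribed density profile
#'
#' Inverse-CDF sampling on the geometry-weighted measure
#' (\eqn{4\pi r^2 \rho(r)\,dr} spherical, \eqn{\rho(z)\,dz} planar): the CDF
#' is tabulated on a fine grid, inverted by monotone interpolation, and
#' uniform deviates are pushed through it, so tails are represented exactly
#' up to grid resolution.  Spherical samples get uniformly random
#' directions; planar samples get uniform (x, y) over `area_L`.
#'
#' @param profile an `analytic_profile`
#' @param N number of points (>= 1)
#' @param seed integer seed (NULL = current RNG stream)
#' @param center center of the spherical cloud (3-vector)
#' @param area_L `c(Lx, Ly)` for planar sampling
#' @param grid_n CDF grid resolution
#' @return N x 3 matrix of positions
#' @export
sample_positions_from_profile <- function(profile, N, seed = NULL,
                                          center = c(0, 0, 0),
                                          area_L = c(10, 10), grid_n = 8192L) {
  stopifnot(inherits(profile, "analytic_profile"), N >= 1)
  sph <- profile$geometry == "spherical"
  with_seed(seed, {
    if (profile$form == "delta") {
      x <- rep(profile$params$R0, N)
    } else {
      g <- seq(profile$support[1], profile$support[2], length.out = grid_n)
      w <- measure_weight(profile)(g)
      if (any(!is.finite(w)) || any(w < 0))
        stop("profile weight must be finite and non-negative", call. = FALSE)
      cdf <- cumsum((head(w, -1) + tail(w, -1)) / 2 * diff(g))
      cdf <- c(0, cdf)
      if (cdf[grid_n] <= 0) stop("non-normalizable profile: zero total weight",
                                 call. = FALSE)
      cdf <- cdf / cdf[grid_n]
      inv <- approxfun(cdf, g, ties = "ordered", rule = 2)
      x <- inv(runif(N))
    }
    if (sph) {
      dirs <- random_unit_vectors(N)
      sweep(dirs * x, 2, center, "+")
    } else {
      cbind(runif(N, 0, area_L[1]), runif(N, 0, area_L[2]), x)
    }
  })
}

#' Wrap raw positions into a minimal configuration
#'
#' Convenience for testing estimators on sampled point clouds: builds an
#' `md_config` holding the positions as a single species in the requested
#' box so that [radial_profile()] and friends can be applied.  For
#' `core = TRUE` a frozen core bead of diameter `sigma_c` is prepended at
#' the box center, which defines \eqn{R_c} for radial profiles.
#'
#' @param positions N x 3 matrix (spherical samples should be centered at
#'   the box center, `L/2`)
#' @param L box edge(s): length 1 (cubic) or 3 (slab when `slab = TRUE`)
#' @param species species tag of the points
#' @param core prepend a frozen core bead at the box center
#' @param sigma_c core diameter when `core = TRUE`
#' @param slab slab geometry (periodic x, y only)
#' @return an `md_config`
#' @export
fixture_config <- function(positions, L, species = "P", core = FALSE,
                           sigma_c = 4, slab = FALSE) {
  L3 <- if (length(L) == 1) rep(L, 3) else L
  box <- if (slab) slab_box(L3[1], L3[2], L3[3]) else cubic_box(L3[1])
  table <- make_interaction_table("M1", sigma_c = sigma_c)
  n <- nrow(positions)
  sp <- rep(species_code(species), n)
  mobile <- rep(TRUE, n)
  core_idx <- integer()
  if (core) {
    positions <- rbind(L3 / 2, positions)
    sp <- c(SPECIES[["c"]], sp)
    mobile <- c(FALSE, mobile)
    core_idx <- 1L
  }
  new_md_config(positions, matrix(0, nrow(positions), 3), sp, mobile,
                matrix(integer(), 0, 2), box, table,
                spec = list(geometry = if (slab) "flat" else "sphere"),
                core_idx = core_idx)
}

#' Small mechanical fixtures with precomputed oracles
#'
#' A named set of tiny configurations whose energies, forces or thickness
#' are known exactly, used as regression anchors for the force kernels and
#' estimators: a bonded dimer at rest length (zero force), a repulsive pair
#' beyond its cutoff, an attractive pair exactly at its cutoff, an
#' attractive pair inside the well with the closed-form energy/force, a
#' 50-bead random periodic cell (energy from the R closed-form pair sum),
#' and a rigid hedgehog particle whose discrete thickness is exact.
#'
#' @param seed seed for the random cell
#' @return named list; each entry has `config` and `oracle`
#' @export
make_mechanical_fixtures <- function(seed = 4242) {
  tab <- make_interaction_table("M1", eps_Ps = 1.5, sigma_c = 4)
  two_bead <- function(r, sp1, sp2, bonded = FALSE, L = 20) {
    pos <- rbind(c(L / 2 - r / 2, L / 2, L / 2), c(L / 2 + r / 2, L / 2, L / 2))
    new_md_config(pos, matrix(0, 2, 3), c(species_code(sp1), species_code(sp2)),
                  c(TRUE, TRUE),
                  if (bonded) matrix(c(1L, 2L), 1, 2) else matrix(integer(), 0, 2),
                  cubic_box(L), tab, spec = list(geometry = "sphere"))
  }
  fixtures <- list()
  fixtures$dimer_rest <- list(
    config = two_bead(1, "s", "s", bonded = TRUE),
    oracle = list(epot = 0, fmax = 0))
  fixtures$repulsive_pair_beyond_cutoff <- list(
    config = two_bead(1.2, "s", "s"),
    oracle = list(epot = 0, fmax = 0))
  fixtures$attractive_pair_at_cutoff <- list(
    config = two_bead(2.5, "P", "s"),
    oracle = list(epot = 0, fmax = 0))
  r_in <- 1.1
  pf <- pair_energy_force(r_in, pair_lookup(tab, "P", "s"))
  fixtures$attractive_pair_in_well <- list(
    config = two_bead(r_in, "P", "s"),
    oracle = list(epot = pf$energy, fmag = abs(pf$force)))
  # 50-bead random periodic cell, half segments half fluid, no bonds
  L <- 6
  cell <- with_seed(seed, {
    pts <- cpp_insert_fluid(matrix(numeric(), 0, 3), integer(), 50L,
                            SPECIES[["s"]] - 1L, tab$sigma_ij, rep(L, 3),
                            rep(TRUE, 3), 0, L, 0.9, 100000L)
    sp <- rep(c(SPECIES[["s"]], SPECIES[["P"]]), each = 25L)
    new_md_config(pts, matrix(0, 50, 3), sp, rep(TRUE, 50),
                  matrix(integer(), 0, 2), cubic_box(L), tab,
                  spec = list(geometry = "sphere"))
  })
  epot_oracle <- 0
  for (i in 1:49) for (j in (i + 1):50) {
    d <- cell$positions[i, ] - cell$positions[j, ]
    d <- d - L * round(d / L)
    r <- sqrt(sum(d^2))
    sp_i <- names(SPECIES)[cell$species[i]]
    sp_j <- names(SPECIES)[cell$species[j]]
    epot_oracle <- epot_oracle +
      pair_energy_force(r, pair_lookup(tab, sp_i, sp_j))$energy
  }
  fixtures$random_cell <- list(config = cell,
                               oracle = list(epot = epot_oracle))
  hedge <- build_hairy_particle(sigma_c = 4, f = 20, M = 10, variant = "M2",
                                L = 30, seed = seed)
  radii <- 2.5 + 0:9
  fixtures$hedgehog <- list(
    config = hedge,
    oracle = list(H = 2 * (mean(radii) - 2), H_star = 2 * (mean(radii) - 2) / 10))
  fixtures
}
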