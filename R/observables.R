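# resolve frames + config from an md_trajectory or an explicit pair
resolve_frames <- function(frames, config) {
  if (inherits(frames, "md_trajectory")) {
    list(frames = frames$frames, config = frames$config)
  } else {
    if (is.matrix(frames)) frames <- list(frames)
    if (is.null(config))
      stop("config required when frames are given as plain matrices", call. = FALSE)
    list(frames = frames, config = config)
  }
}

min_image_disp <- function(pos, center, box) {
  d <- sweep(pos, 2, center)
  for (k in 1:3) if (box$periodic[k]) {
    d[, k] <- d[, k] - box$L[k] * round(d[, k] / box$L[k])
  }
  d
}

# bin edges of width `bw` whose centers sit on integer multiples of `bw`
centered_edges <- function(lo, hi, bw) {
  k0 <- round(lo / bw)
  k1 <- ceiling(hi / bw)
  bw * (seq.int(k0, k1 + 1L) - 0.5)
}

#' Radial density profile around the core
#'
#' Count-in-shell / shell-volume number density of one species as a function
#' of the distance from the core center, averaged over frames.  Shell
#' volumes are the exact \eqn{\frac{4\pi}{3}(r_+^3 - r_-^3)}, so that
#' \eqn{\sum_k \rho_k V_k} equals the mean bead count between the first and
#' last edge by construction.  Bins cover the virtual adsorption sphere
#' \eqn{[R_c, R' = L/2]}; bin centers lie on integer multiples of
#' `bin_width`, so the frozen tethering beads of a \eqn{\sigma_c = 4} core
#' fall in the bin centered exactly at \eqn{r = 2.5}.
#'
#' @param frames an `md_trajectory`, a list of N x 3 position matrices, or a
#'   single matrix
#' @param species species tag `"s"` or `"P"` (or `"c"`)
#' @param bin_width bin width (default 0.05, fine enough to resolve the
#'   segment-layer peaks)
#' @param config the `md_config` the frames belong to (not needed for an
#'   `md_trajectory`)
#' @return object of class `radial_profile`: `r` (bin centers),
#'   `bin_edges`, `density`, `counts` (mean per frame), `species`,
#'   `frames_averaged`, `Rc`, `Rprime`
#' @export
radial_profile <- function(frames, species = "s", bin_width = 0.05,
                           config = NULL) {
  fr <- resolve_frames(frames, config)
  config <- fr$config
  frames <- fr$frames
  if (length(frames) < 1) stop("need at least one frame", call. = FALSE)
  stopifnot(bin_width > 0)
  sel <- config$species == species_code(species)
  if (!any(sel)) stop("no beads of species '", species, "'", call. = FALSE)
  Rc <- if (length(config$core_idx)) unname(config$table$diameters["c"]) / 2 else 0
  center <- if (length(config$core_idx))
    config$positions[config$core_idx, ] else config$box$L / 2
  Rprime <- min(config$box$L) / 2
  edges <- centered_edges(Rc, Rprime, bin_width)
  # clip to [0, R']: shells beyond the inscribed sphere are cut by the box
  edges <- pmin(pmax(edges, 0), Rprime)
  edges <- edges[!duplicated(edges)]
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  for (f in frames) {
    d <- min_image_disp(f[sel, , drop = FALSE], center, config$box)
    r <- sqrt(rowSums(d^2))
    idx <- findInterval(r, edges, left.open = FALSE)
    idx <- idx[idx >= 1 & idx <= nb]
    acc <- acc + tabulate(idx, nbins = nb)
  }
  counts <- acc / length(frames)
  vol <- 4 * pi / 3 * diff(edges^3)
  structure(list(r = (head(edges, -1) + tail(edges, -1)) / 2,
                 bin_edges = edges, density = counts / vol, counts = counts,
                 shell_volumes = vol, species = species,
                 frames_averaged = length(frames), Rc = Rc, Rprime = Rprime),
            class = "radial_profile")
}

#' Planar density profile above the grafted wall
#'
#' As [radial_profile()] but binned along z with slab volumes
#' \eqn{L_x L_y \Delta z}.  Bins cover \eqn{[0, L_z]} with centers on
#' multiples of `bin_width` (half bins at the walls).
#'
#' @inheritParams radial_profile
#' @return object of class `planar_profile`: `z`, `bin_edges`, `density`,
#'   `counts`, `species`, `frames_averaged`, `Lz`, `area`
#' @export
planar_profile <- function(frames, species = "s", bin_width = 0.05,
                           config = NULL) {
  fr <- resolve_frames(frames, config)
  config <- fr$config
  frames <- fr$frames
  if (length(frames) < 1) stop("need at least one frame", call. = FALSE)
  stopifnot(bin_width > 0)
  sel <- config$species == species_code(species)
  if (!any(sel)) stop("no beads of species '", species, "'", call. = FALSE)
  Lz <- config$box$L[3]
  area <- config$box$L[1] * config$box$L[2]
  edges <- centered_edges(0, Lz, bin_width)
  edges <- pmin(pmax(edges, 0), Lz)
  edges <- edges[!duplicated(edges)]
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  for (f in frames) {
    z <- f[sel, 3]
    idx <- findInterval(z, edges, left.open = FALSE, rightmost.closed = TRUE)
    idx <- idx[idx >= 1 & idx <= nb]
    acc <- acc + tabulate(idx, nbins = nb)
  }
  counts <- acc / length(frames)
  vol <- area * diff(edges)
  structure(list(z = (head(edges, -1) + tail(edges, -1)) / 2,
                 bin_edges = edges, density = counts / vol, counts = counts,
                 bin_volumes = vol, species = species,
                 frames_averaged = length(frames), Lz = Lz, area = area),
            class = "planar_profile")
}

profile_axis <- function(profile) {
  if (inherits(profile, "radial_profile")) profile$r else profile$z
}

#' Bulk density from the plateau of a fluid profile
#'
#' Mean density over a window far from the tethered layer, where the profile
#' has reached its constant bulk value \eqn{\rho_b}.  Defaults: the outer
#' 20 percent of \eqn{[R_c, R']} for radial profiles; \eqn{[0.5, 0.8] L_z}
#' (mid-cell, away from both walls) for planar profiles.  A linear slope
#' test over the window flags a non-plateau (attribute `plateau`); a window
#' reaching into the brush (`brush_extent`) warns but proceeds.
#'
#' @param profile a `radial_profile` or `planar_profile` of the fluid
#' @param window numeric `c(lo, hi)` in distance units, or NULL for default
#' @param brush_extent optional maximum brush reach (e.g. \eqn{R_c + M\sigma})
#'   used for the window sanity warning
#' @return the bulk density, with attributes `plateau` (logical) and `slope`
#' @export
estimate_bulk_density <- function(profile, window = NULL, brush_extent = NULL) {
  x <- profile_axis(profile)
  if (is.null(window)) {
    window <- if (inherits(profile, "radial_profile"))
      c(profile$Rc + 0.8 * (profile$Rprime - profile$Rc), profile$Rprime)
    else c(0.5, 0.8) * profile$Lz
  }
  if (!is.null(brush_extent) && window[1] <= brush_extent)
    warning("bulk-density window starts inside the possible brush extent",
            call. = FALSE)
  sel <- x >= window[1] & x <= window[2]
  if (!any(sel)) stop("bulk-density window outside profile support", call. = FALSE)
  vol <- if (inherits(profile, "radial_profile")) profile$shell_volumes else
    profile$bin_volumes
  rho_b <- sum(profile$counts[sel]) / sum(vol[sel])
  plateau <- TRUE
  slope <- 0
  if (sum(sel) >= 5) {
    fit <- lm(profile$density[sel] ~ x[sel])
    slope <- unname(coef(fit)[2])
    se <- suppressWarnings(summary(fit)$coefficients[2, 2])
    plateau <- is.na(se) || se == 0 || abs(slope) < 3 * se
    if (!plateau)
      warning("bulk window density has a statistically significant slope; ",
              "not a plateau", call. = FALSE)
  }
  structure(rho_b, plateau = plateau, slope = slope)
}

#' Excess adsorption around a spherical hairy particle (profile route)
#'
#' Shell-exact quadrature of
#' \eqn{\Gamma = 4\pi \int_{R_c}^{R'} r^2 (\rho(r) - \rho_b)\, dr}:
#' because bin densities are counts per shell volume, the sum
#' \eqn{\sum_k (\rho_k - \rho_b) V_k} carries no midpoint discretisation
#' bias.
#'
#' @param fluid_profile a `radial_profile` of species `P`
#' @param rho_b bulk density (see [estimate_bulk_density()])
#' @return excess number of fluid particles per hairy particle
#' @export
excess_adsorption_spherical <- function(fluid_profile, rho_b) {
  stopifnot(inherits(fluid_profile, "radial_profile"))
  if (rho_b < 0) stop("rho_b must be non-negative", call. = FALSE)
  sum((fluid_profile$density - rho_b) * fluid_profile$shell_volumes)
}

#' Excess adsorption on a flat brush (profile route)
#'
#' One-dimensional quadrature of
#' \eqn{\Gamma^* = \int_0^{L_z} (\rho(z) - \rho_b)\, dz}; the result is
#' already per unit wall area.
#'
#' @param fluid_profile a `planar_profile` of species `P`
#' @param rho_b bulk density
#' @return excess adsorption per unit area
#' @export
excess_adsorption_flat <- function(fluid_profile, rho_b) {
  stopifnot(inherits(fluid_profile, "planar_profile"))
  if (rho_b < 0) stop("rho_b must be non-negative", call. = FALSE)
  sum((fluid_profile$density - rho_b) * diff(fluid_profile$bin_edges))
}

#' Volume of the virtual adsorption system
#'
#' \eqn{V' = \pi L^3/6} (the sphere inscribed in the cubic cell) for a hairy
#' particle, \eqn{V' = V} (the whole cell) for the slab.
#'
#' @param config an `md_config`
#' @return volume
#' @export
v_prime <- function(config) {
  if (config$box$geometry == "cubic") pi * config$box$L[1]^3 / 6
  else prod(config$box$L)
}

#' Excess adsorption from mass balance
#'
#' The experimentalist's route \eqn{\Gamma = V'(\rho_0 - \rho_b)}: every
#' particle missing from the bulk at density \eqn{\rho_b}, relative to the
#' loaded amount \eqn{\rho_0}, is attributed to the adsorption system of
#' volume \eqn{V'}.  Cross-checks the profile route on every state point.
#'
#' @param V_prime virtual-system volume, see [v_prime()]
#' @param rho_0 loading density \eqn{N/V}
#' @param rho_b measured bulk density
#' @return excess number of particles
#' @export
excess_adsorption_mass_balance <- function(V_prime, rho_0, rho_b) {
  stopifnot(V_prime > 0)
  V_prime * (rho_0 - rho_b)
}

#' Loading density referred to the virtual adsorption system
#'
#' For the spherical geometry the virtual adsorption system is the inscribed
#' sphere \eqn{V' = \pi L^3/6}, while particles are loaded into the whole
#' cubic cell.  The cell corners outside the sphere hold bulk fluid at
#' \eqn{\rho_b}, so the loading density *of the virtual system* is
#' \deqn{\rho_0' = \frac{N - \rho_b\,(V - V')}{V'}.}
#' Feeding \eqn{\rho_0'} into [excess_adsorption_mass_balance()] makes the
#' mass-balance route agree identically with the profile-integral route
#' whenever everything outside the corona is at bulk density (for the slab,
#' \eqn{V' = V} and \eqn{\rho_0' = \rho_0}).
#'
#' @param N_total number of fluid particles in the whole cell
#' @param V_total cell volume
#' @param V_prime virtual-system volume
#' @param rho_b bulk density
#' @return the virtual-system loading density
#' @export
virtual_loading_density <- function(N_total, V_total, V_prime, rho_b) {
  stopifnot(V_prime > 0, V_total >= V_prime)
  (N_total - rho_b * (V_total - V_prime)) / V_prime
}

#' Normalise excess adsorption by substrate area
#'
#' \eqn{\Gamma^* = \Gamma / A} with \eqn{A = \pi\sigma_c^2} for the sphere;
#' the flat route is already per area and passes through unchanged.
#'
#' @param Gamma excess adsorption
#' @param geometry `"sphere"` or `"flat"`
#' @param sigma_c core diameter (sphere)
#' @return excess adsorption per unit area
#' @export
normalize_adsorption <- function(Gamma, geometry = c("sphere", "flat"),
                                 sigma_c = NULL) {
  geometry <- match.arg(geometry)
  if (geometry == "flat") return(Gamma)
  if (is.null(sigma_c)) stop("sigma_c required for spherical geometry", call. = FALSE)
  Gamma / (pi * sigma_c^2)
}

#' Corona thickness of a spherical brush
#'
#' Moment-ratio thickness
#' \deqn{H = 2\left(\frac{\int r^3 \rho_s(r)\,dr}{\int r^2 \rho_s(r)\,dr} - R_c\right).}
#' Because the profile density is counts per shell volume, the moment ratio
#' reduces to the count-weighted mean radius, so the estimator is free of
#' \eqn{r^2}-midpoint bias; passing raw radii gives the exact
#' \eqn{2(\langle r\rangle - R_c)}.
#'
#' @param segment_profile a `radial_profile` of the segments, or a numeric
#'   vector of segment radial distances
#' @param Rc core radius \eqn{\sigma_c/2}; taken from the profile if omitted
#' @return thickness H (length units)
#' @export
corona_thickness_spherical <- function(segment_profile, Rc = NULL) {
  if (inherits(segment_profile, "radial_profile")) {
    if (is.null(Rc)) Rc <- segment_profile$Rc
    w <- segment_profile$counts
    if (sum(w) <= 0) stop("empty segment profile", call. = FALSE)
    rbar <- sum(w * segment_profile$r) / sum(w)
  } else {
    r <- as.numeric(segment_profile)
    if (length(r) == 0) stop("no segment radii supplied", call. = FALSE)
    if (is.null(Rc)) stop("Rc required when passing raw radii", call. = FALSE)
    rbar <- mean(r)
  }
  2 * (rbar - Rc)
}

#' Brush thickness on a flat wall
#'
#' First-moment thickness
#' \eqn{H = 2 \int z\rho_s(z)\,dz / \int \rho_s(z)\,dz}, i.e. twice the
#' count-weighted mean height.
#'
#' @param segment_profile a `planar_profile` of the segments, or a numeric
#'   vector of segment heights z
#' @return thickness H
#' @export
brush_thickness_flat <- function(segment_profile) {
  if (inherits(segment_profile, "planar_profile")) {
    w <- segment_profile$counts
    if (sum(w) <= 0) stop("empty segment profile", call. = FALSE)
    2 * sum(w * segment_profile$z) / sum(w)
  } else {
    z <- as.numeric(segment_profile)
    if (length(z) == 0) stop("no segment heights supplied", call. = FALSE)
    2 * mean(z)
  }
}

#' Relative layer thickness
#'
#' \eqn{H^* = H/M}: the thickness in units of the fully stretched contour
#' proxy, the chain length in beads.
#'
#' @param H thickness
#' @param M beads per chain
#' @return dimensionless relative thickness
#' @export
relative_thickness <- function(H, M) {
  stopifnot(M > 0)
  H / M
}

running_mean <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  out <- x
  half <- (k - 1) %/% 2
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' Detect peaks in a density profile
#'
#' Local maxima of the (optionally smoothed) binned density, with a
#' topographic prominence filter: the prominence of a peak is its height
#' above the higher of the two bracketing valleys, walking outwards until a
#' taller bin is met.  Peaks are reported at bin centers, sorted by
#' position.
#'
#' @param profile a `radial_profile` or `planar_profile`
#' @param min_prominence minimum prominence (same units as the density);
#'   0 returns every local maximum
#' @param smooth odd window length of a centered running-mean smoother
#'   applied before detection (1 = no smoothing)
#' @return data frame with columns `position`, `height`, `prominence`
#'   (possibly zero rows)
#' @export
peak_positions <- function(profile, min_prominence = 0, smooth = 1) {
  x <- profile_axis(profile)
  y <- running_mean(profile$density, smooth)
  n <- length(y)
  if (n < 3) return(data.frame(position = numeric(), height = numeric(),
                               prominence = numeric()))
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_peak)
  prom <- vapply(idx, function(i) {
    h <- y[i]
    left <- h; j <- i
    while (j > 1) { j <- j - 1; left <- min(left, y[j]); if (y[j] > h) break }
    right <- h; j <- i
    while (j < n) { j <- j + 1; right <- min(right, y[j]); if (y[j] > h) break }
    h - max(left, right)
  }, numeric(1))
  keep <- prom >= min_prominence & prom > 0
  out <- data.frame(position = x[idx][keep], height = y[idx][keep],
                    prominence = prom[keep])
  out[order(out$position), , drop = FALSE]
}

# relative shape anisotropy of a point cloud from the gyration tensor
shape_anisotropy <- function(pos) {
  c0 <- colMeans(pos)
  d <- sweep(pos, 2, c0)
  S <- crossprod(d) / nrow(d)
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(lam)
  if (tr <= 0) return(0)
  1 - 3 * (lam[1] * lam[2] + lam[1] * lam[3] + lam[2] * lam[3]) / tr^2
}

#' Asymmetry metrics of the segment cloud
#'
#' Two frame-averaged scalars in \eqn{[0, 1]} quantifying the
#' adsorption-induced loss of spherical symmetry of the corona (core-shell
#' versus cone-like morphology): the offset of the segment-cloud centroid
#' from the core center, normalised by the maximum brush reach
#' \eqn{R_c + M\sigma}, and the relative shape anisotropy \eqn{\kappa^2} of
#' the segment gyration tensor (0 for an isotropic cloud, 1 for a rod).
#'
#' @param frames an `md_trajectory`, list of position matrices, or matrix
#' @param config the `md_config` (not needed for an `md_trajectory`)
#' @return list with `centroid_offset` and `anisotropy`
#' @export
asymmetry_metrics <- function(frames, config = NULL) {
  fr <- resolve_frames(frames, config)
  config <- fr$config
  frames <- fr$frames
  if (length(frames) < 1) stop("need at least one frame", call. = FALSE)
  sel <- config$species == SPECIES[["s"]]
  if (!any(sel)) stop("no segments in configuration", call. = FALSE)
  Rc <- if (length(config$core_idx)) unname(config$table$diameters["c"]) / 2 else 0
  center <- if (length(config$core_idx))
    config$positions[config$core_idx, ] else config$box$L / 2
  M <- config$spec$M %||% 1
  reach <- Rc + M * unname(config$table$diameters["s"])
  offs <- ani <- numeric(length(frames))
  for (k in seq_along(frames)) {
    d <- min_image_disp(frames[[k]][sel, , drop = FALSE], center, config$box)
    offs[k] <- sqrt(sum(colMeans(d)^2)) / reach
    ani[k] <- shape_anisotropy(d)
  }
  list(centroid_offset = mean(offs), anisotropy = mean(ani))
}
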