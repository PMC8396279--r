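#' Reduced simulation units
#'
#' The model is formulated in standard Lennard-Jones reduced units: the
#' segment diameter \eqn{\sigma} is the length unit, the segment-segment
#' energy parameter \eqn{\epsilon} the energy unit, the segment mass \eqn{m}
#' the mass unit, and \eqn{\tau = \sigma\sqrt{m/\epsilon}} the time unit.
#' Temperature is reported as \eqn{T^* = k_B T/\epsilon}; all production
#' results in this package are generated at \eqn{T^* = 1}.
#'
#' @param sigma length unit (segment diameter)
#' @param epsilon energy unit
#' @param mass segment mass
#' @param T_star reduced temperature
#' @return an object of class `md_units`
#' @export
reduced_units <- function(sigma = 1, epsilon = 1, mass = 1, T_star = 1) {
  stopifnot(sigma > 0, epsilon > 0, mass > 0, T_star > 0)
  structure(list(sigma = sigma, epsilon = epsilon, mass = mass,
                 tau = sigma * sqrt(mass / epsilon), T_star = T_star),
            class = "md_units")
}

MODEL_VARIANTS <- c("M1", "M1a", "M2", "M2a")

#' Interaction table for a model variant
#'
#' Builds the per-species-pair Lennard-Jones parameters for one of the four
#' model variants.  Species are the core (`c`), chain segments (`s`) and
#' fluid particles (`P`).  Pair diameters follow the additive rule
#' \eqn{\sigma_{ij} = (\sigma_i + \sigma_j)/2}.  Core-core, core-segment and
#' core-particle interactions are always repulsive; particle-segment is
#' always attractive (strength `eps_Ps`); segment-segment and
#' particle-particle are attractive only in the `a` variants (M1a, M2a).
#' Attractive pairs are cut off at \eqn{2.5\,\sigma_{ij}}, repulsive pairs at
#' \eqn{\sigma_{ij}} so that only the repulsive shoulder survives.  Variants
#' M2/M2a differ from M1/M1a by rigid (immobile, radially stretched) ligands,
#' which is a property of the builder, not of the pair table.
#'
#' @param variant one of `"M1"`, `"M1a"`, `"M2"`, `"M2a"`
#' @param eps_Ps particle-segment well depth (the paper varies 1.5 and 3.0)
#' @param sigma_c core diameter
#' @param sigma_P fluid-particle diameter
#' @param sigma_s segment diameter (the length unit)
#' @param kss harmonic bond spring constant, energy/length^2
#' @param rcut_attractive_factor cutoff multiplier for attractive pairs
#' @return an object of class `interaction_table` with 3x3 matrices
#'   `sigma_ij`, `eps_ij`, `rcut_ij` and logical `attractive`, all with
#'   dimnames `c`, `s`, `P`
#' @examples
#' tab <- make_interaction_table("M1", eps_Ps = 1.5, sigma_c = 4)
#' tab$rcut_ij["P", "s"]   # 2.5: attractive pair
#' tab$rcut_ij["c", "s"]   # 2.5: repulsive at contact, sigma_cs = 2.5
#' @export
make_interaction_table <- function(variant = "M1", eps_Ps = 1.5,
                                   sigma_c = 4, sigma_P = 1, sigma_s = 1,
                                   kss = 1000, rcut_attractive_factor = 2.5) {
  if (!is.character(variant) || length(variant) != 1 || !variant %in% MODEL_VARIANTS)
    stop("unknown model variant '", paste(variant, collapse = ","),
         "'; must be one of ", paste(MODEL_VARIANTS, collapse = ", "), call. = FALSE)
  stopifnot(sigma_c > 0, sigma_P > 0, sigma_s > 0, eps_Ps > 0, kss > 0)
  diam <- c(c = sigma_c, s = sigma_s, P = sigma_P)
  sp <- names(diam)
  sigma_ij <- outer(diam, diam, function(a, b) (a + b) / 2)
  eps_ij <- matrix(1, 3, 3, dimnames = list(sp, sp))
  eps_ij["P", "s"] <- eps_ij["s", "P"] <- eps_Ps
  attractive <- matrix(FALSE, 3, 3, dimnames = list(sp, sp))
  attractive["P", "s"] <- attractive["s", "P"] <- TRUE
  if (variant %in% c("M1a", "M2a")) {
    attractive["s", "s"] <- TRUE
    attractive["P", "P"] <- TRUE
  }
  rcut_ij <- ifelse(attractive, rcut_attractive_factor * sigma_ij, sigma_ij)
  dimnames(rcut_ij) <- dimnames(sigma_ij)
  structure(list(variant = variant, eps_Ps = eps_Ps, kss = kss,
                 diameters = diam, sigma_ij = sigma_ij, eps_ij = eps_ij,
                 rcut_ij = rcut_ij, attractive = attractive,
                 rigid_ligands = variant %in% c("M2", "M2a")),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("Interaction table, model", x$variant,
      sprintf("(eps_Ps = %g, kss = %g)\n", x$eps_Ps, x$kss))
  cat("diameters:", paste(names(x$diameters), x$diameters, sep = "=", collapse = "  "), "\n")
  m <- ifelse(x$attractive, "attractive", "repulsive")
  print(m, quote = FALSE)
  invisible(x)
}

#' Look up one species pair in an interaction table
#'
#' @param table an [make_interaction_table()] result
#' @param i,j species tags (`"c"`, `"s"`, `"P"`)
#' @return list with `sigma_ij`, `eps_ij`, `rcut_ij`, `attractive`
#' @export
pair_lookup <- function(table, i, j) {
  stopifnot(inherits(table, "interaction_table"))
  list(i = i, j = j,
       sigma_ij = table$sigma_ij[i, j], eps_ij = table$eps_ij[i, j],
       rcut_ij = table$rcut_ij[i, j], attractive = table$attractive[i, j])
}

#' Shifted-force Lennard-Jones energy and force for one pair
#'
#' Evaluates the truncated, force-shifted Lennard-Jones interaction
#' \deqn{u(r) = u_{LJ}(r) - u_{LJ}(r_c) - (r - r_c)\, u_{LJ}'(r_c), \quad r < r_c}
#' and zero beyond the cutoff.  The linear term removes the force
#' discontinuity at \eqn{r_c}; the constant \eqn{-u_{LJ}(r_c)} additionally
#' makes the energy go to zero continuously (forces, and hence the dynamics,
#' are unaffected by the constant).  The returned force is the scalar
#' magnitude along the separation vector, \eqn{F = -du/dr} (positive =
#' repulsive); both energy and force vanish continuously at the cutoff.
#'
#' @param r separation distance(s), must be > 0
#' @param pair a [pair_lookup()] result, or any list with `sigma_ij`,
#'   `eps_ij`, `rcut_ij`
#' @return list with numeric vectors `energy` and `force`
#' @export
pair_energy_force <- function(r, pair) {
  if (any(r <= 0)) stop("r = 0: singular pair separation", call. = FALSE)
  s <- pair$sigma_ij; e <- pair$eps_ij; rc <- pair$rcut_ij
  ulj <- function(x) 4 * e * ((s / x)^12 - (s / x)^6)
  dulj <- function(x) -24 * e * (2 * (s / x)^12 - (s / x)^6) / x
  inside <- r < rc
  energy <- force <- numeric(length(r))
  if (any(inside)) {
    ri <- r[inside]
    energy[inside] <- ulj(ri) - ulj(rc) - (ri - rc) * dulj(rc)
    force[inside] <- -dulj(ri) + dulj(rc)
  }
  list(energy = energy, force = force)
}

#' Harmonic bond energy and force
#'
#' Chain connectivity uses the harmonic potential
#' \eqn{u_{ss}(r) = k_{ss} (r - \sigma_s)^2} with rest length equal to the
#' segment diameter (tangentially jointed beads).  The default spring
#' constant \eqn{k_{ss} = 1000\,\epsilon/\sigma^2} makes bonds stiff; the
#' free-dimer vibration period is about \eqn{0.1\tau}, which sets the
#' integration timestep (see [run_md()]).
#'
#' @param r separation distance(s)
#' @param kss spring constant
#' @param sigma_s rest length
#' @return list with `energy` and `force` (\eqn{F = -du/dr}, positive pushes
#'   the beads apart)
#' @export
bond_energy_force <- function(r, kss = 1000, sigma_s = 1) {
  list(energy = kss * (r - sigma_s)^2, force = -2 * kss * (r - sigma_s))
}
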