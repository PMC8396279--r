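# Independent O(N^2) reference for forces and potential energy, written
# against the closed-form pair functions only (no shared code with the
# compiled kernels): minimum-image pair sum with 1-2 exclusions plus
# harmonic bonds.
r_reference_forces <- function(config) {
  pos <- config$positions
  n <- nrow(pos)
  box <- config$box
  tab <- config$table
  sp <- c("c", "s", "P")[config$species]
  excl <- matrix(FALSE, n, n)
  if (nrow(config$bonds) > 0) {
    excl[config$bonds] <- TRUE
    excl[config$bonds[, 2:1, drop = FALSE]] <- TRUE
  }
  f <- matrix(0, n, 3)
  epot <- 0
  mi <- function(d) {
    for (k in 1:3) if (box$periodic[k])
      d[k] <- d[k] - box$L[k] * round(d[k] / box$L[k])
    d
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- mi(pos[i, ] - pos[j, ])
      r <- sqrt(sum(d^2))
      if (!excl[i, j]) {
        pe <- pair_energy_force(r, pair_lookup(tab, sp[i], sp[j]))
        epot <- epot + pe$energy
        fv <- pe$force * d / r
        f[i, ] <- f[i, ] + fv
        f[j, ] <- f[j, ] - fv
      }
    }
  }
  if (nrow(config$bonds) > 0) {
    for (b in seq_len(nrow(config$bonds))) {
      i <- config$bonds[b, 1]; j <- config$bonds[b, 2]
      d <- mi(pos[i, ] - pos[j, ])
      r <- sqrt(sum(d^2))
      be <- bond_energy_force(r, tab$kss, unname(tab$diameters["s"]))
      epot <- epot + be$energy
      fv <- be$force * d / r
      f[i, ] <- f[i, ] + fv
      f[j, ] <- f[j, ] - fv
    }
  }
  list(forces = f, epot = epot)
}

# minimum over all bead pairs of distance / sigma_ij (overlap diagnostic)
min_pair_gap <- function(config) {
  pos <- config$positions
  n <- nrow(pos)
  box <- config$box
  s <- config$table$sigma_ij
  best <- Inf
  for (i in seq_len(n - 1)) {
    d <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    for (k in 1:3) if (box$periodic[k])
      d[, k] <- d[, k] - box$L[k] * round(d[, k] / box$L[k])
    r <- sqrt(rowSums(d^2))
    sij <- s[config$species[i], config$species[(i + 1):n]]
    best <- min(best, r / sij)
  }
  best
}
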