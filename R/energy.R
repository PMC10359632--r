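## Pairwise energy model: Lennard-Jones + Coulomb + 12-10 hydrogen bond
## under a smooth (cosine switching) distance cutoff, plus a torsional
## term per rotatable bond. The total is the weighted combination
##   E = sum_pairs Q(r) * (w1 E_LJ + w2 E_C + w3 E_H) + sum_d w4 E_T(d).
## Units are nominally kcal/mol; only relative scale matters because the
## weights absorb units. Dielectric is constant 1 (w2 absorbs any scale).

#' Smooth cutoff (switching) factor
#'
#' Cosine switch taking a pair potential continuously from 1 to 0:
#' 1 for `r <= start`, 0 for `r >= end`, and
#' `0.5 * (1 + cos(pi * (r - start) / (end - start)))` between, which is
#' C1-continuous at both boundaries.
#'
#' @param r Distance(s) in Angstroms.
#' @param start,end Switching radii in Angstroms (`end > start`).
#' @return Dimensionless factor(s) in `[0, 1]`.
#' @export
cutoff_factor <- function(r, start, end) {
  stopifnot(end > start)
  q <- 0.5 * (1 + cos(pi * (r - start) / (end - start)))
  q[r <= start] <- 1
  q[r >= end] <- 0
  q
}

## Vectorised nonbonded kernel: atoms1 (n) against atoms2 (m) given
## parameter tibbles from ff_atom_params() and coordinate matrices.
## `mask` (n x m logical) marks pairs to evaluate. Returns per-term
## matrices (already multiplied by the cutoff factor).
nonbonded_terms <- function(xyz1, par1, xyz2, par2, ff, mask = NULL,
                            zero_action = c("error", "inf")) {
  zero_action <- match.arg(zero_action)
  n <- nrow(xyz1); m <- nrow(xyz2)
  dx <- outer(xyz1[, 1], xyz2[, 1], "-")
  dy <- outer(xyz1[, 2], xyz2[, 2], "-")
  dz <- outer(xyz1[, 3], xyz2[, 3], "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  if (is.null(mask)) mask <- matrix(TRUE, n, m)
  zeros <- mask & r == 0
  if (any(zeros)) {
    if (zero_action == "error") {
      stop("zero interatomic distance (duplicated atoms?)", call. = FALSE)
    }
    r[zeros] <- 1  # placeholder; overwritten with an infinite clash below
  }
  q <- cutoff_factor(r, ff$cutoff_start, ff$cutoff_end)
  live <- mask & q > 0 & !zeros
  lj <- coul <- hb <- matrix(0, n, m)
  if (any(live)) {
    eps <- sqrt(outer(par1$eps, par2$eps))
    rmin <- outer(par1$rmin_half, par2$rmin_half, "+")
    s6 <- (rmin[live] / r[live])^6
    lj[live] <- eps[live] * (s6 * s6 - 2 * s6)
    qq <- outer(par1$q, par2$q)
    coul[live] <- COULOMB_KE * qq[live] / r[live]
    hpair <- outer(par1$donor, par2$acceptor, "&") |
      outer(par1$acceptor, par2$donor, "&")
    hlive <- live & hpair
    if (any(hlive)) {
      s10 <- (ff$hbond_rmin / r[hlive])^10
      s12 <- (ff$hbond_rmin / r[hlive])^12
      hb[hlive] <- ff$hbond_epsilon * (5 * s12 - 6 * s10)
    }
    lj[live] <- lj[live] * q[live]
    coul[live] <- coul[live] * q[live]
    hb[hlive] <- hb[hlive] * q[hlive]
  }
  if (any(zeros)) lj[zeros] <- Inf
  list(lj = lj, coulomb = coul, hbond = hb, r = r, mask = mask)
}

#' Nonbonded energy of one atom pair
#'
#' Lennard-Jones `eps * ((rmin/r)^12 - 2 (rmin/r)^6)` with arithmetic
#' combination of `rmin/2` and geometric combination of `eps`; Coulomb
#' `k_e q_a q_b / r` with `k_e = 332.0637` kcal A / (mol e^2); and a
#' 12-10 hydrogen-bond well `eps_hb (5 (r0/r)^12 - 6 (r0/r)^10)` for
#' donor-acceptor pairs. Each term is multiplied by [cutoff_factor()].
#'
#' @param a,b One-row atom tibbles with `comp_id`, `atom_name`, `x`,
#'   `y`, `z`.
#' @param ff A `chiscan_ff` object.
#' @return Named numeric vector `c(lj =, coulomb =, hbond =)`.
#' @export
pair_energy <- function(a, b, ff = default_parameters()) {
  pa <- ff_atom_params(ff, a$comp_id, a$atom_name)
  pb <- ff_atom_params(ff, b$comp_id, b$atom_name)
  tm <- nonbonded_terms(as.matrix(a[, c("x", "y", "z")]), pa,
                        as.matrix(b[, c("x", "y", "z")]), pb, ff)
  c(lj = tm$lj[1, 1], coulomb = tm$coulomb[1, 1], hbond = tm$hbond[1, 1])
}

#' Torsional energy of one dihedral angle
#'
#' `sum_t (V_t / 2) (1 + cos(n_t chi - gamma_t))` over the terms of the
#' rotating bond.
#'
#' @param chi Dihedral angle in degrees.
#' @param terms Tibble/data frame with columns `v` (barrier, kcal/mol),
#'   `n` (periodicity, positive integer), `gamma` (phase, degrees).
#' @return Energy in kcal/mol.
#' @export
torsion_energy <- function(chi, terms) {
  stopifnot(nrow(terms) > 0)
  if (any(terms$n <= 0)) stop("torsion periodicity must be positive", call. = FALSE)
  sum(terms$v / 2 * (1 + cos(deg2rad(terms$n * chi - terms$gamma))))
}

#' Distribute a torsion energy over the 1-4 pairs of its bond
#'
#' The scanner accounts for every energy contribution pairwise so that
#' partial sums during incremental atom placement stay consistent. The
#' closed-form torsion value is split over the `n_pairs` atom pairs that
#' span the rotating bond; the parts sum to the closed form exactly (the
#' last part takes the floating-point remainder).
#'
#' @param chi Dihedral angle in degrees.
#' @param terms Torsion terms (see [torsion_energy()]).
#' @param n_pairs Number of 1-4 pairs spanning the bond (>= 1).
#' @return Numeric vector of length `n_pairs` summing exactly to
#'   `torsion_energy(chi, terms)`.
#' @export
distribute_torsion <- function(chi, terms, n_pairs) {
  stopifnot(n_pairs >= 1)
  e <- torsion_energy(chi, terms)
  if (n_pairs == 1) return(e)
  part <- e / n_pairs
  c(rep(part, n_pairs - 1), e - (n_pairs - 1) * part)
}

#' Total energy with the weighted linear combination
#'
#' Sums per-pair nonbonded terms and per-dihedral torsion terms and
#' combines them as `w1 * LJ + w2 * Coulomb + w3 * Hbond + w4 * Torsion`.
#' Per-pair contributions are sorted before summation so the result is
#' independent of the order in which pairs are listed.
#'
#' @param atoms Atom tibble (`comp_id`, `atom_name`, `x`, `y`, `z`).
#' @param pairs Tibble with integer columns `i`, `j` indexing rows of
#'   `atoms` (1-2 and 1-3 bonded pairs must already be excluded).
#' @param torsions Optional tibble with columns `chi` (degrees) and a
#'   list-column `terms` of torsion-term tables.
#' @param ff A `chiscan_ff` object.
#' @param keep_pairs Retain the per-pair records in the result.
#' @return An `energy_breakdown`: list with `lj_sum`, `coulomb_sum`,
#'   `hbond_sum`, `torsion_sum` (unweighted sums), `total` (weighted)
#'   and optionally `pairs`.
#' @export
total_energy <- function(atoms, pairs, torsions = NULL,
                         ff = default_parameters(), keep_pairs = FALSE) {
  par <- ff_atom_params(ff, atoms$comp_id, atoms$atom_name,
                        element = atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  lj <- coul <- hb <- numeric(nrow(pairs))
  if (nrow(pairs) > 0) {
    i <- pairs$i; j <- pairs$j
    r <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
    if (any(r == 0)) {
      stop("zero interatomic distance (duplicated atoms?)", call. = FALSE)
    }
    q <- cutoff_factor(r, ff$cutoff_start, ff$cutoff_end)
    live <- q > 0
    if (any(live)) {
      eps <- sqrt(par$eps[i] * par$eps[j])[live]
      rmin <- (par$rmin_half[i] + par$rmin_half[j])[live]
      s6 <- (rmin / r[live])^6
      lj[live] <- eps * (s6 * s6 - 2 * s6) * q[live]
      coul[live] <- COULOMB_KE * (par$q[i] * par$q[j])[live] / r[live] * q[live]
      hpair <- ((par$donor[i] & par$acceptor[j]) |
                  (par$acceptor[i] & par$donor[j]))
      hlive <- live & hpair
      if (any(hlive)) {
        s10 <- (ff$hbond_rmin / r[hlive])^10
        s12 <- (ff$hbond_rmin / r[hlive])^12
        hb[hlive] <- ff$hbond_epsilon * (5 * s12 - 6 * s10) * q[hlive]
      }
    }
  }
  tor <- 0
  if (!is.null(torsions) && nrow(torsions) > 0) {
    tor <- stable_sum(vapply(seq_len(nrow(torsions)), function(d) {
      torsion_energy(torsions$chi[d], torsions$terms[[d]])
    }, numeric(1)))
  }
  energy_breakdown(stable_sum(lj), stable_sum(coul), stable_sum(hb), tor,
                   ff$weights,
                   pairs = if (keep_pairs) {
                     dplyr::mutate(pairs, lj = lj, coulomb = coul, hbond = hb)
                   })
}

energy_breakdown <- function(lj, coulomb, hbond, torsion, weights,
                             pairs = NULL) {
  w <- weights
  structure(list(
    lj_sum = lj, coulomb_sum = coulomb, hbond_sum = hbond,
    torsion_sum = torsion,
    total = w[["w1"]] * lj + w[["w2"]] * coulomb + w[["w3"]] * hbond +
      w[["w4"]] * torsion,
    weights = w, pairs = pairs), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown>\n")
  cat(sprintf("  LJ %.6g | Coulomb %.6g | H-bond %.6g | Torsion %.6g\n",
              x$lj_sum, x$coulomb_sum, x$hbond_sum, x$torsion_sum))
  cat(sprintf("  total (weighted) %.6g\n", x$total))
  invisible(x)
}
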