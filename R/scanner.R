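## Conformational scan of target side chains: depth-first traversal of
## the chi grid with dead-end elimination. Atoms are placed group by
## group down the chain; after each placement the partial energy is
## accumulated and a branch is abandoned when even the best possible
## compensation by the not-yet-computed interactions cannot bring it
## back under the acceptance threshold. The admissible lower bound
## guarantees the accepted set equals what an exhaustive scan accepts.

## chi angles scanned over the half range [-90, 90) when the symmetric
## group makes chi and chi + 180 indistinguishable
SYMMETRY_REDUCED_CHI <- list(ASP = 2L, GLU = 3L, PHE = 2L, TYR = 2L)

#' Specify a chi-grid scan
#'
#' @param step Grid step in degrees; must divide 360 (and 180 when
#'   `symmetry_reduced`). Default 10 for production scans; the test
#'   suite uses 30 for speed.
#' @param window Acceptance window above the per-residue energy minimum
#'   (force-field units, >= 0).
#' @param symmetry_reduced Scan ASP chi2, GLU chi3 and PHE/TYR chi2 over
#'   `[-90, 90)` only (the 180-degree flip is chemically
#'   indistinguishable). ASN chi2 and GLN chi3 are always scanned in
#'   full: their flip swaps an amide O against an N, which only
#'   benchmarking treats as equivalent.
#' @param dee Use dead-end elimination pruning (`FALSE` forces the
#'   exhaustive traversal; results are identical by construction).
#' @param include_initial Additionally evaluate the residue's measured
#'   (generally off-grid) chi vector so an observed, sterically valid
#'   conformation always survives its own scan.
#' @return A `chiscan_scan_spec` list.
#' @export
scan_spec <- function(step = 10, window = 5, symmetry_reduced = FALSE,
                      dee = TRUE, include_initial = TRUE) {
  stopifnot(step > 0, window >= 0)
  if (360 %% step != 0) stop("step must divide 360 degrees", call. = FALSE)
  structure(list(step = step, window = window,
                 symmetry_reduced = symmetry_reduced, dee = dee,
                 include_initial = include_initial),
            class = "chiscan_scan_spec")
}

chi_grid_for <- function(comp_id, chi_idx, spec) {
  if (isTRUE(spec$symmetry_reduced) &&
      identical(SYMMETRY_REDUCED_CHI[[comp_id]], chi_idx)) {
    seq(-90, 90 - spec$step, by = spec$step)
  } else {
    seq(-180, 180 - spec$step, by = spec$step)
  }
}

#' Interaction reach of a scanned side chain
#'
#' The farthest distance a side-chain atom can lie from its CA is taken
#' as the all-trans extension of arginine (the longest side chain) built
#' at ideal geometry, plus a van der Waals radius for each interaction
#' partner, plus the interaction boundary (the outer cutoff radius).
#' Environment atoms beyond this distance from CA can never interact
#' with the scanned side chain.
#'
#' @param ff A `chiscan_ff` object.
#' @return Radius in Angstroms.
#' @export
reach_radius <- function(ff = default_parameters()) {
  ext <- arg_extension()
  ext + 2 * max(ff$elements$vdw_radius) + ff$cutoff_end
}

the_reach_cache <- new.env(parent = emptyenv())

## CA -> farthest side-chain atom distance of ideal all-trans ARG.
arg_extension <- function() {
  if (is.null(the_reach_cache$ext)) {
    r <- build_ideal_residue("ARG", chi = c(180, 180, 180, 180))
    ca <- unlist(r[r$atom_name == "CA", c("x", "y", "z")])
    sc <- r[!(r$atom_name %in% c("N", "CA", "C", "O")), ]
    the_reach_cache$ext <- max(sqrt((sc$x - ca[1])^2 + (sc$y - ca[2])^2 +
                                      (sc$z - ca[3])^2))
  }
  the_reach_cache$ext
}

#' Select the rigid environment of a target residue
#'
#' The scan computes interactions between the target's side-chain atoms
#' and main-chain atoms (N, CA, C, O, OXT, plus CB) of the surrounding
#' residues within the reach radius of the target's CA, plus the
#' target's own backbone. Side-chain atoms of other residues beyond CB
#' never enter the environment. Non-polymer (HETATM) atoms are included
#' as rigid environment whatever their names.
#'
#' @param structure Atom tibble.
#' @param asym_id,seq_id,alt_loc Key of the target residue.
#' @param reach Reach radius in Angstroms (default [reach_radius()]).
#' @param ff A `chiscan_ff` object.
#' @return The environment rows of `structure`, with a `.row` column of
#'   original row indices.
#' @export
select_environment <- function(structure, asym_id, seq_id, alt_loc = "",
                               reach = reach_radius(ff),
                               ff = default_parameters()) {
  mainchain <- c("N", "CA", "C", "O", "OXT", "CB")
  tgt <- structure$asym_id == asym_id & structure$seq_id == seq_id &
    (structure$alt_loc == "" | structure$alt_loc == alt_loc)
  if (!any(tgt)) stop("no residue ", asym_id, ":", seq_id, call. = FALSE)
  ca <- which(tgt & structure$atom_name == "CA")
  if (length(ca) == 0) stop("target residue ", asym_id, ":", seq_id,
                            " has no CA atom", call. = FALSE)
  ca_xyz <- c(structure$x[ca[1]], structure$y[ca[1]], structure$z[ca[1]])
  grid <- build_cell_grid(structure, edge = max(4, reach / 4))
  near <- grid_query_point(grid, ca_xyz, reach)
  keep <- rep(FALSE, nrow(structure))
  keep[near] <- TRUE
  alt_ok <- structure$alt_loc == "" | structure$alt_loc == alt_loc
  own_backbone <- tgt & structure$atom_name %in% mainchain
  other <- !tgt & alt_ok &
    (structure$atom_name %in% mainchain | structure$group == "HETATM")
  sel <- which((keep & other) | own_backbone)
  out <- structure[sel, ]
  out$.row <- sel
  out
}

## Per-pair admissible lower bound of the weighted nonbonded energy over
## all distances >= floor (interval arithmetic, so any weight signs work).
pair_lower_bounds <- function(par1, par2, ff) {
  w <- ff$weights
  floor_r <- ff$bond_min_distance
  q_at_floor <- cutoff_factor(floor_r, ff$cutoff_start, ff$cutoff_end)
  eps <- sqrt(outer(par1$eps, par2$eps))
  rmin <- outer(par1$rmin_half, par2$rmin_half, "+")
  s6 <- (rmin / floor_r)^6
  lj_hi <- eps * (s6 * s6 - 2 * s6) * q_at_floor
  lj_lo <- -eps
  qq <- COULOMB_KE * outer(par1$q, par2$q) / floor_r * q_at_floor
  c_lo <- pmin(qq, 0); c_hi <- pmax(qq, 0)
  hpair <- outer(par1$donor, par2$acceptor, "&") |
    outer(par1$acceptor, par2$donor, "&")
  s10 <- (ff$hbond_rmin / floor_r)^10
  s12 <- (ff$hbond_rmin / floor_r)^12
  h_hi <- ifelse(hpair, ff$hbond_epsilon * (5 * s12 - 6 * s10) * q_at_floor, 0)
  h_lo <- ifelse(hpair, -ff$hbond_epsilon, 0)
  wint <- function(wt, lo, hi) pmin(wt * lo, wt * hi)
  wint(w[["w1"]], lj_lo, lj_hi) + wint(w[["w2"]], c_lo, c_hi) +
    wint(w[["w3"]], h_lo, h_hi)
}

## Admissible bound on a level's weighted torsion contribution.
torsion_bounds <- function(terms, w4) {
  lo <- sum(pmin(0, terms$v)); hi <- sum(pmax(0, terms$v))
  min(w4 * lo, w4 * hi)
}

#' Scan one residue's chi grid with dead-end elimination
#'
#' Depth-first traversal of the chi grid. At depth `g` the atoms moved
#' by `chi_g` are placed and their interactions with the environment and
#' with already-placed side-chain atoms (1-2 and 1-3 bonded pairs
#' excluded, 1-4 included) plus the `chi_g` torsion term are added to
#' the running partial energy. A branch is pruned when this partial
#' energy plus an admissible lower bound on everything still to come
#' exceeds the current best total plus the acceptance window, which can
#' only discard conformations an exhaustive scan would also reject: the
#' completed leaves contain every rotamer [accept_rotamers()] keeps.
#'
#' @param target Atom tibble of the target residue.
#' @param env Environment tibble from [select_environment()].
#' @param chain Transform chain from [build_transform_chain()].
#' @param topo Topology from [chi_definitions()].
#' @param spec A `chiscan_scan_spec`.
#' @param ff A `chiscan_ff` object.
#' @return Tibble of completed rotamer records (`chi1..chi4`, unweighted
#'   term sums `e_lj`, `e_coulomb`, `e_hbond`, `e_torsion`, weighted
#'   `e_total`, `is_initial`, list-column `coords`), sorted by energy,
#'   with pruning statistics in attribute `stats`.
#' @export
dee_scan <- function(target, env, chain, topo, spec, ff = default_parameters()) {
  k <- chain$n_chi
  comp <- topo$comp_id
  w <- ff$weights

  scan_atoms <- chain$atom_names
  n_scan <- length(scan_atoms)
  groups <- vapply(scan_atoms, function(a) {
    topo$build_order$chi_group[match(a, topo$build_order$atom_id)]
  }, integer(1))

  # combined atom table for connectivity: target residue + environment
  tkey <- res_key(target$asym_id[1], target$seq_id[1], target$alt_loc[1])
  env_keys <- res_key(env$asym_id, env$seq_id, env$alt_loc)
  env_out <- env[env_keys != tkey | !(env$atom_name %in% target$atom_name), ]
  comb <- dplyr::bind_rows(target[, c("group", "atom_id", "element",
                                      "atom_name", "alt_loc", "comp_id",
                                      "asym_id", "seq_id", "x", "y", "z",
                                      "model_num")],
                           env_out[, c("group", "atom_id", "element",
                                       "atom_name", "alt_loc", "comp_id",
                                       "asym_id", "seq_id", "x", "y", "z",
                                       "model_num")])
  bonds <- detect_bonds(comb, ff)
  adj <- bond_adjacency(bonds, nrow(comb))

  scan_idx <- match(scan_atoms, target$atom_name)
  env_in_comb <- c(which(res_key(comb$asym_id, comb$seq_id, comb$alt_loc) == tkey &
                           comb$atom_name %in% env$atom_name[env_keys == tkey]),
                   which(seq_len(nrow(comb)) > nrow(target)))
  env_in_comb <- sort(unique(env_in_comb))
  n_env <- length(env_in_comb)

  # topological distances scanned atom -> everything (cap 3)
  dist_to <- lapply(scan_idx, function(a) topo_distances(adj, a, cap = 3L))
  mask_env <- do.call(rbind, lapply(dist_to, function(d) d[env_in_comb] >= 3L))
  mask_intra <- matrix(FALSE, n_scan, n_scan)
  for (a in seq_len(n_scan)) {
    mask_intra[a, ] <- dist_to[[a]][scan_idx] >= 3L
  }
  mask_intra[lower.tri(mask_intra, diag = TRUE)] <- FALSE  # count each pair once

  scan_par <- ff_atom_params(ff, rep(comp, n_scan), scan_atoms)
  env_par <- ff_atom_params(ff, comb$comp_id[env_in_comb],
                            comb$atom_name[env_in_comb],
                            element = comb$element[env_in_comb])
  env_xyz <- as.matrix(comb[env_in_comb, c("x", "y", "z")])

  # torsion terms per chi level
  tor_terms <- lapply(seq_len(k), function(g) {
    q <- topo$chi_defs[topo$chi_defs$index == g, ]
    ff_torsion_terms(ff, comp, g,
                     element_of_atom(comp, q$atom_2),
                     element_of_atom(comp, q$atom_3))
  })

  # admissible tail bounds per depth
  pm_env <- pair_lower_bounds(scan_par, env_par, ff)
  pm_intra <- pair_lower_bounds(scan_par, scan_par, ff)
  tor_lo <- vapply(seq_len(k), function(g) torsion_bounds(tor_terms[[g]],
                                                          w[["w4"]]),
                   numeric(1))
  bound_tail <- numeric(k)  # bound on contributions of levels > g
  for (g in seq_len(k)) {
    future <- groups > g
    b <- 0
    if (any(future)) {
      b <- b + sum(pmin((pm_env * mask_env)[future, , drop = FALSE], 0))
      intra_future <- (outer(groups, groups, pmax) > g) & mask_intra
      b <- b + sum(pmin(pm_intra[intra_future], 0))
    }
    if (g < k) b <- b + sum(tor_lo[(g + 1):k])
    bound_tail[g] <- b
  }

  grids <- lapply(seq_len(k), function(g) chi_grid_for(comp, g, spec))

  # placement state
  records <- list()
  nrec <- 0L
  stats <- c(leaves = 0L, pruned = 0L)
  incumbent <- Inf

  level_delta <- function(S_prev, g, chi_g, placed_xyz) {
    # place group g and return its coordinates plus the energy increments
    delta <- deg2rad(chi_g - chain$initial_chi[g])
    S <- if (g == 1) chain$prefix %*% hom_rz(delta) else
      S_prev %*% chain$mids[[g - 1]] %*% hom_rz(delta)
    grp <- chain$groups[[g]]
    xyz_g <- t(S %*% grp$u)[, 1:3, drop = FALSE]
    rows_g <- which(groups == g)
    tm <- nonbonded_terms(xyz_g, scan_par[rows_g, ], env_xyz, env_par, ff,
                          mask = mask_env[rows_g, , drop = FALSE],
                          zero_action = "inf")
    e_lj <- sum(tm$lj); e_c <- sum(tm$coulomb); e_h <- sum(tm$hbond)
    if (g > 1) {
      prev_rows <- which(groups < g)
      tmi <- nonbonded_terms(xyz_g, scan_par[rows_g, ],
                             placed_xyz[prev_rows, , drop = FALSE],
                             scan_par[prev_rows, ], ff,
                             mask = mask_intra[rows_g, prev_rows, drop = FALSE] |
                               t(mask_intra[prev_rows, rows_g, drop = FALSE]),
                             zero_action = "inf")
      e_lj <- e_lj + sum(tmi$lj); e_c <- e_c + sum(tmi$coulomb)
      e_h <- e_h + sum(tmi$hbond)
    }
    if (length(rows_g) > 1) {
      tms <- nonbonded_terms(xyz_g, scan_par[rows_g, ], xyz_g,
                             scan_par[rows_g, ], ff,
                             mask = mask_intra[rows_g, rows_g, drop = FALSE],
                             zero_action = "inf")
      e_lj <- e_lj + sum(tms$lj); e_c <- e_c + sum(tms$coulomb)
      e_h <- e_h + sum(tms$hbond)
    }
    e_t <- torsion_energy(chi_g, tor_terms[[g]])
    list(S = S, xyz = xyz_g, rows = rows_g,
         e = c(lj = e_lj, coulomb = e_c, hbond = e_h, torsion = e_t))
  }

  evaluate_leaf <- function(chi, is_initial) {
    # full, prune-free evaluation of one chi vector
    S <- NULL
    placed <- matrix(NA_real_, n_scan, 3)
    esum <- c(lj = 0, coulomb = 0, hbond = 0, torsion = 0)
    for (g in seq_len(k)) {
      st <- level_delta(S, g, chi[g], placed)
      S <- st$S
      placed[st$rows, ] <- st$xyz
      esum <- esum + st$e
    }
    total <- w[["w1"]] * esum[["lj"]] + w[["w2"]] * esum[["coulomb"]] +
      w[["w3"]] * esum[["hbond"]] + w[["w4"]] * esum[["torsion"]]
    nrec <<- nrec + 1L
    records[[nrec]] <<- list(chi = chi, e = esum, total = total,
                             is_initial = is_initial, coords = placed)
    if (total < incumbent) incumbent <<- total
    total
  }

  if (isTRUE(spec$include_initial)) {
    evaluate_leaf(chain$initial_chi, is_initial = TRUE)
  }

  dfs <- function(g, S_prev, placed, esum, wsum) {
    for (v in grids[[g]]) {
      st <- level_delta(S_prev, g, v, placed)
      e2 <- esum + st$e
      w2 <- wsum + w[["w1"]] * st$e[["lj"]] + w[["w2"]] * st$e[["coulomb"]] +
        w[["w3"]] * st$e[["hbond"]] + w[["w4"]] * st$e[["torsion"]]
      if (g == k) {
        stats[["leaves"]] <<- stats[["leaves"]] + 1L
        placed[st$rows, ] <- st$xyz
        nrec <<- nrec + 1L
        records[[nrec]] <<- list(
          chi = c(chi_stack[seq_len(g - 1)], v), e = e2, total = w2,
          is_initial = FALSE, coords = placed)
        if (w2 < incumbent) incumbent <<- w2
      } else {
        if (isTRUE(spec$dee) &&
            w2 + bound_tail[g] > incumbent + spec$window + 1e-12) {
          stats[["pruned"]] <<- stats[["pruned"]] + 1L
          next
        }
        placed[st$rows, ] <- st$xyz
        chi_stack[g] <<- v
        dfs(g + 1, st$S, placed, e2, w2)
      }
    }
  }
  chi_stack <- numeric(k)
  dfs(1, NULL, matrix(NA_real_, n_scan, 3),
      c(lj = 0, coulomb = 0, hbond = 0, torsion = 0), 0)

  chi_mat <- matrix(NA_real_, nrec, 4)
  out <- tibble::tibble(
    asym_id = target$asym_id[1], seq_id = target$seq_id[1],
    alt_loc = target$alt_loc[which(target$alt_loc != "")[1]] %|NA|% "",
    comp_id = comp,
    chi1 = NA_real_, chi2 = NA_real_, chi3 = NA_real_, chi4 = NA_real_,
    .rows = nrec)
  for (r in seq_len(nrec)) {
    chi_mat[r, seq_len(k)] <- records[[r]]$chi
  }
  out$chi1 <- chi_mat[, 1]; out$chi2 <- chi_mat[, 2]
  out$chi3 <- chi_mat[, 3]; out$chi4 <- chi_mat[, 4]
  out$e_lj <- vapply(records, function(r) r$e[["lj"]], numeric(1))
  out$e_coulomb <- vapply(records, function(r) r$e[["coulomb"]], numeric(1))
  out$e_hbond <- vapply(records, function(r) r$e[["hbond"]], numeric(1))
  out$e_torsion <- vapply(records, function(r) r$e[["torsion"]], numeric(1))
  out$e_total <- vapply(records, function(r) r$total, numeric(1))
  out$is_initial <- vapply(records, function(r) r$is_initial, logical(1))
  out$coords <- lapply(records, function(r) {
    tibble::tibble(atom_name = scan_atoms, x = r$coords[, 1],
                   y = r$coords[, 2], z = r$coords[, 3])
  })
  ord <- order(out$e_total, out$chi1, out$chi2, out$chi3, out$chi4,
               method = "radix")
  out <- out[ord, ]
  attr(out, "stats") <- stats
  out
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

#' Filter scanned records to the accepted rotamer set
#'
#' Keeps every record whose weighted total energy lies within `window`
#' of the minimum (boundary inclusive), sorted ascending by energy with
#' ties broken by chi lexicographic order.
#'
#' @param records Record tibble from [dee_scan()].
#' @param window Acceptance window (force-field units, >= 0).
#' @return The accepted subset with an added `accepted` column (all
#'   `TRUE`) and `rotamer_id` ordinals.
#' @export
accept_rotamers <- function(records, window) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no scan records: a scan always yields at least one record",
         call. = FALSE)
  }
  emin <- min(records$e_total)
  out <- records[records$e_total <= emin + window, , drop = FALSE]
  ord <- order(out$e_total, out$chi1, out$chi2, out$chi3, out$chi4,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  out$accepted <- TRUE
  out$rotamer_id <- seq_len(nrow(out))
  out
}

#' Generate a structure-specific rotamer library
#'
#' End-to-end driver: detects the targets, builds each residue's
#' transform chain, selects its rigid environment within the reach
#' radius, scans the chi grid under dead-end elimination and keeps the
#' rotamers inside the acceptance window.
#'
#' @param structure Atom tibble from [read_structure()] or the fixture
#'   builders.
#' @param residues Target selector: `NULL` scans every residue of a
#'   supported type; a character vector may mix residue-type codes
#'   (`"SER"`) and keys (`"A:12"` or `"A:12:B"` with an alternate
#'   location).
#' @param spec A `chiscan_scan_spec` (or use `step`/`window` shortcuts).
#' @param ff A `chiscan_ff` object.
#' @param step,window Shortcuts overriding the spec fields.
#' @return A `rotamer_library` tibble: one row per accepted rotamer with
#'   chi angles (degrees), the unweighted energy-term sums, the weighted
#'   total and the side-chain coordinates; scan metadata in
#'   `attr(, "scan")` and the static backbone in `attr(, "backbone")`.
#' @export
generate_library <- function(structure, residues = NULL, spec = scan_spec(),
                             ff = default_parameters(),
                             step = NULL, window = NULL) {
  if (!is.null(step)) spec$step <- step
  if (!is.null(window)) spec$window <- window
  if (360 %% spec$step != 0) stop("step must divide 360 degrees", call. = FALSE)

  res_tbl <- dplyr::distinct(structure[structure$group == "ATOM", ],
                             .data$asym_id, .data$seq_id, .data$comp_id)
  targets <- list()
  for (r in seq_len(nrow(res_tbl))) {
    comp <- res_tbl$comp_id[r]
    if (!(comp %in% SUPPORTED_RESIDUES)) next
    key0 <- paste0(res_tbl$asym_id[r], ":", res_tbl$seq_id[r])
    if (!is.null(residues)) {
      sel <- residues
      keyed <- grepl(":", sel, fixed = TRUE)
      match_type <- comp %in% toupper(sel[!keyed])
      match_key <- any(startsWith(sel[keyed], key0))
      if (!match_type && !match_key) next
    }
    rows <- structure$asym_id == res_tbl$asym_id[r] &
      structure$seq_id == res_tbl$seq_id[r]
    alts <- setdiff(unique(structure$alt_loc[rows]), "")
    if (length(alts) == 0) alts <- ""
    for (alt in alts) {
      targets[[length(targets) + 1L]] <- list(
        asym_id = res_tbl$asym_id[r], seq_id = res_tbl$seq_id[r],
        comp_id = comp, alt_loc = alt)
    }
  }
  if (length(targets) == 0) stop("no scannable residues selected", call. = FALSE)

  reach <- reach_radius(ff)
  lib_rows <- list()
  stats <- list()
  for (tg in targets) {
    rows <- structure$asym_id == tg$asym_id & structure$seq_id == tg$seq_id &
      (structure$alt_loc == "" | structure$alt_loc == tg$alt_loc)
    target <- structure[rows, ]
    target$alt_loc <- tg$alt_loc
    topo <- chi_definitions(tg$comp_id, ff)
    chain <- build_transform_chain(target, topo)
    env <- select_environment(structure, tg$asym_id, tg$seq_id, tg$alt_loc,
                              reach = reach, ff = ff)
    rec <- dee_scan(target, env, chain, topo, spec, ff)
    acc <- accept_rotamers(rec, spec$window)
    stats[[res_key(tg$asym_id, tg$seq_id, tg$alt_loc)]] <-
      c(attr(rec, "stats"), accepted = nrow(acc))
    lib_rows[[length(lib_rows) + 1L]] <- acc
  }
  lib <- dplyr::bind_rows(lib_rows)
  bb_names <- c("N", "CA", "C", "O", "CB", "OXT")
  tgt_keys <- vapply(targets, function(t) paste0(t$asym_id, ":", t$seq_id), "")
  backbone <- structure[paste0(structure$asym_id, ":", structure$seq_id) %in%
                          tgt_keys & structure$atom_name %in% bb_names, ]
  new_rotamer_library(lib, backbone = backbone,
                      scan = list(step = spec$step, window = spec$window,
                                  symmetry_reduced = spec$symmetry_reduced,
                                  weights = ff$weights, stats = stats))
}
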