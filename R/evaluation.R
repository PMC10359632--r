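## Symmetry-aware comparison of rotamer libraries against observed
## residue coordinates. bcRMSD is the minimum RMSD over all candidate
## rotamers and over the side-chain naming symmetries; bcDA are the chi
## differences of the bcRMSD-selected rotamer. No superposition is
## performed: candidates are built on the observed backbone, so both
## conformations already share the structure frame.

#' Side-chain naming symmetry rules of a residue type
#'
#' ASP chi2, GLU chi3 and PHE/TYR chi2 are chemically indistinguishable
#' from their 180-degree flip (the flip permutes equivalent atoms:
#' OD1/OD2, OE1/OE2, CD1/CD2 with CE1/CE2); these rules always apply.
#' In X-ray density an amide oxygen and nitrogen are also hard to tell
#' apart, so ASN chi2 and GLN chi3 (OD1/ND2, OE1/NE2) carry
#' benchmarking-only rules that a comparison applies only when asked.
#'
#' @param residue_type Three-letter code of a supported residue type.
#' @return Tibble with columns `chi` (index), `scope` (`"always"` or
#'   `"benchmarking"`) and a list-column `swap` of atom-name pairs
#'   realizing the flip. Zero rows when the type has no symmetry.
#' @export
symmetry_rules <- function(residue_type) {
  comp <- toupper(residue_type)
  if (!(comp %in% SUPPORTED_RESIDUES)) {
    stop("unsupported residue type '", residue_type, "'", call. = FALSE)
  }
  rules <- list(
    ASP = list(chi = 2L, scope = "always",
               swap = list(c("OD1", "OD2"))),
    GLU = list(chi = 3L, scope = "always",
               swap = list(c("OE1", "OE2"))),
    PHE = list(chi = 2L, scope = "always",
               swap = list(c("CD1", "CD2"), c("CE1", "CE2"))),
    TYR = list(chi = 2L, scope = "always",
               swap = list(c("CD1", "CD2"), c("CE1", "CE2"))),
    ASN = list(chi = 2L, scope = "benchmarking",
               swap = list(c("OD1", "ND2"))),
    GLN = list(chi = 3L, scope = "benchmarking",
               swap = list(c("OE1", "NE2"))))
  r <- rules[[comp]]
  if (is.null(r)) {
    return(tibble::tibble(chi = integer(), scope = character(),
                          swap = list()))
  }
  tibble::tibble(chi = r$chi, scope = r$scope, swap = list(r$swap))
}

## Atom-name vector with a rule's permutation applied.
apply_swap <- function(names, swaps) {
  out <- names
  for (sw in swaps) {
    out[names == sw[1]] <- sw[2]
    out[names == sw[2]] <- sw[1]
  }
  out
}

## Which symmetry rules apply under the benchmarking flag.
active_rules <- function(comp, benchmarking) {
  rules <- symmetry_rules(comp)
  rules[rules$scope == "always" | (benchmarking & rules$scope == "benchmarking"), ]
}

#' Best-case RMSD of a candidate set against an observed residue
#'
#' Minimum over all candidate rotamers, and over the applicable
#' symmetry permutations, of the root-mean-square deviation of the
#' side-chain heavy atoms in the fixed structure frame (candidates
#' share the observed backbone; nothing is superposed).
#'
#' @param observed Atom tibble of the observed residue (backbone plus
#'   side chain).
#' @param candidates A `rotamer_library` subset (or [dee_scan()] output)
#'   for this residue: rows with a `coords` list-column.
#' @param benchmarking Apply the ASN/GLN benchmarking-only folds.
#' @param ff Parameter set (chi definitions).
#' @return List with `rmsd` (Angstroms), `index` (best candidate row)
#'   and `flipped` (whether a symmetry permutation achieved the
#'   minimum).
#' @export
bc_rmsd <- function(observed, candidates, benchmarking = FALSE,
                    ff = default_parameters()) {
  stopifnot(nrow(candidates) >= 1)
  comp <- candidates$comp_id[1]
  rules <- active_rules(comp, benchmarking)
  cand_names <- candidates$coords[[1]]$atom_name
  name_sets <- list(identity = cand_names)
  if (nrow(rules) > 0) {
    for (r in seq_len(nrow(rules))) {
      name_sets[[paste0("flip", r)]] <- apply_swap(cand_names, rules$swap[[r]])
    }
  }
  obs_idx <- lapply(name_sets, function(nm) {
    idx <- match(nm, observed$atom_name)
    if (anyNA(idx)) {
      stop("observed ", comp, " residue lacks atom(s): ",
           paste(nm[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    idx
  })
  obs_xyz <- as.matrix(observed[, c("x", "y", "z")])
  best <- list(rmsd = Inf, index = NA_integer_, flipped = FALSE)
  for (ci in seq_len(nrow(candidates))) {
    cxyz <- as.matrix(candidates$coords[[ci]][, c("x", "y", "z")])
    for (si in seq_along(obs_idx)) {
      d <- cxyz - obs_xyz[obs_idx[[si]], , drop = FALSE]
      rmsd <- sqrt(mean(rowSums(d * d)))
      if (rmsd < best$rmsd - 1e-15) {
        best <- list(rmsd = rmsd, index = ci, flipped = si > 1)
      }
    }
  }
  best
}

#' Best-case dihedral-angle differences
#'
#' Signed circular chi differences (observed minus selected candidate,
#' wrapped into `(-180, 180]`) of the bcRMSD-selected rotamer. For a chi angle
#' with an applicable symmetry rule the difference is folded into the
#' 180-degree equivalence class, i.e. into `(-90, 90]`.
#'
#' @inheritParams bc_rmsd
#' @return List with `bcda` (numeric vector, degrees), `index` and
#'   `rmsd` of the selected rotamer.
#' @export
bc_da <- function(observed, candidates, benchmarking = FALSE,
                  ff = default_parameters()) {
  comp <- candidates$comp_id[1]
  topo <- chi_definitions(comp, ff)
  best <- bc_rmsd(observed, candidates, benchmarking, ff)
  obs_chi <- measure_chi(observed, topo)
  cand_chi <- unlist(candidates[best$index, paste0("chi", seq_len(topo$n_chi))])
  d <- angle_diff(obs_chi, cand_chi)
  rules <- active_rules(comp, benchmarking)
  if (nrow(rules) > 0) {
    for (r in seq_len(nrow(rules))) {
      ci <- rules$chi[r]
      d[ci] <- fold_180(d[ci])
    }
  }
  list(bcda = unname(d), index = best$index, rmsd = best$rmsd)
}

#' Number of accepted rotamers of a library entry
#'
#' @param entry Rows of a `rotamer_library` for one residue.
#' @return Integer count.
#' @export
rotamer_count <- function(entry) {
  if ("accepted" %in% names(entry)) sum(entry$accepted) else nrow(entry)
}

#' Flag evaluation outliers
#'
#' A residue is an RMSD outlier when its bcRMSD is at least 0.1
#' Angstroms (boundary inclusive) -- roughly the coordinate-error scale
#' of good crystal structures -- and an angle outlier when it is an
#' RMSD outlier and any |bcDA| exceeds 10 degrees.
#'
#' @param comparison Tibble with columns `bcrmsd` and `bcda` (list
#'   column of per-chi differences), e.g. from [evaluate_library()].
#' @param rmsd_threshold,angle_threshold Thresholds (0.1 A, 10 deg).
#' @return The input with logical columns `rmsd_outlier` and
#'   `angle_outlier` added/replaced.
#' @export
flag_outliers <- function(comparison, rmsd_threshold = 0.1,
                          angle_threshold = 10) {
  comparison$rmsd_outlier <- comparison$bcrmsd >= rmsd_threshold
  comparison$angle_outlier <- comparison$rmsd_outlier &
    vapply(comparison$bcda, function(d) any(abs(d) > angle_threshold),
           logical(1))
  comparison
}

#' Evaluate a rotamer library against observed coordinates
#'
#' For every residue present in the library, computes the bcRMSD and
#' bcDA against the matching residue of `structure` and applies the
#' outlier thresholds.
#'
#' @param structure Atom tibble with the observed coordinates.
#' @param library A `rotamer_library`.
#' @param benchmarking Apply ASN/GLN benchmarking-only symmetry.
#' @param ff Parameter set.
#' @return A tibble (one row per residue): `asym_id`, `seq_id`,
#'   `alt_loc`, `comp_id`, `n_rotamers`, `bcrmsd`, `best_rotamer`,
#'   `bcda` (list column), `max_abs_bcda`, `rmsd_outlier`,
#'   `angle_outlier`.
#' @export
evaluate_library <- function(structure, library, benchmarking = FALSE,
                             ff = default_parameters()) {
  keys <- dplyr::distinct(library[, c("asym_id", "seq_id", "alt_loc",
                                      "comp_id")])
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    cand <- library[library$asym_id == keys$asym_id[r] &
                      library$seq_id == keys$seq_id[r] &
                      library$alt_loc == keys$alt_loc[r], ]
    obs <- structure[structure$asym_id == keys$asym_id[r] &
                       structure$seq_id == keys$seq_id[r] &
                       (structure$alt_loc == "" |
                          structure$alt_loc == keys$alt_loc[r]), ]
    if (nrow(obs) == 0) {
      stop("structure lacks residue ", keys$asym_id[r], ":", keys$seq_id[r],
           call. = FALSE)
    }
    da <- bc_da(obs, cand, benchmarking, ff)
    tibble::tibble(
      asym_id = keys$asym_id[r], seq_id = keys$seq_id[r],
      alt_loc = keys$alt_loc[r], comp_id = keys$comp_id[r],
      n_rotamers = rotamer_count(cand),
      bcrmsd = da$rmsd, best_rotamer = da$index,
      bcda = list(da$bcda), max_abs_bcda = max(abs(da$bcda)))
  })
  flag_outliers(dplyr::bind_rows(rows))
}

#' Realize an external chi table as a rotamer library on a structure
#'
#' Third-party rotamer libraries given as plain chi tables (columns
#' `comp_id`, `chi1..chi4`, optional `weight`) are turned into
#' coordinate candidates by rotating each matching residue's own side
#' chain to the table's chi values on the observed backbone (the
#' observed internal geometry is reused, isolating the chi angles), so
#' they can be compared with [evaluate_library()].
#'
#' @param structure Atom tibble with observed residues.
#' @param chi_table Data frame with `comp_id` and `chi1..chi4` columns
#'   (NA for absent angles), angles in degrees.
#' @param ff Parameter set.
#' @return A `rotamer_library` (energies are `NA`: external candidates
#'   are not scored).
#' @export
library_from_chi_table <- function(structure, chi_table,
                                   ff = default_parameters()) {
  res_tbl <- dplyr::distinct(structure[structure$group == "ATOM", ],
                             .data$asym_id, .data$seq_id, .data$comp_id)
  res_tbl <- res_tbl[res_tbl$comp_id %in% SUPPORTED_RESIDUES &
                       res_tbl$comp_id %in% chi_table$comp_id, ]
  rows <- list()
  for (r in seq_len(nrow(res_tbl))) {
    comp <- res_tbl$comp_id[r]
    topo <- chi_definitions(comp, ff)
    k <- topo$n_chi
    obs <- structure[structure$asym_id == res_tbl$asym_id[r] &
                       structure$seq_id == res_tbl$seq_id[r], ]
    chain <- build_transform_chain(obs, topo)
    cand <- chi_table[chi_table$comp_id == comp, , drop = FALSE]
    for (ci in seq_len(nrow(cand))) {
      chi <- unlist(cand[ci, paste0("chi", seq_len(k))])
      sc <- evaluate_coordinates(chain, chi)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        asym_id = res_tbl$asym_id[r], seq_id = res_tbl$seq_id[r],
        alt_loc = "", comp_id = comp,
        chi1 = if (k >= 1) chi[1] else NA_real_,
        chi2 = if (k >= 2) chi[2] else NA_real_,
        chi3 = if (k >= 3) chi[3] else NA_real_,
        chi4 = if (k >= 4) chi[4] else NA_real_,
        e_lj = NA_real_, e_coulomb = NA_real_, e_hbond = NA_real_,
        e_torsion = NA_real_, e_total = NA_real_, is_initial = FALSE,
        accepted = TRUE, rotamer_id = ci,
        coords = list(tibble::tibble(atom_name = sc$atom_name,
                                     x = sc$x, y = sc$y, z = sc$z)))
    }
  }
  if (length(rows) == 0) stop("chi table matches no residue", call. = FALSE)
  lib <- dplyr::bind_rows(rows)
  bb_names <- c("N", "CA", "C", "O", "CB", "OXT")
  backbone <- structure[structure$atom_name %in% bb_names, ]
  new_rotamer_library(lib, backbone = backbone,
                      scan = list(step = NA_real_, window = NA_real_))
}
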