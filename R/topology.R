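## Connectivity and chi-topology services: cell-list ("cubing") neighbour
## search, covalent-bond detection (explicit list first, geometric
## fallback), and per-residue-type chi definitions with the incremental
## side-chain build order.

#' Build a cell-list grid over a set of atoms
#'
#' Partitions space into cubes of the given edge so that neighbour
#' queries only examine nearby cells. Cell index is
#' `floor(coordinate / edge)` per axis.
#'
#' @param atoms An atom tibble with `x`, `y`, `z` columns (Angstroms).
#' @param edge Cube edge length in Angstroms (> 0).
#' @return A `chiscan_grid` object.
#' @export
build_cell_grid <- function(atoms, edge) {
  stopifnot(edge > 0, nrow(atoms) > 0)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinate in atom set", call. = FALSE)
  idx <- floor(xyz / edge)
  key <- paste(idx[, 1], idx[, 2], idx[, 3], sep = ",")
  cells <- split(seq_len(nrow(xyz)), key)
  structure(list(edge = edge, xyz = xyz, cell_index = idx, cells = cells),
            class = "chiscan_grid")
}

## All (i, j) pairs with i < j and distance <= radius. Searches the
## ceiling(radius/edge)-cell neighbourhood so correctness does not depend
## on the edge being at least the query radius. Boundary is inclusive.
grid_pairs_within <- function(grid, radius) {
  reach <- as.integer(ceiling(radius / grid$edge))
  offs <- as.matrix(expand.grid(dx = -reach:reach, dy = -reach:reach,
                                dz = -reach:reach))
  out_i <- integer(); out_j <- integer(); out_d <- numeric()
  r2 <- radius^2
  keys <- names(grid$cells)
  keymat <- do.call(rbind, lapply(strsplit(keys, ",", fixed = TRUE), as.integer))
  for (ci in seq_along(keys)) {
    base <- keymat[ci, ]
    ai <- grid$cells[[ci]]
    for (o in seq_len(nrow(offs))) {
      nb_key <- paste(base[1] + offs[o, 1], base[2] + offs[o, 2],
                      base[3] + offs[o, 3], sep = ",")
      aj <- grid$cells[[nb_key]]
      if (is.null(aj)) next
      for (i in ai) {
        jj <- aj[aj > i]
        if (length(jj) == 0) next
        d2 <- colSums((t(grid$xyz[jj, , drop = FALSE]) - grid$xyz[i, ])^2)
        keep <- d2 <= r2 + 1e-12
        if (any(keep)) {
          out_i <- c(out_i, rep.int(i, sum(keep)))
          out_j <- c(out_j, jj[keep])
          out_d <- c(out_d, sqrt(d2[keep]))
        }
      }
    }
  }
  tibble::tibble(i = out_i, j = out_j, dist = out_d) |>
    dplyr::distinct(.data$i, .data$j, .keep_all = TRUE) |>
    dplyr::arrange(.data$i, .data$j)
}

## Atom indices within `radius` of a point (inclusive).
grid_query_point <- function(grid, point, radius) {
  lo <- floor((point - radius) / grid$edge)
  hi <- floor((point + radius) / grid$edge)
  hits <- integer()
  for (cx in lo[1]:hi[1]) for (cy in lo[2]:hi[2]) for (cz in lo[3]:hi[3]) {
    a <- grid$cells[[paste(cx, cy, cz, sep = ",")]]
    if (!is.null(a)) hits <- c(hits, a)
  }
  if (length(hits) == 0) return(integer())
  d2 <- colSums((t(grid$xyz[hits, , drop = FALSE]) - point)^2)
  sort(hits[d2 <= radius^2 + 1e-12])
}

#' Detect covalent bonds of a structure
#'
#' Bonds are taken from the explicit per-residue bond list of the
#' parameter file first; pairs that the list cannot cover (inter-residue
#' links such as the peptide bond and disulfides, and residues absent
#' from the list) are detected geometrically: atoms A, B are bonded when
#' `min_distance < d(A,B) <= r_cov(A) + r_cov(B) + tolerance`, found via
#' a cell grid with edge twice the largest covalent radius present.
#' Polymer (`ATOM`) and non-polymer (`HETATM`) records are never bonded
#' to each other: ligands and probes are rigid nonbonded environment.
#'
#' @param structure An atom tibble (see [read_structure()]).
#' @param ff A `chiscan_ff` parameter object.
#' @return A tibble with integer columns `i`, `j` (row indices into
#'   `structure`, `i < j`) and `dist`.
#' @export
detect_bonds <- function(structure, ff = default_parameters()) {
  n <- nrow(structure)
  if (n == 0) return(tibble::tibble(i = integer(), j = integer(), dist = numeric()))
  elem <- toupper(structure$element)
  rcov <- ff_element_row(ff, elem)$covalent_radius

  rk <- res_key(structure$asym_id, structure$seq_id, structure$alt_loc)
  pairs_i <- integer(); pairs_j <- integer()

  # (a) explicit intra-residue bonds by (comp_id, atom names)
  known_comp <- unique(ff$bonds$comp_id)
  for (key in unique(rk)) {
    rows <- which(rk == key)
    comp <- structure$comp_id[rows[1]]
    btbl <- ff$bonds[ff$bonds$comp_id %in% c(comp, "*"), , drop = FALSE]
    if (nrow(btbl) == 0) next
    nm <- structure$atom_name[rows]
    for (b in seq_len(nrow(btbl))) {
      i <- rows[match(btbl$atom_1[b], nm)]
      j <- rows[match(btbl$atom_2[b], nm)]
      if (!is.na(i) && !is.na(j)) {
        pairs_i <- c(pairs_i, min(i, j)); pairs_j <- c(pairs_j, max(i, j))
      }
    }
  }

  # (b) geometric fallback via cubing for connections the list cannot give
  edge <- 2 * largest_covalent_radius(ff, unique(elem))
  maxlen <- 2 * largest_covalent_radius(ff, unique(elem)) + ff$bond_tolerance
  grid <- build_cell_grid(structure, edge)
  cand <- grid_pairs_within(grid, maxlen)
  if (nrow(cand) > 0) {
    same_res <- rk[cand$i] == rk[cand$j]
    comp_known <- structure$comp_id[cand$i] %in% c(known_comp) &
      structure$comp_id[cand$j] %in% known_comp
    # same-residue pairs of residue types covered by the explicit list are
    # governed by that list alone; polymer atoms never bond geometrically
    # to non-polymer (HETATM) atoms, which stay rigid environment
    cross_group <- structure$group[cand$i] != structure$group[cand$j]
    consider <- !(same_res & comp_known) & !cross_group
    lim <- rcov[cand$i] + rcov[cand$j] + ff$bond_tolerance
    ok <- consider & cand$dist > ff$bond_min_distance & cand$dist <= lim + 1e-12
    pairs_i <- c(pairs_i, cand$i[ok])
    pairs_j <- c(pairs_j, cand$j[ok])
  }

  xyz <- as.matrix(structure[, c("x", "y", "z")])
  out <- tibble::tibble(i = pairs_i, j = pairs_j) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$i, .data$j)
  out$dist <- sqrt(rowSums((xyz[out$i, , drop = FALSE] -
                              xyz[out$j, , drop = FALSE])^2))
  out
}

## Adjacency list (list of integer vectors) from a bond table.
bond_adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

## Topological bond-count distance between atom a and a set of atoms,
## capped at `cap` (used for 1-2/1-3 exclusions; anything farther is cap+1).
topo_distances <- function(adj, a, cap = 3L) {
  n <- length(adj)
  dist <- rep.int(cap + 1L, n)
  dist[a] <- 0L
  frontier <- a
  for (d in seq_len(cap)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[dist[nxt] > d]
    if (length(nxt) == 0) break
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

SUPPORTED_RESIDUES <- c("ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "HIS",
                        "ILE", "LEU", "LYS", "MET", "PHE", "SER", "THR",
                        "TRP", "TYR", "VAL")

#' Chi-angle topology of a residue type
#'
#' Returns the IUPAC chi-angle atom quadruples, the rotatable-bond count
#' and the incremental build order (each side-chain atom tagged with the
#' last chi angle that moves it) for one of the 17 supported residue
#' types. GLY and ALA have no chi angle and PRO's ring would require
#' bond-angle degrees of freedom, so all three are rejected.
#'
#' @param residue_type Three-letter residue code (e.g. `"SER"`).
#' @param ff A `chiscan_ff` parameter object carrying the chi tables.
#' @return A `chiscan_topology` list: `comp_id`, `n_chi`, `chi_defs`
#'   (tibble `index`, `atom_1..atom_4`), `build_order` (tibble
#'   `atom_id`, `chi_group`), `bonds` (intra-residue bond tibble).
#' @export
chi_definitions <- function(residue_type, ff = default_parameters()) {
  comp <- toupper(residue_type)
  if (!(comp %in% SUPPORTED_RESIDUES)) {
    stop("unsupported residue type '", residue_type,
         "' (GLY and ALA have no chi angles; PRO's ring is not scanned; ",
         "supported: ", paste(SUPPORTED_RESIDUES, collapse = ", "), ")",
         call. = FALSE)
  }
  chi <- ff$chi[ff$chi$comp_id == comp, , drop = FALSE]
  chi <- chi[order(chi$index), , drop = FALSE]
  build <- ff$build[ff$build$comp_id == comp, , drop = FALSE]
  if (nrow(chi) == 0 || nrow(build) == 0) {
    stop("parameter file has no chi/build tables for ", comp, call. = FALSE)
  }
  structure(list(
    comp_id = comp,
    n_chi = max(chi$index),
    chi_defs = tibble::as_tibble(chi[, c("index", "atom_1", "atom_2",
                                         "atom_3", "atom_4")]),
    build_order = tibble::as_tibble(build[, c("atom_id", "chi_group")]),
    bonds = tibble::as_tibble(
      ff$bonds[ff$bonds$comp_id %in% c(comp, "*"),
               c("atom_1", "atom_2"), drop = FALSE])
  ), class = "chiscan_topology")
}
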