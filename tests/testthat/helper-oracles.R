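# Independent oracles used to cross-check the package's optimised paths.
# They deliberately avoid the implementation under test: side-chain
# placement uses sequential axis-angle (Rodrigues) rotation on raw
# coordinates instead of the cached transform chains, neighbour search
# is all-against-all, and scan energies are re-assembled from the
# public total_energy() on brute-force pair lists.

rot_axis_angle <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Sequential proximal-to-distal rotation of a residue's side chain to a
# target chi vector, recomputing each axis from the *updated* coordinates.
oracle_sidechain_coords <- function(residue, topo, chi) {
  nm <- residue$atom_name
  xyz <- as.matrix(residue[, c("x", "y", "z")])
  rownames(xyz) <- nm
  groups <- setNames(topo$build_order$chi_group, topo$build_order$atom_id)
  for (i in seq_len(topo$n_chi)) {
    q <- topo$chi_defs[topo$chi_defs$index == i, ]
    p <- lapply(c(q$atom_1, q$atom_2, q$atom_3, q$atom_4),
                function(a) xyz[a, ])
    cur <- chiscan::measure_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    delta <- chiscan::angle_diff(chi[i], cur)
    axis <- p[[4 - 1]] - p[[2]]  # bond atom2 -> atom3
    R <- rot_axis_angle(axis, delta)
    movers <- names(groups)[groups >= i]
    for (a in movers) {
      xyz[a, ] <- as.numeric(R %*% (xyz[a, ] - p[[2]])) + p[[2]]
    }
  }
  moved <- topo$build_order$atom_id
  tibble::tibble(atom_name = moved,
                 x = xyz[moved, 1], y = xyz[moved, 2], z = xyz[moved, 3])
}

# O(n^2) neighbour pairs within a radius (inclusive).
brute_pairs_within <- function(xyz, radius) {
  n <- nrow(xyz)
  out <- list()
  for (i in seq_len(n - 1)) {
    d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
    j <- which(d <= radius + 1e-12)
    if (length(j) > 0) {
      out[[length(out) + 1]] <- cbind(i = i, j = i + j, dist = d[j])
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), dist = numeric()))
  }
  m <- do.call(rbind, out)
  tibble::as_tibble(as.data.frame(m)) |>
    dplyr::mutate(i = as.integer(i), j = as.integer(j)) |>
    dplyr::arrange(i, j)
}

# Exhaustive reference scan of one residue: enumerate the full chi grid
# (plus the measured initial vector), build coordinates with the
# Rodrigues oracle and score with total_energy() over a brute-force
# pair list. Returns the records accepted at `window`.
oracle_scan <- function(structure, asym_id, seq_id, step, window,
                        ff = chiscan::default_parameters(),
                        include_initial = TRUE) {
  rows <- structure$asym_id == asym_id & structure$seq_id == seq_id
  target <- structure[rows, ]
  comp <- target$comp_id[1]
  topo <- chiscan::chi_definitions(comp, ff)
  k <- topo$n_chi
  env <- chiscan::select_environment(structure, asym_id, seq_id, ff = ff)

  # combined atom table: environment (dropping duplicates of the target's
  # own backbone) + scanned side-chain atoms (coordinates replaced later)
  scan_atoms <- topo$build_order$atom_id
  env_keep <- !(env$asym_id == asym_id & env$seq_id == seq_id &
                  duplicated(paste(env$asym_id, env$seq_id, env$atom_name)))
  env_tbl <- env[env_keep, ]
  base <- dplyr::bind_rows(
    env_tbl[, c("group", "atom_id", "element", "atom_name", "alt_loc",
                "comp_id", "asym_id", "seq_id", "x", "y", "z", "model_num")],
    target[match(scan_atoms, target$atom_name),
           c("group", "atom_id", "element", "atom_name", "alt_loc",
             "comp_id", "asym_id", "seq_id", "x", "y", "z", "model_num")])
  n_env <- nrow(env_tbl)
  scan_rows <- n_env + seq_along(scan_atoms)

  bonds <- chiscan::detect_bonds(base, ff)
  # pairwise topological distances via tiny BFS
  adj <- vector("list", nrow(base))
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$i[b]]] <- c(adj[[bonds$i[b]]], bonds$j[b])
    adj[[bonds$j[b]]] <- c(adj[[bonds$j[b]]], bonds$i[b])
  }
  topo_dist <- function(a, cap = 3L) {
    d <- rep(cap + 1L, nrow(base)); d[a] <- 0L; fr <- a
    for (s in seq_len(cap)) {
      nx <- setdiff(unique(unlist(adj[fr])), which(d <= s))
      nx <- nx[d[nx] > s]
      if (!length(nx)) break
      d[nx] <- s; fr <- nx
    }
    d
  }
  pairs <- list()
  for (si in seq_along(scan_rows)) {
    d <- topo_dist(scan_rows[si])
    partners <- c(seq_len(n_env), scan_rows[scan_rows > scan_rows[si]])
    ok <- partners[d[partners] >= 3L]
    if (length(ok)) pairs[[si]] <- cbind(i = scan_rows[si], j = ok)
  }
  pair_tbl <- tibble::as_tibble(as.data.frame(do.call(rbind, pairs)))

  tor_terms <- lapply(seq_len(k), function(g) {
    q <- topo$chi_defs[topo$chi_defs$index == g, ]
    e2 <- substr(q$atom_2, 1, 1); e3 <- substr(q$atom_3, 1, 1)
    key <- paste(sort(c(e2, e3)), collapse = ":")
    hit <- ff$torsions[ff$torsions$key == paste0(comp, ":", g), ]
    if (nrow(hit) == 0) hit <- ff$torsions[ff$torsions$key == key, ]
    if (nrow(hit) == 0) hit <- ff$torsions[ff$torsions$key == "default", ]
    hit
  })

  grid <- lapply(seq_len(k), function(g) seq(-180, 180 - step, by = step))
  chis <- as.matrix(expand.grid(grid))
  if (include_initial) {
    chis <- rbind(chiscan::measure_chi(target, topo), chis)
  }
  res <- lapply(seq_len(nrow(chis)), function(r) {
    chi <- as.numeric(chis[r, ])
    sc <- oracle_sidechain_coords(target, topo, chi)
    at <- base
    at$x[scan_rows] <- sc$x; at$y[scan_rows] <- sc$y; at$z[scan_rows] <- sc$z
    tors <- tibble::tibble(chi = chi, terms = tor_terms)
    eb <- chiscan::total_energy(at, pair_tbl, tors, ff)
    c(chi, eb$total)
  })
  m <- do.call(rbind, res)
  colnames(m) <- c(paste0("chi", seq_len(k)), "e_total")
  out <- tibble::as_tibble(as.data.frame(m))
  out[out$e_total <= min(out$e_total) + window, , drop = FALSE]
}

expect_same_rotamer_set <- function(lib_entry, oracle_entry, k,
                                    tol = 1e-9) {
  keyize <- function(df) {
    do.call(paste, lapply(seq_len(k), function(i) {
      sprintf("%.6f", chiscan::wrap_angle(df[[paste0("chi", i)]]))
    }))
  }
  a <- lib_entry[order(keyize(lib_entry)), ]
  b <- oracle_entry[order(keyize(oracle_entry)), ]
  expect_identical(keyize(a), keyize(b))
  expect_equal(a$e_total, b$e_total, tolerance = tol)
}
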