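## Kinematic transform chains: homogeneous-coordinate matrix pipelines
## that map a chi vector to side-chain atom positions. For each rotatable
## bond a world->bond frame transform T_i puts the bond on the local Z
## axis; evaluating at chi applies
##   p' = T_1^-1 Rz(d1) (T_1 T_2^-1) Rz(d2) ... Rz(d_g) (T_g p)
## with d_i = chi_i - chi_i(initial). Every matrix product that does not
## depend on chi (the bracketed frame changes and T_g p) is pre-multiplied
## once when the chain is built, so a scan evaluates each grid point with
## g small matrix products.

#' Build a transform chain for one residue
#'
#' Constructs the cached homogeneous-matrix pipeline that maps a chi
#' vector to the residue's side-chain coordinates. Rotation axes are the
#' chi bonds (proximal atom -> distal atom along the CA-CB-... direction),
#' each aligned to the local Z axis before its rotation is applied.
#' Evaluating the chain at the initial chi vector (measured from the
#' input coordinates) reproduces those coordinates.
#'
#' @param residue Atom tibble holding one residue (backbone and side
#'   chain; columns `atom_name`, `x`, `y`, `z`).
#' @param topo A `chiscan_topology` from [chi_definitions()].
#' @return A `chiscan_chain` object; see [evaluate_coordinates()].
#' @export
build_transform_chain <- function(residue, topo) {
  nm <- residue$atom_name
  xyz <- as.matrix(residue[, c("x", "y", "z")])
  rownames(xyz) <- nm
  coord <- function(a) {
    i <- match(a, nm)
    if (is.na(i)) stop("missing atom ", a, " in ", topo$comp_id,
                       " residue", call. = FALSE)
    xyz[i, ]
  }

  k <- topo$n_chi
  chi0 <- numeric(k)
  frames <- vector("list", k)
  for (i in seq_len(k)) {
    q <- topo$chi_defs[topo$chi_defs$index == i, ]
    p <- lapply(c(q$atom_1, q$atom_2, q$atom_3, q$atom_4), coord)
    chi0[i] <- measure_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    # axis = bond between quadruple atoms 2 and 3; atom 1 fixes the frame
    frames[[i]] <- bond_frame(p[[1]], p[[2]], p[[3]])
  }

  build <- topo$build_order
  miss <- setdiff(build$atom_id, nm)
  if (length(miss) > 0) {
    stop("missing atom(s) ", paste(miss, collapse = ", "), " in ",
         topo$comp_id, " residue", call. = FALSE)
  }

  # cached constant segments
  prefix <- hom_inverse(frames[[1]])
  mids <- if (k > 1) {
    lapply(seq_len(k - 1), function(i) frames[[i]] %*% hom_inverse(frames[[i + 1]]))
  } else {
    list()
  }
  groups <- lapply(seq_len(k), function(g) {
    atoms <- build$atom_id[build$chi_group == g]
    u <- t(hom_apply(frames[[g]], xyz[atoms, , drop = FALSE]))  # 3 x m
    list(atoms = atoms, u = rbind(u, 1))
  })

  structure(list(
    comp_id = topo$comp_id,
    n_chi = k,
    initial_chi = chi0,
    frames = frames,
    prefix = prefix,
    mids = mids,
    groups = groups,
    atom_names = build$atom_id,
    input_xyz = xyz
  ), class = "chiscan_chain")
}

#' Evaluate side-chain coordinates at a chi vector
#'
#' Applies the cached transform chain. Atoms that depend only on
#' `chi_1..chi_j` are unaffected by the values of more distal angles, so
#' partial evaluation (`upto < n_chi`) is exact for the atoms it returns
#' and lets the scanner place atoms step by step.
#'
#' @param chain A `chiscan_chain` from [build_transform_chain()].
#' @param chi Chi vector in degrees (length `chain$n_chi`, or `upto` when
#'   partially evaluating).
#' @param upto Evaluate atom groups 1..`upto` only (default: all).
#' @param cached Use the pre-multiplied constant segments (default);
#'   `FALSE` recomputes every frame product, which must agree exactly.
#' @return Tibble `atom_name`, `chi_group`, `x`, `y`, `z`.
#' @export
evaluate_coordinates <- function(chain, chi, upto = chain$n_chi,
                                 cached = TRUE) {
  if (length(chi) < upto) {
    stop("chi vector has length ", length(chi), " but ", upto,
         " angles are required", call. = FALSE)
  }
  delta <- deg2rad(chi[seq_len(upto)] - chain$initial_chi[seq_len(upto)])
  out_names <- character(); out_groups <- integer(); out_xyz <- NULL
  if (cached) {
    S <- chain$prefix %*% hom_rz(delta[1])
    for (g in seq_len(upto)) {
      if (g > 1) S <- S %*% chain$mids[[g - 1]] %*% hom_rz(delta[g])
      grp <- chain$groups[[g]]
      p <- t(S %*% grp$u)[, 1:3, drop = FALSE]
      out_names <- c(out_names, grp$atoms)
      out_groups <- c(out_groups, rep.int(g, length(grp$atoms)))
      out_xyz <- rbind(out_xyz, p)
    }
  } else {
    for (g in seq_len(upto)) {
      M <- hom_inverse(chain$frames[[1]]) %*% hom_rz(delta[1])
      if (g > 1) {
        for (i in 2:g) {
          M <- M %*% chain$frames[[i - 1]] %*%
            hom_inverse(chain$frames[[i]]) %*% hom_rz(delta[i])
        }
      }
      M <- M %*% chain$frames[[g]]
      grp <- chain$groups[[g]]
      p <- hom_apply(M, chain$input_xyz[grp$atoms, , drop = FALSE])
      out_names <- c(out_names, grp$atoms)
      out_groups <- c(out_groups, rep.int(g, length(grp$atoms)))
      out_xyz <- rbind(out_xyz, p)
    }
  }
  tibble::tibble(atom_name = out_names, chi_group = out_groups,
                 x = out_xyz[, 1], y = out_xyz[, 2], z = out_xyz[, 3])
}

#' Measure the chi angles of a residue
#'
#' @param residue Atom tibble of one residue.
#' @param topo A `chiscan_topology`; defaults to the residue's type.
#' @param ff Parameter set used when `topo` is derived from the residue.
#' @return Numeric vector of chi angles in degrees.
#' @export
measure_chi <- function(residue, topo = NULL, ff = default_parameters()) {
  if (is.null(topo)) topo <- chi_definitions(residue$comp_id[1], ff)
  nm <- residue$atom_name
  xyz <- as.matrix(residue[, c("x", "y", "z")])
  vapply(seq_len(topo$n_chi), function(i) {
    q <- topo$chi_defs[topo$chi_defs$index == i, ]
    idx <- match(c(q$atom_1, q$atom_2, q$atom_3, q$atom_4), nm)
    if (anyNA(idx)) stop("missing chi-defining atom in residue", call. = FALSE)
    measure_dihedral(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ])
  }, numeric(1))
}
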