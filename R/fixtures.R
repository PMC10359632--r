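## Synthetic ideal-geometry structures: single residues, alpha-helical
## peptides, clash scenarios and coordinate noise. These stand in for
## experimental structures so the whole pipeline is testable offline.
##
## Bond lengths and angles are standard stereochemistry-table values
## (Engh & Huber style restraint targets, rounded); symmetric groups
## (ASP, GLU carboxylates, PHE/TYR rings) use identical lengths/angles on
## both branches so the 180-degree chi symmetry is exact.

IDEAL_BACKBONE <- list(
  n_ca = 1.458, ca_c = 1.525, c_o = 1.231, c_n = 1.329, ca_cb = 1.530,
  ang_n_ca_c = 111.2, ang_ca_c_o = 120.8, ang_ca_c_n = 116.2,
  ang_c_n_ca = 121.7, ang_n_ca_cb = 110.5, omega = 180,
  cb_improper = -122.6  # dihedral CB-CA-N-C (L-configuration)
)

## Side-chain Z-matrix rows: atom, frame (A, B, C), bond r to A, angle
## theta at A, and a dihedral that is either a chi slot ("chi1".. "chi4")
## or a fixed value in degrees (rigid branches and rings).
zrow <- function(atom, A, B, C, r, theta, phi) {
  list(atom = atom, A = A, B = B, C = C, r = r, theta = theta, phi = phi)
}

IDEAL_SIDECHAINS <- list(
  ALA = list(),
  GLY = list(),
  SER = list(zrow("OG", "CB", "CA", "N", 1.417, 110.8, "chi1")),
  CYS = list(zrow("SG", "CB", "CA", "N", 1.808, 114.4, "chi1")),
  THR = list(zrow("OG1", "CB", "CA", "N", 1.433, 109.6, "chi1"),
             zrow("CG2", "CB", "CA", "OG1", 1.521, 110.5, -120)),
  VAL = list(zrow("CG1", "CB", "CA", "N", 1.521, 110.5, "chi1"),
             zrow("CG2", "CB", "CA", "CG1", 1.521, 110.5, -122.6)),
  ASP = list(zrow("CG", "CB", "CA", "N", 1.516, 112.6, "chi1"),
             zrow("OD1", "CG", "CB", "CA", 1.249, 118.4, "chi2"),
             zrow("OD2", "CG", "CB", "OD1", 1.249, 118.4, 180)),
  ASN = list(zrow("CG", "CB", "CA", "N", 1.516, 112.6, "chi1"),
             zrow("OD1", "CG", "CB", "CA", 1.231, 120.8, "chi2"),
             zrow("ND2", "CG", "CB", "OD1", 1.328, 116.4, 180)),
  LEU = list(zrow("CG", "CB", "CA", "N", 1.530, 116.3, "chi1"),
             zrow("CD1", "CG", "CB", "CA", 1.521, 110.7, "chi2"),
             zrow("CD2", "CG", "CB", "CD1", 1.521, 110.7, 122.6)),
  ILE = list(zrow("CG1", "CB", "CA", "N", 1.530, 110.4, "chi1"),
             zrow("CG2", "CB", "CA", "CG1", 1.521, 110.5, -122.6),
             zrow("CD1", "CG1", "CB", "CA", 1.513, 113.8, "chi2")),
  HIS = list(zrow("CG", "CB", "CA", "N", 1.497, 113.8, "chi1"),
             zrow("ND1", "CG", "CB", "CA", 1.378, 122.7, "chi2"),
             zrow("CD2", "CG", "CB", "ND1", 1.354, 129.1, 180),
             zrow("CE1", "ND1", "CG", "CB", 1.321, 109.0, 180),
             zrow("NE2", "CD2", "CG", "CB", 1.374, 107.2, 180)),
  # aromatic rings as regular hexagons (bond 1.39, angles 120) so the
  # chemically indistinguishable chi2 flip maps the ring onto itself
  # exactly
  PHE = list(zrow("CG", "CB", "CA", "N", 1.502, 113.8, "chi1"),
             zrow("CD1", "CG", "CB", "CA", 1.390, 120.0, "chi2"),
             zrow("CD2", "CG", "CB", "CD1", 1.390, 120.0, 180),
             zrow("CE1", "CD1", "CG", "CB", 1.390, 120.0, 180),
             zrow("CE2", "CD2", "CG", "CB", 1.390, 120.0, 180),
             zrow("CZ", "CE1", "CD1", "CG", 1.390, 120.0, 0)),
  TYR = list(zrow("CG", "CB", "CA", "N", 1.512, 113.9, "chi1"),
             zrow("CD1", "CG", "CB", "CA", 1.390, 120.0, "chi2"),
             zrow("CD2", "CG", "CB", "CD1", 1.390, 120.0, 180),
             zrow("CE1", "CD1", "CG", "CB", 1.390, 120.0, 180),
             zrow("CE2", "CD2", "CG", "CB", 1.390, 120.0, 180),
             zrow("CZ", "CE1", "CD1", "CG", 1.390, 120.0, 0),
             zrow("OH", "CZ", "CE1", "CD1", 1.377, 120.0, 180)),
  TRP = list(zrow("CG", "CB", "CA", "N", 1.498, 113.6, "chi1"),
             zrow("CD1", "CG", "CB", "CA", 1.365, 126.9, "chi2"),
             zrow("CD2", "CG", "CB", "CD1", 1.433, 126.6, 180),
             zrow("NE1", "CD1", "CG", "CB", 1.374, 110.2, 180),
             zrow("CE2", "CD2", "CG", "CB", 1.409, 107.2, 180),
             zrow("CE3", "CD2", "CG", "CB", 1.398, 133.9, 0),
             zrow("CZ2", "CE2", "CD2", "CG", 1.394, 122.4, 180),
             zrow("CZ3", "CE3", "CD2", "CG", 1.382, 118.6, 180),
             zrow("CH2", "CZ2", "CE2", "CD2", 1.368, 117.5, 0)),
  MET = list(zrow("CG", "CB", "CA", "N", 1.520, 114.1, "chi1"),
             zrow("SD", "CG", "CB", "CA", 1.803, 112.7, "chi2"),
             zrow("CE", "SD", "CG", "CB", 1.791, 100.9, "chi3")),
  GLU = list(zrow("CG", "CB", "CA", "N", 1.520, 114.1, "chi1"),
             zrow("CD", "CG", "CB", "CA", 1.516, 112.6, "chi2"),
             zrow("OE1", "CD", "CG", "CB", 1.249, 118.4, "chi3"),
             zrow("OE2", "CD", "CG", "OE1", 1.249, 118.4, 180)),
  GLN = list(zrow("CG", "CB", "CA", "N", 1.520, 114.1, "chi1"),
             zrow("CD", "CG", "CB", "CA", 1.516, 112.6, "chi2"),
             zrow("OE1", "CD", "CG", "CB", 1.231, 120.8, "chi3"),
             zrow("NE2", "CD", "CG", "OE1", 1.328, 116.4, 180)),
  LYS = list(zrow("CG", "CB", "CA", "N", 1.520, 114.1, "chi1"),
             zrow("CD", "CG", "CB", "CA", 1.520, 111.3, "chi2"),
             zrow("CE", "CD", "CG", "CB", 1.520, 111.3, "chi3"),
             zrow("NZ", "CE", "CD", "CG", 1.489, 111.9, "chi4")),
  ARG = list(zrow("CG", "CB", "CA", "N", 1.520, 114.1, "chi1"),
             zrow("CD", "CG", "CB", "CA", 1.520, 111.3, "chi2"),
             zrow("NE", "CD", "CG", "CB", 1.461, 112.0, "chi3"),
             zrow("CZ", "NE", "CD", "CG", 1.329, 124.2, "chi4"),
             zrow("NH1", "CZ", "NE", "CD", 1.326, 120.0, 0),
             zrow("NH2", "CZ", "NE", "NH1", 1.326, 120.0, 180))
)

FIXTURE_RESIDUES <- names(IDEAL_SIDECHAINS)

## A commonly observed rotamer per type, used by build_helix defaults.
default_chi <- function(comp_id) {
  k <- length(grep("^chi", vapply(IDEAL_SIDECHAINS[[comp_id]],
                                  function(z) as.character(z$phi)[1], "")))
  if (k == 0) return(numeric())
  c(-65, 180, 180, 180)[seq_len(k)]
}

n_chi_of <- function(comp_id) {
  if (!comp_id %in% FIXTURE_RESIDUES) {
    stop("unsupported residue type '", comp_id, "' in fixtures", call. = FALSE)
  }
  sum(grepl("^chi", vapply(IDEAL_SIDECHAINS[[comp_id]],
                           function(z) as.character(z$phi)[1], "")))
}

place_sidechain <- function(coords, comp_id, chi) {
  zm <- IDEAL_SIDECHAINS[[comp_id]]
  for (z in zm) {
    phi <- z$phi
    if (is.character(phi)) {
      idx <- as.integer(sub("chi", "", phi))
      if (idx > length(chi)) stop("chi vector too short for ", comp_id, call. = FALSE)
      phi <- chi[idx]
    }
    coords[[z$atom]] <- place_atom(coords[[z$A]], coords[[z$B]], coords[[z$C]],
                                   z$r, z$theta, phi)
  }
  coords
}

residue_tibble <- function(coords, comp_id, asym_id, seq_id, start_id, model) {
  nm <- names(coords)
  xyz <- do.call(rbind, coords)
  tibble::tibble(
    group = "ATOM",
    atom_id = start_id + seq_along(nm) - 1L,
    element = element_of_atom(comp_id, nm),
    atom_name = nm,
    alt_loc = "",
    comp_id = comp_id,
    asym_id = asym_id,
    seq_id = seq_id,
    x = unname(xyz[, 1]), y = unname(xyz[, 2]), z = unname(xyz[, 3]),
    model_num = model)
}

#' Build a single residue with ideal geometry
#'
#' Constructs one residue (backbone N, CA, C, O, CB plus side chain)
#' from standard bond lengths and angles, with the requested chi angles
#' and backbone psi (the N-CA-C-O dihedral is placed at `psi + 180`).
#' The measured chi angles of the result equal the request exactly.
#'
#' @param type Residue three-letter code (17 chi-bearing types plus GLY
#'   and ALA).
#' @param chi Chi vector in degrees; defaults to a common rotamer.
#' @param phi,psi Backbone dihedrals in degrees (phi only takes effect in
#'   multi-residue fixtures where a preceding residue exists).
#' @param asym_id,seq_id Chain label and residue number of the output.
#' @return An atom tibble (`chiscan_structure`).
#' @export
build_ideal_residue <- function(type, chi = NULL, phi = -57, psi = -47,
                                asym_id = "A", seq_id = 1L) {
  comp <- toupper(type)
  k <- n_chi_of(comp)
  if (is.null(chi)) chi <- default_chi(comp)
  if (length(chi) != k) {
    stop(comp, " needs ", k, " chi angle(s), got ", length(chi), call. = FALSE)
  }
  bb <- IDEAL_BACKBONE
  coords <- list(N = c(0, 0, 0), CA = c(bb$n_ca, 0, 0))
  th <- deg2rad(bb$ang_n_ca_c)
  coords$C <- coords$CA + bb$ca_c * c(-cos(th), sin(th), 0)
  coords$O <- place_atom(coords$C, coords$CA, coords$N, bb$c_o,
                         bb$ang_ca_c_o, wrap_angle(psi + 180))
  if (comp != "GLY") {
    coords$CB <- place_atom(coords$CA, coords$N, coords$C, bb$ca_cb,
                            bb$ang_n_ca_cb, bb$cb_improper)
  }
  coords <- place_sidechain(coords, comp, chi)
  new_structure(residue_tibble(coords, comp, asym_id, seq_id, 1L, 1L))
}

#' Build an ideal alpha-helical peptide
#'
#' Chains residues with ideal backbone geometry at the given phi/psi
#' (alpha-helix by default, giving consecutive CA-CA distances of about
#' 3.8 Angstroms) and places each side chain at its default chi vector
#' unless overridden.
#'
#' @param sequence Character vector of residue codes.
#' @param phi,psi Backbone dihedrals in degrees applied to every residue.
#' @param chi Optional list (one numeric vector per residue) of chi
#'   vectors; `NULL` entries fall back to the per-type default.
#' @param asym_id Chain label.
#' @return An atom tibble (`chiscan_structure`).
#' @export
build_helix <- function(sequence, phi = -57, psi = -47, chi = NULL,
                        asym_id = "A") {
  stopifnot(length(sequence) >= 1)
  sequence <- toupper(sequence)
  for (s in sequence) n_chi_of(s)  # errors on unsupported types
  bb <- IDEAL_BACKBONE
  rows <- list()
  prev <- NULL
  next_id <- 1L
  for (ri in seq_along(sequence)) {
    comp <- sequence[ri]
    if (is.null(prev)) {
      coords <- list(N = c(0, 0, 0), CA = c(bb$n_ca, 0, 0))
      th <- deg2rad(bb$ang_n_ca_c)
      coords$C <- coords$CA + bb$ca_c * c(-cos(th), sin(th), 0)
    } else {
      coords <- list()
      coords$N <- place_atom(prev$C, prev$CA, prev$N, bb$c_n,
                             bb$ang_ca_c_n, psi)
      coords$CA <- place_atom(coords$N, prev$C, prev$CA, bb$n_ca,
                              bb$ang_c_n_ca, bb$omega)
      coords$C <- place_atom(coords$CA, coords$N, prev$C, bb$ca_c,
                             bb$ang_n_ca_c, phi)
    }
    # carbonyl O anti to the next amide nitrogen
    o_ref <- coords$N
    coords$O <- place_atom(coords$C, coords$CA, o_ref, bb$c_o,
                           bb$ang_ca_c_o, wrap_angle(psi + 180))
    if (comp != "GLY") {
      coords$CB <- place_atom(coords$CA, coords$N, coords$C, bb$ca_cb,
                              bb$ang_n_ca_cb, bb$cb_improper)
    }
    ch <- if (!is.null(chi) && length(chi) >= ri && !is.null(chi[[ri]])) {
      chi[[ri]]
    } else {
      default_chi(comp)
    }
    coords <- place_sidechain(coords, comp, ch)
    rows[[ri]] <- residue_tibble(coords, comp, asym_id, ri, next_id, 1L)
    next_id <- next_id + nrow(rows[[ri]])
    prev <- coords
  }
  new_structure(dplyr::bind_rows(rows))
}

#' Add a clash probe at a rotamer's terminal-atom position
#'
#' Places a single carbon atom (as a HETATM in its own chain) exactly at
#' the position the target residue's terminal side-chain atom would take
#' at the given chi vector, guaranteeing a steric clash for that grid
#' cell. A positive `offset` displaces the probe radially away from the
#' residue's CA.
#'
#' @param structure Atom tibble containing the target residue.
#' @param asym_id,seq_id Key of the target residue.
#' @param chi Chi vector (degrees) whose terminal-atom position to block.
#' @param offset Radial displacement of the probe in Angstroms.
#' @param ff Parameter set (chi definitions).
#' @return The structure with one added probe atom.
#' @export
add_clash_probe <- function(structure, asym_id, seq_id, chi, offset = 0,
                            ff = default_parameters()) {
  res <- structure[structure$asym_id == asym_id & structure$seq_id == seq_id, ]
  if (nrow(res) == 0) stop("no residue ", asym_id, ":", seq_id, call. = FALSE)
  topo <- chi_definitions(res$comp_id[1], ff)
  chain <- build_transform_chain(res, topo)
  sc <- evaluate_coordinates(chain, chi)
  term <- unlist(sc[nrow(sc), c("x", "y", "z")])
  ca <- unlist(res[res$atom_name == "CA", c("x", "y", "z")])
  if (offset != 0) term <- term + offset * vunit(term - ca)
  probe <- tibble::tibble(
    group = "HETATM", atom_id = max(structure$atom_id) + 1L,
    element = "C", atom_name = "PRB", alt_loc = "", comp_id = "PRB",
    asym_id = "Z", seq_id = 999L, x = term[1], y = term[2], z = term[3],
    model_num = 1L)
  new_structure(dplyr::bind_rows(structure, probe))
}

#' Apply isotropic Gaussian coordinate noise
#'
#' Displaces every atom by an independent 3-D normal perturbation,
#' emulating experimental coordinate error. Seeded and reproducible;
#' the caller's RNG state is left untouched.
#'
#' @param structure Atom tibble.
#' @param sigma Per-axis standard deviation in Angstroms (>= 0).
#' @param seed Integer seed.
#' @return The perturbed structure.
#' @export
perturb_coordinates <- function(structure, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(structure)
  n <- nrow(structure)
  noise <- with_preserved_seed(seed, matrix(stats::rnorm(3 * n, 0, sigma), n, 3))
  structure$x <- structure$x + noise[, 1]
  structure$y <- structure$y + noise[, 2]
  structure$z <- structure$z + noise[, 3]
  structure
}

## Run code under a temporary RNG state without disturbing the caller's.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
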