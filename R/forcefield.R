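## Force-field parameter handling. All physical constants live in a single
## CIF-style text file (see inst/extdata/parameters.cif); the scan, energy
## and topology modules only ever see the loaded `chiscan_ff` object.

COULOMB_KE <- 332.0637  # kcal * A / (mol * e^2)

#' Load force-field parameters
#'
#' Reads the CIF-style parameter file that holds every physical constant
#' the scanner uses: Pyykko covalent radii (with uncertainties), van der
#' Waals radii, per-element Lennard-Jones classes, per-atom partial
#' charges, hydrogen-bond donor/acceptor roles and well constants,
#' torsion terms, the energy weights `w1..w4`, the smooth-cutoff radii,
#' chi-angle definitions, side-chain build order and the explicit bond
#' list. Absent optional sections fall back to defaults (weights 1.0,
#' cutoffs 2.5/5.0 Angstroms).
#'
#' @param path Path to a parameter file, or a character vector of its
#'   lines. Defaults to the file shipped with the package.
#' @return A `chiscan_ff` object (a named list of tibbles and scalars).
#' @export
load_parameters <- function(path = chiscan_parameter_file()) {
  text <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  blocks <- cif_parse(text)
  if (length(blocks) == 0L) stop("no data block in parameter file", call. = FALSE)
  block <- blocks[[1L]]

  get_loop <- function(cat) {
    lp <- cif_find_loop(block, cat)
    if (is.null(lp)) return(NULL)
    names(lp) <- sub(paste0(cat, "."), "", names(lp), fixed = TRUE)
    tibble::as_tibble(lp)
  }
  get_item <- function(tag, default = NULL) {
    v <- block$items[[tag]]
    if (is.null(v)) return(default)
    as.numeric(v)
  }

  el <- get_loop("_chiscan_element")
  if (is.null(el)) stop("parameter file lacks the _chiscan_element table", call. = FALSE)
  el <- dplyr::mutate(el, dplyr::across(-"symbol", ~ cif_numeric(.x, "element table")))
  if (any(el$covalent_radius <= 0) || any(el$vdw_radius <= 0)) {
    stop("covalent and van der Waals radii must be positive", call. = FALSE)
  }

  weights <- c(w1 = get_item("_chiscan_weights.w1", 1),
               w2 = get_item("_chiscan_weights.w2", 1),
               w3 = get_item("_chiscan_weights.w3", 1),
               w4 = get_item("_chiscan_weights.w4", 1))
  cutoff_start <- get_item("_chiscan_cutoff.start", 2.5)
  cutoff_end <- get_item("_chiscan_cutoff.end", 5.0)
  if (!(cutoff_end > cutoff_start && cutoff_start > 0)) {
    stop("invalid cutoffs: need cutoff_end > cutoff_start > 0 (got ",
         cutoff_start, ", ", cutoff_end, ")", call. = FALSE)
  }

  tor <- get_loop("_chiscan_torsion")
  if (!is.null(tor)) {
    tor <- dplyr::mutate(tor,
      v = cif_numeric(.data$v, "torsion v"),
      n = cif_numeric(.data$n, "torsion n"),
      gamma = cif_numeric(.data$gamma, "torsion gamma"))
    if (any(tor$n <= 0 | tor$n != round(tor$n))) {
      stop("torsion periodicities must be positive integers", call. = FALSE)
    }
  } else {
    tor <- tibble::tibble(key = "default", v = 0, n = 1, gamma = 0)
  }

  chg <- get_loop("_chiscan_charge")
  if (!is.null(chg)) chg$value <- cif_numeric(chg$value, "charge value")
  hba <- get_loop("_chiscan_hbond_atom")
  chi <- get_loop("_chiscan_chi")
  if (!is.null(chi)) chi$index <- as.integer(chi$index)
  build <- get_loop("_chiscan_build")
  if (!is.null(build)) build$chi_group <- as.integer(build$chi_group)
  bonds <- get_loop("_chiscan_bond_list")

  ff <- structure(list(
    elements = el,
    weights = weights,
    cutoff_start = cutoff_start,
    cutoff_end = cutoff_end,
    bond_tolerance = get_item("_chiscan_bond.tolerance", 0.4),
    bond_min_distance = get_item("_chiscan_bond.min_distance", 0.5),
    hbond_epsilon = get_item("_chiscan_hbond.epsilon", 2.0),
    hbond_rmin = get_item("_chiscan_hbond.rmin", 2.9),
    charges = chg %||% tibble::tibble(comp_id = character(),
                                      atom_id = character(), value = numeric()),
    hbond_atoms = hba %||% tibble::tibble(comp_id = character(),
                                          atom_id = character(), role = character()),
    torsions = tor,
    chi = chi %||% tibble::tibble(),
    build = build %||% tibble::tibble(),
    bonds = bonds %||% tibble::tibble()
  ), class = "chiscan_ff")
  validate_ff(ff)
  ff
}

#' Path of the shipped default parameter file
#' @return A file path.
#' @export
chiscan_parameter_file <- function() {
  system.file("extdata", "parameters.cif", package = "chiscan", mustWork = TRUE)
}

the_ff_cache <- new.env(parent = emptyenv())

#' Default force-field parameters (cached)
#' @return A `chiscan_ff` object loaded from the shipped parameter file.
#' @export
default_parameters <- function() {
  if (is.null(the_ff_cache$ff)) the_ff_cache$ff <- load_parameters()
  the_ff_cache$ff
}

## Startup-style self-test: every atom named in the chi/build tables must
## resolve to element, LJ and charge entries, so failures surface at load
## time rather than mid-scan.
validate_ff <- function(ff) {
  if (nrow(ff$build) > 0) {
    for (i in seq_len(nrow(ff$build))) {
      comp <- ff$build$comp_id[i]; atom <- ff$build$atom_id[i]
      elem <- element_of_atom(comp, atom)
      if (!(elem %in% ff$elements$symbol)) {
        stop("element ", elem, " of ", comp, " ", atom,
             " missing from the element table", call. = FALSE)
      }
      if (is.na(ff_charge(ff, comp, atom))) {
        stop("no partial charge for ", comp, " ", atom, call. = FALSE)
      }
    }
  }
  invisible(ff)
}

#' Largest covalent radius known to a parameter set
#'
#' Twice this value is the cell edge used by the bond-detection grid.
#'
#' @param ff A `chiscan_ff` object.
#' @param elements Optional character vector restricting the maximum to
#'   the elements actually present in the structure being processed.
#' @return Radius in Angstroms.
#' @export
largest_covalent_radius <- function(ff, elements = NULL) {
  tbl <- ff$elements
  if (!is.null(elements)) {
    elements <- toupper(elements)
    unknown <- setdiff(elements, tbl$symbol)
    if (length(unknown) > 0) {
      stop("element(s) not in radius table: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    tbl <- tbl[tbl$symbol %in% elements, , drop = FALSE]
  }
  if (nrow(tbl) == 0L) stop("empty covalent radius table", call. = FALSE)
  max(tbl$covalent_radius)
}

## Deduce the element of a named heavy atom of a standard residue.
element_of_atom <- function(comp_id, atom_name) {
  nm <- toupper(atom_name)
  dplyr::case_when(
    nm == "SE" | (startsWith(nm, "SE") & comp_id %in% c("SEC", "MSE")) ~ "SE",
    startsWith(nm, "S") ~ "S",
    startsWith(nm, "N") ~ "N",
    startsWith(nm, "O") ~ "O",
    startsWith(nm, "C") ~ "C",
    startsWith(nm, "H") ~ "H",
    TRUE ~ substr(nm, 1, 1)
  )
}

## Scalar lookups --------------------------------------------------------

ff_element_row <- function(ff, elem) {
  i <- match(toupper(elem), ff$elements$symbol)
  if (anyNA(i)) {
    stop("element(s) not parameterized: ",
         paste(unique(elem[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  ff$elements[i, , drop = FALSE]
}

ff_charge <- function(ff, comp_id, atom_name) {
  tbl <- ff$charges
  out <- numeric(length(atom_name))
  for (k in seq_along(atom_name)) {
    hit <- which(tbl$comp_id == comp_id[k] & tbl$atom_id == atom_name[k])
    if (length(hit) == 0) hit <- which(tbl$comp_id == "*" & tbl$atom_id == atom_name[k])
    out[k] <- if (length(hit) > 0) tbl$value[hit[1]] else NA_real_
  }
  out
}

ff_hbond_role <- function(ff, comp_id, atom_name) {
  tbl <- ff$hbond_atoms
  out <- character(length(atom_name))
  for (k in seq_along(atom_name)) {
    hit <- which(tbl$comp_id == comp_id[k] & tbl$atom_id == atom_name[k])
    if (length(hit) == 0) hit <- which(tbl$comp_id == "*" & tbl$atom_id == atom_name[k])
    out[k] <- if (length(hit) > 0) tbl$role[hit[1]] else "none"
  }
  out
}

## Torsion terms for chi_k of a residue: residue-specific key first, then
## the element pair of the rotating bond, then "default".
ff_torsion_terms <- function(ff, comp_id, chi_idx, elem_a = "C", elem_b = "C") {
  keys <- c(paste0(comp_id, ":", chi_idx),
            paste(sort(c(toupper(elem_a), toupper(elem_b))), collapse = ":"),
            "default")
  for (key in keys) {
    hit <- ff$torsions[ff$torsions$key == key, , drop = FALSE]
    if (nrow(hit) > 0) return(hit)
  }
  tibble::tibble(key = "none", v = 0, n = 1, gamma = 0)
}

## Per-atom parameter table used by the vectorised energy kernels.
## Atoms whose (residue, name) has no charge entry get q = 0 and are
## listed in attr(, "unparameterized") so callers can warn (never drop).
ff_atom_params <- function(ff, comp_id, atom_name, element = NULL) {
  elem <- if (is.null(element)) element_of_atom(comp_id, atom_name) else
    toupper(element)
  er <- ff_element_row(ff, elem)
  role <- ff_hbond_role(ff, comp_id, atom_name)
  q <- ff_charge(ff, comp_id, atom_name)
  unpar <- which(is.na(q))
  q[unpar] <- 0
  out <- tibble::tibble(
    comp_id = comp_id, atom_name = atom_name, element = elem,
    eps = er$lj_epsilon, rmin_half = er$lj_rmin_half, q = q,
    donor = role %in% c("donor", "both"),
    acceptor = role %in% c("acceptor", "both"))
  if (length(unpar) > 0) {
    attr(out, "unparameterized") <- paste(comp_id[unpar], atom_name[unpar])
  }
  out
}

#' Serialize force-field parameters
#'
#' Writes a `chiscan_ff` object back to the CIF-style parameter format;
#' `load_parameters()` on the result is numerically lossless.
#'
#' @param ff A `chiscan_ff` object.
#' @param path Output file path, or `NULL` to return the lines.
#' @return Invisibly, the character vector of lines written.
#' @export
write_parameters <- function(ff, path = NULL) {
  num <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  el <- ff$elements
  lines <- c(
    "data_chiscan_parameters",
    cif_format_loop(data.frame(
      `_chiscan_element.symbol` = el$symbol,
      `_chiscan_element.covalent_radius` = num(el$covalent_radius),
      `_chiscan_element.covalent_radius_error` = num(el$covalent_radius_error),
      `_chiscan_element.vdw_radius` = num(el$vdw_radius),
      `_chiscan_element.lj_epsilon` = num(el$lj_epsilon),
      `_chiscan_element.lj_rmin_half` = num(el$lj_rmin_half),
      check.names = FALSE)),
    paste("_chiscan_weights.w1", num(ff$weights[["w1"]])),
    paste("_chiscan_weights.w2", num(ff$weights[["w2"]])),
    paste("_chiscan_weights.w3", num(ff$weights[["w3"]])),
    paste("_chiscan_weights.w4", num(ff$weights[["w4"]])),
    paste("_chiscan_cutoff.start", num(ff$cutoff_start)),
    paste("_chiscan_cutoff.end", num(ff$cutoff_end)),
    paste("_chiscan_bond.tolerance", num(ff$bond_tolerance)),
    paste("_chiscan_bond.min_distance", num(ff$bond_min_distance)),
    paste("_chiscan_hbond.epsilon", num(ff$hbond_epsilon)),
    paste("_chiscan_hbond.rmin", num(ff$hbond_rmin)),
    cif_format_loop(data.frame(
      `_chiscan_torsion.key` = ff$torsions$key,
      `_chiscan_torsion.v` = num(ff$torsions$v),
      `_chiscan_torsion.n` = num(ff$torsions$n),
      `_chiscan_torsion.gamma` = num(ff$torsions$gamma),
      check.names = FALSE)))
  if (nrow(ff$charges) > 0) {
    lines <- c(lines, cif_format_loop(data.frame(
      `_chiscan_charge.comp_id` = ff$charges$comp_id,
      `_chiscan_charge.atom_id` = ff$charges$atom_id,
      `_chiscan_charge.value` = num(ff$charges$value),
      check.names = FALSE)))
  }
  if (nrow(ff$hbond_atoms) > 0) {
    lines <- c(lines, cif_format_loop(data.frame(
      `_chiscan_hbond_atom.comp_id` = ff$hbond_atoms$comp_id,
      `_chiscan_hbond_atom.atom_id` = ff$hbond_atoms$atom_id,
      `_chiscan_hbond_atom.role` = ff$hbond_atoms$role,
      check.names = FALSE)))
  }
  if (nrow(ff$chi) > 0) {
    lines <- c(lines, cif_format_loop(stats::setNames(
      as.data.frame(ff$chi),
      paste0("_chiscan_chi.", names(ff$chi)))))
  }
  if (nrow(ff$build) > 0) {
    lines <- c(lines, cif_format_loop(stats::setNames(
      as.data.frame(ff$build),
      paste0("_chiscan_build.", names(ff$build)))))
  }
  if (nrow(ff$bonds) > 0) {
    lines <- c(lines, cif_format_loop(stats::setNames(
      as.data.frame(ff$bonds),
      paste0("_chiscan_bond_list.", names(ff$bonds)))))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
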