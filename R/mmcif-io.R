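## PDBx/mmCIF v5 input and output. Structures are tibbles of atom_site
## records (one row per atom, file order preserved); rotamer libraries
## are written as an atom_site category (one model per rotamer) plus a
## _chiscan_rotamer loop holding chi values (degrees) and energy terms.

MANDATORY_ATOM_SITE <- c("group_PDB", "id", "type_symbol", "label_atom_id",
                         "label_alt_id", "label_comp_id", "label_asym_id",
                         "label_seq_id", "Cartn_x", "Cartn_y", "Cartn_z",
                         "pdbx_PDB_model_num")

new_structure <- function(tbl) {
  stopifnot(all(c("group", "atom_id", "element", "atom_name", "alt_loc",
                  "comp_id", "asym_id", "seq_id", "x", "y", "z",
                  "model_num") %in% names(tbl)))
  class(tbl) <- c("chiscan_structure", class(tibble::as_tibble(tbl)))
  tbl
}

#' Read a structure from PDBx/mmCIF
#'
#' Parses the `atom_site` category. All twelve mandatory items
#' (`group_PDB`, `id`, `type_symbol`, `label_atom_id`, `label_alt_id`,
#' `label_comp_id`, `label_asym_id`, `label_seq_id`, `Cartn_x`,
#' `Cartn_y`, `Cartn_z`, `pdbx_PDB_model_num`) must be present; a
#' missing item is a hard error naming it. `auth_*` items, occupancies
#' and B factors are carried through untouched when present; other
#' categories are ignored. Atom order within the file is preserved.
#'
#' @param path File path, a character vector of lines, or a single
#'   string containing the CIF text.
#' @param model Model number to keep; `NULL` (default) keeps the first
#'   model in the file, `NA` keeps all models.
#' @return A `chiscan_structure` tibble with columns `group`, `atom_id`,
#'   `element`, `atom_name`, `alt_loc` (blank for "."), `comp_id`,
#'   `asym_id`, `seq_id`, `x`, `y`, `z`, `model_num`, plus any `auth_*`
#'   passthrough columns.
#' @export
read_structure <- function(path, model = NULL) {
  text <- if (length(path) == 1L && !grepl("\n", path, fixed = TRUE) &&
              file.exists(path)) readLines(path) else path
  blocks <- cif_parse(text)
  atom <- NULL
  for (b in blocks) {
    atom <- cif_find_loop(b, "_atom_site")
    if (!is.null(atom)) break
  }
  if (is.null(atom)) stop("no atom_site category found", call. = FALSE)
  names(atom) <- sub("^_atom_site\\.", "", names(atom))
  missing <- setdiff(MANDATORY_ATOM_SITE, names(atom))
  if (length(missing) > 0) {
    stop("mandatory atom_site item(s) missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    group = atom$group_PDB,
    atom_id = as.integer(cif_numeric(atom$id, "_atom_site.id")),
    element = toupper(atom$type_symbol),
    atom_name = atom$label_atom_id,
    alt_loc = ifelse(atom$label_alt_id %in% c(".", "?"), "", atom$label_alt_id),
    comp_id = atom$label_comp_id,
    asym_id = atom$label_asym_id,
    seq_id = as.integer(cif_numeric(atom$label_seq_id, "_atom_site.label_seq_id")),
    x = cif_numeric(atom$Cartn_x, "_atom_site.Cartn_x"),
    y = cif_numeric(atom$Cartn_y, "_atom_site.Cartn_y"),
    z = cif_numeric(atom$Cartn_z, "_atom_site.Cartn_z"),
    model_num = as.integer(cif_numeric(atom$pdbx_PDB_model_num,
                                       "_atom_site.pdbx_PDB_model_num")))
  if (!all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    stop("non-finite coordinates in atom_site", call. = FALSE)
  }
  auth <- atom[, grepl("^auth_", names(atom)), drop = FALSE]
  if (ncol(auth) > 0) out <- dplyr::bind_cols(out, tibble::as_tibble(auth))
  if (is.null(model)) {
    out <- out[out$model_num == out$model_num[1], , drop = FALSE]
  } else if (!is.na(model)) {
    out <- out[out$model_num == model, , drop = FALSE]
    if (nrow(out) == 0) stop("no atoms in model ", model, call. = FALSE)
  }
  if (anyDuplicated(out[, c("atom_id", "model_num")])) {
    stop("duplicate (id, model) in atom_site", call. = FALSE)
  }
  new_structure(out)
}

atom_site_lines <- function(structure) {
  fmt3 <- function(v) formatC(v, format = "f", digits = 3)
  cif_format_loop(data.frame(
    `_atom_site.group_PDB` = structure$group,
    `_atom_site.id` = structure$atom_id,
    `_atom_site.type_symbol` = structure$element,
    `_atom_site.label_atom_id` = structure$atom_name,
    `_atom_site.label_alt_id` = ifelse(structure$alt_loc == "", ".",
                                       structure$alt_loc),
    `_atom_site.label_comp_id` = structure$comp_id,
    `_atom_site.label_asym_id` = structure$asym_id,
    `_atom_site.label_seq_id` = structure$seq_id,
    `_atom_site.Cartn_x` = fmt3(structure$x),
    `_atom_site.Cartn_y` = fmt3(structure$y),
    `_atom_site.Cartn_z` = fmt3(structure$z),
    `_atom_site.pdbx_PDB_model_num` = structure$model_num,
    check.names = FALSE))
}

#' Write a structure to PDBx/mmCIF
#'
#' @param structure A `chiscan_structure` tibble.
#' @param path Output path, or `NULL` to return the lines.
#' @param block_name Data block name.
#' @return Invisibly, the lines written. Coordinates use 3 decimals.
#' @export
write_structure <- function(structure, path = NULL,
                            block_name = "chiscan_structure") {
  lines <- c(paste0("data_", block_name), "#", atom_site_lines(structure), "#")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write a rotamer library to PDBx/mmCIF
#'
#' Emits one `atom_site` model per rotamer (backbone atoms of the parent
#' residue plus the rotamer's side-chain coordinates; `pdbx_PDB_model_num`
#' is the global rotamer ordinal) together with a `_chiscan_rotamer`
#' loop holding, per rotamer: the residue key, chi angles in degrees,
#' the energy breakdown in force-field units and the accepted flag.
#' The output is re-readable both by [read_structure()] (as plain
#' models) and by [read_library()].
#'
#' @param lib A `rotamer_library` (see [generate_library()]).
#' @param path Output path, or `NULL` to return the lines.
#' @return Invisibly, the lines written.
#' @export
write_library <- function(lib, path = NULL) {
  if (!inherits(lib, "rotamer_library") || nrow(lib) == 0) {
    stop("empty rotamer library", call. = FALSE)
  }
  backbone <- attr(lib, "backbone")
  num <- function(v) formatC(v, format = "f", digits = 6)
  chifmt <- function(v) ifelse(is.na(v), ".", formatC(v, format = "f", digits = 4))
  meta <- data.frame(
    `_chiscan_rotamer.id` = seq_len(nrow(lib)),
    `_chiscan_rotamer.label_asym_id` = lib$asym_id,
    `_chiscan_rotamer.label_seq_id` = lib$seq_id,
    `_chiscan_rotamer.label_alt_id` = ifelse(lib$alt_loc == "", ".", lib$alt_loc),
    `_chiscan_rotamer.label_comp_id` = lib$comp_id,
    `_chiscan_rotamer.rotamer_id` = lib$rotamer_id,
    `_chiscan_rotamer.chi_1` = chifmt(lib$chi1),
    `_chiscan_rotamer.chi_2` = chifmt(lib$chi2),
    `_chiscan_rotamer.chi_3` = chifmt(lib$chi3),
    `_chiscan_rotamer.chi_4` = chifmt(lib$chi4),
    `_chiscan_rotamer.energy_lj` = num(lib$e_lj),
    `_chiscan_rotamer.energy_coulomb` = num(lib$e_coulomb),
    `_chiscan_rotamer.energy_hbond` = num(lib$e_hbond),
    `_chiscan_rotamer.energy_torsion` = num(lib$e_torsion),
    `_chiscan_rotamer.energy_total` = num(lib$e_total),
    `_chiscan_rotamer.accepted` = ifelse(lib$accepted, "yes", "no"),
    `_chiscan_rotamer.is_initial` = ifelse(lib$is_initial, "yes", "no"),
    check.names = FALSE)

  rows <- list()
  next_id <- 1L
  for (r in seq_len(nrow(lib))) {
    sc <- lib$coords[[r]]
    if (is.null(sc) || nrow(sc) == 0 ||
        !all(is.finite(c(sc$x, sc$y, sc$z)))) {
      stop("rotamer ", r, " has missing coordinates", call. = FALSE)
    }
    bb <- backbone[backbone$asym_id == lib$asym_id[r] &
                     backbone$seq_id == lib$seq_id[r] &
                     (backbone$alt_loc == "" |
                        backbone$alt_loc == lib$alt_loc[r]), ]
    res <- tibble::tibble(
      group = "ATOM",
      atom_id = next_id + seq_len(nrow(bb) + nrow(sc)) - 1L,
      element = c(bb$element, element_of_atom(lib$comp_id[r], sc$atom_name)),
      atom_name = c(bb$atom_name, sc$atom_name),
      alt_loc = lib$alt_loc[r],
      comp_id = lib$comp_id[r],
      asym_id = lib$asym_id[r],
      seq_id = lib$seq_id[r],
      x = c(bb$x, sc$x), y = c(bb$y, sc$y), z = c(bb$z, sc$z),
      model_num = r)
    next_id <- next_id + nrow(res)
    rows[[r]] <- res
  }
  atoms <- dplyr::bind_rows(rows)
  scan <- attr(lib, "scan")
  lines <- c("data_chiscan_rotamer_library", "#",
             paste("_chiscan_scan.step", scan$step %||% "."),
             paste("_chiscan_scan.window", scan$window %||% "."),
             "#", cif_format_loop(meta), "#", atom_site_lines(atoms), "#")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a rotamer library written by [write_library()]
#'
#' @param path File path or CIF text.
#' @return A `rotamer_library` tibble.
#' @export
read_library <- function(path) {
  text <- if (length(path) == 1L && !grepl("\n", path, fixed = TRUE) &&
              file.exists(path)) readLines(path) else path
  blocks <- cif_parse(text)
  block <- blocks[[1]]
  meta <- cif_find_loop(block, "_chiscan_rotamer")
  if (is.null(meta)) stop("no _chiscan_rotamer category found", call. = FALSE)
  names(meta) <- sub("^_chiscan_rotamer\\.", "", names(meta))
  atoms <- read_structure(text, model = NA)
  num <- function(col, tag) cif_numeric(col, tag)
  lib <- tibble::tibble(
    asym_id = meta$label_asym_id,
    seq_id = as.integer(meta$label_seq_id),
    alt_loc = ifelse(meta$label_alt_id == ".", "", meta$label_alt_id),
    comp_id = meta$label_comp_id,
    rotamer_id = as.integer(meta$rotamer_id),
    chi1 = num(meta$chi_1, "chi_1"), chi2 = num(meta$chi_2, "chi_2"),
    chi3 = num(meta$chi_3, "chi_3"), chi4 = num(meta$chi_4, "chi_4"),
    e_lj = num(meta$energy_lj, "energy_lj"),
    e_coulomb = num(meta$energy_coulomb, "energy_coulomb"),
    e_hbond = num(meta$energy_hbond, "energy_hbond"),
    e_torsion = num(meta$energy_torsion, "energy_torsion"),
    e_total = num(meta$energy_total, "energy_total"),
    accepted = meta$accepted == "yes",
    is_initial = meta$is_initial == "yes")
  backbone_names <- c("N", "CA", "C", "O", "CB", "OXT")
  lib$coords <- lapply(seq_len(nrow(lib)), function(r) {
    m <- atoms[atoms$model_num == as.integer(meta$id[r]) &
                 !(atoms$atom_name %in% backbone_names), ]
    tibble::tibble(atom_name = m$atom_name, x = m$x, y = m$y, z = m$z)
  })
  # recover each residue's (static) backbone from its first rotamer model
  first_of_res <- !duplicated(lib[, c("asym_id", "seq_id", "alt_loc")])
  backbone <- dplyr::bind_rows(lapply(which(first_of_res), function(r) {
    m <- atoms[atoms$model_num == as.integer(meta$id[r]) &
                 atoms$atom_name %in% backbone_names, ]
    m$model_num <- 1L
    m
  }))
  step <- block$items[["_chiscan_scan.step"]]
  window <- block$items[["_chiscan_scan.window"]]
  new_rotamer_library(lib, backbone = backbone,
                      scan = list(step = if (!is.null(step)) as.numeric(step),
                                  window = if (!is.null(window)) as.numeric(window)))
}

new_rotamer_library <- function(tbl, backbone, scan = list()) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "backbone") <- backbone
  attr(tbl, "scan") <- scan
  class(tbl) <- c("rotamer_library", class(tbl))
  tbl
}
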