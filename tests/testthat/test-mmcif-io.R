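minimal_cif <- function(drop = NULL) {
  items <- c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_seq_id", "Cartn_x", "Cartn_y", "Cartn_z",
             "pdbx_PDB_model_num")
  vals <- c("ATOM", "1", "O", "OG", ".", "SER", "A", "1",
            "1.234", "-2.000", "0.500", "1")
  keep <- !(items %in% drop)
  c("data_test", "loop_",
    paste0("_atom_site.", items[keep]),
    paste(vals[keep], collapse = " "))
}

test_that("a minimal one-atom atom_site loop parses into one residue", {
  st <- read_structure(minimal_cif())
  expect_s3_class(st, "chiscan_structure")
  expect_equal(nrow(st), 1L)
  expect_equal(st$atom_name, "OG")
  expect_equal(st$comp_id, "SER")
  expect_equal(st$x, 1.234)
  expect_equal(st$alt_loc, "")
})

test_that("missing mandatory atom_site items are hard errors naming them", {
  expect_error(read_structure(minimal_cif(drop = "Cartn_z")), "Cartn_z")
  expect_error(read_structure(minimal_cif(drop = "label_seq_id")),
               "label_seq_id")
  expect_error(read_structure(minimal_cif(drop = c("Cartn_x", "Cartn_y"))),
               "Cartn_x.*Cartn_y")
})

test_that("malformed numeric fields error with context", {
  bad <- sub("-2.000", "not-a-number", minimal_cif())
  expect_error(read_structure(bad), "not-a-number")
})

test_that("structure write/read round-trips coordinates and atom order", {
  st <- build_helix(c("SER", "LEU", "ASP"))
  txt <- write_structure(st)
  back <- read_structure(txt)
  expect_equal(nrow(back), nrow(st))
  expect_identical(back$atom_name, st$atom_name)  # order preserved
  expect_identical(back$comp_id, st$comp_id)
  expect_equal(back$x, st$x, tolerance = 1e-3)
  expect_equal(back$y, st$y, tolerance = 1e-3)
  expect_equal(back$z, st$z, tolerance = 1e-3)
})

test_that("model selection defaults to the first model", {
  two_models <- c("data_t", "loop_",
                  paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                          "label_atom_id", "label_alt_id",
                                          "label_comp_id", "label_asym_id",
                                          "label_seq_id", "Cartn_x", "Cartn_y",
                                          "Cartn_z", "pdbx_PDB_model_num")),
                  "ATOM 1 C CA . GLY A 1 0.0 0.0 0.0 1",
                  "ATOM 1 C CA . GLY A 1 5.0 0.0 0.0 2")
  expect_equal(read_structure(two_models)$x, 0)
  expect_equal(read_structure(two_models, model = 2)$x, 5)
  expect_equal(nrow(read_structure(two_models, model = NA)), 2L)
})

test_that("alternate locations are read as distinct scan targets", {
  alt <- c("data_t", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                   "label_atom_id", "label_alt_id",
                                   "label_comp_id", "label_asym_id",
                                   "label_seq_id", "Cartn_x", "Cartn_y",
                                   "Cartn_z", "pdbx_PDB_model_num")),
           "ATOM 1 N N  . SER A 1 0.0 0.0 0.0 1",
           "ATOM 2 O OG A SER A 1 1.0 0.0 0.0 1",
           "ATOM 3 O OG B SER A 1 0.0 1.0 0.0 1")
  st <- read_structure(alt)
  expect_identical(st$alt_loc, c("", "A", "B"))
})

test_that("library write/read round-trips chi and coordinates losslessly", {
  st <- build_helix(c("ALA", "SER", "LEU", "ALA"))
  lib <- generate_library(st, spec = scan_spec(step = 30, window = 10))
  txt <- write_library(lib)
  back <- read_library(txt)
  expect_equal(nrow(back), nrow(lib))
  expect_equal(back$chi1, lib$chi1, tolerance = 1e-2)
  expect_equal(back$chi2, lib$chi2, tolerance = 1e-2)
  expect_equal(back$e_total, lib$e_total, tolerance = 1e-5)
  for (r in seq_len(nrow(lib))) {
    expect_identical(back$coords[[r]]$atom_name, lib$coords[[r]]$atom_name)
    expect_equal(as.matrix(back$coords[[r]][, c("x", "y", "z")]),
                 as.matrix(lib$coords[[r]][, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
  # the library file is also a plain readable structure (one model per
  # rotamer)
  models <- read_structure(txt, model = NA)
  expect_equal(length(unique(models$model_num)), nrow(lib))
})

test_that("a one-rotamer SER library holds exactly its atom rows", {
  st <- build_ideal_residue("SER", chi = -65)
  lib <- generate_library(st, spec = scan_spec(step = 30, window = 0))
  one <- new_rotamer_library(tibble::as_tibble(lib)[1, ],
                             backbone = attr(lib, "backbone"),
                             scan = attr(lib, "scan"))
  txt <- write_library(one)
  atoms <- read_structure(txt)
  # N, CA, C, O, CB backbone plus the OG side chain
  expect_setequal(atoms$atom_name, c("N", "CA", "C", "O", "CB", "OG"))
  expect_equal(nrow(atoms), 6L)
})

test_that("rotamer identifiers in the output are distinct", {
  st <- build_ideal_residue("SER", chi = -65)
  lib <- generate_library(st, spec = scan_spec(step = 30, window = 1e6))
  txt <- write_library(lib)
  back <- read_library(txt)
  expect_gte(nrow(back), 12L)
  expect_false(anyDuplicated(paste(back$rotamer_id, back$seq_id)) > 0)
})

test_that("degenerate library inputs error", {
  st <- build_ideal_residue("SER", chi = -65)
  lib <- generate_library(st, spec = scan_spec(step = 30, window = 5))
  empty <- new_rotamer_library(tibble::as_tibble(lib)[0, ],
                               backbone = attr(lib, "backbone"),
                               scan = attr(lib, "scan"))
  expect_error(write_library(empty), "empty")
  broken <- lib
  broken$coords[[1]] <- broken$coords[[1]][0, ]
  expect_error(write_library(broken), "missing coordinates")
})

test_that("an independent mmCIF reader agrees with ours", {
  py <- Sys.which("python")
  skip_if(py == "", "no python on PATH")
  st <- build_helix(c("SER", "LEU", "ASP"))
  f <- withr::local_tempfile(fileext = ".cif")
  write_structure(st, f)
  code <- paste0(
    "import gemmi\n",
    "s = gemmi.read_structure('", f, "')\n",
    "atoms = [a for m in s for ch in m for r in ch for a in r]\n",
    "print(len(atoms))\n",
    "print(' '.join(a.name for a in atoms))\n",
    "print(' '.join('%.3f' % a.pos.x for a in atoms))\n")
  out <- tryCatch(system2(py, "-", input = code, stdout = TRUE,
                          stderr = FALSE),
                  warning = function(w) character())
  skip_if(length(out) < 3, "gemmi unavailable")
  expect_equal(as.integer(out[1]), nrow(st))
  expect_identical(strsplit(out[2], " ")[[1]], st$atom_name)
  expect_equal(as.numeric(strsplit(out[3], " ")[[1]]), st$x,
               tolerance = 1e-3)
})
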