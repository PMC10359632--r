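test_that("reach radius is the ARG extension plus vdW pair plus cutoff", {
  ff <- default_parameters()
  r <- build_ideal_residue("ARG", chi = c(180, 180, 180, 180))
  ca <- unlist(r[r$atom_name == "CA", c("x", "y", "z")])
  sc <- r[!(r$atom_name %in% c("N", "CA", "C", "O")), ]
  ext <- max(sqrt((sc$x - ca[1])^2 + (sc$y - ca[2])^2 + (sc$z - ca[3])^2))
  v <- max(ff$elements$vdw_radius)
  expect_equal(reach_radius(ff), ext + 2 * v + ff$cutoff_end)
  expect_gt(reach_radius(ff), 7)
  # raising cutoff_end by 1 A raises the reach by exactly 1 A
  ff2 <- ff; ff2$cutoff_end <- ff$cutoff_end + 1
  expect_equal(reach_radius(ff2), reach_radius(ff) + 1)
})

test_that("an isolated residue's environment is its own backbone", {
  st <- build_ideal_residue("SER", chi = -65)
  env <- select_environment(st, "A", 1L)
  expect_setequal(env$atom_name, c("N", "CA", "C", "O", "CB"))
  st_noca <- st[st$atom_name != "CA", ]
  expect_error(select_environment(st_noca, "A", 1L), "CA")
})

test_that("environment selection equals brute-force distance filtering", {
  st <- build_helix(rep(c("ALA", "LEU", "SER", "GLU", "LYS"), 10))
  ff <- default_parameters()
  reach <- reach_radius(ff)
  mainchain <- c("N", "CA", "C", "O", "OXT", "CB")
  for (seq_id in c(3L, 25L, 48L)) {
    env <- select_environment(st, "A", seq_id, reach = reach, ff = ff)
    ca <- unlist(st[st$asym_id == "A" & st$seq_id == seq_id &
                      st$atom_name == "CA", c("x", "y", "z")])
    d <- sqrt((st$x - ca[1])^2 + (st$y - ca[2])^2 + (st$z - ca[3])^2)
    own <- st$seq_id == seq_id
    want <- which((d <= reach & !own & st$atom_name %in% mainchain) |
                    (own & st$atom_name %in% mainchain))
    expect_setequal(env$.row, want)
    # side-chain atoms of other residues never appear
    expect_false(any(!(env$atom_name %in% mainchain) &
                       env$seq_id != seq_id))
  }
})

test_that("SER with only its own backbone keeps all grid points at a large window", {
  st <- build_ideal_residue("SER", chi = -65)
  lib <- generate_library(st, spec = scan_spec(step = 30, window = 1e6,
                                               include_initial = FALSE))
  expect_equal(nrow(lib), 12L)
  expect_setequal(lib$chi1, seq(-180, 150, by = 30))
})

test_that("a probe on the OG position removes that grid cell", {
  st <- build_ideal_residue("SER", chi = -65)
  probed <- add_clash_probe(st, "A", 1L, chi = 60)
  lib <- generate_library(probed, spec = scan_spec(step = 30, window = 5))
  expect_false(60 %in% lib$chi1)
  clean <- generate_library(st, spec = scan_spec(step = 30, window = 5))
  expect_true(60 %in% clean$chi1 || nrow(clean) < 12)
  # far-away probe removes nothing
  far <- add_clash_probe(st, "A", 1L, chi = 60, offset = 10)
  lib_far <- generate_library(far, spec = scan_spec(step = 30, window = 5))
  expect_setequal(lib_far$chi1, clean$chi1)
})

test_that("DEE returns exactly the exhaustively accepted set", {
  st <- build_helix(c("ALA", "SER", "VAL", "LEU", "ALA", "ASP", "THR"))
  for (target in c(2L, 4L, 6L)) {
    spec <- scan_spec(step = 30, window = 5)
    lib <- generate_library(st, residues = paste0("A:", target), spec = spec)
    k <- chi_definitions(lib$comp_id[1])$n_chi
    want <- oracle_scan(st, "A", target, step = 30, window = 5)
    expect_same_rotamer_set(lib, want, k, tol = 1e-9)
  }
})

test_that("disabling DEE changes nothing (prune admissibility)", {
  st <- build_helix(c("ALA", "MET", "GLU", "ALA"))
  a <- generate_library(st, spec = scan_spec(step = 45, window = 5, dee = TRUE))
  b <- generate_library(st, spec = scan_spec(step = 45, window = 5, dee = FALSE))
  expect_equal(a[, c("comp_id", "chi1", "chi2", "chi3")],
               b[, c("comp_id", "chi1", "chi2", "chi3")],
               ignore_attr = TRUE)
  expect_equal(a$e_total, b$e_total, tolerance = 1e-12)
})

test_that("acceptance window filters inclusively and sorts by energy", {
  rec <- tibble::tibble(
    asym_id = "A", seq_id = 1L, alt_loc = "", comp_id = "SER",
    chi1 = c(0, 30, 60), chi2 = NA_real_, chi3 = NA_real_, chi4 = NA_real_,
    e_lj = 0, e_coulomb = 0, e_hbond = 0, e_torsion = 0,
    e_total = c(1, 0, 10), is_initial = FALSE,
    coords = list(tibble::tibble()))
  kept <- accept_rotamers(rec, window = 5)
  expect_equal(kept$e_total, c(0, 1))
  expect_equal(kept$chi1, c(30, 0))
  # window 0 keeps only the minimum-energy records (boundary inclusive)
  tie <- rec; tie$e_total <- c(0, 0, 3)
  kept0 <- accept_rotamers(tie, window = 0)
  expect_equal(nrow(kept0), 2L)
  expect_equal(kept0$chi1, c(0, 30))  # energy ties break lexicographically
  all_equal <- rec; all_equal$e_total <- c(2, 2, 2)
  expect_equal(nrow(accept_rotamers(all_equal, window = 0)), 3L)
  expect_error(accept_rotamers(rec[0, ], 5), "at least one")
})

test_that("widening the window never removes an accepted rotamer", {
  st <- build_helix(c("ALA", "LEU", "ALA"))
  prev <- NULL
  for (w in c(0, 1, 3, 8, 20)) {
    lib <- generate_library(st, spec = scan_spec(step = 30, window = w))
    keys <- paste(lib$chi1, lib$chi2)
    if (!is.null(prev)) expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("an observed on-grid conformation survives its own scan", {
  st <- build_helix(c("ALA", "SER", "ALA"),
                    chi = list(NULL, -60, NULL))
  lib <- generate_library(st, spec = scan_spec(step = 30, window = 1e6,
                                               include_initial = FALSE))
  expect_true(any(abs(angle_diff(lib$chi1, -60)) < 1e-9))
  # with injection, the off-grid observed chi is present too
  st2 <- build_helix(c("ALA", "SER", "ALA"), chi = list(NULL, -47, NULL))
  lib2 <- generate_library(st2, spec = scan_spec(step = 30, window = 1e6))
  expect_true(any(abs(angle_diff(lib2$chi1, -47)) < 1e-6 & lib2$is_initial))
})

test_that("half-range symmetric scans unfold onto the full scan", {
  for (tp in c("ASP", "PHE")) {
    k <- chi_definitions(tp)$n_chi
    st <- build_ideal_residue(tp, chi = c(-65, 30)[seq_len(k)])
    full <- generate_library(st, spec = scan_spec(step = 30, window = 1e6,
                                                  include_initial = FALSE))
    red <- generate_library(st, spec = scan_spec(step = 30, window = 1e6,
                                                 symmetry_reduced = TRUE,
                                                 include_initial = FALSE))
    expect_equal(nrow(red), nrow(full) / 2)
    keyize <- function(c1, c2) paste(round(wrap_angle(c1), 6),
                                     round(wrap_angle(c2), 6))
    fe <- setNames(full$e_total, keyize(full$chi1, full$chi2))
    base <- fe[keyize(red$chi1, red$chi2)]
    flip <- fe[keyize(red$chi1, red$chi2 + 180)]
    expect_equal(red$e_total, unname(base), tolerance = 1e-9)
    expect_equal(red$e_total, unname(flip), tolerance = 1e-9)
  }
})

test_that("ASN chi2 is always scanned over the full range", {
  st <- build_ideal_residue("ASN", chi = c(-65, 30))
  red <- generate_library(st, spec = scan_spec(step = 30, window = 1e6,
                                               symmetry_reduced = TRUE,
                                               include_initial = FALSE))
  expect_equal(nrow(red), 144L)
  expect_true(any(red$chi2 > 90) && any(red$chi2 < -90))
})
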