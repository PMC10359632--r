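test_that("dihedral measurement follows the IUPAC sign convention", {
  expect_equal(measure_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                c(1, 1, 0)), 0)
  expect_equal(measure_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                c(1, -1, 0)), 180)
  expect_equal(measure_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                c(1, 0, 1)), 90)
  # reversal invariance
  set.seed(3)
  for (i in 1:20) {
    p <- lapply(1:4, function(.) runif(3, -2, 2))
    d1 <- tryCatch(measure_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                   error = function(e) NA)
    if (is.na(d1)) next
    expect_equal(measure_dihedral(p[[4]], p[[3]], p[[2]], p[[1]]), d1)
  }
  expect_error(measure_dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                                c(1, 1, 0)), "degenerate")
  expect_error(measure_dihedral(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0),
                                c(-1, 0, 0)), "collinear")
})

test_that("evaluating a chain at its initial chi reproduces the input", {
  for (tp in c("SER", "LEU", "MET", "LYS", "TRP")) {
    r <- build_ideal_residue(tp)
    topo <- chi_definitions(tp)
    chain <- build_transform_chain(r, topo)
    out <- evaluate_coordinates(chain, chain$initial_chi)
    ref <- as.matrix(r[match(out$atom_name, r$atom_name), c("x", "y", "z")])
    expect_lt(max(abs(as.matrix(out[, c("x", "y", "z")]) - ref)), 1e-6)
    # 360-degree periodicity
    out2 <- evaluate_coordinates(chain, chain$initial_chi + 360)
    expect_lt(max(abs(as.matrix(out2[, c("x", "y", "z")]) -
                        as.matrix(out[, c("x", "y", "z")]))), 1e-6)
  }
})

test_that("set-then-measure returns the requested chi", {
  r <- build_ideal_residue("SER", chi = -60)
  topo <- chi_definitions("SER")
  chain <- build_transform_chain(r, topo)
  for (target in c(60, -120, 175, 0)) {
    out <- evaluate_coordinates(chain, target)
    p <- function(a) unlist(r[r$atom_name == a, c("x", "y", "z")])
    got <- measure_dihedral(p("N"), p("CA"), p("CB"),
                            unlist(out[1, c("x", "y", "z")]))
    expect_equal(got, target, tolerance = 1e-6)
  }
})

test_that("a 10-degree chi change moves the distal atom by the chord length", {
  # artificial sp3 fragment: bond 1.54 A, angle 109.47 deg
  N <- c(0, 1.45, 0); CA <- c(0, 0, 0)
  CB <- place_atom(CA, N, c(1, 2, 0), 1.54, 109.47, -120)
  OG <- place_atom(CB, CA, N, 1.54, 109.47, 60)
  frag <- tibble::tibble(
    group = "ATOM", atom_id = 1:4, element = c("N", "C", "C", "O"),
    atom_name = c("N", "CA", "CB", "OG"), alt_loc = "", comp_id = "SER",
    asym_id = "A", seq_id = 1L,
    x = c(N[1], CA[1], CB[1], OG[1]), y = c(N[2], CA[2], CB[2], OG[2]),
    z = c(N[3], CA[3], CB[3], OG[3]), model_num = 1L)
  chain <- build_transform_chain(frag, chi_definitions("SER"))
  a <- evaluate_coordinates(chain, 60)
  b <- evaluate_coordinates(chain, 70)
  moved <- sqrt(sum((unlist(a[1, c("x", "y", "z")]) -
                       unlist(b[1, c("x", "y", "z")]))^2))
  expected <- 2 * 1.54 * sin(109.47 * pi / 180) * sin(5 * pi / 180)
  expect_equal(moved, expected, tolerance = 1e-9)
  expect_equal(round(expected, 4), 0.2531)
})

test_that("chain evaluation matches the axis-angle oracle on random chi", {
  set.seed(11)
  for (tp in c("SER", "ASP", "ILE", "MET", "LYS", "ARG", "TRP")) {
    r <- build_ideal_residue(tp)
    topo <- chi_definitions(tp)
    chain <- build_transform_chain(r, topo)
    for (rep in 1:5) {
      chi <- runif(topo$n_chi, -180, 180)
      got <- evaluate_coordinates(chain, chi)
      want <- oracle_sidechain_coords(r, topo, chi)
      idx <- match(got$atom_name, want$atom_name)
      expect_lt(max(abs(as.matrix(got[, c("x", "y", "z")]) -
                          as.matrix(want[idx, c("x", "y", "z")]))), 1e-6)
    }
  }
})

test_that("chi rotation never stretches bonds or bends angles", {
  set.seed(5)
  r <- build_ideal_residue("LYS")
  topo <- chi_definitions("LYS")
  chain <- build_transform_chain(r, topo)
  bonds <- detect_bonds(r)
  blen <- function(st) {
    xyz <- as.matrix(st[, c("x", "y", "z")])
    sqrt(rowSums((xyz[bonds$i, ] - xyz[bonds$j, ])^2))
  }
  ref <- blen(r)
  for (rep in 1:10) {
    chi <- runif(4, -180, 180)
    out <- evaluate_coordinates(chain, chi)
    st <- r
    idx <- match(out$atom_name, st$atom_name)
    st$x[idx] <- out$x; st$y[idx] <- out$y; st$z[idx] <- out$z
    expect_lt(max(abs(blen(st) - ref)), 1e-6)
    # CA-CB-CG angle (both atoms static/moving across the chi1 bond)
    p <- function(a) unlist(st[st$atom_name == a, c("x", "y", "z")])
    ang <- acos(sum((p("CA") - p("CB")) * (p("CG") - p("CB"))) /
                  (sqrt(sum((p("CA") - p("CB"))^2)) *
                     sqrt(sum((p("CG") - p("CB"))^2)))) * 180 / pi
    expect_equal(ang, 114.1, tolerance = 1e-4)
  }
})

test_that("caching is semantically invisible", {
  set.seed(13)
  r <- build_ideal_residue("GLU")
  chain <- build_transform_chain(r, chi_definitions("GLU"))
  for (rep in 1:5) {
    chi <- runif(3, -180, 180)
    a <- evaluate_coordinates(chain, chi, cached = TRUE)
    b <- evaluate_coordinates(chain, chi, cached = FALSE)
    expect_equal(as.matrix(a[, c("x", "y", "z")]),
                 as.matrix(b[, c("x", "y", "z")]), tolerance = 1e-12)
  }
})

test_that("partial evaluation equals the matching slice of the full one", {
  r <- build_ideal_residue("LYS")
  chain <- build_transform_chain(r, chi_definitions("LYS"))
  chi <- c(55, -170, 80, 20)
  full <- evaluate_coordinates(chain, chi)
  for (g in 1:3) {
    part <- evaluate_coordinates(chain, chi[seq_len(g)], upto = g)
    ref <- full[full$chi_group <= g, ]
    expect_equal(as.matrix(part[, c("x", "y", "z")]),
                 as.matrix(ref[, c("x", "y", "z")]), tolerance = 1e-12)
  }
  # atoms governed by chi_1..chi_j are unchanged when distal angles vary
  alt <- evaluate_coordinates(chain, c(55, -170, 80, 120))
  expect_equal(as.matrix(alt[alt$chi_group <= 3, c("x", "y", "z")]),
               as.matrix(full[full$chi_group <= 3, c("x", "y", "z")]),
               tolerance = 1e-12)
})

test_that("dimension and atom errors are informative", {
  r <- build_ideal_residue("LYS")
  chain <- build_transform_chain(r, chi_definitions("LYS"))
  expect_error(evaluate_coordinates(chain, c(1, 2)), "length")
  incomplete <- r[r$atom_name != "CD", ]
  expect_error(build_transform_chain(incomplete, chi_definitions("LYS")),
               "CD")
})
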