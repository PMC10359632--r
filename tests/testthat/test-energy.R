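mk_atom <- function(comp, name, pos, elem = NULL) {
  tibble::tibble(group = "ATOM", atom_id = 1L,
                 element = elem %||% substr(name, 1, 1), atom_name = name,
                 alt_loc = "", comp_id = comp, asym_id = "A", seq_id = 1L,
                 x = pos[1], y = pos[2], z = pos[3], model_num = 1L)
}

test_that("the cosine switch is 1, 1/2 and 0 at start, midpoint and end", {
  expect_equal(cutoff_factor(2.5, 2.5, 5), 1)
  expect_equal(cutoff_factor(3.75, 2.5, 5), 0.5)
  expect_equal(cutoff_factor(5, 2.5, 5), 0)
  expect_equal(cutoff_factor(1, 2.5, 5), 1)
  expect_equal(cutoff_factor(9, 2.5, 5), 0)
  r <- seq(2.5, 5, by = 0.01)
  q <- cutoff_factor(r, 2.5, 5)
  expect_true(all(diff(q) <= 0))          # monotone decrease
  expect_true(all(q >= 0 & q <= 1))
})

test_that("LJ equals -eps at rmin and crosses zero at sigma", {
  ff <- default_parameters()
  ff$cutoff_start <- 20; ff$cutoff_end <- 30  # pair well inside the cutoff
  cpar <- ff_atom_params(ff, "LEU", "CG")
  rmin <- 2 * cpar$rmin_half
  eps <- cpar$eps
  e <- pair_energy(mk_atom("LEU", "CG", c(0, 0, 0)),
                   mk_atom("LEU", "CD1", c(rmin, 0, 0)), ff)
  expect_equal(unname(e["lj"]), -eps, tolerance = 1e-12)
  sigma <- rmin / 2^(1 / 6)
  e0 <- pair_energy(mk_atom("LEU", "CG", c(0, 0, 0)),
                    mk_atom("LEU", "CD1", c(sigma, 0, 0)), ff)
  expect_equal(unname(e0["lj"]), 0, tolerance = 1e-10)
})

test_that("all nonbonded terms vanish at and beyond cutoff_end", {
  ff <- default_parameters()
  e <- pair_energy(mk_atom("ASP", "OD1", c(0, 0, 0)),
                   mk_atom("LYS", "NZ", c(ff$cutoff_end, 0, 0)), ff)
  expect_identical(unname(e), c(0, 0, 0))
  e2 <- pair_energy(mk_atom("ASP", "OD1", c(0, 0, 0)),
                    mk_atom("LYS", "NZ", c(7.5, 0, 0)), ff)
  expect_identical(unname(e2), c(0, 0, 0))
})

test_that("Coulomb matches the closed form k_e q1 q2 / r", {
  ff <- default_parameters()
  ff$cutoff_start <- 10; ff$cutoff_end <- 20
  ff$charges <- tibble::tibble(comp_id = c("XXA", "XXB"),
                               atom_id = c("C1", "C2"),
                               value = c(0.5, -0.5))
  ff$hbond_atoms <- ff$hbond_atoms[0, ]
  e <- pair_energy(mk_atom("XXA", "C1", c(0, 0, 0), elem = "C"),
                   mk_atom("XXB", "C2", c(3, 0, 0), elem = "C"), ff)
  expect_equal(unname(e["coulomb"]), -332.0637 * 0.25 / 3.0, tolerance = 1e-12)
})

test_that("the 12-10 hydrogen-bond well applies to donor-acceptor pairs", {
  ff <- default_parameters()
  ff$cutoff_start <- 10; ff$cutoff_end <- 20
  don <- mk_atom("LYS", "NZ", c(0, 0, 0))
  acc <- mk_atom("ASP", "OD1", c(ff$hbond_rmin, 0, 0))
  e <- pair_energy(don, acc, ff)
  expect_equal(unname(e["hbond"]), -ff$hbond_epsilon, tolerance = 1e-12)
  # two plain carbons: no hydrogen-bond term
  e2 <- pair_energy(mk_atom("LEU", "CG", c(0, 0, 0)),
                    mk_atom("LEU", "CD1", c(2.9, 0, 0)), ff)
  expect_identical(unname(e2["hbond"]), 0)
})

test_that("coincident atoms are a hard error", {
  expect_error(pair_energy(mk_atom("LEU", "CG", c(1, 1, 1)),
                           mk_atom("LEU", "CD1", c(1, 1, 1))), "zero")
})

test_that("torsion energy follows (V/2)(1 + cos(n chi - gamma))", {
  terms <- tibble::tibble(v = 1, n = 3, gamma = 0)
  expect_equal(torsion_energy(60, terms), 0, tolerance = 1e-12)
  expect_equal(torsion_energy(0, terms), 1, tolerance = 1e-12)
  expect_equal(torsion_energy(180, terms), 0, tolerance = 1e-12)
  expect_equal(torsion_energy(120, terms), 1, tolerance = 1e-12)
  multi <- tibble::tibble(v = c(1, 0.5), n = c(3, 2), gamma = c(0, 180))
  expect_equal(torsion_energy(90, multi),
               0.5 * (1 + cos(pi * 270 / 180)) +
                 0.25 * (1 + cos(pi * (180 - 180) / 180)),
               tolerance = 1e-12)
  expect_error(torsion_energy(10, tibble::tibble(v = 1, n = 0, gamma = 0)),
               "positive")
})

test_that("pairwise-distributed torsion parts sum exactly to the closed form", {
  terms <- tibble::tibble(v = c(1.3, 0.4), n = c(3, 2), gamma = c(0, 180))
  for (chi in c(-171, -60, 0, 33, 120)) {
    for (m in c(1, 2, 4, 9)) {
      parts <- distribute_torsion(chi, terms, m)
      expect_length(parts, m)
      expect_identical(sum(parts), torsion_energy(chi, terms))
    }
  }
})

test_that("the total obeys the weighted linear combination", {
  ff <- default_parameters()
  st <- build_ideal_residue("ASP", chi = c(-65, 20))
  pairs <- tibble::tibble(i = c(1, 1, 2), j = c(5, 6, 7))
  tors <- tibble::tibble(chi = c(-65, 20),
                         terms = list(tibble::tibble(v = 1.4, n = 3, gamma = 0),
                                      tibble::tibble(v = 0.5, n = 2, gamma = 180)))
  eb <- total_energy(st, pairs, tors, ff)
  expect_equal(eb$total,
               ff$weights[["w1"]] * eb$lj_sum +
                 ff$weights[["w2"]] * eb$coulomb_sum +
                 ff$weights[["w3"]] * eb$hbond_sum +
                 ff$weights[["w4"]] * eb$torsion_sum,
               tolerance = 1e-9)
  # all weights zero -> zero total
  ff0 <- ff; ff0$weights[] <- 0
  expect_equal(total_energy(st, pairs, tors, ff0)$total, 0)
  # doubling w1 doubles the LJ part of the total
  ff2 <- ff; ff2$weights[["w1"]] <- 2 * ff$weights[["w1"]]
  eb2 <- total_energy(st, pairs, tors, ff2)
  expect_equal(eb2$total - eb$total, ff$weights[["w1"]] * eb$lj_sum,
               tolerance = 1e-9)
  # singleton sum equals pair_energy directly
  one <- total_energy(st, tibble::tibble(i = 1L, j = 5L), NULL, ff)
  pe <- pair_energy(st[1, ], st[5, ], ff)
  expect_equal(one$lj_sum, unname(pe["lj"]), tolerance = 1e-12)
})

test_that("energy is invariant under global rigid motion", {
  ff <- default_parameters()
  st <- build_ideal_residue("GLU", chi = c(-65, 170, 20))
  pairs <- tidyr::crossing(i = 1:4, j = 6:9)
  e1 <- total_energy(st, pairs, NULL, ff)$total
  R <- rot_axis_angle(c(1, 2, 3), 77)
  xyz <- as.matrix(st[, c("x", "y", "z")]) %*% t(R)
  st2 <- st
  st2$x <- xyz[, 1] + 5; st2$y <- xyz[, 2] - 3; st2$z <- xyz[, 3] + 11
  e2 <- total_energy(st2, pairs, NULL, ff)$total
  expect_equal(e2, e1, tolerance = 1e-9)
})

test_that("summation order does not change the total", {
  ff <- default_parameters()
  st <- build_helix(c("ASP", "LYS", "GLU"))
  pairs <- tidyr::crossing(i = 1:8, j = 12:20)
  e1 <- total_energy(st, pairs, NULL, ff)$total
  set.seed(9)
  for (rep in 1:3) {
    e2 <- total_energy(st, pairs[sample(nrow(pairs)), ], NULL, ff)$total
    expect_identical(e2, e1)
  }
})

test_that("energy is C1-continuous across the switching boundaries", {
  ff <- default_parameters()
  a <- mk_atom("LEU", "CG", c(0, 0, 0))
  e_at <- function(d) sum(pair_energy(a, mk_atom("LEU", "CD1", c(d, 0, 0)),
                                      ff))
  h <- 1e-6
  for (r0 in c(ff$cutoff_start, ff$cutoff_end)) {
    d_left <- (e_at(r0) - e_at(r0 - h)) / h
    d_right <- (e_at(r0 + h) - e_at(r0)) / h
    expect_lt(abs(d_left - d_right), 1e-3 * (1 + abs(d_left)))
  }
  # value continuity: the largest step shrinks in proportion to the grid
  max_jump <- function(h) {
    max(vapply(c(ff$cutoff_start, ff$cutoff_end), function(r0) {
      r <- seq(r0 - 0.02, r0 + 0.02, by = h)
      max(abs(diff(vapply(r, e_at, numeric(1)))))
    }, numeric(1)))
  }
  expect_lt(max_jump(1e-4), max_jump(1e-3) / 5)
})
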