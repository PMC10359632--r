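## Weight calibration: global-best particle swarm optimisation of the
## energy weights (and optionally torsion barriers) minimising the mean
## best-case RMSD of generated rotamers against reference structures.

#' Calibration objective: mean bcRMSD over reference residues
#'
#' Generates a rotamer library for every reference structure under the
#' candidate parameters and averages the best-case RMSD over all
#' reference residues. References whose observed conformations are
#' energy minima under the parameters give an objective of zero.
#'
#' @param params Numeric vector of candidate values, named per
#'   `param_names`.
#' @param references List of reference entries, each a list with
#'   `structure` (atom tibble) and optional `residues` (selector as in
#'   [generate_library()]).
#' @param param_names Which parameters the vector sets; any of
#'   `"w1".."w4"` (energy weights) and `"torsion_scale"` (multiplies
#'   every torsion barrier).
#' @param spec Scan spec used during calibration; a coarse 30-degree
#'   step keeps the objective tractable.
#' @param ff Base parameter set the candidates modify.
#' @param benchmarking Passed to [evaluate_library()].
#' @return Mean bcRMSD in Angstroms.
#' @export
calibration_objective <- function(params, references,
                                  param_names = c("w1", "w2", "w3", "w4"),
                                  spec = scan_spec(step = 30, window = 0),
                                  ff = default_parameters(),
                                  benchmarking = FALSE) {
  stopifnot(length(params) == length(param_names), length(references) > 0)
  ff2 <- ff
  for (i in seq_along(param_names)) {
    pn <- param_names[i]
    if (pn %in% c("w1", "w2", "w3", "w4")) {
      ff2$weights[[pn]] <- params[i]
    } else if (pn == "torsion_scale") {
      ff2$torsions$v <- ff$torsions$v * params[i]
    } else {
      stop("unknown calibration parameter '", pn, "'", call. = FALSE)
    }
  }
  vals <- unlist(lapply(references, function(ref) {
    lib <- tryCatch(
      generate_library(ref$structure, residues = ref$residues, spec = spec,
                       ff = ff2),
      error = function(e) stop("scan failed on a reference residue: ",
                               conditionMessage(e), call. = FALSE))
    ev <- evaluate_library(ref$structure, lib, benchmarking = benchmarking,
                           ff = ff2)
    ev$bcrmsd
  }))
  mean(vals)
}

#' Global-best particle swarm optimisation
#'
#' Standard gbest PSO with inertia and cognitive/social attraction,
#' positions clamped to the bounds. Deterministic for a fixed seed; the
#' caller's RNG state is preserved. A particle whose objective is
#' non-finite is re-drawn uniformly inside the bounds (and the event
#' counted).
#'
#' @param objective Function mapping a parameter vector to a scalar.
#' @param lower,upper Numeric bounds (finite, `lower < upper`).
#' @param n_particles Swarm size.
#' @param iterations Iteration budget (>= 1).
#' @param inertia,cognitive,social PSO coefficients (defaults are the
#'   standard constriction-equivalent 0.72 / 1.49 / 1.49).
#' @param seed Integer RNG seed.
#' @return A `chiscan_pso` list: `par` (best position), `value` (best
#'   objective), `trace` (per-iteration best objective, non-increasing),
#'   `resets` (non-finite events), `seed`.
#' @export
pso_fit <- function(objective, lower, upper, n_particles = 30,
                    iterations = 200, inertia = 0.72, cognitive = 1.49,
                    social = 1.49, seed = 1L) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(lower < upper),
            n_particles >= 1, iterations >= 1)
  d <- length(lower)
  span <- upper - lower
  with_preserved_seed(seed, {
    pos <- matrix(stats::runif(n_particles * d, rep(lower, each = n_particles),
                               rep(upper, each = n_particles)),
                  n_particles, d)
    vel <- matrix(stats::runif(n_particles * d, -rep(span, each = n_particles),
                               rep(span, each = n_particles)) / 2,
                  n_particles, d)
    resets <- 0L
    evaluate <- function(x) {
      v <- objective(x)
      if (!is.finite(v)) NA_real_ else v
    }
    fit <- apply(pos, 1, evaluate)
    while (anyNA(fit)) {
      bad <- which(is.na(fit))
      resets <- resets + length(bad)
      pos[bad, ] <- matrix(stats::runif(length(bad) * d,
                                        rep(lower, each = length(bad)),
                                        rep(upper, each = length(bad))),
                           length(bad), d)
      fit[bad] <- apply(pos[bad, , drop = FALSE], 1, evaluate)
    }
    pbest <- pos; pbest_fit <- fit
    g <- which.min(fit)
    gbest <- pos[g, ]; gbest_fit <- fit[g]
    trace <- numeric(iterations)
    for (it in seq_len(iterations)) {
      r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
      r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
      vel <- inertia * vel +
        cognitive * r1 * (pbest - pos) +
        social * r2 * sweep(pos, 2, gbest, function(p, gb) gb - p)
      pos <- pos + vel
      # clamp to bounds
      for (j in seq_len(d)) {
        lo <- pos[, j] < lower[j]; hi <- pos[, j] > upper[j]
        pos[lo, j] <- lower[j]; pos[hi, j] <- upper[j]
        vel[lo | hi, j] <- 0
      }
      fit <- apply(pos, 1, evaluate)
      if (anyNA(fit)) {
        bad <- which(is.na(fit))
        resets <- resets + length(bad)
        pos[bad, ] <- matrix(stats::runif(length(bad) * d,
                                          rep(lower, each = length(bad)),
                                          rep(upper, each = length(bad))),
                             length(bad), d)
        fit[bad] <- apply(pos[bad, , drop = FALSE], 1, evaluate)
        fit[is.na(fit)] <- Inf
      }
      improved <- fit < pbest_fit
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_fit[improved] <- fit[improved]
      g <- which.min(pbest_fit)
      if (pbest_fit[g] < gbest_fit) {
        gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
      }
      trace[it] <- gbest_fit
    }
    structure(list(par = gbest, value = gbest_fit, trace = trace,
                   resets = resets, seed = seed,
                   n_particles = n_particles, iterations = iterations),
              class = "chiscan_pso")
  })
}

#' Calibrate energy weights against reference structures
#'
#' Runs [pso_fit()] on [calibration_objective()].
#'
#' @inheritParams calibration_objective
#' @param lower,upper Bounds per parameter (recycled).
#' @param ... Passed to [pso_fit()] (`n_particles`, `iterations`,
#'   `seed`, ...).
#' @return A `chiscan_calibration`: the `chiscan_pso` result plus
#'   `param_names` and the objective settings.
#' @export
calibrate_weights <- function(references,
                              param_names = c("w1", "w2", "w3", "w4"),
                              lower = 0, upper = 2,
                              spec = scan_spec(step = 30, window = 0),
                              ff = default_parameters(), ...) {
  lower <- rep_len(lower, length(param_names))
  upper <- rep_len(upper, length(param_names))
  fit <- pso_fit(function(p) {
    calibration_objective(p, references, param_names, spec, ff)
  }, lower, upper, ...)
  fit$param_names <- param_names
  names(fit$par) <- param_names
  class(fit) <- c("chiscan_calibration", class(fit))
  fit
}

#' @export
print.chiscan_pso <- function(x, ...) {
  cat("<", class(x)[1], "> ", x$n_particles, " particles, ", x$iterations,
      " iterations (seed ", x$seed, ")\n", sep = "")
  cat("  best objective:", format(x$value, digits = 8), "\n")
  if (!is.null(x$param_names)) {
    cat("  parameters:", paste(x$param_names, "=",
                               signif(x$par, 5), collapse = ", "), "\n")
  }
  invisible(x)
}
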