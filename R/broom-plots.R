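## Tidier and plotting methods so results drop straight into dplyr /
## ggplot2 pipelines.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a rotamer library
#'
#' One row per rotamer with the residue key, chi angles and energy
#' terms; the coordinate list-column is dropped.
#'
#' @param x A `rotamer_library`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rotamer_library <- function(x, ...) {
  out <- tibble::as_tibble(x[, setdiff(names(x), "coords")])
  out$residue <- res_key(out$asym_id, out$seq_id, out$alt_loc)
  dplyr::relocate(out, "residue")
}

#' One-row summary of a rotamer library
#'
#' @param x A `rotamer_library`.
#' @param ... Unused.
#' @return A tibble with residue/rotamer counts and scan settings.
#' @export
glance.rotamer_library <- function(x, ...) {
  scan <- attr(x, "scan")
  tibble::tibble(
    n_residues = nrow(dplyr::distinct(x[, c("asym_id", "seq_id", "alt_loc")])),
    n_rotamers = nrow(x),
    mean_rotamers = nrow(x) /
      max(1L, nrow(dplyr::distinct(x[, c("asym_id", "seq_id", "alt_loc")]))),
    step = scan$step %||% NA_real_,
    window = scan$window %||% NA_real_)
}

#' Tidy a PSO fit: the per-iteration best-objective trace
#'
#' @param x A `chiscan_pso` or `chiscan_calibration`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `best_objective`.
#' @export
tidy.chiscan_pso <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$trace), best_objective = x$trace)
}

#' One-row summary of a PSO fit
#'
#' @param x A `chiscan_pso` or `chiscan_calibration`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.chiscan_pso <- function(x, ...) {
  tibble::tibble(value = x$value, iterations = x$iterations,
                 n_particles = x$n_particles, resets = x$resets,
                 seed = x$seed)
}

#' Energy landscape plot of a rotamer library
#'
#' Weighted total energy against chi1, one panel per residue; accepted
#' grid points carry the rotamer ordinal colour scale.
#'
#' @param object A `rotamer_library`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rotamer_library <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chi1, y = .data$e_total,
                                   colour = .data$comp_id)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~ residue, scales = "free_y") +
    ggplot2::labs(x = expression(chi[1] ~ "(deg)"),
                  y = "weighted total energy",
                  colour = "residue type") +
    ggplot2::theme_minimal()
}

#' Convergence plot of a PSO fit
#'
#' @param object A `chiscan_pso` or `chiscan_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chiscan_pso <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$best_objective)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best objective") +
    ggplot2::theme_minimal()
}

#' bcRMSD distribution plot of an evaluation table
#'
#' Histogram of per-residue best-case RMSD with the 0.1 Angstrom
#' outlier threshold marked.
#'
#' @param comparison Output of [evaluate_library()].
#' @param binwidth Histogram bin width in Angstroms.
#' @return A ggplot object.
#' @export
plot_bcrmsd <- function(comparison, binwidth = 0.05) {
  ggplot2::ggplot(comparison, ggplot2::aes(x = .data$bcrmsd)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "best-case RMSD (Å)", y = "residues") +
    ggplot2::theme_minimal()
}
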