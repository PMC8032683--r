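#' Run the full beta-sheet analysis on a trajectory
#'
#' The pipeline applied to every frame: find aligned triples
#' ([find_aligned_triples()]), glue them into sheet components
#' ([connected_components()]), and summarise ([frame_statistics()]). Returns
#' a fitted-object-style result with [tidy()], [glance()] and [autoplot()]
#' methods.
#'
#' @param traj A [cg_trajectory()], or a single [cg_frame()] (treated as a
#'   one-frame trajectory; `group_length` inferred from the frame's peptide
#'   partition).
#' @param alpha,epsilon,use_pbc Detection parameters, see
#'   [detection_params()].
#' @return An object of class `sheet_analysis`.
#' @examples
#' frame <- make_parallel_sheet(sheet_spec(n_strands = 12, strand_len = 32))
#' fit <- analyze_sheets(frame)
#' glance(fit)
#' @export
analyze_sheets <- function(traj, alpha = 0.89, epsilon = 0.7,
                           use_pbc = FALSE) {
  if (inherits(traj, "cg_frame")) {
    gl <- infer_group_length(traj)
    traj <- cg_trajectory(list(traj), gl)
  }
  stopifnot(inherits(traj, "cg_trajectory"))
  params <- detection_params(alpha, epsilon, use_pbc)
  stats <- trajectory_statistics(traj, params)
  structure(
    list(
      stats = stats,
      params = params,
      group_length = trajectory_group_length(traj),
      n_frames = length(traj),
      n_grains = nrow(traj[[1]])
    ),
    class = "sheet_analysis"
  )
}

infer_group_length <- function(frame) {
  if (nrow(frame) == 0L) return(1L)
  as.integer(max(frame$residue_index) + 1L)
}

#' @export
print.sheet_analysis <- function(x, ...) {
  cat(sprintf(
    "<sheet_analysis> %d frame(s) x %d grains (GL = %d), alpha = %g, epsilon = %g nm\n",
    x$n_frames, x$n_grains, x$group_length, x$params$alpha, x$params$epsilon
  ))
  last <- x$stats[nrow(x$stats), ]
  cat(sprintf(
    "  last frame: %d triples, %d components, %.1f%% of grains in sheets\n",
    last$n_triples, last$n_components, 100 * last$fraction_in_sheets
  ))
  invisible(x)
}

#' Tidy per-frame results of a sheet analysis
#'
#' @param x A `sheet_analysis` object.
#' @param ... Unused.
#' @return A tibble with one row per frame: `frame_index`, `n_grains`,
#'   `n_triples`, `n_components`, `n_grains_in_sheets`,
#'   `fraction_in_sheets`.
#' @export
tidy.sheet_analysis <- function(x, ...) {
  select(
    x$stats, "frame_index", "n_grains", "n_triples", "n_components",
    "n_grains_in_sheets", "fraction_in_sheets"
  )
}

#' One-row summary of a sheet analysis
#'
#' @param x A `sheet_analysis` object.
#' @param ... Unused.
#' @return A one-row tibble: frame/grain counts, detection parameters, and
#'   the mean and final sheet fraction and component count.
#' @export
glance.sheet_analysis <- function(x, ...) {
  s <- x$stats
  tibble(
    n_frames = x$n_frames,
    n_grains = x$n_grains,
    group_length = x$group_length,
    alpha = x$params$alpha,
    epsilon = x$params$epsilon,
    mean_fraction_in_sheets = mean(s$fraction_in_sheets),
    final_fraction_in_sheets = s$fraction_in_sheets[nrow(s)],
    final_n_triples = s$n_triples[nrow(s)],
    final_n_components = s$n_components[nrow(s)]
  )
}

#' Plot the time course of a sheet analysis
#'
#' Triple count, component count and sheet fraction per frame, facetted on
#' free y scales.
#'
#' @param object A `sheet_analysis` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sheet_analysis <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object),
    c("n_triples", "n_components", "fraction_in_sheets"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(
    long$metric,
    levels = c("n_triples", "n_components", "fraction_in_sheets"),
    labels = c("aligned triples", "sheet components", "fraction in sheets")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$frame_index, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "frame", y = NULL,
      title = "Beta-sheet structure per frame",
      subtitle = sprintf(
        "alpha = %g, epsilon = %g nm", object$params$alpha,
        object$params$epsilon
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot residue-type composition of sheet grains over frames
#'
#' @param x A `sheet_analysis` object or a per-frame statistics tibble.
#' @return A ggplot object (stacked bars of sheet-grain counts by residue
#'   type).
#' @export
plot_composition <- function(x) {
  stats <- if (inherits(x, "sheet_analysis")) x$stats else x
  long <- composition_table(stats)
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$frame_index, .data$count, fill = .data$residue_name)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "frame", y = "sheet grains", fill = "residue",
      title = "Residue-type composition of detected sheets"
    ) +
    ggplot2::theme_minimal()
}
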