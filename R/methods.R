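# broom-style accessors and ggplot2 autoplot methods for the package's
# result objects.

#' Tidy a PMD differential result
#'
#' @param x A `pmd_differential` from [differential_pmd()].
#' @param ... Unused.
#' @return The underlying tibble (one row per tested PMD).
#' @export
tidy.pmd_differential <- function(x, ...) {
  out <- x
  attr(out, "quant") <- NULL
  class(out) <- setdiff(class(out), "pmd_differential")
  tibble::as_tibble(out)
}

#' One-row summary of a PMD differential result
#'
#' @param x A `pmd_differential`.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param ... Unused.
#' @return A tibble: `n_pmds`, `n_significant`, `min_p_adj`.
#' @export
glance.pmd_differential <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_pmds = nrow(x),
    n_significant = sum(x$p_adj < alpha, na.rm = TRUE),
    min_p_adj = suppressWarnings(min(x$p_adj, na.rm = TRUE))
  )
}

#' Plot per-sample PMD intensities by group
#'
#' Boxplots of the per-sample summed intensity of each tested PMD, split by
#' group -- the relative quantitative view behind a biomarker-reaction
#' call.
#'
#' @param object A `pmd_differential`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pmd_differential <- function(object, ...) {
  q <- attr(object, "quant")
  if (is.null(q) || nrow(q) == 0L) {
    stop("no per-sample quantification stored", call. = FALSE)
  }
  ggplot2::ggplot(q, ggplot2::aes(x = .data$group, y = .data$intensity,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.6) +
    ggplot2::facet_wrap(~pmd, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "summed intensity (log scale)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Tidy a PMD network into its edge list
#'
#' @param x A `pmd_network`.
#' @param ... Unused.
#' @return A tibble `from`, `to`, `pmd`, `pearson_r`.
#' @export
tidy.pmd_network <- function(x, ...) {
  tibble::as_tibble(x$edges)
}

#' One-row topology summary of a PMD network
#'
#' @param x A `pmd_network`.
#' @param ... Unused.
#' @return The [topology()] tibble.
#' @export
glance.pmd_network <- function(x, ...) {
  topology(x)
}

#' Plot a PMD network
#'
#' Fruchterman-Reingold layout with edges coloured by PMD label.
#'
#' @param object A `pmd_network`.
#' @param seed Layout seed (default 1) for a reproducible arrangement.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pmd_network <- function(object, seed = 1, ...) {
  if (nrow(object$nodes) == 0L) stop("empty network", call. = FALSE)
  xy <- withr::with_seed(seed,
    igraph::layout_with_fr(object$graph))
  nd <- object$nodes
  nd$x <- xy[, 1]; nd$y <- xy[, 2]
  ed <- object$edges
  p <- ggplot2::ggplot()
  if (nrow(ed) > 0L) {
    ed <- ed |>
      dplyr::left_join(nd[c("node_id", "x", "y")],
                       by = c(from = "node_id")) |>
      dplyr::left_join(nd[c("node_id", "x", "y")],
                       by = c(to = "node_id"), suffix = c("", "end"))
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = factor(.data$pmd)),
      alpha = 0.6)
  }
  p +
    ggplot2::geom_point(data = nd, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2) +
    ggplot2::labs(colour = "PMD (Da)") +
    ggplot2::theme_void()
}

#' Tidy a resampled degree contrast
#'
#' @param x A `pmd_resample` from [resample_degree_contrast()].
#' @param ... Unused.
#' @return The per-replicate tibble (`rep`, `group`, `mean_degree`).
#' @export
tidy.pmd_resample <- function(x, ...) {
  x$replicates
}

#' Summary of a resampled degree contrast
#'
#' @param x A `pmd_resample`.
#' @param ... Unused.
#' @return The per-group summary tibble with percentile intervals.
#' @export
glance.pmd_resample <- function(x, ...) {
  x$summary
}

#' Plot a PMD frequency spectrum
#'
#' Needle plot of frequency against PMD value for a PMD database.
#'
#' @param object A `pmd_db`.
#' @param top_n Label the `top_n` most frequent values (default 5).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pmd_db <- function(object, top_n = 5, ...) {
  x <- tibble::as_tibble(object)
  lab <- utils::head(x[order(-x$frequency), ], top_n)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$pmd, y = .data$frequency)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pmd, yend = 0)) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(label = format(.data$pmd)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "PMD (Da)", y = "frequency") +
    ggplot2::theme_minimal()
}
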