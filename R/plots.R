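# ggplot2 autoplot methods for result objects.

#' @importFrom ggplot2 ggplot aes geom_point geom_hline geom_vline
#'   geom_histogram geom_path geom_line annotate labs theme_minimal
#'   scale_colour_manual
NULL

diff_colours <- c("more-abundant" = "#c0392b", "less-abundant" = "#2e6da4",
                  "unchanged" = "grey60")

#' Plot single-replicate z-score results
#'
#' Scatter of the standardised score against the raw log2 difference, with
#' the flagging band at +/- the cut-off.
#'
#' @param object A `tic_diff_z`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tic_diff_z
#' @export
autoplot.tic_diff_z <- function(object, ...) {
  cutoff <- attr(object, "z_cutoff")
  ggplot(tidy(object), aes(x = .data$d, y = .data$z,
                           colour = .data$direction)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_hline(yintercept = c(-cutoff, cutoff), linetype = "dashed") +
    scale_colour_manual(values = diff_colours) +
    labs(x = "log2 difference (mutant - wild-type)", y = "z-score",
         colour = NULL) +
    theme_minimal()
}

#' Plot two-replicate signal-to-noise results
#'
#' Effect estimate (average between-strain log2 difference) against the
#' signal-to-noise statistic, with the significance and fold-change
#' cut-offs.
#'
#' @param object A `tic_diff_wstat`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tic_diff_wstat
#' @export
autoplot.tic_diff_wstat <- function(object, ...) {
  snr_cutoff <- attr(object, "snr_cutoff")
  fc_cutoff <- attr(object, "fc_cutoff")
  p <- ggplot(tidy(object), aes(x = .data$mean_diff, y = .data$snr,
                                colour = .data$direction)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_hline(yintercept = snr_cutoff, linetype = "dashed") +
    scale_colour_manual(values = diff_colours) +
    labs(x = "mean log2 difference (mutant - wild-type)",
         y = "signal-to-noise", colour = NULL) +
    theme_minimal()
  if (!is.null(fc_cutoff) && fc_cutoff > 0) {
    p <- p + geom_vline(xintercept = c(-fc_cutoff, fc_cutoff),
                        linetype = "dotted")
  }
  p
}

#' Plot a Venn decomposition
#'
#' Draws 2 or 3 overlapping circles with the disjoint region counts.
#' Circle areas are not scaled to set sizes; this is a labelled diagram,
#' not an area-proportional one.
#'
#' @param object A `venn_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot venn_result
#' @export
autoplot.venn_result <- function(object, ...) {
  nm <- unname(attr(object, "set_names"))
  k <- length(nm)
  centres <- if (k == 2) {
    data.frame(x = c(-0.5, 0.5), y = c(0, 0))
  } else {
    data.frame(x = c(-0.5, 0.5, 0), y = c(0.35, 0.35, -0.55))
  }
  theta <- seq(0, 2 * pi, length.out = 200)
  circles <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(set = nm[i],
               x = centres$x[i] + cos(theta),
               y = centres$y[i] + sin(theta))
  }))
  # region label positions: average of member-circle centres, pushed out
  # for exclusive regions
  lab <- do.call(rbind, lapply(seq_len(nrow(object)), function(r) {
    members <- object$sets[[r]]
    idx <- match(members, nm)
    cx <- mean(centres$x[idx])
    cy <- mean(centres$y[idx])
    if (length(idx) == 1 && k > 1) {
      away <- c(cx - mean(centres$x), cy - mean(centres$y))
      cx <- cx + 0.55 * away[1]
      cy <- cy + 0.55 * away[2]
    }
    data.frame(x = cx, y = cy, n = object$n[r])
  }))
  ggplot() +
    geom_path(data = circles,
              aes(x = .data$x, y = .data$y, group = .data$set,
                  colour = .data$set)) +
    annotate("text", x = lab$x, y = lab$y, label = lab$n, size = 5) +
    labs(colour = NULL, x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot Laurdan fluidity ratios against temperature
#'
#' @param object A `laurdan_series` (see [laurdan_ratio()]); a `strain` or
#'   `group` column, if present, maps to colour.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot laurdan_series
#' @export
autoplot.laurdan_series <- function(object, ...) {
  df <- as_tibble(unclass_result(object))
  grp <- intersect(c("strain", "group"), names(df))[1]
  mapping <- if (!is.na(grp)) {
    aes(x = .data$temperature, y = .data$ratio, colour = .data[[grp]])
  } else {
    aes(x = .data$temperature, y = .data$ratio)
  }
  ggplot(df, mapping) +
    geom_point() +
    geom_line() +
    labs(x = "temperature (°C)", y = "F440 / F490",
         colour = NULL) +
    theme_minimal()
}
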