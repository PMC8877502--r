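# broom-style tidiers for the package's result objects.

#' @rdname tidiers
#' @title Tidy and summarise differential results
#' @description `tidy()` returns the per-protein table as a plain tibble;
#'   `glance()` returns a one-row summary of the fit (population
#'   normalisation constants, cut-offs, flag counts).
#' @param x A `tic_diff_z`, `tic_diff_wstat` or `tic_report` object.
#' @param ... Unused.
#' @method tidy tic_diff_z
#' @export
tidy.tic_diff_z <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname tidiers
#' @method glance tic_diff_z
#' @export
glance.tic_diff_z <- function(x, ...) {
  tibble(
    n = nrow(x),
    mean_d = attr(x, "mean_d"),
    sd_d = attr(x, "sd_d"),
    z_cutoff = attr(x, "z_cutoff"),
    n_flagged = sum(x$flagged),
    n_more_abundant = sum(x$direction == "more-abundant"),
    n_less_abundant = sum(x$direction == "less-abundant")
  )
}

#' @rdname tidiers
#' @method tidy tic_diff_wstat
#' @export
tidy.tic_diff_wstat <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname tidiers
#' @method glance tic_diff_wstat
#' @export
glance.tic_diff_wstat <- function(x, ...) {
  tibble(
    n = nrow(x),
    noise = attr(x, "noise"),
    snr_cutoff = attr(x, "snr_cutoff"),
    fc_cutoff = attr(x, "fc_cutoff"),
    pairing = attr(x, "pairing"),
    n_flagged = sum(x$flagged),
    n_more_abundant = sum(x$direction == "more-abundant"),
    n_less_abundant = sum(x$direction == "less-abundant")
  )
}

#' @rdname tidiers
#' @method tidy tic_report
#' @export
tidy.tic_report <- function(x, ...) {
  tidy(x$diff)
}

#' @rdname tidiers
#' @method glance tic_report
#' @export
glance.tic_report <- function(x, ...) {
  s <- setNames(as.list(x$summary$n), x$summary$quantity)
  dplyr::bind_cols(tibble(procedure = x$procedure), as_tibble(s),
                   tibble(config_hash = x$config_hash))
}

unclass_result <- function(x) {
  cls <- class(x)
  class(x) <- cls[!cls %in% c("tic_diff_z", "tic_diff_wstat",
                              "venn_result", "enrich_result",
                              "laurdan_series", "tic_matrix")]
  for (a in c("mean_d", "sd_d", "z_cutoff", "noise", "snr_cutoff",
              "fc_cutoff", "pairing", "set_names", "adjust", "design")) {
    attr(x, a) <- NULL
  }
  x
}
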