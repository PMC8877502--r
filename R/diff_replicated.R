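#' Two-replicate differential abundance by signal-to-noise (Wstat)
#'
#' The replicated differential procedure for a design with two runs per
#' strain. For every protein detected in all four runs it forms four log2
#' difference values:
#' \describe{
#'   \item{`r0`, `r1`}{within-strain replicate differences (wild-type
#'     rep1 - rep2; mutant rep1 - rep2) — pure technical/biological noise;}
#'   \item{`z0`, `z1`}{between-strain differences paired by replicate index
#'     (mutant rep k - wild-type rep k) — signal plus noise.}
#' }
#' Each of the four populations is centred to across-protein mean zero,
#' which removes global run-to-run intensity offsets. The noise scale is
#' the sample standard deviation of the pooled centred within-strain
#' differences, and the per-protein signal-to-noise statistic is
#' `snr = |z0c + z1c| / noise` with effect estimate
#' `mean_diff = (z0c + z1c) / 2`.
#'
#' A protein is flagged when `snr >= snr_cutoff` **and**
#' `|mean_diff| >= fc_cutoff` (both inclusive). The default `snr_cutoff =
#' 2.8` corresponds to p < 0.05 under Gaussian replicate noise: the null
#' `snr` is distributed as `sqrt(2) * |N(0,1)|`, so
#' `P(snr >= 2.8) = 2 * (1 - pnorm(2.8 / sqrt(2))) ~ 0.048`. The default
#' `fc_cutoff = 1` on the log2 scale requires at least a two-fold average
#' difference. Set `fc_cutoff = 0` to disable the fold-change filter.
#'
#' @param m A `tic_matrix` with exactly two replicates per strain.
#' @param snr_cutoff Signal-to-noise significance cut-off (inclusive).
#' @param fc_cutoff Minimum `|mean_diff|` in log2 units (inclusive);
#'   1 = two-fold.
#' @param pairing `"matched"` pairs mutant rep k with wild-type rep k;
#'   `"crossed"` pairs rep 1 with rep 2. The pairing is arbitrary under
#'   exchangeable replicates, and because `z0 + z1` contains every
#'   between-strain difference exactly once under either choice, `snr`,
#'   `mean_diff` and the flags are identical — only the reported `z0`/`z1`
#'   columns change.
#' @param ref Reference (wild-type) strain label.
#' @return A tibble of class `tic_diff_wstat`: `protein_id`, `r0`, `r1`,
#'   `z0`, `z1` (centred values `r0c` ... `z1c`), `mean_diff`, `snr`,
#'   `direction`, `flagged`. Attribute `noise` records the pooled noise SD.
#' @export
wstat_diff <- function(m, snr_cutoff = 2.8, fc_cutoff = 1,
                       pairing = c("matched", "crossed"), ref = NULL) {
  pairing <- match.arg(pairing)
  if (fc_cutoff < 0) stop_config("fc_cutoff must be non-negative")
  design <- attr(m, "design")
  wt <- ref_strain(design, ref)
  if (any(table(design$strain) != 2)) {
    stop_design("wstat_diff requires exactly two replicates per strain")
  }
  wide <- m %>%
    mutate(role = paste0(ifelse(.data$strain == wt, "wt", "mut"),
                         .data$replicate)) %>%
    tidyr::pivot_wider(id_cols = "protein_id", names_from = "role",
                       values_from = "log2_tic") %>%
    filter(!is.na(.data$wt1) & !is.na(.data$wt2) &
             !is.na(.data$mut1) & !is.na(.data$mut2))
  if (nrow(wide) < 3) {
    stop_stat("wstat_diff: fewer than 3 proteins detected in all four runs")
  }
  r0 <- wide$wt1 - wide$wt2
  r1 <- wide$mut1 - wide$mut2
  if (pairing == "matched") {
    z0 <- wide$mut1 - wide$wt1
    z1 <- wide$mut2 - wide$wt2
  } else {
    z0 <- wide$mut1 - wide$wt2
    z1 <- wide$mut2 - wide$wt1
  }
  r0c <- r0 - mean(r0)
  r1c <- r1 - mean(r1)
  z0c <- z0 - mean(z0)
  z1c <- z1 - mean(z1)
  noise <- sd(c(r0c, r1c))
  if (!is.finite(noise) || noise == 0) {
    stop_stat("wstat_diff: degenerate within-strain difference population (noise SD 0)")
  }
  mean_diff <- (z0c + z1c) / 2
  snr <- abs(z0c + z1c) / noise
  out <- tibble(
    protein_id = wide$protein_id,
    r0 = r0, r1 = r1, z0 = z0, z1 = z1,
    mean_diff = mean_diff, snr = snr,
    flagged = snr >= snr_cutoff & abs(mean_diff) >= fc_cutoff
  ) %>%
    mutate(direction = dplyr::case_when(
      .data$flagged & .data$mean_diff > 0 ~ "more-abundant",
      .data$flagged & .data$mean_diff < 0 ~ "less-abundant",
      TRUE ~ "unchanged"
    )) %>%
    select("protein_id", "r0", "r1", "z0", "z1", "mean_diff", "snr",
           "direction", "flagged")
  structure(out,
            class = c("tic_diff_wstat", class(out)),
            noise = noise, snr_cutoff = snr_cutoff, fc_cutoff = fc_cutoff,
            pairing = pairing)
}

#' Filter differential results by fold change
#'
#' Retains results whose average between-strain log2 difference is at least
#' `fc_cutoff` in absolute value; `fc_cutoff = 1` keeps proteins with at
#' least a two-fold difference.
#'
#' @param results A tibble carrying a `mean_diff` column (for example a
#'   `tic_diff_wstat`).
#' @param fc_cutoff Non-negative log2 threshold (inclusive).
#' @return The filtered tibble, attributes preserved.
#' @export
fold_change_filter <- function(results, fc_cutoff = 1) {
  if (!is.numeric(fc_cutoff) || length(fc_cutoff) != 1 || fc_cutoff < 0) {
    stop_config("fc_cutoff must be a single non-negative number")
  }
  if (!"mean_diff" %in% names(results)) {
    stop_config("results must carry a mean_diff column")
  }
  keep <- abs(results$mean_diff) >= fc_cutoff
  out <- results[keep, , drop = FALSE]
  for (a in c("noise", "snr_cutoff", "pairing")) {
    attr(out, a) <- attr(results, a)
  }
  attr(out, "fc_cutoff") <- fc_cutoff
  out
}
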