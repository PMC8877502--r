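#' Single-replicate differential abundance by z-score
#'
#' For a design with one run per strain, computes for every protein
#' detected in both runs the raw log2 difference `d = log2(TIC mutant) -
#' log2(TIC wild-type)`, standardises the difference population to mean 0
#' and standard deviation 1 (sample SD, n - 1 denominator), and flags
#' proteins whose z-score falls outside the 95% band, `|z| > z_cutoff`
#' (strict inequality). No multiple-testing correction is applied: the rule
#' is a per-protein 95%-confidence screen on the empirical difference
#' population, in which global run-to-run intensity offsets cancel by
#' construction.
#'
#' @param m A `tic_matrix` with exactly one sample per strain.
#' @param z_cutoff Flagging threshold on `|z|`; 1.96 corresponds to the
#'   central 95% of a standard normal.
#' @param ref Reference (wild-type) strain label; inferred for WT-like
#'   labels.
#' @return A tibble of class `tic_diff_z`: `protein_id`, `d`, `z`,
#'   `direction` (`more-abundant` / `less-abundant` / `unchanged`),
#'   `flagged`. Attributes `mean_d`, `sd_d`, `z_cutoff` record the
#'   normalisation.
#' @examples
#' des <- run_design(c("wt", "mut"), c("WT", "mutant"))
#' lg <- cbind(wt = c(10, 11, 12, 13), mut = c(10.5, 10.8, 12.2, 12.6))
#' zscore_diff(tic_matrix(lg, des))
#' @export
zscore_diff <- function(m, z_cutoff = 1.96, ref = NULL) {
  design <- attr(m, "design")
  wt <- ref_strain(design, ref)
  if (any(table(design$strain) != 1)) {
    stop_design("zscore_diff requires exactly one sample per strain")
  }
  wide <- m %>%
    mutate(role = ifelse(.data$strain == wt, "wt", "mut")) %>%
    tidyr::pivot_wider(id_cols = "protein_id", names_from = "role",
                       values_from = "log2_tic") %>%
    filter(!is.na(.data$wt) & !is.na(.data$mut))
  if (nrow(wide) < 3) {
    stop_stat("zscore_diff: fewer than 3 proteins detected in both strains")
  }
  d <- wide$mut - wide$wt
  mu <- mean(d)
  s <- sd(d)
  if (s == 0) stop_stat("zscore_diff: degenerate difference population (SD 0)")
  z <- (d - mu) / s
  out <- tibble(
    protein_id = wide$protein_id,
    d = d,
    z = z,
    flagged = abs(z) > z_cutoff
  ) %>%
    mutate(direction = dplyr::case_when(
      .data$flagged & .data$z > 0 ~ "more-abundant",
      .data$flagged & .data$z < 0 ~ "less-abundant",
      TRUE ~ "unchanged"
    )) %>%
    select("protein_id", "d", "z", "direction", "flagged")
  structure(out,
            class = c("tic_diff_z", class(out)),
            mean_d = mu, sd_d = s, z_cutoff = z_cutoff)
}
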