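#' Describe the run design
#'
#' A design maps each mass-spectrometry run (`sample_id`) to a strain and a
#' replicate index. Exactly two strains are expected: a reference
#' (wild-type) and a comparison (mutant) strain.
#'
#' @param sample_id Character vector of run labels.
#' @param strain Strain label per run (two distinct values).
#' @param replicate Integer replicate index per run (within strain).
#' @return A tibble with class `tic_design`.
#' @export
run_design <- function(sample_id, strain, replicate = NULL) {
  if (anyDuplicated(sample_id)) stop_design("duplicate sample_id in design")
  if (length(unique(strain)) != 2) {
    stop_design("design must name exactly two strains")
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(sample_id), strain, FUN = seq_along)
  }
  d <- tibble(sample_id = as.character(sample_id),
              strain = as.character(strain),
              replicate = as.integer(replicate))
  if (anyDuplicated(d[, c("strain", "replicate")])) {
    stop_design("replicate indices must be unique within strain")
  }
  class(d) <- c("tic_design", class(d))
  d
}

# Identify the reference (wild-type) strain in a design.
ref_strain <- function(design, ref = NULL) {
  strains <- unique(design$strain)
  if (!is.null(ref)) {
    if (!ref %in% strains) {
      stop_design(paste0("reference strain '", ref, "' not in design (",
                         paste(strains, collapse = ", "), ")"))
    }
    return(ref)
  }
  wt_like <- strains[toupper(strains) %in% c("WT", "WILDTYPE", "WILD-TYPE")]
  if (length(wt_like) == 1) return(wt_like)
  stop_design(paste0(
    "cannot infer the reference strain from design strains (",
    paste(strains, collapse = ", "), "); pass ref = explicitly"
  ))
}

#' Roll peptide-level intensities up to protein total ion counts
#'
#' Computes, for every protein and run, the protein total ion count (TIC):
#' the sum of the summed MS/MS fragment-ion intensities over all accepted
#' peptide-spectrum matches assigned to that protein in that run. TIC is a
#' relative measure of protein abundance within a run and is carried on a
#' log2 scale for all downstream statistics. A cell with no PSM (or zero
#' total intensity) is undetected: its `log2_tic` is `NA`, never imputed.
#'
#' Shared-peptide handling is deliberately simple: each PSM counts toward
#' the single `protein_id` it is assigned to in the input; no
#' peptide-to-protein inference is performed. No cross-run normalisation is
#' applied here — the differential procedures absorb global run offsets by
#' centering their difference populations.
#'
#' @param psms Tibble of accepted PSM records (see [read_psm_table()]).
#' @param design A [run_design()] covering every `sample_id` in `psms`.
#' @return A long tibble of class `tic_matrix` with one row per
#'   protein-sample cell: `protein_id`, `sample_id`, `strain`, `replicate`,
#'   `tic`, `log2_tic`, `detected`. Proteins with no accepted PSM in any
#'   sample are absent.
#' @export
rollup_tic <- function(psms, design) {
  if (!inherits(design, "tic_design")) {
    design <- run_design(design$sample_id, design$strain, design$replicate)
  }
  unknown <- setdiff(unique(psms$sample_id), design$sample_id)
  if (length(unknown) > 0) {
    stop_config(paste0("PSM sample_id not in design: ",
                       paste(unknown, collapse = ", ")))
  }
  cells <- psms %>%
    group_by(.data$protein_id, .data$sample_id) %>%
    summarise(tic = sum(.data$fragment_intensity_sum), .groups = "drop")
  all_zero <- cells %>%
    group_by(.data$protein_id) %>%
    summarise(total = sum(.data$tic), .groups = "drop") %>%
    filter(.data$total <= 0)
  if (nrow(all_zero) > 0) {
    warn(paste0("rollup_tic: excluding ", nrow(all_zero),
                " protein(s) with all-zero intensity"))
    cells <- filter(cells, !.data$protein_id %in% all_zero$protein_id)
  }
  grid <- tidyr::expand_grid(protein_id = sort(unique(cells$protein_id)),
                             sample_id = design$sample_id)
  m <- grid %>%
    left_join(cells, by = c("protein_id", "sample_id")) %>%
    mutate(tic = dplyr::coalesce(.data$tic, 0)) %>%
    left_join(design, by = "sample_id") %>%
    mutate(
      detected = .data$tic > 0,
      log2_tic = ifelse(.data$detected, log2(.data$tic), NA_real_)
    ) %>%
    select("protein_id", "sample_id", "strain", "replicate",
           "tic", "log2_tic", "detected")
  new_tic_matrix(m, design)
}

new_tic_matrix <- function(m, design) {
  attr(m, "design") <- design
  class(m) <- c("tic_matrix", class(m))
  m
}

#' Build an expression matrix directly from log2 abundances
#'
#' Convenience constructor for simulations and tests: takes a
#' proteins-by-samples matrix of log2 TIC values (`NA` = undetected) and a
#' design, and returns the same long `tic_matrix` that [rollup_tic()]
#' produces.
#'
#' @param log2_tic Numeric matrix, rownames = protein ids (generated when
#'   absent), colnames matching `design$sample_id` (taken in design order
#'   when absent).
#' @param design A [run_design()].
#' @return A `tic_matrix` tibble.
#' @export
tic_matrix <- function(log2_tic, design) {
  if (!inherits(design, "tic_design")) {
    design <- run_design(design$sample_id, design$strain, design$replicate)
  }
  log2_tic <- as.matrix(log2_tic)
  if (is.null(rownames(log2_tic))) {
    rownames(log2_tic) <- sprintf("P%05d", seq_len(nrow(log2_tic)))
  }
  if (is.null(colnames(log2_tic))) {
    if (ncol(log2_tic) != nrow(design)) {
      stop_design("log2_tic columns do not match the design")
    }
    colnames(log2_tic) <- design$sample_id
  }
  m <- as_tibble(log2_tic, rownames = "protein_id") %>%
    tidyr::pivot_longer(-"protein_id", names_to = "sample_id",
                        values_to = "log2_tic") %>%
    left_join(design, by = "sample_id") %>%
    mutate(
      detected = !is.na(.data$log2_tic),
      tic = ifelse(.data$detected, 2^.data$log2_tic, 0)
    ) %>%
    select("protein_id", "sample_id", "strain", "replicate",
           "tic", "log2_tic", "detected")
  new_tic_matrix(m, design)
}

#' Widen an expression matrix
#'
#' @param m A `tic_matrix`.
#' @param value Which value to spread: `"log2_tic"`, `"tic"` or
#'   `"detected"`.
#' @return A tibble with one row per protein and one column per sample.
#' @export
tic_wide <- function(m, value = c("log2_tic", "tic", "detected")) {
  value <- match.arg(value)
  tidyr::pivot_wider(m, id_cols = "protein_id", names_from = "sample_id",
                     values_from = dplyr::all_of(value))
}

#' Classify proteins by where they were detected
#'
#' Assigns each protein a detection status — `both-strains`, `mutant-only`,
#' `wild-type-only` or `undetected` — and a `quantifiable` flag saying
#' whether it enters the quantitative differential test. Status uses
#' lenient semantics (detected in at least one sample of a strain counts as
#' detected in that strain); `mutant-only` means detected somewhere in the
#' mutant and nowhere in the wild type, the pattern read as overexpression
#' beyond the dynamic range of the comparison. The `rule` controls
#' `quantifiable`: under `"strict"` a protein must be detected in every
#' sample; under `"lenient"` in at least one sample per strain. The default
#' `"auto"` picks strict for replicated designs and lenient for
#' single-replicate designs (where the two coincide).
#'
#' @param m A `tic_matrix`.
#' @param rule `"auto"`, `"strict"` or `"lenient"`.
#' @param ref Reference (wild-type) strain label; inferred when the design
#'   uses a WT-like label.
#' @return A tibble: `protein_id`, `status`, `quantifiable`. Every protein
#'   in `m` appears exactly once.
#' @export
detection_calls <- function(m, rule = c("auto", "strict", "lenient"),
                            ref = NULL) {
  rule <- match.arg(rule)
  design <- attr(m, "design")
  wt <- ref_strain(design, ref)
  n_rep <- min(table(design$strain))
  if (n_rep < 1) stop_design("design has a strain with no samples")
  if (rule == "auto") rule <- if (n_rep >= 2) "strict" else "lenient"
  per <- m %>%
    group_by(.data$protein_id) %>%
    summarise(
      n_wt = sum(.data$detected & .data$strain == wt),
      n_mut = sum(.data$detected & .data$strain != wt),
      n_wt_tot = sum(.data$strain == wt),
      n_mut_tot = sum(.data$strain != wt),
      .groups = "drop"
    ) %>%
    mutate(
      status = dplyr::case_when(
        .data$n_wt > 0 & .data$n_mut > 0 ~ "both-strains",
        .data$n_mut > 0 ~ "mutant-only",
        .data$n_wt > 0 ~ "wild-type-only",
        TRUE ~ "undetected"
      ),
      quantifiable = if (rule == "strict") {
        .data$n_wt == .data$n_wt_tot & .data$n_mut == .data$n_mut_tot
      } else {
        .data$n_wt > 0 & .data$n_mut > 0
      }
    )
  select(per, "protein_id", "status", "quantifiable")
}
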