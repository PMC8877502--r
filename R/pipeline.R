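#' Run the full differential-abundance analysis
#'
#' Orchestrates the pipeline from accepted PSM records to a report:
#' TIC rollup ([rollup_tic()]), detection calls ([detection_calls()]), the
#' differential test appropriate to the design — the single-replicate
#' z-score rule ([zscore_diff()]) or the two-replicate signal-to-noise
#' procedure with fold-change filter ([wstat_diff()]) — followed by
#' optional compartment annotation, signature overlap/Venn analysis of the
#' more-abundant list, and category enrichment over the
#' detected-in-both-strains universe.
#'
#' @param psms PSM tibble (see [read_psm_table()]), or a `tic_matrix`.
#' @param design A [run_design()]; ignored when `psms` is already a
#'   `tic_matrix`.
#' @param compartments Optional named list of compartment [gene_set()]s.
#' @param signatures Optional named list of signature [gene_set()]s to
#'   overlap with the more-abundant protein list (at most 2 enter the Venn
#'   decomposition together with that list).
#' @param categories Optional named list of functional-category
#'   [gene_set()]s for enrichment.
#' @param procedure `"auto"` (dispatch on replicate count), `"zscore"` or
#'   `"wstat"`.
#' @param detection_rule Passed to [detection_calls()].
#' @param z_cutoff,snr_cutoff,fc_cutoff Thresholds for the differential
#'   procedures.
#' @param ref Reference (wild-type) strain label.
#' @return A list of class `tic_report`: `matrix`, `detection`, `diff`,
#'   `procedure`, `compartments`, `overlaps`, `venn`, `enrichment`,
#'   `summary` (counts of detected / differential / more- / less-abundant
#'   proteins), and `config_hash`.
#' @export
run_pipeline <- function(psms, design = NULL, compartments = NULL,
                         signatures = NULL, categories = NULL,
                         procedure = c("auto", "zscore", "wstat"),
                         detection_rule = c("auto", "strict", "lenient"),
                         z_cutoff = 1.96, snr_cutoff = 2.8, fc_cutoff = 1,
                         ref = NULL) {
  procedure <- match.arg(procedure)
  detection_rule <- match.arg(detection_rule)
  if (any(c(z_cutoff, snr_cutoff) <= 0) || fc_cutoff < 0) {
    stop_config("thresholds must be positive (fc_cutoff may be 0)")
  }
  if (inherits(psms, "tic_matrix")) {
    m <- psms
    design <- attr(m, "design")
  } else {
    if (is.null(design)) stop_design("a design is required with PSM input")
    if (!inherits(design, "tic_design")) {
      design <- run_design(design$sample_id, design$strain, design$replicate)
    }
    m <- NULL
  }
  n_rep <- unname(table(design$strain))
  if (length(unique(n_rep)) != 1) {
    stop_design("unbalanced design: strains have different replicate counts")
  }
  n_rep <- n_rep[1]
  if (procedure == "auto") procedure <- if (n_rep >= 2) "wstat" else "zscore"
  if (procedure == "wstat" && n_rep != 2) {
    stop_design("wstat procedure requires exactly two replicates per strain")
  }
  if (procedure == "zscore" && n_rep != 1) {
    stop_design("zscore procedure requires exactly one sample per strain")
  }
  if (is.null(m)) m <- rollup_tic(psms, design)
  wt <- ref_strain(design, ref)
  det <- detection_calls(m, rule = detection_rule, ref = wt)
  quant <- filter(m, .data$protein_id %in%
                    det$protein_id[det$quantifiable])
  quant <- new_tic_matrix(quant, design)
  diff <- if (procedure == "zscore") {
    zscore_diff(quant, z_cutoff = z_cutoff, ref = wt)
  } else {
    wstat_diff(quant, snr_cutoff = snr_cutoff, fc_cutoff = fc_cutoff,
               ref = wt)
  }
  detected_both <- det$protein_id[det$status == "both-strains"]
  up <- diff$protein_id[diff$direction == "more-abundant"]
  down <- diff$protein_id[diff$direction == "less-abundant"]
  comp <- if (!is.null(compartments)) {
    annotate_compartments(detected_both, compartments)
  }
  overlaps <- venn <- NULL
  if (!is.null(signatures) && length(up) > 0) {
    sig_sets <- as_gene_set_list(signatures)
    up_set <- gene_set("more-abundant", up)
    overlaps <- bind_rows(purrr::map(sig_sets, overlap_fraction,
                                     diff_list = up_set))
    if (length(sig_sets) <= 2) {
      venn <- venn_regions(c(list(up_set), sig_sets))
    }
  }
  enrichment <- if (!is.null(categories) && length(detected_both) > 0) {
    q <- intersect(c(up, down), detected_both)
    if (length(q) > 0) {
      enrich_sets(gene_set("differential", q), categories,
                  gene_set("detected-both", detected_both))
    }
  }
  summary <- tibble(
    quantity = c("proteins_in_matrix", "detected_both_strains",
                 "quantified", "differential", "more_abundant",
                 "less_abundant", "mutant_only", "wild_type_only"),
    n = c(dplyr::n_distinct(m$protein_id), length(detected_both),
          nrow(diff), length(up) + length(down), length(up), length(down),
          sum(det$status == "mutant-only"),
          sum(det$status == "wild-type-only"))
  )
  structure(list(
    matrix = m, detection = det, diff = diff, procedure = procedure,
    compartments = comp, overlaps = overlaps, venn = venn,
    enrichment = enrichment, summary = summary,
    config_hash = config_hash(list(
      procedure = procedure, detection_rule = detection_rule,
      z_cutoff = z_cutoff, snr_cutoff = snr_cutoff,
      fc_cutoff = fc_cutoff, design = design
    ))
  ), class = "tic_report")
}

#' @export
print.tic_report <- function(x, ...) {
  cat("<tic_report> procedure: ", x$procedure,
      "  (config ", x$config_hash, ")\n", sep = "")
  s <- setNames(x$summary$n, x$summary$quantity)
  cat("  proteins in matrix: ", s["proteins_in_matrix"],
      "; detected in both strains: ", s["detected_both_strains"], "\n",
      sep = "")
  cat("  differential: ", s["differential"], " (",
      s["more_abundant"], " more / ", s["less_abundant"],
      " less abundant)\n", sep = "")
  if (!is.null(x$overlaps)) {
    cat("  signature overlaps:\n")
    for (i in seq_len(nrow(x$overlaps))) {
      cat("    ", x$overlaps$signature[i], ": ", x$overlaps$n_overlap[i],
          "/", x$overlaps$n_diff[i], " (",
          round(100 * x$overlaps$fraction[i], 1), "%)\n", sep = "")
    }
  }
  invisible(x)
}
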