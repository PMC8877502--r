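# Shared fixture builders. Everything is generated in code; no binary data.

two_strain_design <- function(n_rep = 2) {
  run_design(
    sample_id = c(paste0("WT_r", seq_len(n_rep)),
                  paste0("mut_r", seq_len(n_rep))),
    strain = rep(c("WT", "mutant"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2)
  )
}

# Minimal PSM tibble in the interchange schema; all records pass the
# default identification filters unless overridden.
make_psms <- function(protein_id, sample_id, intensity,
                      peptide = NULL, log_e = -2, missed_cleavages = 0L,
                      charge = 2L) {
  n <- length(protein_id)
  if (is.null(peptide)) peptide <- paste0("PEPTIDE", seq_len(n), "K")
  tibble::tibble(
    protein_id = protein_id,
    peptide = peptide,
    charge = rep_len(as.integer(charge), n),
    parent_mz = rep_len(500.25, n),
    retention_time = rep_len(42.0, n),
    fragment_intensity_sum = intensity,
    sample_id = sample_id,
    log_e = rep_len(log_e, n),
    missed_cleavages = rep_len(as.integer(missed_cleavages), n)
  )
}

write_psm_file <- function(psms, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(psms, path)
  path
}

# Independent brute-force hypergeometric upper tail by enumerating every
# n-subset of a universe of size N with K marked elements.
enum_hyper_tail <- function(N, K, n, k) {
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}
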