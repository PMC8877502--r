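#' Simulate a PSM-level dataset with ground truth
#'
#' Generates peptide-spectrum-match tables with the statistical structure
#' the TIC pipeline assumes, so every stage can be validated against known
#' truth without real instrument data:
#' \itemize{
#'   \item per-protein baseline log2 abundance `b_i ~ Normal(mu0, tau)`
#'     (log-normal TIC);
#'   \item a sparse strain effect: with probability `pi_de` a protein
#'     carries a log2 effect of `+delta` or `-delta` (equal probability)
#'     applied to the mutant samples;
#'   \item per-replicate Gaussian noise `Normal(0, sigma_rep)` on the log2
#'     scale, added independently per protein-sample cell;
#'   \item lossless peptide splitting: each cell's TIC is divided among
#'     the protein's peptides by symmetric Dirichlet weights, so rollup
#'     recovers the latent value exactly;
#'   \item abundance-dependent detection dropout: a cell is zeroed (the
#'     whole protein-sample observation is missing) with probability
#'     `pnorm(qnorm(dropout_rate) - dropout_link_slope * (b_i - mu0)/tau)`,
#'     a probit link that concentrates missingness in the low-abundance
#'     tail.
#' }
#' Generated PSM records carry identification fields that pass the default
#' filters (`log_e < -1.5`, at most one missed cleavage, charge 2-4).
#' The same `seed` and configuration always produce byte-identical output.
#'
#' @param n_proteins Number of simulated proteins.
#' @param n_replicates Runs per strain (1 or 2).
#' @param peptides_per_protein Inclusive integer range, e.g. `c(2, 10)`.
#' @param mu0,tau Mean and SD of the baseline log2 abundance.
#' @param sigma_rep Replicate noise SD (log2 units).
#' @param pi_de Fraction of proteins with a strain effect.
#' @param delta Effect magnitude in log2 units (symmetric +/-).
#' @param dropout_rate Baseline per-cell missingness probability (applied
#'   at the centre of the abundance distribution).
#' @param dropout_link_slope Probit-link slope tying dropout to abundance;
#'   0 makes dropout abundance-independent.
#' @param seed Integer seed; required for reproducibility.
#' @return A list of class `tic_sim`: `psms` (PSM tibble in the
#'   [read_psm_table()] schema), `truth` (tibble `protein_id`, `baseline`,
#'   `effect`, `latent_<sample>` log2 values and `detected_<sample>`
#'   flags), `design` (the [run_design()]), and `config`.
#' @export
simulate_psm_data <- function(n_proteins = 1000, n_replicates = 2,
                              peptides_per_protein = c(2, 10),
                              mu0 = 10, tau = 2, sigma_rep = 0.3,
                              pi_de = 0.1, delta = 2,
                              dropout_rate = 0.1, dropout_link_slope = 1,
                              seed = 1) {
  if (n_proteins < 1) stop_config("n_proteins must be >= 1")
  if (!n_replicates %in% c(1, 2)) {
    stop_config("n_replicates must be 1 or 2 (the supported designs)")
  }
  if (pi_de < 0 || pi_de > 1) stop_config("pi_de must be in [0, 1]")
  if (delta < 0) stop_config("delta must be non-negative")
  if (sigma_rep <= 0) stop_config("sigma_rep must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_config("dropout_rate must be in [0, 1)")
  }
  if (length(peptides_per_protein) != 2 ||
      peptides_per_protein[1] < 1 ||
      peptides_per_protein[2] < peptides_per_protein[1]) {
    stop_config("peptides_per_protein must be an increasing range of positive integers")
  }
  config <- list(
    n_proteins = n_proteins, n_replicates = n_replicates,
    peptides_per_protein = peptides_per_protein, mu0 = mu0, tau = tau,
    sigma_rep = sigma_rep, pi_de = pi_de, delta = delta,
    dropout_rate = dropout_rate, dropout_link_slope = dropout_link_slope,
    seed = seed
  )
  design <- run_design(
    sample_id = c(paste0("WT_r", seq_len(n_replicates)),
                  paste0("mut_r", seq_len(n_replicates))),
    strain = rep(c("WT", "mutant"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2)
  )
  with_seed(seed, {
    protein_id <- sprintf("SIM%05d", seq_len(n_proteins))
    baseline <- rnorm(n_proteins, mu0, tau)
    is_de <- runif(n_proteins) < pi_de
    effect <- ifelse(is_de, ifelse(runif(n_proteins) < 0.5, 1, -1) * delta, 0)
    n_samp <- nrow(design)
    is_mut <- design$strain != "WT"
    # latent log2 TIC per protein x sample
    latent <- outer(baseline, rep(1, n_samp)) +
      outer(effect, as.numeric(is_mut)) +
      matrix(rnorm(n_proteins * n_samp, 0, sigma_rep), n_proteins, n_samp)
    colnames(latent) <- design$sample_id
    p_drop <- if (dropout_rate > 0) {
      pnorm(qnorm(dropout_rate) -
              dropout_link_slope * (baseline - mu0) / tau)
    } else {
      rep(0, n_proteins)
    }
    detected <- matrix(runif(n_proteins * n_samp) >= p_drop,
                       n_proteins, n_samp)
    colnames(detected) <- design$sample_id
    # peptide inventory per protein, with Dirichlet(1) intensity shares
    n_pep <- sample(seq(peptides_per_protein[1], peptides_per_protein[2]),
                    n_proteins, replace = TRUE)
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N", "P",
            "Q", "S", "T", "V", "W", "Y")
    psm_rows <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      k <- n_pep[i]
      g <- rgamma(k, shape = 1)
      w <- g / sum(g)
      peptides <- vapply(seq_len(k), function(j) {
        paste0(paste(sample(aa, 9, replace = TRUE), collapse = ""), "K")
      }, character(1))
      charge <- sample(2:4, k, replace = TRUE)
      parent_mz <- runif(k, 400, 1200)
      rt <- runif(k, 5, 175)
      log_e <- runif(k, -6, -1.6)
      mc <- rbinom(k, 1, 0.2)
      samp_on <- which(detected[i, ])
      if (length(samp_on) == 0) next
      psm_rows[[i]] <- tibble(
        protein_id = protein_id[i],
        peptide = rep(peptides, times = length(samp_on)),
        charge = as.integer(rep(charge, times = length(samp_on))),
        parent_mz = rep(parent_mz, times = length(samp_on)),
        retention_time = rep(rt, times = length(samp_on)),
        fragment_intensity_sum =
          as.vector(outer(w, 2^latent[i, samp_on, drop = TRUE])),
        sample_id = rep(design$sample_id[samp_on], each = k),
        log_e = rep(log_e, times = length(samp_on)),
        missed_cleavages = as.integer(rep(mc, times = length(samp_on)))
      )
    }
    psms <- bind_rows(psm_rows)
    truth <- dplyr::bind_cols(
      tibble(protein_id = protein_id, baseline = baseline, effect = effect),
      as_tibble(latent) %>%
        rlang::set_names(paste0("latent_", design$sample_id)),
      as_tibble(detected) %>%
        rlang::set_names(paste0("detected_", design$sample_id))
    )
    structure(list(psms = psms, truth = truth, design = design,
                   config = config),
              class = "tic_sim")
  })
}

#' @export
print.tic_sim <- function(x, ...) {
  cat("<tic_sim> ", x$config$n_proteins, " proteins x ",
      nrow(x$design), " runs; ", nrow(x$psms), " PSMs; pi_de = ",
      x$config$pi_de, ", delta = ", x$config$delta,
      ", sigma_rep = ", x$config$sigma_rep,
      ", seed = ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' False-positive calibration of the differential procedures
#'
#' Simulates proteins with no strain effect — every log2 value is
#' independent `Normal(mu0, sigma_rep)` — runs the requested differential
#' procedure exactly as the pipeline configures it (fold-change filter
#' disabled), and returns the flagged fraction. Under the defaults the
#' expected values are analytic: the z-score rule flags
#' `2 * (1 - pnorm(z_cutoff)) ~ 0.05`, and the signal-to-noise rule flags
#' `2 * (1 - pnorm(snr_cutoff / sqrt(2))) ~ 0.048`, independent of
#' `sigma_rep`, which cancels in both statistics.
#'
#' @param n_proteins Number of null proteins (>= 1000 recommended; fewer
#'   triggers a warning about Monte-Carlo error).
#' @param sigma_rep Per-cell noise SD on the log2 scale.
#' @param seed Integer seed.
#' @param procedure `"zscore"` (one run per strain) or `"wstat"` (two).
#' @param mu0 Baseline log2 abundance (does not affect the result).
#' @param z_cutoff,snr_cutoff Cut-offs passed to the procedures.
#' @return The flagged fraction (a single number in [0, 1]).
#' @export
null_calibration <- function(n_proteins, sigma_rep = 0.5, seed = 1,
                             procedure = c("zscore", "wstat"),
                             mu0 = 10, z_cutoff = 1.96, snr_cutoff = 2.8) {
  procedure <- match.arg(procedure)
  if (n_proteins < 1) stop_config("n_proteins must be >= 1")
  if (n_proteins < 1000) {
    warn("null_calibration: fewer than 1000 proteins; Monte-Carlo error will be large")
  }
  n_rep <- if (procedure == "wstat") 2 else 1
  design <- run_design(
    sample_id = c(paste0("WT_r", seq_len(n_rep)),
                  paste0("mut_r", seq_len(n_rep))),
    strain = rep(c("WT", "mutant"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2)
  )
  with_seed(seed, {
    lg <- matrix(rnorm(n_proteins * 2 * n_rep, mu0, sigma_rep),
                 nrow = n_proteins)
    m <- tic_matrix(lg, design)
    res <- if (procedure == "zscore") {
      zscore_diff(m, z_cutoff = z_cutoff)
    } else {
      wstat_diff(m, snr_cutoff = snr_cutoff, fc_cutoff = 0)
    }
    mean(res$flagged)
  })
}
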