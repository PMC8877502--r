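#' Shipped stress-signature overlap panels
#'
#' Accession lists of proteins more abundant in the VDAC-less *N. crassa*
#' strain that are shared with transcriptome-derived stress signatures:
#' \describe{
#'   \item{`upr_er`}{29 proteins also predicted to be upregulated under
#'     ER-unfolded-protein-response-inducing conditions (DTT or
#'     tunicamycin).}
#'   \item{`menadione`}{12 proteins also more abundant in
#'     menadione-treated, oxidatively stressed cells.}
#' }
#' The two panels share 8 accessions — the proteins elevated in all three
#' conditions (VDAC loss, oxidative stress, UPR-ER).
#'
#' @return A named list of two [gene_set()]s.
#' @examples
#' panels <- stress_overlap_panels()
#' venn_regions(panels)
#' @export
stress_overlap_panels <- function() {
  list(
    upr_er = read_gene_set(
      system.file("extdata", "upr_er_shared_up.tsv", package = "ticdiff"),
      name = "UPR-ER shared"
    ),
    menadione = read_gene_set(
      system.file("extdata", "menadione_shared_up.tsv", package = "ticdiff"),
      name = "menadione shared"
    )
  )
}
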