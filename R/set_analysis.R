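#' Count proteins per subcellular compartment
#'
#' Intersects a protein list with user-supplied compartment gene sets
#' (mitochondrial, ribosomal, ER, Golgi, ...). Assignment is multi-label: a
#' protein appearing in several compartment lists is counted in each, and
#' is reported in the `multi_label` attribute. Proteins matching no
#' compartment are reported in the `unassigned` attribute.
#'
#' @param proteins Character vector of accessions, or a [gene_set()].
#' @param compartments List of [gene_set()]s (or a named list of character
#'   vectors) with distinct names.
#' @return A tibble with one row per compartment: `compartment`, `n`,
#'   `members` (list-column). Attributes: `unassigned` (character),
#'   `multi_label` (tibble of proteins in more than one compartment).
#' @export
annotate_compartments <- function(proteins, compartments) {
  proteins <- as_gene_set(proteins, "query")$ids
  if (length(proteins) == 0) stop_config("proteins must be non-empty")
  compartments <- as_gene_set_list(compartments)
  nm <- vapply(compartments, function(s) s$name, character(1))
  if (anyDuplicated(nm)) {
    stop_config(paste0("duplicate compartment names: ",
                       paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  rows <- purrr::map(compartments, function(s) {
    memb <- intersect(proteins, s$ids)
    tibble(compartment = s$name, n = length(memb), members = list(memb))
  })
  out <- bind_rows(rows)
  hits <- table(unlist(out$members))
  multi <- tibble(
    protein_id = names(hits)[hits > 1],
    n_compartments = as.integer(hits[hits > 1])
  )
  attr(out, "unassigned") <- setdiff(proteins, names(hits))
  attr(out, "multi_label") <- multi
  out
}

#' Decompose 2-3 gene sets into disjoint Venn regions
#'
#' Computes the classical Venn decomposition: each accession in the union
#' is assigned to exactly one region according to the combination of sets
#' it belongs to (3 regions for two sets, 7 for three). Region counts
#' therefore sum to the size of the union.
#'
#' @param sets List of 2 or 3 [gene_set()]s (or named character vectors).
#' @return A tibble of class `venn_result` with one row per region:
#'   `region` (label like `"A & B"`), `sets` (list of member set names),
#'   `degree` (number of sets in the region), `n`, `members` (list-column).
#'   Attribute `set_names` preserves the input order.
#' @export
venn_regions <- function(sets) {
  sets <- as_gene_set_list(sets)
  k <- length(sets)
  if (k < 2 || k > 3) {
    stop_config("venn_regions supports 2 or 3 sets; report pairwise overlaps for more")
  }
  nm <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop_config("venn_regions: set names must be distinct")
  ids <- purrr::map(sets, "ids")
  universe <- unique(unlist(ids))
  membership <- vapply(ids, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  # every non-empty subset of sets defines a region
  combos <- rev(expand.grid(rep(list(c(TRUE, FALSE)), k)))[, k:1, drop = FALSE]
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(combos)), function(i) {
    pattern <- as.logical(combos[i, ])
    in_region <- apply(membership, 1, function(row) all(row == pattern))
    memb <- universe[in_region]
    tibble(
      region = paste(nm[pattern], collapse = " & "),
      sets = list(nm[pattern]),
      degree = sum(pattern),
      n = length(memb),
      members = list(memb)
    )
  })
  out <- bind_rows(rows) %>% arrange(.data$degree, .data$region)
  structure(out, class = c("venn_result", class(out)), set_names = nm)
}

#' Overlap of a differential list with a signature
#'
#' Returns the number of accessions shared between a differential-protein
#' list and a reference signature (for example a transcriptome-derived
#' stress signature), together with the shared fraction of the
#' differential list.
#'
#' @param diff_list Non-empty [gene_set()] (or character vector) of
#'   differential proteins.
#' @param signature Non-empty [gene_set()] (or character vector).
#' @return A one-row tibble: `diff_list`, `signature`, `n_diff`,
#'   `n_signature`, `n_overlap`, `fraction` (= `n_overlap / n_diff`),
#'   `members` (list-column).
#' @export
overlap_fraction <- function(diff_list, signature) {
  diff_list <- as_gene_set(diff_list, "diff")
  signature <- as_gene_set(signature, "signature")
  if (length(diff_list$ids) == 0) {
    stop_config("diff_list is empty: overlap fraction undefined")
  }
  if (length(signature$ids) == 0) stop_config("signature is empty")
  shared <- intersect(diff_list$ids, signature$ids)
  n_diff <- length(diff_list$ids)
  n_sig <- length(signature$ids)
  tibble(
    diff_list = diff_list$name,
    signature = signature$name,
    n_diff = n_diff,
    n_signature = n_sig,
    n_overlap = length(shared),
    fraction = length(shared) / n_diff,
    members = list(shared)
  )
}

#' Category over-representation by the hypergeometric test
#'
#' Tests each functional category for over-representation in a query list
#' drawn from a stated universe (by default the proteins detected in both
#' strains). For a category of size `K` in a universe of size `N`, a query
#' of size `n` and `k` query hits in the category, the p-value is the
#' hypergeometric upper tail `P(X >= k)`. P-values are adjusted across
#' categories with Benjamini-Hochberg by default. Categories are
#' intersected with the universe before testing, and the query must be a
#' subset of the universe.
#'
#' @param query [gene_set()] (or character vector) of interesting
#'   accessions.
#' @param categories List of [gene_set()]s to test.
#' @param universe [gene_set()] (or character vector) defining the
#'   background.
#' @param adjust Method passed to [stats::p.adjust()]; default `"BH"`.
#' @return A tibble of class `enrich_result`, one row per category:
#'   `category`, `k`, `K`, `n`, `N`, `p_value`, `q_value`, `members`
#'   (list-column of query hits), sorted by `p_value`.
#' @export
enrich_sets <- function(query, categories, universe, adjust = "BH") {
  query <- as_gene_set(query, "query")
  universe <- as_gene_set(universe, "universe")
  categories <- as_gene_set_list(categories)
  stray <- setdiff(query$ids, universe$ids)
  if (length(stray) > 0) {
    stop_config(paste0("query accessions outside the universe: ",
                       paste(head(stray, 10), collapse = ", "),
                       if (length(stray) > 10) ", ..." else ""))
  }
  N <- length(universe$ids)
  n <- length(query$ids)
  rows <- purrr::map(categories, function(cat) {
    in_univ <- intersect(cat$ids, universe$ids)
    hits <- intersect(query$ids, in_univ)
    K <- length(in_univ)
    k <- length(hits)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(category = cat$name, k = k, K = K, n = n, N = N,
           p_value = p, members = list(hits))
  })
  out <- bind_rows(rows) %>%
    mutate(q_value = p.adjust(.data$p_value, method = adjust)) %>%
    select("category", "k", "K", "n", "N", "p_value", "q_value", "members") %>%
    arrange(.data$p_value)
  structure(out, class = c("enrich_result", class(out)), adjust = adjust)
}
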