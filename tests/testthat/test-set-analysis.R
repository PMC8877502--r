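test_that("compartment annotation counts intersections, multi-label allowed", {
  got <- annotate_compartments(c("A", "B", "C"),
                               list(organelle = c("B", "C", "D")))
  expect_equal(got$n, 2L)
  expect_setequal(got$members[[1]], c("B", "C"))
  expect_setequal(attr(got, "unassigned"), "A")

  got2 <- annotate_compartments(
    c("A", "B"),
    list(mito = c("A", "B"), er = c("B", "Z"))
  )
  expect_equal(got2$n[got2$compartment == "mito"], 2L)
  expect_equal(got2$n[got2$compartment == "er"], 1L)
  ml <- attr(got2, "multi_label")
  expect_equal(ml$protein_id, "B")
  expect_equal(ml$n_compartments, 2L)

  expect_error(
    annotate_compartments("A", list(x = "A", x = "B")),
    "duplicate", class = "ticdiff_config_error"
  )
})

test_that("compartment counts equal brute-force intersections on random sets", {
  set.seed(14)
  universe <- sprintf("NCU%05d", 1:200)
  proteins <- sample(universe, 50)
  sets <- list(
    s1 = sample(universe, 40), s2 = sample(universe, 70),
    s3 = sample(universe, 25)
  )
  got <- annotate_compartments(proteins, sets)
  for (nm in names(sets)) {
    expect_equal(got$n[got$compartment == nm],
                 sum(proteins %in% sets[[nm]]))
  }
})

test_that("venn regions are disjoint, exhaustive and order-symmetric", {
  set.seed(21)
  universe <- sprintf("G%04d", 1:120)
  for (rep in 1:5) {
    sets <- list(A = sample(universe, 30), B = sample(universe, 45),
                 C = sample(universe, 20))
    v <- venn_regions(sets)
    expect_equal(nrow(v), 7L)
    expect_equal(sum(v$n), length(unique(unlist(sets))))
    members <- unlist(v$members)
    expect_equal(anyDuplicated(members), 0L)
    # brute-force decomposition per element
    for (r in seq_len(nrow(v))) {
      inside <- v$sets[[r]]
      outside <- setdiff(names(sets), inside)
      expected <- Reduce(intersect, sets[inside])
      for (o in outside) expected <- setdiff(expected, sets[[o]])
      expect_setequal(v$members[[r]], expected)
    }
    # permuting input order permutes labels but not region contents
    v2 <- venn_regions(sets[c("C", "A", "B")])
    key <- function(x) vapply(x$sets, function(s) paste(sort(s), collapse = "|"),
                              character(1))
    expect_equal(sort(paste(key(v), v$n)), sort(paste(key(v2), v2$n)))
  }

  same <- venn_regions(list(X = c("a", "b"), Y = c("b", "a")))
  expect_equal(same$n[same$degree == 2], 2L)
  expect_true(all(same$n[same$degree == 1] == 0L))
  disjoint <- venn_regions(list(X = c("a", "b"), Y = c("c")))
  expect_equal(disjoint$n[disjoint$degree == 2], 0L)
  expect_error(venn_regions(list(A = "a", B = "b", C = "c", D = "d")),
               class = "ticdiff_config_error")
})

test_that("shipped stress-signature panels have the published overlap structure", {
  panels <- stress_overlap_panels()
  expect_equal(length(panels$upr_er), 29L)
  expect_equal(length(panels$menadione), 12L)
  v <- venn_regions(panels)
  expect_equal(v$n[v$degree == 2], 8L)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # N = 20, K = 5, n = 5: enumerate all C(20,5) draws
  universe <- gene_set("u", sprintf("g%02d", 1:20))
  category <- gene_set("cat", sprintf("g%02d", 1:5))
  query <- gene_set("q", sprintf("g%02d", c(1:4, 20)))  # k = 4
  res <- enrich_sets(query, list(category), universe)
  expect_equal(res$k, 4L)
  expect_equal(res$p_value, enum_hyper_tail(20, 5, 5, 4), tolerance = 1e-12)

  # category exactly equals the query: minimal p
  res2 <- enrich_sets(gene_set("q", sprintf("g%02d", 1:5)),
                      list(category), universe)
  expect_equal(res2$p_value, 1 / choose(20, 5), tolerance = 1e-12)

  # k at its expectation is unremarkable
  big_u <- gene_set("u", sprintf("g%03d", 1:100))
  big_c <- gene_set("cat", sprintf("g%03d", 1:50))
  at_exp <- gene_set("q", sprintf("g%03d", c(1:5, 51:55)))  # k = 5 = nK/N
  res3 <- enrich_sets(at_exp, list(big_c), big_u)
  expect_gt(res3$p_value, 0.3)

  expect_error(
    enrich_sets(gene_set("q", "not_in_universe"), list(category), universe),
    "not_in_universe", class = "ticdiff_config_error"
  )
})

test_that("adjusted p-values are BH and monotone in raw p", {
  set.seed(4)
  universe <- sprintf("g%03d", 1:200)
  cats <- lapply(1:8, function(i) sample(universe, sample(10:60, 1)))
  names(cats) <- paste0("c", 1:8)
  query <- sample(universe, 30)
  res <- enrich_sets(query, cats, universe)
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  expect_true(all(diff(res$q_value[order(res$p_value)]) >= -1e-15))
  expect_true(all(res$q_value >= res$p_value - 1e-15))
})

test_that("overlap fractions report count over differential-list size", {
  diff_list <- gene_set("up", sprintf("d%03d", 1:97))
  signature <- gene_set("sig", c(sprintf("d%03d", 1:29), sprintf("x%02d", 1:40)))
  got <- overlap_fraction(diff_list, signature)
  expect_equal(got$n_overlap, 29L)
  expect_equal(got$fraction, 29 / 97, tolerance = 1e-12)

  expect_equal(overlap_fraction(diff_list, gene_set("s", "zzz"))$fraction, 0)
  expect_equal(
    overlap_fraction(diff_list, gene_set("s", c(diff_list$ids, "zzz")))$fraction,
    1
  )
  expect_error(overlap_fraction(gene_set("e", character()), signature),
               class = "ticdiff_config_error")
})
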