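# Direct summation of the hypergeometric mass function: the independent
# oracle for the upper-tail p-value.
pmf_upper_tail <- function(overlap, bicluster_size, pathway_size, universe) {
  ks <- overlap:min(bicluster_size, pathway_size)
  sum(choose(pathway_size, ks) *
        choose(universe - pathway_size, bicluster_size - ks)) /
    choose(universe, bicluster_size)
}

test_that("hypergeometric p-value equals direct pmf summation", {
  expect_equal(hypergeom_pvalue(4, 5, 10, 100),
               pmf_upper_tail(4, 5, 10, 100), tolerance = 1e-10)
  set.seed(51)
  for (i in 1:60) {
    universe <- sample(20:500, 1)
    pathway <- sample.int(universe, 1)
    bicl <- sample.int(universe, 1)
    overlap <- sample(0:min(pathway, bicl), 1)
    p <- hypergeom_pvalue(overlap, bicl, pathway, universe)
    oracle <- pmf_upper_tail(overlap, bicl, pathway, universe)
    expect_equal(p, oracle, tolerance = 1e-10)
  }
})

test_that("hypergeometric edge cases and validation", {
  expect_equal(hypergeom_pvalue(0, 5, 10, 100), 1)       # P(X >= 0) = 1
  expect_equal(hypergeom_pvalue(5, 5, 100, 100), 1)      # pathway = universe
  expect_error(hypergeom_pvalue(6, 5, 10, 100), "inconsistent")
  expect_error(hypergeom_pvalue(2, 5, 101, 100), "inconsistent")
  expect_error(hypergeom_pvalue(-1, 5, 10, 100), "non-negative")
})

test_that("Benjamini-Yekutieli matches the step-down formula", {
  expect_equal(benjamini_yekutieli(0.2), 0.2)  # m = 1: c_1 = 1
  # c_3 = 11/6; all three collapse to 3 * (11/6) * 0.03 / 3 = 0.055
  expect_equal(benjamini_yekutieli(c(0.01, 0.02, 0.03)),
               c(0.055, 0.055, 0.055))
  # explicit step-up computation as an independent check
  p <- c(0.4, 0.01, 0.2, 0.05)
  m <- length(p); cm <- sum(1 / seq_len(m))
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * cm * p[ord] / seq_len(m)))))
  q <- numeric(m); q[ord] <- q_sorted
  expect_equal(benjamini_yekutieli(p), q)
  expect_error(benjamini_yekutieli(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BY q-values dominate BH and are monotone on sorted input", {
  set.seed(53)
  for (i in 1:30) {
    p <- runif(sample(2:40, 1))
    q <- benjamini_yekutieli(p)
    expect_true(all(q >= stats::p.adjust(p, method = "BH") - 1e-12))
    expect_true(all(q >= p - 1e-12 & q <= 1))
    qs <- benjamini_yekutieli(sort(p))
    expect_true(all(diff(qs) >= -1e-12))
  }
})

test_that("pathway enrichment proportion detects exact-pathway biclusters", {
  db <- pathway_db(list(pw0 = 0:9, pw1 = 10:19, pw2 = 20:29), p = 30)
  bc <- bc_from(list(list(0:2, 0:9), list(3:5, 10:19)), n = 6, p = 30)
  res <- pathway_enrichment_proportion(bc, db, q_threshold = 0.05)
  expect_equal(res$proportion, 1)
  expect_equal(nrow(res$results), 2 * 3)
  expect_true(all(res$results$q_value >= res$results$p_value - 1e-12))

  zero <- bc_from(list(list(0, 0:4)), n = 2, p = 40)
  db1 <- pathway_db(list(pw = 30:39), p = 40)
  expect_equal(pathway_enrichment_proportion(zero, db1)$proportion, 0)
  expect_error(pathway_enrichment_proportion(
    bc_from(list(list(integer(), integer())), 2, 30), db), "non-empty")
})

test_that("random gene sets are enriched at no more than the nominal rate", {
  db <- pathway_db(list(pw0 = 0:19, pw1 = 20:39, pw2 = 40:59), p = 200)
  hits <- 0; total <- 0
  for (seed in 1:20) {
    set.seed(seed)
    bc <- random_biclustering(10, 200, K = 5, size_samples = 3,
                              size_genes = 25)
    res <- pathway_enrichment_proportion(bc, db, q_threshold = 0.05)
    enriched <- tapply(res$results$enriched, res$results$bicluster, any)
    hits <- hits + sum(enriched); total <- total + length(enriched)
  }
  # BY controls FDR under dependence; with discrete tests the per-bicluster
  # false-positive rate stays at or below ~0.05 up to Monte-Carlo error
  expect_lte(hits / total, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})

test_that("distinct top-pathway count collapses shared enrichment", {
  db <- pathway_db(list(pwA = 0:9, pwB = 10:19), p = 20)
  same <- bc_from(rep(list(list(0:1, 0:9)), 4), n = 4, p = 20)
  res_same <- pathway_enrichment_proportion(same, db)
  expect_equal(distinct_enriched_count(res_same$results), 1)

  distinct <- bc_from(list(list(0:1, 0:9), list(2:3, 10:19)), n = 4, p = 20)
  res_two <- pathway_enrichment_proportion(distinct, db)
  expect_equal(distinct_enriched_count(res_two$results), 2)

  # exact tie on q: winner is deterministic by pathway id order
  tied <- bc_from(list(list(0:1, c(0:4, 10:14))), n = 4, p = 20)
  res_tie <- pathway_enrichment_proportion(tied, db)
  top <- res_tie$results[order(res_tie$results$q_value,
                               res_tie$results$pathway), ][1, ]
  expect_equal(top$pathway, "pwA")
  expect_equal(distinct_enriched_count(res_tie$results), 1)
})

test_that("knockout score is 1 for the ideal biclustering and 0 when empty", {
  fx <- simulate_knockout_fixture(n_genotypes = 5, n_tissues = 3,
                                  replicates = 2, seed = 3)
  expect_equal(nrow(fx$Y), 30)
  expect_true(all(lengths(fx$genotype_traits) == 6))
  expect_true(all(lengths(fx$tissue_traits) == 10))

  ideal <- ideal_knockout_biclustering(fx)
  res <- knockout_biclustering_score(ideal, fx$genotype_traits,
                                     fx$knockout_pathways, fx$db)
  expect_equal(res$proportion, 1)
  expect_true(all(res$detail$best_f1 == 1))

  none <- biclustering(list(), nrow(fx$Y), ncol(fx$Y))
  expect_equal(knockout_biclustering_score(none, fx$genotype_traits,
                                           fx$knockout_pathways,
                                           fx$db)$proportion, 0)
  expect_error(knockout_biclustering_score(ideal, fx$genotype_traits,
                                           list(), fx$db), "no assigned")
})

test_that("knockout fixture validates its design arithmetic", {
  expect_error(simulate_knockout_fixture(n_genotypes = 0), ">= 1")
  expect_error(simulate_knockout_fixture(n_pathways = 10,
                                         genes_per_pathway = 20, p = 100),
               "exceeds")
  fx <- simulate_knockout_fixture(n_genotypes = 4, n_tissues = 2,
                                  replicates = 2, seed = 5)
  expect_equal(dim(fx$Y), c(16, 80))
  expect_identical(fx$Y,
                   simulate_knockout_fixture(n_genotypes = 4, n_tissues = 2,
                                             replicates = 2, seed = 5)$Y)
  # truth: one bicluster per knockout plus one dense bicluster per tissue
  expect_equal(length(fx$truth), 4 + 2)
})

test_that("zero knockout effect leaves enrichment near the null rate", {
  hits <- 0; total <- 0
  for (seed in 1:10) {
    fx <- simulate_knockout_fixture(n_genotypes = 6, n_tissues = 2,
                                    replicates = 2, genes_per_pathway = 15,
                                    effect_mean = 0, seed = seed)
    set.seed(seed + 1000)
    bc <- random_biclustering(nrow(fx$Y), ncol(fx$Y), K = 6,
                              size_samples = 4, size_genes = 20)
    res <- knockout_biclustering_score(bc, fx$genotype_traits,
                                       fx$knockout_pathways, fx$db,
                                       q_threshold = 0.05)
    hits <- hits + sum(res$detail$enriched)
    total <- total + nrow(res$detail)
  }
  expect_lte(hits / total, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})
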