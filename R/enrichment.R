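#' One-tailed hypergeometric enrichment p-value
#'
#' Upper-tail probability `P(X >= overlap)` where X counts pathway genes in
#' a random draw of `bicluster_size` genes from a universe of
#' `universe_size` containing `pathway_size` pathway genes (Fisher's
#' one-tailed test). Zero overlap gives p = 1.
#'
#' @param overlap Observed pathway genes inside the bicluster.
#' @param bicluster_size Genes in the bicluster.
#' @param pathway_size Genes in the pathway.
#' @param universe_size Genes in the universe.
#' @return The p-value.
#' @export
hypergeom_pvalue <- function(overlap, bicluster_size, pathway_size, universe_size) {
  vals <- c(overlap, bicluster_size, pathway_size, universe_size)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("all counts must be non-negative integers", call. = FALSE)
  }
  if (overlap > min(bicluster_size, pathway_size) ||
      max(bicluster_size, pathway_size) > universe_size) {
    stop("inconsistent counts: overlap <= min(bicluster, pathway) <= universe required",
         call. = FALSE)
  }
  stats::phyper(overlap - 1, m = pathway_size,
                n = universe_size - pathway_size,
                k = bicluster_size, lower.tail = FALSE)
}

#' Benjamini-Yekutieli adjusted q-values
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence:
#' p-values are inflated by the harmonic-number factor `c_m = sum 1/i`
#' relative to Benjamini-Hochberg, then capped at 1. Output is in input
#' order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values; always `>=` the corresponding BH q-values.
#' @export
benjamini_yekutieli <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BY")
}

#' Pathway enrichment proportion of a biclustering
#'
#' Tests every (non-empty bicluster, pathway) pair with the one-tailed
#' hypergeometric test, adjusts all tests jointly with Benjamini-Yekutieli,
#' and reports the fraction of biclusters enriched (any q below
#' `q_threshold`) for at least one pathway — the standard measure of gene
#' clustering quality when the true structure is unknown.
#'
#' @param bc A [biclustering()]; must contain at least one non-empty
#'   bicluster.
#' @param db A [pathway_db()]; its universe size is the test universe.
#' @param q_threshold Significance threshold on the adjusted q-value.
#' @return A list: `proportion`, `n_tested`, and a `results` tibble of
#'   class `enrichment_results` (one row per test: `bicluster`, `pathway`,
#'   `overlap`, `bicluster_genes`, `pathway_genes`, `universe`, `p_value`,
#'   `q_value`, `enriched`), with the adjustment family recorded in the
#'   `adjust_family` attribute.
#' @export
pathway_enrichment_proportion <- function(bc, db, q_threshold = 0.05) {
  stopifnot(inherits(bc, "biclustering"), inherits(db, "pathway_db"))
  nonempty <- which(!vapply(bc$biclusters, is_empty_bicluster, logical(1)))
  if (length(nonempty) == 0) {
    stop("biclustering has no non-empty biclusters to test", call. = FALSE)
  }
  path_ids <- names(db$pathways)
  rows <- list()
  for (k in nonempty) {
    genes_k <- bc$biclusters[[k]]$genes
    for (pid in path_ids) {
      genes_p <- db$pathways[[pid]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        bicluster = k, pathway = pid,
        overlap = length(intersect(genes_k, genes_p)),
        bicluster_genes = length(genes_k),
        pathway_genes = length(genes_p),
        universe = db$p)
    }
  }
  results <- do.call(rbind, rows)
  results$p_value <- mapply(hypergeom_pvalue, results$overlap,
                            results$bicluster_genes, results$pathway_genes,
                            results$universe)
  results$q_value <- benjamini_yekutieli(results$p_value)
  results$enriched <- results$q_value < q_threshold
  attr(results, "adjust_family") <- "joint across all (bicluster, pathway) tests"
  class(results) <- c("enrichment_results", class(results))
  enriched_bc <- tapply(results$enriched, results$bicluster, any)
  list(proportion = mean(enriched_bc),
       n_tested = length(nonempty),
       results = results)
}

#' Count distinct top-enriched pathways
#'
#' For each tested bicluster, takes the pathway with the smallest q-value
#' (ties broken deterministically by pathway id order) and counts how many
#' distinct pathways appear — a guard against a run of many biclusters all
#' enriched for the same pathway looking diverse.
#'
#' @param results An `enrichment_results` tibble from
#'   [pathway_enrichment_proportion()].
#' @return Integer count of distinct top pathways.
#' @export
distinct_enriched_count <- function(results) {
  if (nrow(results) == 0) stop("results must be non-empty", call. = FALSE)
  ord <- order(results$bicluster, results$q_value, results$pathway)
  sorted <- results[ord, ]
  top <- sorted[!duplicated(sorted$bicluster), ]
  length(unique(top$pathway))
}

#' Knockout biclustering score
#'
#' The joint sample-and-gene clustering test available in a knockout
#' design: for each knocked-out gene, find the bicluster whose sample set
#' best matches the knockout genotype's samples (highest F1; ties go to
#' the lowest bicluster index), then test whether that bicluster's genes
#' are enriched for any pathway containing the knocked-out gene. The
#' adjustment family is the per-knockout set of its own pathways (the
#' narrow family matching the question asked of each knockout). The score
#' is the fraction of knockouts whose best-matching bicluster is enriched
#' at `q_threshold`.
#'
#' @param bc A [biclustering()] (empty, or all-empty, scores 0).
#' @param knockout_traits A [trait_annotation()] (or named list) giving
#'   each knockout genotype's sample set.
#' @param gene_pathways Named list mapping each knockout to the pathway ids
#'   containing its gene; every knockout needs at least one.
#' @param db A [pathway_db()].
#' @param q_threshold Significance threshold on the adjusted q-value.
#' @return A list: `proportion` and a `detail` tibble (`knockout`,
#'   `best_bicluster`, `best_f1`, `best_pathway`, `min_q`, `enriched`).
#' @export
knockout_biclustering_score <- function(bc, knockout_traits, gene_pathways,
                                        db, q_threshold = 0.05) {
  stopifnot(inherits(bc, "biclustering"), inherits(db, "pathway_db"))
  kos <- names(knockout_traits)
  if (is.null(kos) || length(kos) == 0) stop("knockout traits required", call. = FALSE)
  for (ko in kos) {
    if (length(knockout_traits[[ko]]) == 0) {
      stop(sprintf("knockout '%s' has an empty sample set", ko), call. = FALSE)
    }
    paths <- gene_pathways[[ko]]
    if (is.null(paths) || length(paths) == 0) {
      stop(sprintf("knockout '%s' has no assigned pathways", ko), call. = FALSE)
    }
    if (!all(paths %in% names(db$pathways))) {
      stop(sprintf("knockout '%s' references pathways absent from the database", ko),
           call. = FALSE)
    }
  }
  rows <- lapply(kos, function(ko) {
    S <- knockout_traits[[ko]]
    if (length(bc) == 0) {
      return(tibble::tibble(knockout = ko, best_bicluster = NA_integer_,
                            best_f1 = 0, best_pathway = NA_character_,
                            min_q = NA_real_, enriched = FALSE))
    }
    f1s <- vapply(bc$biclusters, function(b) f1_trait(S, b$samples), numeric(1))
    best <- which.max(f1s) # which.max takes the lowest index on ties
    genes_b <- bc$biclusters[[best]]$genes
    paths <- sort(gene_pathways[[ko]])
    pvals <- vapply(paths, function(pid) {
      hypergeom_pvalue(length(intersect(genes_b, db$pathways[[pid]])),
                       length(genes_b), length(db$pathways[[pid]]), db$p)
    }, numeric(1))
    qvals <- benjamini_yekutieli(pvals)
    top <- which.min(qvals)
    tibble::tibble(knockout = ko, best_bicluster = as.integer(best),
                   best_f1 = f1s[best], best_pathway = paths[top],
                   min_q = qvals[top], enriched = qvals[top] < q_threshold)
  })
  detail <- do.call(rbind, rows)
  attr(detail, "adjust_family") <- "per knockout, across its own pathways"
  list(proportion = mean(detail$enriched), detail = detail)
}
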