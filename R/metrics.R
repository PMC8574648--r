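#' Jaccard index between two biclusters
#'
#' Cell-set Jaccard: `|A ∩ B| / |A ∪ B|` where each bicluster is the
#' Cartesian product of its sample and gene sets. Two empty biclusters
#' score 0 (nothing was recovered, nothing matched).
#'
#' @param b1,b2 [bicluster()] objects on a common grid.
#' @return A score in `[0, 1]`.
#' @export
jaccard <- function(b1, b2) {
  stopifnot(inherits(b1, "bicluster"), inherits(b2, "bicluster"))
  c1 <- n_cells(b1); c2 <- n_cells(b2)
  if (c1 == 0 && c2 == 0) return(0)
  inter <- intersection_cells(b1, b2)
  inter / (c1 + c2 - inter)
}

#' Mean bicluster redundancy
#'
#' Mean pairwise cell-set Jaccard index across the `K (K - 1) / 2` bicluster
#' pairs of a single run. 0 means the biclusters do not overlap at all
#' (ideal: the output is non-redundant); 1 means all biclusters are
#' identical. Needs at least two biclusters: with K < 2 there are no pairs,
#' so `NA` is returned with a warning rather than a silent 0.
#'
#' @param bc A [biclustering()].
#' @return A score in `[0, 1]`, or `NA` with a warning when K < 2.
#' @export
mbr <- function(bc) {
  stopifnot(inherits(bc, "biclustering"))
  K <- length(bc)
  if (K < 2) {
    warning("MBR is undefined for fewer than 2 biclusters; returning NA")
    return(NA_real_)
  }
  total <- 0
  for (k in seq_len(K - 1)) {
    for (l in (k + 1):K) {
      total <- total + jaccard(bc$biclusters[[k]], bc$biclusters[[l]])
    }
  }
  2 * total / (K * (K - 1))
}

frobenius <- function(M) sqrt(sum(M^2))

#' Normalised reconstruction error
#'
#' `NRE(Y, Yhat) = ||Y - Yhat||_F / (||Y||_F + ||Yhat||_F)` with
#' `Yhat = X B'`. 0 means perfect reconstruction; the maximum 1 is attained
#' e.g. at `Yhat = -Y`. Usable on real data since only Y and the returned
#' loadings are needed. Both Y and Yhat all-zero leaves the ratio undefined
#' and is an error.
#'
#' @param Y Expression matrix (n x p).
#' @param X Sample loadings (n x K).
#' @param B Gene loadings (p x K).
#' @return A score in `[0, 1]`.
#' @export
nre <- function(Y, X, B) {
  Y <- as.matrix(Y)
  Yhat <- factorisation(X, B) |> reconstruct()
  if (!all(dim(Yhat) == dim(Y))) {
    stop(sprintf("reconstruction is %d x %d but Y is %d x %d",
                 nrow(Yhat), ncol(Yhat), nrow(Y), ncol(Y)), call. = FALSE)
  }
  denom <- frobenius(Y) + frobenius(Yhat)
  if (denom == 0) stop("NRE undefined: Y and the reconstruction are both zero", call. = FALSE)
  frobenius(Y - Yhat) / denom
}

# d_max: optimal injective matching of biclusters maximising summed cell
# intersections, via maximum-weight bipartite matching.
match_dmax <- function(M) {
  pos <- which(M > 0, arr.ind = TRUE)
  if (nrow(pos) == 0) return(0)
  ka <- nrow(M); kr <- ncol(M)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, ka), rep(TRUE, kr)),
                                    edges = as.vector(t(cbind(pos[, 1], ka + pos[, 2]))))
  w <- M[pos]
  igraph::max_bipartite_match(g, weights = w)$matching_weight
}

#' Clustering error between two biclusterings
#'
#' Similarity `CE(A, R) = d_max / |U|`, where `d_max` is the largest total
#' cell intersection achievable by a one-to-one pairing of biclusters
#' (solved as an optimal assignment), and `|U|` sums, over grid cells, the
#' larger of the two coverage counts — so overlap and duplicate biclusters
#' inflate the union without inflating the match, and returning extra
#' copies of a bicluster is penalised. 1 means identical biclusterings.
#' Conventions for degenerate input: both biclusterings empty (zero covered
#' cells) score 1; exactly one empty scores 0.
#'
#' @param A,R [biclustering()] objects on a common grid.
#' @return A list of class `ce_decomposition`: `ce`, `d_max`, `u_size`, and
#'   the bicluster-pair `intersection` matrix (in cells).
#' @export
clustering_error <- function(A, R) {
  stopifnot(inherits(A, "biclustering"), inherits(R, "biclustering"))
  if (A$n != R$n || A$p != R$p) {
    stop(sprintf("grid mismatch: %dx%d vs %dx%d", A$n, A$p, R$n, R$p), call. = FALSE)
  }
  empty_a <- total_cells(A) == 0
  empty_r <- total_cells(R) == 0
  if (empty_a && empty_r) {
    return(structure(list(ce = 1, d_max = 0, u_size = 0,
                          intersection = matrix(0, length(A), length(R))),
                     class = "ce_decomposition"))
  }
  if (empty_a || empty_r) {
    return(structure(list(ce = 0, d_max = 0,
                          u_size = sum(pmax(coverage_counts(A), coverage_counts(R))),
                          intersection = matrix(0, length(A), length(R))),
                     class = "ce_decomposition"))
  }
  M <- matrix(0, nrow = length(A), ncol = length(R))
  for (k in seq_len(length(A))) {
    for (l in seq_len(length(R))) {
      M[k, l] <- intersection_cells(A$biclusters[[k]], R$biclusters[[l]])
    }
  }
  d_max <- match_dmax(M)
  u_size <- sum(pmax(coverage_counts(A), coverage_counts(R)))
  structure(list(ce = d_max / u_size, d_max = d_max, u_size = u_size,
                 intersection = M),
            class = "ce_decomposition")
}

#' @export
print.ce_decomposition <- function(x, ...) {
  cat(sprintf("<CE = %.4f (d_max = %g, |U| = %g)>\n", x$ce, x$d_max, x$u_size))
  invisible(x)
}

#' Brute-force clustering error (test oracle)
#'
#' Enumerates every injective matching between the two bicluster sets to
#' find d_max directly, and computes the coverage-aware union from cell
#' counts. Exponential in K, so restricted to at most 6 biclusters per
#' side; exists purely as an independent check on [clustering_error()].
#'
#' @param A,R [biclustering()] objects with at most 6 biclusters each.
#' @return The CE score.
#' @export
ce_brute_force <- function(A, R) {
  stopifnot(inherits(A, "biclustering"), inherits(R, "biclustering"))
  if (A$n != R$n || A$p != R$p) stop("grid mismatch", call. = FALSE)
  if (length(A) > 6 || length(R) > 6) {
    stop("brute-force CE is limited to 6 biclusters per side", call. = FALSE)
  }
  empty_a <- total_cells(A) == 0
  empty_r <- total_cells(R) == 0
  if (empty_a && empty_r) return(1)
  if (empty_a || empty_r) return(0)
  ka <- length(A); kr <- length(R)
  M <- outer(seq_len(ka), seq_len(kr),
             Vectorize(function(k, l) intersection_cells(A$biclusters[[k]],
                                                         R$biclusters[[l]])))
  M <- matrix(M, nrow = ka)
  # recursive enumeration of injective partial matchings
  best <- 0
  recurse <- function(k, used, acc) {
    if (k > ka) {
      best <<- max(best, acc)
      return(invisible())
    }
    recurse(k + 1, used, acc) # leave bicluster k unmatched
    for (l in seq_len(kr)) {
      if (!used[l]) {
        used[l] <- TRUE
        recurse(k + 1, used, acc + M[k, l])
        used[l] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, kr), 0)
  u_size <- sum(pmax(coverage_counts(A), coverage_counts(R)))
  best / u_size
}

#' F1 score of a bicluster's sample set against a trait
#'
#' Precision `|S ∩ F| / |F|` rewards containing only samples with the
#' trait; recall `|S ∩ F| / |S|` rewards containing all of them; F1 is
#' their harmonic mean. An empty bicluster sample set, or one disjoint from
#' the trait, scores 0 (so a maximum over biclusters is always defined).
#'
#' @param S 0-based sample indices carrying the trait (non-empty).
#' @param F_set 0-based sample indices of the bicluster.
#' @return A score in `[0, 1]`.
#' @export
f1_trait <- function(S, F_set) {
  S <- as_index_set(S, "trait sample")
  F_set <- as_index_set(F_set, "bicluster sample")
  if (length(S) == 0) stop("trait sample set must be non-empty", call. = FALSE)
  if (length(F_set) == 0) return(0)
  inter <- length(intersect(S, F_set))
  if (inter == 0) return(0)
  precision <- inter / length(F_set)
  recall <- inter / length(S)
  2 * precision * recall / (precision + recall)
}

#' Trait clustering ability
#'
#' For each trait, the best F1 score over all biclusters' sample sets; the
#' ability is the mean of these per-trait maxima. Restricting `traits` to
#' tissue traits gives the tissue clustering ability, to genotype traits
#' the genotype clustering ability, and so on.
#'
#' @param bc A [biclustering()] (may be empty: ability 0).
#' @param traits A [trait_annotation()] or named list of sample index sets.
#' @return A list: `mean` and a tibble `table` with columns `trait`,
#'   `best_f1`, `best_bicluster` (1-based index, `NA` when K = 0).
#' @export
trait_clustering_ability <- function(bc, traits) {
  stopifnot(inherits(bc, "biclustering"))
  if (length(traits) == 0) stop("at least one trait required", call. = FALSE)
  trait_names <- names(traits)
  rows <- lapply(seq_along(traits), function(i) {
    S <- traits[[i]]
    if (length(bc) == 0) {
      return(tibble::tibble(trait = trait_names[i], best_f1 = 0,
                            best_bicluster = NA_integer_))
    }
    scores <- vapply(bc$biclusters, function(b) f1_trait(S, b$samples),
                     numeric(1))
    best <- which.max(scores) # first index on ties
    tibble::tibble(trait = trait_names[i], best_f1 = scores[best],
                   best_bicluster = as.integer(best))
  })
  table <- do.call(rbind, rows)
  list(mean = mean(table$best_f1), table = table)
}

#' Recovery and relevance scores
#'
#' Recovery of a true bicluster is the best Jaccard index it achieves
#' against any recovered bicluster (how well that truth was found);
#' relevance of a recovered bicluster is its best Jaccard against any true
#' bicluster (whether what was returned matches anything real). An empty
#' recovered set gives recovery 0 everywhere.
#'
#' @param truth,recovered [biclustering()] objects on a common grid.
#' @return A list of two tibbles, `recovery` (one row per true bicluster)
#'   and `relevance` (one row per recovered bicluster), each with `score`
#'   and `best_match` columns.
#' @export
recovery_relevance <- function(truth, recovered) {
  stopifnot(inherits(truth, "biclustering"), inherits(recovered, "biclustering"))
  if (truth$n != recovered$n || truth$p != recovered$p) {
    stop("grid mismatch", call. = FALSE)
  }
  kt <- length(truth); kr <- length(recovered)
  J <- matrix(0, nrow = kt, ncol = kr)
  for (k in seq_len(kt)) {
    for (l in seq_len(kr)) {
      J[k, l] <- jaccard(truth$biclusters[[k]], recovered$biclusters[[l]])
    }
  }
  recovery <- tibble::tibble(
    bicluster = seq_len(kt),
    score = if (kr == 0) rep(0, kt) else apply(J, 1, max),
    best_match = if (kr == 0) rep(NA_integer_, kt) else apply(J, 1, which.max)
  )
  relevance <- tibble::tibble(
    bicluster = seq_len(kr),
    score = if (kt == 0) rep(0, kr) else apply(J, 2, max),
    best_match = if (kt == 0) rep(NA_integer_, kr) else apply(J, 2, which.max)
  )
  list(recovery = recovery, relevance = relevance)
}

#' Run-to-run similarity
#'
#' Clustering error between every unordered pair of runs of a (stochastic)
#' algorithm on one dataset. High values mean the algorithm returns similar
#' biclusters on each re-run; a deterministic method scores exactly 1.
#'
#' @param runs A list of at least two [biclustering()]s on a common grid.
#' @return A list: `pairs` tibble (`run1`, `run2`, `ce`), plus the `mean`
#'   and `median` pairwise score.
#' @export
run_similarity <- function(runs) {
  if (!is.list(runs) || length(runs) < 2) {
    stop("at least two runs are required", call. = FALSE)
  }
  idx <- utils::combn(length(runs), 2)
  ce <- apply(idx, 2, function(ij) {
    clustering_error(runs[[ij[1]]], runs[[ij[2]]])$ce
  })
  pairs <- tibble::tibble(run1 = idx[1, ], run2 = idx[2, ], ce = ce)
  list(pairs = pairs, mean = mean(ce), median = stats::median(ce))
}

#' Pearson correlation for robustness summaries
#'
#' Plain Pearson correlation between, e.g., the initial K an algorithm is
#' started with and the CE it achieves, or between recovered and true K.
#' Constant input leaves the correlation undefined; that case is signalled
#' with a warning and `NA` (matching result tables that mark such entries
#' rather than printing a number).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Pearson r in `[-1, 1]`, or `NA` with a warning.
#' @export
robustness_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("at least 3 observations are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation could not be calculated: constant input")
    return(NA_real_)
  }
  stats::cor(x, y)
}
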