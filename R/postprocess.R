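#' Threshold a factorisation into sparse bicluster memberships
#'
#' Algorithms that return dense loading matrices (NMF and tensor
#' factorisations in particular) often produce factors touching every
#' sample and gene. Thresholding masks the small entries: sample i belongs
#' to factor k iff `|X[i,k]|` exceeds `theta` times the factor's scale
#' (by default the column's maximum absolute entry), and likewise for
#' genes. Loadings from different algorithms differ by arbitrary per-column
#' scalings, so the per-column rule is scale-invariant; alternative rules
#' are pluggable. Absolute values are compared, so negative loadings count
#' as membership (membership is about magnitude, not direction). All-zero
#' columns yield empty biclusters. At `theta = 0` the membership is exactly
#' the non-zero pattern.
#'
#' Binary membership matrices (all entries 0 or 1, as returned by
#' algorithms that do not expose raw loadings) are detected under
#' `binary = "auto"` and passed through unthresholded.
#'
#' @param f A [factorisation()].
#' @param theta Threshold fraction, >= 0 (study default 0.01).
#' @param rule Scaling rule: `"column-max"` (default), `"matrix-max"`, or
#'   `"column-norm"` (per-column Euclidean norm).
#' @param binary `"auto"` (pass 0/1 matrices through) or `"never"`.
#' @return A [biclustering()] with one bicluster per factor, in factor
#'   order (empty biclusters retained).
#' @export
threshold_factorisation <- function(f, theta = 0.01,
                                    rule = c("column-max", "matrix-max", "column-norm"),
                                    binary = c("auto", "never")) {
  stopifnot(inherits(f, "factorisation"))
  rule <- match.arg(rule)
  binary <- match.arg(binary)
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) || theta < 0) {
    stop("theta must be a single value >= 0", call. = FALSE)
  }
  masks <- loading_masks(f, theta, rule, binary)
  blist <- lapply(seq_len(ncol(f$X)), function(k) {
    bicluster(which(masks$X[, k]) - 1L, which(masks$B[, k]) - 1L)
  })
  biclustering(blist, n = nrow(f$X), p = nrow(f$B))
}

# Logical membership masks for both loading matrices under one rule.
loading_masks <- function(f, theta, rule, binary) {
  if (binary == "auto" && all(f$X %in% c(0, 1)) && all(f$B %in% c(0, 1))) {
    return(list(X = f$X == 1, B = f$B == 1))
  }
  list(X = mask_matrix(f$X, theta, rule), B = mask_matrix(f$B, theta, rule))
}

mask_matrix <- function(M, theta, rule) {
  A <- abs(M)
  scale <- switch(rule,
                  "column-max" = apply(A, 2, max),
                  "matrix-max" = rep(max(A), ncol(A)),
                  "column-norm" = sqrt(colSums(A^2)))
  A > rep(theta * scale, each = nrow(A))
}

#' Drop empty biclusters and count the survivors
#'
#' The number of non-empty biclusters surviving post-processing is the
#' recovered K, the quantity to compare against the K a method was started
#' with when judging whether it learns the number of biclusters.
#'
#' @param bc A [biclustering()].
#' @return A list: `biclustering` without empty members, and `k_recovered`.
#' @export
drop_empty_and_count <- function(bc) {
  stopifnot(inherits(bc, "biclustering"))
  keep <- !vapply(bc$biclusters, is_empty_bicluster, logical(1))
  out <- biclustering(bc$biclusters[keep], n = bc$n, p = bc$p)
  list(biclustering = out, k_recovered = sum(keep))
}

#' Evaluate a grid of thresholds
#'
#' Applies [threshold_factorisation()] at each threshold and reports, per
#' row: recovered K, MBR of the thresholded biclustering, NRE of the masked
#' reconstruction (loadings with sub-threshold entries zeroed) when `Y` is
#' supplied, and CE against `truth` when supplied. Used to pick the working
#' threshold from quantities that are available even when the true
#' structure is unknown (MBR, NRE).
#'
#' @param f A [factorisation()].
#' @param thresholds Ascending non-empty numeric vector of thresholds.
#' @param Y Optional expression matrix for the NRE column.
#' @param truth Optional ground-truth [biclustering()] for the CE column.
#' @param rule Scaling rule passed to [threshold_factorisation()].
#' @return A tibble of class `threshold_sweep` with columns `theta`,
#'   `k_recovered`, `mbr`, and optionally `nre` and `ce`.
#' @export
threshold_sweep <- function(f, thresholds, Y = NULL, truth = NULL,
                            rule = "column-max") {
  stopifnot(inherits(f, "factorisation"))
  if (length(thresholds) == 0) stop("thresholds must be non-empty", call. = FALSE)
  if (is.unsorted(thresholds, strictly = FALSE)) {
    stop("thresholds must be ascending", call. = FALSE)
  }
  rows <- lapply(thresholds, function(theta) {
    bc <- threshold_factorisation(f, theta, rule = rule)
    row <- tibble::tibble(
      theta = theta,
      k_recovered = drop_empty_and_count(bc)$k_recovered,
      mbr = if (length(bc) >= 2) mbr(bc) else NA_real_
    )
    if (!is.null(Y)) {
      masks <- loading_masks(f, theta, rule, binary = "never")
      Xm <- f$X * masks$X
      Bm <- f$B * masks$B
      row$nre <- if (frobenius(Y) + frobenius(Xm %*% t(Bm)) > 0) {
        nre(Y, Xm, Bm)
      } else NA_real_
    }
    if (!is.null(truth)) row$ce <- clustering_error(truth, bc)$ce
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_sweep", class(out))
  out
}

#' Plot a threshold sweep
#'
#' @param object A [threshold_sweep()] tibble.
#' @param ... Unused.
#' @return A ggplot with one line per reported metric against the
#'   threshold (square-root x scale so small thresholds stay readable).
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  metrics <- intersect(c("mbr", "nre", "ce"), names(object))
  long <- do.call(rbind, lapply(metrics, function(mname) {
    tibble::tibble(theta = object$theta, metric = mname,
                   value = object[[mname]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$theta, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_sqrt() +
    ggplot2::labs(x = "threshold", y = "score", colour = NULL) +
    ggplot2::theme_minimal()
}
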