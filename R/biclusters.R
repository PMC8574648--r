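#' Construct a bicluster
#'
#' A bicluster is a subset of samples together with a subset of genes whose
#' expression is coherent; equivalently the set of (sample, gene) cells given
#' by the Cartesian product of the two index sets. Indices are 0-based
#' throughout the package, matching the on-disk membership format.
#'
#' A bicluster with either index set empty covers zero cells and is treated
#' as empty everywhere.
#'
#' @param samples Integer vector of 0-based sample indices (duplicates are
#'   collapsed; the set is stored sorted).
#' @param genes Integer vector of 0-based gene indices.
#' @return An object of class `bicluster`.
#' @examples
#' b <- bicluster(samples = 0:2, genes = c(5, 7))
#' n_cells(b)
#' @export
bicluster <- function(samples = integer(), genes = integer()) {
  samples <- as_index_set(samples, "samples")
  genes <- as_index_set(genes, "genes")
  structure(list(samples = samples, genes = genes), class = "bicluster")
}

as_index_set <- function(x, what) {
  if (length(x) == 0) return(integer())
  if (anyNA(x)) stop(sprintf("NA not allowed in %s indices", what), call. = FALSE)
  xi <- as.integer(x)
  if (any(abs(x - xi) > 0)) {
    stop(sprintf("%s indices must be whole numbers", what), call. = FALSE)
  }
  if (any(xi < 0)) stop(sprintf("%s indices must be >= 0 (0-based)", what), call. = FALSE)
  sort(unique(xi))
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("<bicluster: %d samples x %d genes = %d cells>\n",
              length(x$samples), length(x$genes), n_cells(x)))
  invisible(x)
}

#' Number of cells covered by a bicluster
#'
#' @param b A [bicluster()].
#' @return `length(samples) * length(genes)` as a double (cell counts can
#'   exceed the integer range on large grids).
#' @export
n_cells <- function(b) {
  stopifnot(inherits(b, "bicluster"))
  as.double(length(b$samples)) * length(b$genes)
}

#' Is a bicluster empty?
#'
#' Empty means covering zero cells: either index set empty suffices.
#' @param b A [bicluster()].
#' @export
is_empty_bicluster <- function(b) n_cells(b) == 0

#' Materialise the cell set of a bicluster
#'
#' @param b A [bicluster()].
#' @return An integer matrix with columns `sample` and `gene`, one row per
#'   cell of the Cartesian product; zero rows if the bicluster is empty.
#' @examples
#' cells_of(bicluster(samples = c(0, 1), genes = 2))
#' @export
cells_of <- function(b) {
  stopifnot(inherits(b, "bicluster"))
  if (is_empty_bicluster(b)) {
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("sample", "gene"))))
  }
  grid <- expand.grid(sample = b$samples, gene = b$genes,
                      KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(grid)
  storage.mode(m) <- "integer"
  m
}

#' Construct a biclustering
#'
#' An ordered collection of K biclusters over a common n x p grid. Overlap
#' and exact duplicates are permitted (the clustering-error metric penalises
#' duplicates); empty biclusters are retained but contribute zero cells to
#' every metric.
#'
#' @param biclusters A list of [bicluster()] objects (may be empty).
#' @param n Number of samples in the grid.
#' @param p Number of genes in the grid.
#' @return An object of class `biclustering`. Out-of-bounds indices raise an
#'   error naming the offending bicluster.
#' @export
biclustering <- function(biclusters = list(), n, p) {
  stopifnot(is.list(biclusters))
  n <- as.integer(n); p <- as.integer(p)
  if (length(n) != 1 || length(p) != 1 || is.na(n) || is.na(p) || n < 0 || p < 0) {
    stop("n and p must be single non-negative integers", call. = FALSE)
  }
  for (b in biclusters) {
    if (!inherits(b, "bicluster")) stop("all elements must be bicluster objects", call. = FALSE)
  }
  bc <- structure(list(biclusters = biclusters, n = n, p = p),
                  class = "biclustering")
  validate_biclustering(bc) # raises on out-of-bounds
  bc
}

#' @export
print.biclustering <- function(x, ...) {
  k_full <- length(x$biclusters)
  k_nonempty <- sum(!vapply(x$biclusters, is_empty_bicluster, logical(1)))
  cat(sprintf("<biclustering: K=%d (%d non-empty) on a %d x %d grid>\n",
              k_full, k_nonempty, x$n, x$p))
  invisible(x)
}

#' @export
length.biclustering <- function(x) length(x$biclusters)

#' Validate a biclustering
#'
#' Checks each member bicluster against the declared grid bounds, and flags
#' (without erroring) duplicate biclusters and empty biclusters.
#'
#' @param bc A [biclustering()].
#' @return A tibble report with columns `issue` (`"duplicate"` or `"empty"`),
#'   `bicluster` (1-based position in the sequence) and `of` (for duplicates,
#'   the earlier position it repeats; `NA` otherwise). Zero rows means a
#'   clean biclustering. Out-of-bounds indices are an error, not a report row.
#' @export
validate_biclustering <- function(bc) {
  stopifnot(inherits(bc, "biclustering"))
  keys <- character(length(bc$biclusters))
  issues <- list()
  for (k in seq_along(bc$biclusters)) {
    b <- bc$biclusters[[k]]
    if (length(b$samples) && max(b$samples) >= bc$n) {
      stop(sprintf("bicluster %d: sample index %d out of bounds (n = %d)",
                   k, max(b$samples), bc$n), call. = FALSE)
    }
    if (length(b$genes) && max(b$genes) >= bc$p) {
      stop(sprintf("bicluster %d: gene index %d out of bounds (p = %d)",
                   k, max(b$genes), bc$p), call. = FALSE)
    }
    keys[k] <- paste(paste(b$samples, collapse = ","),
                     paste(b$genes, collapse = ","), sep = "|")
    if (is_empty_bicluster(b)) {
      issues[[length(issues) + 1L]] <-
        tibble::tibble(issue = "empty", bicluster = k, of = NA_integer_)
    }
  }
  if (length(keys) > 1) {
    for (k in which(duplicated(keys))) {
      first <- match(keys[k], keys)
      if (!is_empty_bicluster(bc$biclusters[[k]])) {
        issues[[length(issues) + 1L]] <-
          tibble::tibble(issue = "duplicate", bicluster = k, of = first)
      }
    }
  }
  if (length(issues) == 0) {
    return(tibble::tibble(issue = character(), bicluster = integer(),
                          of = integer()))
  }
  do.call(rbind, issues)
}

#' Construct a factorisation
#'
#' Holds the sample loading matrix X (n x K) and gene loading matrix B
#' (p x K) of a matrix factorisation Y ~ X B'. Thresholding the loadings
#' yields bicluster memberships (see [threshold_factorisation()]).
#'
#' @param X Numeric matrix of sample loadings, one column per factor.
#' @param B Numeric matrix of gene loadings, same number of columns as `X`.
#' @return An object of class `factorisation`.
#' @export
factorisation <- function(X, B) {
  X <- as.matrix(X); B <- as.matrix(B)
  if (!is.numeric(X) || !is.numeric(B)) stop("X and B must be numeric matrices", call. = FALSE)
  if (ncol(X) != ncol(B)) {
    stop(sprintf("X and B must have the same number of factors (got %d and %d)",
                 ncol(X), ncol(B)), call. = FALSE)
  }
  structure(list(X = X, B = B), class = "factorisation")
}

#' @export
print.factorisation <- function(x, ...) {
  cat(sprintf("<factorisation: n=%d samples, p=%d genes, K=%d factors>\n",
              nrow(x$X), nrow(x$B), ncol(x$X)))
  invisible(x)
}

#' Reconstruction X B' of a factorisation
#'
#' @param f A [factorisation()].
#' @return The n x p reconstruction matrix.
#' @export
reconstruct <- function(f) {
  stopifnot(inherits(f, "factorisation"))
  f$X %*% t(f$B)
}

#' Construct a pathway database
#'
#' A map from pathway identifiers to gene index sets over a gene universe of
#' size p. Pathways may overlap; empty pathways are rejected.
#'
#' @param pathways Named list of 0-based gene index vectors.
#' @param p Gene universe size.
#' @return An object of class `pathway_db`.
#' @export
pathway_db <- function(pathways, p) {
  p <- as.integer(p)
  if (length(pathways) == 0) stop("pathway database must contain at least one pathway", call. = FALSE)
  if (is.null(names(pathways)) || any(names(pathways) == "")) {
    stop("pathways must be a named list", call. = FALSE)
  }
  pathways <- lapply(pathways, as_index_set, what = "gene")
  for (id in names(pathways)) {
    g <- pathways[[id]]
    if (length(g) == 0) stop(sprintf("pathway '%s' is empty", id), call. = FALSE)
    if (max(g) >= p) stop(sprintf("pathway '%s': gene index %d out of bounds (p = %d)",
                                  id, max(g), p), call. = FALSE)
  }
  structure(list(pathways = pathways, p = p), class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db: %d pathways over %d genes>\n",
              length(x$pathways), x$p))
  invisible(x)
}

#' Construct trait annotations
#'
#' Sample traits (e.g. tissue of origin, genotype) as named sample index
#' sets. Used by the trait F1 metrics.
#'
#' @param traits Named list of 0-based sample index vectors.
#' @param n Number of samples; member indices must be `< n`.
#' @return An object of class `trait_annotation` (a validated named list).
#' @export
trait_annotation <- function(traits, n) {
  n <- as.integer(n)
  if (length(traits) == 0) stop("at least one trait required", call. = FALSE)
  if (is.null(names(traits)) || any(names(traits) == "")) {
    stop("traits must be a named list", call. = FALSE)
  }
  traits <- lapply(traits, as_index_set, what = "sample")
  for (id in names(traits)) {
    s <- traits[[id]]
    if (length(s) == 0) stop(sprintf("trait '%s' has no member samples", id), call. = FALSE)
    if (max(s) >= n) stop(sprintf("trait '%s': sample index %d out of bounds (n = %d)",
                                  id, max(s), n), call. = FALSE)
  }
  structure(traits, class = "trait_annotation", n = n)
}

# Shared helper: cell-count of the intersection of two biclusters.
# |A ∩ B| factorises over the two axes of the Cartesian product.
intersection_cells <- function(b1, b2) {
  s <- length(intersect(b1$samples, b2$samples))
  if (s == 0) return(0)
  g <- length(intersect(b1$genes, b2$genes))
  as.double(s) * g
}

# Coverage-count matrix: entry (i, j) = number of biclusters covering cell
# (i, j). Dense n x p integers; fine at the desk scales this package targets.
coverage_counts <- function(bc) {
  cov <- matrix(0L, nrow = bc$n, ncol = bc$p)
  for (b in bc$biclusters) {
    if (is_empty_bicluster(b)) next
    rows <- b$samples + 1L
    cols <- b$genes + 1L
    cov[rows, cols] <- cov[rows, cols] + 1L
  }
  cov
}

total_cells <- function(bc) {
  sum(vapply(bc$biclusters, n_cells, numeric(1)))
}
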