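#' Write a labelled numeric matrix as tab-separated text
#'
#' First row holds the column labels (the corner cell is empty), first
#' column the row labels. Round-trips exactly through [read_matrix()].
#'
#' @param mat Numeric matrix; missing dimnames are filled with `s<i>` /
#'   `g<j>` (0-based).
#' @param path Output path.
#' @export
write_matrix <- function(mat, path) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("s", seq_len(nrow(mat)) - 1L)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("g", seq_len(ncol(mat)) - 1L)
  header <- paste(c("", colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], format(mat[i, ], digits = 17, trim = TRUE,
                                     scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a labelled numeric matrix from tab-separated text
#'
#' Expects the format written by [write_matrix()]: a header row of column
#' labels and a leading column of row labels. Ragged rows, duplicate
#' labels, empty matrices and non-finite or non-numeric cells are rejected
#' with the offending coordinates in the message.
#'
#' @param path Input path.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("empty matrix: need a header row and at least one data row", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  col_labels <- header[-1]
  if (length(col_labels) == 0) stop("empty matrix: no columns", call. = FALSE)
  if (anyDuplicated(col_labels)) stop("duplicate column labels", call. = FALSE)
  n <- length(lines) - 1L
  row_labels <- character(n)
  mat <- matrix(NA_real_, nrow = n, ncol = length(col_labels))
  for (i in seq_len(n)) {
    row <- fields[[i + 1L]]
    if (length(row) != length(col_labels) + 1L) {
      stop(sprintf("ragged row %d: expected %d fields, found %d",
                   i, length(col_labels) + 1L, length(row)), call. = FALSE)
    }
    row_labels[i] <- row[1]
    vals <- suppressWarnings(as.numeric(row[-1]))
    bad <- which(!is.finite(vals))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   row[bad[1] + 1L], row_labels[i], col_labels[bad[1]]),
           call. = FALSE)
    }
    mat[i, ] <- vals
  }
  if (anyDuplicated(row_labels)) stop("duplicate row labels", call. = FALSE)
  dimnames(mat) <- list(row_labels, col_labels)
  mat
}

#' Write bicluster memberships to the plain-text membership format
#'
#' Format: a header line `n=<n> p=<p>`, then for each bicluster three
#' lines — `bicluster <k>` (0-based), the space-separated 0-based sample
#' indices, and the space-separated gene indices (a blank line for an
#' empty set). Round-trips exactly, including empty biclusters and K = 0.
#'
#' @param bc A [biclustering()].
#' @param path Output path.
#' @export
write_memberships <- function(bc, path) {
  stopifnot(inherits(bc, "biclustering"))
  lines <- sprintf("n=%d p=%d", bc$n, bc$p)
  for (k in seq_along(bc$biclusters)) {
    b <- bc$biclusters[[k]]
    lines <- c(lines, sprintf("bicluster %d", k - 1L),
               paste(b$samples, collapse = " "),
               paste(b$genes, collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read bicluster memberships from the plain-text membership format
#'
#' @param path Input path (format of [write_memberships()]).
#' @return A [biclustering()]; indices at or beyond the declared bounds
#'   are an error.
#' @export
read_memberships <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty membership file", call. = FALSE)
  hd <- regmatches(lines[1], regexec("^n=([0-9]+) p=([0-9]+)$", lines[1]))[[1]]
  if (length(hd) != 3) stop("malformed header; expected 'n=<n> p=<p>'", call. = FALSE)
  n <- as.integer(hd[2]); p <- as.integer(hd[3])
  body <- lines[-1]
  if (length(body) %% 3 != 0) {
    stop("malformed membership file: each bicluster needs 3 lines", call. = FALSE)
  }
  parse_idx <- function(s) {
    if (!nzchar(trimws(s))) return(integer())
    as.integer(strsplit(trimws(s), "\\s+")[[1]])
  }
  blist <- lapply(seq_len(length(body) / 3), function(k) {
    off <- (k - 1L) * 3L
    if (!grepl("^bicluster ", body[off + 1L])) {
      stop(sprintf("expected 'bicluster <k>' at record %d", k), call. = FALSE)
    }
    bicluster(parse_idx(body[off + 2L]), parse_idx(body[off + 3L]))
  })
  biclustering(blist, n = n, p = p)
}

#' Write / read a dataset configuration as flat YAML
#'
#' Every field of the config (dimensions, K, regime, noise, variant, seed)
#' as a flat key-value file, so a simulation is reproducible from its
#' config alone.
#'
#' @param config A [dataset_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "dataset_config"))
  flat <- list(name = config$name, m = config$m, t = config$t, p = config$p,
               K = config$K, size_regime = config$size_regime,
               noise_family = config$noise$family,
               noise_p_negbin = config$noise$p_negbin,
               noise_sigma = config$noise$sigma,
               variant = config$variant, seed = config$seed)
  yaml::write_yaml(flat[!vapply(flat, is.null, logical(1))], path)
  invisible(path)
}

#' @rdname write_config
#' @return `read_config()` returns the [dataset_config()].
#' @export
read_config <- function(path) {
  flat <- yaml::read_yaml(path)
  noise <- switch(flat$noise_family,
                  negbin = noise_spec("negbin", p_negbin = flat$noise_p_negbin),
                  gaussian = noise_spec("gaussian", sigma = flat$noise_sigma),
                  none = noise_spec("none"))
  dataset_config(m = flat$m, t = flat$t, p = flat$p, K = flat$K,
                 size_regime = flat$size_regime, noise = noise,
                 variant = flat$variant, seed = flat$seed, name = flat$name)
}

#' Write pathway / trait / knockout mapping tables
#'
#' Two-column tab-separated files: `(pathway_id, gene_index)` for a pathway
#' database, `(trait_id, sample_index)` for traits, `(knockout_id,
#' pathway_id)` for the knockout map. Headers are written and expected.
#'
#' @param db A [pathway_db()].
#' @param path File path.
#' @export
write_pathway_db <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- c(sprintf("# universe=%d", db$p), "pathway_id\tgene_id")
  for (pid in names(db$pathways)) {
    lines <- c(lines, sprintf("%s\t%d", pid, db$pathways[[pid]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pathway_db
#' @export
read_pathway_db <- function(path) {
  lines <- readLines(path)
  hd <- regmatches(lines[1], regexec("^# universe=([0-9]+)$", lines[1]))[[1]]
  if (length(hd) != 2) stop("malformed pathway file; expected '# universe=<p>' header", call. = FALSE)
  p <- as.integer(hd[2])
  tab <- utils::read.delim(text = lines[-1], header = TRUE,
                           colClasses = c("character", "integer"))
  pathways <- split(tab$gene_id, tab$pathway_id)
  pathway_db(pathways, p = p)
}

#' Write / read trait annotations as a two-column table
#'
#' @param traits A [trait_annotation()].
#' @param path File path.
#' @export
write_traits <- function(traits, path) {
  lines <- c(sprintf("# n=%d", attr(traits, "n")), "trait_id\tsample_id")
  for (tid in names(traits)) {
    lines <- c(lines, sprintf("%s\t%d", tid, traits[[tid]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  lines <- readLines(path)
  hd <- regmatches(lines[1], regexec("^# n=([0-9]+)$", lines[1]))[[1]]
  if (length(hd) != 2) stop("malformed trait file; expected '# n=<n>' header", call. = FALSE)
  tab <- utils::read.delim(text = lines[-1], header = TRUE,
                           colClasses = c("character", "integer"))
  trait_annotation(split(tab$sample_id, tab$trait_id), n = as.integer(hd[2]))
}

#' Log transform commonly applied to expression counts
#'
#' Elementwise `log(x + 1)`.
#'
#' @param Y Numeric matrix.
#' @export
log1p_transform <- function(Y) log1p(Y)

#' Gaussian quantile normalisation per gene
#'
#' Maps each gene's values to standard normal quantiles through their ranks
#' (average ranks on ties, rescaled by 1/(n+1) to stay strictly inside
#' (0, 1)), giving every gene an approximate N(0, 1) distribution.
#'
#' @param Y Numeric matrix, samples by genes.
#' @return A matrix of the same shape and dimnames.
#' @export
quantile_normalise_genes <- function(Y) {
  Y <- as.matrix(Y)
  out <- apply(Y, 2, function(x) stats::qnorm(rank(x, ties.method = "average") /
                                                (length(x) + 1)))
  dimnames(out) <- dimnames(Y)
  out
}
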