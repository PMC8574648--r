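#' Simulate a knockout-design expression fixture
#'
#' Emulates the structure of a multi-tissue knockout RNA-seq experiment:
#' each knockout genotype is observed with `replicates` replicates in each
#' of `n_tissues` tissues, genes are organised into pathways, and each
#' knockout perturbs the genes of its assigned pathway in all of that
#' genotype's samples (an additive negative-binomial effect with mean
#' `effect_mean`). Tissue main effects are implanted as dense biclusters
#' (each tissue's samples across all genes, with a Gamma-drawn mean), so
#' between-tissue differences dominate the matrix the way they do in real
#' multi-tissue data. Ground-truth traits, pathway membership and the
#' knockout-to-pathway map are returned so that the trait-F1, enrichment
#' and knockout-biclustering metrics can be exercised end to end without
#' any external download.
#'
#' The gene universe contains exactly the pathway-linked genes (pathway k
#' owning the contiguous block of `genes_per_pathway` genes), mirroring the
#' restriction of a real analysis to genes sharing a pathway with some
#' knockout.
#'
#' @param n_genotypes Number of knockout genotypes.
#' @param n_tissues Number of tissues.
#' @param replicates Replicates per (genotype, tissue).
#' @param n_pathways Number of pathways; defaults to one per genotype.
#' @param genes_per_pathway Genes in each pathway.
#' @param p Total genes; defaults to `n_pathways * genes_per_pathway` and
#'   must be at least that.
#' @param effect_mean Mean of the additive knockout perturbation (0 makes
#'   knockout biclusters indistinguishable from background).
#' @param background_p Success parameter of the NB(1, p) background.
#' @param seed Master seed.
#' @return A list of class `knockout_fixture` with the expression matrix
#'   `Y` (n = genotypes x tissues x replicates samples), `truth` (knockout
#'   biclusters then tissue biclusters), `genotype_traits`, `tissue_traits`
#'   ([trait_annotation()]s), `db` ([pathway_db()]), `knockout_pathways`
#'   (named list mapping each knockout to its pathway ids), a `design`
#'   tibble (sample, genotype, tissue, replicate) and the `seed`.
#' @export
simulate_knockout_fixture <- function(n_genotypes = 10, n_tissues = 3,
                                      replicates = 3,
                                      n_pathways = n_genotypes,
                                      genes_per_pathway = 20,
                                      p = n_pathways * genes_per_pathway,
                                      effect_mean = 200,
                                      background_p = 0.3,
                                      seed = 1L) {
  counts <- c(n_genotypes, n_tissues, replicates, n_pathways, genes_per_pathway)
  if (any(counts < 1)) stop("all design counts must be >= 1", call. = FALSE)
  if (n_pathways * genes_per_pathway > p) {
    stop(sprintf("n_pathways * genes_per_pathway = %d exceeds p = %d",
                 n_pathways * genes_per_pathway, p), call. = FALSE)
  }
  G <- as.integer(n_genotypes); Tt <- as.integer(n_tissues)
  R <- as.integer(replicates); p <- as.integer(p)
  n <- G * Tt * R

  # tissue-major sample layout: tissue, then genotype, then replicate
  design <- tibble::tibble(
    tissue = rep(seq_len(Tt) - 1L, each = G * R),
    genotype = rep(rep(seq_len(G) - 1L, each = R), times = Tt),
    replicate = rep(seq_len(R) - 1L, times = G * Tt)
  )
  design$sample <- seq_len(n) - 1L
  design <- design[, c("sample", "genotype", "tissue", "replicate")]

  pathways <- stats::setNames(
    lapply(seq_len(n_pathways) - 1L, function(j) {
      j * genes_per_pathway + seq_len(genes_per_pathway) - 1L
    }),
    paste0("pathway", seq_len(n_pathways) - 1L))
  db <- pathway_db(pathways, p = p)

  knockout_ids <- paste0("ko", seq_len(G) - 1L)
  knockout_pathways <- stats::setNames(
    lapply(seq_len(G) - 1L, function(g) names(pathways)[(g %% n_pathways) + 1L]),
    knockout_ids)

  genotype_traits <- trait_annotation(
    stats::setNames(lapply(seq_len(G) - 1L,
                           function(g) design$sample[design$genotype == g]),
                    knockout_ids), n = n)
  tissue_traits <- trait_annotation(
    stats::setNames(lapply(seq_len(Tt) - 1L,
                           function(l) design$sample[design$tissue == l]),
                    paste0("tissue", seq_len(Tt) - 1L)), n = n)

  set.seed(derive_seed(seed, 11L, 0L))
  Y <- matrix(as.numeric(stats::rnbinom(n * p, size = 1, prob = background_p)),
              nrow = n, ncol = p)

  blist <- list()
  # knockout effects: genotype's samples x its pathway's genes
  for (g in seq_len(G) - 1L) {
    rows0 <- genotype_traits[[g + 1L]]
    genes0 <- sort(unique(unlist(pathways[knockout_pathways[[g + 1L]]],
                                 use.names = FALSE)))
    if (effect_mean > 0) {
      set.seed(derive_seed(seed, 12L, g))
      n_disp <- negbin_dispersion(effect_mean, background_p)
      vals <- sample_negbin(n_disp, background_p, length(rows0) * length(genes0))
      Y[rows0 + 1L, genes0 + 1L] <- Y[rows0 + 1L, genes0 + 1L] +
        matrix(vals, nrow = length(rows0))
    }
    blist[[length(blist) + 1L]] <- bicluster(rows0, genes0)
  }
  # tissue main effects: dense biclusters across all genes
  for (l in seq_len(Tt) - 1L) {
    rows0 <- tissue_traits[[l + 1L]]
    set.seed(derive_seed(seed, 13L, l))
    mu_t <- sample_bicluster_mean()
    n_disp <- negbin_dispersion(mu_t, background_p)
    vals <- sample_negbin(n_disp, background_p, length(rows0) * p)
    Y <- Y + 0 # keep Y numeric double
    Y[rows0 + 1L, ] <- Y[rows0 + 1L, ] + matrix(vals, nrow = length(rows0))
    blist[[length(blist) + 1L]] <- bicluster(rows0, seq_len(p) - 1L)
  }

  rownames(Y) <- paste0("s", seq_len(n) - 1L)
  colnames(Y) <- paste0("g", seq_len(p) - 1L)
  structure(list(Y = Y,
                 truth = biclustering(blist, n = n, p = p),
                 genotype_traits = genotype_traits,
                 tissue_traits = tissue_traits,
                 db = db,
                 knockout_pathways = knockout_pathways,
                 design = design,
                 effect_mean = effect_mean,
                 seed = as.integer(seed)),
            class = "knockout_fixture")
}

#' @export
print.knockout_fixture <- function(x, ...) {
  cat(sprintf("<knockout_fixture: %d samples x %d genes, %d knockouts, %d tissues>\n",
              nrow(x$Y), ncol(x$Y), length(x$genotype_traits),
              length(x$tissue_traits)))
  invisible(x)
}

#' Ideal recovered biclustering for a knockout fixture
#'
#' One bicluster per knockout: exactly its genotype's samples crossed with
#' its pathway's genes. By construction this scores 1 on the knockout
#' biclustering score and 1 on genotype clustering ability.
#'
#' @param fixture A [simulate_knockout_fixture()] result.
#' @return A [biclustering()] with one bicluster per knockout.
#' @export
ideal_knockout_biclustering <- function(fixture) {
  stopifnot(inherits(fixture, "knockout_fixture"))
  blist <- lapply(seq_along(fixture$genotype_traits), function(i) {
    genes0 <- sort(unique(unlist(fixture$db$pathways[fixture$knockout_pathways[[i]]],
                                 use.names = FALSE)))
    bicluster(fixture$genotype_traits[[i]], genes0)
  })
  biclustering(blist, n = nrow(fixture$Y), p = ncol(fixture$Y))
}

#' Draw a uniformly random biclustering on a grid
#'
#' Utility for null-rate experiments: each bicluster takes a uniform random
#' sample subset and gene subset of the given sizes.
#'
#' @param n,p Grid dimensions.
#' @param K Number of biclusters.
#' @param size_samples,size_genes Members per bicluster (each >= 1).
#' @return A [biclustering()]. Uses the current RNG state.
#' @export
random_biclustering <- function(n, p, K, size_samples, size_genes) {
  blist <- lapply(seq_len(K), function(k) {
    bicluster(sample.int(n, size_samples) - 1L,
              sample.int(p, size_genes) - 1L)
  })
  biclustering(blist, n = n, p = p)
}
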