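#' Dataset configuration for the simulator
#'
#' Describes one simulated multi-tissue expression dataset: m individuals
#' observed in each of t tissues (n = m*t samples, listed tissue by tissue
#' with individuals in the same order within each tissue), p genes, and K
#' implanted, possibly overlapping biclusters. Each bicluster occupies a
#' contiguous block of individuals, a contiguous run of tissues and a
#' contiguous block of genes; contiguity aids visual inspection without
#' restricting what the algorithms can in principle detect.
#'
#' @param m Number of individuals.
#' @param t Number of tissues.
#' @param p Number of genes.
#' @param K Number of implanted biclusters (0 gives pure background noise).
#' @param size_regime One of `"mixed"`, `"sparse"`, `"dense"`,
#'   `"sparse-square"`, `"dense-square"`; controls the candidate sets that
#'   bicluster gene/individual counts are drawn from. In the square regimes
#'   one fraction is drawn and applied to both axes.
#' @param noise A list as returned by [noise_spec()].
#' @param variant `NULL` for the additive count model, or one of
#'   `"shift-scale"`, `"shift"`, `"scale"`, `"constant-samples"` for the
#'   shift-scale bicluster value models (noiseless by construction).
#' @param seed Default master seed used by [simulate_dataset()].
#' @param name Optional preset name carried for provenance.
#' @return An object of class `dataset_config`.
#' @seealso [make_preset_config()] for the named study presets.
#' @export
dataset_config <- function(m, t, p, K,
                           size_regime = "mixed",
                           noise = noise_spec("negbin", p_negbin = 0.3),
                           variant = NULL,
                           seed = 1L,
                           name = NULL) {
  m <- as.integer(m); t <- as.integer(t); p <- as.integer(p); K <- as.integer(K)
  if (any(c(m, t, p) < 1L)) stop("m, t and p must all be >= 1", call. = FALSE)
  if (K < 0L) stop("K must be >= 0", call. = FALSE)
  size_regime <- match.arg(size_regime,
                           c("mixed", "sparse", "dense", "sparse-square", "dense-square"))
  if (!is.null(variant)) {
    variant <- match.arg(variant, c("shift-scale", "shift", "scale", "constant-samples"))
    noise <- noise_spec("none")
  }
  stopifnot(is.list(noise), !is.null(noise$family))
  structure(list(m = m, t = t, p = p, K = K, n = m * t,
                 size_regime = size_regime, noise = noise,
                 variant = variant, seed = as.integer(seed),
                 name = name),
            class = "dataset_config")
}

#' @export
print.dataset_config <- function(x, ...) {
  noise <- switch(x$noise$family,
                  negbin = sprintf("NB(n_k, %g)", x$noise$p_negbin),
                  gaussian = sprintf("N(mu_k, %g^2)", x$noise$sigma),
                  none = "noiseless")
  cat(sprintf("<dataset_config%s: m=%d t=%d p=%d K=%d, %s biclusters, %s%s>\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$m, x$t, x$p, x$K, x$size_regime, noise,
              if (is.null(x$variant)) "" else paste0(", variant=", x$variant)))
  invisible(x)
}

#' Noise specification
#'
#' @param family `"negbin"` (counts; bicluster values NB with mean mu_k and
#'   success parameter `p_negbin`, background NB(1, `p_negbin`)),
#'   `"gaussian"` (bicluster values N(mu_k, sigma^2), background
#'   N(0, sigma^2), final matrix clipped at zero), or `"none"` (bicluster
#'   cells take the value mu_k exactly; zero background).
#' @param p_negbin Negative-binomial success parameter in (0, 1).
#' @param sigma Gaussian standard deviation.
#' @export
noise_spec <- function(family = c("negbin", "gaussian", "none"),
                       p_negbin = 0.3, sigma = 20) {
  family <- match.arg(family)
  if (family == "negbin") {
    if (!is.numeric(p_negbin) || p_negbin <= 0 || p_negbin >= 1) {
      stop("p_negbin must lie in (0, 1)", call. = FALSE)
    }
    return(list(family = "negbin", p_negbin = p_negbin))
  }
  if (family == "gaussian") {
    if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
    return(list(family = "gaussian", sigma = sigma))
  }
  list(family = "none")
}

# The study's preset table: every named dataset family used in the benchmark.
preset_table <- function() {
  nb <- function(p) noise_spec("negbin", p_negbin = p)
  ga <- function(s) noise_spec("gaussian", sigma = s)
  base <- list(m = 10, t = 10, p = 1000, K = 20, regime = "mixed", noise = nb(0.3))
  # plain field replacement (modifyList would merge noise lists recursively)
  mod <- function(...) {
    args <- list(...)
    out <- base
    for (nm in names(args)) out[[nm]] <- args[[nm]]
    out
  }
  list(
    "base"           = base,
    "N50-T2"         = mod(m = 50, t = 2),
    "N10-T20"        = mod(t = 20),
    "N100-T10"       = mod(m = 100),
    "N500-T10"       = mod(m = 500),
    "G100"           = mod(p = 100),
    "G5000"          = mod(p = 5000),
    "Large-K20"      = mod(m = 300, t = 20, p = 10000),
    "Negbin-medium"  = mod(noise = nb(0.1)),
    "Negbin-high"    = mod(noise = nb(0.01)),
    "Gaussian"       = mod(noise = ga(20)),
    "Gaussian-medium" = mod(noise = ga(100)),
    "Gaussian-high"  = mod(noise = ga(300)),
    "Noiseless"      = mod(noise = noise_spec("none")),
    "Sparse"         = mod(regime = "sparse"),
    "Dense"          = mod(regime = "dense"),
    "Sparse-square"  = mod(regime = "sparse-square"),
    "Dense-square"   = mod(regime = "dense-square"),
    "K5"             = mod(K = 5),
    "K10"            = mod(K = 10),
    "K50"            = mod(K = 50),
    "K70"            = mod(K = 70),
    "Large-K100"     = mod(m = 300, t = 20, p = 10000, K = 100),
    "Large-K400"     = mod(m = 300, t = 20, p = 10000, K = 400),
    # shift-scale value-model variants on the base dimensions (noiseless)
    "shift-scale"      = mod(noise = noise_spec("none"), variant = "shift-scale"),
    "shift"            = mod(noise = noise_spec("none"), variant = "shift"),
    "scale"            = mod(noise = noise_spec("none"), variant = "scale"),
    "constant-samples" = mod(noise = noise_spec("none"), variant = "constant-samples")
  )
}

#' Named dataset presets
#'
#' Returns the configuration of one of the named simulated-dataset families
#' used in the benchmark study (e.g. `"base"`: m=10 individuals, t=10
#' tissues, p=1000 genes, K=20 mixed-size biclusters with NB(n_k, 0.3)
#' values), plus the four shift-scale variants.
#'
#' @param name Preset name (case-insensitive). Unknown names raise an error
#'   listing the valid presets.
#' @param seed Master seed stored in the returned config.
#' @return A [dataset_config()].
#' @examples
#' make_preset_config("base")
#' make_preset_config("Gaussian-high")
#' @export
make_preset_config <- function(name, seed = 1L) {
  tab <- preset_table()
  hit <- match(tolower(name), tolower(names(tab)))
  if (is.na(hit)) {
    stop(sprintf("unknown preset '%s'; valid presets: %s",
                 name, paste(names(tab), collapse = ", ")), call. = FALSE)
  }
  row <- tab[[hit]]
  dataset_config(m = row$m, t = row$t, p = row$p, K = row$K,
                 size_regime = row$regime, noise = row$noise,
                 variant = row$variant, seed = seed,
                 name = names(tab)[hit])
}

#' List available preset names
#' @export
preset_names <- function() names(preset_table())

# Candidate bicluster sizes per regime, as counts along an axis of `total`.
# Fractions are rounded to the nearest integer with a floor of 1 so every
# bicluster is non-degenerate.
regime_fractions <- function(regime) {
  switch(regime,
         "mixed" = c(1 / 100, 1 / 10, 1 / 5, 1 / 2, 1),
         "sparse" = , "sparse-square" = c(1, 2, 3) / 20,
         "dense" = , "dense-square" = c(3, 5, 9) / 10,
         stop("unknown regime: ", regime, call. = FALSE))
}

candidate_sizes <- function(total, regime) {
  pmax(1L, as.integer(round(total * regime_fractions(regime))))
}

#' Draw the shape and placement of one bicluster
#'
#' Draws the gene count g_k, individual count m_k and tissue count t_k from
#' the regime's candidate sets (square regimes draw one fraction and apply
#' it to both the gene and individual axes; t_k is uniform on 1..t), then
#' places contiguous blocks uniformly at random: gene start on
#' `[0, p - g_k]`, individual start on `[0, m - m_k]`, and a contiguous run
#' of t_k tissues. Uses the current RNG state.
#'
#' @param config A [dataset_config()].
#' @return A list of class `bicluster_spec` with fields `g_k`, `m_k`, `t_k`,
#'   `gene_start`, `individual_start`, `tissues` (0-based tissue indices).
#' @export
sample_bicluster_shape <- function(config) {
  stopifnot(inherits(config, "dataset_config"))
  regime <- config$size_regime
  if (grepl("square$", regime)) {
    frac <- sample(regime_fractions(regime), 1L)
    g_k <- max(1L, as.integer(round(config$p * frac)))
    m_k <- max(1L, as.integer(round(config$m * frac)))
  } else {
    g_k <- sample(candidate_sizes(config$p, regime), 1L)
    m_k <- sample(candidate_sizes(config$m, regime), 1L)
  }
  t_k <- sample.int(config$t, 1L)
  gene_start <- sample.int(config$p - g_k + 1L, 1L) - 1L
  individual_start <- sample.int(config$m - m_k + 1L, 1L) - 1L
  tissue_start <- sample.int(config$t - t_k + 1L, 1L) - 1L
  structure(list(g_k = g_k, m_k = m_k, t_k = t_k,
                 gene_start = gene_start,
                 individual_start = individual_start,
                 tissues = tissue_start + seq_len(t_k) - 1L),
            class = "bicluster_spec")
}

#' Draw a bicluster-specific mean
#'
#' mu_k ~ Gamma(shape = alpha, rate = beta). The study defaults alpha = 2,
#' beta = 1/600 give a mean of alpha/beta = 1200 and standard deviation
#' sqrt(alpha)/beta ~= 849, spanning biclusters that are easy to tell apart
#' by eye through to ones with similar means.
#'
#' @param alpha Gamma shape (> 0).
#' @param beta Gamma rate (> 0).
#' @param count Number of draws.
#' @return Numeric vector of draws.
#' @export
sample_bicluster_mean <- function(alpha = 2, beta = 1 / 600, count = 1L) {
  if (!is.numeric(alpha) || alpha <= 0 || !is.numeric(beta) || beta <= 0) {
    stop("alpha and beta must be positive", call. = FALSE)
  }
  stats::rgamma(count, shape = alpha, rate = beta)
}

#' Negative-binomial dispersion for a target mean
#'
#' Under the failures-before-n-th-success parameterisation NB(n_k, p) has
#' mean n_k (1-p)/p, so n_k = mu p / (1-p) gives mean mu and variance mu/p
#' (sd sqrt(mu/p); ~63.2 at mu = 1200, p = 0.3).
#'
#' @param mu Target mean (>= 0), vectorised.
#' @param p Success parameter in (0, 1).
#' @export
negbin_dispersion <- function(mu, p) {
  if (any(mu < 0)) stop("mu must be >= 0", call. = FALSE)
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("p must lie in (0, 1)", call. = FALSE)
  mu * p / (1 - p)
}

#' Draw negative-binomial counts with real-valued dispersion
#'
#' NB(n, p) generalised to non-integer n via the Gamma-Poisson mixture
#' (lambda ~ Gamma(shape n, scale (1-p)/p); draw Poisson(lambda)), which is
#' exactly what [stats::rnbinom()] implements. Mean n(1-p)/p, variance
#' n(1-p)/p^2. `n = 0` yields all-zero draws.
#'
#' @param n Dispersion (>= 0, possibly non-integer).
#' @param p Success parameter in (0, 1).
#' @param count Number of draws.
#' @return Integer-valued numeric vector of non-negative counts.
#' @export
sample_negbin <- function(n, p, count = 1L) {
  if (!is.numeric(n) || length(n) != 1 || n < 0) stop("n must be a single value >= 0", call. = FALSE)
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("p must lie in (0, 1)", call. = FALSE)
  if (n == 0) return(numeric(count))
  as.numeric(stats::rnbinom(count, size = n, prob = p))
}

# Deterministic sub-stream seeds derived from one master seed, keyed by
# (stream, index). Independent streams per bicluster and per purpose mean
# that adding biclusters does not perturb the draws of earlier ones.
derive_seed <- function(master, stream, index = 0L) {
  m <- 2147483587 # large prime < 2^31
  s <- (as.double(master) %% m)
  s <- (s * 48271 + as.double(stream) * 16807 + 7) %% m
  s <- (s * 48271 + as.double(index) * 69621 + 13) %% m
  as.integer(s)
}

# Flattened 0-based sample index for (individual, tissue): tissue-major
# ordering, individuals kept in the same order within each tissue.
sample_index <- function(individual, tissue, m) tissue * m + individual

#' Individual/tissue layout of the flattened sample axis
#'
#' Samples are listed tissue by tissue with individuals in the same order
#' within each tissue, so sample index = tissue * m + individual. This makes
#' every simulated bicluster a flattened tricluster, usable by tensor and
#' plain matrix methods alike.
#'
#' @param m Number of individuals.
#' @param t Number of tissues.
#' @return A tibble with columns `sample`, `individual`, `tissue`
#'   (all 0-based), one row per sample in row order of the matrix.
#' @export
tensor_sample_maps <- function(m, t) {
  tissue <- rep(seq_len(t) - 1L, each = m)
  individual <- rep(seq_len(m) - 1L, times = t)
  tibble::tibble(sample = sample_index(individual, tissue, m),
                 individual = individual, tissue = tissue)
}

#' Flatten a simulated dataset to matrix-plus-maps form
#'
#' @param dataset A `simulated_dataset`.
#' @return A list with the n x p expression matrix `Y` and the sample
#'   layout tibble `maps` (see [tensor_sample_maps()]).
#' @export
flatten_tensor <- function(dataset) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  list(Y = dataset$Y, maps = tensor_sample_maps(dataset$config$m, dataset$config$t))
}

#' Simulate an expression dataset with implanted biclusters
#'
#' Generates Y as a sum over biclusters of value blocks plus background
#' noise: `Y[i,j,l] = sum_k delta[i,k] gamma[j,k] tau[l,k] E_k[i,j,l] + B[i,j,l]`,
#' flattened over (individual, tissue) to an n x p matrix. Under the count
#' model, bicluster values are NB(n_k, p) with n_k chosen so the mean is the
#' Gamma-drawn mu_k, and background is NB(1, p); under the Gaussian model
#' values are N(mu_k, sigma^2) with N(0, sigma^2) background and the final
#' matrix clipped at zero; noiseless datasets use the constant mu_k and no
#' background. Configs with a `variant` use the shift-scale value models
#' instead (see [simulate_shift_scale_dataset()]).
#'
#' Randomness is split into per-bicluster sub-streams (shape, mean, values)
#' plus one background stream, all derived from the master seed, so the
#' same seed reproduces the dataset bit-for-bit.
#'
#' @param config A [dataset_config()].
#' @param seed Master seed; defaults to the seed in `config`.
#' @return An object of class `simulated_dataset`: list with the expression
#'   matrix `Y` (rows `s0..`, columns `g0..`), ground truth `truth`
#'   ([biclustering()]), per-bicluster `specs` and `means`,
#'   `tissue_of_sample` / `individual_of_sample` maps, `config` and `seed`.
#' @examples
#' ds <- simulate_dataset(make_preset_config("G100"), seed = 7)
#' dim(ds$Y)
#' length(ds$truth)
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "dataset_config"))
  if (!is.null(config$variant)) {
    return(simulate_shift_scale_dataset(config, config$variant, seed))
  }
  out <- simulate_blocks(config, seed, value_model = "count")
  out
}

#' Simulate a dataset under the shift-scale value models
#'
#' Within each bicluster, `E_k[i,j,l] = alpha_j * pi_il + beta_j` with
#' `pi_il ~ Exp(1)`, `alpha_j ~ Exp(2) + 1/2` (mean 1, mode 1/2; bounded
#' away from zero so the signal is never flattened) and `beta_j ~ Exp(1)`.
#' The `"shift"` variant fixes alpha = 1, `"scale"` fixes beta = 0 and
#' `"constant-samples"` fixes both, so each sample's value is constant
#' across the bicluster's genes. Exponential draws keep all values
#' non-negative; no background noise is added. Parameters are drawn
#' independently per bicluster.
#'
#' @param config A [dataset_config()].
#' @param variant One of `"shift-scale"`, `"shift"`, `"scale"`,
#'   `"constant-samples"`.
#' @param seed Master seed.
#' @return A `simulated_dataset` (see [simulate_dataset()]).
#' @export
simulate_shift_scale_dataset <- function(config, variant = config$variant,
                                         seed = config$seed) {
  stopifnot(inherits(config, "dataset_config"))
  variant <- match.arg(variant, c("shift-scale", "shift", "scale", "constant-samples"))
  simulate_blocks(config, seed, value_model = "shift-scale", variant = variant)
}

# Shared generator for the additive count model and the shift-scale models.
simulate_blocks <- function(config, seed, value_model, variant = NULL) {
  m <- config$m; t <- config$t; p <- config$p; K <- config$K
  n <- m * t
  Y <- matrix(0, nrow = n, ncol = p)
  specs <- vector("list", K)
  means <- rep(NA_real_, K)
  blist <- vector("list", K)

  for (k in seq_len(K)) {
    set.seed(derive_seed(seed, 1L, k))
    spec <- sample_bicluster_shape(config)
    specs[[k]] <- spec
    genes <- spec$gene_start + seq_len(spec$g_k) - 1L
    individuals <- spec$individual_start + seq_len(spec$m_k) - 1L
    rows0 <- as.integer(outer(individuals, spec$tissues, sample_index, m = m))
    n_vals <- length(rows0) * spec$g_k

    if (value_model == "count") {
      set.seed(derive_seed(seed, 2L, k))
      mu_k <- sample_bicluster_mean()
      means[k] <- mu_k
      set.seed(derive_seed(seed, 3L, k))
      vals <- switch(config$noise$family,
        negbin = {
          n_k <- negbin_dispersion(mu_k, config$noise$p_negbin)
          sample_negbin(n_k, config$noise$p_negbin, n_vals)
        },
        gaussian = stats::rnorm(n_vals, mean = mu_k, sd = config$noise$sigma),
        none = rep(mu_k, n_vals))
      Y[rows0 + 1L, genes + 1L] <- Y[rows0 + 1L, genes + 1L] +
        matrix(vals, nrow = length(rows0), ncol = spec$g_k)
    } else {
      set.seed(derive_seed(seed, 2L, k))
      pi_il <- stats::rexp(length(rows0), rate = 1)
      alpha_j <- if (variant %in% c("shift", "constant-samples")) {
        rep(1, spec$g_k)
      } else stats::rexp(spec$g_k, rate = 2) + 0.5
      beta_j <- if (variant %in% c("scale", "constant-samples")) {
        rep(0, spec$g_k)
      } else stats::rexp(spec$g_k, rate = 1)
      block <- outer(pi_il, alpha_j) + matrix(beta_j, nrow = length(rows0),
                                              ncol = spec$g_k, byrow = TRUE)
      Y[rows0 + 1L, genes + 1L] <- Y[rows0 + 1L, genes + 1L] + block
    }
    blist[[k]] <- bicluster(samples = rows0, genes = genes)
  }

  # background noise stream
  if (value_model == "count" && config$noise$family != "none") {
    set.seed(derive_seed(seed, 4L, 0L))
    bg <- switch(config$noise$family,
                 negbin = as.numeric(stats::rnbinom(n * p, size = 1,
                                                    prob = config$noise$p_negbin)),
                 gaussian = stats::rnorm(n * p, 0, config$noise$sigma))
    Y <- Y + matrix(bg, nrow = n, ncol = p)
    if (config$noise$family == "gaussian") Y[Y < 0] <- 0
  }

  rownames(Y) <- paste0("s", seq_len(n) - 1L)
  colnames(Y) <- paste0("g", seq_len(p) - 1L)
  maps <- tensor_sample_maps(m, t)
  structure(list(Y = Y,
                 truth = biclustering(blist, n = n, p = p),
                 specs = specs,
                 means = means,
                 tissue_of_sample = maps$tissue,
                 individual_of_sample = maps$individual,
                 config = config,
                 seed = as.integer(seed)),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset: %d samples x %d genes, K=%d, seed=%d>\n",
              nrow(x$Y), ncol(x$Y), length(x$truth), x$seed))
  invisible(x)
}

#' Build the exact indicator factorisation of a ground truth
#'
#' X holds 0/1 sample-membership indicators and B gene indicators scaled by
#' each bicluster's value (the mean mu_k by default), so that on noiseless
#' data X B' reproduces Y exactly and thresholding at any theta < 1 recovers
#' the truth.
#'
#' @param truth A [biclustering()].
#' @param values Per-bicluster scale applied to the gene indicator columns;
#'   recycled; defaults to 1.
#' @return A [factorisation()].
#' @export
indicator_factorisation <- function(truth, values = 1) {
  stopifnot(inherits(truth, "biclustering"))
  K <- length(truth)
  values <- rep_len(values, max(K, 1L))
  X <- matrix(0, nrow = truth$n, ncol = K)
  B <- matrix(0, nrow = truth$p, ncol = K)
  for (k in seq_len(K)) {
    b <- truth$biclusters[[k]]
    X[b$samples + 1L, k] <- 1
    B[b$genes + 1L, k] <- values[k]
  }
  factorisation(X, B)
}

#' Plot a simulated dataset as an expression heatmap
#'
#' @param object A `simulated_dataset`.
#' @param ... Unused.
#' @return A ggplot object (samples on the y axis, genes on the x axis,
#'   log1p-scaled fill).
#' @export
autoplot.simulated_dataset <- function(object, ...) {
  Y <- object$Y
  df <- tibble::tibble(
    sample = rep(seq_len(nrow(Y)) - 1L, times = ncol(Y)),
    gene = rep(seq_len(ncol(Y)) - 1L, each = nrow(Y)),
    value = as.vector(log1p(Y))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$sample,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "gene", y = "sample", fill = "log1p(Y)") +
    ggplot2::theme_minimal()
}
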