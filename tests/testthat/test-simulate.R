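test_that("named presets reproduce the study's dataset table", {
  base <- make_preset_config("base")
  expect_equal(c(base$m, base$t, base$p, base$K), c(10, 10, 1000, 20))
  expect_equal(base$size_regime, "mixed")
  expect_equal(base$noise, noise_spec("negbin", p_negbin = 0.3))

  big <- make_preset_config("Large-K400")
  expect_equal(c(big$m, big$t, big$p, big$K), c(300, 20, 10000, 400))

  gh <- make_preset_config("Gaussian-high")
  expect_equal(gh$noise$family, "gaussian")
  expect_equal(gh$noise$sigma, 300)
  expect_equal(c(gh$m, gh$t, gh$p, gh$K), c(10, 10, 1000, 20))

  nh <- make_preset_config("Negbin-high")
  expect_equal(nh$noise$p_negbin, 0.01)
  expect_equal(make_preset_config("Noiseless")$noise$family, "none")
  expect_equal(make_preset_config("Sparse-square")$size_regime, "sparse-square")
  expect_equal(make_preset_config("shift")$variant, "shift")

  expect_error(make_preset_config("nope"), "valid presets")
})

test_that("candidate bicluster sizes follow the regime rules", {
  expect_equal(candidate_sizes(1000, "mixed"), c(10L, 100L, 200L, 500L, 1000L))
  # rounding to nearest with floor 1: m = 10 sparse fractions {.5, 1, 1.5}
  expect_equal(candidate_sizes(10, "sparse"), c(1L, 1L, 2L))
  expect_equal(candidate_sizes(1000, "dense"), c(300L, 500L, 900L))
})

test_that("square regimes tie the gene and individual proportions", {
  config <- dataset_config(m = 10, t = 3, p = 1000, K = 1,
                           size_regime = "dense-square")
  set.seed(11)
  for (i in 1:20) {
    spec <- sample_bicluster_shape(config)
    expect_equal(spec$g_k / config$p, spec$m_k / config$m)
    expect_true((spec$g_k / config$p) %in% (c(3, 5, 9) / 10))
  }
})

test_that("bicluster blocks are contiguous and in bounds", {
  config <- make_preset_config("base")
  set.seed(5)
  for (i in 1:30) {
    spec <- sample_bicluster_shape(config)
    expect_true(spec$g_k %in% candidate_sizes(config$p, "mixed"))
    expect_true(spec$m_k %in% candidate_sizes(config$m, "mixed"))
    expect_gte(spec$gene_start, 0)
    expect_lte(spec$gene_start + spec$g_k, config$p)
    expect_lte(spec$individual_start + spec$m_k, config$m)
    expect_equal(spec$tissues, min(spec$tissues):max(spec$tissues))
    expect_lte(max(spec$tissues), config$t - 1)
  }
})

test_that("bicluster mean distribution has the configured moments", {
  expect_error(sample_bicluster_mean(alpha = -1), "positive")
  # closed form: mean alpha/beta, sd sqrt(alpha)/beta
  expect_equal(2 / (1 / 600), 1200)
  expect_equal(sqrt(2) * 600, 848.5281, tolerance = 1e-6)
  set.seed(1)
  expect_equal(mean(sample_bicluster_mean(1, 1, 2e5)), 1,
               tolerance = 3 / sqrt(2e5))
})

test_that("negative-binomial dispersion matches the mean construction", {
  expect_equal(negbin_dispersion(1200, 0.3), 1200 * 0.3 / 0.7)
  expect_equal(negbin_dispersion(0, 0.3), 0)
  expect_error(negbin_dispersion(1200, 1.2), "\\(0, 1\\)")
  expect_error(negbin_dispersion(-1, 0.3), ">= 0")
  # resulting sd at mu = 1200, p = 0.3 is sqrt(mu/p)
  expect_equal(sqrt(1200 / 0.3), 63.2456, tolerance = 1e-4)
})

test_that("negative-binomial draws have the target mean and sd", {
  expect_equal(sample_negbin(0, 0.3, 10), rep(0, 10))
  n_k <- negbin_dispersion(1200, 0.3)
  set.seed(2)
  draws <- sample_negbin(n_k, 0.3, 2e5)
  expect_true(all(draws >= 0 & draws == round(draws)))
  se <- sqrt(1200 / 0.3) / sqrt(2e5)
  expect_equal(mean(draws), 1200, tolerance = 4 * se / 1200)
  expect_equal(sd(draws), sqrt(1200 / 0.3), tolerance = 0.02)
})

test_that("simulated datasets have the declared shape and ground truth", {
  ds <- simulate_dataset(make_preset_config("base"), seed = 1)
  expect_equal(dim(ds$Y), c(100, 1000))
  expect_equal(length(ds$truth), 20)
  expect_true(all(ds$Y >= 0))
  expect_true(all(ds$Y == round(ds$Y)))
  expect_equal(nrow(validate_biclustering(ds$truth) |>
                      subset(issue == "empty")), 0)
})

test_that("pure background matches the NB(1, p) mean", {
  ds <- simulate_dataset(dataset_config(10, 5, 400, K = 0), seed = 3)
  # NB(1, 0.3) has mean (1 - 0.3)/0.3 = 7/3; 20000 cells, sd sqrt(mu/p)/sqrt(N)
  se <- sqrt((7 / 3) / 0.3) / sqrt(length(ds$Y))
  expect_equal(mean(ds$Y), 7 / 3, tolerance = 4 * se / (7 / 3))
})

test_that("noiseless data equal the indicator reconstruction exactly", {
  config <- dataset_config(4, 3, 60, K = 5, noise = noise_spec("none"))
  ds <- simulate_dataset(config, seed = 9)
  f <- indicator_factorisation(ds$truth, ds$means)
  expect_equal(unname(ds$Y), reconstruct(f))
})

test_that("a full-cover noiseless bicluster gives a constant matrix", {
  # with m = t = p = 1 every candidate size rounds to 1, so the single
  # bicluster covers the whole (1 x 1) grid
  ds <- simulate_dataset(dataset_config(1, 1, 1, K = 1,
                                        noise = noise_spec("none")), seed = 4)
  expect_equal(unname(ds$Y[1, 1]), ds$means[1])
})

test_that("gaussian noise yields non-negative clipped values", {
  ds <- simulate_dataset(make_preset_config("G100", seed = 2))
  expect_true(all(simulate_dataset(
    dataset_config(5, 4, 80, 5, noise = noise_spec("gaussian", sigma = 300)),
    seed = 5)$Y >= 0))
  expect_true(all(ds$Y >= 0))
})

test_that("identical seeds reproduce datasets bit for bit; distinct seeds differ", {
  cfg <- make_preset_config("G100")
  a <- simulate_dataset(cfg, seed = 7)
  b <- simulate_dataset(cfg, seed = 7)
  expect_identical(a$Y, b$Y)
  expect_identical(write_memberships(a$truth, tempfile()) |> readLines(),
                   write_memberships(b$truth, tempfile()) |> readLines())
  c <- simulate_dataset(cfg, seed = 8)
  expect_false(identical(a$Y, c$Y))
})

test_that("adding biclusters does not perturb earlier sub-streams", {
  base <- dataset_config(6, 3, 100, K = 3, noise = noise_spec("none"))
  more <- dataset_config(6, 3, 100, K = 5, noise = noise_spec("none"))
  a <- simulate_dataset(base, seed = 13)
  b <- simulate_dataset(more, seed = 13)
  for (k in 1:3) {
    expect_identical(a$truth$biclusters[[k]], b$truth$biclusters[[k]])
    expect_identical(a$means[k], b$means[k])
  }
})

test_that("K = 20 presets produce overlapping biclusters across seeds", {
  overlap_found <- FALSE
  for (seed in 1:10) {
    truth <- simulate_dataset(make_preset_config("G100"), seed = seed)$truth
    K <- length(truth)
    for (k in seq_len(K - 1)) {
      for (l in (k + 1):K) {
        if (intersection_cells(truth$biclusters[[k]],
                               truth$biclusters[[l]]) > 0) {
          overlap_found <- TRUE
          break
        }
      }
      if (overlap_found) break
    }
    if (overlap_found) break
  }
  expect_true(overlap_found)
})

test_that("planted bicluster cell means recover mu_k plus background", {
  config <- dataset_config(10, 5, 200, K = 1)
  ds <- simulate_dataset(config, seed = 21)
  b <- ds$truth$biclusters[[1]]
  cells <- ds$Y[b$samples + 1, b$genes + 1]
  mu <- ds$means[1]
  expected <- mu + 0.7 / 0.3
  cell_sd <- sqrt(mu / 0.3 + 0.7 / 0.09)
  expect_equal(mean(cells), expected,
               tolerance = 3 * cell_sd / sqrt(length(cells)) / expected)
})

test_that("sample rows are listed tissue-major with individuals in order", {
  maps <- tensor_sample_maps(2, 2)
  expect_equal(maps$individual, c(0L, 1L, 0L, 1L))
  expect_equal(maps$tissue, c(0L, 0L, 1L, 1L))
  expect_equal(maps$sample, 0:3)
  # round trip sample -> (individual, tissue) -> sample
  big <- tensor_sample_maps(10, 10)
  expect_equal(nrow(big), 100)
  expect_equal(big$tissue * 10 + big$individual, big$sample)
  ds <- simulate_dataset(dataset_config(3, 4, 10, 0), seed = 1)
  flat <- flatten_tensor(ds)
  expect_equal(flat$maps$sample, seq_len(nrow(flat$Y)) - 1L)
  expect_equal(ds$tissue_of_sample, flat$maps$tissue)
})

test_that("shift-scale variants honour their parameter constraints", {
  cfg <- dataset_config(6, 3, 80, K = 1, variant = "constant-samples")
  ds <- simulate_dataset(cfg, seed = 2)
  b <- ds$truth$biclusters[[1]]
  block <- ds$Y[b$samples + 1, b$genes + 1, drop = FALSE]
  # alpha = 1, beta = 0: each sample's value constant across the genes
  expect_true(all(apply(block, 1, function(r) diff(range(r)) < 1e-12)))

  shift <- simulate_dataset(dataset_config(6, 3, 80, K = 1, variant = "shift"),
                            seed = 3)
  bs <- shift$truth$biclusters[[1]]
  sblock <- shift$Y[bs$samples + 1, bs$genes + 1, drop = FALSE]
  # alpha = 1: column differences are gene-shift constants
  if (ncol(sblock) > 1) {
    d <- sblock[, -1, drop = FALSE] - sblock[, 1]
    expect_true(all(apply(d, 2, function(col) diff(range(col)) < 1e-12)))
  }
  # no background off-bicluster
  mask <- matrix(TRUE, nrow(ds$Y), ncol(ds$Y))
  mask[b$samples + 1, b$genes + 1] <- FALSE
  expect_true(all(ds$Y[mask] == 0))
  expect_error(simulate_shift_scale_dataset(cfg, variant = "bogus"), "arg")
})

test_that("shift-scale scale parameters have mean 1", {
  set.seed(6)
  alpha <- rexp(2e5, rate = 2) + 0.5
  expect_equal(mean(alpha), 1, tolerance = 4 * 0.5 / sqrt(2e5))
})
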