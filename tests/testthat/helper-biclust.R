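# Build a biclustering from a list of (samples, genes) pairs.
bc_from <- function(pairs, n, p) {
  biclustering(lapply(pairs, function(sg) bicluster(sg[[1]], sg[[2]])), n, p)
}

# Random biclustering for fuzz tests: K biclusters with random (possibly
# empty) sample and gene subsets on an n x p grid.
random_bc <- function(n, p, k, allow_empty = TRUE) {
  blist <- lapply(seq_len(k), function(i) {
    ns <- sample.int(n + as.integer(allow_empty), 1) - as.integer(allow_empty)
    ng <- sample.int(p + as.integer(allow_empty), 1) - as.integer(allow_empty)
    bicluster(if (ns > 0) sample.int(n, ns) - 1L else integer(),
              if (ng > 0) sample.int(p, ng) - 1L else integer())
  })
  biclustering(blist, n, p)
}
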