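# Shared fixtures, built in code. Tests run with logging silenced.
options(spagranger.verbose = FALSE)

# small training configuration used throughout the granger tests; the
# package defaults target real analyses and are far larger
quick_cfg <- function(...) {
  args <- utils::modifyList(list(max_lag = 5L, epochs = 500L, hidden_width = 8L,
                                 lambda_count = 8L, seed = 1L),
                            list(...))
  do.call(granger_config, args)
}

# a directed path 1 -> 2 -> ... -> n (vertex i has parent i - 1), via the
# public API: potential decreasing along the path
path_dag <- function(n) {
  pairs <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  orient_edges(pairs, rev(seq_len(n)))
}

# wrap plain matrices as a normalized_expression (scheme "none") so design
# assembly can be tested on exact values
as_norm_expr <- function(values) {
  structure(list(values = values, scheme = "none",
                 kept_cells = seq_len(nrow(values)),
                 constant_genes = rep(FALSE, ncol(values)),
                 gene_names = colnames(values)),
            class = "normalized_expression")
}

# minimal granger_fit stub with prescribed first-layer blocks
fit_stub <- function(W1, regulators = paste0("r", seq_len(nrow(W1[[1]])))) {
  structure(list(W1 = W1, regulators = regulators,
                 nonzero_fraction = mean(abs(unlist(W1)) > 1e-8),
                 weight_tol = 1e-8),
            class = "granger_fit")
}

# independent brute-force k-NN oracle: per-point loop over all distances
knn_oracle <- function(coords, k) {
  n <- nrow(coords)
  out <- matrix(0L, 0, 2)
  for (i in seq_len(n)) {
    d2 <- colSums((t(coords) - coords[i, ])^2)
    d2[i] <- Inf
    nb <- order(d2, seq_len(n))[seq_len(k)]
    out <- rbind(out, cbind(pmin(i, nb), pmax(i, nb)))
  }
  out <- unique(out)
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# random spatial instance with a smooth tie-free potential
random_instance <- function(n, seed) {
  withr::with_seed(seed, {
    coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    d <- coords[, 1] + 0.3 * coords[, 2] + rnorm(n, sd = 0.01)
    list(coords = coords, d = d)
  })
}

expect_same_edges <- function(a, b) {
  key <- function(e) sort(paste(e[, 1], e[, 2]))
  expect_identical(key(a), key(b))
}
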