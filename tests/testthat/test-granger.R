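test_that("hierarchical penalty computes nested suffix group norms", {
  expect_equal(hierarchical_penalty(list(matrix(0, 1, 3), matrix(0, 1, 3)), 2), 0)
  expect_equal(hierarchical_penalty(list(matrix(2, 1, 1)), 3), 6)
  # L = 2: groups (lag1, lag2) and (lag2): lag1 = (3, 0), lag2 = (0, 4)
  w <- list(matrix(c(3, 0), 1, 2), matrix(c(0, 4), 1, 2))
  expect_equal(hierarchical_penalty(w, 1), 5 + 4)
  expect_equal(hierarchical_penalty(w, 0.5), 4.5)
  expect_error(hierarchical_penalty(w, -1), "nonnegative")
})

test_that("the prox is identity at t = 0, annihilating for large t, and shrinks groups", {
  w <- list(matrix(c(3, 0), 1, 2), matrix(c(0, 4), 1, 2))
  expect_identical(prox_hierarchical(w, 0), w)
  z <- prox_hierarchical(w, 100)
  expect_true(all(unlist(z) == 0))
  one <- prox_hierarchical(list(matrix(c(3, 4), 1, 2)), 2)
  expect_equal(one[[1]], matrix(c(1.8, 2.4), 1, 2))
})

test_that("the prox matches numerical minimization of its objective", {
  worst <- 0
  for (case in 1:30) {
    cfg <- withr::with_seed(case, {
      L <- sample(1:5, 1); d <- sample(1:6, 1)
      list(v = lapply(seq_len(L), function(l) matrix(rnorm(d, sd = 2), 1, d)),
           t = runif(1, 0, 3), L = L, d = d)
    })
    pr <- prox_hierarchical(cfg$v, cfg$t)
    obj <- function(w) {
      wl <- lapply(seq_len(cfg$L), function(l) {
        matrix(w[((l - 1) * cfg$d + 1):(l * cfg$d)], 1, cfg$d)
      })
      0.5 * sum((w - unlist(cfg$v))^2) + hierarchical_penalty(wl, cfg$t)
    }
    num <- optim(unlist(cfg$v), obj, method = "L-BFGS-B",
                 control = list(maxit = 2000, factr = 1e3))
    worst <- max(worst, obj(unlist(pr)) - num$value)
  }
  expect_lte(worst, 1e-6)
})

test_that("prox support is nested in lag and the map is non-expansive", {
  for (case in 1:50) {
    pars <- withr::with_seed(case + 500, {
      L <- sample(2:5, 1); d <- sample(1:4, 1)
      list(u = lapply(seq_len(L), function(l) matrix(rnorm(d), 1, d)),
           w = lapply(seq_len(L), function(l) matrix(rnorm(d), 1, d)),
           t = runif(1, 0, 2), L = L)
    })
    pu <- prox_hierarchical(pars$u, pars$t)
    pw <- prox_hierarchical(pars$w, pars$t)
    # if lag l is zero, all deeper lags are zero
    nz <- vapply(pu, function(b) any(b != 0), TRUE)
    if (any(!nz)) expect_true(all(!nz[min(which(!nz)):pars$L]))
    expect_lte(sqrt(sum((unlist(pu) - unlist(pw))^2)),
               sqrt(sum((unlist(pars$u) - unlist(pars$w))^2)) + 1e-10)
  }
})

test_that("the lagged design matches hand-computed path and diamond aggregates", {
  ops <- build_lag_operators(path_dag(3), 2)
  ne <- as_norm_expr(cbind(r = c(5, 7, 11)))
  des <- assemble_design(ne, "r", ops)
  expect_equal(unname(des$blocks[[1]][, 1]), c(0, 5, 7))
  expect_equal(unname(des$blocks[[2]][, 1]), c(0, 0, 5))

  dia <- orient_edges(rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)), c(3, 2, 2.5, 1))
  dops <- build_lag_operators(dia, 1)
  x <- c(1, 10, 20, 7)
  dd <- assemble_design(as_norm_expr(cbind(r = x)), "r", dops)
  expect_equal(unname(dd$blocks[[1]][4, 1]), (10 + 20) / 2)

  expect_error(assemble_design(ne, character(0), ops), "empty regulator")
  expect_error(assemble_design(ne, "nope", ops), "absent")
})

test_that("training drives noise regulators to zero and favors the true one by 10x", {
  T_ <- 400
  dat <- withr::with_seed(31, {
    x <- rnorm(T_); dec <- rnorm(T_); y <- numeric(T_)
    for (t in 2:T_) y[t] <- 0.9 * x[t - 1] + 0.1 * rnorm(1)
    list(x = x, dec = dec, y = y, noise = rnorm(T_))
  })
  ops <- build_lag_operators(path_dag(T_), 3)
  ne <- as_norm_expr(cbind(x = dat$x, dec = dat$dec))
  des <- assemble_design(ne, c("x", "dec"), ops)
  cfg <- quick_cfg(max_lag = 3)
  self <- aggregate_self(dat$y, ops)

  # pure-noise target at moderate lambda: all regulator groups exactly zero
  fit0 <- fit_single_lambda(des, dat$noise, cfg, lambda = 1, self_column = self)
  expect_true(all(unlist(fit0$W1) == 0))
  expect_equal(estimate_lag(fit0, "x"), 0L)

  fit <- fit_single_lambda(des, dat$y, cfg, lambda = 0.1, self_column = self)
  gn <- vapply(c("x", "dec"), function(r) {
    sqrt(sum(vapply(fit$W1, function(w) sum(w[match(r, des$regulators), ]^2), 0)))
  }, 0)
  expect_gte(gn["x"], 10 * gn["dec"])
  expect_equal(estimate_lag(fit, "x"), 1L)
})

test_that("with lambda 0 and linear activation the fit reproduces OLS predictions", {
  T_ <- 300
  dat <- withr::with_seed(7, {
    x <- rnorm(T_); y <- numeric(T_)
    for (t in 2:T_) y[t] <- 0.8 * x[t - 1] + 0.2 * rnorm(1)
    list(x = x, y = y)
  })
  ops <- build_lag_operators(path_dag(T_), 3)
  des <- assemble_design(as_norm_expr(cbind(x = dat$x)), "x", ops)
  self <- aggregate_self(dat$y, ops)
  cfg <- granger_config(max_lag = 3, hidden_width = 4, activation = "linear",
                        learning_rate = 0.3, epochs = 8000, seed = 1)
  fit <- fit_single_lambda(des, dat$y, cfg, lambda = 0, self_column = self)
  ols <- lm(dat$y ~ do.call(cbind, des$blocks) + self)
  expect_lt(max(abs(predict(fit, des, self) - fitted(ols))), 1e-4)
})

test_that("training is seed-deterministic, records a stabilizing loss, and flags divergence", {
  T_ <- 200
  dat <- withr::with_seed(13, list(x = rnorm(T_), y = rnorm(T_)))
  ops <- build_lag_operators(path_dag(T_), 2)
  des <- assemble_design(as_norm_expr(cbind(x = dat$x)), "x", ops)
  cfg <- quick_cfg(max_lag = 2, epochs = 300)
  f1 <- fit_single_lambda(des, dat$y, cfg, 0.05)
  f2 <- fit_single_lambda(des, dat$y, cfg, 0.05)
  expect_identical(f1$W1, f2$W1)
  expect_identical(f1$loss_trace, f2$loss_trace)
  tail_tr <- utils::tail(f1$loss_trace, max(2, round(0.1 * cfg$epochs)))
  expect_true(all(diff(tail_tr) <= 1e-6))

  bad <- granger_config(max_lag = 2, hidden_width = 4, activation = "linear",
                        learning_rate = 50, epochs = 200, seed = 1)
  expect_error(fit_single_lambda(des, dat$y, bad, 0.01),
               "diverged.*eta = 50")
})

test_that("lambda validity is strict-inside the 5%-95% band", {
  frac_cases <- c(0, 0.04, 0.05, 0.5, 0.95, 0.96, 1.0)
  expected <- c("invalid", "invalid", "invalid", "valid", "invalid",
                "invalid", "invalid")
  for (i in seq_along(frac_cases)) {
    m <- fit_stub(list(matrix(0, 1, 100)))
    m$nonzero_fraction <- frac_cases[i]
    expect_equal(as.character(lambda_validity(m)), expected[i],
                 label = paste("fraction", frac_cases[i]))
  }
})

test_that("estimate_lag reads dominant and deepest-surviving lags from the first layer", {
  W <- list(matrix(c(2, 0), 1, 2), matrix(0, 1, 2), matrix(0, 1, 2))
  m <- fit_stub(W, "r")
  expect_equal(estimate_lag(m, "r"), 1L)
  expect_equal(estimate_lag(m, "r", method = "max_nonzero"), 1L)

  W2 <- list(matrix(1, 1, 2), matrix(3, 1, 2), matrix(1e-3, 1, 2))
  m2 <- fit_stub(W2, "r")
  expect_equal(estimate_lag(m2, "r"), 2L)
  expect_equal(estimate_lag(m2, "r", method = "max_nonzero"), 3L)

  m3 <- fit_stub(list(matrix(0, 1, 2), matrix(0, 1, 2)), "r")
  expect_equal(estimate_lag(m3, "r"), 0L)
  expect_equal(estimate_lag(m3, "r", method = "max_nonzero"), 0L)
  expect_error(estimate_lag(m3, "zz"), "unknown regulator")
})

test_that("sweeping ensembles scores across valid lambdas only", {
  T_ <- 300
  dat <- withr::with_seed(41, {
    x <- rnorm(T_); y <- numeric(T_)
    for (t in 3:T_) y[t] <- 0.7 * x[t - 2] + 0.2 * rnorm(1)
    list(x = x, dec = rnorm(T_), y = y)
  })
  ops <- build_lag_operators(path_dag(T_), 3)
  des <- assemble_design(as_norm_expr(cbind(x = dat$x, dec = dat$dec)),
                         c("x", "dec"), ops)
  cfg <- quick_cfg(max_lag = 3, lambda_grid = c(0.02, 0.1, 0.5))
  self <- aggregate_self(dat$y, ops)
  sw <- sweep_and_ensemble(des, dat$y, cfg, self_column = self)
  expect_gt(sw$scores["x"], sw$scores["dec"])
  expect_equal(unname(sw$lags["x"]), 2L)

  # the ensemble score is the mean of per-valid-fit group norms
  valid_idx <- which(sw$fractions > 0.05 & sw$fractions < 0.95)
  manual <- rowMeans(vapply(valid_idx, function(i) {
    fit <- fit_single_lambda(des, dat$y, cfg, cfg$lambda_grid[i], self_column = self)
    vapply(seq_len(2), function(r) {
      sqrt(sum(vapply(fit$W1, function(w) sum(w[r, ]^2), 0)))
    }, 0)
  }, numeric(2)))
  expect_equal(unname(sw$scores), unname(manual))

  # all lambdas invalid: error with per-lambda diagnostics
  cfg_bad <- quick_cfg(max_lag = 3, lambda_grid = c(50, 100))
  expect_error(sweep_and_ensemble(des, dat$y, cfg_bad, self_column = self),
               "no valid lambda.*fractions")
  expect_warning(
    z <- sweep_and_ensemble(des, dat$y, cfg_bad, self_column = self,
                            on_no_valid = "zero"),
    "zero scores")
  expect_true(all(z$scores == 0))
})

test_that("stratified partitions cover the dataset with balanced classes", {
  ds <- spatial_dataset(matrix(1, 9, 1, dimnames = list(NULL, "g")),
                        cbind(1:9, rep(0, 9)),
                        cell_labels = rep(c("A", "B", "C"), each = 3))
  parts <- stratified_partition(ds, 3, seed = 1)
  idx <- lapply(parts, `[[`, "cell_index")
  expect_equal(sort(unlist(idx)), 1:9)
  expect_equal(anyDuplicated(unlist(idx)), 0L)
  for (p in parts) expect_equal(unname(table(p$cell_labels)), c(1L, 1L, 1L),
                                ignore_attr = TRUE)

  ds10 <- spatial_dataset(matrix(1, 10, 1, dimnames = list(NULL, "g")),
                          cbind(1:10, rep(0, 10)), cell_labels = rep("A", 10))
  sizes <- sort(vapply(stratified_partition(ds10, 3, seed = 2),
                       function(p) length(p$cell_index), 0L), decreasing = TRUE)
  expect_equal(sizes, c(4L, 3L, 3L))

  no_lab <- spatial_dataset(matrix(1, 9, 1, dimnames = list(NULL, "g")),
                            cbind(1:9, rep(0, 9)))
  expect_error(stratified_partition(no_lab, 3), "no cell_labels")
  tiny <- spatial_dataset(matrix(1, 4, 1, dimnames = list(NULL, "g")),
                          cbind(1:4, rep(0, 4)),
                          cell_labels = c("A", "A", "A", "B"))
  expect_error(stratified_partition(tiny, 3), "at least n_parts")
})

test_that("the linear VAR F-test oracle detects, calibrates, and ignores autoregression", {
  dat <- withr::with_seed(55, {
    x <- rnorm(500); y <- numeric(500)
    for (t in 2:500) y[t] <- 0.8 * x[t - 1] + rnorm(1)
    ya <- numeric(500)
    for (t in 2:500) ya[t] <- 0.9 * ya[t - 1] + rnorm(1)
    list(x = x, y = y, ya = ya)
  })
  expect_true(var_granger_oracle(dat$x, dat$y, 3, alpha = 0.01)$causal)
  expect_false(var_granger_oracle(rnorm(500), dat$ya, 2, alpha = 0.05)$causal)
  expect_error(var_granger_oracle(rnorm(8), rnorm(8), 3), "too short")

  # type-I calibration: rejection rate within the binomial 99% CI of alpha
  rej <- withr::with_seed(77, {
    mean(vapply(1:200, function(i) {
      var_granger_oracle(rnorm(300), rnorm(300), 2, alpha = 0.05)$causal
    }, TRUE))
  })
  ci <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})

test_that("the end-to-end pipeline labels directions and returns candidates only", {
  bench <- benchmark_suite("easy", seed = 19)
  keep <- bench$pairs$target %in% bench$truth$planted_pairs$target[1:2]
  pairs <- bench$pairs[keep, , drop = FALSE]
  cfg <- quick_cfg(epochs = 250, lambda_count = 5)
  tab <- suppressWarnings(
    infer_interactions(bench$dataset, pairs, bench$field, cfg,
                       direction = "both", context = "strip"))
  expect_s3_class(tab, "interaction_table")
  expect_setequal(unique(tab$direction), c("forward", "backward"))
  expect_equal(nrow(tab), 2L * nrow(pairs))
  expect_true(all(paste(tab$regulator, tab$target) %in%
                  paste(pairs$regulator, pairs$target)))
  expect_true(all(tab$context == "strip"))
  expect_true(all((tab$score == 0) == (tab$lag == 0L)))

  # a planted forward pair scores higher forward than backward
  pp <- bench$truth$planted_pairs[1, ]
  fw <- tab$score[tab$regulator == pp$regulator & tab$target == pp$target &
                  tab$direction == "forward"]
  bw <- tab$score[tab$regulator == pp$regulator & tab$target == pp$target &
                  tab$direction == "backward"]
  expect_gt(fw, bw)

  empty <- infer_interactions(bench$dataset, candidate_pairs(character(0), character(0)),
                              bench$field, cfg)
  expect_equal(nrow(empty), 0L)
})
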