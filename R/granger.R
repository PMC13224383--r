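#' Training configuration for DAG-structured Granger inference
#'
#' Defaults follow the practice that works on UMI-sparse spatial data: a
#' relatively high learning rate with many proximal-gradient epochs, and a
#' broad regularization grid (30 log-spaced values in (0.01, 10)) pruned by
#' the validity rule; on very sparse real tissue data the useful lambdas
#' tend to fall below 0.1, so narrowing the range there speeds the sweep.
#' For ligand-receptor panels a lower learning rate (0.01) is recommended.
#' Desk-scale analyses and tests typically pass far fewer epochs and a
#' smaller grid.
#'
#' @param max_lag maximum graph lag L.
#' @param k neighbor count for the spatial graph.
#' @param hidden_width width of the single hidden layer.
#' @param activation `"tanh"` or `"linear"`.
#' @param learning_rate proximal gradient step size (eta).
#' @param epochs full-batch proximal-gradient iterations per lambda.
#' @param lambda_grid explicit positive grid (sorted ascending); overrides
#'   `lambda_range`/`lambda_count` when given.
#' @param lambda_range range for the log-spaced default grid.
#' @param lambda_count number of grid points.
#' @param validity_band fits are kept only when the fraction of nonzero
#'   first-layer weights lies strictly inside this band.
#' @param include_self include the target's own lag-aggregated values as an
#'   additional unpenalized predictor, so detected regulator effects are
#'   beyond the target's own graph-past.
#' @param scheduler `"none"` or `"plateau"` (halve the step when the loss has
#'   not improved for `patience` epochs).
#' @param patience plateau patience in epochs.
#' @param seed integer seed for weight initialization.
#' @param weight_tol magnitude below which a weight counts as zero (the prox
#'   produces exact zeros; this is a safety tolerance).
#' @return A list of class `granger_config`.
#' @export
granger_config <- function(max_lag = 5L, k = 7L, hidden_width = 16L,
                           activation = c("tanh", "linear"),
                           learning_rate = 0.1, epochs = 10000L,
                           lambda_grid = NULL, lambda_range = c(0.01, 10),
                           lambda_count = 30L,
                           validity_band = c(0.05, 0.95),
                           include_self = TRUE,
                           scheduler = c("none", "plateau"), patience = 50L,
                           seed = 1L, weight_tol = 1e-8) {
  activation <- match.arg(activation)
  scheduler <- match.arg(scheduler)
  if (is.null(lambda_grid)) {
    lambda_grid <- exp(seq(log(lambda_range[1]), log(lambda_range[2]),
                           length.out = lambda_count))
  }
  lambda_grid <- sort(as.numeric(lambda_grid))
  stopifnot(all(lambda_grid > 0), max_lag >= 1L, hidden_width >= 1L,
            learning_rate > 0, epochs >= 1L,
            length(validity_band) == 2L,
            validity_band[1] > 0, validity_band[1] < validity_band[2],
            validity_band[2] < 1)
  structure(list(max_lag = as.integer(max_lag), k = as.integer(k),
                 hidden_width = as.integer(hidden_width),
                 activation = activation, learning_rate = learning_rate,
                 epochs = as.integer(epochs), lambda_grid = lambda_grid,
                 validity_band = validity_band,
                 include_self = isTRUE(include_self), scheduler = scheduler,
                 patience = as.integer(patience), seed = as.integer(seed),
                 weight_tol = weight_tol),
            class = "granger_config")
}

#' Assemble the lagged regulator design
#'
#' Block l is the lag-l ancestor-aggregation operator applied to the
#' regulator expression columns; vertices with no l-step ancestor get zero
#' rows. On a directed path graph this reduces exactly to the classical
#' time-series lagged design.
#'
#' @param norm_expr a `normalized_expression`.
#' @param regulators character vector of regulator gene names.
#' @param ops a `lag_operators`.
#' @return A list of class `lag_design`: `blocks` (list of L dense N x R
#'   matrices), `regulators`, `max_lag`, `n`.
#' @export
assemble_design <- function(norm_expr, regulators, ops) {
  stopifnot(is(norm_expr, "normalized_expression"), is(ops, "lag_operators"))
  if (length(regulators) == 0L) stop("empty regulator set", call. = FALSE)
  gi <- match(regulators, norm_expr$gene_names)
  if (anyNA(gi)) {
    stop("regulator gene(s) absent: ",
         paste(regulators[is.na(gi)], collapse = ", "), call. = FALSE)
  }
  X <- norm_expr$values[, gi, drop = FALSE]
  if (nrow(X) != ops$n_vertices) {
    stop("expression (", nrow(X), " cells) and operators (", ops$n_vertices,
         " vertices) disagree", call. = FALSE)
  }
  blocks <- lapply(ops$ops, function(A) {
    B <- as.matrix(A %*% X)
    colnames(B) <- regulators
    B
  })
  structure(list(blocks = blocks, regulators = regulators,
                 max_lag = ops$max_lag, n = nrow(X)),
            class = "lag_design")
}

#' Lag-aggregate a target's own expression
#'
#' The mean over lags of the per-lag ancestor averages of y: a single
#' unpenalized predictor summarizing the target's own graph-past.
#'
#' @param y length-N numeric target values.
#' @param ops a `lag_operators`.
#' @return Length-N numeric vector.
#' @export
aggregate_self <- function(y, ops) {
  stopifnot(is(ops, "lag_operators"))
  acc <- numeric(length(y))
  for (A in ops$ops) acc <- acc + as.numeric(A %*% y)
  acc / ops$max_lag
}

#' Hierarchical group penalty over lag suffixes
#'
#' For one regulator with weight blocks w_1, ..., w_L (one block per lag),
#' the penalty is `lambda * sum_{l=1}^{L} ||(w_l, ..., w_L)||_2`: nested
#' groups over lag suffixes, so the lag-l block appears in l groups and
#' longer lags are penalized more heavily than shorter ones.
#'
#' @param weights list of L numeric blocks (vectors or matrices) for one
#'   regulator.
#' @param lambda nonnegative penalty strength.
#' @return Nonnegative scalar.
#' @export
hierarchical_penalty <- function(weights, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)
  L <- length(weights)
  sq <- vapply(weights, function(w) sum(w^2), 0)
  tails <- rev(cumsum(rev(sq)))
  lambda * sum(sqrt(tails))
}

#' Proximal operator of the hierarchical lag penalty
#'
#' Exact prox of `t * sum_l ||(w_l..w_L)||_2` for one regulator's blocks:
#' group soft-thresholding applied from the innermost group (lag L alone)
#' outward to the full group (lags 1..L). For tree-nested groups this
#' leaf-to-root sweep is the exact proximal map, and it produces exact zeros,
#' zeroing longer lags before shorter ones.
#'
#' @param weights list of L numeric blocks for one regulator.
#' @param t nonnegative threshold (lambda times the step size).
#' @return The shrunk blocks, same shapes.
#' @export
prox_hierarchical <- function(weights, t) {
  if (t < 0) stop("threshold must be nonnegative", call. = FALSE)
  if (t == 0) return(weights)
  L <- length(weights)
  for (l in L:1) {
    nrm <- sqrt(sum(vapply(weights[l:L], function(w) sum(w^2), 0)))
    if (nrm <= t) {
      for (j in l:L) weights[[j]][] <- 0
    } else {
      s <- 1 - t / nrm
      for (j in l:L) weights[[j]] <- weights[[j]] * s
    }
  }
  weights
}

# prox applied to the full first layer: W is a list of L (R x d) matrices;
# each regulator row-chain is shrunk independently.
prox_first_layer <- function(W, t) {
  if (t == 0) return(W)
  L <- length(W)
  R <- nrow(W[[1]])
  sq <- vapply(W, function(w) rowSums(w^2), numeric(R))  # R x L
  sq <- matrix(sq, nrow = R)
  for (l in L:1) {
    nrm <- sqrt(rowSums(sq[, l:L, drop = FALSE]))
    s <- ifelse(nrm > t, 1 - t / nrm, 0)
    changed <- s != 1
    if (any(changed)) {
      for (j in l:L) {
        W[[j]][changed, ] <- W[[j]][changed, , drop = FALSE] * s[changed]
        sq[changed, j] <- sq[changed, j] * s[changed]^2
      }
    }
  }
  W
}

#' Fit the lag-operator network at one regularization strength
#'
#' The model predicts a target gene's (normalized) expression at each vertex
#' from its ancestors' regulator expression:
#' `yhat = sigma(sum_l D_l W1_l + y_self w_s + b1) W2 + b2`, where `D_l` is
#' the lag-l design block. Training is full-batch proximal gradient descent:
#' a gradient step on the squared-error loss followed by the exact prox of
#' the hierarchical lag penalty on the first-layer regulator weights (the
#' self term, bias and output layer are unpenalized). The loss trace is
#' recorded; a run whose loss turns non-finite aborts naming lambda and eta.
#'
#' @param design a `lag_design`.
#' @param target length-N numeric target values.
#' @param cfg a `granger_config`.
#' @param lambda penalty strength.
#' @param self_column optional length-N unpenalized predictor (the target's
#'   own lag-aggregated values; see [aggregate_self()]).
#' @return An object of class `granger_fit`: `W1` (list of L R x d
#'   matrices), `w_self`, `b1`, `W2`, `b2`, `activation`, `regulators`,
#'   `loss_trace`, `lambda`, `nonzero_fraction`.
#' @export
fit_single_lambda <- function(design, target, cfg, lambda, self_column = NULL) {
  stopifnot(is(design, "lag_design"), is(cfg, "granger_config"))
  y <- as.numeric(target)
  if (any(!is.finite(y))) stop("target contains non-finite values", call. = FALSE)
  N <- design$n
  if (length(y) != N) stop("target length != design rows", call. = FALSE)
  L <- design$max_lag
  R <- length(design$regulators)
  d <- cfg$hidden_width
  use_self <- !is.null(self_column)
  if (use_self) s_col <- matrix(as.numeric(self_column), ncol = 1L)
  lin <- cfg$activation == "linear"

  params <- withr::with_seed(cfg$seed, {
    list(W1 = lapply(seq_len(L), function(l) matrix(rnorm(R * d, sd = 0.1), R, d)),
         w_self = if (use_self) matrix(rnorm(d, sd = 0.1), 1, d) else NULL,
         b1 = numeric(d),
         W2 = matrix(rnorm(d, sd = 0.5 / sqrt(d)), d, 1),
         b2 = 0)
  })
  eta <- cfg$learning_rate
  trace <- numeric(cfg$epochs)
  best <- Inf
  stall <- 0L
  Dl <- design$blocks
  for (ep in seq_len(cfg$epochs)) {
    Z <- matrix(params$b1, N, d, byrow = TRUE)
    for (l in seq_len(L)) Z <- Z + Dl[[l]] %*% params$W1[[l]]
    if (use_self) Z <- Z + s_col %*% params$w_self
    H <- if (lin) Z else tanh(Z)
    yhat <- drop(H %*% params$W2) + params$b2
    resid <- yhat - y
    loss <- mean(resid^2)
    trace[ep] <- loss
    if (!is.finite(loss)) {
      stop("training diverged (non-finite loss) at lambda = ", lambda,
           ", eta = ", eta, call. = FALSE)
    }
    r <- matrix(2 * resid / N, ncol = 1L)
    gW2 <- t(H) %*% r
    gb2 <- sum(r)
    GZ <- r %*% t(params$W2)
    if (!lin) GZ <- GZ * (1 - H^2)
    gb1 <- colSums(GZ)
    params$W2 <- params$W2 - eta * gW2
    params$b2 <- params$b2 - eta * gb2
    params$b1 <- params$b1 - eta * gb1
    if (use_self) params$w_self <- params$w_self - eta * (t(s_col) %*% GZ)
    for (l in seq_len(L)) {
      params$W1[[l]] <- params$W1[[l]] - eta * (t(Dl[[l]]) %*% GZ)
    }
    params$W1 <- prox_first_layer(params$W1, lambda * eta)
    if (cfg$scheduler == "plateau") {
      if (loss < best - 1e-12) {
        best <- loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) {
          eta <- eta / 2
          stall <- 0L
        }
      }
    }
  }
  nz <- vapply(params$W1, function(w) sum(abs(w) > cfg$weight_tol), 0)
  frac <- sum(nz) / (L * R * d)
  structure(list(W1 = params$W1, w_self = params$w_self, b1 = params$b1,
                 W2 = params$W2, b2 = params$b2, activation = cfg$activation,
                 regulators = design$regulators, loss_trace = trace,
                 lambda = lambda, eta_final = eta,
                 nonzero_fraction = frac, weight_tol = cfg$weight_tol),
            class = "granger_fit")
}

#' Predict from a fitted lag-operator network
#'
#' @param object a `granger_fit`.
#' @param design the `lag_design` it was trained on (or a compatible one).
#' @param self_column the same unpenalized predictor used in training, if any.
#' @param ... unused.
#' @return Length-N numeric predictions.
#' @export
predict.granger_fit <- function(object, design, self_column = NULL, ...) {
  N <- design$n
  d <- length(object$b1)
  Z <- matrix(object$b1, N, d, byrow = TRUE)
  for (l in seq_along(object$W1)) Z <- Z + design$blocks[[l]] %*% object$W1[[l]]
  if (!is.null(object$w_self)) {
    Z <- Z + matrix(as.numeric(self_column), ncol = 1L) %*% object$w_self
  }
  H <- if (object$activation == "linear") Z else tanh(Z)
  drop(H %*% object$W2) + object$b2
}

#' Classify a fit by its first-layer sparsity
#'
#' A regularization setting is valid when the fraction of nonzero
#' first-layer regulator weights lies strictly inside the validity band
#' (default: strictly between 5% and 95%). Fully dense and fully empty fits
#' carry no selection information and are discarded from the ensemble.
#'
#' @param model a `granger_fit`.
#' @param band length-2 numeric validity band.
#' @return `"valid"` or `"invalid"` (with the fraction as attribute
#'   `fraction`).
#' @export
lambda_validity <- function(model, band = c(0.05, 0.95)) {
  f <- model$nonzero_fraction
  out <- if (f > band[1] && f < band[2]) "valid" else "invalid"
  attr(out, "fraction") <- f
  out
}

#' Estimated interaction lag for one regulator
#'
#' The lag at which an interaction operates, read off the fitted first
#' layer. Two readings of "the lag is the maximum of the non-zero weights"
#' are supported:
#' \describe{
#'   \item{dominant (default)}{the lag whose weight block carries the
#'     maximal group norm for the regulator — the graph distance at which
#'     the regulator's influence is strongest. Robust to the tiny
#'     oscillation residue a proximal optimizer can leave in blocks whose
#'     gradient sits near the shrinkage threshold.}
#'   \item{max_nonzero}{the largest lag whose block has any weight above
#'     the zero tolerance — the deepest surviving lag. Equivalent to
#'     `dominant` when the optimizer reaches an exactly sparse solution
#'     with one active lag, but upward-biased under correlated lag
#'     designs.}
#' }
#' Both return 0 when every weight for the regulator is zero.
#'
#' @param model a `granger_fit`.
#' @param regulator regulator name or index.
#' @param method `"dominant"` or `"max_nonzero"`.
#' @return Integer in `[0, L]`.
#' @export
estimate_lag <- function(model, regulator,
                         method = c("dominant", "max_nonzero")) {
  method <- match.arg(method)
  r <- if (is.character(regulator)) match(regulator, model$regulators) else regulator
  if (is.na(r)) stop("unknown regulator: ", regulator, call. = FALSE)
  norms <- vapply(model$W1, function(w) sqrt(sum(w[r, ]^2)), 0)
  if (method == "max_nonzero") {
    nz <- which(norms > model$weight_tol)
    if (length(nz) == 0L) 0L else max(nz)
  } else {
    if (max(norms) <= model$weight_tol) 0L else which.max(norms)
  }
}

group_norms <- function(model) {
  R <- length(model$regulators)
  sq <- numeric(R)
  for (w in model$W1) sq <- sq + rowSums(w^2)
  setNames(sqrt(sq), model$regulators)
}

#' Sweep the regularization grid and ensemble valid fits
#'
#' Fits the model for one target at every lambda in the grid, keeps the fits
#' whose first-layer sparsity is strictly inside the validity band, and
#' averages each regulator's first-layer group norm over the valid fits to
#' obtain its interaction score. The pair's lag estimate is the median (over
#' valid fits in which the regulator survives) of the per-fit deepest
#' surviving lag.
#'
#' @param design a `lag_design` for the target's candidate regulators.
#' @param target length-N numeric target values.
#' @param cfg a `granger_config`.
#' @param self_column optional unpenalized self predictor.
#' @param on_no_valid `"error"` (default) or `"zero"`: what to do when no
#'   lambda is valid — raise with per-lambda diagnostics recommending a wider
#'   grid, or return all-zero scores with a warning.
#' @return A list: `scores` (named per regulator), `lags` (named integer),
#'   `valid_lambdas`, `fractions` (per-lambda nonzero fractions), `fits`
#'   (valid fits only).
#' @export
sweep_and_ensemble <- function(design, target, cfg, self_column = NULL,
                               on_no_valid = c("error", "zero")) {
  on_no_valid <- match.arg(on_no_valid)
  stopifnot(is(design, "lag_design"), is(cfg, "granger_config"))
  grid <- cfg$lambda_grid
  fits <- vector("list", length(grid))
  fracs <- numeric(length(grid))
  for (i in seq_along(grid)) {
    fits[[i]] <- fit_single_lambda(design, target, cfg, grid[i],
                                   self_column = self_column)
    fracs[i] <- fits[[i]]$nonzero_fraction
  }
  valid <- fracs > cfg$validity_band[1] & fracs < cfg$validity_band[2]
  R <- length(design$regulators)
  if (!any(valid)) {
    diag_txt <- paste(sprintf("lambda=%.4g: %.3f", grid, fracs), collapse = "; ")
    if (on_no_valid == "error") {
      stop("no valid lambda: nonzero fractions all outside (",
           cfg$validity_band[1], ", ", cfg$validity_band[2],
           "); sample from a broader range of lambda values. Per-lambda fractions: ",
           diag_txt, call. = FALSE)
    }
    warning("no valid lambda for this target; returning zero scores. ",
            "Per-lambda fractions: ", diag_txt, call. = FALSE)
    return(list(scores = setNames(numeric(R), design$regulators),
                lags = setNames(integer(R), design$regulators),
                valid_lambdas = numeric(0), fractions = fracs, fits = list()))
  }
  vfits <- fits[valid]
  norms <- vapply(vfits, group_norms, numeric(R))
  norms <- matrix(norms, nrow = R, dimnames = list(design$regulators, NULL))
  scores <- rowMeans(norms)
  lags <- integer(R)
  for (r in seq_len(R)) {
    lr <- vapply(vfits, estimate_lag, 0L, regulator = r)
    lr <- lr[lr > 0L]
    if (scores[r] > cfg$weight_tol && length(lr) > 0) {
      lags[r] <- as.integer(floor(median(lr) + 0.5))
    } else {
      scores[r] <- 0
      lags[r] <- 0L
    }
  }
  list(scores = setNames(scores, design$regulators),
       lags = setNames(lags, design$regulators),
       valid_lambdas = grid[valid], fractions = fracs, fits = vfits)
}

#' Infer directed regulator-target interactions from spatial data
#'
#' The end-to-end pipeline: normalize expression, orient the spatial k-NN
#' graph along the (optionally inverted) isodepth into a DAG, build the
#' per-lag ancestor-aggregation operators, and — per target gene — sweep the
#' regularization grid over that target's candidate regulators and ensemble
#' the valid fits into interaction scores with lag estimates. Direction
#' `"both"` concatenates a forward run and a backward run (under the
#' inverted potential) with direction labels, so bidirectional signalling
#' can be probed.
#'
#' A target for which no regularization strength in the grid is valid
#' contributes zero scores (with a warning listing the per-lambda nonzero
#' fractions) rather than aborting the whole run.
#'
#' @param dataset a `spatial_dataset`.
#' @param pairs a `candidate_pairs` table.
#' @param field an `isodepth_field` for the same cells.
#' @param cfg a `granger_config`.
#' @param direction `"forward"`, `"backward"`, or `"both"`.
#' @param context free-text context label stored in the output.
#' @return An `interaction_table` with one row per candidate pair and
#'   direction.
#' @export
infer_interactions <- function(dataset, pairs, field, cfg = granger_config(),
                               direction = c("forward", "backward", "both"),
                               context = "") {
  direction <- match.arg(direction)
  stopifnot(is(dataset, "spatial_dataset"), is(field, "isodepth_field"))
  if (length(field$values) != nrow(dataset$counts)) {
    stop("isodepth length != number of cells", call. = FALSE)
  }
  if (nrow(pairs) == 0L) return(interaction_table())
  pairs <- resolve_pairs(pairs, dataset)
  norm <- normalize_expression(dataset, "log_cpm_z")
  keep <- norm$kept_cells
  coords <- dataset$coords[keep, , drop = FALSE]
  dvals <- field$values[keep]
  knn <- build_knn_graph(coords, cfg$k, duplicates = "jitter", seed = cfg$seed)
  dirs <- if (direction == "both") c("forward", "backward") else direction
  out <- list()
  for (dr in dirs) {
    d_use <- if (dr == "backward") max(dvals) - dvals else dvals
    dag <- orient_edges(knn, d_use, k = cfg$k)
    ops <- build_lag_operators(dag, cfg$max_lag)
    for (tg in sort(unique(pairs$target))) {
      sub <- pairs[pairs$target == tg, , drop = FALSE]
      regs <- sort(unique(sub$regulator))
      design <- assemble_design(norm, regs, ops)
      y <- norm$values[, match(tg, norm$gene_names)]
      self_col <- if (cfg$include_self) aggregate_self(y, ops) else NULL
      sw <- sweep_and_ensemble(design, y, cfg, self_column = self_col,
                               on_no_valid = "zero")
      ptype <- sub$pair_type[match(regs, sub$regulator)]
      out[[length(out) + 1L]] <- data.frame(
        regulator = regs, target = tg, pair_type = ptype, direction = dr,
        score = as.numeric(sw$scores[regs]), lag = as.integer(sw$lags[regs]),
        context = context, stringsAsFactors = FALSE)
      log_msg("[", dr, "] target ", tg, ": ", length(sw$valid_lambdas),
              " valid lambda(s), max score ",
              signif(max(sw$scores), 3))
    }
  }
  tab <- do.call(rbind, out)
  # keep only the requested candidate pairs (a regulator can appear for
  # several targets; every emitted row is a candidate pair by construction)
  interaction_table(tab$regulator, tab$target, tab$pair_type, tab$direction,
                    tab$score, tab$lag, tab$context)
}

#' Partition cells into stratified parts
#'
#' Cells are split into `n_parts` disjoint subsets that together cover the
#' dataset, selecting evenly from each label class so the class distribution
#' is preserved: per class, part sizes differ by at most one.
#'
#' @param dataset a `spatial_dataset` with `cell_labels`.
#' @param n_parts number of parts (default 3).
#' @param seed shuffle seed.
#' @return List of `n_parts` `spatial_dataset`s.
#' @export
stratified_partition <- function(dataset, n_parts = 3L, seed = 1L) {
  stopifnot(is(dataset, "spatial_dataset"))
  labels <- dataset$cell_labels
  if (is.null(labels)) stop("dataset has no cell_labels to stratify by", call. = FALSE)
  n_parts <- as.integer(n_parts)
  tab <- table(labels)
  if (any(tab < n_parts)) {
    stop("every label class must have at least n_parts cells; too small: ",
         paste(names(tab)[tab < n_parts], collapse = ", "), call. = FALSE)
  }
  assignment <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      assignment[idx] <- (seq_along(idx) - 1L) %% n_parts + 1L
    }
  })
  lapply(seq_len(n_parts), function(p) subset_cells(dataset, which(assignment == p)))
}

#' Classical linear Granger F-test on two time series
#'
#' Ordinary-least-squares fit of the full model (y on its own L lags plus
#' x's L lags) against the reduced model (own lags only), with the standard
#' F-test of the x-lag coefficients being jointly zero. Serves as the
#' independent oracle for the directed-path limit of the spatial model.
#'
#' @param x,y numeric series of equal length T, `T > 2L + 2`.
#' @param L maximum lag.
#' @param alpha test level.
#' @return List: `causal` (logical), `p_value`, `f_stat`, `beta_hat` (x-lag
#'   coefficients).
#' @export
var_granger_oracle <- function(x, y, L, alpha = 0.05) {
  T_ <- length(y)
  stopifnot(length(x) == T_, L >= 1)
  if (T_ <= 2 * L + 2) stop("series too short for ", L, " lags", call. = FALSE)
  idx <- (L + 1):T_
  mk_lags <- function(v) {
    m <- sapply(seq_len(L), function(l) v[idx - l])
    colnames(m) <- paste0("l", seq_len(L))
    m
  }
  Yl <- mk_lags(y)
  Xl <- mk_lags(x)
  full <- lm(y[idx] ~ Yl + Xl)
  red <- lm(y[idx] ~ Yl)
  an <- anova(red, full)
  p <- an$`Pr(>F)`[2]
  list(causal = is.finite(p) && p < alpha, p_value = p,
       f_stat = an$F[2],
       beta_hat = coef(full)[grepl("^Xl", names(coef(full)))])
}
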