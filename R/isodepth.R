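#' Construct an isodepth field
#'
#' A per-cell scalar spatial potential with optional layer breakpoints. Layer
#' labels follow the half-open convention: cell i is in layer p iff
#' `b_p <= d_i < b_{p+1}` with sentinel infinities at both ends, so labels
#' run from 0 to `length(breakpoints)`.
#'
#' @param values length-N numeric potential (finite).
#' @param breakpoints strictly increasing numeric vector (possibly empty).
#' @param inverted logical flag recording whether [invert_isodepth()] has
#'   been applied an odd number of times.
#' @return An object of class `isodepth_field` with elements `values`,
#'   `breakpoints`, `layer_labels`, `inverted`.
#' @export
isodepth_field <- function(values, breakpoints = numeric(0), inverted = FALSE) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("isodepth values must be finite", call. = FALSE)
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) > 1 && any(diff(breakpoints) <= 0)) {
    stop("breakpoints must be strictly increasing", call. = FALSE)
  }
  structure(list(values = values, breakpoints = breakpoints,
                 layer_labels = findInterval(values, breakpoints),
                 inverted = isTRUE(inverted)),
            class = "isodepth_field")
}

#' @export
print.isodepth_field <- function(x, ...) {
  cat("isodepth_field:", length(x$values), "cells, range [",
      paste(signif(range(x$values), 4), collapse = ", "), "], ",
      length(x$breakpoints), "breakpoint(s)",
      if (x$inverted) ", inverted" else "", "\n")
  invisible(x)
}

#' Attach a precomputed isodepth to a dataset
#'
#' Validates that an externally computed potential (e.g. imported from a
#' two-column TSV) matches the dataset and derives layer labels.
#'
#' @param dataset a `spatial_dataset`.
#' @param values length-N numeric potential.
#' @param breakpoints sorted numeric vector of layer boundaries.
#' @return An `isodepth_field`.
#' @export
attach_isodepth <- function(dataset, values, breakpoints = numeric(0)) {
  stopifnot(is(dataset, "spatial_dataset"))
  if (length(values) != nrow(dataset$counts)) {
    stop("isodepth length (", length(values), ") != number of cells (",
         nrow(dataset$counts), ")", call. = FALSE)
  }
  isodepth_field(values, breakpoints)
}

#' Invert an isodepth field
#'
#' Replaces each value by `max(d) - d_i`, reversing the ordering of cells
#' along the potential (and hence every edge of a DAG oriented by it).
#' Breakpoints are transformed through the same map and re-sorted; layer
#' labels are recomputed. Applying the inversion twice returns the original
#' values shifted so their minimum is zero.
#'
#' @param field an `isodepth_field`.
#' @return The inverted `isodepth_field` with the `inverted` flag toggled.
#' @export
invert_isodepth <- function(field) {
  stopifnot(is(field, "isodepth_field"))
  m <- max(field$values)
  isodepth_field(m - field$values,
                 breakpoints = sort(m - field$breakpoints),
                 inverted = !field$inverted)
}

#' Select the cells of one tissue layer
#'
#' @param dataset a `spatial_dataset`.
#' @param field an `isodepth_field` with layer labels.
#' @param layer_index integer layer label (0-based, as in the field).
#' @return A `spatial_dataset` subset; original indices in `cell_index`.
#' @export
select_layer <- function(dataset, field, layer_index) {
  stopifnot(is(field, "isodepth_field"))
  idx <- which(field$layer_labels == layer_index)
  if (length(idx) == 0L) {
    stop("no cells in layer ", layer_index, " (labels present: ",
         paste(sort(unique(field$layer_labels)), collapse = ", "), ")", call. = FALSE)
  }
  subset_cells(dataset, idx)
}

#' Select cells near an isodepth boundary
#'
#' Returns the cells whose potential lies within `width` of `boundary_value`,
#' e.g. "within 50 micrometers of the layer boundary" when the field is
#' scaled to the tissue's spatial extent.
#'
#' @param dataset a `spatial_dataset`.
#' @param field an `isodepth_field`.
#' @param boundary_value the boundary's isodepth; defaults to the field's
#'   first breakpoint.
#' @param width nonnegative half-width of the band, in isodepth units.
#' @return A `spatial_dataset` subset.
#' @export
select_boundary <- function(dataset, field, boundary_value = NULL, width) {
  stopifnot(is(field, "isodepth_field"), width >= 0)
  if (is.null(boundary_value)) {
    if (length(field$breakpoints) == 0L) {
      stop("no breakpoints to default the boundary to", call. = FALSE)
    }
    boundary_value <- field$breakpoints[1]
  }
  idx <- which(abs(field$values - boundary_value) <= width)
  if (length(idx) == 0L) {
    stop("empty selection: no cells within ", width, " of isodepth ",
         boundary_value, call. = FALSE)
  }
  subset_cells(dataset, idx)
}

#' Isodepth fitting configuration
#'
#' @param n_pieces number of linear pieces P of the 1-D expression model
#'   (P - 1 breakpoints).
#' @param reduction_dims number of expression principal components used under
#'   the Gaussian likelihood.
#' @param likelihood `"gaussian_on_reduced"` (Gaussian error on PCs of
#'   log1p-CPM expression) or `"poisson"` (Poisson counts with per-cell UMI
#'   exposure).
#' @param seed integer seed controlling parameter initialization.
#' @param epochs total Adam iterations (a warm-up fraction runs with a single
#'   linear piece before breakpoints are introduced).
#' @param learning_rate Adam step size.
#' @param hidden_width width of the two hidden layers of the scalar field
#'   network.
#' @param warmup_frac fraction of epochs spent in the single-piece warm-up.
#' @return A list of class `isodepth_config`.
#' @export
isodepth_config <- function(n_pieces = 1L, reduction_dims = 5L,
                            likelihood = c("gaussian_on_reduced", "poisson"),
                            seed = 1L, epochs = 600L, learning_rate = 0.02,
                            hidden_width = 16L, warmup_frac = 0.3) {
  likelihood <- match.arg(likelihood)
  stopifnot(n_pieces >= 1L, reduction_dims >= 1L, epochs >= 1L,
            learning_rate > 0, hidden_width >= 1L,
            warmup_frac >= 0, warmup_frac < 1)
  structure(list(n_pieces = as.integer(n_pieces),
                 reduction_dims = as.integer(reduction_dims),
                 likelihood = likelihood, seed = as.integer(seed),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 hidden_width = as.integer(hidden_width),
                 warmup_frac = warmup_frac),
            class = "isodepth_config")
}

# --- minimal Adam over a named list of arrays ----------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# forward pass of the scalar field d(s) = s v + MLP(s); sc is N x 2 (already
# centered and scaled), returns list with d and the intermediates needed for
# backprop
field_forward <- function(sc, p) {
  Z1 <- sweep(sc %*% p$W1, 2L, p$b1, "+")
  A1 <- tanh(Z1)
  Z2 <- sweep(A1 %*% p$W2, 2L, p$b2, "+")
  A2 <- tanh(Z2)
  d <- drop(sc %*% p$v + A2 %*% p$W3) + p$b3
  list(d = d, A1 = A1, A2 = A2)
}

# gd: dL/dd (length N). Returns gradients for the field parameters.
field_backward <- function(sc, p, fw, gd) {
  gd <- matrix(gd, ncol = 1L)
  GA2 <- gd %*% t(p$W3)
  GZ2 <- GA2 * (1 - fw$A2^2)
  GA1 <- GZ2 %*% t(p$W2)
  GZ1 <- GA1 * (1 - fw$A1^2)
  list(v = drop(t(sc) %*% gd),
       W1 = t(sc) %*% GZ1, b1 = colSums(GZ1),
       W2 = t(fw$A1) %*% GZ2, b2 = colSums(GZ2),
       W3 = t(fw$A2) %*% gd, b3 = sum(gd))
}

# piecewise-linear head in cumulative form: for output channel j,
#   h_j(d) = c_j + w0_j d + sum_p wp_{p,j} * relu(d - b_p)
# Continuity at every breakpoint holds by construction.
head_forward <- function(d, hp) {
  mu <- outer(d, hp$w0) + matrix(hp$c, length(d), length(hp$c), byrow = TRUE)
  if (length(hp$b) > 0) {
    for (pz in seq_along(hp$b)) {
      r <- pmax(d - hp$b[pz], 0)
      mu <- mu + outer(r, hp$wp[pz, ])
    }
  }
  mu
}

# r: dL/dmu (N x q). Returns head gradients and dL/dd.
head_backward <- function(d, hp, r) {
  gr <- list(c = colSums(r), w0 = drop(t(r) %*% d))
  gd <- drop(r %*% hp$w0)
  if (length(hp$b) > 0) {
    gwp <- matrix(0, length(hp$b), ncol(r))
    gb <- numeric(length(hp$b))
    for (pz in seq_along(hp$b)) {
      act <- d > hp$b[pz]
      rel <- pmax(d - hp$b[pz], 0)
      gwp[pz, ] <- drop(t(r) %*% rel)
      gb[pz] <- -sum((r %*% hp$wp[pz, ]) * act)
      gd <- gd + drop(r %*% hp$wp[pz, ]) * act
    }
    gr$wp <- gwp
    gr$b <- gb
  }
  list(grads = gr, gd = gd)
}

#' Fit the isodepth spatial potential
#'
#' Learns a smooth scalar field d(x, y) and a continuous piecewise-linear
#' 1-D expression model h(d) by maximizing the fit of `h(d(s_i))` to the
#' cells' expression. The field is parameterized as a linear term in the
#' (standardized) coordinates plus a small two-hidden-layer tanh network, so
#' it is continuously differentiable; the linear term is initialized from a
#' regression of the first expression principal component on the coordinates,
#' which points the potential along the direction of maximum spatial
#' expression variation before refinement. Training is full-batch Adam; a
#' warm-up phase uses a single linear piece, after which breakpoints are
#' initialized at quantiles of the current potential and trained jointly.
#'
#' Under `likelihood = "gaussian_on_reduced"` the head models the top
#' principal components of log1p-CPM expression with squared error; under
#' `"poisson"` it models per-gene log-rates of UMI-scaled Poisson counts.
#' After fitting, the potential is affinely rescaled to `[0, D]` where D is
#' the diagonal of the coordinate bounding box, so isodepth widths (e.g. a
#' 50 micrometer boundary band) are on the scale of the tissue.
#'
#' @param dataset a `spatial_dataset` with at least two distinct locations
#'   and at least one non-constant gene.
#' @param cfg an [isodepth_config()].
#' @return A list with `field` (an `isodepth_field`), `expression` (a
#'   `piecewise_expression` for all G genes), and `loss_trace`.
#' @export
fit_isodepth <- function(dataset, cfg = isodepth_config()) {
  stopifnot(is(dataset, "spatial_dataset"), is(cfg, "isodepth_config"))
  N <- nrow(dataset$counts)
  if (nrow(unique(dataset$coords)) < 2L) {
    stop("need at least 2 distinct spatial locations", call. = FALSE)
  }
  if (cfg$n_pieces >= N) stop("n_pieces must be smaller than the number of cells", call. = FALSE)
  norm <- normalize_expression(dataset, "log_cpm_z", zero_umi = "error")
  if (all(norm$constant_genes)) {
    stop("degenerate input: all genes are constant, no direction of expression variation",
         call. = FALSE)
  }
  logcpm <- log1p(1e4 * dataset$counts / dataset$umi_totals)
  ctr <- colMeans(logcpm)
  q <- min(cfg$reduction_dims, sum(!norm$constant_genes), N - 1L)
  pc <- prcomp(logcpm, center = TRUE, scale. = FALSE, rank. = q)
  sc <- scale(dataset$coords)
  sc_center <- attr(sc, "scaled:center")
  sc_scale <- attr(sc, "scaled:scale")
  sc_scale[sc_scale == 0] <- 1
  sc <- sweep(sweep(dataset$coords, 2L, sc_center, "-"), 2L, sc_scale, "/")

  poisson_lik <- cfg$likelihood == "poisson"
  if (poisson_lik) {
    Y <- dataset$counts
    U <- dataset$umi_totals
    qout <- ncol(Y)
  } else {
    Y <- pc$x
    qout <- q
  }
  h <- cfg$hidden_width

  init <- withr::with_seed(cfg$seed, {
    v0 <- coef(lm(pc$x[, 1] ~ sc))[2:3]
    v0[is.na(v0)] <- 0
    nv <- sqrt(sum(v0^2))
    if (nv < 1e-12) v0 <- c(1, 0) else v0 <- v0 / nv
    list(field = list(v = v0,
                      W1 = matrix(rnorm(2 * h, sd = 0.5), 2, h), b1 = numeric(h),
                      W2 = matrix(rnorm(h * h, sd = 0.3), h, h), b2 = numeric(h),
                      W3 = matrix(rnorm(h, sd = 0.01), h, 1), b3 = 0),
         head = list(c = if (poisson_lik) log(pmax(colMeans(Y / U), 1e-8)) else numeric(qout),
                     w0 = rnorm(qout, sd = 0.1),
                     wp = NULL, b = numeric(0)))
  })
  fp <- init$field
  hp <- init$head

  loss_grad <- function(d, hp) {
    mu <- head_forward(d, hp)
    if (poisson_lik) {
      mu <- pmin(mu, 30)
      lam <- U * exp(mu)
      loss <- sum(lam - Y * mu) / N
      r <- (lam - Y) / N
    } else {
      rsd <- mu - Y
      loss <- sum(rsd^2) / N
      r <- 2 * rsd / N
    }
    list(loss = loss, r = r)
  }

  run_epochs <- function(n_ep, fp, hp, trace) {
    st_f <- adam_init(fp)
    st_h <- adam_init(hp[!vapply(hp, is.null, TRUE)])
    for (ep in seq_len(n_ep)) {
      fw <- field_forward(sc, fp)
      lg <- loss_grad(fw$d, hp)
      hb <- head_backward(fw$d, hp, lg$r)
      fg <- field_backward(sc, fp, fw, hb$gd)
      up <- adam_step(fp, fg, st_f, cfg$learning_rate)
      fp <- up$params; st_f <- up$state
      hg <- hb$grads
      hcur <- hp[names(st_h$m)]
      up <- adam_step(hcur, hg[names(hcur)], st_h, cfg$learning_rate)
      hp[names(hcur)] <- up$params; st_h <- up$state
      trace <- c(trace, lg$loss)
    }
    list(fp = fp, hp = hp, trace = trace)
  }

  n_warm <- if (cfg$n_pieces > 1L) max(1L, as.integer(round(cfg$warmup_frac * cfg$epochs))) else cfg$epochs
  res <- run_epochs(n_warm, fp, hp, numeric(0))
  fp <- res$fp; hp <- res$hp; trace <- res$trace
  if (cfg$n_pieces > 1L) {
    d_now <- field_forward(sc, fp)$d
    probs <- seq_len(cfg$n_pieces - 1L) / cfg$n_pieces
    hp$b <- as.numeric(quantile(d_now, probs, names = FALSE, type = 7))
    if (any(diff(hp$b) <= 0)) hp$b <- hp$b + seq_along(hp$b) * 1e-9
    hp$wp <- matrix(0, cfg$n_pieces - 1L, qout)
    res <- run_epochs(cfg$epochs - n_warm, fp, hp, trace)
    fp <- res$fp; hp <- res$hp; trace <- res$trace
  }

  d_hat <- field_forward(sc, fp)$d
  rng <- range(d_hat)
  if (diff(rng) < 1e-12) {
    stop("fitted potential is constant; expression has no usable spatial structure",
         call. = FALSE)
  }
  extent <- sqrt(sum(apply(dataset$coords, 2L, function(z) diff(range(z)))^2))
  if (extent <= 0) extent <- 1
  a <- extent / diff(rng)
  d_scaled <- (d_hat - rng[1]) * a
  bks <- if (length(hp$b) > 0) sort((hp$b - rng[1]) * a) else numeric(0)
  bks <- bks[bks > 0 & bks < extent]
  if (length(bks) > 1) bks <- bks[c(TRUE, diff(bks) > 1e-9)]
  field <- isodepth_field(d_scaled, breakpoints = bks)

  # map the head to per-gene piecewise slopes/intercepts on the rescaled axis
  pw <- build_piecewise(hp, rng, a, poisson_lik,
                        loadings = if (poisson_lik) NULL else pc$rotation,
                        centers = if (poisson_lik) NULL else ctr,
                        gene_names = dataset$gene_names,
                        breakpoints = bks)
  structure(list(field = field, expression = pw, loss_trace = trace,
                 config = cfg),
            class = "isodepth_fit")
}

# Convert the cumulative-form head (on raw d) into per-gene per-piece slopes
# and intercepts on the rescaled isodepth axis. Under the Gaussian route the
# per-PC head is pushed through the PCA loadings back to gene space
# (log1p-CPM scale); under Poisson it is already per gene (log-rate scale).
build_piecewise <- function(hp, rng, a, poisson_lik, loadings, centers,
                            gene_names, breakpoints) {
  P <- length(breakpoints) + 1L
  qout <- length(hp$c)
  # head on rescaled axis: d_raw = d_scaled / a + rng[1]
  c_eff <- hp$c + hp$w0 * rng[1]
  w0_eff <- hp$w0 / a
  slopes_ch <- matrix(0, P, qout)
  ints_ch <- matrix(0, P, qout)
  slopes_ch[1, ] <- w0_eff
  ints_ch[1, ] <- c_eff
  if (P > 1L) {
    # hp$b on raw axis -> rescaled; piece slopes accumulate wp
    b_scaled <- (hp$b - rng[1]) * a
    keep <- b_scaled > 0 & b_scaled < max(b_scaled + 1) # all, then match breakpoints
    wp_eff <- hp$wp / a
    # align stored breakpoints with the (filtered, deduplicated) field ones
    for (k in seq_len(P - 1L)) {
      j <- which.min(abs(b_scaled - breakpoints[k]))
      slopes_ch[k + 1L, ] <- slopes_ch[k, ] + wp_eff[j, ]
      ints_ch[k + 1L, ] <- ints_ch[k, ] - wp_eff[j, ] * breakpoints[k]
    }
  }
  if (poisson_lik) {
    slopes <- t(slopes_ch)
    ints <- t(ints_ch)
    scale_lab <- "log_rate"
  } else {
    slopes <- loadings %*% t(slopes_ch)
    ints <- loadings %*% t(ints_ch) + centers
    scale_lab <- "log1p_cpm"
  }
  rownames(slopes) <- rownames(ints) <- gene_names
  structure(list(breakpoints = breakpoints, slopes = slopes,
                 intercepts = ints, n_pieces = P, scale = scale_lab,
                 gene_names = gene_names),
            class = "piecewise_expression")
}

#' Evaluate the fitted 1-D expression model
#'
#' @param object a `piecewise_expression`.
#' @param d numeric vector of isodepth values.
#' @param genes gene names or indices (default all).
#' @param ... unused.
#' @return A matrix `length(d)` x `length(genes)` of model values on the
#'   model's scale (`log1p_cpm` or `log_rate`).
#' @export
predict.piecewise_expression <- function(object, d, genes = NULL, ...) {
  gi <- if (is.null(genes)) seq_along(object$gene_names) else genes
  if (is.character(gi)) gi <- match(gi, object$gene_names)
  piece <- findInterval(d, object$breakpoints) + 1L
  out <- matrix(0, length(d), length(gi))
  for (jj in seq_along(gi)) {
    g <- gi[jj]
    out[, jj] <- object$intercepts[g, piece] + object$slopes[g, piece] * d
  }
  colnames(out) <- object$gene_names[gi]
  out
}

#' Export an isodepth field as a two-column TSV
#'
#' @param field an `isodepth_field`.
#' @param path output file.
#' @param cell_ids optional identifiers (default 1..N).
#' @return `path`, invisibly.
#' @export
write_isodepth <- function(field, path, cell_ids = NULL) {
  stopifnot(is(field, "isodepth_field"))
  ids <- cell_ids %||% seq_along(field$values)
  write.table(data.frame(cell_id = ids, isodepth = field$values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import an isodepth field from a two-column TSV
#'
#' @param path TSV with columns cell_id, isodepth.
#' @param breakpoints optional layer boundaries.
#' @return An `isodepth_field`.
#' @export
read_isodepth <- function(path, breakpoints = numeric(0)) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  isodepth_field(tab$isodepth, breakpoints = breakpoints)
}
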