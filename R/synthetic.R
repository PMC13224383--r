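#' Ground truth record for synthetic spatial data
#'
#' @param planted_pairs data frame with columns `regulator`, `target`, `lag`,
#'   `beta` (effect size on the log-rate scale per unit of standardized
#'   regulator expression) and optionally `direction` (default `"forward"`).
#' @param n_pieces pieces of the generative piecewise-linear baseline trend.
#' @param noise_sd Gaussian log-rate noise sd (on top of Poisson sampling).
#' @param umi_meanlog,umi_sdlog log-normal parameters of per-cell total UMIs
#'   (defaults mimic UMI-sparse bead data with a median around 500).
#' @param k neighbor count of the generative spatial DAG.
#' @param max_lag deepest lag the generator may plant.
#' @param flat_genes genes simulated without a spatial baseline trend
#'   (log-rate flat in isodepth). Defaults to the planted regulators: the
#'   lag of a planted interaction is carried by the propagation of a
#'   regulator's cell-level expression fluctuations, and is identifiable
#'   only if those fluctuations are not swamped by a smooth spatial trend
#'   (ancestor averages of a smooth monotone field are nearly
#'   lag-invariant).
#' @return A list of class `synthetic_truth`. After [simulate_expression()]
#'   the realized `true_dag_edges`, `umi_totals` and `breakpoints` are
#'   filled in.
#' @export
synthetic_truth <- function(planted_pairs = NULL, n_pieces = 3L,
                            noise_sd = 0.1, umi_meanlog = log(500),
                            umi_sdlog = 0.3, k = 7L, max_lag = 5L,
                            flat_genes = NULL) {
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(regulator = character(), target = character(),
                                lag = integer(), beta = numeric(),
                                direction = character())
  }
  if (is.null(planted_pairs$direction)) {
    planted_pairs$direction <- rep("forward", nrow(planted_pairs))
  }
  if (nrow(planted_pairs) > 0) {
    stopifnot(all(planted_pairs$lag >= 1), all(planted_pairs$lag <= max_lag),
              all(is.finite(planted_pairs$beta)))
    if (any(planted_pairs$regulator %in% planted_pairs$target)) {
      stop("a planted regulator may not also be a planted target", call. = FALSE)
    }
  }
  if (is.null(flat_genes)) flat_genes <- unique(planted_pairs$regulator)
  structure(list(planted_pairs = planted_pairs, n_pieces = as.integer(n_pieces),
                 noise_sd = noise_sd, umi_meanlog = umi_meanlog,
                 umi_sdlog = umi_sdlog, k = as.integer(k),
                 max_lag = as.integer(max_lag),
                 flat_genes = as.character(flat_genes),
                 true_isodepth = NULL, true_dag_edges = NULL,
                 umi_totals = NULL, breakpoints = NULL),
            class = "synthetic_truth")
}

#' Generate cell coordinates with a known spatial potential
#'
#' The true potential is a monotone function of one axis, affinely scaled to
#' the coordinate extent, emulating a layered tissue strip.
#'
#' @param n_cells number of cells (>= 10).
#' @param layout `"grid"` (regular lattice), `"uniform_random"`, or
#'   `"layered_strip"` (uniform with layer breakpoints at equal quantiles).
#' @param seed RNG seed.
#' @param extent length-2 rectangle size in micrometers.
#' @param axis `"x"` or `"y"`: the axis the potential increases along.
#' @param n_layers layer count for `layered_strip`.
#' @return List: `coords` (N x 2), `isodepth` (length N), `breakpoints`,
#'   `layer_labels`.
#' @export
make_spatial_field <- function(n_cells, layout = c("grid", "uniform_random",
                                                   "layered_strip"),
                               seed = 1L, extent = c(1000, 600),
                               axis = c("x", "y"), n_layers = 3L) {
  layout <- match.arg(layout)
  axis <- match.arg(axis)
  if (n_cells < 10L) stop("n_cells must be >= 10", call. = FALSE)
  coords <- withr::with_seed(seed, {
    if (layout == "grid") {
      nr <- floor(sqrt(n_cells))
      nc <- ceiling(n_cells / nr)
      g <- expand.grid(x = seq(0, extent[1], length.out = nc),
                       y = seq(0, extent[2], length.out = nr))
      as.matrix(g[seq_len(n_cells), c("x", "y")])
    } else {
      cbind(x = runif(n_cells, 0, extent[1]), y = runif(n_cells, 0, extent[2]))
    }
  })
  ax <- if (axis == "x") coords[, 1] else coords[, 2]
  ext_ax <- if (axis == "x") extent[1] else extent[2]
  iso <- ax / max(ext_ax, 1e-12) * sqrt(sum(extent^2))
  if (layout == "layered_strip") {
    probs <- seq_len(n_layers - 1L) / n_layers
    bks <- as.numeric(quantile(iso, probs, names = FALSE))
  } else {
    bks <- numeric(0)
  }
  list(coords = coords, isodepth = iso, breakpoints = bks,
       layer_labels = findInterval(iso, bks))
}

#' Simulate UMI counts over a known spatial field and DAG
#'
#' Per-gene baseline log-rates are continuous piecewise-linear functions of
#' the true isodepth (breakpoints at equal quantiles), centered so genes
#' share the library roughly equally; Gaussian noise (sd `truth$noise_sd`) is
#' added on the log-rate scale, and counts are drawn Poisson with per-cell
#' UMI exposure, `c_ig ~ Pois(U_i * exp(f_g))`. For every planted pair, the
#' target's log-rate gains `beta * (lag-l ancestor-average of the
#' regulator's standardized log1p-CPM expression)` computed on the true
#' spatial DAG (k-NN graph oriented by the true isodepth) through the same
#' row-normalized lag operators inference uses, so the planted signal lives
#' exactly in the model family. Set `truth$normalize_ops = FALSE` upstream
#' for a mismatched-generator robustness mode using unnormalized walk sums.
#'
#' @param coords N x 2 coordinates.
#' @param true_isodepth length-N potential.
#' @param truth a [synthetic_truth()].
#' @param G number of genes; planted genes must be among `paste0("g", 1:G)`
#'   unless `gene_names` is supplied.
#' @param seed RNG seed.
#' @param gene_names optional length-G gene names.
#' @return List: `dataset` (a `spatial_dataset` with layer labels as
#'   `cell_labels`) and `truth` (with realized DAG edges, UMIs, breakpoints
#'   filled in).
#' @export
simulate_expression <- function(coords, true_isodepth, truth, G, seed = 1L,
                                gene_names = NULL) {
  stopifnot(is(truth, "synthetic_truth"))
  coords <- as.matrix(coords)
  N <- nrow(coords)
  stopifnot(length(true_isodepth) == N)
  gene_names <- gene_names %||% paste0("g", seq_len(G))
  stopifnot(length(gene_names) == G)
  pp <- truth$planted_pairs
  if (nrow(pp) > 0) {
    missing <- setdiff(unique(c(pp$regulator, pp$target)), gene_names)
    if (length(missing)) stop("planted genes absent from gene_names: ",
                              paste(missing, collapse = ", "), call. = FALSE)
  }
  knn <- build_knn_graph(coords, truth$k, duplicates = "jitter", seed = seed)
  dag <- orient_edges(knn, true_isodepth, k = truth$k)
  ops <- build_lag_operators(dag, truth$max_lag)
  if (isFALSE(truth$normalize_ops)) {
    # mismatched-generator mode: raw walk counts instead of averages
    M <- Matrix::sparseMatrix(i = dag$edges[, 2], j = dag$edges[, 1], x = 1,
                              dims = c(N, N))
    P <- M
    ops$ops[[1]] <- P
    if (truth$max_lag > 1) for (l in 2:truth$max_lag) {
      P <- P %*% M
      ops$ops[[l]] <- P
    }
  }
  P_pieces <- truth$n_pieces
  bks <- if (P_pieces > 1L) {
    as.numeric(quantile(true_isodepth, seq_len(P_pieces - 1L) / P_pieces,
                        names = FALSE))
  } else numeric(0)

  out <- withr::with_seed(seed, {
    U <- pmax(1, round(rlnorm(N, truth$umi_meanlog, truth$umi_sdlog)))
    ext <- diff(range(true_isodepth))
    if (ext <= 0) ext <- 1
    # the G simulated genes take about half the library, so the per-cell
    # total UMI count U stays a valid exposure (>= the panel's row sums)
    base_int <- log(1 / (2 * G))
    f <- matrix(0, N, G)
    for (g in seq_len(G)) {
      flat <- gene_names[g] %in% truth$flat_genes
      w0 <- if (flat) 0 else rnorm(1, sd = 0.7) / ext
      fg <- w0 * true_isodepth
      if (length(bks) > 0 && !flat) {
        wp <- rnorm(length(bks), sd = 0.7) / ext
        for (pz in seq_along(bks)) fg <- fg + wp[pz] * pmax(true_isodepth - bks[pz], 0)
      }
      f[, g] <- fg - mean(fg) + base_int
    }
    f <- f + matrix(rnorm(N * G, sd = truth$noise_sd), N, G)
    counts <- matrix(0, N, G, dimnames = list(NULL, gene_names))
    targets <- unique(pp$target)
    base_genes <- setdiff(gene_names, targets)
    for (g in base_genes) {
      j <- match(g, gene_names)
      counts[, j] <- rpois(N, U * exp(f[, j]))
    }
    if (length(targets) > 0) {
      reg_z <- sapply(unique(pp$regulator), function(g) {
        v <- log1p(1e4 * counts[, match(g, gene_names)] / U)
        if (sd(v) < 1e-12) rep(0, N) else (v - mean(v)) / sd(v)
      })
      reg_z <- matrix(reg_z, nrow = N,
                      dimnames = list(NULL, unique(pp$regulator)))
      for (tg in targets) {
        j <- match(tg, gene_names)
        ftg <- f[, j]
        rows <- which(pp$target == tg)
        for (rr in rows) {
          A <- ops$ops[[pp$lag[rr]]]
          ftg <- ftg + pp$beta[rr] * as.numeric(A %*% reg_z[, pp$regulator[rr]])
        }
        lam <- U * exp(ftg)
        if (any(lam > 1e7)) {
          stop("Poisson rate overflow: planted effect size too large", call. = FALSE)
        }
        counts[, j] <- rpois(N, lam)
      }
    }
    list(counts = counts, U = U)
  })
  labels <- findInterval(true_isodepth, bks)
  ds <- spatial_dataset(out$counts, coords, gene_names = gene_names,
                        cell_labels = paste0("layer", labels),
                        umi_totals = pmax(out$U, rowSums(out$counts)))
  truth$true_isodepth <- true_isodepth
  truth$true_dag_edges <- dag$edges
  truth$umi_totals <- out$U
  truth$base_log_rate <- log(1 / (2 * ncol(out$counts)))
  truth$breakpoints <- bks
  list(dataset = ds, truth = truth)
}

#' Named synthetic benchmark suites
#'
#' Fixed desk-scale scenarios with ground truth for end-to-end evaluation:
#' \describe{
#'   \item{easy}{500 cells, 20 genes; 5 planted pairs (lags 1-3, strong
#'     effect beta = 1) among 40 candidates.}
#'   \item{hard}{500 cells, 30 genes; 10 planted pairs with weak effect
#'     (beta = 0.4) among 80 candidates.}
#'   \item{null}{the easy layout with zero planted pairs (all 40 candidates
#'     are decoys).}
#' }
#' Regulator genes are named `TF1..`, targets `TG1..`; decoy candidates are
#' drawn deterministically from the seed.
#'
#' @param name suite name.
#' @param seed RNG seed; the entire output is a deterministic function of it.
#' @return List: `dataset`, `pairs` (a `candidate_pairs`), `truth`, `field`
#'   (the true isodepth as an `isodepth_field`).
#' @export
benchmark_suite <- function(name = c("easy", "hard", "null"), seed = 7L) {
  name <- match.arg(name)
  n_cells <- 500L
  spec <- switch(name,
    easy = list(G = 20L, n_reg = 8L, n_tgt = 12L, n_planted = 5L,
                beta = 1.0, n_cand = 40L),
    hard = list(G = 30L, n_reg = 10L, n_tgt = 20L, n_planted = 10L,
                beta = 0.4, n_cand = 80L),
    null = list(G = 20L, n_reg = 8L, n_tgt = 12L, n_planted = 0L,
                beta = 1.0, n_cand = 40L))
  regs <- paste0("TF", seq_len(spec$n_reg))
  tgts <- paste0("TG", seq_len(spec$n_tgt))
  genes <- c(regs, tgts)
  planted <- if (spec$n_planted > 0) {
    data.frame(regulator = regs[seq_len(spec$n_planted)],
               target = tgts[seq_len(spec$n_planted)],
               lag = rep_len(c(1L, 2L, 3L), spec$n_planted),
               beta = spec$beta,
               direction = "forward", stringsAsFactors = FALSE)
  } else NULL
  fld <- make_spatial_field(n_cells, "layered_strip", seed = seed,
                            extent = c(1000, 600), n_layers = 3L)
  truth <- synthetic_truth(planted, n_pieces = 3L, max_lag = 5L,
                           flat_genes = regs)
  sim <- simulate_expression(fld$coords, fld$isodepth, truth, G = spec$G,
                             seed = seed + 1L, gene_names = genes)
  all_cand <- expand.grid(regulator = regs, target = tgts,
                          stringsAsFactors = FALSE)
  key <- paste(all_cand$regulator, all_cand$target)
  true_key <- if (is.null(planted)) character(0) else paste(planted$regulator, planted$target)
  decoy_pool <- all_cand[!key %in% true_key, , drop = FALSE]
  n_decoy <- spec$n_cand - length(true_key)
  decoys <- withr::with_seed(seed + 2L, {
    decoy_pool[sample(nrow(decoy_pool), n_decoy), , drop = FALSE]
  })
  cand <- rbind(if (!is.null(planted)) planted[, c("regulator", "target")],
                decoys)
  pairs <- candidate_pairs(cand$regulator, cand$target, "tf_target")
  list(dataset = sim$dataset, pairs = pairs, truth = sim$truth,
       field = isodepth_field(fld$isodepth, breakpoints = fld$breakpoints))
}
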