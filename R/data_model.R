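#' Construct a spatial expression dataset
#'
#' The core container: a nonnegative integer UMI count matrix (cells x genes),
#' matching 2-D spatial coordinates in micrometers, and optional per-cell
#' labels and total UMI counts. Total UMIs default to the per-cell row sums of
#' the count matrix; an externally supplied vector must dominate the row sums
#' (counts for a gene panel cannot exceed the cell's library size).
#'
#' @param counts N x G matrix of nonnegative integer counts (base matrix or
#'   a `Matrix` sparse matrix; stored dense internally).
#' @param coords N x 2 numeric matrix of spatial coordinates (micrometers).
#' @param gene_names length-G character vector of unique gene identifiers;
#'   defaults to `colnames(counts)`.
#' @param cell_labels optional length-N factor/character of cell type or
#'   layer labels.
#' @param umi_totals optional length-N positive integer vector of total UMIs
#'   per cell; defaults to `rowSums(counts)`.
#' @return An object of class `spatial_dataset`: a list with elements
#'   `counts`, `coords`, `gene_names`, `cell_labels`, `umi_totals`, and
#'   `cell_index` (original row indices, preserved through subsetting).
#' @export
spatial_dataset <- function(counts, coords, gene_names = colnames(counts),
                            cell_labels = NULL, umi_totals = NULL) {
  if (is(counts, "Matrix")) counts <- as.matrix(counts)
  counts <- as.matrix(counts)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(counts) != nrow(coords)) {
    stop("dimension mismatch: counts has ", nrow(counts), " cells but coords has ",
         nrow(coords), " rows", call. = FALSE)
  }
  if (ncol(coords) != 2L) stop("coords must have exactly 2 columns", call. = FALSE)
  bad <- which(counts < 0 | (is.finite(counts) & abs(counts - round(counts)) > 1e-8),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("counts must be nonnegative integers; offending entry at cell ",
         bad[1, 1], ", gene ", bad[1, 2], " (value ", counts[bad[1, , drop = FALSE]],
         ")", call. = FALSE)
  }
  if (any(!is.finite(counts))) stop("counts contain non-finite values", call. = FALSE)
  storage.mode(counts) <- "double"
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(counts)))
  gene_names <- as.character(gene_names)
  if (length(gene_names) != ncol(counts)) {
    stop("gene_names length (", length(gene_names), ") != number of genes (",
         ncol(counts), ")", call. = FALSE)
  }
  if (anyDuplicated(gene_names)) {
    stop("duplicate gene names: ",
         paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "),
         call. = FALSE)
  }
  colnames(counts) <- gene_names
  rs <- rowSums(counts)
  if (is.null(umi_totals)) {
    umi_totals <- rs
  } else {
    umi_totals <- as.numeric(umi_totals)
    if (length(umi_totals) != nrow(counts)) {
      stop("umi_totals length != number of cells", call. = FALSE)
    }
    if (any(umi_totals <= 0)) stop("umi_totals must be strictly positive", call. = FALSE)
    if (any(umi_totals < rs - 1e-8)) {
      stop("supplied umi_totals smaller than per-cell count sums", call. = FALSE)
    }
  }
  if (!is.null(cell_labels)) {
    if (length(cell_labels) != nrow(counts)) {
      stop("cell_labels length != number of cells", call. = FALSE)
    }
    cell_labels <- as.character(cell_labels)
  }
  structure(list(counts = counts, coords = coords, gene_names = gene_names,
                 cell_labels = cell_labels, umi_totals = umi_totals,
                 cell_index = seq_len(nrow(counts))),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("spatial_dataset:", nrow(x$counts), "cells x", ncol(x$counts), "genes\n")
  cat("  coordinate range: x [", paste(signif(range(x$coords[, 1]), 4), collapse = ", "),
      "], y [", paste(signif(range(x$coords[, 2]), 4), collapse = ", "), "]\n", sep = "")
  if (!is.null(x$cell_labels)) {
    cat("  labels:", paste(names(table(x$cell_labels)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$counts)

#' Subset a dataset to a set of cells
#'
#' Original row indices are carried along in `cell_index` so selections (a
#' tissue layer, a boundary band, a stratified third) can be traced back to
#' the parent dataset.
#'
#' @param dataset a `spatial_dataset`.
#' @param idx integer vector of cell indices (rows) to keep.
#' @return A `spatial_dataset` with the selected cells.
#' @export
subset_cells <- function(dataset, idx) {
  stopifnot(is(dataset, "spatial_dataset"))
  idx <- as.integer(idx)
  if (length(idx) == 0L) stop("empty cell selection", call. = FALSE)
  if (any(idx < 1L | idx > nrow(dataset$counts))) stop("cell index out of range", call. = FALSE)
  out <- dataset
  out$counts <- dataset$counts[idx, , drop = FALSE]
  out$coords <- dataset$coords[idx, , drop = FALSE]
  out$umi_totals <- dataset$umi_totals[idx]
  out$cell_labels <- if (is.null(dataset$cell_labels)) NULL else dataset$cell_labels[idx]
  out$cell_index <- dataset$cell_index[idx]
  out
}

#' Read a spatial dataset from disk
#'
#' Two plain-text layouts are supported. `csv`: a single delimited table whose
#' first two columns are the spatial coordinates (named `x`, `y`) and whose
#' remaining columns are gene counts, one row per cell. `mtx_dir`: a directory
#' in the usual single-cell exchange layout with `matrix.mtx` (genes x cells,
#' Matrix Market, 1-based per the standard), `features.tsv`, `barcodes.tsv`,
#' and a `coords.tsv` sidecar (columns: barcode, x, y).
#'
#' @param path file (csv) or directory (mtx_dir).
#' @param format one of `"csv"`, `"mtx_dir"`.
#' @return A validated [spatial_dataset()]; gene and cell order follow the
#'   source files.
#' @export
read_dataset <- function(path, format = c("csv", "mtx_dir")) {
  format <- match.arg(format)
  if (format == "csv") {
    tab <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                      comment.char = "#")
    if (ncol(tab) < 3L) stop("csv dataset needs x, y plus at least one gene column", call. = FALSE)
    if (!identical(tolower(colnames(tab)[1:2]), c("x", "y"))) {
      stop("first two csv columns must be the coordinates 'x' and 'y'", call. = FALSE)
    }
    coords <- as.matrix(tab[, 1:2])
    counts <- as.matrix(tab[, -(1:2), drop = FALSE])
    spatial_dataset(counts, coords, gene_names = colnames(tab)[-(1:2)])
  } else {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    barc <- file.path(path, "barcodes.tsv")
    coo <- file.path(path, "coords.tsv")
    for (f in c(mtx, feat, barc, coo)) {
      if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
    }
    m <- Matrix::readMM(mtx)              # genes x cells
    genes <- read.table(feat, header = FALSE, sep = "\t")[[1]]
    cells <- read.table(barc, header = FALSE, sep = "\t")[[1]]
    if (nrow(m) != length(genes)) stop("features.tsv does not match matrix rows", call. = FALSE)
    if (ncol(m) != length(cells)) stop("barcodes.tsv does not match matrix columns", call. = FALSE)
    co <- read.table(coo, header = TRUE, sep = "\t")
    if (!all(c("barcode", "x", "y") %in% colnames(co))) {
      stop("coords.tsv needs columns barcode, x, y", call. = FALSE)
    }
    pos <- match(cells, co$barcode)
    if (anyNA(pos)) stop("coords.tsv missing barcodes: ",
                         paste(head(cells[is.na(pos)], 3), collapse = ", "), call. = FALSE)
    spatial_dataset(t(as.matrix(m)), as.matrix(co[pos, c("x", "y")]),
                    gene_names = as.character(genes))
  }
}

#' Write a spatial dataset to disk
#'
#' Inverse of [read_dataset()] for both supported layouts.
#'
#' @param dataset a `spatial_dataset`.
#' @param path output file (csv) or directory (mtx_dir; created).
#' @param format one of `"csv"`, `"mtx_dir"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("csv", "mtx_dir")) {
  format <- match.arg(format)
  stopifnot(is(dataset, "spatial_dataset"))
  if (format == "csv") {
    tab <- data.frame(x = dataset$coords[, 1], y = dataset$coords[, 2],
                      check.names = FALSE)
    tab <- cbind(tab, as.data.frame(dataset$counts, check.names = FALSE))
    write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- as(as(Matrix::Matrix(t(dataset$counts), sparse = TRUE), "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(dataset$gene_names, file.path(path, "features.tsv"))
    barcodes <- paste0("cell", dataset$cell_index)
    writeLines(barcodes, file.path(path, "barcodes.tsv"))
    co <- data.frame(barcode = barcodes, x = dataset$coords[, 1], y = dataset$coords[, 2])
    write.table(co, file.path(path, "coords.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Construct a candidate regulator-target pair list
#'
#' @param regulator,target character vectors of gene identifiers.
#' @param pair_type `"tf_target"` or `"ligand_receptor"`, recycled.
#' @return A `candidate_pairs` data frame with columns `regulator`, `target`,
#'   `pair_type`, deduplicated.
#' @export
candidate_pairs <- function(regulator, target, pair_type = "tf_target") {
  stopifnot(length(regulator) == length(target))
  pair_type <- as.character(rep_len(pair_type, length(regulator)))
  bad <- setdiff(unique(pair_type), c("tf_target", "ligand_receptor"))
  if (length(bad)) stop("unknown pair_type: ", paste(bad, collapse = ", "), call. = FALSE)
  df <- data.frame(regulator = as.character(regulator),
                   target = as.character(target),
                   pair_type = pair_type, stringsAsFactors = FALSE)
  dup <- duplicated(df)
  if (any(dup)) {
    warning(sum(dup), " duplicate pair(s) removed", call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("candidate_pairs", "data.frame")
  df
}

#' Read a candidate pair list from a delimited file
#'
#' Expects two or three tab- or comma-separated columns: regulator, target,
#' and optionally a pair type (`tf_target` or `ligand_receptor`); the type
#' defaults to `tf_target`. A header row is detected and skipped when the
#' first line contains the word "regulator".
#'
#' @param path delimited file.
#' @param default_type type to assign when the file has no third column.
#' @return A `candidate_pairs` data frame.
#' @export
read_pairs <- function(path, default_type = "tf_target") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty pair file: ", path, call. = FALSE)
  header <- grepl("regulator", tolower(lines[1]))
  if (header) lines <- lines[-1]
  if (length(lines) == 0L) stop("pair file has a header but no rows: ", path, call. = FALSE)
  split_one <- function(ln) strsplit(ln, "[\t,]")[[1]]
  fields <- lapply(lines, split_one)
  ncols <- vapply(fields, length, 1L)
  if (any(ncols < 2L)) stop("pair file rows need at least 2 columns", call. = FALSE)
  reg <- vapply(fields, `[[`, "", 1L)
  tgt <- vapply(fields, `[[`, "", 2L)
  typ <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else default_type, "")
  candidate_pairs(trimws(reg), trimws(tgt), trimws(typ))
}

#' Resolve candidate pairs against a dataset's gene names
#'
#' Pairs naming genes absent from the dataset are dropped with a message
#' giving the dropped count.
#'
#' @param pairs a `candidate_pairs` table.
#' @param dataset a `spatial_dataset`.
#' @return The resolved `candidate_pairs` subset (possibly smaller).
#' @export
resolve_pairs <- function(pairs, dataset) {
  stopifnot(is(dataset, "spatial_dataset"))
  ok <- pairs$regulator %in% dataset$gene_names & pairs$target %in% dataset$gene_names
  if (!any(ok)) stop("no candidate pair resolves against the dataset's gene names", call. = FALSE)
  if (any(!ok)) {
    log_msg("dropped ", sum(!ok), " candidate pair(s) naming genes absent from the dataset")
  }
  out <- pairs[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize expression for autoregressive modelling
#'
#' The default scheme (`log_cpm_z`) computes counts-per-ten-thousand on the
#' per-cell total UMIs, applies `log1p`, and standardizes each gene across
#' cells to zero mean and unit variance (population convention, dividing by
#' the root mean squared deviation, so a two-cell non-constant gene scores
#' exactly -1/+1). Cells with zero total UMIs carry no
#' signal and are dropped (or raise, per `zero_umi`); genes that are constant
#' after transformation are kept as all-zero columns and flagged so candidate
#' pair indices stay stable.
#'
#' @param dataset a `spatial_dataset`.
#' @param scheme `"log_cpm_z"` or `"none"` (raw counts passed through).
#' @param zero_umi `"drop"` (default) or `"error"` for zero-UMI cells.
#' @return An object of class `normalized_expression`: list with `values`
#'   (N' x G matrix), `scheme`, `kept_cells` (row indices into the input
#'   dataset), `constant_genes` (logical per gene), `gene_names`.
#' @export
normalize_expression <- function(dataset, scheme = c("log_cpm_z", "none"),
                                 zero_umi = c("drop", "error")) {
  scheme <- match.arg(scheme)
  zero_umi <- match.arg(zero_umi)
  stopifnot(is(dataset, "spatial_dataset"))
  keep <- which(dataset$umi_totals > 0)
  if (length(keep) < nrow(dataset$counts)) {
    n_zero <- nrow(dataset$counts) - length(keep)
    if (zero_umi == "error") stop(n_zero, " cell(s) with zero total UMIs", call. = FALSE)
    log_msg("dropped ", n_zero, " zero-UMI cell(s)")
  }
  cnt <- dataset$counts[keep, , drop = FALSE]
  u <- dataset$umi_totals[keep]
  if (scheme == "none") {
    vals <- cnt
    const <- apply(vals, 2L, function(v) max(v) == min(v))
  } else {
    vals <- log1p(1e4 * cnt / u)
    mu <- colMeans(vals)
    sdv <- sqrt(colMeans(sweep(vals, 2L, mu, "-")^2))
    const <- sdv < 1e-12
    vals <- sweep(vals, 2L, mu, "-")
    sdv[const] <- 1
    vals <- sweep(vals, 2L, sdv, "/")
    vals[, const] <- 0
    if (any(const)) {
      log_msg(sum(const), " constant gene(s) after normalization set to zero and flagged")
    }
  }
  structure(list(values = vals, scheme = scheme, kept_cells = keep,
                 constant_genes = const, gene_names = dataset$gene_names),
            class = "normalized_expression")
}

#' Construct an interaction table
#'
#' The method's output: one row per scored (regulator, target) pair and
#' direction, with the estimated graph lag and a free-text context label
#' (e.g. a tissue layer or boundary name). Rows are kept sorted by descending
#' score, then lexicographically by regulator and target, so serialization is
#' byte-stable.
#'
#' @param regulator,target,pair_type,direction,score,lag,context column
#'   vectors (recycled where scalar). `direction` is `"forward"` or
#'   `"backward"`; `score` is a nonnegative ensemble group-norm; `lag` is an
#'   integer in `[0, L]`, zero exactly when the score is zero.
#' @return An `interaction_table` data frame.
#' @export
interaction_table <- function(regulator = character(), target = character(),
                              pair_type = character(), direction = character(),
                              score = numeric(), lag = integer(),
                              context = character()) {
  n <- length(regulator)
  df <- data.frame(regulator = as.character(regulator),
                   target = as.character(target),
                   pair_type = as.character(rep_len(pair_type %||% "tf_target", n)),
                   direction = as.character(rep_len(direction %||% "forward", n)),
                   score = as.numeric(score),
                   lag = as.integer(lag),
                   context = as.character(rep_len(context %||% "", n)),
                   stringsAsFactors = FALSE)
  if (n > 0) {
    if (any(df$score < 0)) stop("interaction scores must be nonnegative", call. = FALSE)
    zero_mismatch <- xor(df$score <= 1e-12, df$lag == 0L)
    if (any(zero_mismatch)) {
      stop("lag must be 0 exactly when the score is 0", call. = FALSE)
    }
    df <- df[order(-df$score, df$regulator, df$target, df$direction), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Write an interaction table as TSV
#'
#' Columns: regulator, target, pair_type, direction, score, lag, context.
#' Rows are ordered by descending score with a lexicographic tiebreak, so the
#' file is byte-stable for a fixed table. Optional metadata lines are written
#' as leading `#` comments.
#'
#' @param table an `interaction_table`.
#' @param path output file.
#' @param comments optional character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_interactions <- function(table, path, comments = NULL) {
  stopifnot(is.data.frame(table))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  cols <- c("regulator", "target", "pair_type", "direction", "score", "lag", "context")
  tab <- as.data.frame(table)[, cols, drop = FALSE]
  if (nrow(tab) > 0) {
    tab <- tab[order(-tab$score, tab$regulator, tab$target, tab$direction), , drop = FALSE]
    tab$score <- vapply(tab$score, function(s) format(s, digits = 15, scientific = FALSE,
                                                      trim = TRUE), "")
  }
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(tab) > 0) {
    writeLines(do.call(paste, c(unname(as.list(tab)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read an interaction table written by [write_interactions()]
#'
#' @param path TSV file.
#' @return An `interaction_table`.
#' @export
read_interactions <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE,
                    colClasses = c(regulator = "character", target = "character",
                                   pair_type = "character", direction = "character",
                                   score = "numeric", lag = "integer",
                                   context = "character"))
  tab$context[is.na(tab$context)] <- ""
  interaction_table(tab$regulator, tab$target, tab$pair_type, tab$direction,
                    tab$score, tab$lag, tab$context)
}
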