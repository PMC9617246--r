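#' @importFrom methods as is
#' @importFrom stats cor rnbinom rpois rbinom rexp runif rnorm
NULL

#' Construct an expression dataset
#'
#' A light container for single-cell expression data: a sparse genes-by-cells
#' count matrix plus per-cell metadata, following the Bioconductor
#' convention of genes in rows. Log-normalized values are added by
#' [log_normalize()] and stored alongside the counts.
#'
#' @param counts Non-negative genes-by-cells matrix (coerced to
#'   `dgCMatrix`); rownames are gene symbols, colnames are cell barcodes.
#' @param meta Per-cell `data.frame` with a `barcode` column matching
#'   `colnames(counts)`; typically also `donor`, `group`, `cluster`.
#' @return A list of class `expr_dataset` with elements `counts`, `meta`,
#'   and `logcounts` (NULL until normalized).
#' @export
expr_dataset <- function(counts, meta) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and cell colnames", call. = FALSE)
  }
  if (any(counts@x < 0)) stop("negative counts", call. = FALSE)
  stopifnot(is.data.frame(meta), "barcode" %in% names(meta))
  if (!setequal(meta$barcode, colnames(counts))) {
    stop("metadata barcodes do not match count matrix columns", call. = FALSE)
  }
  meta <- meta[match(colnames(counts), meta$barcode), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta, logcounts = NULL),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("expr_dataset: %d genes x %d cells (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$logcounts)) "raw counts" else "log-normalized"))
  invisible(x)
}

#' Cell-level quality control
#'
#' Retains cells with at least `min_genes` detected genes (nonzero counts)
#' and a mitochondrial count fraction of at most `max_mito`. Mitochondrial
#' genes are identified by symbol prefix (human convention `MT-`).
#' Idempotent.
#'
#' @param x An `expr_dataset` of raw counts.
#' @param min_genes Minimum detected genes per cell (default 500).
#' @param max_mito Maximum mitochondrial fraction (default 0.10).
#' @param mito_pattern Regex identifying mitochondrial gene symbols.
#' @return The filtered `expr_dataset`; per-cell `n_genes` and `pct_mito`
#'   are added to the metadata.
#' @export
filter_cells_qc <- function(x, min_genes = 500L, max_mito = 0.10,
                            mito_pattern = "^MT-") {
  stopifnot(inherits(x, "expr_dataset"))
  n_genes <- Matrix::colSums(x$counts > 0)
  totals <- Matrix::colSums(x$counts)
  mito <- grepl(mito_pattern, rownames(x$counts))
  mito_frac <- if (any(mito)) {
    Matrix::colSums(x$counts[mito, , drop = FALSE]) / pmax(totals, 1)
  } else rep(0, ncol(x$counts))
  keep <- n_genes >= min_genes & mito_frac <= max_mito
  x$meta$n_genes <- as.integer(n_genes)
  x$meta$pct_mito <- as.numeric(mito_frac)
  x$counts <- x$counts[, keep, drop = FALSE]
  if (!is.null(x$logcounts)) x$logcounts <- x$logcounts[, keep, drop = FALSE]
  x$meta <- x$meta[keep, , drop = FALSE]
  rownames(x$meta) <- NULL
  x
}

#' Library-size log-normalization
#'
#' Scales each cell's counts by its total, multiplies by `scale` (default
#' 10,000) and applies `log(1 + x)`; the standard global-scaling
#' "LogNormalize".
#'
#' @param x An `expr_dataset` of raw counts.
#' @param scale Scale factor (default 1e4).
#' @return The dataset with `logcounts` populated.
#' @export
log_normalize <- function(x, scale = 1e4) {
  stopifnot(inherits(x, "expr_dataset"))
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0)) {
    stop("zero-total cell(s) present; run filter_cells_qc first",
         call. = FALSE)
  }
  lc <- x$counts
  lc@x <- log1p(lc@x / rep.int(totals, diff(lc@p)) * scale)
  x$logcounts <- lc
  x
}

with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Expression-bin-controlled gene module score
#'
#' Scores a gene program per cell as the mean log-normalized expression of
#' the program genes minus the mean of bin-matched control genes, the
#' procedure popularized by Seurat's `AddModuleScore`. All genes are sorted
#' canonically (by symbol) and binned into `n_bins` of equal size by their
#' average expression across cells; for each program gene, `n_ctrl` control
#' genes are sampled with replacement from its bin under the given seed.
#'
#' @param x A log-normalized `expr_dataset`.
#' @param program A character vector of gene symbols (or a `gene_set`).
#'   Program genes absent from the matrix are dropped with a warning.
#' @param n_bins Number of expression bins (default 25).
#' @param n_ctrl Control genes sampled per program gene (default 50).
#' @param seed Integer seed controlling control-gene sampling.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(x, program, n_bins = 25L, n_ctrl = 50L, seed = 1L) {
  stopifnot(inherits(x, "expr_dataset"))
  if (is.null(x$logcounts)) stop("run log_normalize first", call. = FALSE)
  if (inherits(program, "gene_set")) program <- program$genes
  genes <- sort(rownames(x$logcounts))
  present <- intersect(program, genes)
  if (length(present) == 0) {
    stop("no program genes present in the matrix", call. = FALSE)
  }
  if (length(present) < length(unique(program))) {
    warning(length(unique(program)) - length(present),
            " program gene(s) absent from the matrix dropped", call. = FALSE)
  }
  lc <- x$logcounts[genes, , drop = FALSE]
  avg <- Matrix::rowMeans(lc)
  n_bins <- min(n_bins, length(genes))
  # equal-occupancy bins by average expression; ties broken by the
  # canonical (alphabetical) gene order for cross-run determinism
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / length(genes))
  names(bin) <- genes
  # program genes are excluded from control pools so a planted program
  # shift cannot leak into the control term
  ctrl <- with_local_seed(seed, {
    unlist(lapply(sort(present), function(g) {
      pool <- setdiff(genes[bin == bin[[g]]], present)
      if (length(pool) == 0) pool <- setdiff(genes, present)
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }))
  })
  prog_mean <- Matrix::colMeans(lc[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(lc[ctrl, , drop = FALSE])
  stats::setNames(as.numeric(prog_mean - ctrl_mean), colnames(lc))
}

#' Rank-based pathway signature score
#'
#' Per cell, ranks all `G` genes by log-normalized expression (average ranks
#' for ties) and scores the pathway as
#' `(mean rank of pathway genes - (G+1)/2) / G`: a signed, scale-free
#' statistic in `(-0.5, 0.5)` that is invariant under any per-cell monotone
#' transform of expression. Serves as a simplified per-cell pathway
#' activity score for metabolic gene sets (and per-sample enrichment when
#' columns are bulk samples).
#'
#' @param x A log-normalized `expr_dataset`.
#' @param pathway Character vector of gene symbols (or `gene_set`); missing
#'   genes dropped with a warning.
#' @return Named numeric vector of per-cell scores.
#' @export
rank_signature_score <- function(x, pathway) {
  stopifnot(inherits(x, "expr_dataset"))
  if (is.null(x$logcounts)) stop("run log_normalize first", call. = FALSE)
  if (inherits(pathway, "gene_set")) pathway <- pathway$genes
  present <- intersect(pathway, rownames(x$logcounts))
  if (length(present) == 0) stop("empty effective pathway", call. = FALSE)
  if (length(present) < length(unique(pathway))) {
    warning(length(unique(pathway)) - length(present),
            " pathway gene(s) absent from the matrix dropped", call. = FALSE)
  }
  rank_signature_scores(x, list(score = present))[, "score"]
}

#' Rank-based signature scores for many pathways at once
#'
#' Computes the per-cell gene rank matrix a single time and scores every
#' pathway against it; identical to calling [rank_signature_score()] per
#' pathway but far cheaper for pathway collections.
#'
#' @param x A log-normalized `expr_dataset`.
#' @param pathways Named list of gene symbol vectors (or `gene_set`s).
#' @return Cells-by-pathways numeric matrix.
#' @export
rank_signature_scores <- function(x, pathways) {
  stopifnot(inherits(x, "expr_dataset"))
  if (is.null(x$logcounts)) stop("run log_normalize first", call. = FALSE)
  m <- as.matrix(x$logcounts)
  g <- nrow(m)
  ranks <- apply(m, 2, rank, ties.method = "average")
  out <- vapply(pathways, function(pw) {
    if (inherits(pw, "gene_set")) pw <- pw$genes
    idx <- match(intersect(pw, rownames(m)), rownames(m))
    if (length(idx) == 0) stop("empty effective pathway", call. = FALSE)
    (colMeans(ranks[idx, , drop = FALSE]) - (g + 1) / 2) / g
  }, numeric(ncol(m)))
  rownames(out) <- colnames(m)
  out
}

#' Comprehensive metabolic score
#'
#' Selects the `top_k` pathways with the highest grand-mean score across all
#' cells and averages them per cell (fewer than `top_k` pathways: all are
#' used).
#'
#' @param scores Cells-by-pathways numeric matrix (e.g. columns of
#'   [rank_signature_score()] results).
#' @param top_k Number of top pathways to average (default 20).
#' @return List with `score` (named per-cell vector) and `pathways`
#'   (selected column names).
#' @export
comprehensive_metabolic_score <- function(scores, top_k = 20L) {
  scores <- as.matrix(scores)
  if (ncol(scores) == 0) stop("no pathway columns", call. = FALSE)
  grand <- colMeans(scores)
  sel <- names(sort(grand, decreasing = TRUE))[seq_len(min(top_k,
                                                           ncol(scores)))]
  list(score = rowMeans(scores[, sel, drop = FALSE]), pathways = sel)
}

#' Correlation between two per-donor score summaries
#'
#' Spearman rank correlation (average ranks on ties) between paired donor
#' means, plus both conventions for a reported R-squared: squared Pearson
#' on the paired means and the squared Spearman coefficient.
#'
#' @param scores_a,scores_b Paired numeric vectors (one value per donor,
#'   length >= 3).
#' @return List with `rho`, `r_squared` (Pearson squared), `rho_squared`.
#' @export
score_correlation <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b))
  if (length(scores_a) < 3) stop("need at least 3 paired donors",
                                 call. = FALSE)
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  rho <- stats::cor(scores_a, scores_b, method = "spearman")
  r <- stats::cor(scores_a, scores_b, method = "pearson")
  list(rho = rho, r_squared = r^2, rho_squared = rho^2)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path (tab-separated: name, description, genes...).
#' @return Named list of `gene_set` objects (`name`, `description`,
#'   `genes`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40),
                            call. = FALSE)
    structure(list(name = f[1], description = f[2],
                   genes = unique(f[-(1:2)])),
              class = "gene_set")
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of `gene_set` objects or plain character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    genes <- if (inherits(s, "gene_set")) s$genes else s
    desc <- if (inherits(s, "gene_set")) s$description else "na"
    paste(c(nm, desc, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 10x-style MTX directory
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`), and
#' `barcodes.tsv`, plus optionally `metadata.csv` with per-cell annotations.
#'
#' @param dir Directory containing the MTX trio.
#' @return An `expr_dataset` (metadata defaults to barcodes only).
#' @export
read_mtx_dataset <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("file not found: ", mtx, call. = FALSE)
  feat_path <- file.path(dir, "features.tsv")
  if (!file.exists(feat_path)) feat_path <- file.path(dir, "genes.tsv")
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- read.delim(feat_path, header = FALSE,
                         stringsAsFactors = FALSE)
  barcodes <- read.delim(file.path(dir, "barcodes.tsv"), header = FALSE,
                         stringsAsFactors = FALSE)
  rownames(counts) <- features[[1]]
  colnames(counts) <- barcodes[[1]]
  meta_path <- file.path(dir, "metadata.csv")
  meta <- if (file.exists(meta_path)) {
    read.csv(meta_path, stringsAsFactors = FALSE)
  } else data.frame(barcode = colnames(counts), stringsAsFactors = FALSE)
  expr_dataset(counts, meta)
}

#' Write an expression dataset as an MTX trio
#'
#' @param x An `expr_dataset`.
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`, `metadata.csv`.
#' @return `dir`, invisibly.
#' @export
write_mtx_dataset <- function(x, dir) {
  stopifnot(inherits(x, "expr_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  write.csv(x$meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}
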