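#' Clone frequency table for a stratum
#'
#' Tabulates cells per clone within a stratum (a donor, group, cluster, or
#' any cell subset) from a clone assignment, yielding the frequency vector
#' underlying the diversity and clonality statistics.
#'
#' @param assignment A `clone_assignment`.
#' @param cells Optional character vector of barcodes restricting the
#'   stratum; default uses all assigned cells.
#' @return Named integer vector of cell counts per clone (names are clone
#'   identifiers). All counts are positive.
#' @export
clone_counts <- function(assignment, cells = NULL) {
  stopifnot(inherits(assignment, "clone_assignment"))
  tab <- assignment$cells
  if (!is.null(cells)) tab <- tab[tab$barcode %in% cells, , drop = FALSE]
  if (nrow(tab) == 0) return(integer(0))
  counts <- table(tab$clone_id)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

as_clone_probs <- function(counts) {
  if (length(counts) == 0) stop("empty clone frequency table", call. = FALSE)
  if (any(counts <= 0)) stop("clone counts must be positive", call. = FALSE)
  counts / sum(counts)
}

#' Shannon entropy of a clone repertoire
#'
#' `H = -sum(p_i * log2(p_i))` over clone frequencies `p_i`, in bits.
#'
#' @param counts Positive clone cell counts (named or not), e.g. from
#'   [clone_counts()]; frequencies are computed internally.
#' @return Entropy in bits; `0 <= H <= log2(N)` for `N` clones.
#' @export
shannon_entropy <- function(counts) {
  p <- as_clone_probs(counts)
  -sum(p * log2(p))
}

#' Repertoire clonality
#'
#' One minus the entropy normalized by its maximum over the number of unique
#' clones: `1 - H / log2(N)`. Zero for a perfectly even repertoire, one for
#' a monoclonal one. The single-clone repertoire (`N = 1`, where the
#' normalization is 0/0) is defined as maximally clonal and returns 1.
#'
#' @inheritParams shannon_entropy
#' @return Clonality in `[0, 1]`.
#' @export
clonality <- function(counts) {
  p <- as_clone_probs(counts)
  n <- length(p)
  if (n == 1L) return(1.0)
  1 - shannon_entropy(counts) / log2(n)
}

#' Jaccard index of two clonotype sets
#'
#' `|A intersect B| / |A union B|` over clonotype identifiers (duplicates
#' ignored). For expanded-clonotype sharing, pass only clones of size > 1.
#'
#' @param a,b Character vectors of clonotype identifiers.
#' @return A fraction in `[0, 1]`. Both sets empty is undefined and errors.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stop("Jaccard index undefined: both sets empty", call. = FALSE)
  length(intersect(a, b)) / u
}

#' Aggregate frequency of the n most abundant clones
#'
#' Sum of the `n` largest clone frequencies; if the repertoire has fewer
#' than `n` clones the result is 1.
#'
#' @inheritParams shannon_entropy
#' @param n Number of top clones (default 20).
#' @return A fraction in `(0, 1]`.
#' @export
top_n_frequency <- function(counts, n = 20L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  p <- as_clone_probs(counts)
  sum(sort(p, decreasing = TRUE)[seq_len(min(n, length(p)))])
}

#' Group-preference ratio of observed to expected cell counts
#'
#' For a clusters-by-groups contingency table of cell counts, the expected
#' count under independence is `row_total * col_total / grand_total`, and
#' `R_O/E` is the elementwise ratio observed/expected. `R > 1` marks
#' enrichment of a cluster in a group. Rows or columns with zero totals have
#' undefined ratios and are reported as `NA` with a warning.
#'
#' @param observed Non-negative integer matrix, clusters in rows, groups in
#'   columns (dimnames recommended).
#' @return A list of class `roe_matrix` with `observed`, `expected`, and
#'   `roe` matrices.
#' @export
roe <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0)) stop("counts must be non-negative", call. = FALSE)
  rt <- rowSums(observed)
  ct <- colSums(observed)
  grand <- sum(observed)
  if (grand == 0) stop("empty contingency table", call. = FALSE)
  expected <- outer(rt, ct) / grand
  r <- observed / expected
  if (any(rt == 0) || any(ct == 0)) {
    warning("zero row/column totals: R_O/E undefined there (NA)",
            call. = FALSE)
    r[rt == 0, ] <- NA_real_
    r[, ct == 0] <- NA_real_
  }
  structure(list(observed = observed, expected = expected, roe = r),
            class = "roe_matrix")
}

#' @export
print.roe_matrix <- function(x, ...) {
  cat("R_O/E (observed / expected cell counts):\n")
  print(round(x$roe, 3))
  invisible(x)
}

#' Pairwise clonal transition index between two clusters
#'
#' Quantifies state transition between clusters `i` and `j` through shared
#' clonotypes. Each clone is restricted to its cells in the two clusters;
#' with counts `n_ki`, `n_kj` and `m_k = n_ki + n_kj`, the per-clone binary
#' entropy `H_k = -sum(q * log2(q))` over `q = (n_ki/m_k, n_kj/m_k)` is 1
#' when the clone is split evenly and 0 when confined to one cluster. The
#' index is the cell-weighted mean `sum_k (m_k / sum m) * H_k`, already in
#' `[0, 1]` since `log2(2) = 1`.
#'
#' @param assignment A `clone_assignment`.
#' @param cluster_labels Named character vector mapping barcode to cluster.
#' @param i,j Distinct cluster labels.
#' @return List of class `transition_index`: `cluster_i`, `cluster_j`,
#'   `ptran`, and `n_clones` contributing (clones with cells in i or j).
#' @export
pairwise_transition_index <- function(assignment, cluster_labels, i, j) {
  stopifnot(inherits(assignment, "clone_assignment"), i != j)
  cl <- cluster_labels[assignment$cells$barcode]
  in_ij <- !is.na(cl) & cl %in% c(i, j)
  if (!any(in_ij)) {
    stop("no cells in cluster '", i, "' or '", j, "'", call. = FALSE)
  }
  sub <- assignment$cells[in_ij, , drop = FALSE]
  cl <- cl[in_ij]
  n_i <- tapply(cl == i, sub$clone_id, sum)
  n_j <- tapply(cl == j, sub$clone_id, sum)
  m <- n_i + n_j
  q_i <- n_i / m
  q_j <- n_j / m
  h <- -(ifelse(q_i > 0, q_i * log2(q_i), 0) +
           ifelse(q_j > 0, q_j * log2(q_j), 0))
  ptran <- sum(m / sum(m) * h)
  structure(list(cluster_i = i, cluster_j = j, ptran = unname(ptran),
                 n_clones = length(m)),
            class = "transition_index")
}

#' @export
print.transition_index <- function(x, ...) {
  cat(sprintf("pTran(%s, %s) = %.4f over %d clones\n",
              x$cluster_i, x$cluster_j, x$ptran, x$n_clones))
  invisible(x)
}

#' Full pairwise transition-index matrix
#'
#' @inheritParams pairwise_transition_index
#' @param clusters Cluster labels to include; default all observed.
#' @return Symmetric matrix of pTran values (`NA` on the diagonal and for
#'   pairs with no cells).
#' @export
transition_matrix <- function(assignment, cluster_labels, clusters = NULL) {
  if (is.null(clusters)) clusters <- sort(unique(unname(cluster_labels)))
  k <- length(clusters)
  out <- matrix(NA_real_, k, k, dimnames = list(clusters, clusters))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      val <- tryCatch(
        pairwise_transition_index(assignment, cluster_labels,
                                  clusters[a], clusters[b])$ptran,
        error = function(e) NA_real_)
      out[a, b] <- out[b, a] <- val
    }
  }
  out
}

#' V-gene usage frequencies per group
#'
#' @param v_calls Character vector of V gene/allele calls (alleles are
#'   stripped).
#' @param groups Group label per element of `v_calls`.
#' @return Matrix of counts, genes in rows, groups in columns.
#' @export
vgene_usage <- function(v_calls, groups) {
  stopifnot(length(v_calls) == length(groups))
  as.matrix(table(strip_allele(v_calls), groups))
}

#' Log2 fold change of V-gene usage between two groups
#'
#' Per gene, a pseudocount-regularized log2 ratio of usage proportions:
#' `log2(((c_a + s) / (T_a + s*K)) / ((c_b + s) / (T_b + s*K)))` with gene
#' counts `c`, group totals `T`, pseudocount `s`, and `K` genes. The
#' pseudocount keeps the ratio finite for genes absent in one group.
#'
#' @param usage Gene-by-group count matrix from [vgene_usage()].
#' @param group_a,group_b Column names to compare (log2FC > 0 means higher
#'   usage in `group_a`).
#' @param pseudocount Additive regularizer (default 0.5).
#' @return Named numeric vector of log2 fold changes per gene.
#' @export
vgene_log2fc <- function(usage, group_a, group_b, pseudocount = 0.5) {
  stopifnot(is.matrix(usage))
  if (!all(c(group_a, group_b) %in% colnames(usage))) {
    stop("group not present in usage matrix", call. = FALSE)
  }
  ca <- usage[, group_a]
  cb <- usage[, group_b]
  ta <- sum(ca)
  tb <- sum(cb)
  if (ta == 0 || tb == 0) stop("empty group", call. = FALSE)
  k <- nrow(usage)
  fa <- (ca + pseudocount) / (ta + pseudocount * k)
  fb <- (cb + pseudocount) / (tb + pseudocount * k)
  log2(fa / fb)
}

#' Per-stratum repertoire metrics table
#'
#' Convenience wrapper computing cells, unique clones, Shannon entropy,
#' clonality, and top-n clone frequency for each stratum of a cell grouping.
#'
#' @param assignment A `clone_assignment`.
#' @param strata Named character vector mapping barcode to stratum label
#'   (donor, group, cluster, ...).
#' @param top_n `n` for [top_n_frequency()] (default 20).
#' @return A `data.frame`, one row per stratum.
#' @export
repertoire_metrics <- function(assignment, strata, top_n = 20L) {
  stopifnot(inherits(assignment, "clone_assignment"))
  labs <- strata[assignment$cells$barcode]
  keep <- !is.na(labs)
  by_stratum <- split(assignment$cells$barcode[keep], labs[keep])
  rows <- lapply(names(by_stratum), function(s) {
    counts <- clone_counts(assignment, by_stratum[[s]])
    data.frame(stratum = s,
               n_cells = sum(counts),
               n_clones = length(counts),
               entropy_bits = shannon_entropy(counts),
               clonality = clonality(counts),
               top_n_freq = top_n_frequency(counts, top_n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
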