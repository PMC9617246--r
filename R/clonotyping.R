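#' Normalized Hamming distance between junction sequences
#'
#' Fraction of mismatching positions between two equal-length nucleotide
#' junction strings; comparison is case-insensitive. Used with a strict
#' `< 0.1` cutoff for B-cell clonal grouping.
#'
#' @param junction_a,junction_b Nucleotide strings of equal, positive length.
#' @return A fraction in `[0, 1]`.
#' @export
normalized_hamming <- function(junction_a, junction_b) {
  if (is.na(junction_a) || is.na(junction_b)) stop("NA junction")
  la <- nchar(junction_a)
  if (la != nchar(junction_b)) {
    stop("junctions have unequal lengths (", la, " vs ", nchar(junction_b),
         "); Hamming distance is only defined within a V/J/length partition",
         call. = FALSE)
  }
  if (la == 0L) stop("zero-length junction", call. = FALSE)
  a <- strsplit(toupper(junction_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(junction_b), "", fixed = TRUE)[[1]]
  sum(a != b) / la
}

#' Strip allele suffix from a V/J gene call
#'
#' `"IGHV4-34*01"` becomes `"IGHV4-34"`; clonal grouping partitions at the
#' gene level.
#'
#' @param call Character vector of gene/allele calls.
#' @return Character vector of gene-level names.
#' @export
strip_allele <- function(call) sub("\\*.*$", "", call)

# pairwise normalized Hamming distance matrix for equal-length junctions
junction_distance_matrix <- function(junctions) {
  n <- length(junctions)
  m <- do.call(rbind, strsplit(toupper(junctions), "", fixed = TRUE))
  d <- matrix(0, n, n)
  len <- ncol(m)
  for (i in seq_len(n - 1)) {
    di <- rowSums(m[(i + 1):n, , drop = FALSE] !=
                    matrix(m[i, ], n - i, len, byrow = TRUE)) / len
    d[i, (i + 1):n] <- di
    d[(i + 1):n, i] <- di
  }
  d
}

# connected components of an adjacency matrix, numbered by first member
# in input order (deterministic clone indices)
adjacency_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  next_id <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    next_id <- next_id + 1L
    queue <- s
    comp[s] <- next_id
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- next_id
      queue <- c(queue, nb)
    }
  }
  comp
}

new_clone_assignment <- function(receptor, barcode, clone_id) {
  cells <- data.frame(barcode = barcode, clone_id = clone_id,
                      stringsAsFactors = FALSE)
  sizes <- table(factor(clone_id, levels = unique(clone_id)))
  clones <- data.frame(clone_id = names(sizes),
                       size = as.integer(sizes),
                       stringsAsFactors = FALSE)
  structure(list(receptor = receptor, cells = cells, clones = clones),
            class = "clone_assignment")
}

#' @export
print.clone_assignment <- function(x, ...) {
  cat(sprintf("%s clone assignment: %d cells in %d clones (%d expanded)\n",
              x$receptor, nrow(x$cells), nrow(x$clones),
              sum(x$clones$size > 1)))
  invisible(x)
}

#' Group B cells into clones
#'
#' Implements the standard two-stage BCR clonal grouping: cells are first
#' partitioned by heavy-chain V gene, J gene (allele suffixes stripped) and
#' junction length; within each partition, cells whose junctions differ by a
#' normalized Hamming distance strictly below `threshold` are linked, and
#' clones are the connected components of that graph (single linkage).
#'
#' Clone identifiers are deterministic: the partition key plus a component
#' index ordered by each component's first cell in input order.
#'
#' @param cells Paired-cell table from [pair_chains()] with `receptor ==
#'   "BCR"`; the heavy chain occupies the `*_1` columns.
#' @param threshold Strict upper bound on normalized junction Hamming
#'   distance for two cells to be linked (default 0.1; distance exactly
#'   equal to the threshold does not link).
#' @return A `clone_assignment`: list with `receptor`, `cells` (barcode,
#'   clone_id) and `clones` (clone_id, size).
#' @export
group_bcr_clones <- function(cells, threshold = 0.1) {
  stopifnot(is.data.frame(cells))
  ok <- !is.na(cells$junction_1) & nzchar(cells$junction_1)
  if (any(!ok)) {
    warning(sum(!ok), " cell(s) without heavy-chain junction excluded from ",
            "clonal grouping", call. = FALSE)
    cells <- cells[ok, , drop = FALSE]
  }
  if (nrow(cells) == 0) {
    return(new_clone_assignment("BCR", character(0), character(0)))
  }
  key <- paste(strip_allele(cells$v_call_1), strip_allele(cells$j_call_1),
               nchar(cells$junction_1), sep = "|")
  clone_id <- character(nrow(cells))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) == 1L) {
      comp <- 1L
    } else {
      d <- junction_distance_matrix(cells$junction_1[idx])
      adj <- d < threshold
      comp <- adjacency_components(adj)
    }
    clone_id[idx] <- paste0(gsub("|", "_", k, fixed = TRUE), "_c", comp)
  }
  new_clone_assignment("BCR", cells$barcode, clone_id)
}

#' Call TCR clonotypes by exact paired-chain identity
#'
#' Two T cells share a clonotype if and only if both the alpha-chain
#' (V gene, J gene, nucleotide junction) and the beta-chain triple are
#' identical; allele suffixes are stripped. Clonotype identifiers are
#' assigned by first appearance.
#'
#' @param cells Paired-cell table from [pair_chains()] with `receptor ==
#'   "TCR"` (TRA in `*_1`, TRB in `*_2`).
#' @return A `clone_assignment`.
#' @export
call_tcr_clonotypes <- function(cells) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) == 0) {
    return(new_clone_assignment("TCR", character(0), character(0)))
  }
  key <- paste(strip_allele(cells$v_call_1), strip_allele(cells$j_call_1),
               toupper(cells$junction_1),
               strip_allele(cells$v_call_2), strip_allele(cells$j_call_2),
               toupper(cells$junction_2), sep = "|")
  idx <- match(key, unique(key))
  new_clone_assignment("TCR", cells$barcode, sprintf("TCR_c%d", idx))
}

#' Annotate clonal expansion levels
#'
#' Bins clone sizes into display levels (1 = "unique", 2 = "double", 3-5 =
#' "small", 6-20 = "medium", >20 = "large") and flags clones with more than
#' one cell as expanded. Only the expanded/unexpanded boundary (size > 1) is
#' analysis-relevant; the finer bins are a plotting convention and all
#' statistics remain computable from the raw sizes.
#'
#' @param assignment A `clone_assignment`.
#' @return The assignment with `expansion_level` (ordered factor) and
#'   `expanded` columns added to both `clones` and `cells`.
#' @export
assign_expansion_level <- function(assignment) {
  stopifnot(inherits(assignment, "clone_assignment"))
  levels_ <- c("unique", "double", "small", "medium", "large")
  size <- assignment$clones$size
  lab <- cut(size, breaks = c(0, 1, 2, 5, 20, Inf), labels = levels_)
  assignment$clones$expansion_level <- factor(as.character(lab),
                                              levels = levels_,
                                              ordered = TRUE)
  assignment$clones$expanded <- size > 1L
  m <- match(assignment$cells$clone_id, assignment$clones$clone_id)
  assignment$cells$expansion_level <- assignment$clones$expansion_level[m]
  assignment$cells$expanded <- assignment$clones$expanded[m]
  assignment
}

#' Write a clone table
#'
#' @param assignment A `clone_assignment` (ideally after
#'   [assign_expansion_level()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(assignment, path) {
  stopifnot(inherits(assignment, "clone_assignment"))
  members <- vapply(split(assignment$cells$barcode, assignment$cells$clone_id),
                    paste, character(1), collapse = ",")
  tab <- assignment$clones
  tab$receptor <- assignment$receptor
  tab$members <- members[tab$clone_id]
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
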