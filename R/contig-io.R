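#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

CONTIG_LOCI <- c("IGH", "IGK", "IGL", "TRA", "TRB")
BCR_LOCI <- c("IGH", "IGK", "IGL")
TCR_LOCI <- c("TRA", "TRB")

# canonical internal column order for a contig table
CONTIG_COLUMNS <- c(
  "barcode", "contig_id", "locus", "v_call", "j_call", "c_call",
  "junction_nt", "junction_aa", "umis", "reads", "productive",
  "high_confidence", "sequence_alignment", "germline_alignment"
)

parse_contig_logical <- function(x, column, rows_offset = 0L) {
  x_chr <- trimws(as.character(x))
  out <- rep(NA, length(x_chr))
  out[x_chr %in% c("True", "TRUE", "true", "T", "t", "1")] <- TRUE
  out[x_chr %in% c("False", "FALSE", "false", "F", "f", "0")] <- FALSE
  out[x_chr %in% c("", "NA", "None")] <- NA
  bad <- which(is.na(out) & !x_chr %in% c("", "NA", "None"))
  if (length(bad) > 0) {
    stop(sprintf("unparseable boolean in column '%s' at row %d: '%s'",
                 column, bad[1] + rows_offset, x_chr[bad[1]]), call. = FALSE)
  }
  as.logical(out)
}

parse_contig_integer <- function(x, column) {
  suppressWarnings(out <- as.integer(x))
  bad <- which(is.na(out) & !is.na(x) & trimws(as.character(x)) != "")
  if (length(bad) > 0) {
    stop(sprintf("unparseable integer in column '%s' at row %d: '%s'",
                 column, bad[1], x[bad[1]]), call. = FALSE)
  }
  out
}

#' Read single-cell V(D)J contig annotations
#'
#' Reads a 10x `filtered_contig_annotations.csv`-style table or an AIRR
#' Rearrangement TSV into the canonical contig table used by all downstream
#' repertoire operations. One row per assembled contig (chain) per cell.
#'
#' The 10x dialect maps `barcode/chain/v_gene/j_gene/c_gene/cdr3_nt/cdr3/
#' umis/reads/productive/high_confidence` onto the canonical fields; the AIRR
#' dialect maps `cell_id/locus/v_call/j_call/c_call/junction/junction_aa/
#' duplicate_count/consensus_count/productive` plus optional IMGT-gapped
#' `sequence_alignment`/`germline_alignment` columns used for somatic
#' hypermutation analysis. AIRR has no standard high-confidence flag: when the
#' column is absent every contig is marked high-confidence (10x pre-filters
#' on the flag upstream of AIRR export).
#'
#' @param path Path to the contig table.
#' @param dialect `"10x-contig-csv"` or `"airr-tsv"`.
#' @return A `data.frame` with columns `barcode`, `contig_id`, `locus`,
#'   `v_call`, `j_call`, `c_call`, `junction_nt`, `junction_aa`, `umis`,
#'   `reads`, `productive`, `high_confidence`, `sequence_alignment`,
#'   `germline_alignment`. Missing optional source columns yield `NA` fields.
#' @seealso [filter_contigs()], [pair_chains()], [write_contigs()]
#' @export
read_contigs <- function(path, dialect = c("10x-contig-csv", "airr-tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "10x-contig-csv") {
    raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    required <- c("barcode", "chain", "v_gene", "j_gene", "umis",
                  "productive", "high_confidence")
    mapping <- c(barcode = "barcode", contig_id = "contig_id",
                 locus = "chain", v_call = "v_gene", j_call = "j_gene",
                 c_call = "c_gene", junction_nt = "cdr3_nt",
                 junction_aa = "cdr3", umis = "umis", reads = "reads")
    if (!("cdr3_nt" %in% names(raw)) && !("cdr3" %in% names(raw))) {
      stop("missing required column: cdr3 or cdr3_nt", call. = FALSE)
    }
  } else {
    raw <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character", sep = "\t")
    required <- c("cell_id", "locus", "v_call", "j_call", "junction",
                  "duplicate_count", "productive")
    mapping <- c(barcode = "cell_id", contig_id = "sequence_id",
                 locus = "locus", v_call = "v_call", j_call = "j_call",
                 c_call = "c_call", junction_nt = "junction",
                 junction_aa = "junction_aa", umis = "duplicate_count",
                 reads = "consensus_count",
                 sequence_alignment = "sequence_alignment",
                 germline_alignment = "germline_alignment")
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(raw)
  pick <- function(field) {
    src <- if (field %in% names(mapping)) mapping[[field]] else NA_character_
    if (!is.na(src) && src %in% names(raw)) raw[[src]]
    else rep(NA_character_, n)
  }
  out <- data.frame(
    barcode = pick("barcode"),
    contig_id = pick("contig_id"),
    locus = pick("locus"),
    v_call = pick("v_call"),
    j_call = pick("j_call"),
    c_call = pick("c_call"),
    junction_nt = pick("junction_nt"),
    junction_aa = pick("junction_aa"),
    umis = parse_contig_integer(pick("umis"), "umis"),
    reads = parse_contig_integer(pick("reads"), "reads"),
    productive = parse_contig_logical(raw[[if (dialect == "10x-contig-csv")
      "productive" else "productive"]], "productive"),
    high_confidence = if ("high_confidence" %in% names(raw)) {
      parse_contig_logical(raw[["high_confidence"]], "high_confidence")
    } else rep(TRUE, n),
    sequence_alignment = pick("sequence_alignment"),
    germline_alignment = pick("germline_alignment"),
    stringsAsFactors = FALSE
  )
  if (n == 0) out <- out[0, , drop = FALSE]
  validate_contigs(out)
  out
}

#' Validate a canonical contig table
#'
#' Checks the structural invariants of a contig table: known loci,
#' non-negative UMI counts, nt/aa junction length consistency (3:1), and
#' equal-length IMGT-gapped observed/germline alignments when both present.
#'
#' @param contigs A contig `data.frame` as returned by [read_contigs()].
#' @return The input, invisibly; errors describe the first violation.
#' @export
validate_contigs <- function(contigs) {
  stopifnot(is.data.frame(contigs))
  missing_cols <- setdiff(CONTIG_COLUMNS, names(contigs))
  if (length(missing_cols) > 0) {
    stop("contig table missing column: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(contigs) == 0) return(invisible(contigs))
  bad_locus <- !is.na(contigs$locus) & !(contigs$locus %in% CONTIG_LOCI)
  if (any(bad_locus)) {
    stop("invalid locus at row ", which(bad_locus)[1], ": '",
         contigs$locus[which(bad_locus)[1]], "'", call. = FALSE)
  }
  if (any(!is.na(contigs$umis) & contigs$umis < 0)) {
    stop("negative umis at row ",
         which(!is.na(contigs$umis) & contigs$umis < 0)[1], call. = FALSE)
  }
  both_junc <- !is.na(contigs$junction_nt) & !is.na(contigs$junction_aa) &
    nzchar(contigs$junction_nt) & nzchar(contigs$junction_aa)
  bad_len <- both_junc &
    nchar(contigs$junction_nt) != 3L * nchar(contigs$junction_aa)
  if (any(bad_len)) {
    stop("junction nt/aa length mismatch at row ", which(bad_len)[1],
         call. = FALSE)
  }
  both_aln <- !is.na(contigs$sequence_alignment) &
    !is.na(contigs$germline_alignment)
  bad_aln <- both_aln & nchar(contigs$sequence_alignment) !=
    nchar(contigs$germline_alignment)
  if (any(bad_aln)) {
    stop("observed/germline alignment length mismatch at row ",
         which(bad_aln)[1], call. = FALSE)
  }
  invisible(contigs)
}

#' Write a contig table in a supported dialect
#'
#' Inverse of [read_contigs()]: writes the canonical contig table as either a
#' 10x-style contig annotation CSV or an AIRR Rearrangement TSV so that
#' reading the file back round-trips all required fields.
#'
#' @param contigs Canonical contig `data.frame`.
#' @param path Output file path.
#' @param dialect `"10x-contig-csv"` or `"airr-tsv"`.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path,
                          dialect = c("10x-contig-csv", "airr-tsv")) {
  dialect <- match.arg(dialect)
  validate_contigs(contigs)
  fmt_bool <- function(x, style) {
    ifelse(is.na(x), "", if (style == "10x") ifelse(x, "True", "False")
           else ifelse(x, "T", "F"))
  }
  if (dialect == "10x-contig-csv") {
    out <- data.frame(
      barcode = contigs$barcode,
      is_cell = "True",
      contig_id = contigs$contig_id,
      high_confidence = fmt_bool(contigs$high_confidence, "10x"),
      chain = contigs$locus,
      v_gene = contigs$v_call,
      d_gene = "",
      j_gene = contigs$j_call,
      c_gene = ifelse(is.na(contigs$c_call), "", contigs$c_call),
      full_length = "True",
      productive = fmt_bool(contigs$productive, "10x"),
      cdr3 = ifelse(is.na(contigs$junction_aa), "", contigs$junction_aa),
      cdr3_nt = ifelse(is.na(contigs$junction_nt), "", contigs$junction_nt),
      reads = ifelse(is.na(contigs$reads), "", contigs$reads),
      umis = contigs$umis,
      stringsAsFactors = FALSE
    )
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    out <- data.frame(
      sequence_id = contigs$contig_id,
      cell_id = contigs$barcode,
      locus = contigs$locus,
      v_call = contigs$v_call,
      j_call = contigs$j_call,
      c_call = ifelse(is.na(contigs$c_call), "", contigs$c_call),
      junction = ifelse(is.na(contigs$junction_nt), "", contigs$junction_nt),
      junction_aa = ifelse(is.na(contigs$junction_aa), "",
                           contigs$junction_aa),
      duplicate_count = contigs$umis,
      consensus_count = ifelse(is.na(contigs$reads), "", contigs$reads),
      productive = fmt_bool(contigs$productive, "airr"),
      high_confidence = fmt_bool(contigs$high_confidence, "airr"),
      sequence_alignment = ifelse(is.na(contigs$sequence_alignment), "",
                                  contigs$sequence_alignment),
      germline_alignment = ifelse(is.na(contigs$germline_alignment), "",
                                  contigs$germline_alignment),
      stringsAsFactors = FALSE
    )
    write.table(out, path, row.names = FALSE, quote = FALSE, sep = "\t")
  }
  invisible(path)
}

#' Quality-filter contigs
#'
#' Removes contigs flagged low-confidence, non-productive, or supported by
#' fewer than `min_umis` UMIs. The confidence and productivity requirements
#' are unconditional; only the UMI floor is tunable. Input row order is
#' preserved and the operation is idempotent.
#'
#' @param contigs Canonical contig `data.frame`.
#' @param min_umis Minimum UMI count to retain a contig (default 2).
#' @return The retained rows, with a `"qc_summary"` attribute counting
#'   contigs failing each rule (a contig may fail several).
#' @export
filter_contigs <- function(contigs, min_umis = 2L) {
  validate_contigs(contigs)
  hc <- !is.na(contigs$high_confidence) & contigs$high_confidence
  prod <- !is.na(contigs$productive) & contigs$productive
  umi_ok <- !is.na(contigs$umis) & contigs$umis >= min_umis
  keep <- hc & prod & umi_ok
  out <- contigs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_summary") <- data.frame(
    rule = c("low_confidence", "non_productive",
             sprintf("umis_lt_%d", as.integer(min_umis)), "total_removed"),
    n_removed = c(sum(!hc), sum(!prod), sum(!umi_ok), sum(!keep))
  )
  out
}

#' Pair receptor chains per cell
#'
#' Groups QC-passing contigs by cell barcode and retains cells with exactly
#' the canonical chain complement: for BCR one IGH and exactly one light
#' chain (IGK or IGL); for TCR one TRA and one TRB. All other barcodes
#' (unpaired, multi-chain, or ambiguous) are dropped. Barcodes bearing both
#' B- and T-cell loci are treated as doublets and dropped with a warning.
#'
#' @param contigs Filtered canonical contig `data.frame`.
#' @param receptor `"BCR"` or `"TCR"`.
#' @return A `data.frame` with one row per retained cell and columns
#'   `barcode`, `receptor`, plus `*_1` fields for the primary chain
#'   (IGH or TRA) and `*_2` fields for the secondary chain (light or TRB):
#'   locus, v_call, j_call, c_call, junction, junction_aa, and (chain 1 only)
#'   sequence/germline alignments. Output order follows first appearance of
#'   each barcode in the input so downstream clone identifiers are stable.
#' @export
pair_chains <- function(contigs, receptor = c("BCR", "TCR")) {
  receptor <- match.arg(receptor)
  validate_contigs(contigs)
  own_loci <- if (receptor == "BCR") BCR_LOCI else TCR_LOCI
  other_loci <- if (receptor == "BCR") TCR_LOCI else BCR_LOCI
  contigs <- contigs[!is.na(contigs$locus), , drop = FALSE]
  barcodes <- unique(contigs$barcode)  # first-appearance order
  mixed <- vapply(split(contigs$locus, contigs$barcode)[barcodes],
                  function(l) any(l %in% own_loci) && any(l %in% other_loci),
                  logical(1))
  if (any(mixed)) {
    warning(sum(mixed), " barcode(s) with mixed BCR/TCR loci dropped as ",
            "doublets", call. = FALSE)
  }
  rows <- lapply(barcodes[!mixed], function(bc) {
    cc <- contigs[contigs$barcode == bc & contigs$locus %in% own_loci, ,
                  drop = FALSE]
    if (receptor == "BCR") {
      c1 <- cc[cc$locus == "IGH", , drop = FALSE]
      c2 <- cc[cc$locus %in% c("IGK", "IGL"), , drop = FALSE]
    } else {
      c1 <- cc[cc$locus == "TRA", , drop = FALSE]
      c2 <- cc[cc$locus == "TRB", , drop = FALSE]
    }
    if (nrow(c1) != 1L || nrow(c2) != 1L || nrow(cc) != 2L) return(NULL)
    data.frame(
      barcode = bc, receptor = receptor,
      locus_1 = c1$locus, v_call_1 = c1$v_call, j_call_1 = c1$j_call,
      c_call_1 = c1$c_call, junction_1 = c1$junction_nt,
      junction_aa_1 = c1$junction_aa,
      sequence_alignment_1 = c1$sequence_alignment,
      germline_alignment_1 = c1$germline_alignment,
      locus_2 = c2$locus, v_call_2 = c2$v_call, j_call_2 = c2$j_call,
      c_call_2 = c2$c_call, junction_2 = c2$junction_nt,
      junction_aa_2 = c2$junction_aa,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(barcode = character(0), receptor = character(0))
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}

#' Write a contig QC summary
#'
#' @param filtered Output of [filter_contigs()] (carries the
#'   `"qc_summary"` attribute).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_summary <- function(filtered, path) {
  qc <- attr(filtered, "qc_summary")
  if (is.null(qc)) stop("no qc_summary attribute; run filter_contigs first")
  write.table(qc, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
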