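#' @importFrom stats qbeta
NULL

# IMGT unique-numbering region boundaries on the V segment, in nt.
# CDR3/junction (nt > 312) is excluded: germline is undefined there.
IMGT_REGIONS <- data.frame(
  region = c("FWR1", "CDR1", "FWR2", "CDR2", "FWR3"),
  start = c(1L, 79L, 115L, 166L, 196L),
  end = c(78L, 114L, 165L, 195L, 312L),
  stringsAsFactors = FALSE
)

#' IMGT V-region boundaries used for SHM analysis
#'
#' Fixed nucleotide spans of FWR1, CDR1, FWR2, CDR2 and FWR3 under IMGT
#' unique numbering (nt 1-312; the junction/CDR3 is excluded from all SHM
#' and selection statistics because no germline is defined there).
#'
#' @return A `data.frame` with columns `region`, `start`, `end`.
#' @export
imgt_regions <- function() IMGT_REGIONS

imgt_region_of <- function(pos) {
  out <- rep(NA_character_, length(pos))
  for (r in seq_len(nrow(IMGT_REGIONS))) {
    hit <- pos >= IMGT_REGIONS$start[r] & pos <= IMGT_REGIONS$end[r]
    out[hit] <- IMGT_REGIONS$region[r]
  }
  out
}

codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- stats::setNames(as.character(gc), names(gc))
    }
    tab
  }
})

translate_codon <- function(codon) {
  aa <- codon_table()[toupper(codon)]
  ifelse(is.na(aa), NA_character_, aa)
}

# precomputed classification of every single-nucleotide codon variant:
# names are "<codon><pos><base>", values "R"/"S"
substitution_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      aa <- codon_table()
      nt <- c("A", "C", "G", "T")
      keys <- character(0)
      vals <- character(0)
      for (codon in names(aa)) {
        chars <- strsplit(codon, "", fixed = TRUE)[[1]]
        for (p in 1:3) {
          for (b in setdiff(nt, chars[p])) {
            mut <- chars
            mut[p] <- b
            mut_aa <- aa[[paste(mut, collapse = "")]]
            keys <- c(keys, paste0(codon, p, b))
            vals <- c(vals, if (mut_aa != aa[[codon]] || mut_aa == "*")
              "R" else "S")
          }
        }
      }
      tab <<- stats::setNames(vals, keys)
    }
    tab
  }
})

# classify a single observed substitution within its germline codon:
# substitute the observed base at codon_pos (1..3) into the germline codon
# alone; "R" if the amino acid changes or a stop appears, "S" otherwise.
classify_substitution <- function(germ_codon, codon_pos, obs_base) {
  cls <- substitution_table()[paste0(toupper(germ_codon), codon_pos,
                                     toupper(obs_base))]
  unname(cls)
}

#' Count replacement and silent mutations against germline
#'
#' Compares an IMGT-gapped observed sequence against its equally gapped
#' germline over nt 1-312. Positions where both characters are unambiguous
#' nucleotides (A/C/G/T) are informative; each informative mismatch is
#' classified one-change-at-a-time by substituting the observed base into
#' the germline codon at that position alone: replacement (R) if the amino
#' acid changes or a stop is created, silent (S) otherwise. Codons whose
#' germline copy contains gaps or ambiguous bases leave their mismatches
#' unclassified (counted as mismatches but neither R nor S).
#'
#' @param observed,germline Equal-length IMGT-gapped nucleotide strings
#'   (IMGT gap character `.` or `-`).
#' @return A list of class `mutation_profile`: `regions` data.frame (region,
#'   informative, mismatches, r, s) and totals `informative`, `mismatches`,
#'   `r`, `s`.
#' @export
count_mutations <- function(observed, germline) {
  if (is.na(observed) || is.na(germline)) stop("NA alignment", call. = FALSE)
  if (nchar(observed) != nchar(germline)) {
    stop("observed and germline alignments have different lengths",
         call. = FALSE)
  }
  len <- min(nchar(observed), 312L)
  obs <- strsplit(toupper(substr(observed, 1, len)), "", fixed = TRUE)[[1]]
  germ <- strsplit(toupper(substr(germline, 1, len)), "", fixed = TRUE)[[1]]
  nt <- c("A", "C", "G", "T")
  informative <- obs %in% nt & germ %in% nt
  mismatch <- informative & obs != germ
  pos <- seq_len(len)
  region <- imgt_region_of(pos)

  cls <- rep(NA_character_, len)
  for (p in which(mismatch)) {
    codon_start <- 3L * ((p - 1L) %/% 3L) + 1L
    if (codon_start + 2L > len) next
    germ_codon <- paste(germ[codon_start:(codon_start + 2L)], collapse = "")
    if (!all(strsplit(germ_codon, "", fixed = TRUE)[[1]] %in% nt)) next
    cls[p] <- classify_substitution(germ_codon, p - codon_start + 1L, obs[p])
  }

  reg_levels <- IMGT_REGIONS$region
  regf <- factor(region, levels = reg_levels)
  regions <- data.frame(
    region = reg_levels,
    informative = as.integer(tapply(informative, regf, sum, default = 0L)),
    mismatches = as.integer(tapply(mismatch, regf, sum, default = 0L)),
    r = as.integer(tapply(!is.na(cls) & cls == "R", regf, sum, default = 0L)),
    s = as.integer(tapply(!is.na(cls) & cls == "S", regf, sum, default = 0L)),
    stringsAsFactors = FALSE
  )
  structure(list(regions = regions,
                 informative = sum(regions$informative),
                 mismatches = sum(regions$mismatches),
                 r = sum(regions$r), s = sum(regions$s)),
            class = "mutation_profile")
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf("mutation profile: %d mismatches (%d R / %d S) over %d informative nt\n",
              x$mismatches, x$r, x$s, x$informative))
  print(x$regions)
  invisible(x)
}

#' Somatic hypermutation frequency
#'
#' Total mismatches divided by informative positions over the IMGT V region
#' (FWR1 through FWR3, nt 1-312; junction excluded).
#'
#' @param profile A `mutation_profile` from [count_mutations()].
#' @return Mutation frequency per informative nucleotide.
#' @export
shm_frequency <- function(profile) {
  stopifnot(inherits(profile, "mutation_profile"))
  if (profile$informative == 0) {
    stop("SHM frequency undefined: no informative positions", call. = FALSE)
  }
  profile$mismatches / profile$informative
}

#' Expected replacement fraction under no selection
#'
#' Enumerates all nine single-nucleotide variants of each germline codon in
#' the chosen region and returns the fraction that change the amino acid or
#' create a stop, under uniform weighting. This is the neutral baseline
#' `p_exp` against which the observed replacement fraction is compared by
#' [selection_sigma()]. Codons containing gaps or ambiguous bases are
#' skipped.
#'
#' @param germline IMGT-gapped (or plain, in-frame) germline nucleotide
#'   string. With `region = NULL` the whole string is treated as in-frame
#'   codons; with `"CDR"` or `"FWR"` the corresponding IMGT regions
#'   (CDR1+CDR2 or FWR1+FWR2+FWR3) are extracted first.
#' @param region `NULL`, `"CDR"` or `"FWR"`.
#' @return `p_exp` in `[0, 1]`, with attributes `n_variants` and
#'   `n_replacement`.
#' @export
expected_replacement_fraction <- function(germline, region = NULL) {
  seq_nt <- toupper(germline)
  if (!is.null(region)) {
    region <- match.arg(region, c("CDR", "FWR"))
    spans <- if (region == "CDR") c("CDR1", "CDR2")
             else c("FWR1", "FWR2", "FWR3")
    chars <- strsplit(seq_nt, "", fixed = TRUE)[[1]]
    pos <- which(imgt_region_of(seq_along(chars)) %in% spans)
    seq_nt <- paste(chars[pos], collapse = "")
  }
  n_codons <- nchar(seq_nt) %/% 3L
  if (n_codons < 1) stop("region shorter than one codon", call. = FALSE)
  codons <- substring(seq_nt, 3 * seq_len(n_codons) - 2,
                      3 * seq_len(n_codons))
  tab <- substitution_table()
  nt <- c("A", "C", "G", "T")
  per_codon_r <- vapply(codons, function(codon) {
    chars <- strsplit(codon, "", fixed = TRUE)[[1]]
    if (!all(chars %in% nt)) return(NA_integer_)  # gap/ambiguous codon
    keys <- unlist(lapply(1:3, function(p) {
      paste0(codon, p, setdiff(nt, chars[p]))
    }))
    sum(tab[keys] == "R")
  }, integer(1), USE.NAMES = FALSE)
  valid <- !is.na(per_codon_r)
  if (!any(valid)) stop("no unambiguous codons in region", call. = FALSE)
  n_var <- 9L * sum(valid)
  n_rep <- sum(per_codon_r[valid])
  structure(n_rep / n_var, n_variants = n_var, n_replacement = n_rep)
}

#' Selection strength from replacement/silent mutation counts
#'
#' A signed selection statistic comparing the observed replacement fraction
#' `r/m` to the neutral expectation `p_exp`. The posterior over the true
#' replacement probability `p` under a uniform prior is `Beta(r+1, m-r+1)`;
#' the statistic is the posterior mean log2 odds minus the neutral log2
#' odds:
#' `sigma = (digamma(r+1) - digamma(m-r+1)) / ln(2) - log2(p_exp/(1-p_exp))`.
#' `sigma > 0` indicates positive selection for replacement mutations
#' (antigen-driven), `sigma < 0` negative selection. The credible interval
#' is the same monotone transform of posterior quantiles of `p`.
#'
#' Note this is a uniform-targeting simplification of full
#' BASELINe-style frameworks: it preserves the sign and ordering semantics
#' of selection strength but does not model SHM hot/cold-spot targeting.
#'
#' @param r Observed replacement mutation count.
#' @param m Total observed mutations in the region (`r <= m`, `m >= 1`;
#'   `m = 0` is undefined — no mutations carries no selection information —
#'   and errors, deliberately distinct from `sigma = 0`).
#' @param p_exp Neutral replacement fraction in `(0, 1)`, from
#'   [expected_replacement_fraction()].
#' @param conf Credible-interval mass (default 0.95).
#' @return A list of class `selection_result`: `r`, `m`, `p_exp`, `sigma`,
#'   `ci_low`, `ci_high`.
#' @export
selection_sigma <- function(r, m, p_exp, conf = 0.95) {
  if (m < 1) stop("selection strength undefined for m = 0 (no mutations)",
                  call. = FALSE)
  stopifnot(r >= 0, r <= m, p_exp > 0, p_exp < 1)
  log2_odds <- function(p) log2(p / (1 - p))
  sigma <- (digamma(r + 1) - digamma(m - r + 1)) / log(2) - log2_odds(p_exp)
  alpha <- (1 - conf) / 2
  q <- qbeta(c(alpha, 1 - alpha), r + 1, m - r + 1)
  structure(list(r = as.integer(r), m = as.integer(m), p_exp = p_exp,
                 sigma = sigma,
                 ci_low = log2_odds(q[1]) - log2_odds(p_exp),
                 ci_high = log2_odds(q[2]) - log2_odds(p_exp)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection strength: sigma = %.3f [%.3f, %.3f] (r=%d, m=%d, p_exp=%.3f)\n",
              x$sigma, x$ci_low, x$ci_high, x$r, x$m, x$p_exp))
  invisible(x)
}

#' Per-sequence SHM and selection analysis
#'
#' Runs [count_mutations()], [shm_frequency()], and region-class selection
#' strength (CDR = CDR1+CDR2, FWR = FWR1+FWR2+FWR3) for every row of a
#' contig table carrying IMGT-gapped `sequence_alignment` and
#' `germline_alignment` columns.
#'
#' @param contigs Canonical contig `data.frame` (typically heavy chains
#'   only) with both alignment columns present.
#' @return A `data.frame` with one row per analyzable sequence: `barcode`,
#'   `c_call`, `shm_freq`, per region class `r`, `m` (total classified
#'   mutations R+S), `p_exp`, `sigma` (NA when `m = 0`).
#' @export
analyze_shm <- function(contigs) {
  validate_contigs(contigs)
  ok <- !is.na(contigs$sequence_alignment) &
    !is.na(contigs$germline_alignment) &
    nzchar(contigs$sequence_alignment) & nzchar(contigs$germline_alignment)
  contigs <- contigs[ok, , drop = FALSE]
  # p_exp depends only on the germline; cache per distinct germline/region
  pexp_cache <- new.env(parent = emptyenv())
  cached_pexp <- function(germ, region_class) {
    key <- paste0(region_class, "|", germ)
    if (is.null(pexp_cache[[key]])) {
      pexp_cache[[key]] <- as.numeric(
        expected_replacement_fraction(germ, region_class))
    }
    pexp_cache[[key]]
  }
  rows <- lapply(seq_len(nrow(contigs)), function(k) {
    prof <- count_mutations(contigs$sequence_alignment[k],
                            contigs$germline_alignment[k])
    reg <- prof$regions
    cdr <- reg[reg$region %in% c("CDR1", "CDR2"), ]
    fwr <- reg[reg$region %in% c("FWR1", "FWR2", "FWR3"), ]
    sig_for <- function(sub, region_class) {
      r <- sum(sub$r)
      m <- sum(sub$r) + sum(sub$s)
      if (m == 0) return(c(r = r, m = m, sigma = NA_real_))
      p_exp <- cached_pexp(contigs$germline_alignment[k], region_class)
      c(r = r, m = m, sigma = selection_sigma(r, m, p_exp)$sigma)
    }
    cdr_stats <- sig_for(cdr, "CDR")
    fwr_stats <- sig_for(fwr, "FWR")
    data.frame(barcode = contigs$barcode[k], c_call = contigs$c_call[k],
               shm_freq = shm_frequency(prof),
               cdr_r = cdr_stats[["r"]], cdr_m = cdr_stats[["m"]],
               cdr_sigma = cdr_stats[["sigma"]],
               fwr_r = fwr_stats[["r"]], fwr_m = fwr_stats[["m"]],
               fwr_sigma = fwr_stats[["sigma"]],
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(barcode = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
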