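#' @importFrom stats rgeom
NULL

NT <- c("A", "C", "G", "T")

random_nt <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")

#' Synthetic germline V-segment pool
#'
#' Deterministically generates a small pool of SYNTHETIC germline V-segment
#' sequences (312 nt, IMGT V-region length, in frame, stop-free) with IMGT
#' region annotations, so somatic-hypermutation analysis is testable without
#' any reference download. The sequences are random in-frame DNA and carry
#' no biological meaning; names make the synthetic origin explicit.
#'
#' @param n Number of segments (default 8).
#' @param prefix Gene-name prefix, e.g. `"IGHV"`.
#' @param seed Internal seed for the pool (fixed default so the pool is a
#'   package constant).
#' @return Named character vector of 312-nt sequences, names like
#'   `"synIGHV1*01"`.
#' @export
synthetic_germline_pool <- function(n = 8L, prefix = "IGHV", seed = 20220914L) {
  with_local_seed(seed + nchar(prefix) * 1000L + n, {
    seqs <- vapply(seq_len(n), function(i) {
      repeat {
        s <- random_nt(312L)
        codons <- substring(s, seq(1, 310, 3), seq(3, 312, 3))
        if (!any(translate_codon(codons) == "*")) return(s)
      }
    }, character(1))
    names(seqs) <- sprintf("syn%s%d*01", prefix, seq_len(n))
    seqs
  })
}

mutate_sequence <- function(seq_nt, rate) {
  chars <- strsplit(seq_nt, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (p in hit) chars[p] <- sample(setdiff(NT, chars[p]), 1)
  paste(chars, collapse = "")
}

# clone-size sampler: "geometric" (prob) or truncated discrete "powerlaw"
# (exponent alpha, support 1..max_size)
sample_clone_sizes <- function(n_cells, dist = c("geometric", "powerlaw"),
                               prob = 0.8, alpha = 2.0, max_size = 100L) {
  dist <- match.arg(dist)
  sizes <- integer(0)
  while (sum(sizes) < n_cells) {
    s <- if (dist == "geometric") {
      1L + rgeom(1, prob)
    } else {
      k <- seq_len(max_size)
      sample(k, 1, prob = k^(-alpha))
    }
    sizes <- c(sizes, min(s, n_cells - sum(sizes)))
  }
  sizes
}

#' Simulation configuration
#'
#' Assembles the full stated world for the synthetic cohort. Defaults mirror
#' the cohort structure of a four-group dermatomyositis study (healthy
#' donors, disease controls, active and remitted patients) at desk scale:
#' active-patient repertoires draw clone sizes from a heavier-tailed
#' distribution (discrete power law, exponent 2.0) than the geometric
#' (p = 0.8) used elsewhere, giving the clonal expansion the analysis is
#' meant to detect.
#'
#' @param seed Mandatory integer seed; every downstream draw derives from
#'   it.
#' @param groups Named list of group settings; each entry is a list with
#'   `n_donors`, `cells_per_donor`, `clone_dist` ("geometric"/"powerlaw"),
#'   `geom_prob`, `pl_alpha`, `isg_shift` (log-scale planted shift of the
#'   interferon program).
#' @param receptor `"BCR"` or `"TCR"` for the repertoire part.
#' @param clone_mut_rate Per-site junction mutation rate within a BCR clone
#'   (default 0.02, well under half the 0.1 grouping threshold).
#' @param shm_rate Per-site V-region mutation rate for SHM simulation
#'   (default 0.03).
#' @param shm_r_odds_mult Multiplier on the replacement odds relative to
#'   neutral (1 = neutral targeting).
#' @param defect_rate Fraction of cells given a QC-failing contig defect
#'   (default 0.08).
#' @param junction_lengths Candidate heavy/beta junction lengths in nt
#'   (multiples of 3).
#' @param n_genes,n_mito Transcriptome size and mitochondrial gene count.
#' @param dispersion Negative-binomial gene-level dispersion (default 0.5).
#' @param qc_fail_rate Fraction of cells planted to fail expression QC.
#' @param n_pathways,pathway_size Metabolic pathway gene sets to plant.
#' @param pathway_coupling Fraction of each group's ISG shift applied to
#'   the first half of the planted pathways (default 0.5, giving the
#'   donor-level ISG/metabolic score correlation the analysis expects;
#'   0 plants the interferon program alone).
#' @param survival_n Number of patients for the survival generator; the
#'   default `NULL` emits one patient per configured donor.
#' @param hazard_low,hazard_ratio,censor_max Survival generator: baseline
#'   exponential hazard per day for the low-marker stratum, hazard ratio
#'   for the high stratum, and upper bound of uniform censoring times.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       groups = NULL,
                       receptor = "BCR",
                       clone_mut_rate = 0.02,
                       shm_rate = 0.03,
                       shm_r_odds_mult = 1.0,
                       defect_rate = 0.08,
                       junction_lengths = c(30L, 36L, 42L, 45L, 48L, 54L),
                       n_genes = 2000L,
                       n_mito = 10L,
                       dispersion = 0.5,
                       qc_fail_rate = 0.10,
                       n_pathways = 30L,
                       pathway_size = 10L,
                       pathway_coupling = 0.5,
                       survival_n = NULL,
                       hazard_low = log(2) / 730,
                       hazard_ratio = 3,
                       censor_max = 1095) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(groups)) {
    groups <- list(
      HD = list(n_donors = 4L, cells_per_donor = 100L,
                clone_dist = "geometric", geom_prob = 0.8, pl_alpha = 2.0,
                isg_shift = 0),
      CtrlIIM = list(n_donors = 5L, cells_per_donor = 100L,
                     clone_dist = "geometric", geom_prob = 0.8,
                     pl_alpha = 2.0, isg_shift = 0),
      Act = list(n_donors = 7L, cells_per_donor = 100L,
                 clone_dist = "powerlaw", geom_prob = 0.8, pl_alpha = 2.0,
                 isg_shift = 1.0),
      Rem = list(n_donors = 3L, cells_per_donor = 100L,
                 clone_dist = "geometric", geom_prob = 0.8, pl_alpha = 2.0,
                 isg_shift = 0)
    )
  }
  stopifnot(clone_mut_rate >= 0, clone_mut_rate <= 1,
            shm_rate >= 0, shm_rate <= 1, defect_rate >= 0, defect_rate < 1,
            qc_fail_rate >= 0, qc_fail_rate < 1)
  if (hazard_low <= 0 || hazard_ratio <= 0) {
    stop("hazards must be positive", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), groups = groups,
                 receptor = receptor, clone_mut_rate = clone_mut_rate,
                 shm_rate = shm_rate, shm_r_odds_mult = shm_r_odds_mult,
                 defect_rate = defect_rate,
                 junction_lengths = as.integer(junction_lengths),
                 n_genes = as.integer(n_genes), n_mito = as.integer(n_mito),
                 dispersion = dispersion, qc_fail_rate = qc_fail_rate,
                 n_pathways = as.integer(n_pathways),
                 pathway_size = as.integer(pathway_size),
                 pathway_coupling = pathway_coupling,
                 survival_n = survival_n,
                 hazard_low = hazard_low, hazard_ratio = hazard_ratio,
                 censor_max = censor_max),
            class = "sim_config")
}

# simulate SHM on a germline: per-site Binomial(rate) mutation count; each
# mutation is replacement with probability from the (possibly enriched)
# neutral odds; a concrete base of the required class is chosen at the site.
simulate_shm_sequence <- function(germline, rate, r_odds_mult,
                                  p_exp = NULL) {
  chars <- strsplit(germline, "", fixed = TRUE)[[1]]
  if (is.null(p_exp)) {
    p_exp <- as.numeric(expected_replacement_fraction(germline))
  }
  odds <- r_odds_mult * p_exp / (1 - p_exp)
  p_r <- odds / (1 + odds)
  hit <- which(runif(length(chars)) < rate)
  for (p in hit) {
    codon_start <- 3L * ((p - 1L) %/% 3L) + 1L
    codon <- chars[codon_start:(codon_start + 2L)]
    alts <- setdiff(NT, chars[p])
    cls <- vapply(alts, function(b) {
      classify_substitution(paste(codon, collapse = ""),
                            p - codon_start + 1L, b)
    }, character(1))
    want <- if (runif(1) < p_r) "R" else "S"
    pool <- alts[cls == want]
    if (length(pool) == 0) pool <- alts
    chars[p] <- if (length(pool) == 1) pool else sample(pool, 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a paired-chain immune repertoire
#'
#' Generates a ground-truthed contig table per the configuration: per donor,
#' clone sizes are drawn from the group's size distribution; each clone gets
#' heavy/alpha V and J genes from the synthetic pool and a random founder
#' junction; BCR member junctions mutate per site at `clone_mut_rate`
#' (TCR members share the founder exactly); a matching light/beta chain is
#' emitted per cell; heavy chains additionally carry IMGT-gapped
#' observed/germline alignments from SHM simulation. A `defect_rate`
#' fraction of cells receives one planted QC defect (low UMI, non-productive
#' flag, low confidence, extra heavy chain, or missing second chain).
#'
#' @param config A `sim_config`.
#' @return List of class `synthetic_repertoire`: `contigs` (canonical
#'   table), `truth` (barcode, donor, group, clone, defect), `config`.
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    bcr <- config$receptor == "BCR"
    heavy_locus <- if (bcr) "IGH" else "TRA"
    v_pool <- synthetic_germline_pool(8L, if (bcr) "IGHV" else "TRAV")
    v_pool_pexp <- vapply(v_pool, function(g) {
      as.numeric(expected_replacement_fraction(g))
    }, numeric(1))
    j_pool <- sprintf("syn%sJ%d*01", if (bcr) "IGH" else "TRA", 1:4)
    v2_pool <- sprintf("syn%sV%d*01", if (bcr) "IGK" else "TRB", 1:6)
    j2_pool <- sprintf("syn%sJ%d*01", if (bcr) "IGK" else "TRB", 1:3)
    isotypes <- c("IGHM", "IGHG1", "IGHG2", "IGHA1")

    acc <- list()  # flat per-contig field accumulators
    push <- function(...) acc[[length(acc) + 1L]] <<- list(...)
    truth_rows <- list()
    cell_n <- 0L
    for (g in names(config$groups)) {
      gs <- config$groups[[g]]
      for (d in seq_len(gs$n_donors)) {
        donor <- sprintf("%s_d%d", g, d)
        sizes <- sample_clone_sizes(gs$cells_per_donor, gs$clone_dist,
                                    gs$geom_prob, gs$pl_alpha)
        for (k in seq_along(sizes)) {
          v_idx <- sample(length(v_pool), 1)
          v_gene <- names(v_pool)[v_idx]
          j_gene <- sample(j_pool, 1)
          jlen <- sample(config$junction_lengths, 1)
          founder <- random_nt(jlen)
          light_v <- sample(v2_pool, 1)
          light_j <- sample(j2_pool, 1)
          light_junction <- random_nt(if (bcr) 27L else jlen)
          light_locus <- if (bcr) sample(c("IGK", "IGL"), 1) else "TRB"
          c_call <- if (bcr) sample(isotypes, 1) else NA_character_
          germ <- unname(v_pool[v_idx])
          clone_id <- sprintf("%s_clone%d", donor, k)
          for (cell in seq_len(sizes[k])) {
            cell_n <- cell_n + 1L
            bc <- sprintf("cell%05d-1", cell_n)
            junction <- if (bcr) {
              mutate_sequence(founder, config$clone_mut_rate)
            } else founder
            obs_aln <- if (bcr) {
              simulate_shm_sequence(germ, config$shm_rate,
                                    config$shm_r_odds_mult,
                                    v_pool_pexp[[v_idx]])
            } else NA_character_
            defect <- if (runif(1) < config$defect_rate) {
              sample(c("low_umi", "non_productive", "low_confidence",
                       "extra_heavy", "missing_light"), 1)
            } else "none"
            umis <- if (defect == "low_umi") 1L else 2L + stats::rpois(1, 4)
            push(bc, sprintf("%s_contig_1", bc), heavy_locus, v_gene,
                 j_gene, c_call, junction, umis, umis * 20L,
                 defect != "non_productive", defect != "low_confidence",
                 obs_aln, if (bcr) germ else NA_character_)
            if (defect != "missing_light") {
              push(bc, sprintf("%s_contig_2", bc), light_locus, light_v,
                   light_j, NA_character_, light_junction,
                   2L + stats::rpois(1, 3), 40L, TRUE, TRUE,
                   NA_character_, NA_character_)
            }
            if (defect == "extra_heavy") {
              push(bc, sprintf("%s_contig_3", bc), heavy_locus, v_gene,
                   j_gene, c_call, junction, umis, umis * 20L,
                   TRUE, TRUE, obs_aln, if (bcr) germ else NA_character_)
            }
            truth_rows[[length(truth_rows) + 1L]] <- data.frame(
              barcode = bc, donor = donor, group = g, clone = clone_id,
              defect = defect, stringsAsFactors = FALSE)
          }
        }
      }
    }
    col <- function(i, mode) {
      v <- vapply(acc, function(r) {
        x <- r[[i]]
        if (is.null(x) || length(x) == 0) NA else x
      }, vector(mode, 1))
      v
    }
    contigs <- data.frame(
      barcode = col(1, "character"), contig_id = col(2, "character"),
      locus = col(3, "character"), v_call = col(4, "character"),
      j_call = col(5, "character"), c_call = col(6, "character"),
      junction_nt = col(7, "character"), junction_aa = NA_character_,
      umis = col(8, "integer"), reads = col(9, "integer"),
      productive = col(10, "logical"), high_confidence = col(11, "logical"),
      sequence_alignment = col(12, "character"),
      germline_alignment = col(13, "character"), stringsAsFactors = FALSE)
    contigs <- contigs[, CONTIG_COLUMNS]
    rownames(contigs) <- NULL
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    validate_contigs(contigs)
    structure(list(contigs = contigs, truth = truth, config = config),
              class = "synthetic_repertoire")
  })
}

#' Simulate a single-cell expression matrix with a planted ISG program
#'
#' Draws negative-binomial counts with log-normal gene means for every cell
#' in the repertoire truth table (or a standalone cohort). The interferon
#' program genes are shifted on the log scale by each group's `isg_shift`
#' (their mean counts multiplied by `exp(shift)`); mitochondrial genes
#' (`MT-` prefix) contribute roughly 4 percent of counts in healthy cells;
#' a `qc_fail_rate` fraction of cells is planted to fail quality control,
#' half by depth collapse (detected genes below threshold) and half by
#' mitochondrial overload. Metabolic pathway gene sets are planted with a
#' group effect shared with the ISG program, giving the correlated
#' structure the score-correlation analysis expects.
#'
#' @param config A `sim_config`.
#' @param cells Optional `data.frame` with `barcode`, `donor`, `group`
#'   columns (e.g. the `truth` of [simulate_repertoire()]); defaults to a
#'   cohort built from the config's group sizes.
#' @return List of class `synthetic_expression`: `dataset`
#'   (an `expr_dataset`), `gene_sets` (named list: `ISG`, `Fibrosis`,
#'   pathway sets), `truth` (list with `qc_fail` barcodes + reason,
#'   `isg_genes`, `isg_shift` per group, `pathway_shift`), `config`.
#' @export
simulate_expression <- function(config, cells = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed + 1L, {
    if (is.null(cells)) {
      rows <- list()
      n <- 0L
      for (g in names(config$groups)) {
        gs <- config$groups[[g]]
        for (d in seq_len(gs$n_donors)) {
          bc <- sprintf("cell%05d-1", n + seq_len(gs$cells_per_donor))
          n <- n + gs$cells_per_donor
          rows[[length(rows) + 1L]] <- data.frame(
            barcode = bc, donor = sprintf("%s_d%d", g, d), group = g,
            stringsAsFactors = FALSE)
        }
      }
      cells <- do.call(rbind, rows)
    }
    n_cells <- nrow(cells)
    g_tot <- config$n_genes
    n_mito <- config$n_mito
    gene_names <- c(sprintf("MT-G%d", seq_len(n_mito)),
                    sprintf("GENE%04d", seq_len(g_tot - n_mito)))
    n_isg <- 15L
    isg_genes <- sprintf("ISG%02d", seq_len(n_isg))
    gene_names[n_mito + seq_len(n_isg)] <- isg_genes
    fib_genes <- sprintf("FIB%02d", seq_len(10L))
    gene_names[n_mito + n_isg + seq_len(10L)] <- fib_genes

    mu <- exp(rnorm(g_tot, -0.5, 1))
    names(mu) <- gene_names
    # high-expressed programs so a log-scale shift of the mean transfers
    # near-linearly to the log-normalized values
    mu[isg_genes] <- exp(rnorm(n_isg, 3.0, 0.2))
    mu[fib_genes] <- exp(rnorm(10L, 2.5, 0.2))
    mito_idx <- seq_len(n_mito)
    mu[mito_idx] <- sum(mu[-mito_idx]) * 0.04 / n_mito

    # planted metabolic pathways over high-expressed non-program genes;
    # the first half share the ISG group effect (at half amplitude)
    pool <- setdiff(gene_names[-(seq_len(n_mito + n_isg + 10L))], isg_genes)
    mu[pool[seq_len(config$n_pathways * config$pathway_size)]] <-
      exp(rnorm(config$n_pathways * config$pathway_size, 2.0, 0.3))
    pathways <- lapply(seq_len(config$n_pathways), function(k) {
      pool[(k - 1) * config$pathway_size + seq_len(config$pathway_size)]
    })
    names(pathways) <- sprintf("PATHWAY_%02d", seq_len(config$n_pathways))
    co_planted <- if (config$pathway_coupling > 0) {
      names(pathways)[seq_len(config$n_pathways %/% 2)]
    } else character(0)

    qc_fail_n <- round(config$qc_fail_rate * n_cells)
    qc_fail_idx <- sample(n_cells, qc_fail_n)
    qc_reason <- sample(c("low_genes", "high_mito"), qc_fail_n,
                        replace = TRUE)

    size_inv <- 1 / config$dispersion  # NB size parameter
    counts <- matrix(0L, g_tot, n_cells,
                     dimnames = list(gene_names, cells$barcode))
    shift_by_group <- vapply(config$groups, function(gs) gs$isg_shift,
                             numeric(1))
    for (j in seq_len(n_cells)) {
      mu_j <- mu
      sh <- if (cells$group[j] %in% names(shift_by_group)) {
        shift_by_group[[cells$group[j]]]
      } else 0
      if (sh != 0) {
        mu_j[isg_genes] <- mu_j[isg_genes] * exp(sh)
        for (pw in co_planted) {
          mu_j[pathways[[pw]]] <-
            mu_j[pathways[[pw]]] * exp(sh * config$pathway_coupling)
        }
      }
      fail <- match(j, qc_fail_idx)
      if (!is.na(fail)) {
        if (qc_reason[fail] == "low_genes") {
          mu_j <- mu_j * 0.05
        } else {
          mu_j[mito_idx] <- mu_j[mito_idx] * 12
        }
      }
      counts[, j] <- rnbinom(g_tot, size = size_inv, mu = mu_j)
    }
    dataset <- expr_dataset(Matrix::Matrix(counts, sparse = TRUE), cells)
    gene_sets <- c(
      list(ISG = structure(list(name = "ISG",
                                description = "synthetic interferon program",
                                genes = isg_genes), class = "gene_set"),
           Fibrosis = structure(list(name = "Fibrosis",
                                     description = "synthetic fibrosis program",
                                     genes = fib_genes), class = "gene_set")),
      lapply(names(pathways), function(nm) {
        structure(list(name = nm, description = "synthetic metabolic pathway",
                       genes = pathways[[nm]]), class = "gene_set")
      })
    )
    names(gene_sets) <- c("ISG", "Fibrosis", names(pathways))
    structure(list(
      dataset = dataset, gene_sets = gene_sets,
      truth = list(qc_fail = data.frame(barcode = cells$barcode[qc_fail_idx],
                                        reason = qc_reason,
                                        stringsAsFactors = FALSE),
                   isg_genes = isg_genes,
                   isg_shift = shift_by_group,
                   co_planted_pathways = co_planted),
      config = config), class = "synthetic_expression")
  })
}

#' Simulate a survival cohort stratified by a baseline marker
#'
#' Event times are exponential with hazard `hazard_low` for patients at or
#' below the marker median and `hazard_low * hazard_ratio` above it;
#' censoring times are uniform on `(0, censor_max)` and the observed time is
#' the minimum of the two.
#'
#' @param config A `sim_config`.
#' @param marker Optional per-patient marker values (default: one patient
#'   per configured donor, marker = standard normal shifted by +2 in groups
#'   with a planted ISG shift, mimicking a disease-activity biomarker).
#' @return A `data.frame`: `id`, `time_days`, `event`, `marker`, `group`,
#'   `true_stratum`.
#' @export
simulate_survival <- function(config, marker = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed + 2L, {
    if (is.null(marker)) {
      if (!is.null(config$survival_n)) {
        n <- as.integer(config$survival_n)
        groups <- rep(c("low_activity", "high_activity"),
                      length.out = n)
        marker <- rnorm(n) + ifelse(groups == "high_activity", 2, 0)
      } else {
        groups <- rep(names(config$groups),
                      vapply(config$groups, `[[`, numeric(1), "n_donors"))
        shift <- vapply(config$groups[groups], function(gs) {
          if (gs$isg_shift > 0) 2 else 0
        }, numeric(1))
        marker <- rnorm(length(groups)) + shift
      }
    } else {
      groups <- rep(NA_character_, length(marker))
    }
    n <- length(marker)
    high <- marker > stats::median(marker)
    hazard <- ifelse(high, config$hazard_low * config$hazard_ratio,
                     config$hazard_low)
    t_event <- rexp(n, hazard)
    t_censor <- runif(n, 0, config$censor_max)
    data.frame(id = sprintf("pt%03d", seq_len(n)),
               time_days = pmin(t_event, t_censor),
               event = t_event <= t_censor,
               marker = marker, group = groups,
               true_stratum = ifelse(high, "high", "low"),
               stringsAsFactors = FALSE)
  })
}

#' Write a full synthetic dataset to disk
#'
#' Emits every standard format the pipeline consumes: the contig table in
#' both dialects, the MTX expression trio with metadata, the survival CSV,
#' demo GMT gene sets, and a ground-truth JSON sufficient to score clone
#' and program recovery.
#'
#' @param config A `sim_config`.
#' @param dir Output directory.
#' @return Invisible list of the generated in-memory objects (`repertoire`,
#'   `expression`, `survival`) plus `paths`.
#' @export
write_synthetic_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- simulate_repertoire(config)
  expr <- simulate_expression(config, rep$truth[, c("barcode", "donor",
                                                    "group")])
  surv <- simulate_survival(config)
  paths <- list(
    contigs_10x = file.path(dir, "filtered_contig_annotations.csv"),
    contigs_airr = file.path(dir, "airr_rearrangement.tsv"),
    expression = file.path(dir, "expression"),
    survival = file.path(dir, "survival.csv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_contigs(rep$contigs, paths$contigs_10x, "10x-contig-csv")
  write_contigs(rep$contigs, paths$contigs_airr, "airr-tsv")
  write_mtx_dataset(expr$dataset, paths$expression)
  write.csv(surv, paths$survival, row.names = FALSE)
  write_gmt(expr$gene_sets, paths$gene_sets)
  jsonlite::write_json(list(
    seed = config$seed,
    clone_truth = rep$truth,
    qc_fail = expr$truth$qc_fail,
    isg_genes = expr$truth$isg_genes,
    isg_shift = as.list(expr$truth$isg_shift),
    hazard_ratio = config$hazard_ratio
  ), paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(repertoire = rep, expression = expr, survival = surv,
                 paths = paths))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1
#' means identical partitions (up to relabeling). Used to score recovery of
#' planted clone memberships against ground truth.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) > 0)
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1.0)
  (sum_ij - expected) / (max_index - expected)
}
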