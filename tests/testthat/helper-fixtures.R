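# shared fixtures and independent oracles for the test suite

# minimal canonical contig row; override any field via ...
make_contig <- function(barcode = "AAACCTG-1", contig_id = paste0(barcode, "_c1"),
                        locus = "IGH", v_call = "IGHV1-1*01",
                        j_call = "IGHJ4*01", c_call = "IGHG1",
                        junction_nt = "TGTGCGAGAGATTTTGACTACTGG",
                        junction_aa = NA_character_,
                        umis = 5L, reads = 100L, productive = TRUE,
                        high_confidence = TRUE,
                        sequence_alignment = NA_character_,
                        germline_alignment = NA_character_) {
  data.frame(barcode = barcode, contig_id = contig_id, locus = locus,
             v_call = v_call, j_call = j_call, c_call = c_call,
             junction_nt = junction_nt, junction_aa = junction_aa,
             umis = umis, reads = reads, productive = productive,
             high_confidence = high_confidence,
             sequence_alignment = sequence_alignment,
             germline_alignment = germline_alignment,
             stringsAsFactors = FALSE)
}

# a valid paired BCR cell (heavy in *_1, light in *_2)
make_bcr_cell <- function(barcode, v = "IGHV1-1*01", j = "IGHJ4*01",
                          junction = "TGTGCGAGAGATTTTGACTACTGG") {
  data.frame(barcode = barcode, receptor = "BCR",
             locus_1 = "IGH", v_call_1 = v, j_call_1 = j,
             c_call_1 = "IGHG1", junction_1 = junction,
             junction_aa_1 = NA_character_,
             sequence_alignment_1 = NA_character_,
             germline_alignment_1 = NA_character_,
             locus_2 = "IGK", v_call_2 = "IGKV1-1*01",
             j_call_2 = "IGKJ1*01", junction_2 = "TGTCAACAGTACAACAGT",
             junction_aa_2 = NA_character_, stringsAsFactors = FALSE)
}

make_tcr_cell <- function(barcode, va = "TRAV1*01", ja = "TRAJ1*01",
                          jxa = "TGTGCTGTGAGT", vb = "TRBV2*01",
                          jb = "TRBJ1*01", jxb = "TGTGCCAGCAGT") {
  data.frame(barcode = barcode, receptor = "TCR",
             locus_1 = "TRA", v_call_1 = va, j_call_1 = ja,
             c_call_1 = NA_character_, junction_1 = jxa,
             junction_aa_1 = NA_character_,
             sequence_alignment_1 = NA_character_,
             germline_alignment_1 = NA_character_,
             locus_2 = "TRB", v_call_2 = vb, j_call_2 = jb,
             c_call_2 = NA_character_, junction_2 = jxb,
             junction_aa_2 = NA_character_, stringsAsFactors = FALSE)
}

random_junction <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# independent oracle: clone memberships as connected components of the
# strict-threshold graph, via igraph, on one V/J/length partition
oracle_single_linkage <- function(junctions, threshold = 0.1) {
  n <- length(junctions)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      chars_i <- strsplit(junctions[i], "")[[1]]
      chars_j <- strsplit(junctions[j], "")[[1]]
      adj[i, j] <- mean(chars_i != chars_j) < threshold
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# small dense expr_dataset from a plain matrix
make_expr <- function(mat, meta = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("G", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  if (is.null(meta)) {
    meta <- data.frame(barcode = colnames(mat), stringsAsFactors = FALSE)
  }
  expr_dataset(Matrix::Matrix(mat, sparse = TRUE), meta)
}

# quick small simulation config for tests (two groups, one donor each)
small_sim_config <- function(seed, receptor = "BCR", cells = 60L, ...) {
  sim_config(
    seed = seed,
    groups = list(
      HD = list(n_donors = 1L, cells_per_donor = cells,
                clone_dist = "geometric", geom_prob = 0.8, pl_alpha = 2.0,
                isg_shift = 0),
      Act = list(n_donors = 1L, cells_per_donor = cells,
                 clone_dist = "powerlaw", geom_prob = 0.8, pl_alpha = 2.0,
                 isg_shift = 1.0)
    ),
    receptor = receptor,
    ...
  )
}

# independent oracle for expected replacement fractions: direct enumeration
# against the standard genetic code, written without the package internals
oracle_codon_rfrac <- function(codon) {
  gc_tab <- Biostrings::GENETIC_CODE
  nt <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  n_rep <- 0
  for (p in 1:3) {
    for (b in setdiff(nt, chars[p])) {
      mut <- chars
      mut[p] <- b
      aa <- gc_tab[[paste(mut, collapse = "")]]
      if (aa != gc_tab[[codon]] || aa == "*") n_rep <- n_rep + 1
    }
  }
  n_rep / 9
}

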