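test_that("Shannon entropy matches closed forms", {
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), 2.0)
  expect_equal(shannon_entropy(5), 0.0)
  expect_equal(shannon_entropy(c(2, 1, 1)), 1.5)  # p = (0.5, 0.25, 0.25)
  expect_error(shannon_entropy(numeric(0)), "empty")
})

test_that("clonality matches its definition and conventions", {
  for (n in c(2, 5, 17, 100)) {
    expect_equal(clonality(rep(3, n)), 0.0, tolerance = 1e-12)
  }
  expect_equal(clonality(7), 1.0)  # single clone: maximal by convention
  # p = (0.9, 0.1): H = -(0.9 log2 0.9 + 0.1 log2 0.1) = 0.4690
  expect_equal(clonality(c(90, 10)), 0.531004406, tolerance = 1e-6)
  # non-decreasing as mass concentrates (nested majorization chain)
  vals <- vapply(0:9, function(k) clonality(c(10 + k * 10, 10, 10)),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("jaccard_index matches set arithmetic", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(jaccard_index(c("a", "b"), c("x", "y")), 0.0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_error(jaccard_index(character(0), character(0)), "empty")

  set.seed(5)
  universe <- sprintf("cl%03d", 1:80)
  for (i in 1:200) {
    a <- sample(universe, sample(0:40, 1))
    b <- sample(universe, sample(1:40, 1))
    brute <- sum(universe %in% a & universe %in% b) /
      sum(universe %in% a | universe %in% b)
    expect_equal(jaccard_index(a, b), brute)
  }
})

test_that("top_n_frequency sums the n largest frequencies", {
  expect_equal(top_n_frequency(10, n = 20), 1.0)
  expect_equal(top_n_frequency(rep(1, 100), n = 20), 0.2)
  expect_equal(top_n_frequency(c(50, 30, 10, 5, 5), n = 2), 0.8)
  expect_error(top_n_frequency(c(1, 2), n = 0), "n")
})

test_that("R_O/E matches the worked example and margin identities", {
  obs <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE,
                dimnames = list(c("c1", "c2"), c("g1", "g2")))
  r <- roe(obs)
  expect_equal(unname(r$expected), matrix(20, 2, 2))
  expect_equal(unname(r$roe), matrix(c(1.5, 0.5, 0.5, 1.5), 2, byrow = TRUE))

  # independent margins give all ones; single column gives all ones
  expect_equal(unname(roe(matrix(7, 3, 4))$roe), matrix(1, 3, 4))
  expect_equal(unname(roe(matrix(c(5, 9, 2), 3, 1))$roe), matrix(1, 3, 1))

  # cluster-size-weighted mean of R within each group is exactly 1
  set.seed(11)
  for (i in 1:50) {
    m <- matrix(rpois(12, 20) + 1, 4, 3)
    rr <- roe(m)$roe
    w <- rowSums(m)
    for (g in 1:3) {
      expect_equal(sum(w * rr[, g]) / sum(w), 1.0, tolerance = 1e-9)
    }
  }

  expect_warning(roe(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "zero")
})

test_that("pairwise transition index matches hand weighting and brute force", {
  cluster_of <- function(cells, labels) stats::setNames(labels, cells)
  clone_cells <- function(spec) {
    # spec: list(clone -> barcodes); builds a TCR assignment with exact ids
    cells <- do.call(rbind, unlist(lapply(names(spec), function(cl) {
      lapply(spec[[cl]], function(bc) {
        make_tcr_cell(bc, jxa = paste0("TGT", strrep(substr(cl, 1, 1), 9)))
      })
    }), recursive = FALSE))
    call_tcr_clonotypes(cells)
  }

  # confinement -> 0
  a <- clone_cells(list(A = c("a1", "a2"), C = c("b1", "b2")))
  labs <- cluster_of(c("a1", "a2", "b1", "b2"), c("i", "i", "j", "j"))
  expect_equal(pairwise_transition_index(a, labs, "i", "j")$ptran, 0.0)

  # one clone split 50/50 -> 1
  a <- clone_cells(list(A = c("a1", "a2")))
  labs <- cluster_of(c("a1", "a2"), c("i", "j"))
  expect_equal(pairwise_transition_index(a, labs, "i", "j")$ptran, 1.0)

  # clone A 2:2, clone B 4:0 -> 0.5
  a <- clone_cells(list(A = c("a1", "a2", "a3", "a4"),
                        C = c("b1", "b2", "b3", "b4")))
  labs <- cluster_of(c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4"),
                     c("i", "i", "j", "j", "i", "i", "i", "i"))
  res <- pairwise_transition_index(a, labs, "i", "j")
  expect_equal(res$ptran, 0.5)
  # symmetry
  expect_equal(pairwise_transition_index(a, labs, "j", "i")$ptran, 0.5)

  # brute-force equality on random instances
  set.seed(23)
  for (rep_i in 1:20) {
    n_clones <- sample(2:50, 1)
    sizes <- sample(1:5, n_clones, replace = TRUE)
    spec <- lapply(seq_len(n_clones), function(k) {
      sprintf("cl%02d_%d", k, seq_len(sizes[k]))
    })
    names(spec) <- replicate(n_clones, {
      paste(sample(LETTERS, 6), collapse = "")
    })
    cells <- do.call(rbind, unlist(lapply(names(spec), function(cl) {
      jx <- paste0("TGT", paste(sample(c("A", "C", "G", "T"), 12,
                                       replace = TRUE), collapse = ""))
      lapply(spec[[cl]], function(bc) make_tcr_cell(bc, jxa = jx))
    }), recursive = FALSE))
    a <- call_tcr_clonotypes(cells)
    all_bc <- unlist(spec)
    labs <- stats::setNames(sample(c("i", "j", "k"), length(all_bc),
                                   replace = TRUE), all_bc)
    got <- tryCatch(pairwise_transition_index(a, labs, "i", "j")$ptran,
                    error = function(e) NA_real_)
    # oracle: direct per-clone entropy sum from the planted memberships
    h_sum <- 0
    m_sum <- 0
    hs <- c()
    ms <- c()
    for (cl in seq_along(spec)) {
      ni <- sum(labs[spec[[cl]]] == "i")
      nj <- sum(labs[spec[[cl]]] == "j")
      m <- ni + nj
      if (m == 0) next
      q <- c(ni, nj) / m
      q <- q[q > 0]
      hs <- c(hs, -sum(q * log2(q)))
      ms <- c(ms, m)
    }
    if (length(ms) == 0) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, sum(ms / sum(ms) * hs))
    }
  }
})

test_that("vgene log2 fold change matches hand evaluation", {
  usage <- matrix(0L, nrow = 10, ncol = 2,
                  dimnames = list(sprintf("V%d", 1:10), c("A", "B")))
  usage[, "A"] <- c(20L, rep(8L, 8), 16L)
  usage[, "B"] <- c(10L, rep(10L, 8), 10L)
  fc <- vgene_log2fc(usage, "A", "B", pseudocount = 0.5)
  # gene 20/100 vs 10/100, K = 10: log2((20.5/105)/(10.5/105))
  expect_equal(unname(fc["V1"]), log2(20.5 / 10.5), tolerance = 1e-9)

  # identical usage -> all zero
  same <- cbind(A = c(5L, 5L, 10L), B = c(5L, 5L, 10L))
  rownames(same) <- c("V1", "V2", "V3")
  expect_equal(unname(vgene_log2fc(same, "A", "B")), rep(0, 3))

  # absent in one group stays finite
  ab <- cbind(A = c(10L, 0L), B = c(0L, 10L))
  rownames(ab) <- c("V1", "V2")
  expect_true(all(is.finite(vgene_log2fc(ab, "A", "B"))))
  expect_error(vgene_log2fc(cbind(A = c(0L, 0L), B = c(1L, 1L)), "A", "B"),
               "empty")
})

test_that("repertoire_metrics aggregates per stratum", {
  cells <- rbind(
    do.call(rbind, lapply(1:4, function(i) {
      make_tcr_cell(sprintf("x%d", i), jxa = "TGTAAAAAAAAA")
    })),
    do.call(rbind, lapply(1:4, function(i) {
      jx <- c("TGTCCCCCCCCC", "TGTGGGGGGGGG", "TGTTTTTTTTTT",
              "TGTCATCATCAT")[i]
      make_tcr_cell(sprintf("y%d", i), jxa = jx)
    }))
  )
  a <- call_tcr_clonotypes(cells)
  strata <- stats::setNames(rep(c("mono", "even"), each = 4),
                            cells$barcode)
  m <- repertoire_metrics(a, strata)
  m <- m[order(m$stratum), ]
  expect_equal(m$clonality[m$stratum == "mono"], 1.0)
  expect_equal(m$clonality[m$stratum == "even"], 0.0)
  expect_equal(m$n_cells, c(4L, 4L))
})
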