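test_that("cell QC applies both thresholds and is idempotent", {
  set.seed(2)
  g <- 600
  mat <- matrix(rpois(g * 10, 2), g, 10)
  rownames(mat) <- c(sprintf("MT-%d", 1:10), sprintf("G%04d", 1:(g - 10)))
  colnames(mat) <- sprintf("c%02d", 1:10)
  # plant 3 violations: two low-gene cells, one high-mito cell
  mat[, 1] <- 0; mat[1:100, 1] <- 1          # 100 detected genes
  mat[, 2] <- 0; mat[1:499, 2] <- 1          # 499 detected genes
  mat[1:10, 3] <- 1000                       # mito overload
  x <- make_expr(mat)
  q <- filter_cells_qc(x, min_genes = 500, max_mito = 0.10)
  expect_equal(colnames(q$counts), sprintf("c%02d", 4:10))
  expect_equal(ncol(filter_cells_qc(q)$counts), ncol(q$counts))

  # boundary: exactly 500 genes and exactly 10% mito are retained
  mat2 <- matrix(0, g, 2,
                 dimnames = list(rownames(mat), c("edge1", "edge2")))
  mat2[11:510, 1] <- 1                       # exactly 500 detected
  mat2[11:550, 2] <- 1                       # 540 non-mito counts
  mat2[1, 2] <- 60                           # 60/600 = exactly 10% mito
  q2 <- filter_cells_qc(make_expr(mat2))
  expect_equal(ncol(q2$counts), 2L)
})

test_that("log-normalization matches the closed form and conserves totals", {
  mat <- matrix(c(10, 90, 9900, 0, 500, 9500), 3, 2,
                dimnames = list(c("a", "b", "c"), c("x", "y")))
  n <- log_normalize(make_expr(mat), scale = 1e4)
  expect_equal(n$logcounts["a", "x"], log(11))  # 10/10000*1e4 = 10
  expect_equal(n$logcounts["a", "y"], 0)
  # exp(value) - 1 sums back to the scale factor for every cell
  dense <- as.matrix(n$logcounts)
  expect_equal(unname(colSums(exp(dense) - 1)), c(1e4, 1e4))
  mat0 <- cbind(mat, z = c(0, 0, 0))
  expect_error(log_normalize(make_expr(mat0)), "zero-total")
})

test_that("module_score is exactly zero on constant matrices", {
  mat <- matrix(3, 200, 15,
                dimnames = list(sprintf("G%03d", 1:200),
                                sprintf("c%02d", 1:15)))
  n <- log_normalize(make_expr(mat))
  for (seed in c(1, 99)) {
    sc <- module_score(n, sprintf("G%03d", 1:10), seed = seed)
    expect_equal(unname(sc), rep(0, 15), tolerance = 1e-12)
  }
})

test_that("module_score is deterministic and gene-order invariant", {
  set.seed(12)
  mat <- matrix(rpois(500 * 30, 5), 500, 30,
                dimnames = list(sprintf("G%03d", 1:500),
                                sprintf("c%02d", 1:30)))
  program <- sprintf("G%03d", c(3, 77, 150))
  n1 <- log_normalize(make_expr(mat))
  n2 <- log_normalize(make_expr(mat[sample(500), ]))
  s1 <- module_score(n1, program, seed = 7)
  s2 <- module_score(n2, program, seed = 7)
  expect_equal(s1, s2)
  expect_equal(s1, module_score(n1, rev(program), seed = 7))
  expect_warning(module_score(n1, c(program, "NOT_A_GENE"), seed = 7),
                 "absent")
  expect_error(module_score(n1, c("NOPE1", "NOPE2"), seed = 7), "program")
})

test_that("a planted program shift is recovered by the module score", {
  cfg <- small_sim_config(seed = 13, cells = 150L, pathway_coupling = 0,
                          qc_fail_rate = 0)
  ex <- simulate_expression(cfg)
  n <- log_normalize(filter_cells_qc(ex$dataset))
  sc <- module_score(n, ex$gene_sets$ISG, seed = 5)
  grp <- n$meta$group
  delta <- mean(sc[grp == "Act"]) - mean(sc[grp == "HD"])
  expect_lt(abs(delta - 1.0), 0.1)
})

test_that("rank_signature_score matches hand arithmetic and invariances", {
  set.seed(4)
  # continuous values: the worked example presumes untied ranks
  mat <- matrix(rexp(100 * 8, 0.1), 100, 8,
                dimnames = list(sprintf("G%03d", 1:100),
                                sprintf("c%d", 1:8)))
  n <- log_normalize(make_expr(mat))
  # pathway = all genes -> 0
  expect_equal(unname(rank_signature_score(n, rownames(mat))), rep(0, 8),
               tolerance = 1e-12)
  # pathway holding the top 10 ranks in a cell scores (95.5 - 50.5)/100
  cell <- as.matrix(n$logcounts)[, 1]
  top10 <- names(sort(cell, decreasing = TRUE))[1:10]
  sc <- rank_signature_score(n, top10)
  expect_equal(unname(sc["c1"]), 0.45, tolerance = 1e-9)
  bottom10 <- names(sort(cell))[1:10]
  expect_lt(rank_signature_score(n, bottom10)[["c1"]], 0)

  # invariance under per-cell monotone transforms of expression
  sq <- n
  sq$logcounts <- n$logcounts^2
  expect_equal(rank_signature_score(sq, top10), sc)

  # multi-pathway version agrees with one-at-a-time calls
  pws <- list(a = top10, b = bottom10)
  multi <- rank_signature_scores(n, pws)
  expect_equal(multi[, "a"], sc)
})

test_that("comprehensive score selects top pathways by grand mean", {
  set.seed(6)
  sc <- matrix(rnorm(20 * 5), 20, 5,
               dimnames = list(sprintf("c%02d", 1:20),
                               sprintf("p%d", 1:5)))
  one <- comprehensive_metabolic_score(sc[, 1, drop = FALSE], top_k = 20)
  expect_equal(unname(one$score), unname(sc[, 1]))
  twin <- comprehensive_metabolic_score(sc[, c(1, 1)], top_k = 2)
  expect_equal(unname(twin$score), unname(sc[, 1]))
  top2 <- comprehensive_metabolic_score(sc, top_k = 2)
  sel <- names(sort(colMeans(sc), decreasing = TRUE))[1:2]
  expect_setequal(top2$pathways, sel)
})

test_that("score_correlation reports Spearman rho and both R-squared conventions", {
  expect_equal(score_correlation(1:5, c(2, 4, 5, 7, 9))$rho, 1.0)
  expect_equal(score_correlation(1:5, 5:1)$rho, -1.0)
  r <- score_correlation(c(1, 2, 3), c(2, 1, 3))
  expect_equal(r$rho, 0.5)
  expect_equal(r$rho_squared, 0.25)
  expect_error(score_correlation(c(1, 1, 1), 1:3), "constant")
  expect_error(score_correlation(1:2, 2:3), "3")
})

test_that("GMT and MTX round-trips preserve content", {
  sets <- list(
    SETA = structure(list(name = "SETA", description = "first",
                          genes = c("G1", "G2", "G3")), class = "gene_set"),
    SETB = structure(list(name = "SETB", description = "second",
                          genes = c("G9", "G4")), class = "gene_set")
  )
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(names(back), c("SETA", "SETB"))
  expect_equal(back$SETA$genes, c("G1", "G2", "G3"))

  set.seed(3)
  mat <- matrix(rpois(50 * 6, 1), 50, 6,
                dimnames = list(sprintf("G%02d", 1:50),
                                sprintf("bc%d-1", 1:6)))
  meta <- data.frame(barcode = colnames(mat),
                     group = rep(c("HD", "Act"), 3),
                     stringsAsFactors = FALSE)
  x <- expr_dataset(Matrix::Matrix(mat, sparse = TRUE), meta)
  dir <- withr::local_tempdir()
  write_mtx_dataset(x, dir)
  back2 <- read_mtx_dataset(dir)
  expect_equal(as.matrix(back2$counts), as.matrix(x$counts))
  expect_equal(back2$meta$group, meta$group)
})
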