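make_pb <- function(counts, species, age = "infant", ct = "COP") {
  n <- ncol(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  meta <- tibble::tibble(
    sample_id = paste0("s", seq_len(n)), species = species,
    age_group = age, individual = paste0("i", seq_len(n)), cell_type = ct)
  colnames(counts) <- meta$sample_id
  pseudobulk_matrix(counts, meta)
}

test_that("pseudobulk container validates its invariants", {
  counts <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), NULL))
  meta <- tibble::tibble(sample_id = paste0("s", 1:3), species = "human",
                         age_group = "infant", individual = c("a", "b", "a"),
                         cell_type = "COP")
  colnames(counts) <- meta$sample_id
  expect_error(pseudobulk_matrix(counts, meta), "duplicate")
  meta$individual <- c("a", "b", "c")
  expect_s3_class(pseudobulk_matrix(counts, meta), "pseudobulk")
  expect_error(pseudobulk_matrix(counts - 0.5, meta), "integer")
})

test_that("aggregation sums cells, drops small groups, and round-trips", {
  cc <- cbind(c(1, 2), c(3, 4), c(10, 20))
  rownames(cc) <- c("g1", "g2")
  colnames(cc) <- c("c1", "c2", "c3")
  meta <- tibble::tibble(cell_id = c("c1", "c2", "c3"),
                         individual = c("i1", "i1", "i2"),
                         cell_type = "COP", species = "human",
                         age_group = "infant")
  agg <- aggregate_pseudobulk(cc, meta, min_cells = 1)
  expect_equal(unname(agg$counts[, "i1__COP"]), c(4, 6))
  # a group below min_cells disappears but is logged
  expect_message(agg2 <- aggregate_pseudobulk(cc, meta, min_cells = 2),
                 "i2__COP")
  expect_false("i2__COP" %in% colnames(agg2$counts))
  expect_equal(attr(agg2, "dropped"), "i2__COP")
  meta$individual[2] <- NA
  expect_error(aggregate_pseudobulk(cc, meta, min_cells = 1), "unlabeled")

  # random multinomial split then re-aggregation recovers the column
  bundle <- .small_bundle()
  pb <- bundle$pseudobulk
  keep <- which(pb$sample_meta$cell_type == "COP")[1:4]
  small <- pseudobulk_matrix(pb$counts[1:50, keep],
                             pb$sample_meta[keep, ])
  cells <- simulate_cells(small, cells_per_sample = 7, seed = 5)
  re <- aggregate_pseudobulk(cells$counts, cells$cell_meta, min_cells = 1)
  re_cols <- re$counts[, colnames(small$counts)]
  expect_equal(unname(re_cols), unname(small$counts))
})

test_that("size factors reproduce median-of-ratios arithmetic", {
  counts <- matrix(c(10, 20, 30, 40, 55,
                     20, 40, 60, 80, 110,
                     12, 18, 33, 44, 50), 5,
                   dimnames = list(paste0("g", 1:5), NULL))
  sf <- size_factors(counts)
  # independent hand computation of the same definition
  geo <- exp(rowMeans(log(counts)))
  raw <- apply(counts / geo, 2, median)
  expect_equal(unname(sf), unname(raw / exp(mean(log(raw)))),
               tolerance = 1e-12)
  # doubling a sample doubles its factor relative to the original
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  same <- matrix(rep(c(5, 9, 13), 4), 3,
                 dimnames = list(paste0("g", 1:3), NULL))
  expect_equal(unname(size_factors(same)), rep(1, 4))
  zeros <- matrix(c(0, 5, 0, 1, 0, 4), 3,
                  dimnames = list(paste0("g", 1:3), NULL))
  expect_warning(size_factors(zeros), "total-count")
})

test_that("dispersion estimates recover the simulation truth", {
  set.seed(42)
  # Poisson limit: large-mean Poisson counts give near-zero dispersion
  pois <- matrix(rpois(200 * 50, 200), 200,
                 dimnames = list(sprintf("g%03d", 1:200), NULL))
  a_pois <- estimate_dispersion(pois, sf = rep(1, 50))
  expect_lt(median(a_pois), 0.02)
  # NB at alpha = 0.5, n = 200 samples: median estimate within 20%
  nb <- matrix(rnbinom(300 * 200, mu = 100, size = 2), 300,
               dimnames = list(sprintf("g%03d", 1:300), NULL))
  a_nb <- estimate_dispersion(nb, sf = rep(1, 200))
  expect_equal(median(a_nb), 0.5, tolerance = 0.2)
  # constant counts across samples -> the floor
  const <- matrix(7, 5, 10, dimnames = list(paste0("g", 1:5), NULL))
  expect_equal(as.vector(estimate_dispersion(const, sf = rep(1, 10))),
               rep(1e-8, 5))
  # all-zero genes are flagged untestable
  z <- rbind(const, g_zero = 0)
  expect_equal(attr(estimate_dispersion(z, sf = rep(1, 10)), "untestable"),
               "g_zero")
})

test_that("Wald test is unbiased for planted effects and null-calibrated", {
  set.seed(7)
  n_genes <- 100
  mu <- 100
  Y <- cbind(
    matrix(rnbinom(n_genes * 10, mu = 2 * mu, size = 10), n_genes),
    matrix(rnbinom(n_genes * 10, mu = mu, size = 10), n_genes))
  pb <- make_pb(Y, rep(c("human", "chimp"), each = 10))
  res <- nb_wald_test(pb, "COP", "infant", "human", "chimp",
                      dispersions = setNames(rep(0.1, n_genes),
                                             rownames(pb$counts)),
                      sf = setNames(rep(1, 20), colnames(pb$counts)))
  expect_equal(mean(res$log2fc), 1, tolerance = 0.2)
  expect_true(mean(res$log2fc) > 0.8 && mean(res$log2fc) < 1.2)

  # identical group means: fold changes near zero, p far from small
  set.seed(8)
  Y0 <- matrix(rnbinom(50 * 20, mu = mu, size = 10), 50)
  pb0 <- make_pb(Y0, rep(c("human", "chimp"), each = 10))
  res0 <- nb_wald_test(pb0, "COP", "infant", "human", "chimp")
  expect_lt(abs(mean(res0$log2fc)), 0.15)
  expect_gt(mean(res0$wald_p), 0.3)

  # null simulation at scale: type-I error close to nominal
  set.seed(9)
  Yn <- matrix(rnbinom(2000 * 20, mu = 80, size = 8), 2000,
               dimnames = list(sprintf("g%04d", 1:2000), NULL))
  pbn <- make_pb(Yn, rep(c("human", "chimp"), each = 10))
  resn <- nb_wald_test(pbn, "COP", "infant", "human", "chimp")
  t1 <- mean(resn$wald_p < 0.05)
  expect_gt(t1, 0.03)
  expect_lt(t1, 0.07)
})

test_that("a group of all-zero counts is floored and flagged, not infinite", {
  Y <- rbind(g_on = c(rep(50, 4), rep(0, 4)),
             g_ok = rep(30, 8))
  pb <- make_pb(Y, rep(c("human", "chimp"), each = 4))
  res <- suppressWarnings(
    nb_wald_test(pb, "COP", "infant", "human", "chimp",
                 dispersions = c(g_on = 0.1, g_ok = 0.1)))
  expect_true(all(is.finite(res$log2fc)))
  expect_true(res$flag_floor[res$gene == "g_on"])
  expect_gt(res$log2fc[res$gene == "g_on"], 3)
})

test_that("scaling one sample's counts scales its size factor, not the fold changes", {
  bundle <- .small_bundle()
  pb <- bundle$pseudobulk
  keep <- pb$sample_meta$cell_type == "COP" &
    pb$sample_meta$age_group == "infant" &
    pb$sample_meta$species %in% c("human", "chimp")
  sub <- pb$counts[, keep]
  sf1 <- size_factors(sub)
  sub2 <- sub
  sub2[, 1] <- sub2[, 1] * 3
  sf2 <- size_factors(sub2)
  expect_equal(unname((sf2[1] / sf2[2]) / (sf1[1] / sf1[2])), 3,
               tolerance = 1e-9)
})

test_that("call_de applies strict thresholds and direction labels", {
  calls <- tibble::tibble(
    gene = paste0("g", 1:6), cell_type = "COP", age_group = "infant",
    contrast = "human_vs_chimp",
    log2fc = c(0.5, 2, 0.9, -0.8, -0.4, 1.4),
    fdr = c(0.01, 0.2, 0.01, 0.04, 0.01, 0.05))
  res <- call_de(calls)
  # g1 at the boundary, g2 weak fdr, g5 weak lfc, g6 fdr at boundary: out
  expect_setequal(res$gene, c("g3", "g4"))
  expect_equal(res$direction[res$gene == "g3"], "gain")
  expect_equal(res$direction[res$gene == "g4"], "loss")
  expect_length(intersect(res$gene[res$direction == "gain"],
                          res$gene[res$direction == "loss"]), 0)
  expect_warning(empty <- call_de(calls[0, ]), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("the engine agrees with DESeq2 on a shared fixture", {
  set.seed(21)
  n_genes <- 150
  lfc <- sample(c(0, 0, 1, -1), n_genes, replace = TRUE)
  mu <- exp(runif(n_genes, log(20), log(500)))
  Y <- cbind(
    matrix(rnbinom(n_genes * 8, mu = mu * 2^lfc, size = 10), n_genes),
    matrix(rnbinom(n_genes * 8, mu = mu, size = 10), n_genes))
  pb <- make_pb(Y, rep(c("human", "chimp"), each = 8))
  ours <- nb_wald_test(pb, "COP", "infant", "human", "chimp")
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      pb$counts, S4Vectors::DataFrame(species = factor(
        rep(c("human", "chimp"), each = 8), levels = c("chimp", "human"))),
      ~species)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds, contrast = c("species", "human", "chimp"))
  })
  expect_gt(cor(ours$log2fc, ref$log2FoldChange, use = "complete.obs"), 0.95)
  both_called <- (ours$fdr < 0.05 & abs(ours$log2fc) > 0.5)
  ref_called <- (!is.na(ref$padj) & ref$padj < 0.05 &
                   abs(ref$log2FoldChange) > 0.5)
  expect_gt(mean(both_called == ref_called), 0.9)
})
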