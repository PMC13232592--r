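test_that("config validation names the offending field", {
  expect_error(sim_config(n_genes = 2), "n_genes")
  expect_error(sim_config(fraction_hiDE = 0.7), "fraction_hiDE")
  expect_error(sim_config(effect_size_lfc = -1), "effect_size_lfc")
  expect_error(sim_config(dispersion_range = c(0.5, 0.1)), "dispersion_range")
  expect_error(sim_config(species = c("a", "a", "b")), "species")
})

test_that("truth generation is deterministic and respects degenerate fractions", {
  cfg <- small_config(seed = 33L)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1$assignments, t2$assignments)
  expect_identical(t1$regulon_edges, t2$regulon_edges)
  expect_identical(t1$baseline_means, t2$baseline_means)
  # no hiDE planted when the fraction is zero (need ciDE so regulons exist
  # in at least one lineage... hiDE gains drive regulons, so relax there)
  cfg0 <- sim_config(n_genes = 300, n_individuals = 4,
                     fraction_hiDE = 0.2, fraction_ciDE = 0, seed = 2L)
  t0 <- generate_truth(cfg0)
  expect_equal(sum(t0$assignments$category == "ciDE"), 0)
})

test_that("planted set sizes follow the binomial design", {
  cfg <- sim_config(n_genes = 500, n_individuals = 4,
                    cell_types = c(A = "neural", B = "neural", C = "OL",
                                   D = "OL"),
                    fraction_hiDE = 0.1, seed = 9L)
  truth <- generate_truth(cfg)
  sizes <- truth$assignments |>
    dplyr::filter(.data$category == "hiDE", .data$direction == "gain") |>
    dplyr::count(.data$cell_type)
  expect_equal(nrow(sizes), 4)
  # each Binomial(500, 0.05): mean 25, sd ~4.9; allow 4 sd
  expect_true(all(abs(sizes$n - 25) < 20))
})

test_that("hiDE and adult-shared plantings never collide", {
  truth <- .small_bundle()$truth
  hide <- truth$assignments |> dplyr::filter(.data$category == "hiDE")
  shared <- truth$assignments |>
    dplyr::filter(.data$category == "shared_adult")
  expect_equal(nrow(dplyr::inner_join(
    hide, shared, by = c("gene", "cell_type", "direction"))), 0)
  expect_true(all(truth$dispersions > 0))
  expect_true(all(truth$baseline_means > 0))
})

test_that("simulated counts embody the planted fold changes", {
  # planted +1 for human infants: group-mean ratio ~2 over many individuals
  cfg <- sim_config(n_genes = 200, n_individuals = 100,
                    cell_types = c(COP = "OL"), dispersion_range = c(0.05, 0.1),
                    size_factor_sdlog = 0, seed = 12L)
  truth <- generate_truth(cfg)
  pb <- simulate_counts(truth, cfg)
  planted <- truth$planted_lfc |>
    dplyr::filter(.data$species == "human", .data$age_group == "infant",
                  .data$lfc == 1)
  meta <- pb$sample_meta
  hcol <- meta$species == "human" & meta$age_group == "infant"
  ccol <- meta$species == "chimp" & meta$age_group == "infant"
  ratio <- rowMeans(pb$counts[planted$gene, hcol, drop = FALSE]) /
    rowMeans(pb$counts[planted$gene, ccol, drop = FALSE])
  expect_equal(median(ratio), 2, tolerance = 0.15)
  # byte-identical on re-run
  pb2 <- simulate_counts(truth, cfg)
  expect_identical(pb$counts, pb2$counts)
})

test_that("near-Poisson limit gives variance close to the mean", {
  cfg <- sim_config(n_genes = 80, n_individuals = 100,
                    cell_types = c(COP = "OL"),
                    dispersion_range = c(1e-6, 2e-6),
                    fraction_ciDE = 0, fraction_shared_adult = 0,
                    size_factor_sdlog = 0, seed = 13L)
  truth <- generate_truth(cfg)
  pb <- simulate_counts(truth, cfg)
  meta <- pb$sample_meta
  cols <- meta$species == "rhesus" & meta$age_group == "adult"  # pure nulls
  m <- rowMeans(pb$counts[, cols])
  v <- apply(pb$counts[, cols], 1, var)
  # variance-to-mean ratio concentrates near 1
  expect_equal(median(v / m), 1, tolerance = 0.15)
})

test_that("zero planted fractions leave no lineage for regulons", {
  cfg <- sim_config(n_genes = 100, n_individuals = 4, fraction_hiDE = 0,
                    seed = 3L)
  expect_error(generate_truth(cfg), "hiDE gains")
})

test_that("every hiDECORE rule has designed passes and failures", {
  truth <- .small_bundle()$truth
  edges <- truth$regulon_edges
  for (col in c("pass_node", "pass_annot", "pass_tf2g", "pass_r2g",
                "pass_role")) {
    expect_gt(sum(edges[[col]]), 0)
    expect_gt(sum(!edges[[col]]), 0)
  }
  expect_gt(sum(edges$pass_all), 0)
  # designed failures carry the designed defect
  expect_true(all(edges$tf2g_score[edges$design == "fail_tf2g"] < 0))
  expect_true(all(edges$role[edges$design == "fail_role"] == "repressor"))
  expect_false(any(edges$region_annotated[edges$design == "fail_annot"]))
  # annotation intervals overlap roughly half the regions
  frac <- mean(unique(edges$region) %in% truth$annotation_truth$region_id)
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.8)
})

test_that("annotated regions really overlap an emitted interval", {
  bundle <- .small_bundle()
  truth <- bundle$truth
  regions <- parse_region_ids(unique(truth$regulon_edges$region))
  ann <- annotate_regions(regions, bundle$annotations)
  annotated_regions <- unique(truth$annotation_truth$region_id)
  expect_setequal(ann$region_id[ann$n_classes > 0], annotated_regions)
})

test_that("fixture bundles round-trip through disk with stable checksums", {
  cfg <- small_config(seed = 44L)
  bundle <- simulate_bundle(cfg)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  man1 <- write_fixture_bundle(bundle, dir1)
  man2 <- write_fixture_bundle(simulate_bundle(cfg), dir2)
  expect_identical(man1$md5, man2$md5)
  back <- read_fixture_bundle(dir1)
  expect_identical(back$pseudobulk$counts, bundle$pseudobulk$counts)
  expect_equal(as.data.frame(back$regulons[, names(bundle$regulons)]),
               as.data.frame(bundle$regulons))
  expect_equal(back$disease_de$gene, bundle$disease_de$gene)
  expect_equal(back$truth$hide_gains$OL, bundle$truth$hide_gains$OL)
  # tampering is caught by the checksum verification
  writeLines("tampered", file.path(dir1, "genes.tsv"))
  expect_error(read_fixture_bundle(dir1), "checksum")
})
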