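toy_edges <- function() {
  tibble::tibble(
    edge_id = c("eA", "eB", "eC"),
    tf = "tf1", region = c("chrS:100-200", "chrS:300-400", "chrS:500-600"),
    target = c("gA", "gB", "gC"),
    tf2g_score = c(0.5, -0.4, 0.6),
    r2g_score = c(0.7, 0.5, 0.8),
    role = "activator", cell_context = "OL")
}

toy_annotation <- function() {
  tibble::tibble(region_id = c("chrS:100-200", "chrS:300-400", "chrS:500-600"),
                 classes = list("HAR", "hINS", character(0)),
                 n_classes = c(1L, 1L, 0L))
}

test_that("half-open overlap rule: touching intervals do not overlap", {
  regions <- tibble::tibble(region_id = c("r1", "r2"), chrom = "chrS",
                            start = c(100L, 100L), end = c(200L, 200L))
  ann <- tibble::tibble(chrom = "chrS", start = c(200L, 199L),
                        end = c(300L, 300L),
                        annotation_class = c("HAR", "hINS"))
  res <- annotate_regions(regions, ann)
  # [100,200) vs [200,300): no overlap; vs [199,300): 1-bp overlap
  expect_equal(res$classes[[1]], "hINS")
  expect_equal(res$classes[[2]], "hINS")
  expect_error(annotate_regions(
    tibble::tibble(region_id = "r", chrom = "chrS", start = 5L, end = 5L),
    ann), "start < end")
  expect_warning(annotate_regions(
    tibble::tibble(region_id = "r", chrom = "chrX", start = 1L, end = 10L),
    ann), "one input only")
})

test_that("interval engine equals the quadratic all-pairs oracle", {
  set.seed(17)
  n <- 1000
  regions <- tibble::tibble(
    region_id = sprintf("r%04d", 1:n),
    chrom = sample(c("chrS", "chrT"), n, replace = TRUE),
    start = sample.int(50000, n))
  regions$end <- regions$start + sample.int(200, n, replace = TRUE)
  m <- 1000
  ann <- tibble::tibble(
    chrom = sample(c("chrS", "chrT"), m, replace = TRUE),
    start = sample.int(50000, m))
  ann$end <- ann$start + sample.int(200, m, replace = TRUE)
  ann$annotation_class <- sample(c("HAR", "hINS", "hDEL"), m, replace = TRUE)
  res <- annotate_regions(regions, ann)
  oracle <- quadratic_overlap(regions, ann)
  expect_identical(res$classes, oracle)
})

test_that("region ids parse to coordinates and reject malformed forms", {
  parsed <- parse_region_ids(c("chrS:100-500", "chr1:0-10"))
  expect_equal(parsed$start, c(100L, 0L))
  expect_equal(parsed$end, c(500L, 10L))
  expect_error(parse_region_ids("region_7"), "chrom:start-end")
})

test_that("three-edge toy network retains exactly the rule-passing edge", {
  # edge A passes everything, B has a negative TF-to-gene score, C sits on
  # an unannotated region
  net <- build_hidecore(toy_edges(), hide_gains = c("tf1", "gA", "gB", "gC"),
                        toy_annotation(), lineage = "OL")
  expect_equal(net$edges$edge_id, "eA")
  expect_equal(sort(net$nodes$gene), c("gA", "tf1"))
  expect_equal(net$provenance$n_failed[net$provenance$rule == "tf2g"], 1)
  expect_equal(net$provenance$n_failed[net$provenance$rule == "annot"], 1)
  # empty gains: everything dies at the node rule
  net0 <- build_hidecore(toy_edges(), character(0), toy_annotation(), "OL")
  expect_equal(nrow(net0$edges), 0)
  expect_equal(net0$provenance$n_failed[net0$provenance$rule == "node"], 3)
})

test_that("fixture networks recover the designed retention set exactly", {
  bundle <- .small_bundle()
  truth <- bundle$truth
  regions <- parse_region_ids(unique(bundle$regulons$region))
  ann <- annotate_regions(regions, bundle$annotations)
  for (lin in names(truth$hide_gains)) {
    net <- build_hidecore(bundle$regulons, truth$hide_gains[[lin]], ann, lin)
    designed <- truth$regulon_edges |>
      dplyr::filter(.data$cell_context == lin, .data$pass_all)
    expect_setequal(net$edges$edge_id, designed$edge_id)
    # provenance conservation
    expect_equal(nrow(net$edges) + sum(net$provenance$n_failed) +
                   net$n_outside_universe, net$n_input)
  }
})

test_that("disabling any retention rule can only grow the network", {
  bundle <- .small_bundle()
  truth <- bundle$truth
  lin <- names(truth$hide_gains)[1]
  regions <- parse_region_ids(unique(bundle$regulons$region))
  ann <- annotate_regions(regions, bundle$annotations)
  all_rules <- c("node", "annot", "tf2g", "r2g", "role")
  full <- build_hidecore(bundle$regulons, truth$hide_gains[[lin]], ann, lin)
  for (drop in all_rules) {
    relaxed <- build_hidecore(bundle$regulons, truth$hide_gains[[lin]], ann,
                              lin, rules = setdiff(all_rules, drop))
    expect_true(all(full$edges$edge_id %in% relaxed$edges$edge_id))
  }
})

test_that("genes outside the universe are excluded and counted separately", {
  edges <- toy_edges()
  net <- build_hidecore(edges, c("tf1", "gA", "gB", "gC"), toy_annotation(),
                        "OL", universe = c("tf1", "gA", "gB"))
  expect_equal(net$n_outside_universe, 1)
  expect_equal(nrow(net$edges) + sum(net$provenance$n_failed) +
                 net$n_outside_universe, net$n_input)
  expect_false("gC" %in% c(net$edges$tf, net$edges$target))
})

test_that("lineage overlap statistics reduce to known extremes", {
  mk_net <- function(genes, lin) {
    structure(list(lineage = lin,
                   nodes = tibble::tibble(gene = genes, kind = "target",
                                          disease_status = "none"),
                   edges = tibble::tibble()),
              class = "hidecore_network")
  }
  uni <- sprintf("u%03d", 1:200)
  a <- mk_net(uni[1:20], "OL")
  expect_equal(lineage_overlap_stats(a, a, uni)$overlap_fraction, 1)
  b <- mk_net(uni[21:40], "neural")
  res <- lineage_overlap_stats(a, b, uni)
  expect_equal(res$overlap_fraction, 0)
  expect_gt(res$p_value, 0.5)
  # hypergeometric p equals the enumeration oracle at small sizes
  c1 <- mk_net(uni[1:10], "OL")
  c2 <- mk_net(uni[6:15], "neural")
  res2 <- lineage_overlap_stats(c1, c2, uni[1:50])
  expect_equal(res2$p_value, enum_hyper_upper(5, 10, 10, 50),
               tolerance = 1e-12)
})

test_that("disease annotation respects lineage matching and truth", {
  net <- build_hidecore(toy_edges(), c("tf1", "gA", "gB", "gC"),
                        toy_annotation(), "OL")
  patient <- tibble::tibble(
    gene = c("gA", "gA", "tf1"), disease = c("ASD", "PD", "ASD"),
    cell_type = c("OL", "OL", "neural"),
    direction = "down", log2fc = -1, fdr = 0.01)
  net <- annotate_disease(net, patient)
  st <- setNames(net$nodes$disease_status, net$nodes$gene)
  expect_equal(unname(st["gA"]), "both")
  # tf1 only deregulated in an unmatched lineage label
  expect_equal(unname(st["tf1"]), "none")

  # on the fixture, node status equals the planted disease truth
  bundle <- .small_bundle()
  truth <- bundle$truth
  lin <- names(truth$hide_gains)[1]
  regions <- parse_region_ids(unique(bundle$regulons$region))
  ann <- annotate_regions(regions, bundle$annotations)
  fnet <- build_hidecore(bundle$regulons, truth$hide_gains[[lin]], ann, lin)
  fnet <- annotate_disease(fnet, bundle$disease_de)
  truth_dis <- truth$disease_truth |> dplyr::filter(.data$lineage == lin)
  for (i in seq_len(nrow(fnet$nodes))) {
    g <- fnet$nodes$gene[i]
    planted <- sort(unique(truth_dis$disease[truth_dis$gene == g]))
    expected <- if (length(planted) == 2) "both"
      else if (length(planted) == 1) planted else "none"
    expect_equal(fnet$nodes$disease_status[i], expected)
  }
})

test_that("lineage-disease Fisher tables reproduce the printed statistics", {
  mk_net <- function(hits, misses, lin, disease) {
    genes <- c(sprintf("%s_h%02d", lin, seq_len(hits)),
               sprintf("%s_m%02d", lin, seq_len(misses)))
    structure(list(
      lineage = lin,
      nodes = tibble::tibble(
        gene = genes, kind = "target",
        disease_status = rep(c(disease, "none"), c(hits, misses))),
      edges = tibble::tibble()), class = "hidecore_network")
  }
  # gene-level: 24/64 OL ASD hits vs 4/68 neural
  res <- lineage_disease_enrichment(mk_net(24, 40, "OL", "ASD"),
                                    mk_net(4, 64, "neural", "ASD"), "ASD")
  expect_equal(res$odds_ratio, 9.6)
  expect_lt(res$p_two_sided, 0.001)
  # TF-level: 7/26 vs 1/26
  res_tf <- lineage_disease_enrichment(mk_net(7, 19, "OL", "ASD"),
                                       mk_net(1, 25, "neural", "ASD"), "ASD")
  expect_equal(round(res_tf$odds_ratio, 1), 9.2)
  expect_equal(res_tf$p_greater, 0.0248, tolerance = 1e-2)
  # equal rates: no association
  res_eq <- lineage_disease_enrichment(mk_net(5, 15, "OL", "ASD"),
                                       mk_net(5, 15, "neural", "ASD"), "ASD")
  expect_equal(res_eq$odds_ratio, 1)
  expect_equal(res_eq$p_two_sided, 1)
})

test_that("per-TF proportions follow the arithmetic and ranking contract", {
  nodes <- tibble::tibble(
    gene = c("tf1", "tf2", paste0("g", 1:6)),
    kind = c("TF", "TF", rep("target", 6)),
    disease_status = c("none", "none", "PD", "PD", "ASD", "none",
                       "none", "none"))
  edges <- tibble::tibble(
    tf = c(rep("tf1", 4), rep("tf2", 2)),
    target = c("g1", "g2", "g3", "g4", "g5", "g6"),
    region = "chrS:0-1", tf2g_score = 1, r2g_score = 1,
    annotation_classes = list("HAR"))
  net <- structure(list(lineage = "OL", nodes = nodes, edges = edges),
                   class = "hidecore_network")
  res <- per_tf_disease_proportions(net)
  r1 <- res[res$tf == "tf1", ]
  expect_equal(r1$n_targets, 4)
  expect_equal(r1$prop_pd, 0.5)
  expect_equal(r1$prop_asd, 0.25)
  expect_equal(r1$prop_total, 0.75)
  expect_equal(res$tf[res$rank == 1], "tf1")
})

test_that("capture concordance recovers the planted rate", {
  bundle <- simulate_bundle(small_config(seed = 77L,
                                         capture_concordance = 0.5))
  truth <- bundle$truth
  regions <- parse_region_ids(unique(bundle$regulons$region))
  ann <- annotate_regions(regions, bundle$annotations)
  fracs <- sapply(names(truth$hide_gains), function(lin) {
    net <- build_hidecore(bundle$regulons, truth$hide_gains[[lin]], ann, lin)
    capture_concordance(net, bundle$capture_pairs,
                        truth$capture_tested_regions)$fraction_edges
  })
  # planted 50% pair concordance, within binomial error
  expect_equal(mean(fracs), 0.5, tolerance = 0.25)
  net <- build_hidecore(bundle$regulons, truth$hide_gains[[1]], ann,
                        names(truth$hide_gains)[1])
  expect_error(capture_concordance(net, bundle$capture_pairs[0, ]),
               "no tested regions")
  # a capture superset of the network yields perfect concordance
  full_pairs <- net$edges |> dplyr::distinct(.data$region,
                                             gene = .data$target)
  res_full <- capture_concordance(net, full_pairs)
  expect_equal(res_full$fraction_regions, 1)
  expect_equal(res_full$fraction_edges, 1)
})
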