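#' Simulation configuration
#'
#' Defines the study conditions the synthetic bundle emulates: three
#' primate species sampled in two age groups across several cell types,
#' with planted species- and age-specific log2 fold-change effects on a
#' negative-binomial pseudobulk background. Defaults give the standard
#' validation bundle: 2000 genes, 10 individuals per species per age
#' group, 4 cell types spanning the neural and oligodendrocyte lineages,
#' planted |log2FC| = 1 (comfortably above the 0.5 calling bound).
#'
#' @param n_genes Number of genes.
#' @param n_individuals Individuals per species per age group.
#' @param cell_types Named character vector: names are cell-type labels,
#'   values their lineage tags (`"neural"`, `"OL"`, `"other"`).
#' @param species Species labels; the first is the focal (human) species,
#'   the second the chimpanzee analogue.
#' @param effect_size_lfc Planted |log2FC| (> 0; default 1).
#' @param dispersion_range Log-uniform sampling range for NB dispersions
#'   (`variance = mean + alpha * mean^2`).
#' @param baseline_mean_range Log-uniform range of expected counts at unit
#'   size factor.
#' @param fraction_hiDE,fraction_ciDE Per-cell-type probability that a gene
#'   is planted as human (resp. chimpanzee) infant-specific DE, split
#'   evenly between gains and losses. Must lie in \[0, 0.5).
#' @param fraction_shared_adult Probability of planting a human DE effect
#'   shared by infants and adults (these genes must be excluded from hiDE
#'   by the age-specificity rule).
#' @param size_factor_sdlog SD of the log-normal per-sample size factors.
#' @param n_regulon_edges Total regulon edges across lineages.
#' @param disease_hit_rate Probability that a lineage hiDE gain is planted
#'   as deregulated in that lineage's matched disease (ASD for OL, PD for
#'   neural); the cross-lineage rate is a quarter of this.
#' @param capture_concordance Probability that a retained network
#'   region-target pair is present in the synthetic capture assay.
#' @param seed Integer seed driving every random draw.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_individuals = 10,
                       cell_types = c(L2_3 = "neural", InhN = "neural",
                                      COP = "OL", OPC = "OL"),
                       species = c("human", "chimp", "rhesus"),
                       effect_size_lfc = 1,
                       dispersion_range = c(0.01, 0.2),
                       baseline_mean_range = c(10, 1000),
                       fraction_hiDE = 0.1,
                       fraction_ciDE = 0.1,
                       fraction_shared_adult = 0.05,
                       size_factor_sdlog = 0.2,
                       n_regulon_edges = 120,
                       disease_hit_rate = 0.4,
                       capture_concordance = 0.9,
                       seed = 1L) {
  check_field <- function(ok, field, what) {
    if (!ok) abort(sprintf("invalid sim_config field `%s`: %s", field, what))
  }
  check_field(is.numeric(n_genes) && n_genes >= 10, "n_genes", ">= 10 required")
  check_field(is.numeric(n_individuals) && n_individuals >= 2,
              "n_individuals", ">= 2 required")
  check_field(length(cell_types) >= 1 && !is.null(names(cell_types)) &&
                all(cell_types %in% c("neural", "OL", "other")),
              "cell_types", "named vector with lineage tags neural/OL/other")
  check_field(length(species) == 3 && !anyDuplicated(species),
              "species", "exactly 3 distinct species labels")
  check_field(effect_size_lfc > 0, "effect_size_lfc", "must be > 0")
  check_field(length(dispersion_range) == 2 && all(dispersion_range > 0) &&
                diff(dispersion_range) >= 0,
              "dispersion_range", "increasing pair of positive reals")
  check_field(all(baseline_mean_range > 0) && diff(baseline_mean_range) >= 0,
              "baseline_mean_range", "increasing pair of positive reals")
  for (f in c("fraction_hiDE", "fraction_ciDE", "fraction_shared_adult")) {
    v <- get(f)
    check_field(is.numeric(v) && v >= 0 && v < 0.5, f, "must lie in [0, 0.5)")
  }
  check_field(fraction_hiDE + fraction_ciDE + fraction_shared_adult < 1,
              "fraction_hiDE", "planted fractions must sum below 1")
  check_field(size_factor_sdlog >= 0, "size_factor_sdlog", "must be >= 0")
  check_field(n_regulon_edges >= 14, "n_regulon_edges", ">= 14 required")
  check_field(disease_hit_rate > 0 && disease_hit_rate <= 1,
              "disease_hit_rate", "must lie in (0, 1]")
  check_field(capture_concordance >= 0 && capture_concordance <= 1,
              "capture_concordance", "must lie in [0, 1]")
  check_field(is.numeric(seed) && seed == round(seed) && abs(seed) < 2^31,
              "seed", "must be a 32-bit integer")
  structure(list(
    n_genes = as.integer(n_genes), n_individuals = as.integer(n_individuals),
    cell_types = cell_types, species = species,
    effect_size_lfc = effect_size_lfc, dispersion_range = dispersion_range,
    baseline_mean_range = baseline_mean_range,
    fraction_hiDE = fraction_hiDE, fraction_ciDE = fraction_ciDE,
    fraction_shared_adult = fraction_shared_adult,
    size_factor_sdlog = size_factor_sdlog,
    n_regulon_edges = as.integer(n_regulon_edges),
    disease_hit_rate = disease_hit_rate,
    capture_concordance = capture_concordance,
    seed = as.integer(seed)), class = "sim_config")
}

edge_categories <- c("pass", "fail_node_tf", "fail_node_target",
                     "fail_annot", "fail_tf2g", "fail_r2g", "fail_role")

#' Generate planted ground truth
#'
#' Draws every latent quantity the downstream modules are validated
#' against: per-gene NB baselines and dispersions; per-cell-type gene
#' labels (hiDE, ciDE, adult-shared, null) and the planted log2FC table
#' they imply; a regulon edge table in which every hiDECORE retention rule
#' has edges designed to pass and to fail it; interval annotations
#' (HAR/hINS/hDEL on a synthetic chromosome `chrS`) overlapping roughly
#' half of the regulon regions; planted disease deregulation linked to
#' each lineage; and a capture-assay pair set with known concordance.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_truth"`; see the elements' own tibbles.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  baseline_means <- setNames(exp(runif(
    n, log(config$baseline_mean_range[1]), log(config$baseline_mean_range[2]))),
    genes)
  dispersions <- setNames(exp(runif(
    n, log(config$dispersion_range[1]), log(config$dispersion_range[2]))),
    genes)

  probs <- c(hiDE_gain = config$fraction_hiDE / 2,
             hiDE_loss = config$fraction_hiDE / 2,
             ciDE_gain = config$fraction_ciDE / 2,
             ciDE_loss = config$fraction_ciDE / 2,
             shared_adult_gain = config$fraction_shared_adult / 2,
             shared_adult_loss = config$fraction_shared_adult / 2)
  probs <- c(probs, null = 1 - sum(probs))
  assignments <- list_rbind(map(names(config$cell_types), function(ct) {
    lab <- sample(names(probs), n, replace = TRUE, prob = probs)
    tibble(gene = genes, cell_type = ct, label = lab)
  })) |>
    filter(.data$label != "null") |>
    mutate(category = sub("_(gain|loss)$", "", .data$label),
           direction = sub("^.*_", "", .data$label)) |>
    select("gene", "cell_type", "category", "direction")

  E <- config$effect_size_lfc
  human <- config$species[1]
  chimp <- config$species[2]
  lfc_rows <- assignments |>
    mutate(lfc = if_else(.data$direction == "gain", E, -E),
           species = if_else(.data$category == "ciDE", chimp, human))
  planted_lfc <- bind_rows(
    lfc_rows |> mutate(age_group = "infant"),
    lfc_rows |> filter(.data$category == "shared_adult") |>
      mutate(age_group = "adult")) |>
    select("gene", "species", "age_group", "cell_type", "lfc")

  lineage_of <- config$cell_types
  hide_gains <- map(c(neural = "neural", OL = "OL"), function(lin) {
    cts <- names(lineage_of)[lineage_of == lin]
    assignments |>
      filter(.data$cell_type %in% cts, .data$category == "hiDE",
             .data$direction == "gain") |>
      pull(.data$gene) |>
      unique() |>
      sort()
  })
  hide_gains <- hide_gains[lengths(hide_gains) > 0]

  regulons <- simulate_regulon_truth(config, genes, assignments, hide_gains)
  regions <- regulons$regions
  edges <- regulons$edges
  annotation_truth <- regulons$annotation_truth

  disease_truth <- simulate_disease_truth(config, genes, hide_gains)

  capture <- simulate_capture_truth(config, edges, annotation_truth)

  structure(list(
    config = config,
    genes = genes,
    baseline_means = baseline_means,
    dispersions = dispersions,
    assignments = assignments,
    planted_lfc = planted_lfc,
    hide_gains = hide_gains,
    regulon_edges = edges,
    regions = regions,
    annotation_truth = annotation_truth,
    disease_truth = disease_truth,
    capture_pairs = capture$pairs,
    capture_tested_regions = capture$tested),
    class = "sim_truth")
}

# Regulon edges designed so each hiDECORE retention rule has passing and
# failing representatives; regions live on chrS, ~half annotated.
simulate_regulon_truth <- function(config, genes, assignments, hide_gains) {
  lineages <- names(hide_gains)
  if (!length(lineages)) {
    abort("no lineage has planted hiDE gains; increase fraction_hiDE")
  }
  per_lineage <- ceiling(config$n_regulon_edges / length(lineages))
  all_edges <- list()
  region_counter <- 0L
  for (lin in lineages) {
    gains <- hide_gains[[lin]]
    non_gains <- setdiff(genes, gains)
    if (length(gains) < 4) abort("too few hiDE gains to build regulons")
    tf_pool <- head(gains, max(4, min(8, length(gains) %/% 4)))
    target_pool <- setdiff(gains, tf_pool)
    if (!length(target_pool)) target_pool <- gains
    cats <- c(edge_categories,
              sample(edge_categories, per_lineage - length(edge_categories),
                     replace = TRUE,
                     prob = c(0.4, 0.08, 0.12, 0.1, 0.1, 0.1, 0.1)))
    k <- length(cats)
    # regulon-tool convention: region identifiers carry their own
    # half-open coordinates
    reg_start <- (region_counter + seq_len(k) - 1L) * 1000L + 100L
    region_ids <- sprintf("chrS:%d-%d", reg_start, reg_start + 400L)
    region_counter <- region_counter + k
    tf <- sample(tf_pool, k, replace = TRUE)
    target <- sample(target_pool, k, replace = TRUE)
    tf[cats == "fail_node_tf"] <-
      sample(non_gains, sum(cats == "fail_node_tf"), replace = TRUE)
    target[cats == "fail_node_target"] <-
      sample(non_gains, sum(cats == "fail_node_target"), replace = TRUE)
    tf2g <- runif(k, 0.2, 0.9)
    tf2g[cats == "fail_tf2g"] <- -runif(sum(cats == "fail_tf2g"), 0.2, 0.9)
    r2g <- runif(k, 0.2, 0.9)
    r2g[cats == "fail_r2g"] <- -runif(sum(cats == "fail_r2g"), 0.2, 0.9)
    role <- ifelse(cats == "fail_role", "repressor", "activator")
    annotated <- cats != "fail_annot"
    node_fail <- cats %in% c("fail_node_tf", "fail_node_target")
    # node-rule failures don't need an annotated region; randomise those so
    # roughly half of all regions end up annotated
    annotated[node_fail] <- runif(sum(node_fail)) < 0.5
    all_edges[[lin]] <- tibble(
      edge_id = paste0(lin, "_e", sprintf("%03d", seq_len(k))),
      tf = tf, region = region_ids, target = target,
      tf2g_score = round(tf2g, 4), r2g_score = round(r2g, 4),
      role = role, cell_context = lin,
      design = cats, region_annotated = annotated)
  }
  edges <- list_rbind(all_edges)
  # rule-by-rule truth; pass_all is the designed retention set
  edges <- edges |>
    mutate(
      pass_node = !.data$design %in% c("fail_node_tf", "fail_node_target"),
      pass_annot = .data$region_annotated,
      pass_tf2g = .data$tf2g_score > 0,
      pass_r2g = .data$r2g_score > 0,
      pass_role = .data$role == "activator",
      pass_all = .data$pass_node & .data$pass_annot & .data$pass_tf2g &
        .data$pass_r2g & .data$pass_role)
  regions <- parse_region_ids(edges$region)
  annot_rows <- edges |>
    mutate(chrom = regions$chrom, start = regions$start,
           end = regions$end) |>
    filter(.data$region_annotated)
  classes <- map(seq_len(nrow(annot_rows)), function(i) {
    sample(c("HAR", "hINS", "hDEL"), sample(1:2, 1))
  })
  annotation_truth <- annot_rows |>
    mutate(annotation_class = classes) |>
    select("region_id" = "region", "chrom", "start", "end",
           "annotation_class") |>
    unnest("annotation_class")
  list(edges = edges, regions = regions, annotation_truth = annotation_truth)
}

# Lineage-matched planted disease deregulation: ASD concentrates in the OL
# lineage's hiDE gains, PD in the neural lineage's, with a weaker
# cross-lineage rate and a background of non-planted genes.
simulate_disease_truth <- function(config, genes, hide_gains) {
  rate <- config$disease_hit_rate
  matched <- c(OL = "ASD", neural = "PD")
  rows <- list()
  for (lin in names(hide_gains)) {
    gains <- hide_gains[[lin]]
    for (dis in c("ASD", "PD")) {
      r <- if (identical(matched[[lin]], dis)) rate else rate / 4
      hit <- gains[runif(length(gains)) < r]
      if (length(hit)) {
        rows[[paste(lin, dis)]] <- tibble(
          gene = hit, lineage = lin, disease = dis,
          direction = sample(c("up", "down"), length(hit), replace = TRUE))
      }
    }
  }
  planted <- unique(unlist(hide_gains))
  background_pool <- setdiff(genes, planted)
  n_bg <- min(length(background_pool), 200L)
  bg <- sample(background_pool, n_bg)
  rows[["background"]] <- tibble(
    gene = bg,
    lineage = sample(c("OL", "neural"), n_bg, replace = TRUE),
    disease = sample(c("ASD", "PD"), n_bg, replace = TRUE),
    direction = sample(c("up", "down"), n_bg, replace = TRUE))
  list_rbind(rows) |> distinct(.data$gene, .data$lineage, .data$disease,
                               .keep_all = TRUE)
}

# Capture assay truth over the designed retention set: every annotated
# retained region is "tested"; each region-target pair is captured with
# probability capture_concordance.
simulate_capture_truth <- function(config, edges, annotation_truth) {
  retained <- edges |>
    filter(.data$pass_all, .data$region %in% annotation_truth$region_id)
  tested <- unique(retained$region)
  keep <- runif(nrow(retained)) < config$capture_concordance
  pairs <- retained[keep, c("region", "target")] |>
    rename(gene = "target") |>
    distinct()
  # decoy pairs so the capture table is not a subset of the network
  if (nrow(retained)) {
    decoys <- tibble(region = sample(tested, min(10, length(tested)),
                                     replace = TRUE),
                     gene = sample(edges$tf, min(10, length(tested)),
                                   replace = TRUE))
    pairs <- distinct(bind_rows(pairs, decoys))
  }
  list(pairs = pairs, tested = tested)
}

#' Simulate pseudobulk counts from planted truth
#'
#' Counts are drawn per gene and sample from
#' `NB(mean = baseline * 2^planted_lfc * size_factor, dispersion)`, with
#' log-normal per-sample size factors. One sample per (species, age group,
#' individual, cell type); individuals are distinct between age groups
#' (cross-sectional design). Deterministic given the config seed.
#'
#' @param truth A [generate_truth()] result.
#' @param config The matching [sim_config()]; defaults to the one stored
#'   in `truth`.
#' @return A [pseudobulk_matrix()] whose `sample_meta` carries the true
#'   `size_factor` column.
#' @export
simulate_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!identical(config$n_genes, truth$config$n_genes) ||
      !identical(config$cell_types, truth$config$cell_types) ||
      !identical(config$species, truth$config$species)) {
    abort("config dimensions do not match the truth object")
  }
  set.seed(config$seed + 1L)
  grid <- crossing(species = config$species,
                   age_group = c("infant", "adult"),
                   idx = seq_len(config$n_individuals),
                   cell_type = names(config$cell_types)) |>
    mutate(individual = sprintf("%s_%s_%02d", .data$species,
                                .data$age_group, .data$idx),
           sample_id = paste(.data$individual, .data$cell_type, sep = "__"))
  sf <- rlnorm(nrow(grid), 0, config$size_factor_sdlog)
  mu <- truth$baseline_means %o% sf
  dimnames(mu) <- list(truth$genes, grid$sample_id)
  planted <- truth$planted_lfc |>
    group_by(.data$species, .data$age_group, .data$cell_type) |>
    summarise(gene = list(.data$gene), lfc = list(.data$lfc), .groups = "drop")
  for (i in seq_len(nrow(planted))) {
    cols <- grid$species == planted$species[i] &
      grid$age_group == planted$age_group[i] &
      grid$cell_type == planted$cell_type[i]
    g <- planted$gene[[i]]
    mu[g, cols] <- mu[g, cols] * 2^planted$lfc[[i]]
  }
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = rep(1 / truth$dispersions, ncol(mu))),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  meta <- grid |>
    mutate(size_factor = sf) |>
    select("sample_id", "species", "age_group", "individual", "cell_type",
           "size_factor")
  pseudobulk_matrix(counts, meta)
}

#' Split pseudobulk columns into synthetic cells
#'
#' Multinomial split of each pseudobulk sample into `cells_per_sample`
#' equal-probability cells; summing the cells back recovers the original
#' column exactly. Exists to exercise [aggregate_pseudobulk()].
#'
#' @param pb A `pseudobulk` object.
#' @param cells_per_sample Cells per pseudobulk sample (default 20).
#' @param seed Optional seed.
#' @return List with `counts` (genes x cells) and `cell_meta`.
#' @export
simulate_cells <- function(pb, cells_per_sample = 20, seed = NULL) {
  stopifnot(inherits(pb, "pseudobulk"))
  with_seed(seed, {
    k <- cells_per_sample
    pieces <- map(seq_len(ncol(pb$counts)), function(j) {
      y <- pb$counts[, j]
      cells <- vapply(y, function(yy) rmultinom(1, yy, rep(1 / k, k))[, 1],
                      integer(k))
      m <- t(cells)
      colnames(m) <- paste0(colnames(pb$counts)[j], "_c", seq_len(k))
      m
    })
    counts <- do.call(cbind, pieces)
    cell_meta <- pb$sample_meta[rep(seq_len(nrow(pb$sample_meta)), each = k), ] |>
      mutate(cell_id = colnames(counts)) |>
      select("cell_id", "individual", "cell_type", "species", "age_group")
    list(counts = counts, cell_meta = cell_meta)
  })
}

#' Emit the public regulon edge table
#'
#' The columns a regulon inference tool would hand downstream; the hidden
#' design/truth columns stay in `truth$regulon_edges`.
#'
#' @param truth A `sim_truth`.
#' @return Tibble `edge_id`, `tf`, `region`, `target`, `tf2g_score`,
#'   `r2g_score`, `role`, `cell_context`.
#' @export
simulate_regulons <- function(truth) {
  truth$regulon_edges[, c("edge_id", "tf", "region", "target", "tf2g_score",
                          "r2g_score", "role", "cell_context")]
}

#' Emit interval annotations (BED-style tibble)
#'
#' One interval per (annotated region, class), placed inside the region it
#' is designed to overlap, on the synthetic chromosome `chrS`. Coordinates
#' are 0-based half-open.
#'
#' @param truth A `sim_truth`.
#' @return Tibble `chrom`, `start`, `end`, `annotation_class`, `source`.
#' @export
simulate_annotations <- function(truth) {
  truth$annotation_truth |>
    transmute(chrom = .data$chrom,
              start = .data$start + 100L,
              end = .data$start + 300L,
              annotation_class = .data$annotation_class,
              source = paste0(.data$annotation_class, "_set"))
}

#' Emit the patient differential-expression table
#'
#' One row per planted (gene, lineage, disease) deregulation event, with a
#' log2FC whose sign matches the planted direction and an FDR below 0.05.
#'
#' @param truth A `sim_truth`.
#' @param seed Optional seed for the nuisance columns (defaults to the
#'   config seed offset so the bundle stays deterministic).
#' @return Tibble `gene`, `disease`, `cell_type` (lineage label),
#'   `direction`, `log2fc`, `fdr`.
#' @export
simulate_disease_tables <- function(truth, seed = truth$config$seed + 2L) {
  dt <- truth$disease_truth
  with_seed(seed, {
    tibble(gene = dt$gene, disease = dt$disease, cell_type = dt$lineage,
           direction = dt$direction,
           log2fc = round(ifelse(dt$direction == "up", 1, -1) *
                            runif(nrow(dt), 0.6, 2.5), 4),
           fdr = round(runif(nrow(dt), 1e-6, 0.04), 6))
  })
}

#' Simulate a disease risk-gene list with planted enrichment
#'
#' Builds a gene list whose membership rate among a given set of "planted"
#' genes is `enrichment` times the background rate, sized so the expected
#' list length is `list_size`. Used to validate the overrepresentation
#' statistics against a known effect.
#'
#' @param universe All gene identifiers.
#' @param planted The genes carrying the enrichment (e.g. hiDE gains of a
#'   cell type).
#' @param enrichment Rate ratio planted vs background (default 3).
#' @param list_size Expected list size (default 100).
#' @param seed Optional seed.
#' @return Character vector of list members.
#' @export
simulate_risk_set <- function(universe, planted, enrichment = 3,
                              list_size = 100, seed = NULL) {
  planted <- intersect(planted, universe)
  with_seed(seed, {
    G <- length(planted)
    N <- length(universe)
    p0 <- list_size / (N + (enrichment - 1) * G)
    p <- ifelse(universe %in% planted, pmin(1, enrichment * p0), p0)
    universe[runif(N) < p]
  })
}

#' Simulate a full fixture bundle
#'
#' One-shot generation of every synthetic input the pipeline consumes.
#'
#' @param config A [sim_config()].
#' @return List of class `"sim_bundle"`: `truth`, `pseudobulk`,
#'   `regulons`, `annotations`, `disease_de`, `capture_pairs`, `config`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  truth <- generate_truth(config)
  structure(list(
    truth = truth,
    pseudobulk = simulate_counts(truth, config),
    regulons = simulate_regulons(truth),
    annotations = simulate_annotations(truth),
    disease_de = simulate_disease_tables(truth),
    capture_pairs = truth$capture_pairs,
    config = config), class = "sim_bundle")
}
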