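#' Parse coordinate-carrying region identifiers
#'
#' Regulon tools commonly name accessible-chromatin regions by their
#' coordinates, `chrom:start-end` with 0-based half-open positions. This
#' turns such identifiers into an interval tibble ready for
#' [annotate_regions()].
#'
#' @param ids Character vector of `chrom:start-end` identifiers.
#' @return Tibble `region_id`, `chrom`, `start`, `end`.
#' @export
parse_region_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- lengths(m) != 4
  if (any(bad)) {
    abort(paste0("region id(s) not in chrom:start-end form: ",
                 paste(head(ids[bad], 5), collapse = ", ")))
  }
  tibble(region_id = ids,
         chrom = map_chr(m, 2),
         start = as.integer(map_chr(m, 3)),
         end = as.integer(map_chr(m, 4)))
}

#' Annotate regulatory regions with overlapping interval classes
#'
#' Intersects regulon regions with HAR/hINS/hDEL annotation intervals.
#' Coordinates are 0-based half-open on both sides; two features overlap
#' iff they share at least one base, i.e. `region.start < interval.end`
#' and `interval.start < region.end`. The sweep is delegated to the
#' interval tree machinery of `GenomicRanges`; chromosomes present in one
#' input only yield a warning and no matches.
#'
#' @param regions Tibble `region_id`, `chrom`, `start`, `end` (half-open).
#' @param annotations Tibble `chrom`, `start`, `end`, `annotation_class`
#'   (values `HAR`, `hINS`, `hDEL`).
#' @return Tibble `region_id`, `classes` (list column of character
#'   vectors, `character(0)` for unannotated regions), `n_classes`. One
#'   row per input region, input order preserved.
#' @export
annotate_regions <- function(regions, annotations) {
  stopifnot(all(c("region_id", "chrom", "start", "end") %in% names(regions)),
            all(c("chrom", "start", "end", "annotation_class") %in%
                  names(annotations)))
  if (any(regions$start >= regions$end) ||
      any(annotations$start >= annotations$end)) {
    abort("intervals must satisfy start < end (0-based half-open)")
  }
  bad_class <- setdiff(unique(annotations$annotation_class),
                       c("HAR", "hINS", "hDEL"))
  if (length(bad_class)) {
    abort(paste0("unknown annotation class: ", paste(bad_class, collapse = ", ")))
  }
  only_r <- setdiff(unique(regions$chrom), unique(annotations$chrom))
  only_a <- setdiff(unique(annotations$chrom), unique(regions$chrom))
  if (length(only_r) || length(only_a)) {
    warn(paste0("chromosome(s) present in one input only: ",
                paste(c(only_r, only_a), collapse = ", ")))
  }
  classes <- rep(list(character(0)), nrow(regions))
  if (nrow(annotations) > 0 && nrow(regions) > 0) {
    # half-open -> 1-based closed for IRanges: [start+1, end]
    gr_r <- GRanges(regions$chrom, IRanges(regions$start + 1, regions$end))
    gr_a <- GRanges(annotations$chrom,
                    IRanges(annotations$start + 1, annotations$end))
    hits <- suppressWarnings(findOverlaps(gr_r, gr_a, minoverlap = 1))
    if (length(hits)) {
      by_region <- split(annotations$annotation_class[subjectHits(hits)],
                         queryHits(hits))
      idx <- as.integer(names(by_region))
      classes[idx] <- map(by_region, function(x) sort(unique(x)))
    }
  }
  tibble(region_id = regions$region_id, classes = classes,
         n_classes = lengths(classes))
}

hidecore_rules <- c("node", "annot", "tf2g", "r2g", "role")

#' Build the hiDECORE network for one lineage
#'
#' Filters regulon edges down to the human infant DE core: an edge
#' TF -> region -> target is retained iff both the TF and the target are
#' hiDE expression gains in the lineage (node rule), the mediating region
#' overlaps at least one human-specific sequence change (HAR/hINS/hDEL),
#' the TF-to-gene and region-to-gene scores are both positive, and the
#' regulon is an activator. Each excluded edge is attributed to its first
#' failing rule in the fixed order (node, annot, tf2g, r2g, role), so the
#' provenance counts always sum to the number of edges considered.
#'
#' @param edges Regulon edge tibble (`tf`, `region`, `target`,
#'   `tf2g_score`, `r2g_score`, `role`, `cell_context`). Only rows with
#'   `cell_context == lineage` are considered when the column is present.
#' @param hide_gains Character vector: hiDE expression gains of the
#'   lineage.
#' @param region_annotation Result of [annotate_regions()] (or tibble
#'   `region_id`, `classes`).
#' @param lineage Lineage label for the network.
#' @param universe Optional gene universe; edges whose TF or target is
#'   absent are excluded before the rules and counted separately.
#' @param rules Which retention rules to apply (default all of
#'   `"node"`, `"annot"`, `"tf2g"`, `"r2g"`, `"role"`). Disabling a rule
#'   can only grow the network; exists for sensitivity analyses.
#' @return Object of class `"hidecore_network"`: `lineage`, `edges`
#'   (retained, with `annotation_classes` list column), `nodes` (`gene`,
#'   `kind` TF/target/both, `disease_status` initialised `"none"`),
#'   `provenance` (rule failure counts), `n_input`,
#'   `n_outside_universe`.
#' @export
build_hidecore <- function(edges, hide_gains, region_annotation, lineage,
                           universe = NULL, rules = hidecore_rules) {
  rules <- match.arg(rules, hidecore_rules, several.ok = TRUE)
  edges <- as_tibble(edges)
  if ("cell_context" %in% names(edges)) {
    edges <- filter(edges, .data$cell_context == lineage)
  }
  n_input <- nrow(edges)
  n_outside <- 0L
  if (!is.null(universe)) {
    outside <- !(edges$tf %in% universe) | !(edges$target %in% universe)
    n_outside <- sum(outside)
    edges <- edges[!outside, , drop = FALSE]
  }
  ann <- setNames(region_annotation$classes, region_annotation$region_id)
  edge_classes <- ann[edges$region]
  edge_classes[map_lgl(edge_classes, is.null)] <- list(character(0))
  pass <- tibble(
    node = edges$tf %in% hide_gains & edges$target %in% hide_gains,
    annot = lengths(edge_classes) > 0,
    tf2g = edges$tf2g_score > 0,
    r2g = edges$r2g_score > 0,
    role = edges$role == "activator")
  active <- hidecore_rules[hidecore_rules %in% rules]
  retained <- Reduce(`&`, pass[active], rep(TRUE, nrow(edges)))
  first_fail <- rep(NA_character_, nrow(edges))
  remaining <- !retained
  for (rule in active) {
    hit <- remaining & !pass[[rule]]
    first_fail[hit] <- rule
    remaining <- remaining & !hit
  }
  provenance <- tibble(
    rule = active,
    n_failed = map_int(active, function(r)
      sum(first_fail == r, na.rm = TRUE)))
  kept <- edges[retained, , drop = FALSE] |>
    mutate(annotation_classes = edge_classes[retained])
  if (any(kept$tf == kept$target)) {
    warn(sprintf("%d retained self-loop edge(s) (tf == target)",
                 sum(kept$tf == kept$target)))
  }
  node_tbl <- bind_rows(tibble(gene = kept$tf, is_tf = TRUE),
                        tibble(gene = kept$target, is_tf = FALSE)) |>
    group_by(.data$gene) |>
    summarise(kind = if (all(.data$is_tf)) "TF"
              else if (all(!.data$is_tf)) "target" else "both",
              .groups = "drop") |>
    mutate(disease_status = "none")
  structure(list(lineage = lineage, edges = kept, nodes = node_tbl,
                 provenance = provenance, n_input = n_input,
                 n_outside_universe = n_outside),
            class = "hidecore_network")
}

#' @export
print.hidecore_network <- function(x, ...) {
  cat(sprintf("hiDECORE network [%s]: %d edges retained of %d (%d nodes)\n",
              x$lineage, nrow(x$edges), x$n_input, nrow(x$nodes)))
  pf <- x$provenance
  cat("  failures by first rule:",
      paste(sprintf("%s=%d", pf$rule, pf$n_failed), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname build_hidecore
#' @param x A `hidecore_network`.
#' @param ... Unused.
#' @export
tidy.hidecore_network <- function(x, ...) {
  x$edges |>
    mutate(lineage = x$lineage,
           annotation = map_chr(.data$annotation_classes, paste,
                                collapse = ";")) |>
    select(any_of(c("lineage", "edge_id", "tf", "region", "target",
                    "tf2g_score", "r2g_score", "annotation")))
}

#' @rdname build_hidecore
#' @export
glance.hidecore_network <- function(x, ...) {
  tibble(lineage = x$lineage, n_edges = nrow(x$edges),
         n_nodes = nrow(x$nodes),
         n_tfs = sum(x$nodes$kind != "target"),
         n_input = x$n_input,
         n_outside_universe = x$n_outside_universe)
}

network_genes <- function(net) sort(unique(net$nodes$gene))

#' Gene overlap between two lineage networks
#'
#' Jaccard-style overlap of the node sets plus a hypergeometric
#' enrichment of the intersection against a stated gene universe.
#'
#' @param net_a,net_b `hidecore_network` objects.
#' @param universe Character vector of genes eligible for either network
#'   (the DE universe).
#' @return One-row tibble: sizes, `overlap_fraction`
#'   (|A n B| / |A u B|), per-lineage fractions, `odds_ratio`, `p_value`
#'   (upper-tail hypergeometric).
#' @export
lineage_overlap_stats <- function(net_a, net_b, universe) {
  ga <- network_genes(net_a)
  gb <- network_genes(net_b)
  universe <- unique(universe)
  if (!all(c(ga, gb) %in% universe)) {
    abort("universe must contain every network gene")
  }
  k <- length(intersect(ga, gb))
  u <- length(union(ga, gb))
  N <- length(universe)
  a <- k; b <- length(ga) - k; cc <- length(gb) - k; dd <- N - a - b - cc
  tibble(
    lineage_a = net_a$lineage, lineage_b = net_b$lineage,
    n_a = length(ga), n_b = length(gb), n_overlap = k,
    overlap_fraction = if (u == 0) NA_real_ else k / u,
    fraction_of_a = if (length(ga)) k / length(ga) else NA_real_,
    fraction_of_b = if (length(gb)) k / length(gb) else NA_real_,
    odds_ratio = if ((a * dd) == 0 && (b * cc) == 0) NaN
                 else if ((b * cc) == 0) Inf else (a * dd) / (b * cc),
    p_value = hypergeom_upper_tail(k, length(ga), length(gb), N))
}

#' Annotate network nodes with patient-disease status
#'
#' Marks each node `ASD`, `PD`, `both`, or `none` according to
#' lineage-matched membership in the patient DE tables: a gene counts as
#' deregulated only if the patient-table label maps to this network's
#' lineage.
#'
#' @param network A `hidecore_network`.
#' @param patient_de Tibble `gene`, `disease` (ASD/PD), `cell_type`
#'   (disease-dataset label), `direction`, ...
#' @param lineage_map Tibble `lineage`, `disease_label` mapping network
#'   lineages to patient-table labels. Defaults to the identity map for
#'   this network's lineage.
#' @return The network with `nodes$disease_status` filled in and a
#'   `status_counts` element (tibble `disease_status`, `n`).
#' @export
annotate_disease <- function(network, patient_de,
                             lineage_map = tibble(lineage = network$lineage,
                                                  disease_label = network$lineage)) {
  labels <- lineage_map$disease_label[lineage_map$lineage == network$lineage]
  matched <- patient_de |> filter(.data$cell_type %in% labels)
  asd <- unique(matched$gene[matched$disease == "ASD"])
  pd <- unique(matched$gene[matched$disease == "PD"])
  network$nodes <- network$nodes |>
    mutate(disease_status = case_when(
      .data$gene %in% asd & .data$gene %in% pd ~ "both",
      .data$gene %in% asd ~ "ASD",
      .data$gene %in% pd ~ "PD",
      TRUE ~ "none"))
  network$status_counts <- count(network$nodes, .data$disease_status, name = "n")
  network
}

#' Lineage-by-disease Fisher enrichment
#'
#' The stacked-bar statistic: does one lineage's network carry a higher
#' fraction of disease-deregulated genes than the other? Builds the 2x2
#' table (rows = lineages, columns = disease-hit vs not) over network
#' genes, or over TFs only, and reports the unconditional odds ratio with
#' one- and two-sided exact p-values. Both variants exist because
#' gene-level and TF-level contrasts answer different questions.
#'
#' @param net_a,net_b Disease-annotated `hidecore_network` objects
#'   ([annotate_disease()] first).
#' @param disease `"ASD"` or `"PD"`; a hit is that status or `"both"`.
#' @param tfs_only Restrict to TF nodes (kind `TF` or `both`).
#' @return One-row tibble with the table cells, `odds_ratio`,
#'   `p_greater`, `p_two_sided`.
#' @export
lineage_disease_enrichment <- function(net_a, net_b, disease = c("ASD", "PD"),
                                       tfs_only = FALSE) {
  disease <- match.arg(disease)
  cells <- function(net) {
    nodes <- net$nodes
    if (tfs_only) nodes <- filter(nodes, .data$kind %in% c("TF", "both"))
    hit <- nodes$disease_status %in% c(disease, "both")
    c(sum(hit), sum(!hit))
  }
  ca <- cells(net_a)
  cb <- cells(net_b)
  tibble(
    disease = disease, tfs_only = tfs_only,
    lineage_a = net_a$lineage, lineage_b = net_b$lineage,
    hit_a = ca[1], miss_a = ca[2], hit_b = cb[1], miss_b = cb[2],
    odds_ratio = odds_ratio(ca[1], ca[2], cb[1], cb[2]),
    p_greater = fisher_exact(ca[1], ca[2], cb[1], cb[2], "greater"),
    p_two_sided = fisher_exact(ca[1], ca[2], cb[1], cb[2], "two.sided"))
}

#' Per-TF disease-hit proportions over network targets
#'
#' For every TF with retained targets: how many targets are deregulated in
#' each disease, the corresponding proportions, and a ranking by the total
#' disease-hit proportion (ties broken by target count, then TF id). TFs
#' without targets are dropped with a warning.
#'
#' @param network A disease-annotated `hidecore_network`.
#' @return Tibble `tf`, `n_targets`, `n_asd`, `n_pd`, `prop_asd`,
#'   `prop_pd`, `prop_total`, `rank`.
#' @export
per_tf_disease_proportions <- function(network) {
  status <- setNames(network$nodes$disease_status, network$nodes$gene)
  tab <- network$edges |>
    distinct(.data$tf, .data$target) |>
    mutate(st = unname(status[.data$target])) |>
    group_by(.data$tf) |>
    summarise(n_targets = n(),
              n_asd = sum(.data$st %in% c("ASD", "both")),
              n_pd = sum(.data$st %in% c("PD", "both")),
              .groups = "drop") |>
    mutate(prop_asd = .data$n_asd / .data$n_targets,
           prop_pd = .data$n_pd / .data$n_targets,
           prop_total = (.data$n_asd + .data$n_pd) / .data$n_targets)
  all_tfs <- unique(network$nodes$gene[network$nodes$kind != "target"])
  no_targets <- setdiff(all_tfs, tab$tf)
  if (length(no_targets)) {
    warn(paste0("TF(s) without retained targets excluded: ",
                paste(no_targets, collapse = ", ")))
  }
  tab |>
    arrange(desc(.data$prop_total), desc(.data$n_targets), .data$tf) |>
    mutate(rank = row_number())
}

#' Concordance of network region-target links with a capture assay
#'
#' Restricts the network's region -> target pairs to regions present in
#' the capture assay's tested set, then reports the fraction of tested
#' regions with at least one captured target and the fraction of
#' region-target pairs confirmed by the assay.
#'
#' @param network A `hidecore_network`.
#' @param capture_pairs Tibble `region`, `gene`: interactions observed in
#'   the capture assay.
#' @param tested_regions Regions assayed (default: regions appearing in
#'   `capture_pairs`).
#' @return One-row tibble: `n_regions_tested`, `n_regions_matched`,
#'   `fraction_regions`, `n_pairs`, `n_pairs_matched`, `fraction_edges`.
#' @export
capture_concordance <- function(network, capture_pairs,
                                tested_regions = unique(capture_pairs$region)) {
  if (!length(tested_regions)) abort("empty capture set: no tested regions")
  net_pairs <- network$edges |>
    distinct(.data$region, gene = .data$target) |>
    filter(.data$region %in% tested_regions)
  if (nrow(net_pairs) == 0) {
    warn("no network region overlaps the capture assay's tested set")
    return(tibble(n_regions_tested = 0L, n_regions_matched = 0L,
                  fraction_regions = NA_real_, n_pairs = 0L,
                  n_pairs_matched = 0L, fraction_edges = NA_real_))
  }
  matched_pairs <- semi_join(net_pairs, capture_pairs, by = c("region", "gene"))
  regions <- unique(net_pairs$region)
  regions_matched <- unique(matched_pairs$region)
  tibble(n_regions_tested = length(regions),
         n_regions_matched = length(regions_matched),
         fraction_regions = length(regions_matched) / length(regions),
         n_pairs = nrow(net_pairs),
         n_pairs_matched = nrow(matched_pairs),
         fraction_edges = nrow(matched_pairs) / nrow(net_pairs))
}
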