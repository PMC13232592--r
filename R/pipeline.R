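#' Pipeline configuration
#'
#' Validated bag of thresholds, seeds and paths for [run_pipeline()].
#' Unknown keys are rejected so typos never silently fall back to
#' defaults.
#'
#' @param out_dir Output directory for stage tables and the run log.
#' @param sim A [sim_config()] describing the synthetic bundle to analyse
#'   (the pipeline's input stage).
#' @param lfc_threshold,fdr_threshold DE calling rule (strict bounds;
#'   defaults 0.5 and 0.05).
#' @param min_cells Minimum cells per pseudobulk group when aggregating
#'   cell-level input (default 10).
#' @param set_logic `"both"` (a species-specific call needs both pairwise
#'   contrasts) or `"either"`.
#' @param seed Integer master seed for stage-level randomness (module
#'   score backgrounds).
#' @param ... Reserved; any unnamed or unknown argument errors.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("hidecore_run_"),
                            sim = sim_config(),
                            lfc_threshold = 0.5,
                            fdr_threshold = 0.05,
                            min_cells = 10,
                            set_logic = c("both", "either"),
                            seed = 1L, ...) {
  extras <- list(...)
  if (length(extras)) {
    abort(paste0("unknown pipeline_config key(s): ",
                 paste(names(extras), collapse = ", ")))
  }
  if (!inherits(sim, "sim_config")) abort("`sim` must be a sim_config()")
  if (!is.numeric(lfc_threshold) || lfc_threshold < 0) {
    abort("lfc_threshold must be >= 0")
  }
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold > 1) {
    abort("fdr_threshold must lie in (0, 1]")
  }
  if (!is.numeric(min_cells) || min_cells < 1) abort("min_cells must be >= 1")
  set_logic <- match.arg(set_logic)
  if (!is.numeric(seed) || seed != round(seed)) abort("seed must be integer")
  structure(list(out_dir = out_dir, sim = sim,
                 lfc_threshold = lfc_threshold,
                 fdr_threshold = fdr_threshold,
                 min_cells = min_cells, set_logic = set_logic,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# all four Wald tables needed for one focal species' infant-specific sets
wald_tables_for <- function(pb, focal, others, cell_types) {
  res <- list()
  for (age in c("infant", "adult")) {
    for (other in others) {
      res[[paste(age, other, sep = ".")]] <- list_rbind(
        map(cell_types, function(ct)
          nb_wald_test(pb, ct, age, focal, other)))
    }
  }
  res
}

#' Infant-specific DE sets for a focal species
#'
#' Runs the DE engine for the focal species against both comparison
#' species, in infants and adults, across all cell types, and applies the
#' species-specificity and age-specificity set logic.
#'
#' @param pb A `pseudobulk` object.
#' @param focal Focal species label.
#' @param others The two comparison species.
#' @param lfc_threshold,fdr_threshold Calling rule.
#' @param mode Set logic (see [species_specific_de()]).
#' @return List: `specific` (the infant-specific set), `shared`,
#'   `adult_only`, `infant`, `adult` (species-specific per age), `calls`
#'   (the four raw Wald tables).
#' @export
infant_specific_sets <- function(pb, focal, others,
                                 lfc_threshold = 0.5, fdr_threshold = 0.05,
                                 mode = "both") {
  cts <- unique(pb$sample_meta$cell_type)
  calls <- wald_tables_for(pb, focal, others, cts)
  sp <- function(age) {
    species_specific_de(calls[[paste(age, others[1], sep = ".")]],
                        calls[[paste(age, others[2], sep = ".")]],
                        lfc_threshold, fdr_threshold, mode = mode)
  }
  infant <- sp("infant")
  adult <- sp("adult")
  out <- age_specific_sets(infant, adult)
  out$infant <- infant
  out$adult <- adult
  out$calls <- calls
  out
}

#' Run the full analysis pipeline on a synthetic bundle
#'
#' Executes the stages in dependency order — simulate, differential
#' expression, divergence sets, disease intersection, hiDECORE network,
#' module scoring — writing each stage's tables under `out_dir` and a
#' machine-readable run log (`run_log.json`) recording parameters, seeds
#' and output checksums. Re-running with an identical config reproduces
#' identical checksums.
#'
#' @param config A [pipeline_config()].
#' @return List with the in-memory stage results (`bundle`, `hide`,
#'   `cide`, `upset`, `matched`, `directionality`, `networks`,
#'   `enrichment`, `trajectory`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir)) {
    abort(paste0("cannot create out_dir: ", config$out_dir))
  }
  paths <- character()
  emit <- function(tbl, name) {
    p <- file.path(config$out_dir, name)
    readr::write_tsv(tbl, p)
    paths[[name]] <<- p
    p
  }

  # -- simulate ---------------------------------------------------------
  bundle <- simulate_bundle(config$sim)
  pb <- bundle$pseudobulk
  species <- config$sim$species
  lineage_of <- config$sim$cell_types

  # -- de + sets --------------------------------------------------------
  hide <- infant_specific_sets(pb, species[1], species[2:3],
                               config$lfc_threshold, config$fdr_threshold,
                               mode = config$set_logic)
  cide <- infant_specific_sets(pb, species[2], c(species[1], species[3]),
                               config$lfc_threshold, config$fdr_threshold,
                               mode = config$set_logic)
  emit(list_rbind(hide$calls), "de_calls_human.tsv")
  emit(hide$specific, "hide_sets.tsv")
  emit(cide$specific, "cide_sets.tsv")
  upset <- upset_counts(hide$specific)
  emit(upset, "hide_upset.tsv")

  # -- disease intersection --------------------------------------------
  lineage_map <- tibble(evo_cell_type = names(lineage_of),
                        disease_label = unname(lineage_of))
  evo_calls <- bind_rows(
    hide$specific |> mutate(species = species[1]),
    cide$specific |> mutate(species = species[2])) |>
    mutate(category = paste0(.data$species, "_", .data$direction))
  matched <- suppressWarnings(patient_de_scatter(
    evo_calls, bundle$disease_de, lineage_map))
  gains_only <- matched |> filter(grepl("_gain$", .data$category))
  directionality <- if (nrow(gains_only)) {
    suppressWarnings(directionality_contingency(gains_only))
  } else NULL
  if (!is.null(directionality) && nrow(directionality$results)) {
    emit(directionality$results, "directionality.tsv")
  }

  # -- hidecore ---------------------------------------------------------
  regions <- parse_region_ids(unique(bundle$regulons$region))
  region_annotation <- annotate_regions(
    regions, bundle$annotations)
  gains_by_lineage <- map(
    setNames(unique(unname(lineage_of)), unique(unname(lineage_of))),
    function(lin) {
      cts <- names(lineage_of)[lineage_of == lin]
      unique(hide$specific$gene[hide$specific$cell_type %in% cts &
                                  hide$specific$direction == "gain"])
    })
  networks <- list()
  for (lin in intersect(c("OL", "neural"), names(gains_by_lineage))) {
    net <- build_hidecore(bundle$regulons, gains_by_lineage[[lin]],
                          region_annotation, lin,
                          universe = rownames(pb$counts))
    net <- annotate_disease(net, bundle$disease_de)
    networks[[lin]] <- net
    write_network(net, file.path(config$out_dir,
                                 paste0("hidecore_", lin, ".json")))
    paths[[paste0("hidecore_", lin, ".json")]] <-
      file.path(config$out_dir, paste0("hidecore_", lin, ".json"))
  }
  enrichment <- NULL
  if (all(c("OL", "neural") %in% names(networks))) {
    enrichment <- bind_rows(
      lineage_disease_enrichment(networks$OL, networks$neural, "ASD"),
      lineage_disease_enrichment(networks$neural, networks$OL, "PD"))
    emit(enrichment, "lineage_disease_enrichment.tsv")
  }

  # -- module scoring ---------------------------------------------------
  trajectory <- NULL
  neural_gains <- gains_by_lineage[["neural"]] %||% character(0)
  if (length(neural_gains) >= 3) {
    expr <- log1p(sweep(pb$counts, 2, size_factors(pb$counts), "/"))
    meta <- pb$sample_meta |>
      transmute(nucleus = .data$sample_id, age_group = .data$age_group)
    trajectory <- suppressWarnings(module_trajectory_table(
      neural_gains, expr, meta, seed = config$seed))
    emit(trajectory$group_means, "module_trajectory.tsv")
  }

  manifest <- tibble(file = names(paths),
                     md5 = unname(tools::md5sum(unlist(paths))))
  run_log <- list(
    parameters = list(lfc_threshold = config$lfc_threshold,
                      fdr_threshold = config$fdr_threshold,
                      set_logic = config$set_logic,
                      min_cells = config$min_cells,
                      seed = config$seed,
                      sim = unclass(config$sim)),
    outputs = manifest)
  jsonlite::write_json(run_log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  list(bundle = bundle, hide = hide, cide = cide, upset = upset,
       matched = matched, directionality = directionality,
       networks = networks, enrichment = enrichment,
       trajectory = trajectory, manifest = manifest)
}
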