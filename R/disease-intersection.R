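#' Risk-gene overrepresentation across a cell-type grid
#'
#' For every (cell type, direction) DE set and every disease risk-gene
#' list: the overlap, unconditional odds ratio, upper-tail hypergeometric
#' p against that cell type's tested universe, the display score, and
#' BH-FDR applied once across the whole (cell type x list) grid within a
#' direction — the dot-plot contract (rows = cell types, columns =
#' diseases). Risk genes absent from a universe are dropped from K, with
#' the count reported.
#'
#' @param desets Tibble `gene`, `cell_type`, `direction`.
#' @param risk_lists Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Either a character vector used for all cell types, or a
#'   named list keyed by cell type (each must contain its DE set).
#' @return Tibble: `cell_type`, `direction`, `list_name`, `overlap`,
#'   `list_size`, `query_size`, `universe_size`, `odds_ratio`, `p_value`,
#'   `fdr`, `score`, `n_outside_universe`.
#' @export
risk_gene_overrepresentation <- function(desets, risk_lists, universe) {
  stopifnot(all(c("gene", "cell_type", "direction") %in% names(desets)))
  get_universe <- function(ct) {
    if (is.list(universe)) {
      if (is.null(universe[[ct]])) abort(paste0("no universe for cell type ", ct))
      universe[[ct]]
    } else universe
  }
  grid <- desets |> distinct(.data$cell_type, .data$direction)
  rows <- pmap(grid, function(cell_type, direction) {
    genes <- desets$gene[desets$cell_type == cell_type &
                           desets$direction == direction]
    res <- enrich_sets(unique(genes), risk_lists, get_universe(cell_type))
    res$cell_type <- cell_type
    res$direction <- direction
    res
  })
  out <- list_rbind(rows)
  # grid-wide BH within each direction, replacing the per-call adjustment
  out |>
    group_by(.data$direction) |>
    mutate(fdr = bh_fdr(.data$p_value)) |>
    ungroup() |>
    select("cell_type", "direction", "list_name", "overlap", "list_size",
           "query_size", "universe_size", "odds_ratio", "p_value", "fdr",
           "score", "n_outside_universe")
}

#' Match evolutionary DE calls to patient DE on a cell-type basis
#'
#' Inner join of evolutionary DE results and a patient DE table on gene,
#' within explicitly mapped cell types; one output row per (gene,
#' evolutionary cell type, matched disease label). Labels appearing in
#' the inputs but absent from the map trigger a warning with a count —
#' matching is never inferred silently.
#'
#' @param evo_calls Tibble `gene`, `cell_type`, `log2fc` (evolutionary),
#'   plus optional columns carried through (e.g. `direction`, `species`).
#' @param patient_de Tibble `gene`, `cell_type` (disease label),
#'   `disease`, `direction`, `log2fc`, `fdr`.
#' @param lineage_map Tibble `evo_cell_type`, `disease_label`
#'   (many-to-many).
#' @return Tibble `gene`, `evo_cell_type`, `disease_label`, `disease`,
#'   `evo_log2fc`, `disease_log2fc`, `disease_direction`, plus carried
#'   columns.
#' @export
patient_de_scatter <- function(evo_calls, patient_de, lineage_map) {
  stopifnot(all(c("evo_cell_type", "disease_label") %in% names(lineage_map)))
  unmapped_evo <- setdiff(unique(evo_calls$cell_type),
                          lineage_map$evo_cell_type)
  if (length(unmapped_evo)) {
    warn(sprintf("%d evolutionary cell type(s) not in lineage_map: %s",
                 length(unmapped_evo), paste(unmapped_evo, collapse = ", ")))
  }
  unmapped_dis <- setdiff(unique(patient_de$cell_type),
                          lineage_map$disease_label)
  if (length(unmapped_dis)) {
    warn(sprintf("%d patient-table label(s) not in lineage_map: %s",
                 length(unmapped_dis), paste(unmapped_dis, collapse = ", ")))
  }
  evo <- evo_calls |>
    rename(evo_cell_type = "cell_type", evo_log2fc = "log2fc") |>
    inner_join(lineage_map, by = "evo_cell_type",
               relationship = "many-to-many")
  pat <- patient_de |>
    rename(disease_label = "cell_type", disease_log2fc = "log2fc",
           disease_direction = "direction")
  inner_join(evo, pat, by = c("gene", "disease_label"),
             relationship = "many-to-many", suffix = c("_evo", "_disease"))
}

#' Directionality contingency analysis per cell type
#'
#' The directionality heatmap statistic: per evolutionary cell type,
#' cross-tabulates the evolutionary category (by default focal-species
#' gains vs comparison-species gains) against the patient DE direction
#' (up/down) and runs the chi-square test of independence with Pearson
#' residuals. Cell types whose table loses a dimension (an empty row or
#' column leaves fewer than 2 levels) are dropped and reported.
#'
#' @param matched Tibble from [patient_de_scatter()] with an added
#'   `category` column (e.g. `"human_gain"` / `"chimp_gain"`), plus
#'   `evo_cell_type` and `disease_direction`.
#' @return List: `results` tibble (`cell_type`, `statistic`, `df`,
#'   `p_value`, `max_residual`, `max_residual_cell`), `tests` (named list
#'   of `chisq_indep` objects), `dropped` (cell types without a testable
#'   table).
#' @export
directionality_contingency <- function(matched) {
  stopifnot(all(c("evo_cell_type", "category", "disease_direction") %in%
                  names(matched)))
  if (nrow(matched) == 0) abort("matched table is empty")
  cts <- unique(matched$evo_cell_type)
  tests <- list()
  dropped <- character()
  for (ct in cts) {
    sub <- matched[matched$evo_cell_type == ct, ]
    tab <- table(sub$category, sub$disease_direction)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      dropped <- c(dropped, ct)
      next
    }
    tests[[ct]] <- chi_square_independence(unclass(tab))
  }
  if (length(dropped)) {
    warn(paste0("cell type(s) dropped (degenerate table): ",
                paste(dropped, collapse = ", ")))
  }
  results <- list_rbind(imap(tests, function(tst, ct) {
    res <- tst$residuals
    i <- which.max(res)
    tibble(cell_type = ct, statistic = tst$statistic, df = tst$df,
           p_value = tst$p_value,
           max_residual = res[i],
           max_residual_cell = paste(rownames(res)[(i - 1) %% nrow(res) + 1],
                                     colnames(res)[(i - 1) %/% nrow(res) + 1],
                                     sep = "/"))
  }))
  list(results = results, tests = tests, dropped = dropped)
}

#' Module-score trajectory of a DE set across development
#'
#' Scores a gene module ([score_module()]) in every nucleus of a
#' developmental expression matrix, together with a size-matched random
#' background module drawn under the same seed stream, and summarises
#' both per age group.
#'
#' @param module Character vector: the gene set (e.g. hiDE neural gains
#'   deregulated in patients).
#' @param expression Genes x nuclei normalized log expression matrix.
#' @param nucleus_meta Tibble, one row per nucleus (column order matching
#'   the matrix): `nucleus`, `age_group`, optionally `age_years`.
#' @param n_bins,n_ctrl Passed to [score_module()].
#' @param seed Seed; the background module is drawn from it too.
#' @return List of class `"module_trajectory"`: `scores` (per nucleus:
#'   `nucleus`, `age_group`, `age_years?`, `score`, `which`
#'   module/background), `group_means` (`which`, `age_group`, mean, sd,
#'   n), `module`, `background`.
#' @export
module_trajectory_table <- function(module, expression, nucleus_meta,
                                    n_bins = 25, n_ctrl = 50, seed = 1L) {
  stopifnot(all(c("nucleus", "age_group") %in% names(nucleus_meta)),
            nrow(nucleus_meta) == ncol(expression))
  measured <- intersect(unique(module), rownames(expression))
  background <- with_seed(seed, {
    sample(setdiff(rownames(expression), measured), length(measured))
  })
  s_mod <- score_module(expression, measured, n_bins, n_ctrl, seed = seed)
  s_bg <- score_module(expression, background, n_bins, n_ctrl, seed = seed)
  scores <- bind_rows(
    s_mod |> mutate(which = "module"),
    s_bg |> mutate(which = "background")) |>
    left_join(nucleus_meta, by = "nucleus")
  group_means <- scores |>
    group_by(.data$which, .data$age_group) |>
    summarise(mean_score = mean(.data$score), sd_score = sd(.data$score),
              n = n(), .groups = "drop")
  structure(list(scores = scores, group_means = group_means,
                 module = measured, background = background),
            class = "module_trajectory")
}

#' @export
print.module_trajectory <- function(x, ...) {
  cat(sprintf("module trajectory: %d module genes, %d nuclei\n",
              length(x$module), nrow(x$scores) / 2))
  print(x$group_means)
  invisible(x)
}

#' @rdname module_trajectory_table
#' @param x A `module_trajectory`.
#' @param ... Unused.
#' @export
tidy.module_trajectory <- function(x, ...) x$scores

#' @rdname module_trajectory_table
#' @export
glance.module_trajectory <- function(x, ...) {
  wide <- pivot_wider(x$group_means[, c("which", "age_group", "mean_score")],
                      names_from = "which", values_from = "mean_score")
  tibble(n_module_genes = length(x$module),
         n_nuclei = nrow(x$scores) / 2,
         mean_module_score = mean(x$scores$score[x$scores$which == "module"]),
         mean_background_score =
           mean(x$scores$score[x$scores$which == "background"]),
         n_age_groups = nrow(wide))
}
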