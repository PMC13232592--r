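#' Species-specific DE sets from two pairwise contrasts
#'
#' A gene is a focal-species gain in a cell type iff it passes the calling
#' rule as a gain in BOTH pairwise contrasts (focal vs each of the two
#' other species); losses symmetrically. A gene significant in only one
#' contrast, or with conflicting signs, is excluded. An alternative
#' one-vs-pooled-rest mode is available for comparison but the
#' both-contrast rule is the default set logic.
#'
#' @param calls_vs_b,calls_vs_c Wald tables for the focal species versus
#'   the two comparison species (same focal species, age group stratum).
#' @param lfc_threshold,fdr_threshold Passed to [call_de()].
#' @param mode `"both"` (default): intersect the two contrasts.
#'   `"either"`: union (looser; for sensitivity analyses only).
#' @return Tibble `gene`, `cell_type`, `age_group`, `direction`.
#' @export
species_specific_de <- function(calls_vs_b, calls_vs_c,
                                lfc_threshold = 0.5, fdr_threshold = 0.05,
                                mode = c("both", "either")) {
  mode <- match.arg(mode)
  cts_b <- unique(calls_vs_b$cell_type)
  cts_c <- unique(calls_vs_c$cell_type)
  if (!setequal(cts_b, cts_c)) {
    abort(sprintf("mismatched cell types between call tables: %s vs %s",
                  paste(cts_b, collapse = ","), paste(cts_c, collapse = ",")))
  }
  de_b <- call_de(calls_vs_b, lfc_threshold, fdr_threshold)
  de_c <- call_de(calls_vs_c, lfc_threshold, fdr_threshold)
  key <- c("gene", "cell_type", "age_group", "direction")
  out <- switch(mode,
    both = inner_join(de_b[c(key, "log2fc")], de_c[c(key, "log2fc")],
                      by = key, suffix = c("_b", "_c")) |>
      mutate(log2fc = (.data$log2fc_b + .data$log2fc_c) / 2) |>
      select(all_of(key), "log2fc"),
    either = distinct(bind_rows(de_b[c(key, "log2fc")],
                                de_c[c(key, "log2fc")]), .data$gene,
                      .data$cell_type, .data$age_group, .data$direction,
                      .keep_all = TRUE))
  arrange(out, .data$cell_type, .data$direction, .data$gene)
}

#' Age-specific (infant-only) DE sets
#'
#' The hiDE/ciDE construction: an infant species-specific DE gene is
#' age-specific iff it is NOT also species-specific DE in adults in the
#' same cell type and the same direction. A gene gained in infants but
#' lost in adults is retained (the direction differs).
#'
#' @param infant_sets,adult_sets Tibbles from [species_specific_de()] for
#'   the same focal species.
#' @return List of tibbles: `specific` (the hiDE/ciDE set), `shared`
#'   (infant DE also DE in adults, same cell type and direction),
#'   `adult_only`.
#' @export
age_specific_sets <- function(infant_sets, adult_sets) {
  key <- c("gene", "cell_type", "direction")
  list(
    specific = anti_join(infant_sets, adult_sets, by = key),
    shared = semi_join(infant_sets, adult_sets, by = key),
    adult_only = anti_join(adult_sets, infant_sets, by = key))
}

#' Exclusive intersection sizes over cell types (UpSet counts)
#'
#' For each (gene, direction), the membership pattern is the sorted set of
#' cell types in which the gene is DE in that direction; patterns are
#' counted exclusively, so the pattern sizes partition the union of the
#' sets.
#'
#' @param sets Tibble with columns `gene`, `cell_type`, `direction`.
#' @return Tibble `direction`, `pattern` (cell types joined by `"&"`),
#'   `degree` (number of cell types in the pattern), `n`, sorted by
#'   decreasing `n`.
#' @export
upset_counts <- function(sets) {
  stopifnot(all(c("gene", "cell_type", "direction") %in% names(sets)))
  sets |>
    distinct(.data$gene, .data$cell_type, .data$direction) |>
    group_by(.data$gene, .data$direction) |>
    summarise(pattern = paste(sort(unique(.data$cell_type)), collapse = "&"),
              degree = n_distinct(.data$cell_type), .groups = "drop") |>
    count(.data$direction, .data$pattern, .data$degree, name = "n") |>
    arrange(desc(.data$n), .data$pattern)
}

#' Jaccard index of two gene sets
#'
#' |A intersect B| / |A union B|. Two empty sets return 1 by convention,
#' with a warning (the quantity is otherwise 0/0).
#'
#' @param a,b Character vectors.
#' @return Number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0) {
    warn("Jaccard of two empty sets: returning 1 by convention")
    return(1)
  }
  length(intersect(a, b)) / length(u)
}

#' Fraction of run-A DE calls replicated with the same sign in run B
#'
#' Robustness measure for a re-run of the DE analysis (e.g. after adding a
#' sample): of the genes called DE in run A (per cell type), the fraction
#' that are called DE in run B in the same direction.
#'
#' @param calls_a,calls_b Wald tables for the two runs.
#' @param lfc_threshold,fdr_threshold Calling thresholds.
#' @return Tibble `cell_type`, `n_a` (DE calls in A), `n_consistent`,
#'   `consistency` in \[0, 1\].
#' @export
consistency_fraction <- function(calls_a, calls_b,
                                 lfc_threshold = 0.5, fdr_threshold = 0.05) {
  de_a <- call_de(calls_a, lfc_threshold, fdr_threshold)
  de_b <- call_de(calls_b, lfc_threshold, fdr_threshold)
  key <- c("gene", "cell_type", "direction")
  de_a |>
    mutate(consistent = vec_in(de_a[key], de_b[key])) |>
    group_by(.data$cell_type) |>
    summarise(n_a = n(), n_consistent = sum(.data$consistent),
              consistency = mean(.data$consistent), .groups = "drop")
}

# row-wise membership of df rows of `x` in `table` (same columns)
vec_in <- function(x, table) {
  kx <- do.call(paste, c(x, sep = "\r"))
  kt <- do.call(paste, c(table, sep = "\r"))
  kx %in% kt
}

#' Confounder flag tests for a DE set
#'
#' Checks whether a DE gene set is overrepresented in flag lists such as
#' inter-individual highly variable genes, postmortem-interval-associated
#' genes, or sex-associated genes. A high (non-significant) upper-tail
#' hypergeometric p indicates the set is NOT enriched for the confounder.
#' Thin wrapper over [enrich_sets()].
#'
#' @param genes Character vector: the DE set to screen.
#' @param flag_lists Named list of character vectors.
#' @param universe Character vector; defaults should be the genes tested
#'   in the DE run that produced `genes`.
#' @return Tibble from [enrich_sets()].
#' @export
flag_confounders <- function(genes, flag_lists, universe) {
  enrich_sets(genes, flag_lists, universe)
}
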