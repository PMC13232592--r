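#' Per-nucleus gene module score with expression-matched background
#'
#' For each nucleus, the mean normalized expression of the module genes
#' minus the mean of expression-matched control genes: genes are split
#' into `n_bins` bins by mean expression and, for each module gene,
#' `n_ctrl` control genes are drawn (without replacement within a draw)
#' from the same bin. A random gene set therefore scores 0 in
#' expectation, and a constant expression matrix scores exactly 0.
#' Expression is expected to be library-size normalized and
#' log-transformed already.
#'
#' @param expression Genes x nuclei numeric matrix with gene rownames.
#' @param module Character vector of module genes; members missing from
#'   the matrix are dropped with a warning, and an error is raised if none
#'   are measured.
#' @param n_bins Expression bins (default 25).
#' @param n_ctrl Control genes per module gene (default 50). Bins smaller
#'   than `n_ctrl` are sampled with replacement, with a warning.
#' @param seed Seed for the control draws (the score is deterministic
#'   given it).
#' @return Tibble `nucleus`, `score`, with attributes `module_genes` and
#'   `control_genes`.
#' @export
score_module <- function(expression, module, n_bins = 25, n_ctrl = 50,
                         seed = NULL) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)))
  missing_genes <- setdiff(module, rownames(expression))
  if (length(missing_genes) == length(unique(module))) {
    abort(paste0("module entirely unmeasured: ",
                 paste(head(missing_genes, 10), collapse = ", ")))
  }
  if (length(missing_genes)) {
    warn(sprintf("%d module gene(s) not measured were dropped",
                 length(missing_genes)))
  }
  module <- intersect(unique(module), rownames(expression))
  gene_means <- rowMeans(expression)
  n_bins_eff <- min(n_bins, length(unique(gene_means)))
  breaks <- unique(quantile(gene_means,
                            probs = seq(0, 1, length.out = n_bins_eff + 1)))
  bin <- if (length(breaks) < 2) rep(1L, length(gene_means))
         else cut(gene_means, breaks = breaks, include.lowest = TRUE,
                  labels = FALSE)
  controls <- with_seed(seed, {
    unlist(map(module, function(g) {
      pool <- setdiff(rownames(expression)[bin == bin[rownames(expression) == g]],
                      module)
      if (!length(pool)) pool <- setdiff(rownames(expression), g)
      if (length(pool) < n_ctrl) {
        warn(sprintf("bin of gene %s has %d candidates < n_ctrl = %d; sampling with replacement",
                     g, length(pool), n_ctrl))
        sample(pool, n_ctrl, replace = TRUE)
      } else {
        sample(pool, n_ctrl, replace = FALSE)
      }
    }))
  })
  module_mean <- colMeans(expression[module, , drop = FALSE])
  ctrl_mean <- colMeans(expression[controls, , drop = FALSE])
  out <- tibble(nucleus = colnames(expression) %||%
                  as.character(seq_len(ncol(expression))),
                score = unname(module_mean - ctrl_mean))
  attr(out, "module_genes") <- module
  attr(out, "control_genes") <- controls
  out
}

#' Cell-type proportion dynamics across age groups
#'
#' Per individual, the fraction of each cell type within a stated
#' denominator (a lineage's cell types); per age group, the mean fraction;
#' and the infant-versus-adult log2 fold change per cell type, with a
#' configurable pseudo-fraction guarding zero group means. Individuals
#' with no cells in the denominator are excluded with a warning.
#'
#' @param cell_meta Tibble with one row per cell: `individual`,
#'   `age_group`, `cell_type` (plus anything else).
#' @param denominator Character vector of cell types forming the
#'   denominator lineage (default: all observed cell types).
#' @param pseudo_fraction Added to both group means before the log2 ratio
#'   when either is zero (default 1e-4).
#' @return List of class `"proportion_table"`: `per_individual`
#'   (`individual`, `age_group`, `cell_type`, `n`, `fraction`),
#'   `group_means`, `log2fc` (`cell_type`, `infant_mean`, `adult_mean`,
#'   `log2fc`).
#' @export
proportions_by_age <- function(cell_meta,
                               denominator = unique(cell_meta$cell_type),
                               pseudo_fraction = 1e-4) {
  stopifnot(all(c("individual", "age_group", "cell_type") %in%
                  names(cell_meta)))
  denom_cells <- cell_meta |> filter(.data$cell_type %in% denominator)
  denom_n <- denom_cells |> count(.data$individual, name = "n_denom")
  excluded <- setdiff(unique(cell_meta$individual), denom_n$individual)
  if (length(excluded)) {
    warn(paste0("individual(s) with zero denominator cells excluded: ",
                paste(excluded, collapse = ", ")))
  }
  per_individual <- denom_cells |>
    count(.data$individual, .data$age_group, .data$cell_type, name = "n") |>
    left_join(denom_n, by = "individual") |>
    # every cell type observed for every retained individual, zeros included
    complete_fractions(denominator) |>
    mutate(fraction = .data$n / .data$n_denom)
  group_means <- per_individual |>
    group_by(.data$age_group, .data$cell_type) |>
    summarise(mean_fraction = mean(.data$fraction),
              sd_fraction = sd(.data$fraction),
              n_individuals = n(), .groups = "drop")
  lfc <- group_means |>
    select("age_group", "cell_type", "mean_fraction") |>
    pivot_wider(names_from = "age_group", values_from = "mean_fraction")
  for (col in c("infant", "adult")) {
    if (!col %in% names(lfc)) lfc[[col]] <- NA_real_
  }
  lfc$infant_mean <- lfc$infant
  lfc$adult_mean <- lfc$adult
  lfc$log2fc <- ifelse(
    lfc$infant_mean > 0 & lfc$adult_mean > 0,
    log2(lfc$infant_mean / lfc$adult_mean),
    log2((lfc$infant_mean + pseudo_fraction) /
           (lfc$adult_mean + pseudo_fraction)))
  structure(list(per_individual = per_individual,
                 group_means = group_means,
                 log2fc = lfc[, c("cell_type", "infant_mean", "adult_mean",
                                  "log2fc")]),
            class = "proportion_table")
}

complete_fractions <- function(tbl, denominator) {
  frame <- tbl |> distinct(.data$individual, .data$age_group, .data$n_denom)
  crossing(frame, cell_type = denominator) |>
    left_join(tbl |> select("individual", "cell_type", "n"),
              by = c("individual", "cell_type")) |>
    mutate(n = replace_na(.data$n, 0L))
}

#' @export
print.proportion_table <- function(x, ...) {
  cat("cell-type proportions by age group\n")
  print(x$log2fc)
  invisible(x)
}

#' @rdname proportions_by_age
#' @param x A `proportion_table`.
#' @param ... Unused.
#' @export
tidy.proportion_table <- function(x, ...) x$per_individual

#' @rdname proportions_by_age
#' @export
glance.proportion_table <- function(x, ...) {
  tibble(n_individuals = n_distinct(x$per_individual$individual),
         n_cell_types = n_distinct(x$per_individual$cell_type),
         n_age_groups = n_distinct(x$per_individual$age_group))
}

#' Descriptive trend fit over age
#'
#' Locally weighted (loess) smoothing of module scores or cell-type
#' fractions against log-scaled age, `log2(age + offset)` with a default
#' offset of 0.1 years so prenatal/0-year samples are admitted. Purely
#' descriptive; with fewer than 4 distinct ages the group means are
#' returned instead, with a warning.
#'
#' @param age Ages in years.
#' @param y Scores or fractions, same length.
#' @param log_age Fit on `log2(age + offset)` (default TRUE).
#' @param offset Years added before the log (default 0.1).
#' @param span loess span (default 0.75).
#' @param n_grid Evaluation grid size (default 100).
#' @return Tibble `age`, `t` (transformed axis), `fitted`.
#' @export
fit_trend <- function(age, y, log_age = TRUE, offset = 0.1, span = 0.75,
                      n_grid = 100) {
  stopifnot(length(age) == length(y))
  t <- if (log_age) log2(age + offset) else age
  ux <- sort(unique(t))
  if (length(ux) < 4) {
    warn("fewer than 4 distinct ages: returning group means, not a smooth")
    means <- tibble(t = ux) |>
      mutate(fitted = map_dbl(.data$t, function(tt) mean(y[t == tt])))
    means$age <- if (log_age) 2^means$t - offset else means$t
    return(means[, c("age", "t", "fitted")])
  }
  grid <- seq(min(t), max(t), length.out = n_grid)
  fit <- loess(y ~ t, data = data.frame(t = t, y = y), span = span,
               degree = 2)
  tibble(age = if (log_age) 2^grid - offset else grid,
         t = grid,
         fitted = predict(fit, newdata = data.frame(t = grid)))
}
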