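#' Pseudobulk count matrix
#'
#' Container for per-individual, per-cell-type summed counts: the unit of
#' replication for the cross-species differential expression analyses. The
#' counts are an integer genes x samples matrix; `sample_meta` describes
#' every column.
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames are
#'   gene identifiers), samples in columns.
#' @param sample_meta Data frame with one row per column of `counts`, with
#'   at least `sample_id`, `species`, `age_group` (`"infant"`/`"adult"`),
#'   `individual`, `cell_type`. `sample_id` must match `colnames(counts)`.
#' @return An object of class `"pseudobulk"`.
#' @export
pseudobulk_matrix <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  sample_meta <- as_tibble(sample_meta)
  needed <- c("sample_id", "species", "age_group", "individual", "cell_type")
  missing_cols <- setdiff(needed, names(sample_meta))
  if (length(missing_cols)) {
    abort(paste0("sample_meta is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.null(colnames(counts))) colnames(counts) <- sample_meta$sample_id
  if (!identical(colnames(counts), sample_meta$sample_id)) {
    abort("colnames(counts) must equal sample_meta$sample_id, in order")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  key <- paste(sample_meta$individual, sample_meta$cell_type)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (individual, cell_type) sample keys: ",
                 paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  if (is.null(rownames(counts))) {
    abort("counts must carry gene identifiers as rownames")
  }
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  species: %s | age groups: %s | cell types: %s\n",
              paste(unique(x$sample_meta$species), collapse = "/"),
              paste(unique(x$sample_meta$age_group), collapse = "/"),
              paste(unique(x$sample_meta$cell_type), collapse = ", ")))
  invisible(x)
}

#' @rdname pseudobulk_matrix
#' @param x A `pseudobulk` object.
#' @param ... Unused.
#' @export
tidy.pseudobulk <- function(x, ...) {
  as_tibble(x$counts, rownames = "gene") |>
    pivot_longer(-"gene", names_to = "sample_id", values_to = "count") |>
    left_join(x$sample_meta, by = "sample_id")
}

#' @rdname pseudobulk_matrix
#' @export
glance.pseudobulk <- function(x, ...) {
  tibble(n_genes = nrow(x$counts), n_samples = ncol(x$counts),
         n_species = n_distinct(x$sample_meta$species),
         n_cell_types = n_distinct(x$sample_meta$cell_type),
         total_counts = sum(x$counts))
}

subset_pseudobulk <- function(pb, keep) {
  pseudobulk_matrix(pb$counts[, keep, drop = FALSE],
                    pb$sample_meta[keep, , drop = FALSE])
}

#' Aggregate cell-level counts to pseudobulk
#'
#' Sums gene counts over cells sharing an (individual, cell type) label.
#' Groups with fewer than `min_cells` cells are dropped; the dropped groups
#' are reported in the `"dropped"` attribute and as a message.
#'
#' @param cell_counts Genes x cells matrix (dense or `Matrix` sparse) with
#'   gene rownames and cell-id colnames.
#' @param cell_meta Data frame with one row per cell: `cell_id`,
#'   `individual`, `cell_type`, `species`, `age_group`.
#' @param min_cells Minimum cells required to keep a pseudobulk sample
#'   (default 10).
#' @return A [pseudobulk_matrix()] object; dropped groups in
#'   `attr(, "dropped")`.
#' @export
aggregate_pseudobulk <- function(cell_counts, cell_meta, min_cells = 10) {
  cell_meta <- as_tibble(cell_meta)
  needed <- c("cell_id", "individual", "cell_type", "species", "age_group")
  missing_cols <- setdiff(needed, names(cell_meta))
  if (length(missing_cols)) {
    abort(paste0("cell_meta is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- is.na(cell_meta$individual) | is.na(cell_meta$cell_type)
  if (any(bad)) {
    abort(paste0("unlabeled cells (no individual or cell type): ",
                 paste(head(cell_meta$cell_id[bad], 10), collapse = ", ")))
  }
  if (!setequal(colnames(cell_counts), cell_meta$cell_id)) {
    abort("colnames(cell_counts) and cell_meta$cell_id must agree")
  }
  cell_meta <- cell_meta[match(colnames(cell_counts), cell_meta$cell_id), ]
  group <- paste(cell_meta$individual, cell_meta$cell_type, sep = "__")
  sizes <- table(group)
  keep_groups <- names(sizes)[sizes >= min_cells]
  dropped <- setdiff(names(sizes), keep_groups)
  if (length(dropped)) {
    inform(sprintf("dropping %d pseudobulk group(s) below min_cells = %d: %s",
                   length(dropped), min_cells, paste(dropped, collapse = ", ")))
  }
  if (!length(keep_groups)) abort("no group reaches min_cells")
  design <- sparseMatrix(
    i = seq_along(group)[group %in% keep_groups],
    j = match(group[group %in% keep_groups], keep_groups),
    x = 1, dims = c(length(group), length(keep_groups)))
  agg <- as.matrix(cell_counts %*% design)
  colnames(agg) <- keep_groups
  meta <- cell_meta |>
    mutate(sample_id = group) |>
    filter(.data$sample_id %in% keep_groups) |>
    distinct(.data$sample_id, .data$species, .data$age_group,
             .data$individual, .data$cell_type) |>
    arrange(match(.data$sample_id, keep_groups))
  out <- pseudobulk_matrix(agg, meta)
  attr(out, "dropped") <- dropped
  out
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: each sample's factor is the median, over genes
#' expressed in every sample, of the ratio of its count to the gene's
#' geometric mean. Factors are rescaled to geometric mean 1. When no gene
#' is expressed in all samples the total-count ratio is used instead, with
#' a warning.
#'
#' @param x A `pseudobulk` object or a genes x samples count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "pseudobulk")) x$counts else as.matrix(x)
  if (ncol(counts) < 2) abort("need at least 2 samples for size factors")
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    warn("no gene expressed in all samples; falling back to total-count ratios")
    sf <- colSums(counts)
    if (any(sf == 0)) abort("sample with zero total counts")
  } else {
    lc <- log(counts[ok, , drop = FALSE])
    loggeo <- rowMeans(lc)
    sf <- exp(apply(lc - loggeo, 2, median))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

row_var <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Method-of-moments dispersion estimates
#'
#' Per-gene negative-binomial dispersion under the parameterization
#' `variance = mean + alpha * mean^2`, estimated on normalized counts as
#' `alpha = (s^2 - m)/m^2`, floored at `alpha_min`. When `group` is given,
#' the estimate is formed within each group and pooled with degrees-of-
#' freedom weights, so a real between-group expression difference does not
#' inflate the dispersion of exactly the genes under test. All-zero genes
#' get `alpha_min` and are flagged in the `"untestable"` attribute.
#'
#' @param x `pseudobulk` object or count matrix.
#' @param sf Size factors (defaults to [size_factors()] of `x`).
#' @param group Optional factor/character of length `ncol`, the contrast
#'   groups to estimate within.
#' @param alpha_min Dispersion floor (default 1e-8).
#' @return Named numeric vector of dispersions, one per gene.
#' @export
estimate_dispersion <- function(x, sf = NULL, group = NULL, alpha_min = 1e-8) {
  counts <- if (inherits(x, "pseudobulk")) x$counts else as.matrix(x)
  if (ncol(counts) < 3) abort("need at least 3 samples to estimate dispersion")
  sf <- sf %||% size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  if (is.null(group)) group <- rep("all", ncol(counts))
  group <- as.character(group)
  num <- rep(0, nrow(counts))
  den <- 0
  for (g in unique(group)) {
    cols <- group == g
    if (sum(cols) < 2) next
    m <- rowMeans(norm[, cols, drop = FALSE])
    v <- row_var(norm[, cols, drop = FALSE])
    a <- ifelse(m > 0, (v - m) / m^2, 0)
    num <- num + (sum(cols) - 1) * a
    den <- den + (sum(cols) - 1)
  }
  if (den == 0) abort("no group with at least 2 samples")
  alpha <- pmax(num / den, alpha_min)
  untestable <- rowSums(counts) == 0
  alpha[untestable] <- alpha_min
  alpha <- setNames(alpha, rownames(counts))
  attr(alpha, "untestable") <- rownames(counts)[untestable]
  alpha
}

# Vectorised ML fit of per-group NB means with fixed dispersion.
# For each gene, mean for sample j is s_j * q; Newton iterations on
# eta = log q using the expected information Sum m/(1 + alpha m).
fit_nb_group_mean <- function(Y, s, alpha, floor_q, max_iter = 100) {
  totals <- rowSums(Y)
  q <- pmax(totals / sum(s), floor_q)
  r <- 1 / alpha
  for (i in seq_len(max_iter)) {
    M <- q %o% s
    score <- totals - rowSums((Y + r) * M / (M + r))
    info <- rowSums(M / (1 + alpha * M))
    step <- score / pmax(info, 1e-12)
    step <- pmax(pmin(step, 2), -2)
    q <- q * exp(step)
    if (max(abs(step)) < 1e-10) break
  }
  floored <- q < floor_q | totals == 0
  q <- pmax(q, floor_q)
  M <- q %o% s
  info <- rowSums(M / (1 + alpha * M))
  list(q = q, info = info, floored = floored)
}

#' Negative-binomial Wald test between two species groups
#'
#' The DE engine of the package: within one cell type and age group, fit
#' per-gene NB means for the two species by maximum likelihood with fixed
#' dispersion (Newton iterations on the log mean), form
#' `log2fc = log2(mu_A / mu_B)` with a pseudo-mean floor, Wald standard
#' error from the Fisher information of the two fits, a two-sided normal
#' p-value, and BH-FDR across genes within this contrast. Positive
#' `log2fc` means higher expression in `species_a`.
#'
#' @param pb A [pseudobulk_matrix()] object.
#' @param cell_type,age_group Which stratum to test.
#' @param species_a,species_b The contrast (A vs B); log2fc > 0 means
#'   higher in A.
#' @param dispersions Optional per-gene dispersions; estimated with
#'   [estimate_dispersion()] (within-group) when `NULL`.
#' @param sf Optional size factors for the contrast's samples.
#' @param pseudo_floor Floor on the fitted group mean at unit size factor;
#'   default half a count spread over the group
#'   (`0.5 / sum(size factors)`). Genes hitting the floor are flagged.
#' @return Tibble with one row per gene: `gene`, `cell_type`, `age_group`,
#'   `contrast`, `base_mean`, `log2fc`, `se`, `stat`, `wald_p`, `fdr`,
#'   `flag_floor`.
#' @export
nb_wald_test <- function(pb, cell_type, age_group, species_a, species_b,
                         dispersions = NULL, sf = NULL, pseudo_floor = NULL) {
  stopifnot(inherits(pb, "pseudobulk"))
  meta <- pb$sample_meta
  keep <- meta$cell_type == cell_type & meta$age_group == age_group &
    meta$species %in% c(species_a, species_b)
  if (!any(keep)) abort("no samples match the requested stratum")
  sub <- subset_pseudobulk(pb, keep)
  grp <- sub$sample_meta$species
  if (sum(grp == species_a) < 2 || sum(grp == species_b) < 2) {
    abort("both contrast groups need at least 2 samples")
  }
  counts <- sub$counts
  sf <- sf %||% size_factors(counts)
  dispersions <- dispersions %||%
    estimate_dispersion(counts, sf = sf, group = grp)
  alpha <- dispersions[rownames(counts)]
  sa <- sf[grp == species_a]
  sb <- sf[grp == species_b]
  fa <- fit_nb_group_mean(counts[, grp == species_a, drop = FALSE], sa, alpha,
                          floor_q = pseudo_floor %||% (0.5 / sum(sa)))
  fb <- fit_nb_group_mean(counts[, grp == species_b, drop = FALSE], sb, alpha,
                          floor_q = pseudo_floor %||% (0.5 / sum(sb)))
  log2fc <- log2(fa$q / fb$q)
  se <- sqrt(1 / pmax(fa$info, 1e-12) + 1 / pmax(fb$info, 1e-12)) / log(2)
  stat <- log2fc / se
  # t reference with the dispersion-estimation df: the plug-in MoM
  # dispersion makes a plain normal reference anticonservative at
  # pseudobulk sample sizes
  df <- max(length(sa) + length(sb) - 2, 1)
  p <- 2 * stats::pt(-abs(stat), df = df)
  tibble(
    gene = rownames(counts),
    cell_type = cell_type,
    age_group = age_group,
    contrast = paste0(species_a, "_vs_", species_b),
    base_mean = rowMeans(sweep(counts, 2, sf, "/")),
    log2fc = log2fc, se = se, stat = stat, wald_p = p,
    fdr = bh_fdr(p),
    flag_floor = fa$floored | fb$floored)
}

#' Call differentially expressed genes
#'
#' Applies the calling rule |log2FC| > `lfc_threshold` and
#' FDR < `fdr_threshold` (both strict) to a table of Wald results and
#' labels each passing gene `"gain"` (log2fc positive: higher in the focal
#' species) or `"loss"`.
#'
#' @param calls Tibble from [nb_wald_test()] (or with compatible columns).
#' @param lfc_threshold Absolute log2 fold-change bound, exclusive
#'   (default 0.5).
#' @param fdr_threshold FDR bound, exclusive (default 0.05).
#' @return Tibble `gene`, `cell_type`, `age_group`, `contrast`,
#'   `direction`, `log2fc`, `fdr`. Empty with a warning if `calls` is
#'   empty.
#' @export
call_de <- function(calls, lfc_threshold = 0.5, fdr_threshold = 0.05) {
  if (nrow(calls) == 0) {
    warn("empty call table: returning empty DE set")
    return(tibble(gene = character(), cell_type = character(),
                  age_group = character(), contrast = character(),
                  direction = character(), log2fc = numeric(),
                  fdr = numeric()))
  }
  calls |>
    filter(abs(.data$log2fc) > lfc_threshold, .data$fdr < fdr_threshold) |>
    mutate(direction = if_else(.data$log2fc > 0, "gain", "loss")) |>
    select(any_of(c("gene", "cell_type", "age_group", "contrast")),
           "direction", "log2fc", "fdr")
}
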