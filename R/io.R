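#' Read a pseudobulk bundle (Matrix Market counts + TSV metadata)
#'
#' @param mtx_path Matrix Market coordinate file of counts (genes x
#'   samples); values must be non-negative integers.
#' @param genes_path TSV with a `gene` column (row order of the matrix).
#' @param samples_path TSV of sample metadata (column order), with at
#'   least the [pseudobulk_matrix()] columns.
#' @return A `pseudobulk` object.
#' @export
read_counts <- function(mtx_path, genes_path, samples_path) {
  counts <- as.matrix(readMM(mtx_path))
  if (any(counts != round(counts)) || any(counts < 0)) {
    abort(paste0(mtx_path, ": counts must be non-negative integers"))
  }
  genes <- read_tsv_strict(genes_path)
  if (!"gene" %in% names(genes)) abort(paste0(genes_path, ": no `gene` column"))
  if (anyDuplicated(genes$gene)) {
    abort(paste0(genes_path, ": duplicate gene id(s): ",
                 paste(unique(genes$gene[duplicated(genes$gene)]),
                       collapse = ", ")))
  }
  samples <- read_tsv_strict(samples_path)
  if (nrow(genes) != nrow(counts) || nrow(samples) != ncol(counts)) {
    abort("matrix dimensions do not match genes/samples tables")
  }
  rownames(counts) <- genes$gene
  colnames(counts) <- samples$sample_id
  pseudobulk_matrix(counts, samples)
}

#' Write a pseudobulk bundle
#'
#' @param pb A `pseudobulk` object.
#' @param mtx_path,genes_path,samples_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(pb, mtx_path, genes_path, samples_path) {
  writeMM(Matrix::Matrix(pb$counts, sparse = TRUE), mtx_path)
  readr::write_tsv(tibble(gene = rownames(pb$counts)), genes_path)
  readr::write_tsv(pb$sample_meta, samples_path)
  invisible(c(mtx_path, genes_path, samples_path))
}

read_tsv_strict <- function(path, col_names = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_tsv(path, col_names = col_names, show_col_types = FALSE,
                  na = ".", progress = FALSE)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then tab-separated gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(sprintf("%s line %d: GMT needs name, description and >= 1 gene",
                    path, i))
    }
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- imap(sets, function(genes, nm)
    paste(c(nm, "synthetic", genes), collapse = "\t"))
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read interval annotations from BED (0-based half-open)
#'
#' Columns: chrom, start, end, then optionally the annotation class
#' (HAR/hINS/hDEL) in column 4 and a source label in column 5.
#'
#' @param path BED file path.
#' @return Tibble `chrom`, `start`, `end`, `annotation_class`, `source`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- map(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(sprintf("%s line %d: BED needs at least 3 columns", path, i))
    }
    start <- suppressWarnings(as.integer(parts[2]))
    end <- suppressWarnings(as.integer(parts[3]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("%s line %d: non-integer coordinates", path, i))
    }
    if (start >= end) {
      abort(sprintf("%s line %d: start >= end (%d >= %d)", path, i,
                    start, end))
    }
    tibble(chrom = parts[1], start = start, end = end,
           annotation_class = if (length(parts) >= 4) parts[4] else NA_character_,
           source = if (length(parts) >= 5) parts[5] else NA_character_)
  })
  list_rbind(rows)
}

#' Write interval annotations to BED
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `annotation_class`, `source`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end",
            intersect(c("annotation_class", "source"), names(intervals)))
  lines <- do.call(paste, c(intervals[cols], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a regulon edge table
#'
#' TSV with header: `tf`, `region`, `target`, `tf2g_score`, `r2g_score`,
#' `role` (activator/repressor), `cell_context`; an `edge_id` column is
#' added when missing. Self-loop edges (tf == target) are allowed but
#' flagged with a warning.
#'
#' @param path TSV path.
#' @return Tibble of regulon edges.
#' @export
read_regulons <- function(path) {
  edges <- read_tsv_strict(path)
  needed <- c("tf", "region", "target", "tf2g_score", "r2g_score", "role",
              "cell_context")
  missing_cols <- setdiff(needed, names(edges))
  if (length(missing_cols)) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_role <- setdiff(unique(edges$role), c("activator", "repressor"))
  if (length(bad_role)) {
    abort(paste0(path, ": role must be activator/repressor, found: ",
                 paste(bad_role, collapse = ", ")))
  }
  if (!"edge_id" %in% names(edges)) {
    edges$edge_id <- sprintf("e%05d", seq_len(nrow(edges)))
  }
  if (any(edges$tf == edges$target)) {
    warn(sprintf("%d self-loop regulon edge(s)", sum(edges$tf == edges$target)))
  }
  edges
}

#' Read a patient differential-expression table
#'
#' TSV with header: `gene`, `disease`, `cell_type`, `direction`,
#' `log2fc`, `fdr`. Rows at or above `fdr_threshold` are dropped (patient
#' significance is taken as given, pre-filtered here); a direction
#' inconsistent with the sign of log2fc is an error.
#'
#' @param path TSV path.
#' @param fdr_threshold Significance pre-filter (default 0.05).
#' @return Tibble of significant patient DE rows.
#' @export
read_patient_de <- function(path, fdr_threshold = 0.05) {
  tab <- read_tsv_strict(path)
  needed <- c("gene", "disease", "cell_type", "direction", "log2fc", "fdr")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- (tab$direction == "up" & tab$log2fc < 0) |
    (tab$direction == "down" & tab$log2fc > 0)
  if (any(bad)) {
    abort(sprintf("%s: %d row(s) with direction inconsistent with log2fc sign",
                  path, sum(bad)))
  }
  dup <- duplicated(tab[, c("gene", "disease", "cell_type")])
  if (any(dup)) {
    abort(sprintf("%s: duplicate (gene, disease, cell_type) row(s): %s", path,
                  paste(head(tab$gene[dup], 5), collapse = ", ")))
  }
  filter(tab, .data$fdr < fdr_threshold)
}

#' Write a hiDECORE network to JSON
#'
#' @param network A `hidecore_network` (disease-annotated or not).
#' @param path Output JSON path.
#' @export
write_network <- function(network, path) {
  payload <- list(
    lineage = network$lineage,
    n_input = network$n_input,
    n_outside_universe = network$n_outside_universe,
    provenance = network$provenance,
    nodes = network$nodes,
    edges = network$edges |>
      mutate(annotation = map_chr(.data$annotation_classes, paste,
                                  collapse = ";")) |>
      select(-"annotation_classes"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a fixture bundle to disk
#'
#' Emits every synthetic input as plain text (Matrix Market counts, TSV
#' tables, BED annotations, JSON truth) plus `manifest.json` listing each
#' file with its MD5 checksum — identical seed and config give identical
#' checksums.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (`file`, `md5`, `bytes`), invisibly also
#'   written as `manifest.json`.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("cannot create directory: ", dir))
  write_counts(bundle$pseudobulk,
               file.path(dir, "counts.mtx"),
               file.path(dir, "genes.tsv"),
               file.path(dir, "samples.tsv"))
  readr::write_tsv(bundle$regulons, file.path(dir, "regulons.tsv"))
  write_bed(bundle$annotations, file.path(dir, "annotations.bed"))
  readr::write_tsv(bundle$disease_de, file.path(dir, "disease_de.tsv"))
  readr::write_tsv(bundle$capture_pairs, file.path(dir, "capture_pairs.tsv"))
  truth <- bundle$truth
  jsonlite::write_json(
    list(config = unclass(truth$config),
         genes = truth$genes,
         baseline_means = truth$baseline_means,
         dispersions = truth$dispersions,
         assignments = truth$assignments,
         planted_lfc = truth$planted_lfc,
         hide_gains = truth$hide_gains,
         regulon_edges = truth$regulon_edges,
         regions = truth$regions,
         annotation_truth = truth$annotation_truth,
         disease_truth = truth$disease_truth,
         capture_tested_regions = truth$capture_tested_regions),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  files <- c("counts.mtx", "genes.tsv", "samples.tsv", "regulons.tsv",
             "annotations.bed", "disease_de.tsv", "capture_pairs.tsv",
             "truth.json")
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))),
    bytes = file.size(file.path(dir, files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  manifest
}

#' Read a fixture bundle back from disk
#'
#' @param dir Bundle directory written by [write_fixture_bundle()].
#' @param check Verify MD5 checksums against the manifest (default TRUE).
#' @return List with `pseudobulk`, `regulons`, `annotations`,
#'   `disease_de`, `capture_pairs`, `truth` (plain-list form), `manifest`.
#' @export
read_fixture_bundle <- function(dir, check = TRUE) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) abort(paste0("no manifest in ", dir))
  manifest <- as_tibble(jsonlite::read_json(manifest_path,
                                            simplifyVector = TRUE))
  if (check) {
    md5 <- unname(tools::md5sum(file.path(dir, manifest$file)))
    bad <- which(md5 != manifest$md5)
    if (length(bad)) {
      abort(paste0("checksum mismatch for: ",
                   paste(manifest$file[bad], collapse = ", ")))
    }
  }
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE)
  list(
    pseudobulk = read_counts(file.path(dir, "counts.mtx"),
                             file.path(dir, "genes.tsv"),
                             file.path(dir, "samples.tsv")),
    regulons = read_regulons(file.path(dir, "regulons.tsv")),
    annotations = read_bed(file.path(dir, "annotations.bed")),
    disease_de = read_tsv_strict(file.path(dir, "disease_de.tsv")),
    capture_pairs = read_tsv_strict(file.path(dir, "capture_pairs.tsv")),
    truth = truth_raw,
    manifest = manifest)
}
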