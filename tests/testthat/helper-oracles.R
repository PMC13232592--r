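# Independent brute-force oracles used across the suite. These never call
# the implementation paths they check.

# Upper-tail hypergeometric by direct summation of choose()-based point
# masses over the support.
enum_hyper_upper <- function(k, K, n, N) {
  js <- max(0, n - (N - K)):min(K, n)
  js <- js[js >= k]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Fisher exact p by enumerating every table with the observed margins.
enum_fisher <- function(a, b, c, d,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  K <- a + b; n <- a + c; N <- a + b + c + d
  js <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  switch(alternative,
    greater = sum(probs[js >= a]),
    less = sum(probs[js <= a]),
    two.sided = {
      p_obs <- probs[js == a]
      sum(probs[probs <= p_obs * (1 + 1e-7)])
    })
}

# Quadratic all-pairs half-open interval overlap.
quadratic_overlap <- function(regions, intervals) {
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    hit <- intervals$chrom == regions$chrom[i] &
      regions$start[i] < intervals$end &
      intervals$start < regions$end[i]
    out[[i]] <- sort(unique(intervals$annotation_class[hit]))
  }
  out
}

# Exclusive membership-pattern counts by per-gene enumeration.
enum_upset <- function(sets) {
  sets <- unique(sets[, c("gene", "cell_type", "direction")])
  keys <- split(sets$cell_type, paste(sets$gene, sets$direction, sep = "\r"))
  pats <- vapply(keys, function(x) paste(sort(unique(x)), collapse = "&"), "")
  dirs <- sub("^.*\r", "", names(keys))
  as.data.frame(table(direction = dirs, pattern = pats),
                stringsAsFactors = FALSE)
}

# Nested-loop join of evolutionary calls with a patient table via a map.
loop_join <- function(evo, patient, map) {
  rows <- list()
  for (i in seq_len(nrow(evo))) {
    for (m in seq_len(nrow(map))) {
      if (evo$cell_type[i] != map$evo_cell_type[m]) next
      for (j in seq_len(nrow(patient))) {
        if (patient$cell_type[j] != map$disease_label[m]) next
        if (patient$gene[j] != evo$gene[i]) next
        rows[[length(rows) + 1]] <- data.frame(
          gene = evo$gene[i], evo_cell_type = evo$cell_type[i],
          disease_label = patient$cell_type[j],
          disease = patient$disease[j])
      }
    }
  }
  if (!length(rows)) return(data.frame(gene = character()))
  do.call(rbind, rows)
}

key3 <- function(d) paste(d$gene, d$cell_type, d$direction)
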