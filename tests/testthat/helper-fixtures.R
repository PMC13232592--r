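# Small shared fixtures, built once per test run.

small_config <- function(seed = 11L, ...) {
  sim_config(n_genes = 400, n_individuals = 6,
             cell_types = c(L2_3 = "neural", COP = "OL"),
             n_regulon_edges = 40, seed = seed, ...)
}

# cached small bundle for modules that only need structure, not power
.small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_bundle(small_config())
    cache
  }
})

# cached default-condition bundle + hiDE recovery (shared by the
# acceptance tests so the expensive run happens once)
.default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 101L)
      bundle <- simulate_bundle(cfg)
      hide <- infant_specific_sets(bundle$pseudobulk, "human",
                                   c("chimp", "rhesus"))
      cache <<- list(cfg = cfg, bundle = bundle, hide = hide)
    }
    cache
  }
})
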