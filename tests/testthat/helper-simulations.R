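# Memoised recognition-rate runs shared across test files: scenario
# replicates are generated once per (scenario, statistic, mode) key and the
# per-replicate result tables cached for the session.
.sim_cache <- new.env(parent = emptyenv())

scenario_tables <- function(tag, set_stat = "l2norm",
                            perm_type = "sample", n_rep = 50L,
                            n_perm = 200L, master_seed = 20240901L) {
  key <- paste(tag, set_stat, perm_type, n_rep, n_perm, sep = "/")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  tables <- simulate_replicates(tag, n_rep, seed = master_seed,
                                FUN = function(d) {
    run_gsa(d$counts, d$labels, d$sets, gene_stat = "signal2noise",
            set_stat = set_stat, n_perm = n_perm, perm_type = perm_type,
            seed = d$config$seed %% 1000000L)$table
  })
  .sim_cache[[key]] <- tables
  tables
}

scenario_rr <- function(tag, ...) {
  recognition_rate(scenario_tables(tag, ...), "SET_001")
}
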