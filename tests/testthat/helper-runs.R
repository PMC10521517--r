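# Cache of paper-default synthetic runs shared by the recovery tests, so the
# 20-seed ensemble is generated once per test session.
.run_cache <- new.env(parent = emptyenv())

paper_runs <- function(n_seeds = 20) {
  key <- paste0("runs_", n_seeds)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- lapply(seq_len(n_seeds), function(s)
      generate_assay_set(paper_default_config(seed = s)))
  }
  .run_cache[[key]]
}
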