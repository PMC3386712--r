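# Shared Monte-Carlo benchmark for the statistical-replication tests: 50
# synthesized recordings under the default study conditions, every detector
# family grid-searched per recording. Computed once, on first use.

.bench_env <- new.env(parent = emptyenv())

replication_bench <- function() {
  if (is.null(.bench_env$bench)) {
    .bench_env$bench <- monte_carlo(
      c("amvd", "amd", "ared", "shod",
        "fsd-prod", "ltsd-sum", "mbgtd-prod", "mbcd-prod", "frd-prod"),
      n_runs = 50, seed = 101, roc_specs = "shod")
  }
  .bench_env$bench
}

bench_mean_acc <- function(bench, label) {
  s <- bench$summary
  s$accuracy[s$detector == label]
}
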