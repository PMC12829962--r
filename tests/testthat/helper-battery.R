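# Shared scaled-down replication battery for the headline checks:
# 2 species sets x 5 replicate runs x 50 full rounds per method, all from
# master seed 1, with shared round-0 states across methods. Cached across
# test blocks because several checks read the same runs.

.acc <- new.env(parent = emptyenv())
.ACC_MASTER <- 1L
.ACC_SETS <- 2L
.ACC_RUNS <- 5L

acc_set <- function(s) {
  key <- paste0("set", s)
  if (is.null(.acc[[key]]))
    .acc[[key]] <- sample_species_set(mix_seed(.ACC_MASTER, s), set_id = s)
  .acc[[key]]
}

acc_runs <- function(method, mu = 0.01) {
  key <- paste0(method, "_mu", mu)
  if (is.null(.acc[[key]])) {
    cfg <- experiment_config(method = method, rounds = 50L, mu = mu)
    out <- list()
    for (s in seq_len(.ACC_SETS))
      for (r in seq_len(.ACC_RUNS))
        out[[paste(s, r)]] <- run_experiment(acc_set(s), cfg, run_index = r)
    .acc[[key]] <- out
  }
  .acc[[key]]
}

# change in the maximum degradation score, round 50 minus round 0
acc_delta <- function(run) {
  max(run$rounds[[51]]$D) - max(run$rounds[[1]]$D)
}

# release assay on each run's best round-50 community: end-of-assay mean D
# minus first-assay-round mean D, one value per run
acc_drops <- function(method) {
  key <- paste0("drops_", method)
  if (is.null(.acc[[key]])) {
    runs <- acc_runs(method)
    cfg <- experiment_config()
    .acc[[key]] <- vapply(names(runs), function(nm) {
      s <- as.integer(strsplit(nm, " ")[[1]][1])
      run <- runs[[nm]]
      last <- run$rounds[[51]]
      winner <- which.max(last$D)
      D <- stability_assay(acc_set(s), last$inocula[[winner]], rounds = 25L,
                           replicates = 5L,
                           seed = mix_seed(.ACC_MASTER, 77L, s,
                                           run$run_index),
                           cfg = cfg)
      mean(D[, 25]) - mean(D[, 1])
    }, numeric(1))
  }
  .acc[[key]]
}
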