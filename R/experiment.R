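# Orchestration: multi-round selection runs, exhaustive enumeration and
# ranking of species combinations, stability assays, sensitivity sweeps.

#' Experiment configuration
#'
#' Defaults are the standard batch-culture design: 21 tubes, a pool of 15
#' species, 4 nutrients at 2000 units, 10 toxins at 700 units, Hill
#' constant 700, 10-cell inocula, 80 time-steps per round, 50 rounds,
#' mutation probability 0.01 with lognormal(0, 0.4) effect, 7 selected
#' parents, ~20-fold dilution bottleneck, and 5 tubes each for invasions
#' and removals.
#'
#' @param method propagation method, one of NS, PS, PR, PIS, PIR, MS, MR,
#'   MIS, MIR, DS, DR.
#' @param n_tubes number of communities per round.
#' @param pool_size species pool size.
#' @param n_nutrients,nutrient_amount nutrients and initial units each.
#' @param n_toxins,toxin_amount toxic compounds and initial units each.
#' @param hill_K Hill constant of the death function.
#' @param inoculum cells per species at inoculation.
#' @param initial_richness species draws per tube in round 0.
#' @param t_end time-steps per round.
#' @param rounds selection rounds after round 0.
#' @param mu,sigma2 mutation probability and lognormal variance.
#' @param n_selected parents selected per round.
#' @param dilution_factor bottleneck for NS and the propagule family.
#' @param invasion_tubes,removal_tubes tubes receiving/losing species.
#' @param extra_count_rate Poisson rate of the "1 + Poisson" species
#'   change counts.
#' @param dilution_scale sweep multiplier: scales the transferred fraction
#'   (NS/PS/MS families) and the per-species inoculum (DS family).
#' @param ds_fixed_inoculum if `TRUE` (default) disassembly inoculates
#'   exactly 10 cells per species; otherwise `max(1, Poisson(10))`.
#' @param ps_score_proportional propagule parentage proportional to score
#'   instead of the equal 3-offspring split.
#' @param maint_revert see [activation_substep()].
#' @param replicates bookkeeping: replicate runs per condition.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(method = "DS", n_tubes = 21L, pool_size = 15L,
                              n_nutrients = 4L, nutrient_amount = 2000,
                              n_toxins = 10L, toxin_amount = 700,
                              hill_K = 700, inoculum = 10L,
                              initial_richness = 4L, t_end = 80L,
                              rounds = 50L, mu = 0.01, sigma2 = 0.4,
                              n_selected = 7L, dilution_factor = 20,
                              invasion_tubes = 5L, removal_tubes = 5L,
                              extra_count_rate = 0.5, dilution_scale = 1,
                              ds_fixed_inoculum = TRUE,
                              ps_score_proportional = FALSE,
                              maint_revert = TRUE, replicates = 10L) {
  cfg <- list(method = method, n_tubes = as.integer(n_tubes),
              pool_size = as.integer(pool_size),
              n_nutrients = as.integer(n_nutrients),
              nutrient_amount = nutrient_amount,
              n_toxins = as.integer(n_toxins), toxin_amount = toxin_amount,
              hill_K = hill_K, inoculum = as.integer(inoculum),
              initial_richness = as.integer(initial_richness),
              t_end = as.integer(t_end), rounds = as.integer(rounds),
              mu = mu, sigma2 = sigma2, n_selected = as.integer(n_selected),
              dilution_factor = dilution_factor,
              invasion_tubes = as.integer(invasion_tubes),
              removal_tubes = as.integer(removal_tubes),
              extra_count_rate = extra_count_rate,
              dilution_scale = dilution_scale,
              ds_fixed_inoculum = isTRUE(ds_fixed_inoculum),
              ps_score_proportional = isTRUE(ps_score_proportional),
              maint_revert = isTRUE(maint_revert),
              replicates = as.integer(replicates))
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

validate_config <- function(cfg) {
  if (!cfg$method %in% .METHODS)
    stop("unknown method '", cfg$method, "'; use one of ",
         paste(.METHODS, collapse = ", "))
  pos <- c("n_tubes", "pool_size", "n_nutrients", "nutrient_amount",
           "n_toxins", "toxin_amount", "hill_K", "inoculum",
           "initial_richness", "t_end", "n_selected", "dilution_factor",
           "dilution_scale")
  for (fld in pos)
    if (!is.numeric(cfg[[fld]]) || length(cfg[[fld]]) != 1L ||
        is.na(cfg[[fld]]) || cfg[[fld]] <= 0)
      stop("config field '", fld, "' must be a positive number")
  if (cfg$rounds < 0) stop("rounds must be non-negative")
  if (cfg$mu < 0 || cfg$mu > 1) stop("mu must lie in [0, 1]")
  if (cfg$n_selected > cfg$n_tubes)
    stop("cannot select more parents than tubes")
  if (cfg$invasion_tubes > cfg$n_tubes || cfg$removal_tubes > cfg$n_tubes)
    stop("invasion/removal tube counts cannot exceed n_tubes")
  invisible(cfg)
}

new_tube_from_cfg <- function(set, inoc, cfg) {
  new_tube(set, inoc,
           N0 = rep(cfg$nutrient_amount, set$n_nutrients),
           T0 = rep(cfg$toxin_amount, set$n_toxins),
           K = cfg$hill_K)
}

#' Canonical key for a species composition
#' @param species integer species ids.
#' @return A single string, e.g. `"02+05+11"`; `""` for the empty set.
#' @export
composition_key <- function(species) {
  paste(sprintf("%02d", sort(unique(as.integer(species)))), collapse = "+")
}

#' Run a multi-round selection experiment
#'
#' Round 0 assembles 21 communities of 4 random species each (every pool
#' species covered) and grows them; each later round propagates by
#' `cfg$method` and grows again. The round-0 state is a deterministic
#' function of the species-set seed and `run_index` only, so different
#' methods (and different mutation rates) run from identical initial
#' communities and can be compared pairwise. Every tube-round and every
#' propagation step draws from its own named RNG substream (see
#' [mix_seed()]), making any part of a run replayable in isolation.
#'
#' @param set a `species_set`.
#' @param cfg an `experiment_config`.
#' @param run_index replicate index (also a seed key).
#' @param engine simulation engine passed to [run_round()].
#' @return A list of class `selection_run`: `cfg`, `set_id`, `run_index`,
#'   and `rounds`, a list of per-round records (scores `D`, penalized
#'   `Dhat` for the DS family, `selected`, initial and surviving
#'   compositions, the 21 inocula and end-of-round lineage tables, the
#'   per-species abundance matrix, per-tube biomass `auc`).
#' @export
run_experiment <- function(set, cfg, run_index = 1L, engine = "cpp") {
  validate_config(cfg)
  base <- set$rng_seed
  run_index <- as.integer(run_index)
  set.seed(mix_seed(base, run_index, .PROC$init))
  comps0 <- sample_initial_communities(set, cfg$n_tubes, cfg$initial_richness)
  cells0 <- round(cfg$inoculum * cfg$dilution_scale)
  inocula <- lapply(comps0, function(cc) ancestral_inoculum(set, cc, cells0))
  repo <- if (cfg$method %in% c("DS", "DR")) init_repository(set) else NULL
  lid_next <- set$size + 1L
  records <- vector("list", cfg$rounds + 1L)

  for (rnd in 0:cfg$rounds) {
    tubes <- vector("list", cfg$n_tubes)
    for (ti in seq_len(cfg$n_tubes)) {
      tube <- new_tube_from_cfg(set, inocula[[ti]], cfg)
      tube$next_lid <- max(lid_next, tube$next_lid)
      set.seed(mix_seed(base, run_index, rnd, ti, .PROC$growth))
      tube <- run_round(tube, set, cfg$t_end, cfg$mu, cfg$sigma2,
                        cfg$maint_revert, engine)
      lid_next <- max(lid_next, tube$next_lid)
      tubes[[ti]] <- tube
    }
    D <- vapply(tubes, degradation_score, numeric(1))
    rec <- list(
      round = rnd,
      D = D,
      initial_composition = lapply(tubes, `[[`, "initial_species"),
      composition = lapply(tubes, surviving_species),
      abundance = t(vapply(tubes, species_abundance, numeric(set$size),
                           pool_size = set$size)),
      inocula = inocula,
      lineages = lapply(tubes, lineage_table),
      auc = vapply(tubes, function(tb) sum(tb$traj), numeric(1)),
      Dhat = NULL, selected = NULL)
    if (rnd < cfg$rounds) {
      set.seed(mix_seed(base, run_index, rnd, .PROC$propagate,
                        match(cfg$method, .METHODS)))
      pr <- propagate(tubes, D, cfg, set, repo, round = rnd)
      inocula <- pr$inocula
      repo <- pr$repo
      rec$Dhat <- pr$info$dhat
      rec$selected <- pr$info$selected
      rec$propagation <- pr$info
    } else if (cfg$method %in% c("DS", "DR")) {
      # score bookkeeping for the final round (no propagation follows)
      rec$Dhat <- tube_penalized_scores(tubes, D)
      rec$selected <- rank_and_select(rec$Dhat, cfg$n_selected)
    } else {
      rec$selected <- rank_and_select(D, cfg$n_selected)
    }
    records[[rnd + 1L]] <- rec
  }
  structure(list(cfg = cfg, set_id = set$set_id, run_index = run_index,
                 seed = base, rounds = records),
            class = "selection_run")
}

#' @export
print.selection_run <- function(x, ...) {
  last <- x$rounds[[length(x$rounds)]]
  cat(sprintf(
    "<selection_run> method %s, %d rounds, set %d run %d; last-round max D = %.3f\n",
    x$cfg$method, length(x$rounds) - 1L, x$set_id, x$run_index, max(last$D)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Exhaustive enumeration and ranking

#' All non-empty species subsets of a pool
#' @param pool_size pool size (at most 20).
#' @return A list of integer vectors, ordered by richness then
#'   lexicographically.
#' @export
enumerate_compositions <- function(pool_size) {
  if (pool_size > 20L)
    stop("refusing to enumerate 2^", pool_size,
         " subsets; use subset_species_set() first")
  out <- list()
  for (rich in seq_len(pool_size)) {
    cm <- combn(pool_size, rich)
    out <- c(out, lapply(seq_len(ncol(cm)), function(j) cm[, j]))
  }
  out
}

#' Score every possible species combination
#'
#' Grows each of the `2^pool - 1` non-empty subsets for one round from 10
#' ancestral cells per species (no mutation) and averages the degradation
#' score over seeded replicates. The resulting table, sorted best to
#' worst, is the absolute yardstick selected communities are ranked
#' against.
#'
#' @param set a `species_set` (pool of at most 20 species).
#' @param replicates growth replicates per subset (default 3).
#' @param seed integer seed for the replicate substreams.
#' @param cfg an `experiment_config` supplying tube conditions.
#' @param score if `FALSE`, skip the growth simulations and return the
#'   composition bookkeeping only (`D` is `NA`) — useful to inspect the
#'   combinatorics cheaply.
#' @param engine simulation engine.
#' @return A `data.frame` with `composition` (canonical key), `richness`
#'   and mean `D`, sorted by decreasing `D` (ties: lexicographic key).
#' @export
enumerate_all_communities <- function(set, replicates = 3L, seed = 1L,
                                      cfg = experiment_config(),
                                      score = TRUE, engine = "cpp") {
  comps <- enumerate_compositions(set$size)
  keys <- vapply(comps, composition_key, character(1))
  rich <- lengths(comps)
  D <- rep(NA_real_, length(comps))
  if (score) {
    cells <- round(cfg$inoculum * cfg$dilution_scale)
    for (ci in seq_along(comps)) {
      inoc <- ancestral_inoculum(set, comps[[ci]], cells)
      ds <- numeric(replicates)
      for (rep_i in seq_len(replicates)) {
        set.seed(mix_seed(seed, .PROC$enumerate, ci, rep_i))
        tube <- new_tube_from_cfg(set, inoc, cfg)
        tube <- run_round(tube, set, cfg$t_end, mu = 0,
                          sigma2 = cfg$sigma2, cfg$maint_revert, engine)
        ds[rep_i] <- degradation_score(tube)
      }
      D[ci] <- mean(ds)
    }
  }
  tab <- data.frame(composition = keys, richness = rich, D = D,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$D, tab$composition), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Rank of a composition in an enumeration table
#'
#' @param table output of [enumerate_all_communities()].
#' @param composition integer species ids (or a canonical key string).
#' @return 1-based rank by mean degradation score.
#' @export
community_rank <- function(table, composition) {
  key <- if (is.character(composition)) composition
         else composition_key(composition)
  hit <- match(key, table$composition)
  if (is.na(hit)) stop("composition ", key, " not present in the table")
  hit
}

#' Most common exact species combination in a round
#'
#' The predominant community of a round is the most frequent exact
#' (surviving) species set among the 21 tubes; a set that is a strict
#' subset of another present set is still its own combination. Frequency
#' ties are broken towards the higher mean degradation score.
#'
#' @param record one per-round record of a `selection_run`.
#' @return Integer species ids of the predominant combination.
#' @export
predominant_community <- function(record) {
  keys <- vapply(record$composition, composition_key, character(1))
  counts <- table(keys)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    meanD <- vapply(top, function(k) mean(record$D[keys == k]), numeric(1))
    top <- top[order(-meanD, top)][1L]
  }
  idx <- which(keys == top)[1L]
  record$composition[[idx]]
}

# ---------------------------------------------------------------------------
# Stability assay and sensitivity sweeps

#' Replace every lineage of an inoculum by its ancestral genotype
#'
#' Cells per species are preserved; lineages collapse onto the ancestral
#' investment vector. Used for the "what if the community had never
#' evolved" baselines.
#'
#' @param inoc an inoculum list.
#' @param set the `species_set`.
#' @return An inoculum of ancestral lineages.
#' @export
ancestral_counterpart <- function(inoc, set) {
  species <- sort(unique(inoc$sp))
  cells <- vapply(species, function(s) sum(inoc$p0[inoc$sp == s]), numeric(1))
  list(sp = species, lid = species,
       f = set$f0[species, , drop = FALSE], p0 = cells)
}

#' Ecological stability assay: transfers without selection or mutation
#'
#' Seeds `replicates` tubes with an identical inoculum (typically the
#' winning community's last selection-round inoculum) and grows and
#' ~20-fold-dilutes them for `rounds` rounds, no-selection style, with
#' mutation switched off. The first assay round therefore reproduces the
#' selection-context growth in expectation; later rounds reveal where the
#' community drifts once the selection scaffold is removed.
#'
#' @param set a `species_set`.
#' @param inoc the inoculum to assay.
#' @param rounds transfer rounds (default 25).
#' @param replicates independent replicate tubes (default 10).
#' @param seed integer seed.
#' @param cfg an `experiment_config` supplying tube conditions.
#' @param engine simulation engine.
#' @return A `replicates x rounds` matrix of degradation scores.
#' @export
stability_assay <- function(set, inoc, rounds = 25L, replicates = 10L,
                            seed = 1L, cfg = experiment_config(),
                            engine = "cpp") {
  D <- matrix(NA_real_, replicates, rounds)
  factor <- cfg$dilution_factor / cfg$dilution_scale
  for (rep_i in seq_len(replicates)) {
    cur <- inoc
    for (rnd in seq_len(rounds)) {
      set.seed(mix_seed(seed, rep_i, rnd, .PROC$stability))
      tube <- new_tube_from_cfg(set, cur, cfg)
      tube <- run_round(tube, set, cfg$t_end, mu = 0, sigma2 = cfg$sigma2,
                        cfg$maint_revert, engine)
      D[rep_i, rnd] <- degradation_score(tube)
      if (rnd < rounds) cur <- dilute(tube, factor)
    }
  }
  D
}

#' Sensitivity sweep over one experimental parameter
#'
#' Reruns the experiment over a grid of values for one design parameter
#' and records the last-round maximum degradation score, plus the Spearman
#' rank correlation between parameter and outcome. Pool-size sweeps
#' subsample the given species set rather than drawing new species.
#'
#' @param set a `species_set`.
#' @param cfg an `experiment_config` (the baseline design).
#' @param parameter one of `"invasion_tubes"`, `"pool_size"`,
#'   `"n_tubes"`, `"dilution_scale"`, `"t_end"`.
#' @param values grid of parameter values.
#' @param runs replicate runs per value.
#' @param seed integer seed (drives pool subsampling and run indices).
#' @param engine simulation engine.
#' @return A list with `table` (`parameter`, `value`, `run`, `max_D`) and
#'   the Spearman `rho` and `p` (both `NA` for a single-value grid).
#' @export
sensitivity_sweep <- function(set, cfg, parameter, values, runs = 2L,
                              seed = 1L, engine = "cpp") {
  allowed <- c("invasion_tubes", "pool_size", "n_tubes", "dilution_scale",
               "t_end")
  if (!parameter %in% allowed)
    stop("unknown sweep parameter '", parameter, "'")
  rows <- list()
  for (v in values) {
    cfg_v <- cfg
    set_v <- set
    if (parameter == "pool_size") {
      set.seed(mix_seed(seed, match(v, values), 7L))
      if (v > set$size) stop("pool_size sweep cannot exceed the pool")
      if (v < set$size)
        set_v <- subset_species_set(set, sort(sample.int(set$size, v)))
      cfg_v$pool_size <- as.integer(v)
      # tube counts may now exceed what richness can cover; leave design as is
    } else {
      cfg_v[[parameter]] <- if (parameter %in% c("invasion_tubes", "n_tubes",
                                                 "t_end"))
        as.integer(v) else v
      if (parameter == "n_tubes")
        cfg_v$removal_tubes <- min(cfg_v$removal_tubes, as.integer(v))
    }
    validate_config(cfg_v)
    for (run_i in seq_len(runs)) {
      run <- run_experiment(set_v, cfg_v, run_index = run_i, engine = engine)
      last <- run$rounds[[length(run$rounds)]]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = parameter, value = v, run = run_i, max_D = max(last$D))
    }
  }
  tab <- do.call(rbind, rows)
  if (length(unique(tab$value)) > 1L) {
    ct <- suppressWarnings(cor.test(tab$value, tab$max_D,
                                    method = "spearman", exact = FALSE))
    list(table = tab, rho = unname(ct$estimate), p = ct$p.value)
  } else {
    list(table = tab, rho = NA_real_, p = NA_real_)
  }
}
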