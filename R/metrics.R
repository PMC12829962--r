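# Community-level analytics: Hill-number diversity, Bray-Curtis beta
# diversity, toxin/nutrient coverage, investment, biomass and synergy.

#' Effective number of species (Hill number of order 1)
#'
#' `exp(H') = exp(-sum p_i log p_i)` on relative abundances
#' `p_i = S_i / S_tot` (lineages of a species summed first). Equals the
#' richness when abundances are uniform. An empty community is reported as
#' 0 by convention.
#'
#' @param ab per-species abundance vector (zeros for absent species).
#' @return A number in `{0} U [1, length(ab)]`.
#' @export
effective_species <- function(ab) {
  tot <- sum(ab)
  if (tot <= 0) return(0)
  p <- ab[ab > 0] / tot
  exp(-sum(p * log(p)))
}

#' Between-community (beta) diversity of a round
#'
#' Mean Bray-Curtis dissimilarity over all unordered pairs of tubes
#' (`choose(21, 2) = 210` pairs for the standard design), computed on raw
#' per-species population counts with absent species as zeros. A pair of
#' empty tubes contributes 0 (identical).
#'
#' @param abundance tubes-by-species count matrix.
#' @return Mean dissimilarity in `[0, 1]`.
#' @export
beta_diversity <- function(abundance) {
  if (nrow(abundance) < 2L) stop("need at least two communities")
  # vegan warns on empty communities; their pairs are defined below
  d <- as.matrix(suppressWarnings(vegan::vegdist(abundance, method = "bray")))
  d[!is.finite(d)] <- 0  # empty-vs-empty pairs
  mean(d[lower.tri(d)])
}

#' Population-weighted total investment of one species
#'
#' `f~_i = sum_l S_l f_l. / sum_l S_l` over the lineages of species `i`:
#' the species' total degradation investment, weighted towards its
#' abundant lineages so that rare recent mutants do not dominate.
#'
#' @param S lineage population sizes.
#' @param fdot lineage total investments (`sum_k f_k`).
#' @return The weighted mean; `NA` if the species has no cells.
#' @export
weighted_investment <- function(S, fdot) {
  if (sum(S) <= 0) return(NA_real_)
  sum(S * fdot) / sum(S)
}

# Per-species lineage-weighted investment *vectors* for a lineage table:
# f~_ik = sum_l S_l f_lk / sum_l S_l, one row per present species.
species_weighted_f <- function(lt) {
  species <- sort(unique(lt$sp[lt$S > 0]))
  f <- t(vapply(species, function(s) {
    idx <- lt$sp == s & lt$S > 0
    colSums(lt$f[idx, , drop = FALSE] * lt$S[idx]) / sum(lt$S[idx])
  }, numeric(ncol(lt$f))))
  list(species = species, f = f)
}

#' Toxin coverage: effective number of toxins invested into
#'
#' Per species, the lineage-population-weighted investment vector; summed
#' over the present species (not weighted by species abundance) to the
#' community investment profile `f~_.k`, normalized to sum 1, and turned
#' into an effective number via the exponential Shannon index. 0 when
#' nobody invests in anything.
#'
#' @param lt a lineage table (`sp`, `S`, `f`), e.g. from a run record.
#' @return A value in `[0, n_toxins]`.
#' @export
toxin_coverage <- function(lt) {
  if (!any(lt$S > 0)) stop("empty community")
  sw <- species_weighted_f(lt)
  prof <- colSums(sw$f)
  if (sum(prof) <= 0) return(0)
  p <- prof[prof > 0] / sum(prof)
  exp(-sum(p * log(p)))
}

#' Nutrient coverage: effective number of nutrients taken up
#'
#' As [toxin_coverage()] but on the species' uptake preference vectors
#' `n_ij` (which do not mutate, so no lineage weighting), summed over
#' present species and normalized.
#'
#' @param species integer ids of the present species.
#' @param set the `species_set`.
#' @return A value in `[0, n_nutrients]`.
#' @export
nutrient_coverage <- function(species, set) {
  if (length(species) == 0L) stop("empty community")
  prof <- colSums(set$n[species, , drop = FALSE])
  if (sum(prof) <= 0) return(0)
  p <- prof[prof > 0] / sum(prof)
  exp(-sum(p * log(p)))
}

#' Community mean investment
#'
#' The unweighted mean over present species of their population-weighted
#' total investments ([weighted_investment()]): freshly sampled pools have
#' a theoretical mean of 0.5.
#'
#' @param lt a lineage table.
#' @return Mean total investment of the community.
#' @export
community_mean_investment <- function(lt) {
  present <- lt$S > 0
  if (!any(present)) stop("empty community")
  species <- sort(unique(lt$sp[present]))
  mean(vapply(species, function(s) {
    idx <- lt$sp == s
    weighted_investment(lt$S[idx], rowSums(lt$f[idx, , drop = FALSE]))
  }, numeric(1)))
}

#' Biomass as area under the growth curves
#'
#' The discrete sum of the per-step total population over a round,
#' summed over species (10 constant cells over 80 steps give 800).
#'
#' @param traj a `t_end x species` trajectory matrix (from `tube$traj`).
#' @return Total cell-steps.
#' @export
biomass_auc <- function(traj) {
  if (is.null(traj)) stop("tube has no recorded trajectory")
  sum(traj)
}

#' Synergy of a community over its monocultures
#'
#' The co-culture's one-round value (degradation score or biomass AUC,
#' from 10 ancestral cells per species, averaged over seeded replicates)
#' minus the sum of the member species' monoculture values under the same
#' protocol. Monocultures have synergy exactly 0 because the co-culture
#' is its own monoculture (shared seeds).
#'
#' @param set a `species_set`.
#' @param composition integer species ids.
#' @param mode `"degradation"` or `"biomass"`.
#' @param replicates growth replicates (default 3).
#' @param seed integer seed.
#' @param cfg an `experiment_config` supplying tube conditions.
#' @param engine simulation engine.
#' @return The synergy value.
#' @export
synergy <- function(set, composition, mode = c("degradation", "biomass"),
                    replicates = 3L, seed = 1L, cfg = experiment_config(),
                    engine = "cpp") {
  mode <- match.arg(mode)
  if (length(composition) == 0L) stop("empty composition")
  value_of <- function(species) {
    key <- sum(2^(as.integer(species) - 1L))
    vals <- numeric(replicates)
    for (rep_i in seq_len(replicates)) {
      set.seed(mix_seed(seed, .PROC$synergy, key, rep_i))
      inoc <- ancestral_inoculum(set, species,
                                 round(cfg$inoculum * cfg$dilution_scale))
      tube <- new_tube_from_cfg(set, inoc, cfg)
      tube <- run_round(tube, set, cfg$t_end, mu = 0, sigma2 = cfg$sigma2,
                        cfg$maint_revert, engine)
      vals[rep_i] <- if (mode == "degradation") degradation_score(tube)
                     else biomass_auc(tube$traj)
    }
    mean(vals)
  }
  co <- value_of(composition)
  monos <- vapply(composition, function(s) value_of(s), numeric(1))
  co - sum(monos)
}

#' Cumulative number of unique communities explored
#'
#' Counts, per round, how many distinct species combinations have been
#' assembled in any tube from round 0 up to that round — the search-space
#' exploration each propagation method achieves.
#'
#' @param run a `selection_run` (or its `rounds` list).
#' @return An integer vector, one entry per round (round 0 first).
#' @export
cumulative_unique_communities <- function(run) {
  records <- if (inherits(run, "selection_run")) run$rounds else run
  seen <- character(0)
  vapply(records, function(rec) {
    keys <- vapply(rec$initial_composition, composition_key, character(1))
    seen <<- union(seen, keys)
    length(seen)
  }, integer(1))
}

#' Per-round summary metrics of a selection run
#'
#' @param run a `selection_run`.
#' @param set the `species_set` the run used.
#' @return A `data.frame` with one row per round: max/mean/median `D`,
#'   mean effective species number, beta diversity, mean toxin and
#'   nutrient coverage, mean community investment, mean biomass AUC, and
#'   the cumulative unique-community count.
#' @export
run_metrics <- function(run, set) {
  cum <- cumulative_unique_communities(run)
  rows <- lapply(seq_along(run$rounds), function(i) {
    rec <- run$rounds[[i]]
    nonempty <- vapply(rec$lineages, function(lt) any(lt$S > 0), logical(1))
    data.frame(
      round = rec$round,
      max_D = max(rec$D),
      mean_D = mean(rec$D),
      median_D = median(rec$D),
      effective_species = mean(apply(rec$abundance, 1, effective_species)),
      beta_diversity = beta_diversity(rec$abundance),
      toxin_coverage = mean(vapply(rec$lineages[nonempty], toxin_coverage,
                                   numeric(1))),
      nutrient_coverage = mean(vapply(rec$composition[nonempty],
                                      nutrient_coverage, numeric(1),
                                      set = set)),
      mean_investment = mean(vapply(rec$lineages[nonempty],
                                    community_mean_investment, numeric(1))),
      mean_auc = mean(rec$auc),
      unique_communities = cum[i])
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Statistical test pass-throughs (labelled, with the pairing conventions
# used when comparing selection methods run from shared initial conditions)

#' Spearman rank correlation
#' @param x,y paired samples.
#' @return List with `rho` and `p` (asymptotic).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("samples must be paired")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Paired Wilcoxon signed-rank test
#'
#' Pairs are runs sharing initial conditions across methods. Identical
#' samples (all differences zero) are reported as `p = 1` by convention.
#'
#' @param x,y paired samples.
#' @param alternative as in [wilcox.test()].
#' @return List with `statistic` and `p`.
#' @export
wilcoxon_paired <- function(x, y, alternative = "two.sided") {
  if (length(x) != length(y)) stop("samples must be paired")
  if (all(x == y)) return(list(statistic = 0, p = 1))
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                     alternative = alternative))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Kruskal-Wallis H test
#' @param values numeric values.
#' @param groups group labels, same length.
#' @return List with `H` and `p`.
#' @export
kruskal_h <- function(values, groups) {
  if (length(values) != length(groups)) stop("values and groups must align")
  kt <- kruskal.test(values, factor(groups))
  list(H = unname(kt$statistic), p = kt$p.value)
}
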