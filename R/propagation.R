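# Propagation: how scored communities found the next round's communities.
#
# Eleven methods. NS: no selection, every tube is diluted into its own
# offspring. Propagule family (PS/PR/PIS/PIR): the 7 best (or random) tubes
# are each diluted into 3 offspring; the invasion variants add random
# species to 5 offspring. Migrant-pool family (MS/MR/MIS/MIR): the selected
# tubes are pooled and the pool is split over 21 offspring. Disassembly
# family (DS/DR): selected communities are taken apart into a per-species
# repository and offspring are re-assembled at a fixed 10 cells per member
# species, with random species removals and additions; scores are penalized
# for extinctions.

.METHODS <- c("NS", "PS", "PR", "PIS", "PIR", "MS", "MR", "MIS", "MIR",
              "DS", "DR")
.random_mode <- function(method) method %in% c("PR", "PIR", "MR", "MIR", "DR")

#' Select parent communities by score
#'
#' Top-`k` by score with ties broken towards the lower tube index, or (for
#' the random controls) a uniform `k`-subset that ignores the scores.
#'
#' @param scores per-tube scores.
#' @param k number of parents (default 7).
#' @param random_mode if `TRUE`, ignore scores and pick uniformly.
#' @return Integer tube indices, length `k`.
#' @export
rank_and_select <- function(scores, k = 7L, random_mode = FALSE) {
  if (k > length(scores)) stop("cannot select ", k, " of ", length(scores))
  if (random_mode) return(sort(sample.int(length(scores), k)))
  order(-scores, seq_along(scores))[seq_len(k)]
}

#' Extinction-penalized degradation score
#'
#' `Dhat = D * surviving / initial`: the disassembly family scales a
#' community's score by the fraction of its member species that survived
#' the round, to favour communities whose members do not drive one another
#' extinct (e.g. a 5-species community losing one member is scaled by 0.8).
#'
#' @param D degradation score(s).
#' @param n_surviving,n_initial species counts (vectorized).
#' @return Penalized score(s).
#' @export
penalized_score <- function(D, n_surviving, n_initial) {
  stopifnot(all(n_initial >= 1), all(n_surviving >= 0),
            all(n_surviving <= n_initial))
  D * n_surviving / n_initial
}

#' Sample offspring parentage in proportion to penalized scores
#'
#' `n_offspring` i.i.d. categorical draws with probability
#' `Dhat_n / sum(Dhat)` (with replacement). If every score is zero the
#' probability is undefined and assignment falls back to uniform.
#'
#' @param selected_scores non-negative scores of the selected parents.
#' @param n_offspring number of offspring (default 21).
#' @return Integer parent indices (into `selected_scores`).
#' @export
sample_parent_assignment <- function(selected_scores, n_offspring = 21L) {
  if (any(selected_scores < 0)) stop("scores must be non-negative")
  k <- length(selected_scores)
  if (sum(selected_scores) <= 0)
    return(sample.int(k, n_offspring, replace = TRUE))
  sample.int(k, n_offspring, replace = TRUE, prob = selected_scores)
}

#' Dilute a tube into an offspring inoculum
#'
#' Approximately `factor`-fold dilution: per lineage the transferred count
#' is `min(Poisson(S / factor), S)`. Transferred cells keep their lineage
#' genotype and are all inactive at the start of the new round.
#'
#' @param tube a completed `tube` (or a lineage table with `sp`, `lid`,
#'   `f`, `S`).
#' @param factor dilution factor (default 20).
#' @return An inoculum list (`sp`, `lid`, `f`, `p0`).
#' @export
dilute <- function(tube, factor = 20) {
  if (factor <= 1) stop("dilution factor must exceed 1")
  lt <- if (inherits(tube, "tube")) lineage_table(tube) else tube
  L <- length(lt$sp)
  if (L == 0L)
    return(list(sp = integer(0), lid = integer(0),
                f = matrix(0, 0, ncol(lt$f)), p0 = numeric(0)))
  counts <- pmin(rpois(L, lt$S / factor), lt$S)
  keep <- counts > 0
  list(sp = lt$sp[keep], lid = lt$lid[keep],
       f = lt$f[keep, , drop = FALSE], p0 = counts[keep])
}

# Merge an invader species (10 ancestral cells) into an inoculum. If an
# ancestral lineage of that species is already in the inoculum the cells
# are added to it, otherwise a new ancestral lineage row is appended.
add_ancestral_cells <- function(inoc, set, species, cells = 10) {
  hit <- which(inoc$sp == species & inoc$lid == species)
  if (length(hit) == 1L) {
    inoc$p0[hit] <- inoc$p0[hit] + cells
  } else {
    inoc$sp <- c(inoc$sp, species)
    inoc$lid <- c(inoc$lid, species)
    inoc$f <- rbind(inoc$f, set$f0[species, , drop = FALSE])
    inoc$p0 <- c(inoc$p0, cells)
  }
  inoc
}

# Invasion step shared by PIS/PIR/MIS/MIR: 5 uniformly chosen offspring
# each receive 1 + Poisson(0.5) distinct invader species at 10 ancestral
# inactive cells apiece (invaders already present still get the cells).
apply_invasions <- function(inocula, set, cfg) {
  targets <- sample.int(length(inocula), cfg$invasion_tubes)
  added <- list()
  for (ti in targets) {
    n_inv <- 1L + rpois(1, cfg$extra_count_rate)
    invaders <- sample.int(set$size, min(n_inv, set$size))
    for (s in invaders)
      inocula[[ti]] <- add_ancestral_cells(inocula[[ti]], set, s,
                                           round(cfg$inoculum *
                                                   cfg$dilution_scale))
    added[[length(added) + 1L]] <- list(tube = ti, species = invaders)
  }
  list(inocula = inocula, added = added)
}

#' No-selection propagation (NS)
#'
#' Every tube is diluted ~20-fold into its own offspring; scores are not
#' used. The baseline for change driven purely by ecological dynamics.
#'
#' @param tubes list of completed tubes.
#' @param cfg an `experiment_config`.
#' @return List with `inocula` (one per tube) and `info`.
#' @export
propagate_no_selection <- function(tubes, cfg) {
  factor <- cfg$dilution_factor / cfg$dilution_scale
  list(inocula = lapply(tubes, dilute, factor = factor),
       info = list(method = "NS", selected = seq_along(tubes)))
}

#' Propagule-family propagation (PS, PR, PIS, PIR)
#'
#' The 7 selected parents each found 3 offspring by independent ~20-fold
#' dilutions (`cfg$ps_score_proportional = TRUE` switches to
#' score-proportional parentage instead of the equal split). PIS/PIR then
#' invade 5 random offspring with random species.
#'
#' @param tubes list of completed tubes.
#' @param scores per-tube degradation scores.
#' @param cfg an `experiment_config` (its `method` picks the variant).
#' @param set the `species_set` (for invader genotypes).
#' @return List with `inocula` and `info` (selected, parent per offspring,
#'   invasions).
#' @export
propagate_propagule <- function(tubes, scores, cfg, set) {
  n <- length(tubes)
  sel <- rank_and_select(scores, cfg$n_selected, .random_mode(cfg$method))
  if (cfg$ps_score_proportional) {
    parent <- sel[sample_parent_assignment(scores[sel], n)]
  } else {
    parent <- rep(sel, each = n %/% cfg$n_selected)[seq_len(n)]
  }
  factor <- cfg$dilution_factor / cfg$dilution_scale
  inocula <- lapply(parent, function(p) dilute(tubes[[p]], factor))
  added <- NULL
  if (cfg$method %in% c("PIS", "PIR")) {
    inv <- apply_invasions(inocula, set, cfg)
    inocula <- inv$inocula
    added <- inv$added
  }
  list(inocula = inocula,
       info = list(method = cfg$method, selected = sel, parent = parent,
                   invasions = added))
}

#' Migrant-pool-family propagation (MS, MR, MIS, MIR)
#'
#' The selected parents are mixed into one migrant pool; each of the 21
#' offspring then receives, per pooled lineage, `Poisson(S / 21)` cells
#' drawn without replacement against what remains of the pool (so the
#' total transferred never exceeds the pool). MIS/MIR add invasions.
#'
#' @inheritParams propagate_propagule
#' @return List with `inocula` and `info`.
#' @export
propagate_migrant_pool <- function(tubes, scores, cfg, set) {
  n <- length(tubes)
  sel <- rank_and_select(scores, cfg$n_selected, .random_mode(cfg$method))
  # pool the selected tubes' lineages, merging by lineage id
  sp <- integer(0); lid <- integer(0); S <- numeric(0); frows <- list()
  for (p in sel) {
    lt <- lineage_table(tubes[[p]])
    for (i in seq_along(lt$sp)) {
      hit <- which(lid == lt$lid[i])
      if (length(hit) == 1L) {
        S[hit] <- S[hit] + lt$S[i]
      } else {
        sp <- c(sp, lt$sp[i]); lid <- c(lid, lt$lid[i])
        S <- c(S, lt$S[i]); frows[[length(frows) + 1L]] <- lt$f[i, ]
      }
    }
  }
  f <- if (length(frows)) do.call(rbind, frows) else matrix(0, 0, set$n_toxins)
  remaining <- S
  rate <- S * cfg$dilution_scale / n
  inocula <- vector("list", n)
  for (ti in seq_len(n)) {
    draws <- if (length(S)) pmin(rpois(length(S), rate), remaining)
             else numeric(0)
    remaining <- remaining - draws
    keep <- draws > 0
    inocula[[ti]] <- list(sp = sp[keep], lid = lid[keep],
                          f = f[keep, , drop = FALSE], p0 = draws[keep])
  }
  added <- NULL
  if (cfg$method %in% c("MIS", "MIR")) {
    inv <- apply_invasions(inocula, set, cfg)
    inocula <- inv$inocula
    added <- inv$added
  }
  list(inocula = inocula,
       info = list(method = cfg$method, selected = sel,
                   pool_size = sum(S), invasions = added))
}

# ---------------------------------------------------------------------------
# Disassembly

#' Initialize the disassembly species repository
#'
#' One entry per pool species holding its ancestral genotype, so every
#' species can be (re-)introduced from round 0 onward.
#'
#' @param set a `species_set`.
#' @return A list of class `repository`, one entry per species with the
#'   lineage snapshot (`lid`, `f`, `S`), `round` and `score`.
#' @export
init_repository <- function(set) {
  structure(lapply(seq_len(set$size), function(s)
    list(lid = s, f = set$f0[s, , drop = FALSE], S = 1,
         round = 0L, score = NA_real_)),
    class = "repository")
}

#' Update the repository from the selected communities of a round
#'
#' For each species present in at least one selected tube, store the
#' lineage composition snapshot from the highest-scoring (penalized)
#' selected tube containing it. Species absent from every selected tube
#' keep their previous entry, so they can later be re-introduced from the
#' most recent round in which they were seen.
#'
#' @param repo a `repository`.
#' @param tubes list of completed tubes.
#' @param dhat penalized scores of all tubes.
#' @param selected indices of the selected tubes.
#' @param round round index stored on updated entries.
#' @return The updated `repository`.
#' @export
update_repository <- function(repo, tubes, dhat, selected, round = NA_integer_) {
  for (s in seq_along(repo)) {
    holders <- selected[vapply(selected, function(ti)
      s %in% surviving_species(tubes[[ti]]), logical(1))]
    if (length(holders) == 0L) next
    best <- holders[order(-dhat[holders], holders)][1L]
    lt <- lineage_table(tubes[[best]])
    idx <- which(lt$sp == s & lt$S > 0)
    repo[[s]] <- list(lid = lt$lid[idx], f = lt$f[idx, , drop = FALSE],
                      S = lt$S[idx], round = as.integer(round),
                      score = dhat[best])
  }
  repo
}

# Inoculate one species from its repository snapshot: `cells` cells drawn
# with replacement across the snapshot's lineages in proportion to their
# recorded abundances.
repo_inoculate <- function(repo_entry, species, cells) {
  nl <- length(repo_entry$lid)
  counts <- if (nl == 1L) cells
            else as.numeric(rmultinom(1, cells, prob = repo_entry$S))
  keep <- counts > 0
  list(sp = rep(as.integer(species), sum(keep)),
       lid = repo_entry$lid[keep],
       f = repo_entry$f[keep, , drop = FALSE],
       p0 = counts[keep])
}

#' Disassembly-family propagation (DS, DR)
#'
#' (i) penalize scores for extinctions; (ii) select 7 parents (top
#' penalized score, or uniformly for DR); (iii) update the per-species
#' repository from the selected tubes; (iv) draw each offspring's
#' composition from a parent sampled in proportion to the penalized scores
#' (uniform for DR); (v) 5 random offspring each lose `1 + Poisson(0.5)`
#' species (never one unique to that offspring, never the last one);
#' (vi) 5 freshly-drawn offspring each gain `1 + Poisson(0.5)` species,
#' preferring species currently absent from every offspring; (vii) any
#' pool species still missing is added to a random offspring, so all
#' species stay available every round; (viii) each member species is
#' inoculated with 10 cells sampled from its repository snapshot, all
#' inactive.
#'
#' @inheritParams propagate_propagule
#' @param repo the current `repository`.
#' @param round round index recorded on repository updates.
#' @return List with `inocula`, the updated `repo`, and `info` (penalized
#'   scores, selected, parentage, removals, additions).
#' @export
propagate_disassembly <- function(tubes, scores, cfg, set, repo,
                                  round = NA_integer_) {
  n <- length(tubes)
  dhat <- tube_penalized_scores(tubes, scores)
  random <- .random_mode(cfg$method)
  sel <- rank_and_select(dhat, cfg$n_selected, random)
  repo <- update_repository(repo, tubes, dhat, sel, round)
  parent <- if (random) sel[sample.int(length(sel), n, replace = TRUE)]
            else sel[sample_parent_assignment(dhat[sel], n)]
  comps <- lapply(parent, function(p) surviving_species(tubes[[p]]))

  # (v) removals
  removals <- list()
  rm_tubes <- sample.int(n, cfg$removal_tubes)
  for (ti in rm_tubes) {
    n_rm <- 1L + rpois(1, cfg$extra_count_rate)
    n_rm <- min(n_rm, max(length(comps[[ti]]) - 1L, 0L))
    removed <- integer(0)
    for (q in seq_len(n_rm)) {
      counts <- table(factor(unlist(comps), levels = seq_len(set$size)))
      cand <- comps[[ti]][counts[comps[[ti]]] >= 2]
      if (length(cand) == 0L) break  # all members unique here: remove none
      victim <- cand[sample.int(length(cand), 1L)]
      comps[[ti]] <- setdiff(comps[[ti]], victim)
      removed <- c(removed, victim)
    }
    removals[[length(removals) + 1L]] <- list(tube = ti, species = removed)
  }

  # (vi) invasions, preferring globally-absent species
  additions <- list()
  inv_tubes <- sample.int(n, cfg$invasion_tubes)
  for (ti in inv_tubes) {
    n_inv <- 1L + rpois(1, cfg$extra_count_rate)
    addedi <- integer(0)
    for (q in seq_len(n_inv)) {
      absent_all <- setdiff(seq_len(set$size), unique(unlist(comps)))
      cand <- setdiff(absent_all, comps[[ti]])
      if (length(cand) == 0L) cand <- setdiff(seq_len(set$size), comps[[ti]])
      if (length(cand) == 0L) break  # tube already holds the whole pool
      sp_new <- cand[sample.int(length(cand), 1L)]
      comps[[ti]] <- sort(c(comps[[ti]], sp_new))
      addedi <- c(addedi, sp_new)
    }
    additions[[length(additions) + 1L]] <- list(tube = ti, species = addedi)
  }

  # (vii) coverage guarantee
  repeat {
    missing <- setdiff(seq_len(set$size), unique(unlist(comps)))
    if (length(missing) == 0L) break
    s <- missing[1L]
    ti <- sample.int(n, 1L)
    comps[[ti]] <- sort(unique(c(comps[[ti]], s)))
    additions[[length(additions) + 1L]] <- list(tube = ti, species = s,
                                                coverage = TRUE)
  }

  # (viii) inoculation from the repository
  base_cells <- round(cfg$inoculum * cfg$dilution_scale)
  inocula <- lapply(comps, function(cc) {
    parts <- lapply(cc, function(s) {
      cells <- if (cfg$ds_fixed_inoculum) base_cells
               else max(1, rpois(1, base_cells))
      repo_inoculate(repo[[s]], s, cells)
    })
    list(sp = unlist(lapply(parts, `[[`, "sp"), use.names = FALSE),
         lid = unlist(lapply(parts, `[[`, "lid"), use.names = FALSE),
         f = do.call(rbind, c(lapply(parts, `[[`, "f"),
                              list(matrix(0, 0, set$n_toxins)))),
         p0 = unlist(lapply(parts, `[[`, "p0"), use.names = FALSE))
  })
  list(inocula = inocula, repo = repo,
       info = list(method = cfg$method, dhat = dhat, selected = sel,
                   parent = parent, removals = removals,
                   additions = additions, compositions = comps))
}

# Penalized scores of a round's tubes; a community that started empty
# (possible under the random controls) scores 0.
tube_penalized_scores <- function(tubes, scores) {
  n_init <- vapply(tubes, function(tb) length(tb$initial_species), integer(1))
  n_surv <- vapply(tubes, function(tb)
    length(intersect(surviving_species(tb), tb$initial_species)), integer(1))
  ifelse(n_init == 0L, 0,
         penalized_score(scores, n_surv, pmax(n_init, 1L)))
}

# Dispatch on cfg$method. Returns list(inocula, repo, info).
propagate <- function(tubes, scores, cfg, set, repo = NULL,
                      round = NA_integer_) {
  out <- switch(cfg$method,
    NS = propagate_no_selection(tubes, cfg),
    PS = , PR = , PIS = , PIR = propagate_propagule(tubes, scores, cfg, set),
    MS = , MR = , MIS = , MIR = propagate_migrant_pool(tubes, scores, cfg, set),
    DS = , DR = propagate_disassembly(tubes, scores, cfg, set, repo, round),
    stop("unknown propagation method: ", cfg$method))
  if (is.null(out$repo)) out$repo <- repo
  out
}
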