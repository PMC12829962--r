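# One simulated batch-culture "tube": lineages of cells growing on 4
# nutrients while degrading 10 toxic compounds over 80 discrete time-steps.
#
# A lineage is a genotype within a species: it shares all ancestral
# parameters except the degradation investment vector f, which mutation can
# change. Cells are either inactive (p0) or active (p1); division is
# two-stage (an inactive cell pays nutrients to activate, an active cell
# divides for free into two inactive daughters). Each time-step applies, in
# order: toxin degradation, activation (with maintenance of already-active
# cells), replication + mutation, and toxin-driven death.
#
# Two engines implement the identical algorithm with the identical RNG call
# sequence: the exported R substeps below (readable reference) and the Rcpp
# engine in src/engine.cpp (default, ~100x faster). Seeded runs are
# bit-identical between the two; a test asserts it.

#' Create a tube at the start of a round
#'
#' @param set a `species_set`.
#' @param inoc inoculum: list with integer vectors `sp`, `lid`, an
#'   `L x n_toxins` investment matrix `f` and counts `p0` (all cells are
#'   inactive at the start of a round).
#' @param N0 initial nutrient amounts (default 2000 units each).
#' @param T0 initial toxin amounts (default 700 units each).
#' @param K Hill constant of the death function (default 700, the same
#'   scale as the initial toxin amount, so an undegraded toxin kills at
#'   half its maximal rate).
#' @return A list of class `tube`.
#' @export
new_tube <- function(set, inoc,
                     N0 = rep(2000, set$n_nutrients),
                     T0 = rep(700, set$n_toxins),
                     K = 700) {
  keep <- inoc$p0 > 0
  L <- sum(keep)
  structure(list(
    sp = as.integer(inoc$sp[keep]),
    lid = as.integer(inoc$lid[keep]),
    f = matrix(inoc$f[keep, , drop = FALSE], nrow = L),
    p0 = as.numeric(inoc$p0[keep]),
    p1 = numeric(L),
    flags = matrix(FALSE, L, set$n_nutrients),
    N = as.numeric(N0), T = as.numeric(T0),
    N0 = as.numeric(N0), T0 = as.numeric(T0),
    K = K,
    initial_species = sort(unique(as.integer(inoc$sp[keep]))),
    t = 0L,
    traj = NULL,
    next_lid = max(set$size, inoc$lid, 0L) + 1L),
    class = "tube")
}

#' Ancestral inoculum for a set of species
#'
#' @param set a `species_set`.
#' @param species integer species ids.
#' @param cells cells per species (default 10, all inactive).
#' @return An inoculum list usable by [new_tube()].
#' @export
ancestral_inoculum <- function(set, species, cells = 10) {
  species <- as.integer(species)
  list(sp = species, lid = species,
       f = set$f0[species, , drop = FALSE],
       p0 = rep(cells, length(species)))
}

#' @export
print.tube <- function(x, ...) {
  cat(sprintf("<tube> %d lineages, %d species, %s cells after %d steps\n",
              length(x$sp), length(unique(x$sp[x$p0 + x$p1 > 0])),
              format(sum(x$p0 + x$p1)), x$t))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pure per-step quantities

#' Rescaled nutrient preferences under depletion
#'
#' When a nutrient's amount `N_j` falls below a species' preference `n_j`,
#' that preference is zeroed (flagged) for the rest of the round. The
#' surviving preferences are renormalized to sum to 1 and the lineage's
#' maximum per-cell uptake drops to `u = sum` of the surviving raw
#' preferences.
#'
#' @param n raw preference vector (sums to 1 at round start).
#' @param N current nutrient amounts.
#' @param flags logical vector of already-flagged nutrients.
#' @return A list with `nhat` (rescaled preferences; zeros if `u = 0`),
#'   `u`, and the updated `flags`.
#' @export
effective_preferences <- function(n, N, flags = rep(FALSE, length(n))) {
  flags <- flags | (N < n)
  u <- sum(n[!flags])
  nhat <- numeric(length(n))
  if (u > 0) nhat[!flags] <- n[!flags] / u
  list(nhat = nhat, u = u, flags = flags)
}

#' Maximum number of cells current nutrients can support
#'
#' `S_max = floor(min_j N_j / nhat_j)` over nutrients with positive
#' rescaled preference; 0 for a fully starved lineage.
#'
#' @param nhat rescaled preferences.
#' @param N current nutrient amounts.
#' @return A non-negative number.
#' @export
max_supported_cells <- function(nhat, N) {
  idx <- nhat > 0
  if (!any(idx)) return(0)
  floor(min(N[idx] / nhat[idx]))
}

#' Per-cell activation probability
#'
#' `a (1 - f.) u sum_j nhat_j N_j(t) / N_j(t0)`: the species' intrinsic
#' activation probability, discounted by its degradation investment, its
#' uptake efficiency under depletion, and the preference-weighted remaining
#' nutrient fraction.
#'
#' @param a intrinsic activation probability.
#' @param fdot total degradation investment of the lineage.
#' @param u maximum uptake (from [effective_preferences()]).
#' @param nhat rescaled preferences.
#' @param N,N0 current and initial nutrient amounts.
#' @return A probability in `[0, 1]`.
#' @export
activation_probability <- function(a, fdot, u, nhat, N, N0) {
  a * (1 - fdot) * u * sum(nhat * N / N0)
}

#' Per-cell, per-step death probability (Hill function of toxin load)
#'
#' `sum_k m_k T_k^2 / (T_k^2 + K^2)`, capped at 1. At `T = K` a toxin
#' contributes half its maximal death rate `m_k`.
#'
#' @param m per-toxin death rates of the species.
#' @param T current toxin amounts.
#' @param K Hill constant.
#' @return A probability in `[0, 1]`.
#' @export
death_probability <- function(m, T, K) {
  T2 <- T * T
  min(1, sum(m * T2 / (T2 + K * K)))
}

# Per-step cache: updates depletion flags (index order, no RNG) and
# computes nhat, u, smax and fdot for every lineage.
step_prep <- function(tube, set) {
  L <- length(tube$sp)
  J <- set$n_nutrients
  nhat <- matrix(0, L, J)
  u <- smax <- fdot <- numeric(L)
  for (i in seq_len(L)) {
    s <- tube$sp[i]
    ep <- effective_preferences(set$n[s, ], tube$N, tube$flags[i, ])
    tube$flags[i, ] <- ep$flags
    nhat[i, ] <- ep$nhat
    u[i] <- ep$u
    smax[i] <- if (ep$u > 0) max_supported_cells(ep$nhat, tube$N) else 0
    fdot[i] <- sum(tube$f[i, ])
  }
  list(tube = tube, nhat = nhat, u = u, smax = smax, fdot = fdot)
}

# ---------------------------------------------------------------------------
# Substeps (reference engine). Each takes the per-step cache `prep` and a
# processing order `perm`; called standalone (both NULL) they compute the
# cache themselves and process lineages in index order, which is convenient
# in tests.

.substep_args <- function(tube, set, prep, perm) {
  if (is.null(prep)) {
    prep <- step_prep(tube, set)
  } else {
    prep$tube <- tube  # cache precomputed; state comes from the caller
  }
  if (is.null(perm)) perm <- seq_along(prep$tube$sp)
  prep$perm <- perm
  prep
}

#' Toxin degradation substep
#'
#' For each lineage, `C = min(S, S_max)` cells each remove `f_k u` units of
#' every still-present toxin `k` and pay `nhat_j` times the investment
#' aimed at still-present toxins in nutrients. Depleted toxins are not
#' degraded and their share of the nutrient cost is not charged. Resources
#' are deducted sequentially in a per-step shuffled lineage order, with
#' amounts capped at what remains. No randomness.
#'
#' @param tube a `tube`.
#' @param set the `species_set`.
#' @param prep,perm internal per-step cache and processing order; leave
#'   `NULL` to compute on the fly.
#' @return The updated `tube`.
#' @export
degradation_substep <- function(tube, set, prep = NULL, perm = NULL) {
  pr <- .substep_args(tube, set, prep, perm)
  tube <- pr$tube
  for (i in pr$perm) {
    S <- tube$p0[i] + tube$p1[i]
    if (S <= 0 || pr$u[i] <= 0 || pr$fdot[i] <= 0) next
    C <- min(S, pr$smax[i])
    if (C <= 0) next
    fi <- tube$f[i, ]
    present <- tube$T > 0
    factive <- sum(fi[present])
    if (factive <= 0) next
    rem <- pmin(C * fi[present] * pr$u[i], tube$T[present])
    tube$T[present] <- tube$T[present] - rem
    cost <- pmin(C * pr$nhat[i, ] * factive, tube$N)
    tube$N <- tube$N - cost
  }
  tube
}

#' Activation substep
#'
#' Already-active cells first pay maintenance of `nhat_j (1 - f.)` per
#' nutrient to stay active; cells that cannot afford full maintenance
#' revert to the inactive pool (configurable). Then
#' `min(Poisson(p * n_eligible), n_eligible)` inactive cells activate,
#' where `p` is [activation_probability()] evaluated on the nutrient
#' amounts left after degradation and `n_eligible = min(p0, S_max)`; each
#' activating cell pays the same per-cell cost. Activation is additionally
#' capped by what the remaining nutrients can pay for.
#'
#' @inheritParams degradation_substep
#' @param maint_revert if `TRUE` (default) active cells that cannot pay
#'   maintenance revert to inactive; if `FALSE` they stay active and
#'   consume what is left.
#' @return The updated `tube`.
#' @export
activation_substep <- function(tube, set, prep = NULL, perm = NULL,
                               maint_revert = TRUE) {
  pr <- .substep_args(tube, set, prep, perm)
  tube <- pr$tube
  Nsnap <- tube$N
  for (i in pr$perm) {
    onemf <- 1 - pr$fdot[i]
    if (pr$u[i] <= 0) {
      if (maint_revert && tube$p1[i] > 0) {
        tube$p0[i] <- tube$p0[i] + tube$p1[i]
        tube$p1[i] <- 0
      }
      next
    }
    nh <- pr$nhat[i, ]
    pos <- nh > 0
    if (tube$p1[i] > 0 && onemf > 0) {
      if (!maint_revert) {
        cost <- pmin(tube$p1[i] * nh * onemf, tube$N)
        tube$N <- tube$N - cost
      } else {
        afford <- min(tube$N[pos] / (nh[pos] * onemf))
        paid <- min(tube$p1[i], floor(afford))
        cost <- pmin(paid * nh * onemf, tube$N)
        tube$N <- tube$N - cost
        if (paid < tube$p1[i]) {
          tube$p0[i] <- tube$p0[i] + (tube$p1[i] - paid)
          tube$p1[i] <- paid
        }
      }
    }
    s <- tube$sp[i]
    pact <- activation_probability(set$a[s], pr$fdot[i], pr$u[i], nh,
                                   Nsnap, tube$N0)
    nelig <- min(tube$p0[i], pr$smax[i])
    if (pact > 0 && nelig > 0) {
      act <- min(rpois(1, pact * nelig), nelig)
      if (onemf > 0) {
        afford <- min(tube$N[pos] / (nh[pos] * onemf))
        act <- min(act, floor(afford))
      }
      if (act > 0) {
        cost <- pmin(act * nh * onemf, tube$N)
        tube$N <- tube$N - cost
        tube$p0[i] <- tube$p0[i] - act
        tube$p1[i] <- tube$p1[i] + act
      }
    }
  }
  tube
}

#' Replication and mutation substep
#'
#' Active cells divide with probability `r (1 - f.)` (no nutrient cost):
#' `min(Poisson(r (1 - f.) p1), p1)` divisions, each replacing one active
#' cell by two inactive daughters. One daughter keeps the parent genotype;
#' the other mutates with probability `mu`, multiplying every unmasked
#' investment entry by an independent lognormal(0, sigma^2) factor and
#' founding a new lineage of one cell. If a mutant's total investment
#' exceeds 1 the whole vector is rescaled to sum exactly 1 (relative
#' allocation preserved).
#'
#' @inheritParams degradation_substep
#' @param mu per-division mutation probability (default 0.01).
#' @param sigma2 lognormal variance parameter of the mutation multiplier
#'   (default 0.4; the median multiplier is 1).
#' @return The updated `tube` (new lineages appended; `tube$next_lid`
#'   advanced).
#' @export
replication_mutation_substep <- function(tube, set, mu = 0.01, sigma2 = 0.4,
                                         prep = NULL, perm = NULL) {
  pr <- .substep_args(tube, set, prep, perm)
  tube <- pr$tube
  sdlog <- sqrt(sigma2)
  nb_sp <- integer(0); nb_lid <- integer(0)
  nb_f <- list(); nb_flag <- list()
  for (i in pr$perm) {
    s <- tube$sp[i]
    prob <- set$r[s] * (1 - pr$fdot[i])
    if (prob <= 0 || tube$p1[i] <= 0) next
    d <- min(rpois(1, prob * tube$p1[i]), tube$p1[i])
    if (d <= 0) next
    tube$p1[i] <- tube$p1[i] - d
    nmut <- 0
    if (mu > 0) nmut <- rbinom(1, d, mu)
    tube$p0[i] <- tube$p0[i] + 2 * d - nmut
    if (nmut > 0) {
      for (mt in seq_len(nmut)) {
        fnew <- tube$f[i, ]
        idx <- which(set$mask_f[s, ] > 0)
        if (length(idx) > 0)
          fnew[idx] <- fnew[idx] * rlnorm(length(idx), 0, sdlog)
        tot <- sum(fnew)
        if (tot > 1) fnew <- fnew / tot
        nb_sp <- c(nb_sp, s)
        nb_lid <- c(nb_lid, tube$next_lid)
        tube$next_lid <- tube$next_lid + 1L
        nb_f[[length(nb_f) + 1L]] <- fnew
        nb_flag[[length(nb_flag) + 1L]] <- tube$flags[i, ]
      }
    }
  }
  if (length(nb_sp) > 0) {
    tube$sp <- c(tube$sp, nb_sp)
    tube$lid <- c(tube$lid, nb_lid)
    tube$f <- rbind(tube$f, do.call(rbind, nb_f))
    tube$p0 <- c(tube$p0, rep(1, length(nb_sp)))
    tube$p1 <- c(tube$p1, rep(0, length(nb_sp)))
    tube$flags <- rbind(tube$flags, do.call(rbind, nb_flag))
  }
  tube
}

#' Death substep
#'
#' Every cell (active or inactive) dies with probability given by
#' [death_probability()]: per lineage `min(Poisson(p S), S)` deaths,
#' allocated between the inactive and active pools by a hypergeometric
#' draw (cells are exchangeable).
#'
#' @inheritParams degradation_substep
#' @return The updated `tube`.
#' @export
death_substep <- function(tube, set, prep = NULL, perm = NULL) {
  if (is.null(perm)) perm <- seq_along(tube$sp)
  for (i in perm) {
    S <- tube$p0[i] + tube$p1[i]
    if (S <= 0) next
    s <- tube$sp[i]
    pdeath <- death_probability(set$m[s, ], tube$T, tube$K)
    if (pdeath <= 0) next
    deaths <- min(rpois(1, pdeath * S), S)
    if (deaths <= 0) next
    d1 <- if (tube$p1[i] <= 0) 0
          else if (tube$p0[i] <= 0) deaths
          else rhyper(1, tube$p1[i], tube$p0[i], deaths)
    tube$p1[i] <- tube$p1[i] - d1
    tube$p0[i] <- tube$p0[i] - (deaths - d1)
  }
  tube
}

prune_tube <- function(tube) {
  keep <- tube$p0 + tube$p1 > 0
  if (all(keep)) return(tube)
  tube$sp <- tube$sp[keep]
  tube$lid <- tube$lid[keep]
  tube$f <- tube$f[keep, , drop = FALSE]
  tube$p0 <- tube$p0[keep]
  tube$p1 <- tube$p1[keep]
  tube$flags <- tube$flags[keep, , drop = FALSE]
  tube
}

# ---------------------------------------------------------------------------

#' Run one batch-culture round
#'
#' Applies the four substeps in order for `t_end` time-steps and records
#' the per-step population of each species (for biomass area-under-curve).
#' Uses the current RNG state; both engines consume the identical draw
#' sequence, so a seeded round is bit-identical between `engine = "cpp"`
#' (default, compiled) and `engine = "R"` (reference).
#'
#' @param tube a fresh `tube` from [new_tube()].
#' @param set the `species_set`.
#' @param t_end time-steps per round (default 80).
#' @param mu per-division mutation probability (default 0.01).
#' @param sigma2 lognormal variance of the mutation multiplier (default 0.4).
#' @param maint_revert see [activation_substep()].
#' @param engine `"cpp"` or `"R"`.
#' @return The `tube` after `t_end` steps, with `tube$traj` a
#'   `t_end x pool` matrix of per-step species populations.
#' @export
run_round <- function(tube, set, t_end = 80L, mu = 0.01, sigma2 = 0.4,
                      maint_revert = TRUE, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    res <- cpp_run_round(tube$sp, tube$lid, tube$f, tube$p0, tube$p1,
                         tube$flags, tube$N, tube$T, tube$N0, tube$T0,
                         set$a, set$r, set$n, set$m,
                         matrix(as.integer(set$mask_f), nrow = set$size),
                         tube$K, as.integer(t_end), mu, sqrt(sigma2),
                         maint_revert, tube$next_lid)
    tube$sp <- res$sp; tube$lid <- res$lid
    tube$f <- matrix(res$f, nrow = length(res$sp))
    tube$p0 <- res$p0; tube$p1 <- res$p1
    tube$flags <- matrix(res$flags, nrow = length(res$sp))
    tube$N <- res$N; tube$T <- res$T
    tube$traj <- res$traj
    tube$next_lid <- res$next_lid
    tube$t <- tube$t + as.integer(t_end)
    return(tube)
  }
  traj <- matrix(0, t_end, set$size)
  for (t in seq_len(t_end)) {
    L <- length(tube$sp)
    if (L > 0) {
      perm <- if (L > 1) order(runif(L)) else 1L
      pr <- step_prep(tube, set)
      tube <- pr$tube
      tube <- degradation_substep(tube, set, pr, perm)
      tube <- activation_substep(tube, set, pr, perm, maint_revert)
      tube <- replication_mutation_substep(tube, set, mu, sigma2, pr, perm)
      # newborn mutant lineages are subject to death in their birth step,
      # processed after the shuffled pre-existing lineages
      newborn <- seq_len(length(tube$sp) - L) + L
      tube <- death_substep(tube, set, pr, c(perm, newborn))
      tube <- prune_tube(tube)
    }
    tot <- tube$p0 + tube$p1
    for (i in seq_along(tube$sp))
      traj[t, tube$sp[i]] <- traj[t, tube$sp[i]] + tot[i]
  }
  tube$traj <- traj
  tube$t <- tube$t + as.integer(t_end)
  tube
}

#' Degradation score of a completed round
#'
#' `D = 1 - sqrt(mean_k (T_k(t_end) / T_k(t0))^2)`: one minus the
#' root-mean-square of the final-to-initial toxin ratios. 1 means all
#' toxins fully degraded, 0 none.
#'
#' @param tube a `tube` after [run_round()].
#' @return A score in `[0, 1]`.
#' @export
degradation_score <- function(tube) {
  if (any(tube$T0 <= 0)) stop("degradation score undefined for T0 = 0")
  1 - sqrt(mean((tube$T / tube$T0)^2))
}

#' Species present in a tube (positive total population)
#' @param tube a `tube`.
#' @return Sorted integer species ids.
#' @export
surviving_species <- function(tube) {
  sort(unique(tube$sp[tube$p0 + tube$p1 > 0]))
}

#' Per-species abundance vector over the whole pool
#'
#' Lineages of one species are summed; absent species are zeros.
#'
#' @param tube a `tube`.
#' @param pool_size pool size (length of the result).
#' @return A numeric vector of length `pool_size`.
#' @export
species_abundance <- function(tube, pool_size) {
  ab <- numeric(pool_size)
  tot <- tube$p0 + tube$p1
  for (i in seq_along(tube$sp)) ab[tube$sp[i]] <- ab[tube$sp[i]] + tot[i]
  ab
}

# End-of-round lineage snapshot used by records, the repository and dilution.
lineage_table <- function(tube) {
  list(sp = tube$sp, lid = tube$lid, f = tube$f, S = tube$p0 + tube$p1)
}
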