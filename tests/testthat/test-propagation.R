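test_that("parent selection ranks by score with deterministic tie-breaks", {
  expect_identical(rank_and_select(seq(1, 0.2, length.out = 21)), 1:7)
  expect_identical(rank_and_select(rep(0.5, 21)), 1:7)
  expect_identical(rank_and_select(c(0.1, 0.9, 0.9, 0.2), k = 2L), 2:3)
  set.seed(1); r1 <- rank_and_select(rep(0, 21), random_mode = TRUE)
  set.seed(1); r2 <- rank_and_select(rep(0, 21), random_mode = TRUE)
  expect_identical(r1, r2)
  expect_length(unique(r1), 7L)
  expect_error(rank_and_select(rep(1, 5), k = 7L), "cannot select")
})

test_that("penalized score scales by the surviving fraction", {
  expect_equal(penalized_score(0.5, 4, 5), 0.4)
  expect_equal(penalized_score(0.7, 3, 3), 0.7)
  expect_equal(penalized_score(0.7, 0, 3), 0)
  expect_equal(penalized_score(c(0.5, 1), c(4, 2), c(5, 4)), c(0.4, 0.5))
  expect_error(penalized_score(0.5, 4, 0))
})

test_that("offspring parentage is proportional to penalized scores", {
  set.seed(1)
  expect_true(all(sample_parent_assignment(c(1, 0, 0, 0, 0, 0, 0)) == 1L))
  draws <- sample_parent_assignment(c(2, 1, 1, 0, 0, 0, 0),
                                    n_offspring = 20000L)
  freq <- tabulate(draws, 7) / 20000
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_true(all(abs(freq[1:3] - c(0.5, 0.25, 0.25)) < 4 * se))
  expect_true(all(freq[4:7] == 0))
  # all-zero scores: uniform fallback covers every parent
  unif <- replicate(500, sample_parent_assignment(rep(0, 7), 1L))
  expect_setequal(unique(unif), 1:7)
  expect_error(sample_parent_assignment(c(1, -0.1)), "non-negative")
})

test_that("dilution transfers Poisson(S/factor) cells per lineage", {
  tube <- fake_tube(sp = c(1L, 2L), p0 = c(1500, 500), p1 = c(500, 0))
  totals <- vapply(1:1000, function(i) {
    set.seed(i)
    sum(dilute(tube, 20)$p0)
  }, numeric(1))
  expect_lt(abs(mean(totals) - 2500 / 20), 3 * sd(totals) / sqrt(1000))
  # truncation: never more cells than the parent lineage held
  small <- fake_tube(sp = 1L, p0 = 3)
  for (i in 1:50) {
    set.seed(i)
    expect_lte(sum(dilute(small, 1.5)$p0), 3)
  }
  empty <- fake_tube(sp = integer(0), p0 = numeric(0))
  expect_length(dilute(empty, 20)$p0, 0L)
  expect_error(dilute(tube, 1), "exceed 1")
})

test_that("propagule selection gives each chosen parent three offspring", {
  set <- test_pool()
  tubes <- lapply(1:21, function(i)
    fake_tube(sp = ((i %% 15) + 1), p0 = 1000 + i, n_toxins = 10L))
  scores <- seq(1, 0.2, length.out = 21)
  cfg <- experiment_config(method = "PS", rounds = 1)
  set.seed(3)
  out <- propagate_propagule(tubes, scores, cfg, set)
  expect_identical(out$info$selected, 1:7)
  expect_identical(as.vector(table(out$info$parent)), rep(3L, 7))
  expect_length(out$inocula, 21L)

  # PIS with no invasion tubes collapses to PS exactly
  cfg_pis <- experiment_config(method = "PIS", rounds = 1, invasion_tubes = 0L)
  set.seed(3); ps <- propagate_propagule(tubes, scores, cfg, set)
  set.seed(3); pis <- propagate_propagule(tubes, scores, cfg_pis, set)
  expect_identical(ps$inocula, pis$inocula)

  # random control ignores scores but is seeded
  cfg_pr <- experiment_config(method = "PR", rounds = 1)
  set.seed(5); pr1 <- propagate_propagule(tubes, scores, cfg_pr, set)
  set.seed(5); pr2 <- propagate_propagule(tubes, scores, cfg_pr, set)
  expect_identical(pr1$info$selected, pr2$info$selected)
})

test_that("invaders add ten ancestral cells even when already present", {
  set <- test_pool()
  inoc <- list(sp = 3L, lid = 3L, f = set$f0[3, , drop = FALSE], p0 = 5)
  merged <- commselect:::add_ancestral_cells(inoc, set, 3L, 10)
  expect_equal(merged$p0, 15)          # merged into the ancestral lineage
  grown <- commselect:::add_ancestral_cells(inoc, set, 7L, 10)
  expect_equal(sum(grown$p0), 15)
  expect_setequal(grown$sp, c(3L, 7L))
  # a mutated lineage of the same species stays separate from the invader
  mut <- list(sp = 3L, lid = 99L, f = set$f0[3, , drop = FALSE] * 0.5, p0 = 5)
  both <- commselect:::add_ancestral_cells(mut, set, 3L, 10)
  expect_equal(sort(both$p0), c(5, 10))
})

test_that("invasion counts average 1 + Poisson(0.5) species per tube", {
  set <- test_pool()
  tubes <- lapply(1:21, function(i) fake_tube(sp = 1L, p0 = 100,
                                              n_toxins = 10L))
  cfg <- experiment_config(method = "PIS", rounds = 1)
  counts <- c()
  for (i in 1:300) {
    set.seed(i)
    out <- propagate_propagule(tubes, rep(0.5, 21), cfg, set)
    counts <- c(counts, vapply(out$info$invasions, function(x)
      length(x$species), integer(1)))
  }
  expect_lt(abs(mean(counts) - 1.5), 3 * sd(counts) / sqrt(length(counts)))
})

test_that("migrant pool draws without replacement and mixes all parents", {
  set <- test_pool()
  # parent 1 monopolizes species 9; the pool must make it reachable
  tubes <- c(list(fake_tube(sp = c(1L, 9L), p0 = c(500, 4000),
                            n_toxins = 10L)),
             lapply(2:21, function(i) fake_tube(sp = 1L, lid = 1L, p0 = 500,
                                                n_toxins = 10L)))
  scores <- c(1, seq(0.9, 0.2, length.out = 20))
  cfg <- experiment_config(method = "MS", rounds = 1)
  pool_total <- 500 * 7 + 4000  # 7 selected tubes (ancestral lid 1 merges)
  for (i in 1:30) {
    set.seed(i)
    out <- propagate_migrant_pool(tubes, scores, cfg, set)
    transferred <- sum(unlist(lapply(out$inocula, `[[`, "p0")))
    expect_lte(transferred, pool_total)
    expect_identical(out$info$pool_size, pool_total)
    # species 9 reaches essentially every offspring (rate 4000/21 per tube)
    has9 <- vapply(out$inocula, function(x) 9L %in% x$sp, logical(1))
    expect_gt(mean(has9), 0.9)
  }
  # identical parents: offspring expectation matches the parent composition
  same <- lapply(1:21, function(i) fake_tube(sp = c(1L, 2L), lid = c(1L, 2L),
                                             p0 = c(600, 300),
                                             n_toxins = 10L))
  got <- vapply(1:200, function(i) {
    set.seed(1e5 + i)
    inoc <- propagate_migrant_pool(same, rep(0.5, 21), cfg, set)$inocula[[1]]
    c(sum(inoc$p0[inoc$sp == 1]), sum(inoc$p0[inoc$sp == 2]))
  }, numeric(2))
  expect_equal(rowMeans(got) / sum(rowMeans(got)), c(2 / 3, 1 / 3),
               tolerance = 0.05)
})

test_that("repository tracks the best-scoring holder of each species", {
  set <- test_pool()
  repo <- init_repository(set)
  expect_length(repo, 15L)
  expect_identical(repo[[4]]$f[1, ], set$f0[4, ])

  tubeA <- fake_tube(sp = c(2L, 3L), lid = c(2L, 3L), p0 = c(100, 50),
                     n_toxins = 10L)
  tubeB <- fake_tube(sp = c(2L, 5L), lid = c(2L, 5L), p0 = c(80, 10),
                     n_toxins = 10L)
  dhat <- c(0.3, 0.6)
  repo2 <- update_repository(repo, list(tubeA, tubeB), dhat,
                             selected = 1:2, round = 3L)
  expect_equal(repo2[[2]]$S, 80)       # species 2 snapshot from tube B (0.6)
  expect_equal(repo2[[2]]$score, 0.6)
  expect_equal(repo2[[3]]$S, 50)       # only tube A holds species 3
  expect_identical(repo2[[7]], repo[[7]])  # absent species keep old entries
})

test_that("disassembly re-assembles offspring at fixed inocula with full pool coverage", {
  set <- test_pool()
  cfg <- experiment_config(method = "DS", rounds = 1)
  repo <- init_repository(set)
  tubes <- lapply(1:21, function(i) {
    sp <- sort(unique(((i - 1):(i + 2)) %% 15 + 1))
    fake_tube(sp = sp, p0 = rep(100, length(sp)), n_toxins = 10L)
  })
  scores <- seq(0.9, 0.1, length.out = 21)
  for (i in 1:25) {
    set.seed(i)
    out <- propagate_disassembly(tubes, scores, cfg, set, repo, round = 1L)
    expect_length(out$inocula, 21L)
    # coverage invariant: every pool species is in at least one offspring
    expect_setequal(unique(unlist(out$info$compositions)), 1:15)
    for (ti in 1:21) {
      inoc <- out$inocula[[ti]]
      comp <- out$info$compositions[[ti]]
      expect_setequal(unique(inoc$sp), comp)
      # fixed-inoculum mode: exactly 10 cells per member species
      for (s in comp) expect_equal(sum(inoc$p0[inoc$sp == s]), 10)
      expect_gte(length(comp), 1L)
    }
    # removals never strip a species held nowhere else
    for (rm in out$info$removals)
      for (s in rm$species)
        expect_true(s %in% unlist(out$info$compositions))
  }
})

test_that("no-selection propagation maps each parent to its own offspring", {
  set <- test_pool()
  tubes <- lapply(1:21, function(i) fake_tube(sp = i %% 15 + 1L,
                                              lid = i %% 15 + 1L,
                                              p0 = 2000, n_toxins = 10L))
  cfg <- experiment_config(method = "NS", rounds = 1)
  set.seed(2); o1 <- propagate_no_selection(tubes, cfg)
  set.seed(2); o2 <- propagate_no_selection(tubes, cfg)
  expect_identical(o1, o2)
  for (i in seq_along(tubes))
    expect_true(all(o1$inocula[[i]]$sp %in% tubes[[i]]$sp))
  totals <- vapply(1:300, function(i) {
    set.seed(i)
    sum(unlist(lapply(propagate_no_selection(tubes, cfg)$inocula,
                      `[[`, "p0")))
  }, numeric(1))
  expect_equal(mean(totals), 21 * 2000 / 20, tolerance = 0.02)
})
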