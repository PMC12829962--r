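test_that("preference rescaling under depletion matches closed forms", {
  # ample nutrients: identity
  ep <- effective_preferences(c(0.5, 0.3, 0.2, 0), rep(2000, 4))
  expect_equal(ep$nhat, c(0.5, 0.3, 0.2, 0))
  expect_equal(ep$u, 1)
  # one nutrient below its preference is zeroed and flagged
  ep <- effective_preferences(c(0.5, 0.3, 0.2, 0), c(2000, 0.2, 2000, 2000))
  expect_equal(ep$u, 0.7)
  expect_equal(ep$nhat, c(5 / 7, 0, 2 / 7, 0))
  expect_identical(ep$flags, c(FALSE, TRUE, FALSE, FALSE))
  # flags are sticky: recovered nutrient amounts do not unflag
  ep2 <- effective_preferences(c(0.5, 0.3, 0.2, 0), rep(2000, 4), ep$flags)
  expect_equal(ep2$u, 0.7)
  # everything depleted: starved state
  ep <- effective_preferences(c(0.5, 0.5, 0, 0), c(0.1, 0.1, 5, 5))
  expect_equal(ep$u, 0)
})

test_that("max supported cells follows min_j N_j / nhat_j", {
  expect_equal(max_supported_cells(c(1, 0, 0, 0), c(2000, 1, 1, 1)), 2000)
  expect_equal(max_supported_cells(c(0.5, 0.5, 0, 0), c(10, 4, 99, 99)), 8)
  expect_equal(max_supported_cells(c(0.5, 0.5, 0, 0), rep(0, 4)), 0)
  expect_equal(max_supported_cells(rep(0, 4), rep(2000, 4)), 0)
})

test_that("activation and death probabilities match their closed forms", {
  # fresh tube, no investment: probability is the intrinsic a
  expect_equal(activation_probability(0.37, 0, 1, c(0.5, 0.5), c(2000, 2000),
                                      c(2000, 2000)), 0.37)
  # nutrients halved uniformly: probability halves
  expect_equal(activation_probability(0.37, 0, 1, c(0.5, 0.5), c(1000, 1000),
                                      c(2000, 2000)), 0.37 / 2)
  # full investment: no activation
  expect_equal(activation_probability(0.9, 1, 1, c(1, 0), c(2000, 1),
                                      c(2000, 2000)), 0)
  # Hill half-maximum at T = K
  expect_equal(death_probability(0.02, 700, 700), 0.01)
  expect_equal(death_probability(c(0.01, 0.02), c(700, 700), 700), 0.015)
  expect_equal(death_probability(0.02, 0, 700), 0)
  # cap at 1
  expect_equal(death_probability(rep(1, 200), rep(1e6, 200), 700), 1)
})

test_that("degradation substep removes f*u per cell and charges nutrients", {
  set <- fix_single(f = 0.3)
  tube <- new_tube(set, ancestral_inoculum(set, 1L, 10), N0 = 2000, T0 = 700)
  out <- degradation_substep(tube, set)
  expect_equal(out$T, 700 - 10 * 0.3 * 1)       # 10 cells, f = 0.3, u = 1
  expect_equal(out$N, 2000 - 10 * 1 * 0.3)      # cost C * nhat * f.
  # zero investment: nothing happens
  set0 <- fix_single(f = 0)
  tube0 <- new_tube(set0, ancestral_inoculum(set0, 1L, 10))
  out0 <- degradation_substep(tube0, set0)
  expect_equal(out0$T, tube0$T)
  expect_equal(out0$N, tube0$N)
  # depleted toxin: no degradation and no cost for its share
  tube$T <- 0
  outd <- degradation_substep(tube, set)
  expect_equal(outd$T, 0)
  expect_equal(outd$N, tube$N)
})

test_that("substeps respect investment trade-offs and counts stay feasible", {
  # full investment: no activation, no division
  set <- fix_single(a = 1, r = 1, f = 1)
  tube <- new_tube(set, ancestral_inoculum(set, 1L, 50))
  set.seed(1)
  tube2 <- activation_substep(tube, set)
  expect_equal(tube2$p1, 0)
  tube2$p1 <- 10; tube2$p0 <- 40
  tube3 <- replication_mutation_substep(tube2, set, mu = 0.5)
  expect_equal(tube3$p0 + tube3$p1, 50)  # no divisions happened
  # no toxins present: no deaths
  set2 <- fix_single(m = 0.02)
  tubeb <- new_tube(set2, ancestral_inoculum(set2, 1L, 50), T0 = 700)
  tubeb$T <- 0
  set.seed(2)
  expect_equal(sum(death_substep(tubeb, set2)$p0), 50)
  # mu = 0 never creates lineages
  set3 <- fix_single(a = 0.9, r = 0.9)
  tb <- new_tube(set3, ancestral_inoculum(set3, 1L, 100))
  set.seed(3)
  tb <- run_round(tb, set3, t_end = 40, mu = 0)
  expect_identical(length(tb$sp), 1L)
  expect_identical(tb$next_lid, new_tube(set3, ancestral_inoculum(set3, 1L, 100))$next_lid)
})

test_that("seeded rounds are deterministic and empty tubes coast", {
  set <- test_pool()
  inoc <- ancestral_inoculum(set, c(1L, 4L, 7L, 12L), 10)
  tb <- new_tube(set, inoc)
  set.seed(9); a <- run_round(tb, set)
  set.seed(9); b <- run_round(tb, set)
  expect_identical(a, b)

  empty <- new_tube(set, ancestral_inoculum(set, integer(0), 10))
  set.seed(1)
  out <- run_round(empty, set)
  expect_equal(out$N, out$N0)
  expect_equal(out$T, out$T0)
  expect_equal(sum(out$traj), 0)
})

test_that("R and compiled engines are bit-identical on seeded runs", {
  cases <- list(
    list(set = test_pool(), species = c(2L, 5L, 9L, 14L), mu = 0.05,
         N0 = rep(600, 4)),
    list(set = fix_competitors(), species = 1:2, mu = 0.2, N0 = 400))
  for (cs in cases) {
    tb <- new_tube(cs$set, ancestral_inoculum(cs$set, cs$species, 10),
                   N0 = cs$N0,
                   T0 = rep(700, cs$set$n_toxins))
    set.seed(31); a <- run_round(tb, cs$set, t_end = 80, mu = cs$mu,
                                 engine = "cpp")
    sa <- .Random.seed
    set.seed(31); b <- run_round(tb, cs$set, t_end = 80, mu = cs$mu,
                                 engine = "R")
    expect_identical(.Random.seed, sa)  # same number of RNG draws
    for (fld in c("sp", "lid", "f", "p0", "p1", "flags", "N", "T", "traj",
                  "next_lid"))
      expect_identical(a[[fld]], b[[fld]])
  }
})

test_that("resources never increase and populations stay integral", {
  set <- test_pool()
  tb <- new_tube(set, ancestral_inoculum(set, c(1L, 3L, 8L, 11L), 10))
  set.seed(17)
  prevN <- tb$N; prevT <- tb$T
  for (t in 1:80) {
    tb <- run_round(tb, set, t_end = 1L, mu = 0.05)
    expect_true(all(tb$N <= prevN + 1e-9))
    expect_true(all(tb$T <= prevT + 1e-9))
    expect_true(all(tb$N >= -1e-9) && all(tb$T >= -1e-9))
    expect_true(all(tb$p0 == round(tb$p0)) && all(tb$p0 >= 0))
    expect_true(all(tb$p1 == round(tb$p1)) && all(tb$p1 >= 0))
    prevN <- tb$N; prevT <- tb$T
  }
})

test_that("total investment stays in [0, 1] under mutation stress", {
  set <- manual_species_set(a = 0.9, r = 0.9, n = matrix(1, 1, 1),
                            m = matrix(0, 1, 2),
                            f0 = matrix(c(0.5, 0.4), 1, 2))
  set.seed(23)
  divisions <- 0; explored <- 0
  while (divisions < 1e5) {
    tb <- new_tube(set, ancestral_inoculum(set, 1L, 500),
                   N0 = 3e4, T0 = c(700, 700))
    before <- 500
    tb <- run_round(tb, set, t_end = 80, mu = 0.05)
    divisions <- divisions + (sum(tb$p0 + tb$p1) - before)  # net, no deaths
    explored <- explored + length(tb$sp)
    tots <- rowSums(tb$f)
    expect_true(all(tots >= 0 & tots <= 1 + 1e-12))
    expect_true(all(tb$f >= 0))
  }
  expect_gt(explored, 100)  # the stress test really explored mutants
})

test_that("mean trajectory of a simple birth system matches the expectation recursion", {
  # one species, one nutrient, no death, no degradation, vast nutrients:
  # activation ~ a p0, division ~ r p1, both linear, so the expectation
  # obeys p0' = p0 - a p0 + 2 r (p1 + a p0), p1' = (1 - r)(p1 + a p0)
  # (activation reads nutrient fractions that stay ~ 1 at N0 = 1e8).
  a <- 0.25; r <- 0.3; steps <- 10L; n_runs <- 400L; start <- 200
  set <- fix_single(a = a, r = r)
  oracle <- function() {
    p0 <- start; p1 <- 0
    for (t in seq_len(steps)) {
      act <- a * p0
      p1a <- p1 + act
      div <- r * p1a
      p0 <- p0 - act + 2 * div
      p1 <- p1a - div
    }
    p0 + p1
  }
  tb <- new_tube(set, ancestral_inoculum(set, 1L, start), N0 = 1e8, T0 = 700)
  finals <- vapply(seq_len(n_runs), function(i) {
    set.seed(1000 + i)
    out <- run_round(tb, set, t_end = steps, mu = 0)
    sum(out$p0 + out$p1)
  }, numeric(1))
  mc_se <- sd(finals) / sqrt(n_runs)
  expect_lt(abs(mean(finals) - oracle()), 3 * mc_se)
})

test_that("higher investment slows growth and speeds degradation", {
  low <- fix_single(a = 0.6, r = 0.6, f = 0.2)
  high <- fix_single(a = 0.6, r = 0.6, f = 0.6)
  pops <- sapply(list(low, high), function(set) {
    mean(vapply(1:100, function(i) {
      set.seed(i)
      tb <- run_round(new_tube(set, ancestral_inoculum(set, 1L, 20)),
                      set, t_end = 30, mu = 0)
      sum(tb$p0 + tb$p1)
    }, numeric(1)))
  })
  # per-cell removal: pin the population (no activation, no death) so the
  # comparison is not confounded by growth feedback
  degr <- sapply(c(0.2, 0.6), function(f) {
    set <- fix_single(a = 0, r = 0.6, f = f)
    set.seed(1)
    tb <- run_round(new_tube(set, ancestral_inoculum(set, 1L, 20)),
                    set, t_end = 30, mu = 0)
    700 - tb$T
  })
  expect_gt(pops[1], pops[2])   # growth suffers from investment
  expect_lt(degr[1], degr[2])   # per-cell degradation benefits from it
  expect_equal(degr, c(30 * 20 * 0.2, 30 * 20 * 0.6))  # deterministic here
})

test_that("degradation score follows the root-mean-square definition", {
  set <- test_pool()
  tb <- new_tube(set, ancestral_inoculum(set, 1L, 10))
  tb$T <- rep(0, 10)
  expect_equal(degradation_score(tb), 1)
  tb$T <- tb$T0
  expect_equal(degradation_score(tb), 0)
  tb$T <- tb$T0 / 2
  expect_equal(degradation_score(tb), 0.5)
  tb$T0 <- rep(0, 10)
  expect_error(degradation_score(tb), "undefined")
  # any reachable final state scores in [0, 1]
  tb2 <- new_tube(set, ancestral_inoculum(set, c(2L, 6L, 13L), 10))
  set.seed(4)
  tb2 <- run_round(tb2, set)
  expect_gte(degradation_score(tb2), 0)
  expect_lte(degradation_score(tb2), 1)
})
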