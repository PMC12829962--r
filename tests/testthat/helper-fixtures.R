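# Hand-built fixtures: tiny species sets with known parameters, and
# minimal fake tubes for testing propagation bookkeeping in isolation.

# A species set from explicit parameter matrices (one row per species).
# Sparsity masks are inferred from the nonzero pattern.
manual_species_set <- function(a, r, n, m, f0, set_id = 99L, seed = 0L) {
  n <- rbind(n); m <- rbind(m); f0 <- rbind(f0)
  size <- length(a)
  stopifnot(nrow(n) == size, nrow(m) == size, nrow(f0) == size,
            ncol(m) == ncol(f0))
  structure(list(
    a = a, r = r, n = n, m = m, f0 = f0,
    mask_n = matrix(as.integer(n > 0), size),
    mask_m = matrix(as.integer(m > 0), size),
    mask_f = matrix(as.integer(f0 > 0), size),
    size = as.integer(size),
    n_nutrients = ncol(n), n_toxins = ncol(m),
    set_id = as.integer(set_id), rng_seed = as.integer(seed)),
    class = "species_set")
}

# One species, one nutrient, one toxin; immortal unless m is given.
fix_single <- function(a = 0.5, r = 0.5, f = 0, m = 0) {
  manual_species_set(a = a, r = r, n = matrix(1, 1, 1),
                     m = matrix(m, 1, 1), f0 = matrix(f, 1, 1))
}

# Two species competing for the same single nutrient, degrading the same
# single toxin with different investments.
fix_competitors <- function(f1 = 0.3, f2 = 0.6, m = 0.01) {
  manual_species_set(a = c(0.5, 0.5), r = c(0.5, 0.5),
                     n = matrix(1, 2, 1),
                     m = matrix(m, 2, 1),
                     f0 = matrix(c(f1, f2), 2, 1))
}

# A minimal completed "tube" for propagation bookkeeping tests.
fake_tube <- function(sp, p0, lid = sp, f = NULL, p1 = rep(0, length(sp)),
                      initial_species = sort(unique(sp)), n_toxins = 1L,
                      T = 350, T0 = 700) {
  if (is.null(f)) f <- matrix(0, length(sp), n_toxins)
  structure(list(sp = as.integer(sp), lid = as.integer(lid), f = f,
                 p0 = as.numeric(p0), p1 = as.numeric(p1),
                 flags = matrix(FALSE, length(sp), 1L),
                 N = 100, T = rep(T, n_toxins),
                 N0 = 100, T0 = rep(T0, n_toxins), K = 700,
                 initial_species = as.integer(initial_species),
                 t = 80L, traj = NULL,
                 next_lid = max(sp, lid, 0L) + 1L),
            class = "tube")
}

# The default 15-species pool used across integration tests.
test_pool <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sample_species_set(mix_seed(1, 1), set_id = 1L)
    cache
  }
})
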