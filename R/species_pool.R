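# Species pool: ancestral parameter sampling and initial community assembly.
#
# A species is a row of random parameters: activation and replication
# probabilities a, r ~ Beta(2,2); nutrient uptake preferences n (sparse,
# rescaled to sum 1); per-toxin death rates m (sparse, Uni(0.001, 0.02));
# and an ancestral degradation investment vector f0 (sparse, rescaled so
# that its total is itself a Uni(0,1) draw, giving a theoretical mean total
# investment of 0.5). Sparsity masks are Bernoulli(0.5) per coordinate and
# are a fixed species property: masked entries stay zero forever, also
# under mutation.

#' Sample the ancestral parameters of one species
#'
#' Draws one species for the metacommunity pool. Uses the current RNG
#' state; seed with [set.seed()] (or use [sample_species_set()]) for
#' reproducibility.
#'
#' A species whose nutrient mask comes out all zero could never consume
#' anything (and its preference rescaling would be undefined), so the
#' nutrient mask is redrawn until it has at least one nonzero entry.
#' All-zero death or investment masks are allowed: they describe
#' toxin-immune and non-degrading species respectively.
#'
#' @param n_nutrients number of nutrients (default 4).
#' @param n_toxins number of toxic compounds (default 10).
#' @param species_id integer id stored on the result.
#' @return A list of class `species_params` with fields `species_id`, `a`,
#'   `r`, `n`, `m`, `f0`, `mask_n`, `mask_m`, `mask_f`.
#' @export
sample_species <- function(n_nutrients = 4L, n_toxins = 10L, species_id = 1L) {
  if (n_nutrients < 1L || n_toxins < 1L)
    stop("need at least one nutrient and one toxin")
  a <- rbeta(1, 2, 2)
  r <- rbeta(1, 2, 2)
  repeat {
    mask_n <- rbinom(n_nutrients, 1L, 0.5)
    if (any(mask_n > 0)) break
  }
  n <- runif(n_nutrients) * mask_n
  n <- n / sum(n)
  mask_m <- rbinom(n_toxins, 1L, 0.5)
  m <- runif(n_toxins, 0.001, 0.02) * mask_m
  mask_f <- rbinom(n_toxins, 1L, 0.5)
  f_raw <- runif(n_toxins) * mask_f
  f_target <- runif(1)
  f0 <- if (any(mask_f > 0)) f_raw / sum(f_raw) * f_target else f_raw
  structure(list(species_id = as.integer(species_id), a = a, r = r,
                 n = n, m = m, f0 = f0,
                 mask_n = as.integer(mask_n), mask_m = as.integer(mask_m),
                 mask_f = as.integer(mask_f)),
            class = "species_params")
}

#' Sample a species set (the metacommunity pool)
#'
#' Deterministically draws `size` species given `seed`. Parameters are
#' stored column-bound into matrices, one row per species, which is the
#' layout the simulation engine consumes.
#'
#' @param seed integer seed; the set is a pure function of it.
#' @param size pool size (default 15).
#' @param n_nutrients,n_toxins environment dimensions.
#' @param set_id integer label stored on the set.
#' @return A list of class `species_set` with fields `a`, `r` (length
#'   `size`), matrices `n` (`size` x nutrients), `m`, `f0`, `mask_f`
#'   (`size` x toxins), `mask_n`, `mask_m`, plus `size`, `n_nutrients`,
#'   `n_toxins`, `set_id`, `rng_seed`.
#' @export
sample_species_set <- function(seed, size = 15L, n_nutrients = 4L,
                               n_toxins = 10L, set_id = 1L) {
  if (size < 1L) stop("pool size must be at least 1")
  set.seed(seed)
  sps <- lapply(seq_len(size), function(i)
    sample_species(n_nutrients, n_toxins, species_id = i))
  structure(list(
    a = vapply(sps, `[[`, numeric(1), "a"),
    r = vapply(sps, `[[`, numeric(1), "r"),
    n = do.call(rbind, lapply(sps, `[[`, "n")),
    m = do.call(rbind, lapply(sps, `[[`, "m")),
    f0 = do.call(rbind, lapply(sps, `[[`, "f0")),
    mask_n = do.call(rbind, lapply(sps, `[[`, "mask_n")),
    mask_m = do.call(rbind, lapply(sps, `[[`, "mask_m")),
    mask_f = do.call(rbind, lapply(sps, `[[`, "mask_f")),
    size = as.integer(size),
    n_nutrients = as.integer(n_nutrients),
    n_toxins = as.integer(n_toxins),
    set_id = as.integer(set_id),
    rng_seed = as.integer(seed)),
    class = "species_set")
}

#' @export
print.species_set <- function(x, ...) {
  cat(sprintf("<species_set> %d species, %d nutrients, %d toxins (seed %d)\n",
              x$size, x$n_nutrients, x$n_toxins, x$rng_seed))
  cat(sprintf("  mean a = %.3f, mean r = %.3f, mean total investment = %.3f\n",
              mean(x$a), mean(x$r), mean(rowSums(x$f0))))
  invisible(x)
}

#' Subset a species set
#'
#' Used by pool-size sensitivity sweeps, which subsample the existing pool
#' rather than drawing new species (new draws would add variance between
#' pool sizes).
#'
#' @param set a `species_set`.
#' @param species integer ids to keep (become ids `1..length(species)`).
#' @return A smaller `species_set`.
#' @export
subset_species_set <- function(set, species) {
  stopifnot(all(species %in% seq_len(set$size)))
  out <- set
  out$a <- set$a[species]
  out$r <- set$r[species]
  for (fld in c("n", "m", "f0", "mask_n", "mask_m", "mask_f"))
    out[[fld]] <- set[[fld]][species, , drop = FALSE]
  out$size <- length(species)
  out$parent_species <- as.integer(species)
  out
}

#' Assemble the initial communities of a run
#'
#' Each of `n_tubes` tubes receives `richness` draws with replacement from
#' the pool; duplicate draws within a tube collapse to presence (the
#' inoculum is per distinct species). Every pool species is guaranteed to
#' appear in at least one tube: any missing species replaces a uniformly
#' chosen redundantly-covered species (one present in two or more tubes) in
#' a uniformly chosen tube, until coverage holds.
#'
#' @param set a `species_set`.
#' @param n_tubes number of communities (default 21).
#' @param richness species draws per tube (default 4).
#' @return A list of `n_tubes` integer vectors of distinct species ids.
#' @export
sample_initial_communities <- function(set, n_tubes = 21L, richness = 4L) {
  pool <- set$size
  if (n_tubes * richness < pool)
    stop("cannot cover ", pool, " species with ", n_tubes, " x ", richness,
         " draws")
  tubes <- lapply(seq_len(n_tubes), function(i)
    sort(unique(sample.int(pool, richness, replace = TRUE))))
  repeat {
    missing <- setdiff(seq_len(pool), unique(unlist(tubes)))
    if (length(missing) == 0L) break
    counts <- table(factor(unlist(tubes), levels = seq_len(pool)))
    dup <- as.integer(names(counts)[counts >= 2])
    # tubes holding at least one redundantly-covered species
    cand <- which(vapply(tubes, function(tt) any(tt %in% dup), logical(1)))
    if (length(missing) > 1L) missing <- missing[sample.int(length(missing), 1L)]
    if (length(cand) > 0L) {
      ti <- cand[sample.int(length(cand), 1L)]
      repl <- intersect(tubes[[ti]], dup)
      victim <- repl[sample.int(length(repl), 1L)]
      tubes[[ti]] <- sort(unique(c(setdiff(tubes[[ti]], victim), missing)))
    } else {
      # duplicate draws collapsed to presence, so some tube has a spare
      # inoculum slot: the missing species takes one
      ti <- sample.int(n_tubes, 1L)
      tubes[[ti]] <- sort(unique(c(tubes[[ti]], missing)))
    }
  }
  tubes
}

#' Serialize a species set to JSON
#'
#' @param set a `species_set`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly if written to file.
#' @export
species_set_to_json <- function(set, path = NULL) {
  js <- jsonlite::toJSON(unclass(set), digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a species set back from JSON
#' @param path file path or JSON string.
#' @return A `species_set`.
#' @export
species_set_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  for (fld in c("n", "m", "f0", "mask_n", "mask_m", "mask_f"))
    x[[fld]] <- matrix(as.numeric(x[[fld]]), nrow = x$size)
  x$size <- as.integer(x$size)
  x$n_nutrients <- as.integer(x$n_nutrients)
  x$n_toxins <- as.integer(x$n_toxins)
  structure(x, class = "species_set")
}

#' Tidy data frame view of a species set
#'
#' One row per species x parameter coordinate, convenient for inspection
#' and CSV export.
#'
#' @param x a `species_set`.
#' @param ... unused.
#' @return A `data.frame` with columns `species_id`, `parameter`,
#'   `coordinate`, `value`.
#' @export
as.data.frame.species_set <- function(x, ...) {
  rows <- list()
  for (i in seq_len(x$size)) {
    rows[[length(rows) + 1L]] <- data.frame(
      species_id = i,
      parameter = c("a", "r",
                    rep("n", x$n_nutrients),
                    rep("m", x$n_toxins),
                    rep("f0", x$n_toxins)),
      coordinate = c(1L, 1L, seq_len(x$n_nutrients),
                     seq_len(x$n_toxins), seq_len(x$n_toxins)),
      value = c(x$a[i], x$r[i], x$n[i, ], x$m[i, ], x$f0[i, ]))
  }
  do.call(rbind, rows)
}
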