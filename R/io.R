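# Configuration files, CSV/JSON ledgers, command-line entry point.

.LEDGER_VERSION <- 1L

#' Load an experiment configuration from YAML or JSON
#'
#' Keys mirror the arguments of [experiment_config()]; anything not given
#' keeps its default (an empty file yields the full default design).
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return An `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("malformed config file: expected a key-value map")
  known <- names(formals(experiment_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(experiment_config, vals)
}

#' Write the per-round lineage CSV of a run
#'
#' One row per (round, tube, species, lineage) with the end-of-round cell
#' counts, the lineage's total investment, and the tube's degradation
#' score. Round-trips losslessly through [read_round_csv()].
#'
#' @param run a `selection_run`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_round_csv <- function(run, path) {
  rows <- list()
  for (rec in run$rounds) {
    for (ti in seq_along(rec$lineages)) {
      lt <- rec$lineages[[ti]]
      if (length(lt$sp) == 0L) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        round = rec$round, tube = ti, species_id = lt$sp,
        lineage_id = lt$lid, cells = lt$S,
        f_total = rowSums(lt$f), D = rec$D[ti])
    }
  }
  dt <- if (length(rows)) data.table::rbindlist(rows)
        else data.table::data.table(round = integer(0), tube = integer(0),
                                    species_id = integer(0),
                                    lineage_id = integer(0),
                                    cells = numeric(0), f_total = numeric(0),
                                    D = numeric(0))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a per-round lineage CSV
#' @param path file written by [write_round_csv()].
#' @return A `data.table`.
#' @export
read_round_csv <- function(path) {
  data.table::fread(path)
}

#' Write a self-contained JSON ledger of a run
#'
#' Holds the configuration, the serialized species set (with its seed),
#' the run index, and per-round scores, selections and compositions:
#' together with the package this reproduces the run exactly.
#'
#' @param run a `selection_run`.
#' @param set the `species_set` used.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_run_ledger <- function(run, set, path) {
  led <- list(
    ledger_version = .LEDGER_VERSION,
    package_version = as.character(utils::packageVersion("commselect")),
    config = unclass(run$cfg),
    species_set = unclass(set),
    run_index = run$run_index,
    seed = run$seed,
    rounds = lapply(run$rounds, function(rec) list(
      round = rec$round, D = rec$D, Dhat = rec$Dhat,
      selected = rec$selected,
      initial_composition = rec$initial_composition,
      composition = rec$composition)))
  jsonlite::write_json(led, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a run ledger
#' @param path file written by [write_run_ledger()].
#' @return The ledger as a list; errors on a ledger from a newer schema.
#' @export
read_run_ledger <- function(path) {
  led <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(led$ledger_version) || led$ledger_version > .LEDGER_VERSION)
    stop("ledger schema version ", led$ledger_version,
         " is newer than this package understands (", .LEDGER_VERSION, ")")
  led
}
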