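# End-to-end orchestration: matrix -> search -> consensus -> calibration ->
# body-length prediction -> size bins -> ancestral-state reconstruction,
# with every stage writing standard formats so stages are independently
# runnable, and a manifest recording seeds, versions and output hashes.

#' Pipeline configuration
#'
#' Either a list built here or a YAML file with the same fields (see
#' [run_pipeline()]). Paths may be omitted when a precomputed object is
#' passed to `run_pipeline()` directly.
#'
#' @param matrix path to a TNT matrix (or a [character_matrix()]).
#' @param scaffold optional path to a Newick backbone (or `phylo`).
#' @param tree optional precomputed consensus topology; skips the search.
#' @param ages path to an age table (or data frame).
#' @param extant path to an extant allometry table (or data frame).
#' @param fossil_hw path to a fossil head-width table (columns `taxon`,
#'   `specimen`, `hw_cm`; or data frame / named vector).
#' @param osmo optional path to an osmoregulation table (columns `taxon`,
#'   `state`) for the binary reconstruction.
#' @param out_dir output directory (created if needed).
#' @param seed master seed (mandatory).
#' @param min_branch minimum branch duration, Myr.
#' @param bin_width fine size-bin width, cm.
#' @param n_replicates,max_trees search settings.
#' @param n_iter,burn_in,thin MCMC settings.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix, ages, extant, fossil_hw,
                            scaffold = NULL, tree = NULL, osmo = NULL,
                            out_dir = tempfile("crocsize_run_"), seed,
                            min_branch = 5, bin_width = 50,
                            n_replicates = 5L, max_trees = 50L,
                            n_iter = 10000L, burn_in = 1000L, thin = 10L) {
  if (missing(seed)) .stopf("`seed` is mandatory")
  structure(list(matrix = matrix, ages = ages, extant = extant,
                 fossil_hw = fossil_hw, scaffold = scaffold, tree = tree,
                 osmo = osmo, out_dir = out_dir, seed = as.integer(seed),
                 min_branch = min_branch, bin_width = bin_width,
                 n_replicates = as.integer(n_replicates),
                 max_trees = as.integer(max_trees),
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin)),
            class = "pipeline_config")
}

.load_or <- function(x, loader) {
  if (is.character(x) && length(x) == 1L) loader(x) else x
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages: read inputs; heuristic parsimony search under the scaffold (or
#' use the supplied tree); strict consensus; mbl time calibration; Bayesian
#' body-length prediction for fossil tips; size-bin classification; ordered
#' parsimony reconstruction of size bins (and of osmoregulation if coded).
#' Writes `consensus.nwk`, `calibrated.nwk`, `predictions.csv`,
#' `asr_bins.csv`, optionally `asr_osmo.csv`, and `manifest.json` to the
#' output directory. Re-running with the same config reproduces identical
#' outputs.
#'
#' @param config a [pipeline_config()], or path to a YAML file of its fields.
#' @return (invisibly) a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cm <- .stage("read_matrix", .load_or(config$matrix, read_tnt_matrix))
  ages <- .stage("read_ages",
                 .load_or(config$ages, function(p) read_table(p, "age")))
  extant <- .stage("read_extant",
                   .load_or(config$extant, function(p) read_table(p, "allometry")))
  fossil_hw <- .stage("read_fossil",
                      .load_or(config$fossil_hw, function(p) read_table(p, "allometry")))
  scaffold <- .stage("read_scaffold", .load_or(config$scaffold, read_newick))

  if (is.null(config$tree)) {
    trees <- .stage("search", heuristic_search(cm, scaffold,
      search_config(n_replicates = config$n_replicates,
                    max_trees = config$max_trees, seed = config$seed)))
    cons <- .stage("consensus", strict_consensus(trees))
  } else {
    trees <- NULL
    cons <- .stage("read_tree", .load_or(config$tree, read_newick))
  }
  write_newick(cons, file.path(config$out_dir, "consensus.nwk"))

  cal <- .stage("calibrate", calibrate_mbl(cons, ages,
    calibration_config(min_branch = config$min_branch)))
  write_newick(cal, file.path(config$out_dir, "calibrated.nwk"))

  pred <- .stage("predict", predict_tl(cal, extant, fossil_hw,
    mcmc = mcmc_config(n_iter = config$n_iter, burn_in = config$burn_in,
                       thin = config$thin, seed = config$seed + 1L)))
  utils::write.csv(pred, file.path(config$out_dir, "predictions.csv"),
                   row.names = FALSE)

  ## bins over fossil predictions plus extant observed means
  agg <- .aggregate_extant(extant)
  mean_tl <- c(stats::setNames(pred$mean_cm, pred$taxon),
               stats::setNames(10^agg$y, agg$taxon))
  mean_tl <- mean_tl[intersect(names(mean_tl), cal$tip.label)]
  bins <- bin_lengths(mean_tl, width = config$bin_width)
  amap <- .stage("asr", asr_bins(cons, bins))
  asr_df <- data.frame(node = names(amap),
                       states = vapply(amap, paste, character(1), collapse = "|"),
                       stringsAsFactors = FALSE)
  utils::write.csv(asr_df, file.path(config$out_dir, "asr_bins.csv"),
                   row.names = FALSE)

  osmo_map <- NULL
  if (!is.null(config$osmo)) {
    osmo <- .stage("read_osmo", .load_or(config$osmo, function(p) {
      d <- utils::read.table(p, header = TRUE, sep = ",",
                             stringsAsFactors = FALSE)
      stats::setNames(d$state, d$taxon)
    }))
    osmo_map <- .stage("asr_osmo", asr_binary(cons, osmo))
    utils::write.csv(
      data.frame(node = names(osmo_map),
                 states = vapply(osmo_map, paste, character(1), collapse = "|")),
      file.path(config$out_dir, "asr_osmo.csv"), row.names = FALSE)
  }

  files <- list.files(config$out_dir, pattern = "\\.(nwk|csv)$",
                      full.names = TRUE)
  manifest <- list(
    package = as.character(utils::packageVersion("crocsize")),
    seed = config$seed,
    settings = list(min_branch = config$min_branch,
                    bin_width = config$bin_width,
                    log_base = 10,
                    lambda = attr(pred, "lambda"),
                    n_iter = config$n_iter),
    hashes = as.list(stats::setNames(unname(tools::md5sum(sort(files))),
                                     basename(sort(files)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(matrix = cm, trees = trees, consensus = cons,
                 calibrated = cal, predictions = pred, bins = bins,
                 asr = amap, asr_osmo = osmo_map, manifest = manifest,
                 out_dir = config$out_dir))
}
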