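#' Pipeline run configuration
#'
#' Two entry modes are supported.  In `structure` mode molecules are read
#' (SMILES file or list of graphs), dissected, descriptor-filtered and —
#' when binding records are supplied — scored.  In `table` mode no
#' structures are needed: a descriptor table (id, HAC, MW) and a binding
#' table (id, delta_g, optional ic50_nM) are scored directly, which is how
#' published descriptor/energy tables are re-analysed.
#'
#' @param mode `"structure"` or `"table"`.
#' @param molecules SMILES file path or list of `molecular_graph`
#'   (structure mode).
#' @param descriptors TSV path or data.frame with `id`, `HAC`, `MW`
#'   (table mode).
#' @param records TSV path or data.frame with `id`, `delta_g`, optional
#'   `ic50_nM`.
#' @param temperature_K temperature for the pKi conversion.
#' @param rotb_threshold rotatable-bond selection gate (default 10,
#'   inclusive).
#' @param le_tolerance tie tolerance for LE priority orders.
#' @param out_dir output directory (created); `NULL` for no files.
#' @param seed integer seed recorded with the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("structure", "table"), molecules = NULL,
                       descriptors = NULL, records = NULL,
                       temperature_K = 298.15, rotb_threshold = 10L,
                       le_tolerance = 0.005, out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(temperature_K > 0, rotb_threshold >= 0)
  structure(list(mode = mode, molecules = molecules,
                 descriptors = descriptors, records = records,
                 temperature_K = temperature_K,
                 rotb_threshold = as.integer(rotb_threshold),
                 le_tolerance = le_tolerance, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file with fields matching [run_config()] arguments.
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

.load_records <- function(x) {
  if (is.null(x)) return(NULL)
  df <- if (is.character(x)) utils::read.delim(x, stringsAsFactors = FALSE) else
    as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c("id", "delta_g") %in% names(df)))
    stop("binding records need columns 'id' and 'delta_g'")
  if (any(!is.finite(df$delta_g))) stop("non-finite delta_g in records")
  df
}

#' Run the fragment analysis pipeline
#'
#' Orchestrates dissect, descriptors, rotatable-bond filter, efficiency
#' scoring, normalisation and priority ordering according to the
#' configuration, writing TSV/JSON outputs and a run log when an output
#' directory is set.
#'
#' @param config a [run_config()].
#' @return object of class `fragrank_run`: list with `config`, `counts`,
#'   `descriptors`, `scores`, `frameworks`, `orders`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  say <- function(level, fmt, ...) {
    line <- sprintf("%s [%s] %s", format(Sys.time(), "%H:%M:%S"), level,
                    sprintf(fmt, ...))
    log <<- c(log, line)
  }
  stage <- "input"
  result <- tryCatch({
    frameworks <- NULL
    dissections <- NULL
    if (config$mode == "structure") {
      stage <- "parse"
      mols <- if (is.character(config$molecules))
        read_smiles(config$molecules) else config$molecules
      say("INFO", "parsed %d molecules", length(mols))
      stage <- "dissect"
      dissections <- lapply(mols, dissect_molecule)
      scaffolds <- lapply(dissections, `[[`, "scaffold")
      stage <- "descriptors"
      desc <- descriptor_table(scaffolds)
      stage <- "filter"
      rotb_ok <- desc$RotB <= config$rotb_threshold
      say("INFO", "rotatable-bond filter (<= %d): kept %d, discarded %d",
          config$rotb_threshold, sum(rotb_ok), sum(!rotb_ok))
      if (!any(rotb_ok))
        say("WARNING", "all structures filtered out; no scores computed")
      kept_desc <- desc[rotb_ok, , drop = FALSE]
      stage <- "frameworks"
      frameworks <- group_by_framework(mols[rotb_ok])
      counts <- list(parsed = length(mols), kept = sum(rotb_ok),
                     discarded = sum(!rotb_ok))
    } else {
      stage <- "tables"
      desc <- if (is.character(config$descriptors))
        utils::read.delim(config$descriptors, stringsAsFactors = FALSE) else
          as.data.frame(config$descriptors, stringsAsFactors = FALSE)
      if (!all(c("id", "HAC", "MW") %in% names(desc)))
        stop("descriptor table needs columns 'id', 'HAC', 'MW'")
      kept_desc <- desc
      counts <- list(parsed = nrow(desc), kept = nrow(desc), discarded = 0L)
      say("INFO", "table mode: %d descriptor rows", nrow(desc))
    }

    stage <- "score"
    records <- .load_records(config$records)
    scores <- NULL
    orders <- NULL
    if (!is.null(records) && nrow(kept_desc)) {
      records <- records[records$id %in% kept_desc$id, , drop = FALSE]
      constants <- thermo_constants(config$temperature_K)
      scores <- score_fragments(records, kept_desc, constants)
      if (nrow(scores) >= 2L) {
        stage <- "normalize"
        scores <- normalized_scores(scores)
        stage <- "orders"
        orders <- list(
          BE = priority_order(stats::setNames(scores$delta_g, scores$id),
                              larger_is_better = FALSE, metric = "BE"),
          LE = priority_order(stats::setNames(scores$LE, scores$id),
                              tolerance = config$le_tolerance, metric = "LE"),
          BEI = priority_order(stats::setNames(scores$BEI, scores$id),
                               metric = "BEI"))
        if (!is.null(records$ic50_nM))
          orders$experimental <-
            ic50_priority_order(stats::setNames(records$ic50_nM, records$id))
      }
      say("INFO", "scored %d fragments", nrow(scores))
    }

    out <- structure(list(config = config, counts = counts,
                          descriptors = kept_desc, scores = scores,
                          frameworks = frameworks, dissections = dissections,
                          orders = orders, log = log),
                     class = "fragrank_run")
    if (!is.null(config$out_dir)) .write_run_outputs(out, config$out_dir)
    out
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

.write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wtsv(run$descriptors, "descriptors.tsv")
  if (!is.null(run$scores)) wtsv(run$scores, "scores.tsv")
  if (!is.null(run$frameworks)) wtsv(run$frameworks, "frameworks.tsv")
  if (!is.null(run$dissections)) {
    dj <- lapply(run$dissections, function(d) list(
      id = d$mol$id, roles = d$roles,
      n_ring_systems = length(d$ring_systems),
      scaffold_atoms = nrow(d$scaffold$atoms),
      scaffold_smiles = smiles_string(d$scaffold),
      framework_hash = d$framework$hash))
    jsonlite::write_json(dj, file.path(dir, "dissection.json"),
                         auto_unbox = TRUE)
  }
  report <- list(counts = run$counts,
                 orders = lapply(run$orders, format),
                 seed = run$config$seed,
                 temperature_K = run$config$temperature_K)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(run)
}

#' @export
print.fragrank_run <- function(x, ...) {
  cat("<fragrank pipeline run>\n")
  cat(sprintf("  mode: %s; parsed %d, kept %d, discarded %d\n",
              x$config$mode, x$counts$parsed, x$counts$kept,
              x$counts$discarded))
  if (!is.null(x$scores))
    cat(sprintf("  scored fragments: %d\n", nrow(x$scores)))
  for (nm in names(x$orders))
    cat(sprintf("  %-12s: %s\n", nm, format(x$orders[[nm]])))
  invisible(x)
}
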