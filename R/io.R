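#' Read identification records from CSV
#'
#' Strict reader for the canonical record schema: one row per
#' identification with an individual ID, a collection-event ID, an ordinal
#' clock value and an ISO-8601 date, plus any attribute columns. Columns may
#' be renamed through `column_map`. Unparseable dates and missing columns
#' are reported with the offending line numbers; exact duplicate rows are
#' dropped with a warning.
#'
#' @param path CSV file with a header row.
#' @param column_map named character vector mapping the canonical names
#'   `individual`, `event`, `ordinal`, `date` to columns of the file, e.g.
#'   `c(individual = "whale_id", ordinal = "frame")`. Unmapped canonical
#'   names are looked up literally.
#' @return validated identification records (data.frame); attribute columns
#'   are carried through unchanged.
#' @export
read_identifications <- function(path, column_map = NULL) {
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L)
    stop(sprintf("input file is empty: %s", path), call. = FALSE)
  canonical <- c("individual", "event", "ordinal", "date")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols) > 0L)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- raw
  names(out)[match(map, names(out))] <- names(map)

  ord <- suppressWarnings(as.numeric(out$ordinal))
  bad <- which(!is.finite(ord))
  if (length(bad) > 0L)
    stop("non-numeric ordinal value(s) at data line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  out$ordinal <- ord
  dt <- as.Date(as.character(out$date), format = "%Y-%m-%d")
  bad <- which(is.na(dt))
  if (length(bad) > 0L)
    stop("unparseable date(s) (expected YYYY-MM-DD) at data line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  out$date <- dt

  dup <- duplicated(out)
  if (any(dup)) {
    warning(sprintf("%d exact duplicate row(s) dropped", sum(dup)),
            call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  validate_records(out)
}

#' Write identification records to CSV
#'
#' Inverse of [read_identifications()]; a write/read round trip is lossless.
#'
#' @param records identification records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_identifications <- function(records, path) {
  records <- validate_records(records)
  records$date <- format(records$date, "%Y-%m-%d")
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a half-weight index matrix as square CSV
#'
#' @param hwi an `"hwi_matrix"`.
#' @param path output CSV path (IDs as header row and first column).
#' @return `path`, invisibly.
#' @export
write_hwi_csv <- function(hwi, path) {
  stopifnot(inherits(hwi, "hwi_matrix"))
  utils::write.csv(as.data.frame(hwi$hwi), path, row.names = TRUE)
  invisible(path)
}

#' Read a half-weight index matrix from square CSV
#'
#' @param path CSV written by [write_hwi_csv()] (or any square matrix with
#'   IDs as header row and first column).
#' @return symmetric numeric matrix with ID dimnames.
#' @export
read_hwi_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' Write dyadic associations as a long-format edge list
#'
#' One row per dyad with the half-weight index and its tallies
#' (`x`, `yab`, `ya`, `yb`).
#'
#' @param hwi an `"hwi_matrix"`.
#' @param path output CSV path.
#' @param nonzero_only drop never-associated dyads (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(hwi, path, nonzero_only = TRUE) {
  stopifnot(inherits(hwi, "hwi_matrix"))
  ut <- which(upper.tri(hwi$hwi), arr.ind = TRUE)
  df <- data.frame(
    id1 = hwi$ids[ut[, 1L]], id2 = hwi$ids[ut[, 2L]],
    hwi = hwi$hwi[ut], x = hwi$x[ut], yab = hwi$yab[ut],
    ya = hwi$ya[ut], yb = hwi$yb[ut])
  if (nonzero_only) df <- df[df$hwi > 0, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an association network as GraphML
#'
#' Builds an undirected weighted graph from the half-weight indices
#' (non-zero dyads become edges with a `weight` attribute; optional node
#' attributes, e.g. unit membership or community assignment, are attached)
#' and writes GraphML via igraph.
#'
#' @param hwi an `"hwi_matrix"`.
#' @param path output `.graphml` path.
#' @param node_attrs optional named list of vectors (named by individual ID)
#'   to attach as vertex attributes.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(hwi, path, node_attrs = NULL) {
  stopifnot(inherits(hwi, "hwi_matrix"))
  g <- igraph::graph_from_adjacency_matrix(hwi$hwi, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(node_attrs)) {
    for (nm in names(node_attrs)) {
      vals <- node_attrs[[nm]][igraph::V(g)$name]
      g <- igraph::set_vertex_attr(g, nm, value = as.vector(vals))
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Configuration for the end-to-end analysis pipeline
#'
#' @param input path to a records CSV, or a records data.frame.
#' @param column_map passed to [read_identifications()].
#' @param criteria association criteria to evaluate (any subset of
#'   `"probabilistic"`, `"same_frame"`, `"encounter"`).
#' @param threshold `"fitted"` to estimate the probabilistic association
#'   threshold from the data via the LIR model, or an explicit integer.
#' @param min_days,require_years individual-restriction filter (see
#'   [restrict_individuals()]); `min_days = 0` disables filtering.
#' @param subset_by optional attribute column: the LIR model is additionally
#'   fitted per subset for comparison (does not change the main threshold).
#' @param membership_col optional attribute column used as group membership
#'   for the Mantel test.
#' @param max_lag,offset,binning LIR settings (see [empirical_lir()]).
#' @param n_permutations,n_trials permutation-test settings.
#' @param seed integer seed governing all randomized stages.
#' @param outdir output directory, or `NULL` for no file output.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(input,
                       column_map = NULL,
                       criteria = c("probabilistic", "same_frame",
                                    "encounter"),
                       threshold = "fitted",
                       min_days = 5L,
                       require_years = NULL,
                       subset_by = NULL,
                       membership_col = NULL,
                       max_lag = NULL, offset = "auto", binning = "unit",
                       n_permutations = 1000L, n_trials = 1000L,
                       seed = 42L, outdir = NULL) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  if (!identical(threshold, "fitted") &&
      (!is.numeric(threshold) || length(threshold) != 1L || threshold < 1))
    stop("`threshold` must be \"fitted\" or a single integer >= 1",
         call. = FALSE)
  structure(
    list(input = input, column_map = column_map, criteria = criteria,
         threshold = threshold, min_days = min_days,
         require_years = require_years, subset_by = subset_by,
         membership_col = membership_col,
         max_lag = max_lag, offset = offset, binning = binning,
         n_permutations = n_permutations, n_trials = n_trials,
         seed = as.integer(seed), outdir = outdir),
    class = "run_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [run_config()].
#' @return list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$require_years))
    vals$require_years <- as.integer(vals$require_years)
  do.call(run_config, vals)
}

#' Run the full analysis pipeline
#'
#' End-to-end workflow: read (or accept) identification records, estimate
#' the probabilistic association threshold from the lagged identification
#' rate (unless an explicit threshold is given), apply the
#' individual-restriction filter, build daily associations and half-weight
#' matrices under each requested criterion, and evaluate each with the full
#' battery. Given a seed, reruns are reproducible; with `outdir` set, the
#' fit (JSON), per-criterion HWI matrices (CSV), the evaluation report
#' (JSON) and a run log are written.
#'
#' @param config a `"run_config"`.
#' @return list of class `"pipeline_result"` with `records`, `fit` (or
#'   `NULL` when the threshold was explicit), `subset_fits` (when
#'   `subset_by` was given), `threshold`, `ids`, and `reports` — one
#'   `"evaluation_report"` per criterion.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  records <- stage("read", {
    if (is.character(config$input))
      read_identifications(config$input, config$column_map)
    else validate_records(config$input)
  })

  fit <- NULL
  subset_fits <- NULL
  if (identical(config$threshold, "fitted")) {
    fit <- stage("lir", {
      curve <- empirical_lir(records, max_lag = config$max_lag,
                             offset = config$offset,
                             binning = config$binning)
      fit_residence_model(curve, seed = config$seed)
    })
    if (!fit$informative)
      stop("pipeline stage 'lir' failed: LIR fit is non-informative; ",
           "supply an explicit threshold", call. = FALSE)
    threshold <- fit$threshold$threshold
  } else {
    threshold <- as.integer(config$threshold)
  }
  if (!is.null(config$subset_by))
    subset_fits <- stage("lir_subsets",
                         fit_by_subset(records, config$subset_by,
                                       max_lag = config$max_lag,
                                       offset = config$offset,
                                       binning = config$binning,
                                       seed = config$seed))

  ids <- stage("restrict", {
    if (config$min_days > 0L || !is.null(config$require_years))
      restrict_individuals(records, min_days = config$min_days,
                           require_years = config$require_years)
    else sort(unique(records$individual))
  })

  membership <- NULL
  if (!is.null(config$membership_col)) {
    if (!config$membership_col %in% names(records))
      stop(sprintf("pipeline stage 'membership' failed: column '%s' not found",
                   config$membership_col), call. = FALSE)
    first <- !duplicated(records$individual)
    membership <- stats::setNames(
      as.character(records[[config$membership_col]][first]),
      records$individual[first])
  }

  reports <- list()
  for (crit in config$criteria) {
    reports[[crit]] <- stage(paste0("evaluate_", crit), {
      assoc <- daily_associations(
        records, criterion = crit,
        threshold = if (crit == "probabilistic") threshold else NULL,
        ids = ids)
      evaluate_social_structure(
        assoc, ids = ids, membership = membership,
        n_permutations = config$n_permutations,
        n_trials = config$n_trials, seed = config$seed)
    })
  }

  result <- structure(
    list(records = records, fit = fit, subset_fits = subset_fits,
         threshold = threshold, ids = ids, reports = reports,
         seed = config$seed),
    class = "pipeline_result"
  )
  if (!is.null(config$outdir)) write_pipeline_outputs(result, config)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: threshold %d, %d individuals retained\n",
              x$threshold, length(x$ids)))
  if (!is.null(x$fit)) print(x$fit)
  for (r in x$reports) print(r)
  invisible(x)
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$fit)) {
    fit_out <- result$fit[c("a", "b", "c_out", "loglik", "n_pairs",
                            "converged", "informative")]
    fit_out$threshold <- result$threshold
    jsonlite::write_json(fit_out, file.path(config$outdir, "lir_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report_list <- lapply(result$reports, report_to_list)
  meta <- list(seed = result$seed,
               threshold = result$threshold,
               threshold_source = if (is.null(result$fit)) "explicit"
                                  else "fitted",
               n_individuals = length(result$ids),
               package_version =
                 as.character(utils::packageVersion("probassoc")))
  jsonlite::write_json(list(metadata = meta, reports = report_list),
                       file.path(config$outdir, "evaluation_report.json"),
                       auto_unbox = TRUE, digits = NA)
  for (crit in names(result$reports))
    write_hwi_csv(result$reports[[crit]]$hwi,
                  file.path(config$outdir, sprintf("hwi_%s.csv", crit)))
  log_lines <- c(
    sprintf("probassoc %s", meta$package_version),
    sprintf("seed: %d", result$seed),
    sprintf("threshold: %d (%s)", result$threshold, meta$threshold_source),
    sprintf("individuals retained: %d", length(result$ids)),
    sprintf("criteria: %s", paste(names(result$reports), collapse = ", ")))
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  invisible(config$outdir)
}
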