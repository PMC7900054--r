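# File formats and pipeline assembly: the canonical trials CSV, the
# end-to-end analysis report, and its JSON serialisation.

#' Read meta-analyses from a trials CSV
#'
#' The canonical input format is a UTF-8 comma-separated table with one
#' row per trial and header
#' `meta_id,trial_id,events_t,size_t,events_c,size_c`; optional columns
#' `measure` (`rr`/`or`) and `model` (`fixed`/`random`) set the pooling
#' configuration per meta-analysis (they must be constant within a
#' meta-analysis). Rows are grouped by `meta_id` preserving file order.
#'
#' @param path Path to the CSV file.
#' @param config Default [pooling_config()] for meta-analyses without
#'   per-file configuration columns.
#' @return A list of [meta_analysis_spec()].
#' @export
read_trials_csv <- function(path, config = pooling_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("meta_id", "trial_id", "events_t", "size_t", "events_c", "size_c")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  # validate rows, reporting data line numbers (header is line 1)
  problems <- character(0)
  for (col in c("events_t", "size_t", "events_c", "size_c")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v != round(v) | v < 0)
    for (b in bad) {
      problems <- c(problems, sprintf("line %d: %s = '%s' is not a non-negative integer",
                                      b + 1L, col, df[[col]][b]))
    }
    df[[col]] <- v
  }
  if (!length(problems)) {
    bad <- which(df$events_t > df$size_t | df$events_c > df$size_c |
                   df$size_t < 1 | df$size_c < 1)
    for (b in bad) {
      problems <- c(problems, sprintf(
        "line %d: counts violate 0 <= events <= size >= 1 (%d/%d vs %d/%d)",
        b + 1L, df$events_t[b], df$size_t[b], df$events_c[b], df$size_c[b]))
    }
  }
  if (length(problems)) {
    stop("malformed trials CSV:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }

  ids <- unique(df$meta_id)
  lapply(ids, function(id) {
    sub <- df[df$meta_id == id, , drop = FALSE]
    cfg <- config
    if (all(c("measure", "model") %in% names(df))) {
      if (length(unique(sub$measure)) > 1L || length(unique(sub$model)) > 1L) {
        stop("meta-analysis '", id, "' has inconsistent measure/model rows",
             call. = FALSE)
      }
      cfg <- pooling_config(measure = sub$measure[1], model = sub$model[1],
                            alpha = config$alpha,
                            zero_cell = config$zero_cell)
    }
    trials <- lapply(seq_len(nrow(sub)), function(i) {
      two_by_two_trial(sub$trial_id[i], sub$events_t[i], sub$size_t[i],
                       sub$events_c[i], sub$size_c[i])
    })
    meta_analysis_spec(id, trials, cfg)
  })
}

#' Write meta-analyses to a trials CSV
#'
#' Inverse of [read_trials_csv()]: serialises a list of meta-analysis
#' specifications to the canonical CSV format, including the per-meta
#' `measure` and `model` columns.
#'
#' @param specs List of [meta_analysis_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(specs, path) {
  rows <- do.call(rbind, lapply(specs, function(m) {
    do.call(rbind, lapply(m$trials, function(tr) {
      data.frame(meta_id = m$meta_id, trial_id = tr$trial_id,
                 events_t = tr$events_t, size_t = tr$size_t,
                 events_c = tr$events_c, size_c = tr$size_c,
                 measure = m$config$measure, model = m$config$model,
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full fragility pipeline
#'
#' For every supplied meta-analysis: pools it, and — when the pooled
#' confidence interval excludes 1 — runs the fragility search and
#' computes the fragility quotient. Non-significant (or inestimable)
#' meta-analyses are listed as excluded with a reason, mirroring the
#' inclusion rule of a fragility survey. The included records are then
#' summarised with [summarize_corpus()].
#'
#' @param input One of: a path to a trials CSV, a list of
#'   [meta_analysis_spec()], a `synthetic_corpus`, or a [corpus_model()]
#'   (which is simulated first using its own seed).
#' @param config Default [pooling_config()] applied when reading a CSV;
#'   specs and corpora carry their own configuration.
#' @param moves Move set for [meta_fragility()].
#' @param timestamp Logical; record the wall-clock time in the
#'   provenance block. Off by default so that reports are byte-identical
#'   across reruns with the same inputs and seed.
#' @return An object of class `analysis_report`: `meta` (data frame with
#'   one row per included meta-analysis: id, trials, sample size, pooled
#'   effect and CI, p-value, index, quotient, convergence, trace
#'   length), `excluded` (id + reason), `summary` (a `corpus_summary`,
#'   or `NULL` with a notice when nothing was included) and `provenance`.
#' @export
run_pipeline <- function(input, config = pooling_config(),
                         moves = c("both", "add-only"),
                         timestamp = FALSE) {
  moves <- match.arg(moves)
  seed <- NULL
  if (inherits(input, "corpus_model")) {
    seed <- input$seed
    input <- simulate_corpus(input)
  }
  if (inherits(input, "synthetic_corpus")) {
    seed <- input$model$seed
    specs <- input$specs
  } else if (is.character(input) && length(input) == 1L) {
    specs <- read_trials_csv(input, config = config)
  } else if (is.list(input) &&
             all(vapply(input, inherits, logical(1), "meta_analysis_spec"))) {
    specs <- input
  } else {
    stop("'input' must be a trials CSV path, a list of meta_analysis_spec, ",
         "a synthetic_corpus, or a corpus_model", call. = FALSE)
  }

  rows <- list()
  excluded <- list()
  for (m in specs) {
    res <- tryCatch(pool(m), error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        meta_id = m$meta_id, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
      next
    }
    if (!is_significant(res)) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        meta_id = m$meta_id,
        reason = sprintf("pooled CI includes 1 (p = %.4g)", res$p_value),
        stringsAsFactors = FALSE)
      next
    }
    fr <- meta_fragility(m, moves = moves)
    rows[[length(rows) + 1L]] <- data.frame(
      meta_id = m$meta_id, k = res$k, sample_size = m$sample_size,
      effect = exp(res$log_effect), ci_low = res$ci_low,
      ci_high = res$ci_high, p_value = res$p_value,
      index = if (fr$converged) fr$index else NA_integer_,
      quotient_pct = fr$quotient_pct,
      converged = fr$converged, trace_length = nrow(fr$trace),
      stringsAsFactors = FALSE)
  }

  meta_tbl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(meta_id = character(0), k = integer(0),
               sample_size = integer(0), effect = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0),
               p_value = numeric(0), index = integer(0),
               quotient_pct = numeric(0), converged = logical(0),
               trace_length = integer(0), stringsAsFactors = FALSE)
  excluded_tbl <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(meta_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)

  ok <- meta_tbl[meta_tbl$converged %in% TRUE, , drop = FALSE]
  summary <- NULL
  notice <- NULL
  if (nrow(ok)) {
    summary <- summarize_corpus(ok[, c("meta_id", "index", "quotient_pct",
                                       "p_value", "sample_size")])
  } else {
    notice <- "no significant meta-analyses: summary is empty"
  }

  structure(
    list(meta = meta_tbl, excluded = excluded_tbl, summary = summary,
         notice = notice,
         provenance = list(
           config = unclass(config), moves = moves, seed = seed,
           version = as.character(utils::packageVersion("metafragility")),
           timestamp = if (isTRUE(timestamp))
             format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z") else NULL)),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("fragility analysis report: %d included, %d excluded\n",
              nrow(x$meta), nrow(x$excluded)))
  if (!is.null(x$summary)) print(x$summary) else cat(" ", x$notice, "\n")
  invisible(x)
}

#' Serialise an analysis report to JSON
#'
#' Writes the full report — per-meta table, exclusions, corpus summary,
#' cumulative curves and provenance — as JSON with full numeric
#' precision, so that [read_report_json()] round-trips it losslessly and
#' reports from identical inputs are byte-identical.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (!inherits(report, "analysis_report")) {
    stop("'report' must be an analysis_report", call. = FALSE)
  }
  payload <- list(
    meta = report$meta,
    excluded = report$excluded,
    summary = if (is.null(report$summary)) NULL else {
      s <- report$summary
      list(n_records = s$n_records, index = s$index,
           quotient_pct = s$quotient_pct,
           cumsum_index = s$cumsum_index,
           cumsum_quotient = s$cumsum_quotient,
           pearson_index_p = s$pearson_index_p,
           pearson_quotient_p = s$pearson_quotient_p,
           conf = s$conf, scale = s$scale)
    },
    notice = report$notice,
    provenance = report$provenance)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read an analysis report back from JSON
#'
#' @param path Path written by [write_report_json()].
#' @return An `analysis_report`.
#' @export
read_report_json <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  # empty tables serialise as [] and come back as bare lists
  if (!is.data.frame(p$meta) && !length(p$meta)) {
    p$meta <- data.frame(meta_id = character(0), k = integer(0),
                         sample_size = integer(0), effect = numeric(0),
                         ci_low = numeric(0), ci_high = numeric(0),
                         p_value = numeric(0), index = integer(0),
                         quotient_pct = numeric(0), converged = logical(0),
                         trace_length = integer(0), stringsAsFactors = FALSE)
  }
  if (!is.data.frame(p$excluded) && !length(p$excluded)) {
    p$excluded <- data.frame(meta_id = character(0), reason = character(0),
                             stringsAsFactors = FALSE)
  }
  summary <- NULL
  if (!is.null(p$summary)) {
    s <- p$summary
    summary <- structure(
      list(n_records = s$n_records, index = as.list(s$index),
           quotient_pct = as.list(s$quotient_pct),
           cumsum_index = as.data.frame(s$cumsum_index),
           cumsum_quotient = as.data.frame(s$cumsum_quotient),
           pearson_index_p = if (is.null(s$pearson_index_p)) NULL
             else as.list(s$pearson_index_p),
           pearson_quotient_p = if (is.null(s$pearson_quotient_p)) NULL
             else as.list(s$pearson_quotient_p),
           conf = s$conf, scale = s$scale),
      class = "corpus_summary")
  }
  structure(
    list(meta = as.data.frame(p$meta), excluded = as.data.frame(p$excluded),
         summary = summary, notice = p$notice,
         provenance = p$provenance),
    class = "analysis_report")
}

#' Export cumulative-count curves as CSV
#'
#' Writes the cumulative-count curves of a corpus summary (one block for
#' the fragility index, one for the quotient) in long format:
#' `measure,value,cum_count`.
#'
#' @param summary A `corpus_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cumsum_csv <- function(summary, path) {
  if (!inherits(summary, "corpus_summary")) {
    stop("'summary' must be a corpus_summary", call. = FALSE)
  }
  long <- rbind(
    cbind(measure = "index", summary$cumsum_index),
    cbind(measure = "quotient_pct", summary$cumsum_quotient))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
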