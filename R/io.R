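#' Read trial records from delimited text
#'
#' Reads a CSV/TSV of trial-level recognition data with header columns
#' `subject`, `condition` (target proportion), `stimulus`, `response`,
#' and optionally `confidence` and `rt`.  Rows failing validation are
#' reported with their row numbers.
#'
#' @param path file path.
#' @param sep field separator (`","` by default; use `"\t"` for TSV).
#' @param rt_unit `"s"` (default) or `"ms"`; millisecond RTs are converted
#'   to seconds on ingest.
#' @param needs_cl,needs_rt require (and validate) the confidence / rt
#'   columns, as the intended model variant demands.
#' @return a validated data frame of trial records.
#' @export
read_trials <- function(path, sep = ",", rt_unit = c("s", "ms"),
                        needs_cl = FALSE, needs_rt = FALSE) {
  rt_unit <- match.arg(rt_unit)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if ("rt" %in% names(df) && rt_unit == "ms") df$rt <- df$rt / 1000
  validate_trials(df, needs_cl = needs_cl,
                  needs_rt = needs_rt || ("rt" %in% names(df) && needs_rt))
}

#' Write trial records to CSV
#' @param trials a trial-record data frame.
#' @param path destination file.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write long-format count tables
#'
#' Count tables are stored long: one row per
#' (subject, condition, stimulus, category) cell with a `count` column.
#'
#' @param path file path.
#' @return `read_counts`: a data frame of class `"mptdc_counts"`.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject", "condition", "stimulus", "category", "count")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("count file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(df$count < 0 | df$count != round(df$count)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(df, class = c("mptdc_counts", "data.frame"))
}

#' @rdname read_counts
#' @param counts long-format counts (e.g. from [aggregate_counts()]).
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize a model specification to JSON
#'
#' The document records the constructor arguments, the parameter table and
#' every branch's ordered term list, so a spec can be inspected, stored
#' and rebuilt bit-identically.
#'
#' @param model an [mptdc_model()].
#' @param path optional file; when omitted the JSON string is returned.
#' @return `model_to_json`: the JSON string (invisibly when written to
#'   `path`); `model_from_json`: the rebuilt `mptdc_model`.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "mptdc_model"))
  doc <- list(
    family = model$family, variant = model$variant,
    n_conditions = model$n_conditions, target_props = model$target_props,
    n_cl_bins = model$n_cl_bins, n_rt_bins = model$n_rt_bins,
    categories = model$categories,
    parameters = model$params,
    branches = lapply(model$branches, function(b)
      list(tree = b$tree, state = b$state, category = b$category,
           terms = b$terms)))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname model_to_json
#' @param json a JSON string or file path produced by [model_to_json()].
#' @export
model_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  model <- mptdc_model(doc$family, doc$variant, doc$n_conditions,
                       doc$target_props)
  # integrity check: the rebuilt branch structure must match the document
  rebuilt <- jsonlite::fromJSON(model_to_json(model),
                                simplifyDataFrame = FALSE,
                                simplifyVector = TRUE)
  if (!identical(rebuilt, doc))
    stop("serialized model does not match its rebuilt specification",
         call. = FALSE)
  model
}

#' Write a fit result to JSON
#'
#' @param fit an `"mptdc_fit"`.
#' @param path destination file.
#' @param seed optional seed to embed for provenance.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "mptdc_fit"))
  doc <- list(family = fit$model$family, variant = fit$model$variant,
              estimates = as.list(fit$estimates),
              se = as.list(fit$se),
              logLik = fit$logLik, chisq = fit$chisq, gsq = fit$gsq,
              df = fit$df, aic = fit$aic, aicc = fit$aicc,
              n = fit$n, p = fit$p, converged = fit$converged,
              n_restarts = fit$n_restarts, seed = seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
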