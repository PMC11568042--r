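#' Log-normal quantile RT bin boundaries
#'
#' Computes per-subject cutoffs for discretizing response times into bins
#' by the log-normal approximation: the RTs are log-transformed, the mean
#' and SD of the logs are taken, the equal-probability normal quantiles
#' `k/n_bins` (k = 1..n_bins-1) are computed on the log scale and
#' back-transformed by exponentiation.  For two bins the single cutoff
#' reduces to `exp(mean(log(rts)))`, the geometric mean.
#'
#' @param rts positive response times (seconds), at least 2.
#' @param n_bins number of bins (>= 2; 2 is the validated default).
#' @return an object of class `"mptdc_binning"`: list with `cutoffs`
#'   (strictly increasing, length `n_bins - 1`) and `n_bins`.
#' @examples
#' lognormal_bin_boundaries(c(1, 4), 2)$cutoffs  # 2, the geometric mean
#' @export
lognormal_bin_boundaries <- function(rts, n_bins = 2L) {
  if (length(rts) < 2L)
    stop("need at least 2 RTs to set bin boundaries", call. = FALSE)
  if (any(!is.finite(rts)) || any(rts <= 0))
    stop("all RTs must be positive and finite", call. = FALSE)
  if (n_bins < 2L || n_bins != round(n_bins))
    stop("`n_bins` must be an integer >= 2", call. = FALSE)
  lx <- log(rts)
  m <- mean(lx)
  s <- stats::sd(lx)
  probs <- seq_len(n_bins - 1L) / n_bins
  cutoffs <- exp(m + s * stats::qnorm(probs))
  if (anyDuplicated(cutoffs))  # degenerate (constant RTs) with > 2 bins
    stop("degenerate RT distribution: bin cutoffs are not distinct",
         call. = FALSE)
  structure(list(cutoffs = cutoffs, n_bins = as.integer(n_bins)),
            class = "mptdc_binning")
}

#' Assign an RT to a bin
#'
#' Bin 1 is the fast bin.  An RT exceeding a cutoff falls in the slower
#' bin; ties at the cutoff go to the faster bin.
#'
#' @param rt positive response time(s), same unit as the cutoffs.
#' @param rule an `"mptdc_binning"` rule from [lognormal_bin_boundaries()].
#' @return integer bin index (vectorized), 1 = fast.
#' @export
assign_bin <- function(rt, rule) {
  stopifnot(inherits(rule, "mptdc_binning"))
  if (any(rt <= 0)) stop("RTs must be positive", call. = FALSE)
  findInterval(rt, rule$cutoffs, left.open = TRUE) + 1L
}

#' Aggregate trial records into per-subject count tables
#'
#' Counts trials into the multinomial category layout of a model variant:
#' condition x stimulus trees, categories formed by response, optional
#' confidence bin and optional RT bin.  RT cutoffs are set per subject by
#' pooling all of that subject's trials (see [lognormal_bin_boundaries()]),
#' unless explicit `rules` are supplied.
#'
#' @param trials a data frame of trial records with columns `subject`,
#'   `condition` (target proportion), `stimulus` (`"old"`/`"new"`),
#'   `response` (`"old"`/`"new"`), and -- as required by `model` --
#'   `confidence` (`"high"`/`"medium"`/`"low"`) and `rt` (positive seconds).
#' @param model the [mptdc_model()] whose category layout to use.
#' @param rules optional named list of `"mptdc_binning"` rules, one per
#'   subject id; computed from the data when omitted.
#' @return a long-format data frame of class `"mptdc_counts"` with columns
#'   `subject`, `condition`, `stimulus`, `category`, `count`, covering
#'   every cell of the layout (zeros included).
#' @export
aggregate_counts <- function(trials, model, rules = NULL) {
  stopifnot(inherits(model, "mptdc_model"))
  trials <- validate_trials(trials, needs_cl = model$n_cl_bins > 1L,
                            needs_rt = model$n_rt_bins > 1L)
  conds <- model$target_props
  bad <- !trials$condition %in% conds
  if (any(bad))
    stop("trial condition(s) not in the model's target proportions (rows ",
         paste(utils::head(which(bad), 5L), collapse = ", "), ")",
         call. = FALSE)

  subjects <- unique(trials$subject)
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    tr <- trials[trials$subject == subjects[i], , drop = FALSE]
    cat_lab <- tr$response
    if (model$n_cl_bins > 1L) cat_lab <- paste(cat_lab, tr$confidence,
                                               sep = ".")
    if (model$n_rt_bins > 1L) {
      rule <- if (!is.null(rules)) rules[[as.character(subjects[i])]]
              else lognormal_bin_boundaries(tr$rt, model$n_rt_bins)
      if (is.null(rule))
        stop("no binning rule for subject ", subjects[i], call. = FALSE)
      bin_lab <- c("fast", "slow")[assign_bin(tr$rt, rule)]
      cat_lab <- paste(cat_lab, bin_lab, sep = ".")
    }
    grid <- expand.grid(category = model$categories,
                        stimulus = c("old", "new"),
                        condition = conds,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key_all <- paste(grid$condition, grid$stimulus, grid$category)
    key_obs <- paste(tr$condition, tr$stimulus, cat_lab)
    tab <- table(factor(key_obs, levels = key_all))
    out[[i]] <- data.frame(subject = subjects[i],
                           condition = grid$condition,
                           stimulus = grid$stimulus,
                           category = grid$category,
                           count = as.integer(tab),
                           stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), class = c("mptdc_counts", "data.frame"))
}

validate_trials <- function(trials, needs_cl, needs_rt) {
  required <- c("subject", "condition", "stimulus", "response",
                if (needs_cl) "confidence", if (needs_rt) "rt")
  missing <- setdiff(required, names(trials))
  if (length(missing))
    stop("trial data lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows))
      problems <<- c(problems, paste0(what, " (rows ",
                                      paste(utils::head(rows, 5L),
                                            collapse = ", "),
                                      if (length(rows) > 5L) ", ...", ")"))
  }
  note(which(!trials$stimulus %in% c("old", "new")),
       "stimulus must be 'old' or 'new'")
  note(which(!trials$response %in% c("old", "new")),
       "response must be 'old' or 'new'")
  if (needs_cl)
    note(which(!trials$confidence %in% c("high", "medium", "low")),
         "confidence must be 'high', 'medium' or 'low'")
  if (needs_rt)
    note(which(!is.finite(trials$rt) | trials$rt <= 0),
         "rt must be positive")
  if (length(problems))
    stop("invalid trial data: ", paste(problems, collapse = "; "),
         call. = FALSE)
  trials
}

#' Counts for one subject as a trees x categories matrix
#'
#' Converts long-format counts (see [aggregate_counts()], [read_counts()])
#' into the trees-by-categories matrix layout the fitting functions use,
#' optionally selecting one subject from a multi-subject table.  Matrices
#' are passed through after a shape check.
#'
#' @param model an [mptdc_model()] fixing the layout.
#' @param counts a count matrix or long-format count data frame.
#' @param subject subject id to select when `counts` spans several.
#' @return a numeric matrix, rows ordered as `model$trees`, columns as
#'   `model$categories`.
#' @export
count_matrix <- function(model, counts, subject = NULL) {
  if (is.matrix(counts)) {
    if (!all(dim(counts) == c(nrow(model$trees), length(model$categories))))
      stop("count matrix must be ", nrow(model$trees), " trees x ",
           length(model$categories), " categories", call. = FALSE)
    return(counts)
  }
  stopifnot(is.data.frame(counts))
  if (!is.null(subject)) counts <- counts[counts$subject == subject, ,
                                          drop = FALSE]
  if ("subject" %in% names(counts) && length(unique(counts$subject)) > 1L)
    stop("counts contain several subjects; pass `subject =`", call. = FALSE)
  if (!all(counts$category %in% model$categories))
    stop("count categories do not match the model's category layout",
         call. = FALSE)
  m <- matrix(0, nrow = nrow(model$trees), ncol = length(model$categories),
              dimnames = list(tree_labels(model), model$categories))
  row_id <- match(paste(counts$condition, counts$stimulus),
                  paste(model$trees$target_prop, model$trees$stimulus))
  if (anyNA(row_id))
    stop("count conditions/stimuli do not match the model's trees",
         call. = FALSE)
  col_id <- match(counts$category, model$categories)
  for (k in seq_len(nrow(counts)))
    m[row_id[k], col_id[k]] <- m[row_id[k], col_id[k]] + counts$count[k]
  m
}
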