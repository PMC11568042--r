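#' Select the better-fitting of two models for one subject
#'
#' Compares two converged fits of the same data by AICc (default) or AIC;
#' the model with the strictly smaller criterion wins.  Exact ties are
#' flagged rather than broken arbitrarily.
#'
#' @param fit_a,fit_b `"mptdc_fit"` objects for the two candidate models.
#' @param labels length-2 character vector naming the candidates; defaults
#'   to their model families.
#' @param criterion `"AICc"` or `"AIC"`.
#' @param subject optional subject id carried into the record.
#' @return a one-row data frame: `subject`, `label_a`, `label_b`,
#'   criterion value per model, `winner` (`NA` on a tie), `delta`
#'   (criterion of loser minus winner, 0 on a tie) and `tie`.
#' @export
select_best <- function(fit_a, fit_b, labels = NULL,
                        criterion = c("AICc", "AIC"), subject = NA) {
  stopifnot(inherits(fit_a, "mptdc_fit"), inherits(fit_b, "mptdc_fit"))
  criterion <- match.arg(criterion)
  if (!fit_a$converged || !fit_b$converged)
    stop("both fits must have converged", call. = FALSE)
  if (is.null(labels))
    labels <- c(fit_a$model$family, fit_b$model$family)
  va <- if (criterion == "AICc") fit_a$aicc else fit_a$aic
  vb <- if (criterion == "AICc") fit_b$aicc else fit_b$aic
  tie <- va == vb
  winner <- if (tie) NA_character_ else labels[which.min(c(va, vb))]
  data.frame(subject = subject, label_a = labels[1], label_b = labels[2],
             criterion = criterion, value_a = va, value_b = vb,
             winner = winner, delta = abs(va - vb), tie = tie,
             stringsAsFactors = FALSE)
}

#' Cross-tabulate best-model selections under two comparisons
#'
#' Builds the 2x2 table of winners: rows are the winner under comparison
#' A, columns the winner under comparison B, for the subjects present in
#' both.
#'
#' @param winners_a,winners_b character vectors of per-subject winners
#'   (same subject order), e.g. the `winner` column of [select_best()]
#'   records.
#' @param levels the two candidate labels fixing row/column order
#'   (default `c("SDT", "2HT")`).
#' @return a 2x2 integer matrix.
#' @export
selection_crosstab <- function(winners_a, winners_b,
                               levels = c("SDT", "2HT")) {
  if (length(winners_a) != length(winners_b))
    stop("winner vectors must have equal length", call. = FALSE)
  keep <- !is.na(winners_a) & !is.na(winners_b)
  table(factor(winners_a[keep], levels = levels),
        factor(winners_b[keep], levels = levels))
}

#' Chi-squared test of independence for a 2x2 selection crosstab
#'
#' Pearson's statistic without continuity correction,
#' \eqn{\chi^2 = N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}, with `df = 1`,
#' upper-tail p value and the phi effect size \eqn{\phi = \sqrt{\chi^2/N}}.
#' Degenerate margins (a zero row or column total) give `chisq = 0`,
#' `phi = 0` with a warning.
#'
#' @param table a 2x2 matrix/table of non-negative counts.
#' @return an object of class `"mptdc_indep"`: `chisq`, `df`, `p_value`,
#'   `phi`, `n`.
#' @examples
#' chi2_independence(matrix(c(38, 3, 0, 6), 2))  # phi = .786
#' @export
chi2_independence <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L)))
    stop("`table` must be 2x2", call. = FALSE)
  if (any(tb < 0) || any(!is.finite(tb)))
    stop("cell counts must be non-negative and finite", call. = FALSE)
  n <- sum(tb)
  if (n < 1) stop("empty table", call. = FALSE)
  a <- tb[1, 1]; b <- tb[1, 2]; c_ <- tb[2, 1]; d <- tb[2, 2]
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) {
    warning("degenerate margin(s): chi-squared and phi set to 0")
    chisq <- 0
  } else {
    chisq <- n * (a * d - b * c_)^2 / prod(margins)
  }
  structure(list(chisq = chisq, df = 1L,
                 p_value = stats::pchisq(chisq, 1L, lower.tail = FALSE),
                 phi = sqrt(chisq / n), n = n, table = tb),
            class = "mptdc_indep")
}

#' @export
print.mptdc_indep <- function(x, ...) {
  cat(sprintf("2x2 independence test: X2(1) = %.3f, p = %.4f, phi = %.3f (N = %d)\n",
              x$chisq, x$p_value, x$phi, as.integer(x$n)))
  invisible(x)
}
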