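#' Parametric bootstrap goodness-of-fit test
#'
#' Simulates `B` datasets from the fitted parameters, holding the observed
#' per-tree trial totals fixed (the paradigm fixes block composition),
#' refits the same model to each, and compares the observed Pearson
#' chi-squared with the empirical `1 - alpha` quantile of the bootstrap
#' chi-squared distribution.  The null of adequate fit is retained when
#' the observed statistic does not exceed the critical value.  Each
#' bootstrap refit is warm-started at the original estimate plus
#' `n_restarts - 1` random starts; failed refits are dropped and counted.
#'
#' @param model an [mptdc_model()].
#' @param fit the `"mptdc_fit"` for the observed data (must have
#'   converged).
#' @param B number of bootstrap samples (default 1000).
#' @param alpha test level (default .05).
#' @param seed integer seed; the full bootstrap distribution is
#'   reproducible from it.
#' @param n_restarts optimizer starts per refit (default 2: warm start
#'   plus one random restart).
#' @return An object of class `"mptdc_gof"`: `statistic` (observed
#'   chi-squared), `boot` (the retained bootstrap statistics),
#'   `critical_value` (order statistic at `ceiling((1 - alpha) * m)` of the
#'   `m` retained refits), `reject`, `B`, `alpha`, `seed`,
#'   `n_failed_refits`.
#' @export
parametric_bootstrap_gof <- function(model, fit, B = 1000L, alpha = 0.05,
                                     seed = NULL, n_restarts = 2L) {
  stopifnot(inherits(model, "mptdc_model"), inherits(fit, "mptdc_fit"))
  if (B < 1L) stop("`B` must be >= 1", call. = FALSE)
  if (!fit$converged)
    stop("the observed-data fit did not converge", call. = FALSE)
  totals <- rowSums(fit$observed)
  p_hat <- prob_matrix(model, fit$estimates)

  boot <- local_seed(seed, {
    vapply(seq_len(B), function(b) {
      sim <- draw_tree_counts(p_hat, totals)
      refit <- suppressWarnings(tryCatch(
        fit_mptdc(model, sim, n_restarts = n_restarts,
                  start = fit$estimates, compute_se = FALSE),
        error = function(e) NULL))
      if (is.null(refit) || !is.finite(refit$chisq)) NA_real_
      else refit$chisq
    }, 0)
  })
  failed <- sum(is.na(boot))
  boot <- boot[!is.na(boot)]
  if (!length(boot))
    stop("all bootstrap refits failed", call. = FALSE)
  crit <- sort(boot)[ceiling((1 - alpha) * length(boot))]
  structure(list(statistic = fit$chisq, boot = boot,
                 critical_value = crit,
                 reject = fit$chisq > crit,
                 B = as.integer(B), alpha = alpha, seed = seed,
                 n_failed_refits = failed),
            class = "mptdc_gof")
}

draw_tree_counts <- function(p, totals) {
  out <- p
  for (t in seq_len(nrow(p)))
    out[t, ] <- stats::rmultinom(1L, totals[t], p[t, ])
  out
}

#' @export
print.mptdc_gof <- function(x, ...) {
  cat(sprintf(paste0("Parametric bootstrap GOF: X2 = %.3f, critical value ",
                     "(alpha = %.2f) = %.3f\n"),
              x$statistic, x$alpha, x$critical_value))
  cat(sprintf("  %s the null of adequate fit (B = %d, %d refit(s) failed)\n",
              if (x$reject) "REJECT" else "retain", x$B, x$n_failed_refits))
  invisible(x)
}
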