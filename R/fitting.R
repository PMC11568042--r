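# parameter transforms for unconstrained optimization:
#   logit for [0,1] probabilities, log for sigma and criterion increments,
#   identity for dprime and base criteria.  Transformed coordinates are
#   boxed so estimates stay numerically finite on the natural scale.
TRANSFORM_BOX <- c(logit = 16, log = 12, identity = 25)

to_eta <- function(model, theta) {
  tr <- model$params$transform
  eta <- theta
  eta[tr == "logit"] <- stats::qlogis(pmin(pmax(theta[tr == "logit"],
                                                1e-7), 1 - 1e-7))
  eta[tr == "log"] <- log(pmax(theta[tr == "log"], 1e-7))
  b <- TRANSFORM_BOX[tr]
  pmin(pmax(eta, -b), b)
}

to_theta <- function(model, eta) {
  tr <- model$params$transform
  theta <- eta
  theta[tr == "logit"] <- stats::plogis(eta[tr == "logit"])
  theta[tr == "log"] <- exp(eta[tr == "log"])
  names(theta) <- model$params$name
  theta
}

#' Multinomial negative log-likelihood of an MPT-DC model
#'
#' The multinomial kernel \eqn{-\sum_{trees}\sum_k n_k \log p_k}; the
#' count-dependent constant is omitted (it cancels from all likelihood
#' ratios and information criteria).  Returns `Inf` when a category with a
#' zero model probability has a positive count.
#'
#' @param model an [mptdc_model()].
#' @param params named in-bounds parameter vector.
#' @param counts count matrix (trees x categories) or long-format counts
#'   for a single subject (see [aggregate_counts()]).
#' @return the negative log-likelihood (kernel only).
#' @export
negative_log_likelihood <- function(model, params, counts) {
  theta <- validate_params(model, params)
  n <- count_matrix(model, counts)
  nll_cells(prob_matrix(model, theta), n)
}

nll_cells <- function(p, n) {
  pos <- n > 0
  if (any(p[pos] <= 0)) return(Inf)
  -sum(n[pos] * log(p[pos]))
}

#' Pearson chi-squared statistic
#'
#' \eqn{\sum (O-E)^2/E} over cells with positive expected counts.  Cells
#' with `E = 0` and `O = 0` contribute nothing; `E = 0` with `O > 0`
#' yields `Inf` with a warning.
#'
#' @param observed,expected matching numeric vectors/matrices of observed
#'   and expected counts.
#' @return the statistic.
#' @export
pearson_chi2 <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("`observed` and `expected` must have the same layout",
         call. = FALSE)
  o <- as.numeric(observed)
  e <- as.numeric(expected)
  if (any(e == 0 & o > 0)) {
    warning("observed counts in cells with zero expectation: chi-squared ",
            "is infinite")
    return(Inf)
  }
  keep <- e > 0
  sum((o[keep] - e[keep])^2 / e[keep])
}

gsq_stat <- function(observed, expected) {
  o <- as.numeric(observed)
  e <- as.numeric(expected)
  pos <- o > 0
  if (any(e[pos] <= 0)) return(Inf)
  2 * sum(o[pos] * log(o[pos] / e[pos]))
}

#' Corrected AIC
#'
#' `AICc = AIC + 2 p (p + 1) / (n - p - 1)`, the small-sample correction
#' for `p` free parameters and `n` observations (total trials).
#'
#' @param aic the AIC value.
#' @param p number of free parameters.
#' @param n number of observations.
#' @return the corrected value (`Inf` with a warning when `n <= p + 1`).
#' @export
aicc <- function(aic, p, n) {
  if (n <= p + 1) {
    warning("AICc undefined for n <= p + 1; returning Inf")
    return(Inf)
  }
  aic + (2 * p * (p + 1)) / (n - p - 1)
}

#' Maximum-likelihood fit of an MPT-DC model
#'
#' Minimizes the multinomial negative log-likelihood over the
#' box-constrained parameter space, working in transformed coordinates
#' (log-odds for probabilities, log for `sigma` and criterion increments)
#' with one deterministic mid-range start plus random restarts.  Standard
#' errors come from the inverse observed information at the optimum,
#' mapped to the natural scale by the delta method; they are reported as
#' `NA` when the information matrix is singular or an estimate lies on a
#' bound (which happens with sparse cells, e.g. many RT bins).
#'
#' @param model an [mptdc_model()].
#' @param counts count matrix (trees x categories) or long-format counts
#'   for one subject; every tree must contain at least one trial.
#' @param n_restarts number of optimizer starts (default 10).
#' @param seed optional integer seed for the random restarts.
#' @param tolerance relative convergence tolerance passed to the optimizer.
#' @param start optional named parameter vector used as the first start.
#' @param compute_se set `FALSE` to skip the Hessian/standard-error step
#'   (used for bootstrap refits, where only the fit statistic is needed).
#'
#' @return An object of class `"mptdc_fit"`: estimates, standard errors,
#'   log-likelihood kernel, Pearson `chisq`, likelihood-ratio `gsq`,
#'   degrees of freedom, `aic`, `aicc`, total trials `n`, parameter count
#'   `p`, expected counts, a convergence flag and the number of restarts
#'   used.  Non-convergence is flagged, not raised.
#' @examples
#' m <- mptdc_model("2HT", "classic")
#' cn <- matrix(c(65, 35, 15, 85, 75, 25, 25, 75, 85, 15, 35, 65),
#'              nrow = 6, byrow = TRUE)
#' fit <- fit_mptdc(m, cn, n_restarts = 2, seed = 1)
#' coef(fit)
#' @export
fit_mptdc <- function(model, counts, n_restarts = 10L, seed = NULL,
                      tolerance = 1e-10, start = NULL, compute_se = TRUE) {
  stopifnot(inherits(model, "mptdc_model"))
  n <- count_matrix(model, counts)
  if (any(rowSums(n) < 1))
    stop("every tree needs at least one trial", call. = FALSE)
  if (any(n < 0)) stop("negative counts", call. = FALSE)

  obj <- function(eta) {
    val <- nll_cells(prob_matrix(model, to_theta(model, eta)), n)
    if (!is.finite(val)) 1e10 else val
  }
  box <- TRANSFORM_BOX[model$params$transform]

  starts <- list(if (is.null(start)) default_params(model)
                 else validate_params(model, start))
  if (n_restarts > 1L) {
    rand <- local_seed(seed, random_params(model, n_restarts - 1L))
    if (n_restarts == 2L) rand <- matrix(rand, nrow = 1L,
                                         dimnames = list(NULL, names(rand)))
    for (i in seq_len(nrow(rand))) starts[[i + 1L]] <- rand[i, ]
  }

  best <- NULL
  converged_any <- FALSE
  for (s in starts) {
    res <- tryCatch(
      stats::nlminb(to_eta(model, s), obj, lower = -box, upper = box,
                    control = list(rel.tol = tolerance, iter.max = 500L,
                                   eval.max = 2000L)),
      error = function(e) NULL)
    if (is.null(res)) next
    # codes 7 (singular) and 8 (false convergence) arise on likelihood
    # ridges at boundary solutions; the minimizer there is a valid
    # boundary MLE, so they count as converged (the message is kept)
    if (res$convergence == 0 ||
        grepl("singular convergence|false convergence", res$message))
      converged_any <- TRUE
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best))
    stop("optimizer failed from every start", call. = FALSE)

  eta_hat <- best$par
  theta_hat <- to_theta(model, eta_hat)
  p_hat <- prob_matrix(model, theta_hat)
  expected <- p_hat * rowSums(n)
  nll <- nll_cells(p_hat, n)

  se <- if (compute_se) se_delta(model, obj, eta_hat, theta_hat)
        else rep(NA_real_, nrow(model$params))

  n_total <- sum(n)
  p_free <- nrow(model$params)
  df <- nrow(n) * (ncol(n) - 1L) - p_free
  aic <- 2 * nll + 2 * p_free
  structure(list(
    model = model,
    estimates = theta_hat,
    se = se,
    logLik = -nll,
    chisq = pearson_chi2(n, expected),
    gsq = gsq_stat(n, expected),
    df = df,
    aic = aic,
    aicc = aicc(aic, p_free, n_total),
    n = n_total, p = p_free,
    observed = n, expected = expected,
    converged = converged_any && is.finite(nll),
    optimizer_message = best$message,
    n_restarts = length(starts)),
    class = "mptdc_fit")
}

# delta-method SEs on the natural scale from the transformed-space Hessian;
# NA where the information matrix is singular or an estimate is on a bound
se_delta <- function(model, obj, eta_hat, theta_hat) {
  pt <- model$params
  se <- rep(NA_real_, nrow(pt))
  names(se) <- pt$name
  on_bound <- (pt$transform == "logit" &
                 (theta_hat < 1e-5 | theta_hat > 1 - 1e-5)) |
    (pt$transform == "log" & theta_hat < 1e-5) |
    abs(abs(eta_hat) - TRANSFORM_BOX[pt$transform]) < 1e-6
  H <- tryCatch(stats::optimHess(eta_hat, obj), error = function(e) NULL)
  if (is.null(H)) {
    warning("Hessian could not be computed; standard errors undefined")
    return(se)
  }
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
    warning("observed information matrix is singular; standard errors ",
            "undefined")
    return(se)
  }
  jac <- ifelse(pt$transform == "logit", theta_hat * (1 - theta_hat),
                ifelse(pt$transform == "log", theta_hat, 1))
  se_all <- abs(jac) * sqrt(diag(V))
  se[!on_bound] <- se_all[!on_bound]
  if (any(on_bound))
    warning("estimate(s) on a parameter bound: ",
            paste(pt$name[on_bound], collapse = ", "),
            "; their standard errors are undefined")
  se
}

#' @export
coef.mptdc_fit <- function(object, ...) object$estimates

#' @export
logLik.mptdc_fit <- function(object, ...) {
  structure(object$logLik, df = object$p, nobs = object$n,
            class = "logLik")
}

#' @export
print.mptdc_fit <- function(x, digits = 3, ...) {
  cat(sprintf("MPT-DC fit: %s %s  (%d parameters, n = %d trials)\n",
              x$model$family, x$model$variant, x$p, x$n))
  est <- format(round(x$estimates, digits))
  se <- ifelse(is.na(x$se), "NA", format(round(x$se, digits)))
  tab <- data.frame(estimate = est, se = se)
  print(tab)
  cat(sprintf("logLik %.3f  X2 %.3f  G2 %.3f  df %d  AIC %.2f  AICc %.2f\n",
              x$logLik, x$chisq, x$gsq, x$df, x$aic, x$aicc))
  if (!x$converged) cat("warning: optimizer did not report convergence\n")
  invisible(x)
}

# evaluate `expr` under a temporary RNG state when seed is non-NULL
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
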