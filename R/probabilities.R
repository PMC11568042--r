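#' Category probabilities of an MPT-DC model
#'
#' Evaluates the probability of every response category in every processing
#' tree at a given parameter set.  For the 2HT family each category
#' probability is a sum of branch products of detection, guessing,
#' confidence (`L`) and RT-bin (`H`) probabilities; for the SDT family it is
#' the Gaussian mass between adjacent decision criteria (old items
#' `N(dprime, sigma)`, new items `N(0, 1)`), multiplied by the `H` terms
#' when RT bins are modeled.  Within each tree the probabilities sum to 1.
#'
#' @param model an [mptdc_model()].
#' @param params named numeric vector with one value per free parameter of
#'   `model`, inside the parameter bounds.
#' @param tree optional tree index (row of `model$trees`); if supplied only
#'   that tree's probability vector is returned.
#'
#' @return A numeric matrix (trees x categories, with dimnames) or, when
#'   `tree` is given, a named probability vector over the tree's categories.
#'
#' @examples
#' m <- mptdc_model("2HT", "classic")
#' p <- c(do = .5, dn = .5, g1 = .5, g2 = .5, g3 = .5)
#' category_probabilities(m, p, tree = 1)  # P(Hit) = .75
#'
#' @export
category_probabilities <- function(model, params, tree = NULL) {
  stopifnot(inherits(model, "mptdc_model"))
  theta <- validate_params(model, params)
  pm <- prob_matrix(model, theta)
  if (is.null(tree)) return(pm)
  if (!tree %in% seq_len(nrow(model$trees)))
    stop("`tree` must be an index in 1..", nrow(model$trees), call. = FALSE)
  pm[tree, ]
}

validate_params <- function(model, params) {
  pt <- model$params
  if (is.null(names(params)))
    stop("`params` must be a named vector", call. = FALSE)
  missing <- setdiff(pt$name, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  theta <- as.numeric(params[pt$name])
  if (any(!is.finite(theta) & !(pt$lower == -Inf | pt$upper == Inf)))
    stop("non-finite parameter value", call. = FALSE)
  bad <- which(theta < pt$lower | theta > pt$upper | is.na(theta))
  if (length(bad))
    stop("parameter(s) out of bounds: ",
         paste(sprintf("%s = %g", pt$name[bad], theta[bad]), collapse = ", "),
         call. = FALSE)
  names(theta) <- pt$name
  theta
}

# criterion values per condition: K columns, row j gives c_{kj}
criteria_matrix <- function(model, theta) {
  cp <- model$compiled
  base <- theta[cp$c_idx]
  if (cp$K == 1L) return(matrix(base, ncol = 1L))
  incr <- cumsum(c(0, theta[cp$dc_idx]))
  outer(base, rep(1, cp$K)) + matrix(incr, nrow = model$n_conditions,
                                     ncol = cp$K, byrow = TRUE)
}

# Gaussian interval masses: array [condition, stimulus(old,new), region]
interval_masses <- function(model, theta) {
  cp <- model$compiled
  crit <- criteria_matrix(model, theta)
  J <- model$n_conditions
  K <- cp$K
  mu <- c(theta[cp$dprime_idx], 0)
  sd_ <- c(theta[cp$sigma_idx], 1)
  out <- array(0, dim = c(J, 2L, K + 1L))
  for (s in 1:2) {
    cdf <- stats::pnorm((crit - mu[s]) / sd_[s])      # J x K
    full <- cbind(0, cdf, 1)
    out[, s, ] <- full[, -1L, drop = FALSE] - full[, -(K + 2L), drop = FALSE]
  }
  out
}

# core evaluator: trees x categories probability matrix
prob_matrix <- function(model, theta) {
  cp <- model$compiled
  v <- numeric(cp$n_terms)
  v[cp$which_p] <- theta[cp$p_par]
  v[cp$which_q] <- 1 - theta[cp$q_par]
  if (length(cp$which_iv)) {
    masses <- interval_masses(model, theta)
    v[cp$which_iv] <- masses[cbind(cp$iv_j, cp$iv_stim, cp$iv_region)]
  }
  b <- exp(as.vector(cp$M %*% log(pmax(v, 1e-300))))
  # a branch containing an exactly-zero term has exactly zero probability
  # (the floor above only guards the log; structural zeros must be exact)
  b[as.vector(cp$M %*% (v == 0)) > 0] <- 0
  cells <- as.vector(cp$S %*% b)
  matrix(cells, nrow = nrow(model$trees), ncol = cp$ncat, byrow = TRUE,
         dimnames = list(tree_labels(model), model$categories))
}

tree_labels <- function(model)
  paste0(format(model$trees$target_prop, trim = TRUE), ".",
         model$trees$stimulus)

#' Random in-bounds parameter sets
#'
#' Draws parameter values uniformly from plausible in-bounds ranges
#' (probabilities from (0, 1); `dprime` from (-2, 4); `sigma` from
#' (0.5, 3); base criteria from (-3, 1.5); criterion increments from
#' (0, 1.5)).  Used for property checks and as random restart points.
#'
#' @param model an [mptdc_model()].
#' @param n number of draws.
#' @return if `n == 1` a named vector, else a matrix with `n` rows.
#' @export
random_params <- function(model, n = 1L) {
  pt <- model$params
  draw1 <- function(role, lower, upper) {
    switch(role,
           sensitivity = stats::runif(1, -2, 4),
           variability = stats::runif(1, 0.5, 3),
           criterion = stats::runif(1, -3, 1.5),
           criterion_increment = stats::runif(1, 1e-3, 1.5),
           stats::runif(1, 0, 1))
  }
  out <- matrix(NA_real_, nrow = n, ncol = nrow(pt),
                dimnames = list(NULL, pt$name))
  for (i in seq_len(n))
    out[i, ] <- vapply(seq_len(nrow(pt)), function(k)
      draw1(pt$role[k], pt$lower[k], pt$upper[k]), 0)
  if (n == 1L) out[1L, ] else out
}

# deterministic mid-range starting point for the optimizer
default_params <- function(model) {
  pt <- model$params
  val <- vapply(pt$role, function(r)
    switch(r,
           sensitivity = 1,
           variability = 1,
           criterion = if (model$n_cl_bins > 1L) -1 else 0,
           criterion_increment = 0.5,
           0.5), 0)
  names(val) <- pt$name
  val
}
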