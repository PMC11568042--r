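#' Build an MPT-DC recognition-memory model
#'
#' Constructs one of the eight model variants used in the MPT-DC framework
#' for old/new recognition: the two-high-threshold (`"2HT"`) or
#' signal-detection (`"SDT"`) family, either in its classic form or extended
#' with three confidence-level bins (`"CL"`), two response-time bins
#' (`"RT"`), or both (`"CL_RT"`).  The model is represented declaratively as
#' a set of processing trees (one old-item and one new-item tree per
#' target-proportion condition), each tree a list of branches whose
#' probability is an ordered product of parameter terms, complements and --
#' for the SDT family -- Gaussian criterion-interval masses.
#'
#' Free-parameter totals reproduce the standard layout: classic models have
#' 5 parameters (`do`, `dn`, `g_j` for 2HT; `dprime`, `sigma`, `c_j` for
#' SDT, with the new-item familiarity distribution fixed at mean 0 and SD
#' 1); the CL extension adds two nested confidence parameters per latent
#' state for 2HT (total 13) or four non-negative criterion increments for
#' SDT (total 9); the RT extension adds one fast-bin probability `H` per
#' latent state (2HT, total 9) or per response category (SDT, total 9); and
#' the joint CL+RT models carry one `H` per state-by-confidence branch
#' class (2HT, total 25) or per category-by-confidence class (SDT, total
#' 21).  Confidence and RT parameters are shared across conditions.
#'
#' @param family `"2HT"` or `"SDT"`.
#' @param variant `"classic"`, `"CL"`, `"RT"` or `"CL_RT"`.
#' @param n_conditions number of target-proportion conditions J (default 3).
#' @param target_props target proportions labelling the conditions; length
#'   `n_conditions`, strictly increasing.  Default `c(.35, .50, .65)`.
#'
#' @return An object of class `"mptdc_model"`: a list with the model
#'   layout (`trees`, `branches`, `categories`), the free-parameter table
#'   (`params`: name, role, bounds, optimizer transform, condition index)
#'   and a compiled representation used for fast probability evaluation.
#'
#' @examples
#' m <- mptdc_model("2HT", "CL_RT")
#' n_parameters(m)  # 25
#' m2 <- mptdc_model("SDT", "classic")
#' category_probabilities(m2, c(dprime = 0, sigma = 1, c1 = 0, c2 = 0, c3 = 0))
#'
#' @export
mptdc_model <- function(family = c("2HT", "SDT"),
                        variant = c("classic", "CL", "RT", "CL_RT"),
                        n_conditions = 3L,
                        target_props = NULL) {
  family <- match.arg(family)
  variant <- match.arg(variant)
  if (!is.numeric(n_conditions) || length(n_conditions) != 1L ||
      n_conditions < 1 || n_conditions != round(n_conditions))
    stop("`n_conditions` must be a positive integer", call. = FALSE)
  J <- as.integer(n_conditions)
  if (is.null(target_props)) {
    target_props <- if (J == 3L) c(.35, .50, .65) else seq_len(J) / (J + 1)
  }
  if (length(target_props) != J || is.unsorted(target_props, strictly = TRUE) ||
      any(target_props <= 0 | target_props >= 1))
    stop("`target_props` must be ", J,
         " strictly increasing proportions in (0, 1)", call. = FALSE)

  has_cl <- variant %in% c("CL", "CL_RT")
  has_rt <- variant %in% c("RT", "CL_RT")
  n_cl <- if (has_cl) 3L else 1L
  n_rt <- if (has_rt) 2L else 1L

  params <- build_param_table(family, variant, J)
  categories <- category_labels(has_cl, has_rt)
  trees <- data.frame(
    tree = seq_len(2L * J),
    condition = rep(seq_len(J), each = 2L),
    target_prop = rep(target_props, each = 2L),
    stimulus = rep(c("old", "new"), J),
    stringsAsFactors = FALSE
  )
  branches <- build_branches(family, variant, J, trees, categories)

  model <- structure(
    list(family = family, variant = variant,
         n_conditions = J, target_props = target_props,
         n_cl_bins = n_cl, n_rt_bins = n_rt,
         categories = categories, trees = trees,
         params = params, branches = branches),
    class = "mptdc_model")
  model$compiled <- compile_model(model)
  model
}

#' Number of free parameters of a model
#' @param model an `mptdc_model`.
#' @return integer count of free parameters.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "mptdc_model"))
  nrow(model$params)
}

# Ordered category labels: response, then confidence high->low, then RT
# fast->slow (fixed lexicographic layout for stable serialization).
category_labels <- function(has_cl, has_rt) {
  resp <- c("old", "new")
  cl <- if (has_cl) c("high", "medium", "low") else ""
  rt <- if (has_rt) c("fast", "slow") else ""
  out <- character(0)
  for (r in resp) for (c_ in cl) for (b in rt) {
    out <- c(out, paste(c(r, c_, b)[nzchar(c(r, c_, b))], collapse = "."))
  }
  out
}

build_param_table <- function(family, variant, J) {
  has_cl <- variant %in% c("CL", "CL_RT")
  has_rt <- variant %in% c("RT", "CL_RT")
  rows <- list()
  add <- function(name, role, lower, upper, transform, condition = NA_integer_)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, role = role, lower = lower, upper = upper,
      transform = transform, condition = condition, stringsAsFactors = FALSE)

  states <- c("do", "dn", "go", "gn")
  sdt_classes <- c("hit", "miss", "fa", "cr")
  cl_bins <- c("high", "medium", "low")

  if (family == "2HT") {
    add("do", "detection", 0, 1, "logit")
    add("dn", "detection", 0, 1, "logit")
    for (j in seq_len(J)) add(paste0("g", j), "guessing", 0, 1, "logit", j)
    if (has_cl)
      for (s in states) for (k in 1:2)
        add(paste0("L_", s, k), "confidence", 0, 1, "logit")
    if (has_rt) {
      cls <- if (has_cl) as.vector(outer(states, cl_bins, paste, sep = "_"))
             else states
      for (b in cls) add(paste0("H_", b), "rt", 0, 1, "logit")
    }
  } else {
    add("dprime", "sensitivity", -Inf, Inf, "identity")
    add("sigma", "variability", 0, Inf, "log")
    for (j in seq_len(J)) add(paste0("c", j), "criterion", -Inf, Inf, "identity", j)
    if (has_cl)
      for (k in 2:5) add(paste0("dc", k), "criterion_increment", 0, Inf, "log")
    if (has_rt) {
      cls <- if (has_cl) as.vector(outer(sdt_classes, cl_bins, paste, sep = "_"))
             else sdt_classes
      for (b in cls) add(paste0("H_", b), "rt", 0, 1, "logit")
    }
  }
  do.call(rbind, rows)
}

# A branch term is one of:
#   list(type = "p", par = <name>)   the parameter's value
#   list(type = "q", par = <name>)   its complement 1 - value
#   list(type = "iv", j, stim, region)  Gaussian mass of criterion region
# The branch probability is the ordered product of its terms.
term_p <- function(par) list(type = "p", par = par)
term_q <- function(par) list(type = "q", par = par)
term_iv <- function(j, stim, region) list(type = "iv", j = j, stim = stim,
                                          region = region)

# CL split: high = L1, medium = (1-L1)L2, low = (1-L1)(1-L2)
cl_terms <- function(l1, l2) {
  list(high = list(term_p(l1)),
       medium = list(term_q(l1), term_p(l2)),
       low = list(term_q(l1), term_q(l2)))
}

build_branches <- function(family, variant, J, trees, categories) {
  has_cl <- variant %in% c("CL", "CL_RT")
  has_rt <- variant %in% c("RT", "CL_RT")
  cl_bins <- if (has_cl) c("high", "medium", "low") else NA_character_
  rt_bins <- if (has_rt) c("fast", "slow") else NA_character_

  out <- list()
  emit <- function(tree, state, response, cl, rt, terms) {
    cat_lab <- paste(c(response,
                       if (!is.na(cl)) cl,
                       if (!is.na(rt)) rt), collapse = ".")
    stopifnot(cat_lab %in% categories)
    out[[length(out) + 1L]] <<- list(tree = tree, state = state,
                                     category = cat_lab, terms = terms)
  }

  # expand a base branch (state-level) over CL and RT bins
  expand <- function(tree, state, response, base_terms, rt_class_stub) {
    cls <- if (has_cl) cl_bins else NA_character_
    for (cl in cls) {
      terms_cl <- base_terms
      if (has_cl) {
        ct <- cl_terms(paste0("L_", state, 1), paste0("L_", state, 2))[[cl]]
        terms_cl <- c(terms_cl, ct)
      }
      if (has_rt) {
        h <- if (has_cl) paste0("H_", rt_class_stub, "_", cl)
             else paste0("H_", rt_class_stub)
        emit(tree, state, response, cl, "fast", c(terms_cl, list(term_p(h))))
        emit(tree, state, response, cl, "slow", c(terms_cl, list(term_q(h))))
      } else {
        emit(tree, state, response, cl, NA_character_, terms_cl)
      }
    }
  }

  for (t in seq_len(nrow(trees))) {
    j <- trees$condition[t]
    stim <- trees$stimulus[t]
    g <- paste0("g", j)
    if (family == "2HT") {
      # high-threshold structure: no detect-new on old trees, no detect-old
      # on new trees
      if (stim == "old") {
        expand(t, "do", "old", list(term_p("do")), "do")
        expand(t, "go", "old", list(term_q("do"), term_p(g)), "go")
        expand(t, "gn", "new", list(term_q("do"), term_q(g)), "gn")
      } else {
        expand(t, "dn", "new", list(term_p("dn")), "dn")
        expand(t, "go", "old", list(term_q("dn"), term_p(g)), "go")
        expand(t, "gn", "new", list(term_q("dn"), term_q(g)), "gn")
      }
    } else {
      # SDT reparametrized as a multinomial model: each response (x CL)
      # category receives the Gaussian mass of one criterion interval.
      # K criteria split the familiarity axis into K + 1 regions, ordered
      # low -> high familiarity.
      if (has_cl) {
        # regions 1..6: new.high, new.medium, new.low, old.low, old.medium,
        # old.high (the old/new boundary is the middle criterion)
        region_of <- c(new.high = 1L, new.medium = 2L, new.low = 3L,
                       old.low = 4L, old.medium = 5L, old.high = 6L)
        for (resp in c("old", "new")) for (cl in cl_bins) {
          region <- region_of[[paste(resp, cl, sep = ".")]]
          base <- list(term_iv(j, stim, region))
          state <- if (stim == "old") {
            if (resp == "old") "hit" else "miss"
          } else if (resp == "old") "fa" else "cr"
          if (has_rt) {
            h <- paste0("H_", state, "_", cl)
            emit(t, state, resp, cl, "fast", c(base, list(term_p(h))))
            emit(t, state, resp, cl, "slow", c(base, list(term_q(h))))
          } else {
            emit(t, state, resp, cl, NA_character_, base)
          }
        }
      } else {
        for (resp in c("old", "new")) {
          region <- if (resp == "old") 2L else 1L
          base <- list(term_iv(j, stim, region))
          state <- if (stim == "old") {
            if (resp == "old") "hit" else "miss"
          } else if (resp == "old") "fa" else "cr"
          if (has_rt) {
            h <- paste0("H_", state)
            emit(t, state, resp, NA_character_, "fast",
                 c(base, list(term_p(h))))
            emit(t, state, resp, NA_character_, "slow",
                 c(base, list(term_q(h))))
          } else {
            emit(t, state, resp, NA_character_, NA_character_, base)
          }
        }
      }
    }
  }
  out
}

# Compile the declarative branch list into index vectors and incidence
# matrices so that probability evaluation is a handful of vectorized
# operations (important: the likelihood is evaluated thousands of times per
# fit).
compile_model <- function(model) {
  branches <- model$branches
  pn <- model$params$name
  J <- model$n_conditions
  K <- if (model$family == "SDT") {
    if (model$n_cl_bins > 1L) 5L else 1L
  } else 0L

  term_key <- function(tm) {
    if (tm$type == "iv") paste("iv", tm$j, tm$stim, tm$region, sep = ":")
    else paste(tm$type, tm$par, sep = ":")
  }
  keys <- character(0)
  defs <- list()
  branch_terms <- vector("list", length(branches))
  for (b in seq_along(branches)) {
    ids <- integer(0)
    for (tm in branches[[b]]$terms) {
      k <- term_key(tm)
      i <- match(k, keys)
      if (is.na(i)) {
        keys <- c(keys, k)
        defs[[length(defs) + 1L]] <- tm
        i <- length(keys)
      }
      ids <- c(ids, i)
    }
    branch_terms[[b]] <- ids
  }
  n_terms <- length(defs)
  type <- vapply(defs, `[[`, "", "type")
  par_idx <- ifelse(type %in% c("p", "q"),
                    match(vapply(defs, function(d)
                      if (d$type == "iv") "" else d$par, ""), pn),
                    NA_integer_)
  if (any(type != "iv" & is.na(par_idx)))
    stop("internal error: branch refers to unknown parameter")
  iv <- type == "iv"
  iv_j <- vapply(defs, function(d) if (d$type == "iv") d$j else NA_integer_, 1L)
  iv_stim <- vapply(defs, function(d)
    if (d$type == "iv") match(d$stim, c("old", "new")) else NA_integer_, 1L)
  iv_region <- vapply(defs, function(d)
    if (d$type == "iv") d$region else NA_integer_, 1L)

  M <- matrix(0, nrow = length(branches), ncol = n_terms)
  for (b in seq_along(branches)) M[b, branch_terms[[b]]] <-
    M[b, branch_terms[[b]]] + 1
  # cell index: (tree - 1) * n_categories + category position
  ncat <- length(model$categories)
  cell_of <- vapply(branches, function(br)
    (br$tree - 1L) * ncat + match(br$category, model$categories), 1L)
  n_cells <- nrow(model$trees) * ncat
  S <- matrix(0, nrow = n_cells, ncol = length(branches))
  S[cbind(cell_of, seq_along(branches))] <- 1

  list(n_terms = n_terms,
       which_p = which(type == "p"), p_par = par_idx[type == "p"],
       which_q = which(type == "q"), q_par = par_idx[type == "q"],
       which_iv = which(iv), iv_j = iv_j[iv], iv_stim = iv_stim[iv],
       iv_region = iv_region[iv],
       K = K,
       dprime_idx = match("dprime", pn),
       sigma_idx = match("sigma", pn),
       c_idx = match(paste0("c", seq_len(J)), pn),
       dc_idx = if (K == 5L) match(paste0("dc", 2:5), pn) else integer(0),
       M = M, S = S, n_cells = n_cells, ncat = ncat)
}

#' @export
print.mptdc_model <- function(x, ...) {
  cat(sprintf("MPT-DC model: %s %s\n", x$family, x$variant))
  cat(sprintf("  conditions: %d (target proportions %s)\n", x$n_conditions,
              paste(format(x$target_props), collapse = ", ")))
  cat(sprintf("  trees: %d   categories per tree: %d   branches: %d\n",
              nrow(x$trees), length(x$categories), length(x$branches)))
  cat(sprintf("  free parameters: %d\n", nrow(x$params)))
  cat("  ", paste(x$params$name, collapse = " "), "\n", sep = "")
  invisible(x)
}
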