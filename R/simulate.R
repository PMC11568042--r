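#' Define a simulation design
#'
#' Bundles a generating model, its parameter values and the sampling plan
#' for synthetic recognition data.  The default trial allocation emulates
#' the target-proportion block design: each condition is a block of
#' `block_size` test trials (default 100) of which a fraction equal to the
#' block's target proportion are old items, so e.g. the .35 block
#' contributes 35 old-item and 65 new-item trials.  Pass a single number
#' (or a vector, one per tree) as `trials_per_tree` to override, e.g.
#' `trials_per_tree = 100` for a balanced 100-trials-per-tree plan.
#'
#' @param model generating [mptdc_model()].
#' @param params named generating parameter vector (in bounds).
#' @param n_subjects number of simulated subjects.
#' @param trials_per_tree `NULL` for the block design, or trial totals per
#'   tree (recycled over the `2 J` trees).
#' @param block_size trials per condition block for the default design.
#' @param seed integer seed; one global seed spawns per-subject child
#'   seeds so each subject is independently reproducible.
#' @param rt_emission optional per-branch-class log-normal RT emission for
#'   trial-level simulation: a data frame with columns `class`, `meanlog`,
#'   `sdlog` (classes as in the matching RT variant's `H_*` parameter
#'   names, without the `H_` prefix).
#' @param cl_emission optional per-state confidence emission for
#'   trial-level simulation from a classic model: data frame with columns
#'   `class`, `high`, `medium`, `low` (rows summing to 1).
#' @return an object of class `"mptdc_design"`.
#' @export
simulation_design <- function(model, params, n_subjects = 1L,
                              trials_per_tree = NULL, block_size = 100L,
                              seed = NULL, rt_emission = NULL,
                              cl_emission = NULL) {
  stopifnot(inherits(model, "mptdc_model"))
  theta <- validate_params(model, params)
  if (is.null(trials_per_tree)) {
    tp <- model$trees$target_prop
    trials_per_tree <- round(block_size *
                               ifelse(model$trees$stimulus == "old",
                                      tp, 1 - tp))
  } else {
    trials_per_tree <- rep_len(trials_per_tree, nrow(model$trees))
  }
  if (any(trials_per_tree < 1))
    stop("every tree needs at least one trial", call. = FALSE)
  if (!is.null(rt_emission)) {
    req <- c("class", "meanlog", "sdlog")
    if (!all(req %in% names(rt_emission)))
      stop("`rt_emission` needs columns class, meanlog, sdlog",
           call. = FALSE)
  }
  structure(list(model = model, params = theta,
                 n_subjects = as.integer(n_subjects),
                 trials_per_tree = as.integer(trials_per_tree),
                 seed = seed, rt_emission = rt_emission,
                 cl_emission = cl_emission),
            class = "mptdc_design")
}

subject_seeds <- function(design) {
  if (is.null(design$seed)) return(rep(list(NULL), design$n_subjects))
  as.list(local_seed(design$seed,
                     sample.int(.Machine$integer.max - 1L,
                                design$n_subjects)))
}

#' Simulate multinomial count tables
#'
#' Draws, for each subject and tree, category counts from a multinomial
#' with the model's category probabilities and the design's per-tree
#' trial totals.
#'
#' @param design an [simulation_design()].
#' @return a list of count matrices (trees x categories), one per subject,
#'   named `S1`, `S2`, ...
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "mptdc_design"))
  p <- prob_matrix(design$model, design$params)
  seeds <- subject_seeds(design)
  out <- lapply(seq_len(design$n_subjects), function(i)
    local_seed(seeds[[i]], draw_tree_counts(p, design$trials_per_tree)))
  names(out) <- paste0("S", seq_len(design$n_subjects))
  out
}

#' Simulate trial-level records
#'
#' Samples, per trial, a latent branch of the generating model by its
#' probability, emits the branch's response (and confidence when the
#' model carries CL bins, or from `cl_emission` for a classic model), and
#' draws the RT from the branch class's log-normal emission.  The
#' generating model must not itself contain RT bins (RTs are continuous
#' here; they become bins only through [aggregate_counts()]).
#'
#' @param design an [simulation_design()] with an `rt_emission` spec.
#' @return a data frame of trial records (`subject`, `condition`,
#'   `stimulus`, `response`, `confidence` if available, `rt`).
#' @export
simulate_trials <- function(design) {
  stopifnot(inherits(design, "mptdc_design"))
  model <- design$model
  if (model$n_rt_bins > 1L)
    stop("trial-level simulation requires a model without RT bins; ",
         "use the classic or CL variant with an `rt_emission` spec",
         call. = FALSE)
  if (is.null(design$rt_emission))
    stop("`rt_emission` is required for trial-level simulation",
         call. = FALSE)
  em <- design$rt_emission
  has_cl <- model$n_cl_bins > 1L
  cl_em <- design$cl_emission
  if (!has_cl && !is.null(cl_em) &&
      !all(c("class", "high", "medium", "low") %in% names(cl_em)))
    stop("`cl_emission` needs columns class, high, medium, low",
         call. = FALSE)

  # branch table with probabilities and class labels
  br <- model$branches
  theta <- design$params
  cp <- model$compiled
  v <- numeric(cp$n_terms)
  v[cp$which_p] <- theta[cp$p_par]
  v[cp$which_q] <- 1 - theta[cp$q_par]
  if (length(cp$which_iv)) {
    masses <- interval_masses(model, theta)
    v[cp$which_iv] <- masses[cbind(cp$iv_j, cp$iv_stim, cp$iv_region)]
  }
  bprob <- exp(as.vector(cp$M %*% log(pmax(v, 1e-300))))
  b_tree <- vapply(br, `[[`, 1L, "tree")
  b_state <- vapply(br, `[[`, "", "state")
  b_cat <- vapply(br, `[[`, "", "category")
  b_resp <- sub("\\..*$", "", b_cat)
  b_cl <- if (has_cl) sub("^[a-z]+\\.", "", b_cat) else NA_character_
  b_class <- if (has_cl) paste(b_state, b_cl, sep = "_") else b_state
  miss_cls <- setdiff(unique(b_class), em$class)
  if (length(miss_cls))
    stop("`rt_emission` lacks class(es): ",
         paste(miss_cls, collapse = ", "), call. = FALSE)
  em_row <- match(b_class, em$class)

  seeds <- subject_seeds(design)
  out <- vector("list", design$n_subjects)
  for (i in seq_len(design$n_subjects)) {
    out[[i]] <- local_seed(seeds[[i]], {
      rows <- list()
      for (t in seq_len(nrow(model$trees))) {
        n_t <- design$trials_per_tree[t]
        if (n_t == 0L) next
        idx <- which(b_tree == t)
        pick <- idx[sample.int(length(idx), n_t, replace = TRUE,
                               prob = bprob[idx])]
        conf <- if (has_cl) b_cl[pick]
          else if (!is.null(cl_em)) {
            vapply(pick, function(k) {
              r <- match(b_state[k], cl_em$class)
              sample(c("high", "medium", "low"), 1L,
                     prob = as.numeric(cl_em[r, c("high", "medium",
                                                  "low")]))
            }, "")
          } else NA_character_
        rt <- stats::rlnorm(n_t, em$meanlog[em_row[pick]],
                            em$sdlog[em_row[pick]])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = paste0("S", i),
          condition = model$trees$target_prop[t],
          stimulus = model$trees$stimulus[t],
          response = b_resp[pick],
          confidence = conf,
          rt = rt, stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    })
  }
  res <- do.call(rbind, out)
  if (all(is.na(res$confidence))) res$confidence <- NULL
  rownames(res) <- NULL
  res
}

#' Model-recovery study
#'
#' For each generating design, simulates subjects, fits every candidate
#' model to each subject's counts, selects the best candidate by AICc (or
#' AIC), and reports the proportion of subjects for which the selected
#' candidate belongs to the generating model's family.
#'
#' @param designs a named list of [simulation_design()]s (the generators).
#' @param candidates a list of [mptdc_model()]s fitted to every simulated
#'   dataset (typically the SDT/2HT pair of one variant).
#' @param criterion `"AICc"` or `"AIC"`.
#' @param n_restarts optimizer starts per fit.
#' @param seed seed for the whole study; per-design seeds are derived from
#'   it unless a design carries its own.
#' @return an object of class `"mptdc_recovery"`: a data frame with one
#'   row per design (`design`, `true_family`, `n_subjects`, `n_failed`,
#'   `prop_true`) plus a `selections` attribute holding the per-subject
#'   winner tables.
#' @export
recovery_study <- function(designs, candidates, criterion = c("AICc", "AIC"),
                           n_restarts = 3L, seed = NULL) {
  criterion <- match.arg(criterion)
  if (!length(designs)) stop("need at least one design", call. = FALSE)
  if (is.null(names(designs)))
    names(designs) <- paste0("design", seq_along(designs))
  fam <- vapply(candidates, function(m) m$family, "")
  design_seeds <- if (is.null(seed)) rep(list(NULL), length(designs))
    else as.list(local_seed(seed, sample.int(.Machine$integer.max - 1L,
                                             length(designs))))

  rows <- list()
  selections <- list()
  for (d in seq_along(designs)) {
    design <- designs[[d]]
    if (is.null(design$seed)) design$seed <- design_seeds[[d]]
    counts <- simulate_counts(design)
    winners <- rep(NA_character_, length(counts))
    failed <- 0L
    for (i in seq_along(counts)) {
      fit_seed <- if (is.null(design$seed)) NULL
                  else (design$seed %% 1000000000L) + i
      crit <- vapply(candidates, function(mod) {
        f <- suppressWarnings(tryCatch(
          fit_mptdc(mod, counts[[i]], n_restarts = n_restarts,
                    seed = fit_seed, compute_se = FALSE),
          error = function(e) NULL))
        if (is.null(f) || !f$converged) return(NA_real_)
        if (criterion == "AICc") f$aicc else f$aic
      }, 0)
      if (anyNA(crit)) { failed <- failed + 1L; next }
      winners[i] <- fam[which.min(crit)]
    }
    ok <- !is.na(winners)
    rows[[d]] <- data.frame(
      design = names(designs)[d],
      true_family = design$model$family,
      n_subjects = length(counts),
      n_failed = failed,
      prop_true = mean(winners[ok] == design$model$family),
      stringsAsFactors = FALSE)
    selections[[names(designs)[d]]] <- winners
  }
  out <- do.call(rbind, rows)
  attr(out, "selections") <- selections
  class(out) <- c("mptdc_recovery", "data.frame")
  out
}

#' Plausible generating parameters for each variant
#'
#' Mid-range generating values for simulation studies: moderate detection
#' (`do = dn = .6`) with guessing tracking the target proportion
#' (`g = .3/.5/.7`); SDT sensitivity `dprime = 1.5` with old-item SD
#' `sigma = 1.3`; confidence mass favoring high confidence in detection
#' states and flatter confidence for guessing; detection/guessing fast-bin
#' probabilities around .7/.4 (detection responses are faster).
#'
#' @param model an [mptdc_model()].
#' @return a named in-bounds parameter vector for `model`.
#' @export
reference_params <- function(model) {
  stopifnot(inherits(model, "mptdc_model"))
  pt <- model$params
  J <- model$n_conditions
  val <- numeric(nrow(pt))
  names(val) <- pt$name
  g_vals <- if (J == 3L) c(.3, .5, .7) else seq(.3, .7, length.out = J)
  for (k in seq_len(nrow(pt))) {
    nm <- pt$name[k]
    val[k] <-
      if (nm %in% c("do", "dn")) 0.6
      else if (grepl("^g[0-9]+$", nm)) g_vals[pt$condition[k]]
      else if (nm == "dprime") 1.5
      else if (nm == "sigma") 1.3
      else if (grepl("^c[0-9]+$", nm)) {
        # criteria shift down as target proportion rises
        base <- if (model$n_cl_bins > 1L) -1.6 else 0.6
        base - 0.35 * (pt$condition[k] - 1L)
      }
      else if (grepl("^dc", nm)) 0.55
      else if (grepl("^L_d[on]1$", nm)) 0.7    # detection: mostly high CL
      else if (grepl("^L_d[on]2$", nm)) 0.6
      else if (grepl("^L_g[on]1$", nm)) 0.35   # guessing: flatter CL
      else if (grepl("^L_g[on]2$", nm)) 0.5
      else if (grepl("^H_(do|dn)", nm)) 0.7    # detection is fast
      else if (grepl("^H_(go|gn)", nm)) 0.4
      else if (grepl("^H_(hit|cr)", nm)) 0.65  # correct responses faster
      else if (grepl("^H_(miss|fa)", nm)) 0.45
      else 0.5
  }
  val
}
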