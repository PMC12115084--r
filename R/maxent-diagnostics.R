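#' Percent contribution of each variable
#'
#' Credits every accepted coordinate-descent update's objective gain to
#' the variable owning the updated feature, accumulates the (positive)
#' credits per variable, and normalizes them to sum to 100.
#'
#' @param model a [fit_maxent()] model.
#' @return data.frame with `variable` and `percent`, descending; percents
#'   sum to 100 (all-zero traces return 0 for every variable).
#' @export
percent_contribution <- function(model) {
  vars <- vapply(model$defs, `[[`, character(1), "variable")
  credit <- stats::setNames(numeric(length(model$variables)),
                            model$variables)
  if (nrow(model$trace) > 0L) {
    per_feat <- tapply(model$trace$gain, vars[model$trace$feature], sum)
    credit[names(per_feat)] <- per_feat
  }
  total <- sum(credit)
  pct <- if (total > 0) 100 * credit / total else credit
  out <- data.frame(variable = names(pct), percent = unname(pct))
  out <- out[order(-out$percent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutation importance of each variable
#'
#' For each variable, its values are permuted across the evaluation
#' points (presences and background pooled), the model is re-scored, and
#' the drop in AUC is recorded. Drops (clamped at 0) are normalized to
#' sum to 100.
#'
#' @param model a [fit_maxent()] model.
#' @param presences,background evaluation points (environmental
#'   data.frames, or coordinates plus `stack`).
#' @param stack optional [env_stack()].
#' @param seed RNG seed for the permutation.
#' @return data.frame with `variable`, `auc_drop`, `percent` (sums to
#'   100), descending.
#' @export
permutation_importance <- function(model, presences, background,
                                   stack = NULL, seed = 42L) {
  pe <- eval_env(model, presences, stack)
  be <- eval_env(model, background, stack)
  m <- nrow(pe)
  env <- rbind(pe, be)
  base <- auc_scores_env(model, env, m)
  drops <- with_seed(seed, vapply(model$variables, function(v) {
    perm <- env
    perm[[v]] <- perm[[v]][sample.int(nrow(perm))]
    base - auc_scores_env(model, perm, m)
  }, numeric(1)))
  drops <- pmax(drops, 0)
  pct <- if (sum(drops) > 0) 100 * drops / sum(drops) else drops
  out <- data.frame(variable = names(drops), auc_drop = unname(drops),
                    percent = unname(pct))
  out <- out[order(-out$percent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

auc_scores_env <- function(model, env, n_presence) {
  s <- predict_env(model, env, "raw")
  auc_scores(s[seq_len(n_presence)], s[-seq_len(n_presence)])
}

#' Jackknife training gains per variable
#'
#' Regularized training gain (`log(n_background)` minus the optimized
#' objective) of (i) the model using only each variable and (ii) the
#' model excluding it, alongside the full-model gain.
#'
#' @inheritParams permutation_importance
#' @param features,n_hinge_knots,reg_multiplier passed to the refits
#'   (defaults mirror the fitted model).
#' @return data.frame with `variable`, `gain_only`, `gain_without`, and
#'   attribute `full_gain`.
#' @export
jackknife_gains <- function(model, presences, background, stack = NULL,
                            features = c("linear", "quadratic", "hinge"),
                            n_hinge_knots = 5L, reg_multiplier = NULL) {
  if (is.null(reg_multiplier)) reg_multiplier <- model$reg_multiplier
  pe <- eval_env(model, presences, stack)
  be <- eval_env(model, background, stack)
  refit_gain <- function(vars) {
    m <- fit_maxent(pe[vars], be[vars],
                    variables = vars, features = features,
                    n_hinge_knots = n_hinge_knots,
                    reg_multiplier = reg_multiplier,
                    categorical = intersect(model$categorical, vars))
    m$gain
  }
  vars <- model$variables
  out <- data.frame(
    variable = vars,
    gain_only = vapply(vars, refit_gain, numeric(1)),
    gain_without = if (length(vars) > 1L) {
      vapply(vars, function(v) refit_gain(setdiff(vars, v)), numeric(1))
    } else {
      rep(0, length(vars))
    }
  )
  rownames(out) <- NULL
  attr(out, "full_gain") <- refit_gain(vars)
  out
}

#' Response curve of one variable
#'
#' Sweeps the variable across its background range (categorical: its
#' levels) while holding all other variables at their background mean
#' (categorical: mode), and evaluates the model's suitability.
#'
#' @param model a [fit_maxent()] model.
#' @param variable variable name.
#' @param n_points sweep resolution for continuous variables.
#' @param transform output transform (defaults to the model's).
#' @return data.frame with columns `value` and `suitability`.
#' @export
response_curve <- function(model, variable, n_points = 100L,
                           transform = NULL) {
  if (!variable %in% model$variables) {
    stop("variable '", variable, "' is not in the model", call. = FALSE)
  }
  if (is.null(transform)) transform <- model$transform
  sm <- model$bg_summary
  xs <- if (sm[[variable]]$categorical) {
    sm[[variable]]$levels
  } else {
    seq(sm[[variable]]$min, sm[[variable]]$max, length.out = n_points)
  }
  env <- as.data.frame(lapply(sm, function(s) {
    rep(if (s$categorical) s$mode else s$mean, length(xs))
  }))
  names(env) <- model$variables
  env[[variable]] <- xs
  data.frame(value = xs,
             suitability = predict_env(model, env, transform))
}

#' Tune regularization and feature classes
#'
#' Grid search over regularization multipliers and feature-class sets,
#' scored either by the sample-size-corrected information criterion on
#' the presence likelihood (`"aicc"`, default; the likelihood is taken
#' under the background-normalized Gibbs density and `k` counts non-zero
#' weights) or by test AUC on a held-out presence split (`"auc"`).
#'
#' @param presences,background environmental data.frames (or coordinates
#'   plus `stack`).
#' @param stack optional [env_stack()].
#' @param reg_multipliers candidate regularization multipliers.
#' @param feature_sets list of feature-class character vectors.
#' @param criterion `"aicc"` or `"auc"`.
#' @param split_ratio train fraction for the `"auc"` criterion.
#' @param n_hinge_knots hinge knots for sets containing `"hinge"`.
#' @param seed RNG seed (split).
#' @return list with `best` (the winning settings and refitted model) and
#'   `results` (one row per grid point: reg_multiplier, features, k,
#'   score).
#' @export
tune_model <- function(presences, background, stack = NULL,
                       reg_multipliers = c(0.5, 1, 2, 4),
                       feature_sets = list(c("linear", "quadratic"),
                                           c("linear", "quadratic",
                                             "hinge")),
                       criterion = c("aicc", "auc"), split_ratio = 0.75,
                       n_hinge_knots = 5L, seed = 42L) {
  criterion <- match.arg(criterion)
  pe <- if (!is.null(stack)) {
    env <- extract_env(stack, cells = cell_index(stack, presences$x,
                                                 presences$y))
    env[stats::complete.cases(env), , drop = FALSE]
  } else {
    presences
  }
  be <- if (!is.null(stack) && !all(names(pe) %in% names(background))) {
    env <- extract_env(stack, cells = background$cell)
    env[stats::complete.cases(env), , drop = FALSE]
  } else {
    background
  }
  rows <- list()
  best <- NULL
  for (fs in feature_sets) {
    for (reg in reg_multipliers) {
      if (criterion == "aicc") {
        mdl <- fit_maxent(pe, be, features = fs,
                          n_hinge_knots = n_hinge_knots,
                          reg_multiplier = reg)
        k <- sum(abs(mdl$lambda) > 0)
        m <- mdl$n_presence
        ll <- sum(log(predict_env(mdl, pe, "raw")))
        score <- if (m - k - 1 <= 0) Inf else
          2 * k - 2 * ll + 2 * k * (k + 1) / (m - k - 1)
        better <- is.null(best) || score < best$score
      } else {
        sp <- split_train_test(pe, ratio = split_ratio, seed = seed)
        mdl <- fit_maxent(sp$train, be, features = fs,
                          n_hinge_knots = n_hinge_knots,
                          reg_multiplier = reg)
        k <- sum(abs(mdl$lambda) > 0)
        score <- model_auc(mdl, sp$test, be)
        better <- is.null(best) || score > best$score
      }
      rows[[length(rows) + 1L]] <-
        data.frame(reg_multiplier = reg,
                   features = paste(fs, collapse = "+"),
                   k = k, score = score)
      if (better) {
        best <- list(reg_multiplier = reg, features = fs, score = score,
                     model = mdl)
      }
    }
  }
  list(best = best, results = do.call(rbind, rows))
}
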