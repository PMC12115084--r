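#' Maximum-entropy species distribution model
#'
#' Fits the presence-background maximum-entropy (Gibbs) model: the
#' predicted distribution over landscape cells is
#' \eqn{q_\lambda(i) \propto \exp(\sum_j \lambda_j f_j(i))}, where the
#' \eqn{f_j} are environmental features scaled to `[0, 1]` over the
#' background sample. The weights minimize the convex L1-regularized
#' negative log-likelihood of the presence sample under \eqn{q_\lambda},
#' \deqn{L(\lambda) = -\overline{\eta}_{pres} + \log \sum_{bg} e^{\eta}
#'   + \sum_j \beta_j |\lambda_j|,}
#' by cyclic coordinate descent with a one-dimensional Newton step,
#' soft-thresholding, and backtracking (the objective is non-increasing
#' across updates). Per-feature penalties \eqn{\beta_j} scale with the
#' feature's background SD and shrink with the square root of the
#' presence count; `reg_multiplier` scales them globally.
#'
#' @param presences data.frame of presence points: either coordinates
#'   (`x`, `y`) when `stack` is supplied, or environmental values per
#'   point (SWD style) when it is not.
#' @param background background sample in the same format as `presences`,
#'   or `NULL` to draw `n_background` random cells from `stack`.
#' @param stack an [env_stack()]; optional when both `presences` and
#'   `background` carry environmental columns.
#' @param variables layer/column names to use (default: all).
#' @param features feature classes for continuous variables: subset of
#'   `"linear"`, `"quadratic"`, `"hinge"`, `"product"`.
#' @param n_hinge_knots hinge knots per variable (quantile-placed).
#' @param reg_multiplier global regularization multiplier (> 0).
#' @param n_background background sample size when sampling from `stack`.
#' @param dedupe collapse presences to one per grid cell (default `TRUE`
#'   when a `stack` is given).
#' @param transform default output transform: `"cloglog"` (default),
#'   `"logistic"`, or `"raw"`.
#' @param tol convergence tolerance on the per-cycle objective
#'   improvement.
#' @param max_cycles cap on full coordinate-descent passes; failure to
#'   converge is an error carrying the final objective gap.
#' @param seed seed for the background draw (recorded in the model).
#' @param categorical variable names to treat as categorical when fitting
#'   from SWD-style data (taken from the `stack` otherwise).
#' @return an object of class `maxent_model`; see Details. Key elements:
#'   `lambda` (named weights), `defs` (feature definitions and scaling
#'   bounds), `beta`, `log_z` and `entropy` over the training background,
#'   `trace` (per-update objective gains, for percent contribution),
#'   `gain` (regularized training gain), `n_presence`, `n_background`.
#' @seealso [predict.maxent_model()], [model_auc()], [jackknife_gains()],
#'   [percent_contribution()], [permutation_importance()],
#'   [response_curve()], [tune_model()]
#' @export
fit_maxent <- function(presences, background = NULL, stack = NULL,
                       variables = NULL,
                       features = c("linear", "quadratic", "hinge"),
                       n_hinge_knots = 5L, reg_multiplier = 1,
                       n_background = 10000L, dedupe = !is.null(stack),
                       transform = c("cloglog", "logistic", "raw"),
                       tol = 1e-7, max_cycles = 2000L, seed = 42L,
                       categorical = NULL) {
  transform <- match.arg(transform)
  prep <- prepare_swd(presences, background, stack, variables,
                      n_background, dedupe, seed,
                      categorical = categorical)
  pres_env <- prep$pres_env
  bg_env <- prep$bg_env
  if (nrow(pres_env) < 5L) {
    stop("need at least 5 presence points, got ", nrow(pres_env),
         call. = FALSE)
  }
  categorical <- intersect(prep$categorical, names(bg_env))
  defs <- build_feature_defs(bg_env,
                             classes = setdiff(features, "product"),
                             categorical = categorical,
                             n_hinge_knots = n_hinge_knots,
                             products = "product" %in% features)
  Fp <- feature_matrix(defs, pres_env)
  Fb <- feature_matrix(defs, bg_env)
  beta <- feature_penalties(defs, Fb, nrow(Fp), reg_multiplier)
  core <- maxent_core(Fp, Fb, beta, tol = tol, max_cycles = max_cycles)
  q <- exp(core$eta_b - core$log_z)
  entropy <- -sum(q * log(pmax(q, 1e-300)))
  structure(
    list(lambda = stats::setNames(core$lambda,
                                  vapply(defs, `[[`, character(1), "name")),
         defs = defs, beta = beta, reg_multiplier = reg_multiplier,
         log_z = core$log_z, entropy = entropy, transform = transform,
         variables = names(bg_env), categorical = categorical,
         trace = core$trace, objective = core$objective,
         gain = log(nrow(Fb)) - core$objective,
         converged = core$converged, n_cycles = core$n_cycles,
         n_presence = nrow(Fp), n_background = nrow(Fb),
         bg_summary = background_summary(bg_env, categorical),
         seed = seed),
    class = "maxent_model"
  )
}

# Resolve presence/background inputs into environmental data.frames.
prepare_swd <- function(presences, background, stack, variables,
                        n_background, dedupe, seed, categorical = NULL) {
  if (is.null(categorical)) {
    categorical <- if (!is.null(stack)) stack$categorical else character()
  }
  if (!is.null(stack)) {
    if (is.null(variables)) variables <- names(stack$layers)
    if (is.null(background)) {
      background <- sample_background(stack, n = n_background, seed = seed)
    }
    get_env <- function(pts) {
      if (all(variables %in% names(pts))) return(pts[variables])
      cells <- if ("cell" %in% names(pts)) pts$cell else
        cell_index(stack, pts$x, pts$y)
      if (dedupe) cells <- unique(cells)
      cells <- cells[!is.na(cells)]
      env <- extract_env(stack, cells = cells, layers = variables)
      env[stats::complete.cases(env), , drop = FALSE]
    }
    pres_env <- get_env(presences)
    bg_env <- if (all(variables %in% names(background))) {
      background[variables]
    } else {
      cells <- if ("cell" %in% names(background)) background$cell else
        cell_index(stack, background$x, background$y)
      env <- extract_env(stack, cells = cells[!is.na(cells)],
                         layers = variables)
      env[stats::complete.cases(env), , drop = FALSE]
    }
  } else {
    if (is.null(background)) {
      stop("supply either a raster `stack` or an explicit background",
           call. = FALSE)
    }
    if (is.null(variables)) {
      variables <- setdiff(names(presences), c("x", "y", "species", "cell"))
    }
    pres_env <- presences[variables]
    bg_env <- background[variables]
  }
  list(pres_env = as.data.frame(pres_env), bg_env = as.data.frame(bg_env),
       categorical = categorical)
}

background_summary <- function(bg_env, categorical) {
  lapply(stats::setNames(names(bg_env), names(bg_env)), function(v) {
    x <- bg_env[[v]]
    if (v %in% categorical) {
      tab <- table(x)
      list(mode = as.numeric(names(tab)[which.max(tab)]),
           levels = as.numeric(names(tab)), categorical = TRUE)
    } else {
      list(mean = mean(x), min = min(x), max = max(x), categorical = FALSE)
    }
  })
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Coordinate-descent solver for the L1-regularized maxent objective.
maxent_core <- function(Fp, Fb, beta, tol = 1e-7, max_cycles = 2000L) {
  if (!all(is.finite(Fp)) || !all(is.finite(Fb))) {
    stop("non-finite feature values", call. = FALSE)
  }
  beta <- unname(beta)
  J <- ncol(Fb)
  n <- nrow(Fb)
  lambda <- numeric(J)
  eta_b <- numeric(n)
  log_z <- log(n)
  mean_fp <- unname(colMeans(Fp))
  pen <- 0
  obj <- log_z  # mean presence eta is 0 at lambda = 0
  trace <- list()
  converged <- FALSE
  cycle <- 0L
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  while (cycle < max_cycles) {
    cycle <- cycle + 1L
    obj_start <- obj
    for (j in seq_len(J)) {
      q <- exp(eta_b - log_z)
      fj <- Fb[, j]
      e1 <- sum(q * fj)
      h <- max(sum(q * fj^2) - e1^2, 1e-10)
      g <- e1 - mean_fp[j]
      target <- soft(lambda[j] - g / h, beta[j] / h)
      d <- target - lambda[j]
      if (abs(d) < 1e-12) next
      step <- 1
      accepted <- FALSE
      for (bt in 1:30) {
        cand <- lambda[j] + step * d
        new_eta <- eta_b + (step * d) * fj
        new_log_z <- log_sum_exp(new_eta)
        new_pen <- pen - beta[j] * abs(lambda[j]) + beta[j] * abs(cand)
        new_obj <- new_log_z - sum(mean_fp * lambda) -
          mean_fp[j] * (cand - lambda[j]) + new_pen
        if (new_obj <= obj - 1e-14) {
          gain <- obj - new_obj
          lambda[j] <- cand
          eta_b <- new_eta
          log_z <- new_log_z
          pen <- new_pen
          obj <- new_obj
          trace[[length(trace) + 1L]] <- c(j = j, gain = gain)
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
    }
    if (obj_start - obj < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("maxent solver did not converge in ", max_cycles,
         " cycles (last-cycle objective gap ",
         format(obj_start - obj, digits = 4), " > tol ", tol, ")",
         call. = FALSE)
  }
  tr <- if (length(trace)) {
    m <- do.call(rbind, trace)
    data.frame(feature = as.integer(m[, "j"]), gain = m[, "gain"])
  } else {
    data.frame(feature = integer(), gain = numeric())
  }
  list(lambda = lambda, eta_b = eta_b, log_z = log_z,
       objective = obj, trace = tr, converged = converged,
       n_cycles = cycle)
}

#' @export
print.maxent_model <- function(x, ...) {
  nz <- sum(abs(x$lambda) > 0)
  cat("<maxent_model> ", length(x$lambda), " features (", nz,
      " active), ", x$n_presence, " presences / ", x$n_background,
      " background\n", sep = "")
  cat(sprintf("  reg multiplier %.3g, training gain %.4f, %d cycles\n",
              x$reg_multiplier, x$gain, x$n_cycles))
  cat("  output transform:", x$transform, "\n")
  invisible(x)
}

#' Predict suitability from a fitted maxent model
#'
#' The raw output is the Gibbs density relative to the training
#' background, \eqn{e^{\eta - \log Z}} (raw values over the training
#' background sum to 1). The cloglog transform
#' \eqn{1 - \exp(-e^{H} \cdot raw)} (with \eqn{H} the entropy of the
#' background distribution) maps it to a `[0, 1]` suitability index; the
#' logistic transform is \eqn{e^{H} raw / (1 + e^{H} raw)}.
#'
#' @param object a [fit_maxent()] model.
#' @param newdata an [env_stack()] (returns a suitability matrix with
#'   nodata preserved) or a data.frame of environmental values (returns a
#'   vector).
#' @param transform output scale; defaults to the model's setting.
#' @param clamp clamp features outside the training-background range to
#'   its bounds (default `TRUE`), so predictions plateau rather than
#'   extrapolate under novel conditions.
#' @param ... unused.
#' @return numeric matrix (for a stack) or vector of suitabilities.
#' @export
predict.maxent_model <- function(object, newdata,
                                 transform = NULL, clamp = TRUE, ...) {
  if (is.null(transform)) transform <- object$transform
  transform <- match.arg(transform, c("cloglog", "logistic", "raw"))
  if (inherits(newdata, "env_stack")) {
    cells <- valid_cells(newdata)
    env <- extract_env(newdata, cells = cells,
                       layers = object$variables)
    ok <- stats::complete.cases(env)
    vals <- rep(NA_real_, length(cells))
    vals[ok] <- predict_env(object, env[ok, , drop = FALSE], transform,
                            clamp = clamp)
    out <- matrix(NA_real_, newdata$n_rows, newdata$n_cols)
    out[cells] <- vals
    return(out)
  }
  predict_env(object, newdata, transform, clamp = clamp)
}

predict_env <- function(model, env, transform, clamp = TRUE) {
  FF <- feature_matrix(model$defs, env, clamp = clamp)
  eta <- drop(FF %*% unname(model$lambda))
  raw <- exp(eta - model$log_z)
  switch(transform,
         raw = raw,
         cloglog = 1 - exp(-exp(model$entropy) * raw),
         logistic = {
           s <- exp(model$entropy) * raw
           s / (1 + s)
         })
}

#' Random background sample over valid cells
#'
#' Uniform without replacement over non-nodata cells; when `n` is at
#' least the number of valid cells, all of them are returned.
#'
#' @param stack an [env_stack()].
#' @param n sample size.
#' @param seed RNG seed (local to this call).
#' @return data.frame with `cell`, `x`, `y`.
#' @export
sample_background <- function(stack, n = 10000L, seed = 42L) {
  vc <- valid_cells(stack)
  cells <- if (n >= length(vc)) vc else
    with_seed(seed, sample(vc, n))
  cell_coordinates(stack, sort(cells))
}

#' Train/test split of presence points
#'
#' `round(n * ratio)` points (at least 1, at most n - 1 when n >= 2) go to
#' the training set; the rest are the test set. Disjoint and exhaustive.
#'
#' @param points data.frame of points.
#' @param ratio training fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_train_test <- function(points, ratio = 0.75, seed = 42L) {
  stopifnot(ratio > 0, ratio < 1)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points to split", call. = FALSE)
  n_train <- min(max(round(n * ratio), 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = points[sort(idx), , drop = FALSE],
       test = points[sort(setdiff(seq_len(n), idx)), , drop = FALSE])
}

#' Rank-based AUC of presence vs background scores
#'
#' The Mann-Whitney statistic: the probability that a random presence
#' outranks a random background point, ties counted one half.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_scores <- function(presence_scores, background_scores) {
  m <- length(presence_scores)
  n <- length(background_scores)
  stopifnot(m > 0, n > 0)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' AUC of a fitted model on evaluation points
#'
#' @param model a [fit_maxent()] model.
#' @param presences,background evaluation points (coordinates with
#'   `stack`, or environmental data.frames).
#' @param stack optional [env_stack()] to extract values from.
#' @return AUC in `[0, 1]`.
#' @export
model_auc <- function(model, presences, background, stack = NULL) {
  pe <- eval_env(model, presences, stack)
  be <- eval_env(model, background, stack)
  auc_scores(predict_env(model, pe, "raw"), predict_env(model, be, "raw"))
}

eval_env <- function(model, pts, stack) {
  if (all(model$variables %in% names(pts))) {
    return(as.data.frame(pts[model$variables]))
  }
  if (is.null(stack)) {
    stop("points lack environmental columns and no `stack` was given",
         call. = FALSE)
  }
  cells <- if ("cell" %in% names(pts)) pts$cell else
    cell_index(stack, pts$x, pts$y)
  env <- extract_env(stack, cells = cells[!is.na(cells)],
                     layers = model$variables)
  env[stats::complete.cases(env), , drop = FALSE]
}

#' Spearman collinearity screen over environmental layers
#'
#' Computes pairwise Spearman correlations of the continuous layers over
#' the union of presence and background locations. For every pair with
#' \eqn{|\rho|} above the threshold, the member with the lower
#' single-variable jackknife training gain is dropped (pairs handled in
#' descending \eqn{|\rho|} order). Constant layers are excluded up front.
#'
#' @param stack an [env_stack()].
#' @param presences presence points (`x`, `y` or `cell`).
#' @param background background sample (default: drawn from `stack`).
#' @param threshold absolute Spearman cutoff (default 0.75).
#' @param n_background background size if sampling.
#' @param seed RNG seed for the background draw.
#' @return list with `retained` (layer names, categorical layers always
#'   retained), `dropped` (data.frame: variable, partner, rho),
#'   `constant` (excluded constant layers), and `rho` (correlation
#'   matrix).
#' @export
spearman_screen <- function(stack, presences, background = NULL,
                            threshold = 0.75, n_background = 2000L,
                            seed = 42L) {
  if (is.null(background)) {
    background <- sample_background(stack, n = n_background, seed = seed)
  }
  vars <- names(stack$layers)
  cont <- setdiff(vars, stack$categorical)
  pres_env <- extract_env(stack,
                          cells = cell_index(stack, presences$x,
                                             presences$y))
  pres_env <- pres_env[stats::complete.cases(pres_env), , drop = FALSE]
  bg_env <- extract_env(stack, cells = background$cell)
  bg_env <- bg_env[stats::complete.cases(bg_env), , drop = FALSE]
  env <- rbind(pres_env, bg_env)
  if (nrow(env) < 3L) stop("need at least 3 sample locations", call. = FALSE)
  const <- cont[vapply(env[cont], function(x) stats::sd(x) == 0, logical(1))]
  if (length(const) > 0L) {
    warning("constant layer(s) excluded from screening: ",
            paste(const, collapse = ", "), call. = FALSE)
  }
  cont <- setdiff(cont, const)
  rho <- stats::cor(env[cont], method = "spearman")
  gains <- NULL  # computed lazily, only if some pair exceeds the threshold
  keep <- cont
  dropped <- list()
  repeat {
    sub <- abs(rho[keep, keep, drop = FALSE])
    diag(sub) <- 0
    mx <- max(sub)
    if (mx <= threshold || length(keep) < 2L) break
    if (is.null(gains)) {
      gains <- single_variable_gains(env[cont], nrow(pres_env))
    }
    idx <- which(sub == mx, arr.ind = TRUE)[1, ]
    pair <- keep[idx]
    loser <- pair[which.min(gains[pair])]
    dropped[[length(dropped) + 1L]] <-
      data.frame(variable = loser, partner = setdiff(pair, loser)[1],
                 rho = rho[pair[1], pair[2]])
    keep <- setdiff(keep, loser)
  }
  list(retained = c(keep, intersect(vars, stack$categorical)),
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(variable = character(), partner = character(),
                    rho = numeric()),
       constant = const, rho = rho)
}

# Quick single-variable training gains (linear + quadratic features) used
# to rank the members of a correlated pair.
single_variable_gains <- function(env, n_presence) {
  pres <- env[seq_len(n_presence), , drop = FALSE]
  bg <- env[-seq_len(n_presence), , drop = FALSE]
  vapply(stats::setNames(names(env), names(env)), function(v) {
    defs <- build_feature_defs(bg[v], classes = c("linear", "quadratic"),
                               n_hinge_knots = 0L)
    if (length(defs) == 0L) return(0)
    Fp <- feature_matrix(defs, pres[v])
    Fb <- feature_matrix(defs, bg[v])
    beta <- feature_penalties(defs, Fb, nrow(Fp), 1)
    core <- maxent_core(Fp, Fb, beta, tol = 1e-6, max_cycles = 2000L)
    log(nrow(Fb)) - core$objective
  }, numeric(1))
}

# Seed-local RNG evaluation: runs `expr` under `seed` and restores the
# caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
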