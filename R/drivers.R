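#' Assemble the driver table for the invasibility model
#'
#' One row per plot: the response is the invader's importance value in the
#' plot (0 where absent), and the predictors are the plot's Shannon
#' diversity plus bioclimatic layers sampled at the plot's grid cell.
#' Plots falling on nodata cells (or outside the raster extent) are
#' dropped and counted.
#'
#' @param survey a `survey_data` data.frame (see [read_survey()]).
#' @param stack an [env_stack()] holding the predictor layers.
#' @param invader invader species name.
#' @param env_vars layer names to sample (default the coldest/warmest
#'   temperature and precipitation set `bio1, bio6, bio8, bio17, bio18`).
#' @return data.frame of class `driver_table` with columns `plot_id`,
#'   `response`, `shannon`, and one column per layer; attribute
#'   `n_dropped` counts plots lost to nodata.
#' @export
build_driver_table <- function(survey, stack, invader,
                               env_vars = c("bio1", "bio6", "bio8",
                                            "bio17", "bio18")) {
  div <- survey_diversity(survey)
  # invader importance per plot, vectorized over the long table
  tot_h <- tapply(survey$height_cm, survey$plot_id, sum)
  tot_c <- tapply(survey$cover, survey$plot_id, sum)
  tot_a <- tapply(survey$abundance, survey$plot_id, sum)
  inv <- survey[survey$species == invader, , drop = FALSE]
  iv <- rep(0, length(tot_h))
  names(iv) <- names(tot_h)
  if (nrow(inv) > 0L) {
    pid <- as.character(inv$plot_id)
    rh <- ifelse(tot_h[pid] > 0, inv$height_cm / tot_h[pid], 0)
    rc <- ifelse(tot_c[pid] > 0, inv$cover / tot_c[pid], 0)
    ra <- ifelse(tot_a[pid] > 0, inv$abundance / tot_a[pid], 0)
    iv[pid] <- (rh + rc + ra) / 3
  }
  first <- !duplicated(survey$plot_id)
  meta <- survey[first, c("plot_id", "longitude", "latitude"), drop = FALSE]
  env <- extract_env(stack, x = meta$longitude, y = meta$latitude,
                     layers = env_vars)
  tab <- data.frame(plot_id = meta$plot_id,
                    response = unname(iv[as.character(meta$plot_id)]),
                    shannon = div$shannon[match(meta$plot_id, div$plot_id)])
  tab <- cbind(tab, env)
  keep <- stats::complete.cases(tab)
  if (!any(keep)) {
    stop("all plots fall outside the raster extent or on nodata cells",
         call. = FALSE)
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " plot(s) dropped (nodata or outside extent)")
  }
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("driver_table", "data.frame")
  out
}

#' Standardize predictor columns to mean 0, SD 1
#'
#' Z-scores each chosen column using the population (1/n) standard
#' deviation, so the transformed column has unit second moment about
#' zero; idempotent on already-standardized columns.
#'
#' @param table a data.frame.
#' @param cols columns to standardize; defaults to all numeric columns
#'   except `response` and `plot_id`.
#' @return the table with the chosen columns z-scored; constant columns
#'   are an error.
#' @export
standardize <- function(table,
                        cols = setdiff(names(table)[vapply(table, is.numeric,
                                                           logical(1))],
                                       c("response", "plot_id"))) {
  for (cl in cols) {
    x <- table[[cl]]
    s <- sqrt(mean((x - mean(x))^2))
    if (!is.finite(s) || s == 0) {
      stop("cannot standardize constant column '", cl, "'", call. = FALSE)
    }
    table[[cl]] <- (x - mean(x)) / s
  }
  table
}

#' Greedy collinearity screen by pairwise Spearman correlation
#'
#' Repeatedly finds the predictor pair with the largest absolute Spearman
#' correlation above `threshold` and drops the member less correlated
#' (Spearman) with the response, until no pair exceeds the threshold.
#'
#' @param table data.frame with a `response` column and candidate
#'   predictor columns.
#' @param candidates candidate column names (default: all numeric columns
#'   except `response`/`plot_id`).
#' @param threshold absolute Spearman cutoff (default 0.75).
#' @return list with `retained` (column names) and `dropped`
#'   (data.frame of dropped variable, its partner, and their rho).
#' @export
collinearity_screen <- function(table, candidates = NULL, threshold = 0.75) {
  if (is.null(candidates)) {
    candidates <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                          c("response", "plot_id"))
  }
  keep <- candidates
  dropped <- list()
  repeat {
    if (length(keep) < 2L) break
    rho <- stats::cor(table[keep], method = "spearman")
    diag(rho) <- 0
    mx <- max(abs(rho))
    if (mx <= threshold) break
    idx <- which(abs(rho) == mx, arr.ind = TRUE)[1, ]
    pair <- keep[idx]
    with_resp <- abs(stats::cor(table[pair], table$response,
                                method = "spearman"))
    loser <- pair[which.min(with_resp)]
    dropped[[length(dropped) + 1L]] <-
      data.frame(dropped = loser, partner = setdiff(pair, loser)[1],
                 rho = mx)
    keep <- setdiff(keep, loser)
  }
  list(retained = keep,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(dropped = character(), partner = character(),
                    rho = numeric()))
}

#' Fit the invasibility driver model
#'
#' Gaussian-identity GLM (default) of the invader's importance value on the
#' standardized predictors, reporting standardized coefficients, Wald
#' tests with significance tiers, and \eqn{R^2 = 1 - SSE/SST}. A
#' quasi-binomial alternative for the bounded response is available via
#' `family`.
#'
#' @param table a [build_driver_table()] result (or any data.frame with a
#'   `response` column and numeric predictors).
#' @param predictors predictor column names (default: all numeric except
#'   `response`/`plot_id`).
#' @param family `"gaussian"` (identity link) or `"quasibinomial"` (logit).
#' @param standardize_predictors z-score predictors before fitting
#'   (default `TRUE`, so coefficient magnitudes are comparable).
#' @return object of class `driver_fit`: list with `coefficients`
#'   (data.frame: term, estimate, std_error, statistic, p_value, tier),
#'   `r_squared`, `n`, `family`, and the underlying `glm` object.
#' @export
fit_glm <- function(table, predictors = NULL, family = c("gaussian",
                                                         "quasibinomial"),
                    standardize_predictors = TRUE) {
  family <- match.arg(family)
  if (is.null(predictors)) {
    predictors <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                          c("response", "plot_id"))
  }
  if (nrow(table) <= length(predictors) + 1L) {
    stop("need n > p + 1 rows to fit the model", call. = FALSE)
  }
  if (standardize_predictors) table <- standardize(table, predictors)
  X <- as.matrix(table[predictors])
  qr_X <- qr(cbind(1, X))
  if (qr_X$rank < ncol(X) + 1L) {
    dep <- predictors[qr_X$pivot[seq(qr_X$rank + 1L, ncol(X) + 1L)] - 1L]
    stop("singular design; linearly dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  fam <- if (family == "gaussian") stats::gaussian() else
    stats::quasibinomial()
  fml <- stats::reformulate(predictors, response = "response")
  fit <- stats::glm(fml, data = table, family = fam)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm),
    estimate = sm[, 1], std_error = sm[, 2], statistic = sm[, 3],
    p_value = sm[, 4], tier = significance_tier(sm[, 4]),
    row.names = NULL
  )
  mu <- stats::fitted(fit)
  r2 <- 1 - sum((table$response - mu)^2) /
    sum((table$response - mean(table$response))^2)
  structure(list(coefficients = coefs, r_squared = r2, n = nrow(table),
                 family = family, model = fit),
            class = "driver_fit")
}

#' @export
print.driver_fit <- function(x, ...) {
  cat("Invasibility driver model (", x$family, "), n = ", x$n,
      ", R^2 = ", round(x$r_squared, 3), "\n", sep = "")
  df <- x$coefficients
  df$estimate <- round(df$estimate, 4)
  df$std_error <- round(df$std_error, 4)
  df$statistic <- round(df$statistic, 3)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
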