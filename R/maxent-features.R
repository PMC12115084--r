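# Feature construction for the maximum-entropy model.
#
# A feature definition list is built from the background sample: each
# feature is a transform of one layer (linear, quadratic, forward/reverse
# hinge, categorical indicator) or of a pair (product), min-max scaled to
# [0, 1] over the background. Constant-over-background features are
# dropped.

build_feature_defs <- function(bg_env, classes = c("linear", "quadratic",
                                                   "hinge"),
                               categorical = character(),
                               n_hinge_knots = 5L, products = FALSE) {
  vars <- names(bg_env)
  cont <- setdiff(vars, categorical)
  defs <- list()
  add <- function(variable, type, param = NA_real_, partner = NA_character_) {
    defs[[length(defs) + 1L]] <<- list(variable = variable, type = type,
                                       param = param, partner = partner)
  }
  for (v in cont) {
    x <- bg_env[[v]]
    if ("linear" %in% classes) add(v, "linear")
    if ("quadratic" %in% classes) add(v, "quadratic")
    if ("hinge" %in% classes && n_hinge_knots > 0L) {
      knots <- stats::quantile(x, probs = seq_len(n_hinge_knots) /
                                 (n_hinge_knots + 1), names = FALSE)
      for (k in unique(knots)) {
        add(v, "hinge_fwd", param = k)
        add(v, "hinge_rev", param = k)
      }
    }
  }
  for (v in intersect(vars, categorical)) {
    for (lev in sort(unique(bg_env[[v]]))) add(v, "indicator", param = lev)
  }
  if (products && length(cont) > 1L) {
    pairs <- utils::combn(cont, 2)
    for (i in seq_len(ncol(pairs))) {
      add(pairs[1, i], "product", partner = pairs[2, i])
    }
  }
  raw <- raw_feature_matrix(defs, bg_env)
  lo <- apply(raw, 2, min)
  hi <- apply(raw, 2, max)
  keep <- which(hi > lo)
  defs <- defs[keep]
  for (i in seq_along(defs)) {
    defs[[i]]$lo <- lo[keep[i]]
    defs[[i]]$hi <- hi[keep[i]]
    defs[[i]]$name <- feature_name(defs[[i]])
  }
  defs
}

feature_name <- function(d) {
  switch(d$type,
         linear = d$variable,
         quadratic = paste0(d$variable, "^2"),
         hinge_fwd = sprintf("hinge(%s>%.6g)", d$variable, d$param),
         hinge_rev = sprintf("hinge(%s<%.6g)", d$variable, d$param),
         indicator = sprintf("%s==%.6g", d$variable, d$param),
         product = paste0(d$variable, "*", d$partner))
}

raw_feature_matrix <- function(defs, env) {
  out <- matrix(0, nrow(env), length(defs))
  for (j in seq_along(defs)) {
    d <- defs[[j]]
    x <- env[[d$variable]]
    out[, j] <- switch(d$type,
                       linear = x,
                       quadratic = x^2,
                       hinge_fwd = pmax(0, x - d$param),
                       hinge_rev = pmax(0, d$param - x),
                       indicator = as.numeric(x == d$param),
                       product = x * env[[d$partner]])
  }
  out
}

# Scaled design matrix (features in [0,1] over the background used to
# build the defs). New data outside the background range is clamped to
# the bounds by default — the standard maxent treatment, which makes
# predictions plateau rather than extrapolate under novel climates.
feature_matrix <- function(defs, env, clamp = TRUE) {
  if (any(!vapply(env, function(v) all(is.finite(v)), logical(1)))) {
    stop("non-finite environmental values in feature construction",
         call. = FALSE)
  }
  raw <- raw_feature_matrix(defs, env)
  lo <- vapply(defs, `[[`, numeric(1), "lo")
  hi <- vapply(defs, `[[`, numeric(1), "hi")
  out <- sweep(sweep(raw, 2, lo, "-"), 2, hi - lo, "/")
  if (clamp) out <- pmin(pmax(out, 0), 1)
  colnames(out) <- vapply(defs, `[[`, character(1), "name")
  out
}

# Per-feature L1 penalties: scale with feature SD over the background and
# shrink with the presence count; hinge features get a lighter class
# multiplier (they come in bundles).
feature_penalties <- function(defs, Fb, n_presence, reg_multiplier = 1) {
  sds <- apply(Fb, 2, stats::sd)
  class_mult <- vapply(defs, function(d) {
    if (d$type %in% c("hinge_fwd", "hinge_rev")) 0.5 else 1.0
  }, numeric(1))
  pmax(reg_multiplier * class_mult * sds / sqrt(max(n_presence, 1)), 1e-12)
}
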