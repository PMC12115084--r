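#' Synthetic inputs with known ground truth
#'
#' Seeded generators for every input the pipeline consumes: spatially
#' smooth cross-correlated environmental stacks, occurrence points drawn
#' from a known Gibbs suitability model, vegetation plot surveys whose
#' invader importance declines with community diversity, and risk
#' scoresheets realizing a chosen risk level. All generators are pure
#' functions of their arguments (seed included).
#'
#' @name synthetic-data
NULL

# Plausible value ranges for a subtropical monsoon port hinterland
# (annual mean ~17.4 degC, annual precipitation ~1480 mm); temperatures in
# degC, precipitation in mm.
BIOCLIM_RANGES <- list(
  bio1 = c(15, 19), bio2 = c(6, 9), bio3 = c(22, 30), bio4 = c(600, 800),
  bio5 = c(30, 35), bio6 = c(0, 6), bio7 = c(26, 31), bio8 = c(17, 28),
  bio9 = c(5, 10), bio10 = c(26, 30), bio11 = c(5, 9),
  bio12 = c(1250, 1700), bio13 = c(180, 260), bio14 = c(30, 70),
  bio15 = c(40, 70), bio16 = c(410, 470), bio17 = c(120, 200),
  bio18 = c(300, 500), bio19 = c(130, 220), elev = c(0, 600)
)

# Box (moving-average) smoother with window half-width w, edge-corrected
# via a summed-area table.
box_smooth <- function(m, w) {
  if (w < 1L) return(m)
  nr <- nrow(m)
  nc <- ncol(m)
  P <- matrix(0, nr + 1L, nc + 1L)
  P[-1L, -1L] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r <- seq_len(nr)
  cidx <- seq_len(nc)
  r1 <- pmax(r - w, 1L); r2 <- pmin(r + w, nr)
  c1 <- pmax(cidx - w, 1L); c2 <- pmin(cidx + w, nc)
  S <- P[r2 + 1L, c2 + 1L, drop = FALSE] - P[r1, c2 + 1L, drop = FALSE] -
    P[r2 + 1L, c1, drop = FALSE] + P[r1, c1, drop = FALSE]
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  S / cnt
}

rescale_range <- function(m, range) {
  lo <- min(m, na.rm = TRUE)
  hi <- max(m, na.rm = TRUE)
  if (hi == lo) return(matrix(mean(range), nrow(m), ncol(m)))
  range[1] + (m - lo) / (hi - lo) * (range[2] - range[1])
}

#' Generate a synthetic environmental landscape
#'
#' Each layer is seeded white noise smoothed by a truncated
#' moving-average kernel and min-max rescaled to a plausible bioclim
#' range. A correlation plan mixes latent fields
#' (`latent_j = rho * latent_i + sqrt(1 - rho^2) * independent`) before
#' rescaling, so the target Spearman correlations survive the monotone
#' rescale. Land cover is a quantile quantization of its own latent
#' field.
#'
#' @param n_rows,n_cols grid size (at least 20 x 20 for SDM use).
#' @param cell_size_km cell edge length in km.
#' @param smoothness kernel half-width in cells (>= 1).
#' @param correlation_plan list of `c(layer_i, layer_j, rho)` triples,
#'   applied in order: layer_j is re-mixed towards layer_i (a layer
#'   should appear as `layer_j` at most once, or later mixes dilute
#'   earlier targets). The default couples precipitation totals and
#'   summer temperatures, leaving the driver variables (`bio1`, `bio6`,
#'   `bio8`, `bio17`, `bio18`) unplanned.
#' @param layers continuous layer names to generate.
#' @param n_landcover number of land-cover classes.
#' @param mask_fraction fraction of cells set to nodata (a smoothed
#'   latent field's lowest quantile, so the mask is spatially coherent).
#' @param seed RNG seed.
#' @return an [env_stack()] with the requested layers plus `landcover`.
#' @export
gen_landscape <- function(n_rows = 60L, n_cols = 60L, cell_size_km = 0.5,
                          smoothness = 4L,
                          correlation_plan = list(
                            c("bio12", "bio16", "0.9"),
                            c("bio12", "bio13", "0.8"),
                            c("bio5", "bio10", "0.85")
                          ),
                          layers = names(BIOCLIM_RANGES),
                          n_landcover = 5L, mask_fraction = 0,
                          seed = 42L) {
  stopifnot(n_rows >= 20L, n_cols >= 20L, smoothness >= 1L)
  with_seed(seed, {
    latent <- lapply(stats::setNames(layers, layers), function(nm) {
      box_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                 smoothness)
    })
    for (triple in correlation_plan) {
      li <- triple[1]; lj <- triple[2]; rho <- as.numeric(triple[3])
      if (!li %in% layers || !lj %in% layers) next
      a <- scale_field(latent[[li]])
      b <- scale_field(latent[[lj]])
      latent[[lj]] <- rho * a + sqrt(1 - rho^2) * b
    }
    out <- lapply(stats::setNames(layers, layers), function(nm) {
      rng <- BIOCLIM_RANGES[[nm]]
      if (is.null(rng)) rng <- c(0, 1)
      rescale_range(latent[[nm]], rng)
    })
    lc_latent <- box_smooth(matrix(stats::rnorm(n_rows * n_cols),
                                   n_rows, n_cols), smoothness)
    qs <- stats::quantile(lc_latent, probs = seq_len(n_landcover - 1L) /
                            n_landcover)
    out$landcover <- matrix(1 + rowSums(outer(as.numeric(lc_latent), qs,
                                              ">")),
                            n_rows, n_cols)
    if (mask_fraction > 0) {
      mk <- box_smooth(matrix(stats::rnorm(n_rows * n_cols),
                              n_rows, n_cols), smoothness)
      bad <- mk <= stats::quantile(mk, mask_fraction)
      out <- lapply(out, function(m) {
        m[bad] <- NA_real_
        m
      })
    }
    env_stack(out, cell_size = cell_size_km, origin = c(0, 0),
              categorical = "landcover")
  })
}

scale_field <- function(m) (m - mean(m)) / stats::sd(m)

#' Ground-truth suitability model
#'
#' The true Gibbs model behind [gen_occurrences()]: a linear predictor
#' over layers min-max normalized to `[0, 1]` across valid cells, with
#' optional quadratic terms.
#'
#' @param linear named numeric vector of coefficients on normalized
#'   layers.
#' @param quadratic named numeric vector of coefficients on squared
#'   normalized layers.
#' @param intercept intercept (irrelevant to the Gibbs distribution;
#'   kept for completeness).
#' @return object of class `truth_model`.
#' @export
truth_model <- function(linear, quadratic = numeric(), intercept = 0) {
  stopifnot(length(linear) >= 1L, !is.null(names(linear)),
            all(is.finite(c(linear, quadratic, intercept))))
  structure(list(linear = linear, quadratic = quadratic,
                 intercept = intercept),
            class = "truth_model")
}

# Linear predictor of the truth model at given cells.
truth_eta <- function(stack, truth, cells = valid_cells(stack)) {
  vars <- union(names(truth$linear), names(truth$quadratic))
  env <- extract_env(stack, cells = cells, layers = vars)
  all_env <- extract_env(stack, cells = valid_cells(stack), layers = vars)
  eta <- rep(truth$intercept, length(cells))
  for (v in vars) {
    lo <- min(all_env[[v]])
    hi <- max(all_env[[v]])
    z <- if (hi > lo) (env[[v]] - lo) / (hi - lo) else env[[v]] * 0
    if (!is.na(truth$linear[v])) eta <- eta + truth$linear[v] * z
    if (!is.na(truth$quadratic[v])) eta <- eta + truth$quadratic[v] * z^2
  }
  eta
}

#' True suitability surface of a truth model
#'
#' @param stack an [env_stack()].
#' @param truth a [truth_model()].
#' @return matrix of the Gibbs probability of each cell (normalized over
#'   valid cells; `NA` on nodata).
#' @export
truth_surface <- function(stack, truth) {
  vc <- valid_cells(stack)
  eta <- truth_eta(stack, truth, vc)
  p <- exp(eta - log_sum_exp(eta))
  out <- matrix(NA_real_, stack$n_rows, stack$n_cols)
  out[vc] <- p
  out
}

#' Draw occurrence points from a truth model
#'
#' Cells are sampled (with replacement) with probability proportional to
#' `exp(eta)`, the same Gibbs likelihood the maxent fitter maximizes;
#' points are placed at cell centres.
#'
#' @param stack an [env_stack()].
#' @param truth a [truth_model()].
#' @param n number of points.
#' @param species species label.
#' @param seed RNG seed.
#' @return data.frame with `species`, `x`, `y`, `cell`.
#' @export
gen_occurrences <- function(stack, truth, n, species = "invader",
                            seed = 42L) {
  vc <- valid_cells(stack)
  eta <- truth_eta(stack, truth, vc)
  p <- exp(eta - log_sum_exp(eta))
  cells <- with_seed(seed, sample(vc, n, replace = TRUE, prob = p))
  xy <- cell_coordinates(stack, cells)
  data.frame(species = species, x = xy$x, y = xy$y, cell = cells)
}

#' Generate a synthetic vegetation survey
#'
#' Plots are placed on random valid cells. Each plot gets a companion
#' community with geometric-series abundances (richness drawn from
#' `richness_range`), and the invader's target importance value is
#' \deqn{IV = clip(\beta_0 + \beta_{shannon} H + \sum_v \beta_v z_v +
#'   \epsilon,\ 0,\ 0.95),}
#' with `H` the companion Shannon diversity (nats), `z_v` the landscape
#' z-score of layer `v` at the plot, and
#' \eqn{\epsilon \sim N(0, \sigma^2)}. The target is realized by setting
#' the invader's height, cover and abundance to the shares that make each
#' relative metric equal the target (abundance rounded to an integer,
#' hence a small reconstruction slack). Targets at or below
#' `absence_below` leave the invader out of the plot.
#'
#' The default negative `beta_shannon` encodes diversity-mediated
#' invasion resistance; `env_beta` defaults to a positive coefficient on
#' the coldest-month minimum temperature (colder plots are less
#' invaded). The default `absence_below` and `sigma` jointly put the
#' invader's occurrence rate near two thirds of plots and the driver
#' GLM's explained variance near 0.45 under the default settings.
#'
#' @param stack an [env_stack()].
#' @param n_plots number of plots.
#' @param invader invader species name.
#' @param beta0 intercept of the importance target.
#' @param beta_shannon diversity coefficient (< 0 for resistance).
#' @param env_beta named coefficients on landscape-z-scored layers.
#' @param sigma noise SD of the importance target.
#' @param richness_range integer range of companion richness.
#' @param n_species_pool size of the companion species pool.
#' @param n_families number of families in the pool taxonomy.
#' @param absence_below targets at or below this leave the plot
#'   uninvaded.
#' @param seed RNG seed.
#' @return a `survey_data` data.frame (one row per plot x species) with
#'   attributes `targets` (per-plot importance targets) and `dominant`
#'   (per-plot true dominant species from the generated numbers).
#' @export
gen_survey <- function(stack, n_plots = 595L,
                       invader = "Solidago canadensis",
                       beta0 = 1.0, beta_shannon = -0.4,
                       env_beta = c(bio6 = 0.05), sigma = 0.11,
                       richness_range = 3:10, n_species_pool = 120L,
                       n_families = 15L, absence_below = 0.32,
                       seed = 42L) {
  stopifnot(n_plots >= 1L)
  with_seed(seed, {
    vc <- valid_cells(stack)
    cells <- sample(vc, n_plots, replace = TRUE)
    xy <- cell_coordinates(stack, cells)
    jit <- stack$cell_size * 0.4
    x <- xy$x + stats::runif(n_plots, -jit, jit)
    y <- xy$y + stats::runif(n_plots, -jit, jit)
    elev <- if ("elev" %in% names(stack$layers)) {
      stack$layers[["elev"]][cells]
    } else {
      rep(0, n_plots)
    }
    habitat <- sample(c("forest", "wetland", "grassland"), n_plots,
                      replace = TRUE)
    # companion community: geometric abundance series
    S <- sample(richness_range, n_plots, replace = TRUE)
    idx <- rep(seq_len(n_plots), S)
    within <- sequence(S)
    theta <- stats::runif(n_plots, 0.35, 0.9)
    ab <- pmax(1, round(20 * theta[idx]^(within - 1)))
    tot_ab <- as.numeric(rowsum(ab, idx))
    p_i <- ab / tot_ab[idx]
    H <- as.numeric(rowsum(-p_i * log(p_i), idx))
    heights <- pmin(pmax(stats::rlnorm(length(idx), log(20), 0.6), 3), 120)
    cover_tot <- stats::runif(n_plots, 0.3, 0.85)
    covers <- cover_tot[idx] * p_i *
      stats::runif(length(idx), 0.7, 1.3)
    # distinct companion names per plot: stride trick over the pool
    stride <- sample(1:9, n_plots, replace = TRUE)
    offset <- sample.int(n_species_pool, n_plots, replace = TRUE)
    sp_idx <- ((offset[idx] + within * stride[idx]) %% n_species_pool) + 1L
    pool <- sprintf("sp%03d", seq_len(n_species_pool))
    fam_of_pool <- sprintf("fam%02d",
                           sample.int(n_families, n_species_pool,
                                      replace = TRUE,
                                      prob = 0.75^seq_len(n_families)))
    # invader importance target
    zsum <- rep(0, n_plots)
    for (v in names(env_beta)) {
      layer_vals <- stack$layers[[v]][vc]
      z <- (stack$layers[[v]][cells] - mean(layer_vals)) /
        stats::sd(layer_vals)
      zsum <- zsum + env_beta[[v]] * z
    }
    target <- beta0 + beta_shannon * H + zsum +
      stats::rnorm(n_plots, 0, sigma)
    target <- pmin(pmax(target, 0), 0.95)
    present <- target > absence_below
    # Invader rows realizing the target importance: the invader enters
    # with a small abundance (1-3 ramets), and the height and cover
    # shares absorb the rest of the target, so IV =
    # (rel_h + rel_c + rel_a) / 3 = target up to clipping. Keeping the
    # abundance share small stops invader dominance from mechanically
    # depressing the plot's measured diversity.
    tot_h <- as.numeric(rowsum(heights, idx))
    tot_c <- as.numeric(rowsum(covers, idx))
    t_p <- target[present]
    inv_ab <- sample(1:3, sum(present), replace = TRUE)
    ra <- inv_ab / (inv_ab + tot_ab[present])
    # high targets need a larger abundance share (height/cover shares
    # are capped at 0.95): raise it just enough to keep IV realizable
    need <- 3 * t_p - 1.9
    boost <- need > ra
    if (any(boost)) {
      ra_need <- pmin(need[boost], 0.95)
      inv_ab[boost] <- pmax(inv_ab[boost],
                            round(ra_need / (1 - ra_need) *
                                    tot_ab[present][boost]))
      ra <- inv_ab / (inv_ab + tot_ab[present])
    }
    s_hc <- pmin(pmax((3 * t_p - ra) / 2, 0), 0.95)
    ratio <- s_hc / (1 - s_hc)
    inv_h <- ratio * tot_h[present]
    # invader cover cannot exceed the whole plot: where the target share
    # would need more, the invader takes full cover and companion covers
    # shrink so the share still comes out right
    inv_c <- ratio * tot_c[present]
    over <- which(inv_c > 1)
    if (length(over) > 0L) {
      sc <- rep(1, n_plots)
      p_over <- which(present)[over]
      sc[p_over] <- (1 / ratio[over]) / tot_c[present][over]
      covers <- covers * sc[idx]
      tot_c <- as.numeric(rowsum(covers, idx))
      inv_c[over] <- 1
    }
    comp <- data.frame(
      plot_id = sprintf("plot%04d", idx),
      longitude = x[idx], latitude = y[idx], elevation = elev[idx],
      habitat = habitat[idx],
      species = pool[sp_idx], family = fam_of_pool[sp_idx],
      abundance = ab, height_cm = heights, cover = pmin(covers, 1)
    )
    pres_idx <- which(present)
    invr <- data.frame(
      plot_id = sprintf("plot%04d", pres_idx),
      longitude = x[pres_idx], latitude = y[pres_idx],
      elevation = elev[pres_idx], habitat = habitat[pres_idx],
      species = invader, family = "Asteraceae",
      abundance = inv_ab, height_cm = inv_h, cover = inv_c
    )
    survey <- rbind(comp, invr)
    survey <- survey[order(survey$plot_id, survey$species), , drop = FALSE]
    rownames(survey) <- NULL
    survey <- as_survey_data(survey)
    attr(survey, "targets") <- data.frame(
      plot_id = sprintf("plot%04d", seq_len(n_plots)),
      target = ifelse(present, target, 0),
      shannon_companion = H, cell = cells
    )
    attr(survey, "dominant") <- generator_dominants(survey)
    survey
  })
}

# True dominant species per plot from the generated numbers (highest
# importance value, lexicographic ties).
generator_dominants <- function(survey) {
  tot_h <- tapply(survey$height_cm, survey$plot_id, sum)
  tot_c <- tapply(survey$cover, survey$plot_id, sum)
  tot_a <- tapply(survey$abundance, survey$plot_id, sum)
  pid <- as.character(survey$plot_id)
  iv <- (survey$height_cm / tot_h[pid] + survey$cover / tot_c[pid] +
           survey$abundance / tot_a[pid]) / 3
  ord <- order(survey$plot_id, -iv, survey$species)
  first <- !duplicated(survey$plot_id[ord])
  data.frame(plot_id = survey$plot_id[ord][first],
             dominant = survey$species[ord][first])
}

#' Perturb a landscape into a future climate scenario
#'
#' Emulates a future climate layer set by shifting temperature layers by
#' `delta_temp` degC and scaling precipitation layers by
#' `precip_factor`, each plus a smooth seeded anomaly field. Topography
#' and land cover are unchanged. (Scenario stacks are independent
#' perturbations, not a temporal trajectory.)
#'
#' @param stack an [env_stack()] from [gen_landscape()].
#' @param delta_temp uniform warming applied to temperature layers
#'   (degC).
#' @param precip_factor multiplicative change of precipitation layers.
#' @param anomaly_sd SD of the smooth anomaly added to each perturbed
#'   layer (in the layer's units for temperature; as a fraction for
#'   precipitation).
#' @param smoothness anomaly kernel half-width in cells.
#' @param seed RNG seed.
#' @return a perturbed [env_stack()] on the same grid.
#' @export
gen_scenario_stack <- function(stack, delta_temp = 1.5,
                               precip_factor = 1.05, anomaly_sd = 0.3,
                               smoothness = 4L, seed = 42L) {
  temp_layers <- intersect(names(stack$layers),
                           paste0("bio", c(1, 2, 5, 6, 8:11)))
  prec_layers <- intersect(names(stack$layers),
                           paste0("bio", c(12, 13, 14, 16:19)))
  with_seed(seed, {
    layers <- stack$layers
    nr <- stack$n_rows
    nc <- stack$n_cols
    anomaly <- function() {
      box_smooth(matrix(stats::rnorm(nr * nc), nr, nc), smoothness) |>
        scale_field()
    }
    for (nm in temp_layers) {
      layers[[nm]] <- layers[[nm]] + delta_temp + anomaly_sd * anomaly()
    }
    for (nm in prec_layers) {
      layers[[nm]] <- layers[[nm]] *
        (precip_factor + 0.02 * anomaly_sd * anomaly())
    }
    env_stack(layers, cell_size = stack$cell_size, origin = stack$origin,
              categorical = stack$categorical)
  })
}

#' Generate a risk scoresheet realizing a target level
#'
#' Indicator scores are sampled (integers on the 0-4 scale, biased
#' towards the target band) and re-drawn until [assess()] returns the
#' requested level; the rejection loop is bounded and deterministic
#' under the seed.
#'
#' @param target_level desired risk level (1 = high, 2 = medium,
#'   3 = low).
#' @param species species label.
#' @param max_tries rejection-sampling bound.
#' @param seed RNG seed.
#' @return a [risk_scoresheet()] whose assessment yields `target_level`.
#' @export
gen_risk_scoresheet <- function(target_level, species = "invader",
                                max_tries = 1000L, seed = 42L) {
  stopifnot(target_level %in% 1:3)
  pool <- switch(target_level, `1` = 2:4, `2` = 1:3, `3` = 0:1)
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      sheet <- risk_scoresheet(
        species, stats::setNames(sample(pool, length(RISK_CODES),
                                        replace = TRUE), RISK_CODES))
      if (assess(sheet)$level == target_level) return(sheet)
    }
    stop("could not realize risk level ", target_level, " in ",
         max_tries, " tries", call. = FALSE)
  })
}
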