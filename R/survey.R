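#' Read a vegetation plot survey from CSV
#'
#' One row per (plot, species). Required columns: `plot_id`, `longitude`,
#' `latitude`, `elevation`, `habitat`, `species`, `abundance`, `height_cm`,
#' `cover_pct` (cover in percent on disk; converted to a fraction).
#' An optional `family` column is carried through.
#'
#' @param path CSV file path.
#' @return a `survey_data` data.frame, one row per (plot, species), with
#'   cover as a fraction in `[0, 1]`.
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("plot_id", "longitude", "latitude", "elevation", "habitat",
                "species", "abundance", "height_cm", "cover_pct")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("survey CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(df$abundance < 0 | df$height_cm < 0 |
                 df$cover_pct < 0 | df$cover_pct > 100)
  if (length(bad) > 0L) {
    stop("invalid observation value(s) at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (plot ", df$plot_id[bad[1]], ", species '", df$species[bad[1]],
         "'): abundance/height must be >= 0 and cover_pct in [0, 100]",
         call. = FALSE)
  }
  dup <- duplicated(df[, c("plot_id", "species")])
  if (any(dup)) {
    stop("duplicated species within a plot at data row(s) ",
         paste(utils::head(which(dup), 5L), collapse = ", "), call. = FALSE)
  }
  df$cover <- df$cover_pct / 100
  df$cover_pct <- NULL
  if (is.null(df$family)) df$family <- NA_character_
  as_survey_data(df)
}

as_survey_data <- function(df) {
  class(df) <- c("survey_data", "data.frame")
  df
}

#' Write a survey table to CSV in the on-disk layout
#'
#' @param survey a `survey_data` data.frame (cover as a fraction).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  out <- as.data.frame(survey)
  out$cover_pct <- out$cover * 100
  out$cover <- NULL
  keep <- c("plot_id", "longitude", "latitude", "elevation", "habitat",
            "species", "family", "abundance", "height_cm", "cover_pct")
  utils::write.csv(out[, intersect(keep, names(out))], path,
                   row.names = FALSE)
  invisible(path)
}

# Rows of one plot, with basic presence checks.
plot_rows <- function(survey, plot_id) {
  rows <- survey[survey$plot_id == plot_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("plot '", plot_id, "' not found in the survey", call. = FALSE)
  }
  rows
}

#' Relative height, cover, abundance and importance value per species
#'
#' Within one plot, each metric is normalized by its plot total
#' (`rel_x = x / sum(x)`), and the importance value is the weighted mean of
#' the three relative metrics (equal weights by default, the standard
#' herbaceous-community convention).
#'
#' A metric whose plot total is zero yields zero relatives for every
#' species, with a warning naming the metric.
#'
#' @param plot one plot's rows of a `survey_data` data.frame.
#' @param weights length-3 numeric weights for (height, cover, abundance);
#'   normalized to sum to 1.
#' @return data.frame with `species`, `rel_height`, `rel_cover`,
#'   `rel_abundance`, `importance`.
#' @export
relative_metrics <- function(plot, weights = c(1, 1, 1)) {
  if (nrow(plot) == 0L) stop("plot has no observations", call. = FALSE)
  stopifnot(length(weights) == 3L, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  rel <- function(x, what) {
    tot <- sum(x)
    if (tot <= 0) {
      warning("all-zero ", what, " in plot '", plot$plot_id[1],
              "'; relative ", what, " set to 0", call. = FALSE)
      return(rep(0, length(x)))
    }
    x / tot
  }
  data.frame(
    species = plot$species,
    rel_height = rel(plot$height_cm, "height"),
    rel_cover = rel(plot$cover, "cover"),
    rel_abundance = rel(plot$abundance, "abundance"),
    importance = NA_real_
  ) -> out
  out$importance <- w[1] * out$rel_height + w[2] * out$rel_cover +
    w[3] * out$rel_abundance
  out
}

#' Shannon-Wiener diversity of one plot
#'
#' \eqn{H = -\sum p_i \log p_i} over species abundance shares, in nats by
#' default (`base = exp(1)`); set `base = 2` for bits.
#'
#' @param plot one plot's rows of a `survey_data` data.frame.
#' @param base logarithm base.
#' @return data.frame with `plot_id`, `richness`, `shannon`.
#' @export
shannon_index <- function(plot, base = exp(1)) {
  if (nrow(plot) == 0L || sum(plot$abundance) <= 0) {
    stop("Shannon index undefined: plot '",
         if (nrow(plot) > 0L) plot$plot_id[1] else "?",
         "' has no positive abundances", call. = FALSE)
  }
  p <- plot$abundance / sum(plot$abundance)
  p <- p[p > 0]
  data.frame(plot_id = plot$plot_id[1],
             richness = sum(plot$abundance > 0),
             shannon = -sum(p * log(p, base = base)))
}

# Vectorized plot-level diversity for a whole survey.
survey_diversity <- function(survey, base = exp(1)) {
  tot <- tapply(survey$abundance, survey$plot_id, sum)
  plh <- -tapply(seq_len(nrow(survey)), survey$plot_id, function(i) {
    p <- survey$abundance[i] / sum(survey$abundance[i])
    p <- p[p > 0]
    sum(p * log(p, base = base))
  })
  rich <- tapply(survey$abundance > 0, survey$plot_id, sum)
  data.frame(plot_id = names(tot), richness = as.integer(rich),
             shannon = ifelse(tot > 0, as.numeric(plh), NA_real_),
             row.names = NULL)
}

#' Occurrence rate of a species across plots
#'
#' @param survey a `survey_data` data.frame.
#' @param species species name.
#' @return list with `presences`, `plots`, and `rate` (percent; round to
#'   one decimal for display).
#' @export
occurrence_rate <- function(survey, species) {
  if (nrow(survey) == 0L) stop("empty survey dataset", call. = FALSE)
  plots <- unique(survey$plot_id)
  present <- unique(survey$plot_id[survey$species == species &
                                     survey$abundance > 0])
  list(presences = length(present), plots = length(plots),
       rate = 100 * length(present) / length(plots))
}

#' Family composition of the surveyed flora
#'
#' Percent of distinct species per family; families below `merge_below`
#' percent are pooled into `"others"`. Species with no family mapping are
#' assigned `"unknown"` (with a warning).
#'
#' @param survey a `survey_data` data.frame.
#' @param taxonomy optional named character vector (species -> family)
#'   overriding the survey's `family` column.
#' @param merge_below merge threshold in percent (default 1.0).
#' @return data.frame with `family`, `n_species`, `percent`, sorted by
#'   descending percent with `"others"` last.
#' @export
family_composition <- function(survey, taxonomy = NULL, merge_below = 1.0) {
  sp <- unique(survey$species)
  if (!is.null(taxonomy)) {
    fam <- unname(taxonomy[sp])
  } else {
    fam <- survey$family[match(sp, survey$species)]
  }
  unmapped <- is.na(fam) | fam == ""
  if (any(unmapped)) {
    warning(sum(unmapped), " species without a family mapping assigned to",
            " 'unknown'", call. = FALSE)
    fam[unmapped] <- "unknown"
  }
  tab <- table(fam)
  pct <- 100 * as.numeric(tab) / length(sp)
  res <- data.frame(family = names(tab), n_species = as.integer(tab),
                    percent = pct)
  small <- res$percent < merge_below
  if (any(small) && sum(!small) > 0L) {
    merged <- data.frame(family = "others",
                         n_species = sum(res$n_species[small]),
                         percent = sum(res$percent[small]))
    res <- rbind(res[!small, , drop = FALSE], merged)
  }
  res <- res[order(res$family == "others", -res$percent), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Welch two-sample t test with significance tiers
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value, plus the conventional significance
#' tiers `*`, `**`, `***` at 0.05 / 0.01 / 0.001.
#'
#' @param a,b numeric vectors (each of length >= 2 with finite variance).
#' @return list with `t`, `df`, `p`, `tier`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: both groups constant; t test undefined, report no effect
    # when the constants agree
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1, tier = "ns"))
    }
    stop("both groups are constant with different means; t undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  p <- ht$p.value
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = p,
       tier = significance_tier(p))
}

#' @rdname welch_t_test
#' @param p p-value(s).
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Community-type summary table
#'
#' Assigns each plot a dominant species (highest importance value, ties
#' broken lexicographically), then tabulates per dominant: companion
#' species (most frequent co-occurring species), number of plots, and the
#' mean and SD of the dominant's cover (%) and height (cm).
#'
#' @param survey a `survey_data` data.frame.
#' @param n_companions how many companion species to list per type.
#' @return data.frame with `dominant`, `companions`, `n_plots`,
#'   `cover_mean`, `cover_sd`, `height_mean`, `height_sd`, ordered by
#'   descending `n_plots`; plot counts partition the dataset.
#' @export
community_summary <- function(survey, n_companions = 3L) {
  ids <- unique(survey$plot_id)
  dominant <- character(length(ids))
  dom_cover <- numeric(length(ids))
  dom_height <- numeric(length(ids))
  for (k in seq_along(ids)) {
    rows <- survey[survey$plot_id == ids[k], , drop = FALSE]
    rm <- suppressWarnings(relative_metrics(rows))
    ord <- order(-rm$importance, rm$species)
    dominant[k] <- rm$species[ord[1]]
    i <- which(rows$species == dominant[k])
    dom_cover[k] <- rows$cover[i] * 100
    dom_height[k] <- rows$height_cm[i]
  }
  types <- sort(unique(dominant))
  out <- lapply(types, function(sp) {
    sel <- dominant == sp
    comp <- survey$species[survey$plot_id %in% ids[sel] &
                             survey$species != sp]
    comp_top <- names(sort(table(comp), decreasing = TRUE))
    data.frame(
      dominant = sp,
      companions = paste(utils::head(comp_top, n_companions),
                         collapse = ", "),
      n_plots = sum(sel),
      cover_mean = mean(dom_cover[sel]),
      cover_sd = if (sum(sel) > 1L) stats::sd(dom_cover[sel]) else 0,
      height_mean = mean(dom_height[sel]),
      height_sd = if (sum(sel) > 1L) stats::sd(dom_height[sel]) else 0
    )
  })
  res <- do.call(rbind, out)
  res <- res[order(-res$n_plots, res$dominant), , drop = FALSE]
  rownames(res) <- NULL
  res
}
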