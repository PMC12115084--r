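# Shared fixtures and independent oracles, all built in code.

# One plot's rows in the long survey layout (cover as a fraction).
make_plot <- function(plot_id, species, abundance, height, cover,
                      family = NA_character_, lon = 0.5, lat = 0.5,
                      habitat = "grassland") {
  invascape:::as_survey_data(data.frame(
    plot_id = plot_id, longitude = lon, latitude = lat, elevation = 10,
    habitat = habitat, species = species, family = family,
    abundance = abundance, height_cm = height, cover = cover
  ))
}

bind_survey <- function(...) {
  invascape:::as_survey_data(do.call(rbind, lapply(list(...),
                                                   as.data.frame)))
}

# The 12 community-type plot counts of the study area's vegetation table.
community_type_counts <- c(166, 81, 60, 45, 45, 41, 36, 29, 26, 24, 22, 20)

# Survey in which plot i's dominant is "domXX" with a weak companion;
# counts per dominant follow `counts`.
make_typed_survey <- function(counts) {
  doms <- sprintf("dom%02d", seq_along(counts))
  rows <- list()
  pid <- 0L
  for (k in seq_along(counts)) {
    for (i in seq_len(counts[k])) {
      pid <- pid + 1L
      id <- sprintf("p%04d", pid)
      rows[[length(rows) + 1L]] <- make_plot(
        id, species = c(doms[k], "companion_sp"),
        abundance = c(10, 2), height = c(80, 10), cover = c(0.6, 0.1)
      )
    }
  }
  do.call(bind_survey, rows)
}

# Presence/absence fixture: `presences` plots contain the invader,
# the rest only a companion.
make_occurrence_survey <- function(n_plots, presences,
                                   invader = "Solidago canadensis") {
  rows <- lapply(seq_len(n_plots), function(i) {
    id <- sprintf("p%04d", i)
    if (i <= presences) {
      make_plot(id, species = c(invader, "other_sp"),
                abundance = c(5, 3), height = c(90, 20),
                cover = c(0.4, 0.2))
    } else {
      make_plot(id, species = "other_sp", abundance = 3, height = 20,
                cover = 0.2)
    }
  })
  do.call(bind_survey, rows)
}

# Exhaustive natural-breaks oracle: minimal within-class SSD over all
# contiguous partitions of the sorted values into k classes.
brute_force_jenks_ssd <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (i in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, i], n)
    tot <- 0
    for (j in seq_len(k)) tot <- tot + ssd(x[(b[j] + 1):b[j + 1]])
    if (tot < best) best <- tot
  }
  best
}

# Small two-layer stack with deterministic gradients (no RNG).
make_gradient_stack <- function(n = 20) {
  g <- matrix(seq(0, 1, length.out = n * n), n, n)
  env_stack(list(a = g, b = t(g)), cell_size = 1)
}

# High-contrast two-layer stack for Gibbs recovery tests: iid U-shaped
# fields give the feature spread that makes n = 2000 presences
# informative.
make_contrast_stack <- function(seed, n = 100) {
  invascape:::with_seed(seed, env_stack(list(
    bio1 = matrix(stats::rbeta(n * n, 0.3, 0.3), n, n),
    bio16 = matrix(stats::rbeta(n * n, 0.3, 0.3), n, n)
  )))
}

# Area report with a planted suitable/non-suitable split on `valid`
# cells (suitable split evenly-ish across low/medium/high).
make_area_report <- function(valid, suitable, cell_area = 1,
                             scenario = "current", period = "current") {
  low <- suitable %/% 3
  med <- suitable %/% 3
  high <- suitable - low - med
  cls <- rep(1:4, times = c(valid - suitable, low, med, high))
  cls <- array(cls)
  attr(cls, "labels") <- c("non", "low", "medium", "high")
  class_areas(cls, cell_area, scenario = scenario, period = period)
}

random_scoresheet <- function() {
  risk_scoresheet("sp", stats::setNames(stats::runif(14, 0, 4),
                                        invascape:::RISK_CODES))
}
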