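#' Fisher-Jenks natural breaks
#'
#' Exact dynamic-programming optimum of the one-dimensional natural-breaks
#' problem: partition the sorted values into `k` contiguous classes
#' minimizing the total within-class sum of squared deviations. For inputs
#' larger than `max_n`, a seeded subsample of `max_n` values is classified
#' exactly and the resulting breaks applied to the full data.
#'
#' Breaks are reported as midpoints between the boundary values of
#' adjacent classes, so classifying with left-closed intervals reproduces
#' the optimal assignment.
#'
#' @param values numeric vector with at least `k` distinct finite values
#'   (`NA` ignored).
#' @param k number of classes (default 4: non / low / medium / high).
#' @param labels class labels, lowest to highest (length `k`).
#' @param max_n exact-DP size cap; larger inputs are subsampled.
#' @param seed RNG seed for the subsample.
#' @return object of class `jenks_breaks`: list with `breaks` (k - 1
#'   ascending thresholds), `k`, `labels`, and `ssd` (within-class sum of
#'   squares attained on the classified sample).
#' @export
jenks_breaks <- function(values, k = 4L,
                         labels = c("non", "low", "medium", "high"),
                         max_n = 10000L, seed = 42L) {
  x <- values[is.finite(values)]
  if (length(unique(x)) < k) {
    stop("need at least ", k, " distinct values for ", k, " classes",
         call. = FALSE)
  }
  if (length(labels) != k) labels <- paste0("class", seq_len(k))
  if (length(x) > max_n) {
    x <- with_seed(seed, sample(x, max_n))
    if (length(unique(x)) < k) {  # pathological subsample; top up
      extra <- setdiff(sort(unique(values[is.finite(values)])), unique(x))
      x <- c(x, extra[seq_len(min(k, length(extra)))])
    }
  }
  x <- sort(x)
  n <- length(x)
  # DP over prefix sums: ssd(i, j) = within-class SSD of x[i..j]
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  cost <- matrix(Inf, k, n)     # cost[c, j]: best SSD of x[1..j] in c classes
  cut <- matrix(0L, k, n)       # first index of the last class
  cost[1L, ] <- cs2[-1L] - cs[-1L]^2 / seq_len(n)
  cut[1L, ] <- 1L
  for (cl in 2L:k) {
    for (j in cl:n) {
      i <- cl:j                     # candidate starts of the last class
      s <- cs[j + 1L] - cs[i]
      ssd_last <- cs2[j + 1L] - cs2[i] - s^2 / (j - i + 1L)
      v <- cost[cl - 1L, i - 1L] + ssd_last
      arg <- which.min(v)
      cost[cl, j] <- v[arg]
      cut[cl, j] <- i[arg]
    }
  }
  # recover class boundaries
  bounds <- integer(k - 1L)
  j <- n
  for (cl in k:2L) {
    i <- cut[cl, j]
    bounds[cl - 1L] <- i    # first index of class `cl`
    j <- i - 1L
  }
  breaks <- (x[bounds - 1L] + x[bounds]) / 2
  structure(list(breaks = breaks, k = k, labels = labels,
                 ssd = cost[k, n]),
            class = "jenks_breaks")
}

#' @export
print.jenks_breaks <- function(x, ...) {
  cat("Natural breaks (", x$k, " classes): ",
      paste(format(x$breaks, digits = 4), collapse = ", "),
      "  [SSD ", format(x$ssd, digits = 5), "]\n", sep = "")
  invisible(x)
}

#' Classify a suitability surface by breaks
#'
#' Classes are left-closed/right-open intervals, with the top class
#' closed above: `[min, b1)`, `[b1, b2)`, ..., `[b_{k-1}, max]`. Nodata
#' (`NA`) is preserved.
#'
#' @param surface numeric matrix (or vector) of suitabilities.
#' @param breaks a [jenks_breaks()] object or a numeric vector of
#'   ascending thresholds.
#' @return integer matrix/vector of class indices `1..k` with `NA`
#'   preserved; attribute `labels` carries the class labels.
#' @export
classify_surface <- function(surface, breaks) {
  b <- if (inherits(breaks, "jenks_breaks")) breaks$breaks else breaks
  labels <- if (inherits(breaks, "jenks_breaks")) breaks$labels else
    paste0("class", seq_len(length(b) + 1L))
  if (is.unsorted(b, strictly = TRUE)) {
    stop("breaks must be strictly ascending", call. = FALSE)
  }
  cls <- rep(NA_integer_, length(surface))
  ok <- !is.na(surface)
  cls[ok] <- 1L + rowSums(outer(as.numeric(surface[ok]), b, ">="))
  if (is.matrix(surface)) {
    cls <- matrix(cls, nrow(surface), ncol(surface))
  }
  attr(cls, "labels") <- labels
  cls
}

#' Per-class habitat areas
#'
#' Multiplies class cell counts by the cell area. The total-suitable
#' percentage pools every class above the first ("non-suitable") level.
#'
#' @param classified a [classify_surface()] result.
#' @param cell_area_km2 area of one cell in km^2.
#' @param scenario,period tags carried into the report (e.g.
#'   `"SSP1-2.6"`, `"2070s"`).
#' @return object of class `area_report`: data.frame with `class`,
#'   `label`, `cells`, `area_km2`, `percent`, plus attributes
#'   `total_suitable_percent`, `valid_cells`, `scenario`, `period`.
#' @export
class_areas <- function(classified, cell_area_km2,
                        scenario = "current", period = "current") {
  labels <- attr(classified, "labels")
  k <- length(labels)
  counts <- tabulate(as.integer(classified)[!is.na(classified)], nbins = k)
  valid <- sum(counts)
  if (valid == 0L) stop("no valid cells to report", call. = FALSE)
  rep_df <- data.frame(
    class = seq_len(k), label = labels, cells = counts,
    area_km2 = counts * cell_area_km2,
    percent = 100 * counts / valid
  )
  structure(rep_df,
            total_suitable_percent = 100 * sum(counts[-1L]) / valid,
            valid_cells = valid, cell_area_km2 = cell_area_km2,
            scenario = scenario, period = period,
            class = c("area_report", "data.frame"))
}

#' Area change between two scenarios
#'
#' Future minus current per-class areas (km^2) and the change of the
#' total-suitable percentage in points. Requires matching grids (same
#' valid-cell count and cell area).
#'
#' @param current,future [class_areas()] reports on the same domain.
#' @return object of class `scenario_delta`: data.frame with `class`,
#'   `label`, `delta_km2`; attribute `delta_total_percent` (points).
#' @export
scenario_delta <- function(current, future) {
  if (attr(current, "valid_cells") != attr(future, "valid_cells") ||
      attr(current, "cell_area_km2") != attr(future, "cell_area_km2")) {
    stop("reports are not on the same grid domain", call. = FALSE)
  }
  out <- data.frame(class = current$class, label = current$label,
                    delta_km2 = future$area_km2 - current$area_km2)
  structure(out,
            delta_total_percent = attr(future, "total_suitable_percent") -
              attr(current, "total_suitable_percent"),
            scenario = attr(future, "scenario"),
            period = attr(future, "period"),
            class = c("scenario_delta", "data.frame"))
}

#' Tabulate total-suitable percentages across scenario reports
#'
#' @param reports list of [class_areas()] reports.
#' @return data.frame with `scenario`, `period`,
#'   `total_suitable_percent`, `total_suitable_km2`, and logical
#'   `is_max` flagging the maximum total-suitable percentage.
#' @export
scenario_table <- function(reports) {
  stopifnot(length(reports) >= 1L)
  rows <- lapply(reports, function(r) {
    data.frame(scenario = attr(r, "scenario"), period = attr(r, "period"),
               total_suitable_percent = attr(r, "total_suitable_percent"),
               total_suitable_km2 = sum(r$area_km2[-1L]))
  })
  out <- do.call(rbind, rows)
  out$is_max <- out$total_suitable_percent ==
    max(out$total_suitable_percent)
  rownames(out) <- NULL
  out
}
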