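#' Invasion risk scoring
#'
#' A weighted multi-criteria scoring system for invasive alien species.
#' Fourteen expert-assigned indicator scores, each on a `[0, 4]` scale, are
#' aggregated into four component scores and one composite:
#'
#' * `P1` (introduction and colonization risk) — weighted sum
#'   `0.3 P11 + 0.3 P12 + 0.2 P13 + 0.2 P14` over environmental
#'   suitability, food factor suitability, growth/reproduction traits, and
#'   natural enemies;
#' * `P2` (spread risk) — geometric mean `(P21 P22 P23 P24)^(1/4)` over
#'   distribution, existing management, spread capacity, and suitable
#'   habitat range;
#' * `P3` (potential hazards and impacts) — `max(P31, P32, P33)` over
#'   socio-economic impact, ecological impact, and importance of affected
#'   targets;
#' * `P4` (hazard control) — arithmetic mean `(P41 + P42 + P43) / 3` over
#'   difficulty of identification, monitoring, and control;
#' * composite `P = (P1 P2 P3 P4)^(1/4)`.
#'
#' Composite scores in `[2.8, 4.0]` are level 1 (high risk), `[1.2, 2.8)`
#' level 2 (medium), `[0, 1.2)` level 3 (low); boundary ties go to the
#' higher-risk level.
#'
#' @name risk-scoring
NULL

RISK_CODES <- c("P11", "P12", "P13", "P14",
                "P21", "P22", "P23", "P24",
                "P31", "P32", "P33",
                "P41", "P42", "P43")

#' Construct a risk scoresheet
#'
#' @param species species name.
#' @param indicators named numeric vector or list with exactly one value
#'   per indicator code `P11...P43`, each in `scale`.
#' @param scale length-2 numeric, the closed score range (default
#'   `c(0, 4)`).
#' @return an object of class `risk_scoresheet`.
#' @export
risk_scoresheet <- function(species, indicators, scale = c(0, 4)) {
  ind <- unlist(indicators)
  missing <- setdiff(RISK_CODES, names(ind))
  if (length(missing) > 0L) {
    stop("scoresheet is missing indicator(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(ind), RISK_CODES)
  if (length(extra) > 0L) {
    stop("unknown indicator code(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  ind <- ind[RISK_CODES]
  if (any(!is.finite(ind)) || any(ind < scale[1]) || any(ind > scale[2])) {
    bad <- RISK_CODES[!is.finite(ind) | ind < scale[1] | ind > scale[2]]
    stop("indicator(s) outside [", scale[1], ", ", scale[2], "]: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(species = species, indicators = ind,
                 scale = as.numeric(scale)),
            class = "risk_scoresheet")
}

#' Read / write scoresheets as JSON
#'
#' JSON layout: `{"species": ..., "scale": [0, 4],
#' "indicators": {"P11": 3, ...}}`.
#'
#' @param path JSON file path.
#' @return [risk_scoresheet()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_risk_scoresheet <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_scoresheet(x$species, x$indicators,
                  scale = if (!is.null(x$scale)) x$scale else c(0, 4))
}

#' @rdname read_risk_scoresheet
#' @param sheet a [risk_scoresheet()].
#' @export
write_risk_scoresheet <- function(sheet, path) {
  jsonlite::write_json(
    list(species = sheet$species, scale = sheet$scale,
         indicators = as.list(sheet$indicators)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

ind <- function(sheet, code) unname(sheet$indicators[[code]])

#' Component scores of the risk system
#'
#' @param sheet a [risk_scoresheet()].
#' @return the component score (numeric scalar).
#' @export
score_introduction <- function(sheet) {
  0.3 * ind(sheet, "P11") + 0.3 * ind(sheet, "P12") +
    0.2 * ind(sheet, "P13") + 0.2 * ind(sheet, "P14")
}

#' @rdname score_introduction
#' @export
score_spread <- function(sheet) {
  v <- c(ind(sheet, "P21"), ind(sheet, "P22"),
         ind(sheet, "P23"), ind(sheet, "P24"))
  if (any(v < 0)) stop("spread indicators must be >= 0", call. = FALSE)
  prod(v)^(1 / 4)
}

#' @rdname score_introduction
#' @export
score_impact <- function(sheet) {
  max(ind(sheet, "P31"), ind(sheet, "P32"), ind(sheet, "P33"))
}

#' @rdname score_introduction
#' @export
score_control <- function(sheet) {
  (ind(sheet, "P41") + ind(sheet, "P42") + ind(sheet, "P43")) / 3
}

#' Composite risk score
#'
#' Geometric mean of the four component scores.
#'
#' @param P1,P2,P3,P4 component scores (each >= 0).
#' @return composite `P = (P1 P2 P3 P4)^(1/4)`.
#' @export
composite_score <- function(P1, P2, P3, P4) {
  v <- c(P1, P2, P3, P4)
  if (any(v < 0)) stop("component scores must be >= 0", call. = FALSE)
  prod(v)^(1 / 4)
}

#' Risk level from a composite score
#'
#' @param P composite score in `[0, upper]`.
#' @param thresholds ascending length-2 numeric `(t_low, t_high)`; scores
#'   `>= t_high` are level 1, `>= t_low` level 2, below level 3.
#' @param upper top of the score scale.
#' @return integer level 1 (high), 2 (medium) or 3 (low).
#' @export
classify_level <- function(P, thresholds = c(1.2, 2.8), upper = 4) {
  if (any(!is.finite(P)) || any(P < 0) || any(P > upper)) {
    stop("composite score must lie in [0, ", upper, "]", call. = FALSE)
  }
  ifelse(P >= thresholds[2], 1L, ifelse(P >= thresholds[1], 2L, 3L))
}

#' Full risk assessment of a scoresheet
#'
#' @param sheet a [risk_scoresheet()].
#' @return object of class `risk_result`: list with `species`, `P1`, `P2`,
#'   `P3`, `P4`, `P` (unrounded), and `level`. Rounding to 2 decimals is a
#'   display concern only (`print` method).
#' @export
assess <- function(sheet) {
  P1 <- score_introduction(sheet)
  P2 <- score_spread(sheet)
  P3 <- score_impact(sheet)
  P4 <- score_control(sheet)
  P <- composite_score(P1, P2, P3, P4)
  structure(list(species = sheet$species, P1 = P1, P2 = P2, P3 = P3,
                 P4 = P4, P = P,
                 level = classify_level(P, upper = sheet$scale[2])),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat("Invasion risk assessment:", x$species, "\n")
  cat(sprintf("  P1 (introduction) = %.2f\n", x$P1))
  cat(sprintf("  P2 (spread)       = %.2f\n", x$P2))
  cat(sprintf("  P3 (impact)       = %.2f\n", x$P3))
  cat(sprintf("  P4 (control)      = %.2f\n", x$P4))
  cat(sprintf("  composite P = %.2f -> level %d (%s risk)\n", x$P, x$level,
              c("high", "medium", "low")[x$level]))
  invisible(x)
}
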