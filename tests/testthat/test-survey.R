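test_that("survey CSV round-trips and validates", {
  sv <- make_plot("p1", c("a", "b"), abundance = c(3, 1),
                  height = c(100, 50), cover = c(0.5, 0.2),
                  family = c("famA", "famB"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(sv, path)
  back <- read_survey(path)
  expect_s3_class(back, "survey_data")
  expect_equal(nrow(back), 2L)
  expect_equal(back$cover, c(0.5, 0.2))
  expect_equal(length(unique(back$plot_id)), 1L)

  # malformed input: missing column, negative height
  raw <- utils::read.csv(path)
  utils::write.csv(raw[setdiff(names(raw), "abundance")], path,
                   row.names = FALSE)
  expect_error(read_survey(path), "abundance")
  raw$height_cm[2] <- -5
  utils::write.csv(raw, path, row.names = FALSE)
  expect_error(read_survey(path), "row")
})

test_that("relative metrics normalize per plot and average into importance", {
  sv <- make_plot("p1", c("s1", "s2", "s3"), abundance = c(1, 1, 1),
                  height = c(100, 50, 50), cover = c(0.2, 0.2, 0.2))
  rm <- relative_metrics(sv)
  expect_equal(rm$rel_height, c(0.5, 0.25, 0.25))
  expect_equal(sum(rm$rel_cover), 1, tolerance = 1e-9)
  expect_equal(sum(rm$rel_abundance), 1, tolerance = 1e-9)

  # hand-evaluated importance: heights (2,1), covers (1,1), abund (3,1)
  sv2 <- make_plot("p2", c("s1", "s2"), abundance = c(3, 1),
                   height = c(2, 1), cover = c(1, 1))
  rm2 <- relative_metrics(sv2)
  expect_equal(rm2$importance[1], (2 / 3 + 1 / 2 + 3 / 4) / 3,
               tolerance = 1e-12)

  # single species: everything is 1
  one <- relative_metrics(make_plot("p3", "s", 5, 30, 0.4))
  expect_equal(one$importance, 1)

  # all-zero metric flagged, not fatal
  z <- make_plot("p4", c("s1", "s2"), abundance = c(1, 1),
                 height = c(0, 0), cover = c(0.1, 0.1))
  expect_warning(rmz <- relative_metrics(z), "height")
  expect_equal(rmz$rel_height, c(0, 0))
})

test_that("Shannon index matches hand values and the vegan oracle", {
  expect_equal(shannon_index(make_plot("p", paste0("s", 1:4),
                                       abundance = rep(5, 4),
                                       height = rep(10, 4),
                                       cover = rep(0.1, 4)))$shannon,
               log(4), tolerance = 1e-12)
  expect_equal(shannon_index(make_plot("p", "s", 3, 10, 0.1))$shannon, 0)
  h <- shannon_index(make_plot("p", c("a", "b", "c"),
                               abundance = c(2, 1, 1),
                               height = rep(10, 3),
                               cover = rep(0.1, 3)))$shannon
  expect_equal(h, 1.03972, tolerance = 1e-5)
  skip_if_not_installed("vegan")
  expect_equal(h, unname(vegan::diversity(c(2, 1, 1))), tolerance = 1e-12)
  expect_error(shannon_index(make_plot("p", "s", 0, 10, 0.1)),
               "abundance")
})

test_that("occurrence rate reproduces direct fractions", {
  sv <- make_occurrence_survey(595, 403)
  r <- occurrence_rate(sv, "Solidago canadensis")
  expect_equal(r$presences, 403L)
  expect_equal(r$plots, 595L)
  expect_equal(round(r$rate, 1), 67.7)

  expect_equal(occurrence_rate(sv, "never_seen")$rate, 0)
  sv3 <- make_occurrence_survey(3, 1)
  expect_equal(round(occurrence_rate(sv3, "Solidago canadensis")$rate, 1),
               33.3)
})

test_that("family composition merges rare families and sums to 100", {
  sv <- make_plot("p1", paste0("s", 1:10), abundance = rep(1, 10),
                  height = rep(10, 10), cover = rep(0.05, 10),
                  family = c(rep("famA", 5), rep("famB", 4), "famC"))
  fc <- family_composition(sv)
  expect_equal(fc$percent[fc$family == "famA"], 50)
  expect_equal(sum(fc$percent), 100, tolerance = 1e-6)

  # a 1-in-205 family (0.49%) is merged into "others"
  fam205 <- c(rep("big", 204), "tiny")
  sv205 <- make_plot("p1", sprintf("s%03d", 1:205),
                     abundance = rep(1, 205), height = rep(10, 205),
                     cover = rep(0.004, 205), family = fam205)
  fc205 <- family_composition(sv205)
  expect_true("others" %in% fc205$family)
  expect_false("tiny" %in% fc205$family)
  expect_equal(sum(fc205$percent), 100, tolerance = 1e-6)

  # degenerate: one family only
  svone <- make_plot("p1", c("a", "b"), abundance = c(1, 1),
                     height = c(1, 1), cover = c(0.1, 0.1),
                     family = c("solo", "solo"))
  expect_equal(family_composition(svone)$percent, 100)

  # unmapped species flagged into "unknown"
  svna <- make_plot("p1", c("a", "b"), abundance = c(1, 1),
                    height = c(1, 1), cover = c(0.1, 0.1),
                    family = c("famA", NA))
  expect_warning(fcna <- family_composition(svna), "unknown")
  expect_true("unknown" %in% fcna$family)
})

test_that("Welch t test matches hand evaluation and tiers p-values", {
  r <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(r$t), 3.674, tolerance = 1e-3)
  expect_equal(r$df, 4, tolerance = 1e-9)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  expect_equal(significance_tier(c(0.2, 0.04, 0.009, 0.0009)),
               c("ns", "*", "**", "***"))
})

test_that("community summary partitions plots by dominant species", {
  sv <- make_typed_survey(community_type_counts)
  cs <- community_summary(sv)
  expect_equal(nrow(cs), 12L)
  expect_equal(sum(cs$n_plots), 595L)
  expect_equal(cs$n_plots, sort(community_type_counts, decreasing = TRUE))

  single <- community_summary(make_plot("p1", c("a", "b"),
                                        abundance = c(5, 1),
                                        height = c(50, 5),
                                        cover = c(0.5, 0.1)))
  expect_equal(nrow(single), 1L)
  expect_equal(single$dominant, "a")
  expect_equal(single$n_plots, 1L)
})

test_that("survey-wide diversity helper agrees with per-plot computation", {
  st <- gen_landscape(n_rows = 25, n_cols = 25, seed = 3)
  sv <- gen_survey(st, n_plots = 40, seed = 3)
  div <- invascape:::survey_diversity(sv)
  for (id in div$plot_id[c(1, 10, 25)]) {
    one <- shannon_index(sv[sv$plot_id == id, ])
    expect_equal(div$shannon[div$plot_id == id], one$shannon,
                 tolerance = 1e-12)
  }
  expect_true(all(div$shannon <= log(div$richness) + 1e-12))
  expect_true(all(div$shannon >= 0))
})
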