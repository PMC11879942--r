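make_cohort_df <- function() {
  set.seed(3)
  g <- rep(c("Sham", "HTN-CM"), each = 30)
  p <- rep(rep(PATTERN_LEVELS <- c("EA_SEPARATION", "EA_HALF_SEPARATION",
                                   "EA_FUSION"), each = 10), 2)
  data.frame(group = g, pattern = p,
             pattern_code = match(p, PATTERN_LEVELS),
             hr = rnorm(60, 330, 40),
             y = rnorm(60, 10 + 2 * (g == "HTN-CM") + match(p, PATTERN_LEVELS)))
}

test_that("Pearson against the coded pattern matches the textbook formula", {
  d <- make_cohort_df()
  expect_equal(cohort_pearson(d, "pattern_code")$r, 1)
  d2 <- data.frame(pattern_code = c(1, 2, 3), y = c(6, 4, 2), hr = 1:3)
  expect_equal(cohort_pearson(d2, "y")$r, -1)
  res <- cohort_pearson(d, "y", against = "pattern_code")
  expect_equal(res$r, r_brute(d$y, d$pattern_code), tolerance = 1e-12)
  expect_equal(res$p, p_brute(res$r, nrow(d)), tolerance = 1e-12)
  res_hr <- cohort_pearson(d, "y", against = "hr")
  expect_equal(res_hr$r, r_brute(d$y, d$hr), tolerance = 1e-12)
  d$z <- 5
  expect_error(cohort_pearson(d, "z"), "degenerate")
  expect_error(cohort_pearson(d[1:2, ], "y"), "at least 3")
})

test_that("a null factor in a balanced design gets F = 0", {
  cells <- expand.grid(group = c("Sham", "HTN-CM"),
                       pattern = c("EA_SEPARATION", "EA_HALF_SEPARATION",
                                   "EA_FUSION"))
  d <- cells[rep(seq_len(6), each = 4), ]
  d$pattern_code <- match(d$pattern, c("EA_SEPARATION", "EA_HALF_SEPARATION",
                                       "EA_FUSION"))
  # outcome depends on pattern only; within-cell +/-1 keeps MSE > 0 and
  # leaves every group marginal identical
  d$y <- d$pattern_code * 3 + rep(c(-1, 1), 12)
  a <- two_way_anova(d, "y")
  expect_equal(a$statistic[a$term == "group"], 0, tolerance = 1e-12)
  expect_gt(a$statistic[a$term == "pattern"], 1)
  expect_equal(a$statistic[a$term == "group:pattern"], 0, tolerance = 1e-12)
})

test_that("single-group cohorts drop the group factor with a warning", {
  d <- make_cohort_df()
  d1 <- d[d$group == "Sham", ]
  expect_warning(a <- two_way_anova(d1, "y"), "single group")
  expect_true("pattern" %in% a$term)
  expect_false("group" %in% a$term)
})

test_that("Tukey pairwise p-values match a direct studentized-range computation", {
  sim <- generate_cohort(small_cfg(seed = 5L, n = 4L), keep_maps = FALSE)
  d <- sim$cohort
  tl <- tukey_letters(d, "e_over_eprime")
  cell <- interaction(factor(d$group, c("Sham", "HTN-CM")),
                      factor(d$pattern, c("EA_SEPARATION",
                                          "EA_HALF_SEPARATION", "EA_FUSION")),
                      sep = ":", lex.order = TRUE)
  means <- tapply(d$e_over_eprime, cell, mean)
  ns <- tapply(d$e_over_eprime, cell, length)
  k <- nlevels(cell)
  df_res <- nrow(d) - k
  mse <- sum(tapply(d$e_over_eprime, cell, function(v)
    sum((v - mean(v))^2))) / df_res
  for (i in seq_len(nrow(tl$pairwise))) {
    c1 <- tl$pairwise$cell1[i]
    c2 <- tl$pairwise$cell2[i]
    q <- abs(means[[c1]] - means[[c2]]) /
      sqrt(mse / 2 * (1 / ns[[c1]] + 1 / ns[[c2]]))
    expect_equal(tl$pairwise$p[i],
                 stats::ptukey(q, k, df_res, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("compact letters separate a far-shifted cell and join identical ones", {
  d <- data.frame(
    group = "Sham",
    pattern = rep(c("EA_SEPARATION", "EA_HALF_SEPARATION", "EA_FUSION"),
                  each = 4),
    pattern_code = rep(1:3, each = 4),
    y = c(1, 2, 1, 2, 1, 2, 1, 2, 101, 102, 101, 102))
  tl <- tukey_letters(d, "y")
  lt <- tl$letters
  expect_equal(lt[["Sham:EA_FUSION"]], "a")
  expect_equal(lt[["Sham:EA_SEPARATION"]], lt[["Sham:EA_HALF_SEPARATION"]])
  expect_false(lt[["Sham:EA_FUSION"]] == lt[["Sham:EA_SEPARATION"]])
})

test_that("the full report is deterministic and invariant to row order", {
  sim <- generate_cohort(small_cfg(seed = 9L, n = 4L), keep_maps = FALSE)
  rep1 <- run_full_analysis(sim$cohort)
  perm <- sim$cohort[sample(nrow(sim$cohort)), ]
  rep2 <- run_full_analysis(perm)
  expect_equal(rep1$pearson, rep2$pearson, tolerance = 1e-10)
  expect_equal(rep1$cell_table, rep2$cell_table)
  expect_equal(lapply(rep1$anova, `[[`, "p"),
               lapply(rep2$anova, `[[`, "p"), tolerance = 1e-10)
  expect_s3_class(rep1, "stats_report")
  expect_true(all(abs(rep1$pearson$r) <= 1))
  expect_true(all(rep1$pearson$p >= 0 & rep1$pearson$p <= 1))
  # rendered 6-cell table covers every outcome
  expect_equal(ncol(rep1$cell_table), 7)
  expect_output(print(rep1), "Pearson")
})
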