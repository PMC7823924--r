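test_that("25(OH)D categories use the stated boundaries and tie rule", {
  got <- categorize25OHD(c(24.9, 25.0, 49.9, 50.0, 74.9, 75.0, 75.1))
  expect_equal(as.character(got),
               c("<25", ">=25 and <50", ">=25 and <50", ">=50 and <75",
                 ">=50 and <75", ">=50 and <75", ">75"))
  expect_equal(levels(got)[1], "<25")          # reference level
  expect_error(categorize25OHD(c(30, 0)), "positive")
})

test_that("a null cohort yields odds ratios near one on both exposure forms", {
  co <- simulateObservationalCohort(25000, orPer50 = 1, confounding = 0,
                                    seed = 101)
  fit <- fitTieredLogistic(co, "continuous", "basic")
  expect_true(fit$ci_low < 1 && 1 < fit$ci_high)
  cat <- fitTieredLogistic(co, "categorical", "basic")
  expect_equal(cat$or[1], 1)                   # reference by construction
  expect_true(is.na(cat$pval[1]))
})

test_that("adjustment attenuates a confounded estimate toward the injected effect", {
  co <- simulateObservationalCohort(40000, orPer50 = 0.95, confounding = 1,
                                    seed = 202)
  basic <- fitTieredLogistic(co, "continuous", "basic")
  ses <- fitTieredLogistic(co, "continuous", "socioeconomic")
  life <- fitTieredLogistic(co, "continuous", "lifestyle")
  expect_lt(basic$or, ses$or)                  # monotone attenuation
  expect_lt(ses$or, life$or)
  expect_lt(abs(log(life$or) - log(0.95)), abs(log(basic$or) - log(0.95)))
  # categorical form agrees in direction: protective across top categories
  cat <- fitTieredLogistic(co, "categorical", "lifestyle")
  expect_true(all(cat$or[-1] < 1))
})

test_that("curvature and interaction tests are calibrated under the null and detect signal", {
  # null: linear effect only; p-values should not pile up near zero
  ps <- sapply(1:40, function(i) {
    co <- simulateObservationalCohort(3000, orPer50 = 0.9, confounding = 0,
                                      seed = 500 + i)
    trendCurvatureInteraction(co, "basic")
  })
  expect_lte(mean(ps["pCurvature", ] < 0.05), 0.15)
  expect_lte(mean(ps["pInteractionSex", ] < 0.05), 0.15)
  expect_gt(mean(ps["pCurvature", ]), 0.25)

  # strong injected effect drives the trend test
  co <- simulateObservationalCohort(20000, orPer50 = 0.85, confounding = 0,
                                    seed = 77)
  p <- trendCurvatureInteraction(co, "basic")
  expect_lt(p["pTrend"], 1e-6)

  # injected curvature is detected: rebuild outcome with a quadratic term
  co2 <- simulateObservationalCohort(20000, orPer50 = 1, confounding = 0,
                                     seed = 88)
  eta <- -1.9 + 1.2 * (co2$ln_25ohd - mean(co2$ln_25ohd))^2
  set.seed(89)
  co2$depression <- rbinom(nrow(co2), 1, plogis(eta))
  p2 <- trendCurvatureInteraction(co2, "basic")
  expect_lt(p2["pCurvature"], 1e-6)
})

test_that("prevalence tabulation matches hand counts and is row-order invariant", {
  co <- simulateObservationalCohort(8000, orPer50 = 0.9, confounding = 1,
                                    seed = 55)
  tab <- tabulatePrevalence(co, "sex")
  expect_equal(sum(tab$n), nrow(co))
  expect_equal(tab$n[tab$group == "female"],
               sum(co$sex == "female"))
  expect_equal(tab$cases[tab$group == "male"],
               sum(co$depression[co$sex == "male"]))
  expect_lt(abs(sum(tab$pct) - 100), 0.11)     # conservation up to rounding
  shuffled <- co[sample(nrow(co)), ]
  expect_equal(tabulatePrevalence(shuffled, "sex"), tab)

  one <- co[1, ]
  t1 <- tabulatePrevalence(one, "sex")
  expect_equal(t1$pct[t1$n == 1], 100)
  expect_equal(t1$n[t1$group != one$sex], 0)   # empty group emitted
})

test_that("percentages from printed counts use half-up rounding to one decimal", {
  counts <- data.frame(group = c("Male", "Female"),
                       n = c(116698, 113134),
                       cases = c(11292, 18855))
  got <- tabulateCounts(counts)
  expect_equal(got$pct, c(50.8, 49.2))
  expect_equal(got$casePct, c(9.7, 16.7))
  # explicit half-up behaviour where half-even would round down
  expect_equal(tabulateCounts(data.frame(group = "g", n = 1225),
                              total = 10000)$pct, 12.3)
})
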