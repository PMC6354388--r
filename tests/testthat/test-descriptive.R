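test_that("prevalence_table counts and partitions", {
  ds <- data.frame(outcome = c(rep(1, 3), rep(0, 7)),
                   region = rep(c("A", "B"), 5))
  overall <- prevalence_table(ds)
  expect_equal(overall$percent, 30)
  expect_equal(overall$n, 10)

  by_reg <- prevalence_table(ds, by = "region")
  expect_equal(sum(by_reg$cut), overall$cut)
  expect_equal(sum(by_reg$n), overall$n)
  expect_error(prevalence_table(ds[0, ]), "empty")
  expect_error(prevalence_table(ds, by = "nope"), "unknown grouping")

  # hotspot region floats to the top of simulated prevalences
  g <- sn_region_graph(1)
  dsh <- small_survey(seed = 21, women_target = 8000, hotspot = "Matam",
                      hotspot_effect = 2.5)
  pt <- prevalence_table(dsh, by = "region")
  expect_equal(pt$region[which.max(pt$percent)], "Matam")
})

test_that("cumulative age-at-cutting arithmetic", {
  expect_equal(cumulative_age_at_cutting(c(63.3, 9.5, 14.9, 5.1, 0.9)),
               c(63.3, 72.8, 87.7, 92.8, 93.7))
  expect_equal(cumulative_age_at_cutting(c(61.7, 9.5, 13.8, 6.0, 0.7)),
               c(61.7, 71.2, 85.0, 91.0, 91.7))
  expect_equal(cumulative_age_at_cutting(rep(0, 4)), rep(0, 4))
  expect_error(cumulative_age_at_cutting(c(5, -1)), "non-negative")
  # monotone, bounded by 100 when inputs sum <= 100
  set.seed(3)
  for (i in 1:20) {
    x <- diff(sort(c(0, runif(5, 0, 100), 100)))[1:5]
    cum <- cumulative_age_at_cutting(x)
    expect_true(all(diff(cum) >= 0))
    expect_lte(cum[length(cum)], 100)
  }
})

test_that("unadjusted ORs match the cross-product and Wald closed form", {
  mk <- function(a, b, c, d) {
    data.frame(outcome = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
               exposed = c(rep("yes", a + b), rep("no", c + d)))
  }
  r <- unadjusted_or(mk(10, 10, 10, 10), "exposed", reference = "no")
  expect_equal(r$or[r$level == "yes"], 1)

  r2 <- unadjusted_or(mk(20, 10, 10, 20), "exposed", reference = "no")
  expect_equal(r2$or[r2$level == "yes"], 4)
  # frozen Wald CI: exp(log 4 +/- 1.96... * sqrt(0.25+0.1+0.1+0.05))
  # computed with the closed form below, independently of the package
  z <- qnorm(0.975)
  se <- sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20)
  expect_equal(r2$ci_low[r2$level == "yes"], exp(log(4) - z * se),
               tolerance = 1e-12)
  expect_equal(r2$ci_high[r2$level == "yes"], exp(log(4) + z * se),
               tolerance = 1e-12)

  # zero cell triggers the flagged Haldane-Anscombe correction
  r3 <- unadjusted_or(mk(5, 0, 3, 7), "exposed", reference = "no")
  expect_true(r3$corrected[r3$level == "yes"])
  expect_true(is.finite(r3$or[r3$level == "yes"]))

  expect_error(unadjusted_or(mk(5, 5, 0, 0)[1:10, ], "exposed", "yes"),
               "single level")
})

test_that("binary-covariate OR equals the IRLS logistic coefficient", {
  set.seed(8)
  for (i in 1:5) {
    n <- 400
    x <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-0.5 + 0.9 * x))
    ds <- data.frame(outcome = y, xc = ifelse(x == 1, "yes", "no"))
    r <- unadjusted_or(ds, "xc", reference = "no")
    X <- cbind(1, x)
    beta <- irls_logit(X, y)
    expect_equal(r$or[r$level == "yes"], unname(exp(beta[2])),
                 tolerance = 1e-6)
  }
})

test_that("baseline table layout and partition property", {
  ds <- small_survey(seed = 31, women_target = 2500)
  bt <- baseline_table(ds)
  # ages {20,30,40}: mean 30, sd 10 via the same code path
  toy <- as.data.frame(ds)[1:3, ]
  toy$age <- c(20L, 30L, 40L)
  toy$outcome <- c(0L, 1L, 0L)
  bt_toy <- baseline_table(validate_dataset(toy))
  expect_equal(bt_toy$overall[bt_toy$variable == "age"], 30)
  expect_equal(bt_toy$overall_sd[bt_toy$variable == "age"], 10)

  # categorical percents sum to 100 per column within rounding
  for (var in c("wealth", "ethnicity", "region")) {
    sub <- bt[bt$variable == var, ]
    expect_equal(sum(sub$overall), 100, tolerance = 1e-8)
    expect_equal(sum(sub$cut), 100, tolerance = 1e-8)
    expect_equal(sum(sub$uncut), 100, tolerance = 1e-8)
  }
  # all-married degenerate case
  toy2 <- as.data.frame(ds)[1:5, ]
  toy2$married <- 1L
  bt2 <- baseline_table(validate_dataset(toy2))
  expect_equal(bt2$overall[bt2$variable == "married" & bt2$level == "1"], 100)
})
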