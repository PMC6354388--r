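test_that("build_design shapes and errors", {
  g <- sn_region_graph(1)
  ds <- small_survey(seed = 51, women_target = 1200)
  spec <- model_spec(fixed = c(wealth = "richest", urban = "0"),
                     nonlinear = list(age = list(n_inner_knots = 8)),
                     include_structured = TRUE, include_unstructured = TRUE)
  bl <- build_design(ds, spec, g)
  expect_equal(sum(grepl("^wealth:", colnames(bl$W))), 4) # 5 levels - ref
  expect_equal(nrow(bl$W), bl$n)
  expect_true(all(rowSums(bl$B$age) - 1 < 1e-12))
  expect_equal(max(bl$region_idx), 11)
  expect_true(all(table(bl$region_idx) > 0))

  # intercept-only
  bl0 <- build_design(ds, model_spec(include_structured = FALSE,
                                     include_unstructured = FALSE), g)
  expect_equal(ncol(bl0$W), 0)

  # region in data but not graph
  g_small <- region_graph(g$labels[1:5],
                          g$adjacency[g$adjacency[, 1] %in% g$labels[1:5] &
                                      g$adjacency[, 2] %in% g$labels[1:5], ])
  expect_error(build_design(ds, spec, g_small), "not in graph")

  # unseen factor level
  ds_bad <- as.data.frame(ds)
  ds_bad$wealth[1] <- "gilded"
  expect_error(build_design(validate_dataset(ds_bad, g), spec, g), "unseen")

  # rows with missing model fields are dropped with a message
  spec_pa <- model_spec(fixed = c(partner_education = "higher"))
  expect_message(bl_pa <- build_design(ds, spec_pa, g), "dropping")
  expect_equal(bl_pa$n + bl_pa$n_dropped, nrow(ds))
})

test_that("boundary config: iterations == burn_in stores nothing", {
  g <- sn_region_graph(1)
  ds <- small_survey(seed = 52, women_target = 500)
  bl <- build_design(ds, model_spec(include_structured = FALSE,
                                    include_unstructured = FALSE), g)
  fit <- gibbs_fit(bl, config = mcmc_config(50, 50, 1, seed = 1))
  expect_equal(fit$n_stored, 0)
  expect_length(fit$intercept, 0)
})

test_that("intercept-only posterior matches 1-D quadrature oracle", {
  g <- region_graph(c("A", "B"), rbind(c("A", "B")))
  y <- c(rep(1, 30), rep(0, 70))
  ds <- data.frame(outcome = y, wave = 1L, region = rep(c("A", "B"), 50),
                   cluster = rep(c("A_c1", "B_c1"), 50),
                   household = "h", age = 30L, urban = 0L, married = 0L,
                   education = "none", partner_education = "none",
                   wealth = "middle", family_size = "small",
                   ethnicity = "Wolof", religion = "muslim",
                   partner_age = 40L)
  bl <- build_design(validate_dataset(ds, g),
                     model_spec(include_structured = FALSE,
                                include_unstructured = FALSE), g)
  fit <- gibbs_fit(bl, config = mcmc_config(3000, 500, 1, seed = 2))
  oracle <- quad_intercept_posterior(y)
  mc_se <- oracle$sd / sqrt(coda_ess(fit$intercept))
  expect_lt(abs(mean(fit$intercept) - oracle$mean), 3 * mc_se + 0.01)
  # posterior mean prevalence close to 0.3
  expect_lt(abs(mean(plogis(fit$intercept)) - 0.3), 0.05)
})

test_that("fixed-effects-only posterior approaches the IRLS MLE", {
  g <- sn_region_graph(1)
  ds <- small_survey(seed = 53, women_target = 5000)
  spec <- model_spec(fixed = c(urban = "0", wealth = "richest"),
                     nonlinear = list(),
                     include_structured = FALSE, include_unstructured = FALSE)
  bl <- build_design(ds, spec, g)
  fit <- gibbs_fit(bl, config = mcmc_config(1200, 300, 1, seed = 3))
  X <- cbind(1, bl$W)
  mle <- irls_logit(X, bl$y)
  post <- c(mean(fit$intercept), colMeans(fit$gamma))
  draws <- cbind(fit$intercept, fit$gamma)
  for (k in seq_along(post)) {
    mc_se <- sd(draws[, k]) / sqrt(coda_ess(draws[, k]))
    # MLE vs posterior mean differ O(1/n) too; allow 3 MC SEs + small slack
    expect_lt(abs(post[k] - mle[k]), 3 * mc_se + 0.02)
  }
})

test_that("stored draws respect sum-to-zero constraints and determinism", {
  g <- sn_region_graph(1)
  ds <- small_survey(seed = 54, women_target = 1500)
  spec <- model_spec(fixed = c(urban = "0"),
                     nonlinear = list(age = list(n_inner_knots = 6)))
  bl <- build_design(ds, spec, g)
  cfg <- mcmc_config(300, 100, 2, seed = 4)
  fit <- gibbs_fit(bl, config = cfg)
  expect_equal(fit$n_stored, 100)
  expect_true(all(abs(rowSums(fit$f_str)) < 1e-8))
  expect_true(all(abs(rowSums(fit$f_unstr)) < 1e-8))
  # spline: mean over observations of each stored curve is zero
  fitted_means <- fit$alpha$age %*% t(bl$B$age) |> rowMeans()
  expect_true(all(abs(fitted_means) < 1e-8))

  fit2 <- gibbs_fit(bl, config = cfg)
  expect_identical(fit$intercept, fit2$intercept)
  expect_identical(fit$f_str, fit2$f_str)
  expect_identical(fit$alpha$age, fit2$alpha$age)

  fit3 <- gibbs_fit(bl, config = mcmc_config(300, 100, 2, seed = 5))
  expect_false(identical(fit$intercept, fit3$intercept))
})

test_that("probit link runs and tracks the probit MLE", {
  g <- sn_region_graph(1)
  ds <- small_survey(seed = 55, women_target = 2500)
  spec <- model_spec(fixed = c(urban = "0"), nonlinear = list(),
                     include_structured = FALSE,
                     include_unstructured = FALSE, link = "probit")
  bl <- build_design(ds, spec, g)
  fit <- gibbs_fit(bl, config = mcmc_config(800, 200, 1, seed = 6))
  gl <- suppressWarnings(glm.fit(cbind(1, bl$W), bl$y,
                                 family = binomial("probit")))
  expect_lt(abs(mean(fit$intercept) - gl$coefficients[1]), 0.1)
  expect_lt(abs(mean(fit$gamma[, 1]) - gl$coefficients[2]), 0.15)
})

test_that("posterior predictive prevalence reproduces observed prevalence", {
  g <- sn_region_graph(1)
  ds <- small_survey(seed = 56, women_target = 1500)
  bl <- build_design(ds, model_spec(include_structured = FALSE,
                                    include_unstructured = FALSE), g)
  fit <- gibbs_fit(bl, config = mcmc_config(500, 200, 1, seed = 7))
  pp <- posterior_predictive_prevalence(fit, bl)
  # intercept-only: every region's prediction is the pooled prevalence
  expect_lt(max(abs(colMeans(pp) - mean(bl$y))), 0.05)

  # all-zero outcomes concentrate near 0
  bl0 <- bl
  bl0$y <- rep(0, bl$n)
  fit0 <- gibbs_fit(bl0, config = mcmc_config(500, 200, 1, seed = 8))
  expect_lt(max(posterior_predictive_prevalence(fit0, bl0)), 0.05)
  expect_error(gibbs_fit(bl0, y = rep(2, bl$n),
                         config = mcmc_config(50, 10, 1, seed = 9)),
               "binary")
})
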