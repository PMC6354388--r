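# a hand-built fit object lets the summary layer be tested without MCMC
fake_fit <- function(gamma_draws, f_str, f_unstr, labels = colnames(f_str),
                     spec = model_spec(fixed = c(urban = "0"))) {
  structure(list(
    intercept = rep(0, nrow(f_str)), gamma = gamma_draws,
    alpha = list(), f_str = f_str, f_unstr = f_unstr,
    tau2 = matrix(1, nrow(f_str), 2,
                  dimnames = list(NULL, c("tau2_str", "tau2_unstr"))),
    spline_meta = list(), labels = labels,
    comp = stats::setNames(rep(1L, length(labels)), labels),
    config = mcmc_config(10, 0, 1, seed = 1), spec = spec,
    n_stored = nrow(f_str),
    include_structured = TRUE, include_unstructured = TRUE),
    class = "geofgm_fit")
}

test_that("fixed_effect_por summarizes draws on the OR scale", {
  g <- matrix(0, 200, 2, dimnames = list(NULL, c("urban:1", "x:b")))
  g[, 2] <- log(2)
  f <- matrix(0, 200, 2, dimnames = list(NULL, c("A", "B")))
  fit <- fake_fit(g, f, f)
  por <- fixed_effect_por(fit)
  expect_equal(por$por[por$term == "urban:1"], 1)
  expect_equal(por$por[por$term == "x:b"], 2)
  expect_equal(por$ci_low[por$term == "x:b"], 2) # degenerate draws
  expect_true(any(grepl("\\(ref\\)", por$term)))
  expect_equal(por$por[grepl("\\(ref\\)", por$term)], 1)
  expect_error(fixed_effect_por(fit, level = 1.2), "level")
  # intervals contain their point estimate
  set.seed(2)
  g2 <- matrix(rnorm(400, 0.3, 0.5), 200, 2,
               dimnames = list(NULL, c("urban:1", "x:b")))
  por2 <- fixed_effect_por(fake_fit(g2, f, f))
  ok <- !grepl("ref", por2$term)
  expect_true(all(por2$ci_low[ok] <= por2$por[ok] &
                  por2$por[ok] <= por2$ci_high[ok]))
})

test_that("total_spatial_effect adds whichever blocks exist", {
  set.seed(3)
  fs <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  fu <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  fit <- fake_fit(matrix(0, 100, 0), fs, fu)
  expect_equal(total_spatial_effect(fit), fs + fu)
  fit$include_unstructured <- FALSE
  expect_equal(total_spatial_effect(fit), fs)
  fit$include_structured <- FALSE
  expect_error(total_spatial_effect(fit), "no spatial block")
})

test_that("classify_regions three-way categories and monotonicity", {
  set.seed(4)
  draws <- cbind(hot = rnorm(500, 1.5, 0.3), cold = rnorm(500, -2, 0.3),
                 grey = rnorm(500, 0, 0.3))
  cls <- classify_regions(draws, 0.95)
  expect_equal(cls$category, c("positive", "negative", "not_significant"))
  expect_true(all(cls$ci_low <= cls$por & cls$por <= cls$ci_high))
  expect_error(classify_regions(draws, 1.5), "nominal_level")

  # monotone in the nominal level: significant at 95% => significant at 90%
  for (seed in 1:10) {
    set.seed(seed)
    d <- matrix(rnorm(500 * 5, rep(seq(-1, 1, length.out = 5), each = 500),
                      0.6), 500, 5, dimnames = list(NULL, paste0("R", 1:5)))
    c95 <- classify_regions(d, 0.95)
    c90 <- classify_regions(d, 0.90)
    sig95 <- c95$category != "not_significant"
    sig90 <- c90$category != "not_significant"
    expect_true(all(!sig95 | sig90))
  }
})

test_that("curve_summary bands, nesting and range guard", {
  g <- sn_region_graph(1)
  ds <- small_survey(seed = 61, women_target = 2000)
  spec <- model_spec(nonlinear = list(age = list(n_inner_knots = 6)),
                     include_structured = FALSE,
                     include_unstructured = FALSE)
  bl <- build_design(ds, spec, g)
  fit <- gibbs_fit(bl, config = mcmc_config(400, 100, 2, seed = 62))
  cs80 <- curve_summary(fit, "age", grid = 15:49, level = 0.80)
  cs95 <- curve_summary(fit, "age", grid = 15:49, level = 0.95)
  expect_true(all(cs80$band_low <= cs80$mean & cs80$mean <= cs80$band_high))
  expect_true(all(cs95$band_low <= cs80$band_low + 1e-12))
  expect_true(all(cs80$band_high <= cs95$band_high + 1e-12))
  expect_error(curve_summary(fit, "age", grid = c(10, 20)), "outside")
  expect_error(curve_summary(fit, "height"), "not a fitted")
})

test_that("harmonize_waves merges subdivided regions correctly", {
  map <- c(A = "A", B1 = "B", B2 = "B", C = "C")
  s1 <- c(A = 30, B = 40, C = 10)
  s2 <- c(A = 28, B1 = 10, B2 = 20, C = 12)
  out <- harmonize_waves(s1, s2, map)
  expect_equal(out$wave2[out$region == "B"], 15) # unweighted mean
  expect_equal(out$difference[out$region == "A"], -2)
  # identity map reduces to plain differences
  id <- c(A = "A", B = "B")
  out2 <- harmonize_waves(c(A = 1, B = 2), c(A = 4, B = 2), id)
  expect_equal(out2$difference, c(3, 0))
  expect_error(harmonize_waves(s1, c(s2, Z = 1), map), "unmapped")
  # weighted alternative preserves the weighted mean
  outw <- harmonize_waves(s1, s2, map, weights = c(A = 1, B1 = 3, B2 = 1,
                                                   C = 1))
  expect_equal(outw$wave2[outw$region == "B"], (30 + 20) / 4)
  # totals preserved: mean of merged values = mean of inputs per parent
  expect_equal(out$wave2[out$region == "B"], mean(s2[c("B1", "B2")]))
})

test_that("export_choropleth falls back to a table and renders polygons", {
  cls <- data.frame(region = c("A", "B"), por = c(2, 0.5),
                    ci_low = c(1.2, 0.3), ci_high = c(3, 0.8),
                    category = c("positive", "negative"),
                    nominal_level = 0.95)
  expect_warning(out <- export_choropleth(cls), "tabular fallback")
  expect_identical(out, cls)

  geo <- data.frame(region = rep(c("A", "B"), each = 4),
                    x = c(0, 1, 1, 0, 1, 2, 2, 1),
                    y = c(0, 0, 1, 1, 0, 0, 1, 1))
  gf <- withr::local_tempfile(fileext = ".csv")
  write.csv(geo, gf, row.names = FALSE)
  img <- withr::local_tempfile(fileext = ".png")
  export_choropleth(cls, geometry = gf, file = img)
  expect_true(file.exists(img) && file.size(img) > 0)
  cls2 <- rbind(cls, data.frame(region = "C", por = 1, ci_low = 0.5,
                                ci_high = 2, category = "not_significant",
                                nominal_level = 0.95))
  expect_error(export_choropleth(cls2, geometry = gf, file = img),
               "missing regions: C")
})

test_that("stepwise sensitivity flags the planted age confounder", {
  # hand-built world: true age effect zero; region B is both older and at
  # higher risk, so the unadjusted age curve is spuriously increasing and
  # adjusting for region should move the curve far more than a null factor
  set.seed(81)
  n <- 3000
  region <- sample(c("A", "B"), n, replace = TRUE)
  age <- ifelse(region == "B",
                pmin(49L, 15L + rpois(n, 22)), pmin(49L, 15L + rpois(n, 8)))
  eta <- -1 + 1.8 * (region == "B")
  ds <- data.frame(
    outcome = rbinom(n, 1, plogis(eta)), wave = 1L, region = region,
    cluster = paste0(region, "_c1"), household = "h", age = as.integer(age),
    urban = 0L, married = 0L, education = "none",
    partner_education = "none", wealth = "middle",
    family_size = sample(c("small", "middle", "large"), n, TRUE),
    ethnicity = "Wolof", religion = "muslim", partner_age = 40L)
  g <- region_graph(c("A", "B"), rbind(c("A", "B")))
  base <- model_spec(nonlinear = list(age = list(n_inner_knots = 5)),
                     include_structured = FALSE,
                     include_unstructured = FALSE)
  out <- stepwise_sensitivity(
    validate_dataset(ds, g), base,
    candidate_factors = c(family_size = "small", region = "A"),
    config = mcmc_config(400, 150, 2, seed = 82), graph = g)
  expect_equal(out$step, 0:2)
  expect_equal(out$added[1], "(base)")
  chg <- out$max_abs_change
  # region (the confounder) moves the curve far more than the null factor
  expect_gt(chg[out$added == "region"], 2 * chg[out$added == "family_size"])

  # base spec = full spec: a repeated factor is a zero-change no-op
  out2 <- stepwise_sensitivity(
    validate_dataset(ds, g),
    model_spec(fixed = c(region = "A"),
               nonlinear = list(age = list(n_inner_knots = 5)),
               include_structured = FALSE, include_unstructured = FALSE),
    candidate_factors = c(region = "A"),
    config = mcmc_config(200, 100, 2, seed = 83), graph = g)
  expect_equal(out2$max_abs_change[2], 0)
  expect_match(out2$added[2], "no-op")
})
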