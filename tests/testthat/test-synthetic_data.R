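test_that("default_truth constraints and determinism", {
  g <- sn_region_graph(1)
  t1 <- default_truth(g, seed = 5)
  t2 <- default_truth(g, seed = 5)
  expect_equal(t1$f_str, t2$f_str)
  expect_equal(t1$f_unstr, t2$f_unstr)
  expect_lt(abs(sum(t1$f_str)), 1e-10)
  expect_lt(abs(sum(t1$f_unstr)), 1e-10)
  expect_false(isTRUE(all.equal(t1$f_str,
                                default_truth(g, seed = 6)$f_str)))
  expect_error(default_truth(g), "seed")

  # zero-variance limit via the ricar draw
  expect_true(all(geofgm:::ricar(g, 0) == 0))

  # per-component centering on a disconnected graph
  gd <- region_graph(c("A", "B", "C", "D"), rbind(c("A", "B"), c("C", "D")))
  td <- default_truth(gd, seed = 2)
  expect_lt(abs(sum(td$f_str[c("A", "B")])), 1e-10)
  expect_lt(abs(sum(td$f_str[c("C", "D")])), 1e-10)
})

test_that("split_region_map produces the wave-2 frame", {
  g1 <- sn_region_graph(1)
  sp <- split_region_map(g1, sn_wave2_splits())
  expect_length(sp$graph$labels, 14)
  expect_setequal(names(sp$map), sp$graph$labels)
  expect_equal(sum(sp$map != names(sp$map)), 3) # three fresh labels
  expect_equal(length(connected_components(sp$graph)),
               length(connected_components(g1)))
  # parts are mutually adjacent and inherit external neighbours
  nb <- geofgm:::neighbour_list(sp$graph)
  expect_true("Kaffrine" %in% nb$Kaolack)
  external <- setdiff(nb$Kaolack, c("Kaffrine", "Kaolack"))
  expect_true(all(external %in% nb$Kaffrine))

  id <- split_region_map(g1, list())
  expect_identical(id$graph, g1)
  expect_identical(unname(id$map), g1$labels)

  expect_error(split_region_map(g1, list(Kaolack = c("Dakar", "K2"))),
               "collides")
  # component count preserved on random graphs
  for (seed in 1:5) {
    gr <- random_graph(8, seed = seed + 40, p_edge = 0.2)
    spr <- split_region_map(gr, list(R01 = c("R01", "R01b"),
                                     R05 = c("R05a", "R05b")))
    expect_equal(length(connected_components(spr$graph)),
                 length(connected_components(gr)))
  }
})

test_that("simulate_survey respects the truth", {
  g <- sn_region_graph(1)
  design <- default_design(g, women_target = 600)

  # saturation: intercept -50 -> all outcomes 0
  tr0 <- ground_truth(g, intercept = -50)
  ds0 <- simulate_survey(tr0, design, g, wave = 1, seed = 1)
  expect_true(all(ds0$outcome == 0))

  # binomial oracle: null model, prevalence 0.5 within 3 MC SEs
  trn <- ground_truth(g, intercept = 0)
  big <- default_design(g, women_target = 100000)
  dsn <- simulate_survey(trn, big, g, wave = 1, seed = 2)
  n <- nrow(dsn)
  expect_lt(abs(mean(dsn$outcome) - 0.5), 3 * sqrt(0.25 / n))

  # planted hotspot: empirical log-odds gap ~ +2
  fs <- stats::setNames(rep(0, 11), g$labels)
  fs["Kolda"] <- 2
  trh <- ground_truth(g, intercept = -1, f_str = fs)
  # note centering shifts all regions by -2/11; the *difference* stays 2
  dsh <- simulate_survey(trh, default_design(g, women_target = 60000), g,
                         wave = 1, seed = 3)
  lo <- function(p) log(p / (1 - p))
  p_hot <- mean(dsh$outcome[dsh$region == "Kolda"])
  p_rest <- mean(dsh$outcome[dsh$region != "Kolda"])
  expect_lt(abs((lo(p_hot) - lo(p_rest)) - 2), 0.2)

  # determinism: identical seeds give byte-identical CSVs
  ds_a <- simulate_survey(default_truth(g, seed = 9), design, g, 1, seed = 4)
  ds_b <- simulate_survey(default_truth(g, seed = 9), design, g, 1, seed = 4)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds_a, fa)
  write_dataset(ds_b, fb)
  expect_identical(readLines(fa), readLines(fb))

  # wave 2 from a wave-1 truth requires the map
  sp <- split_region_map(g, sn_wave2_splits())
  expect_error(simulate_survey(default_truth(g, seed = 9), design, sp$graph,
                               wave = 2, seed = 5), "wave_region_map")
  d2 <- default_design(sp$graph, women_target = 600,
                       wave_region_map = sp$map)
  ds2 <- simulate_survey(default_truth(g, seed = 9), d2, sp$graph, wave = 2,
                         seed = 5)
  expect_true(all(ds2$region %in% sp$graph$labels))
  tr2 <- attr(ds2, "truth")
  expect_setequal(names(tr2$f_str), sp$graph$labels)
})

test_that("null spatial effects give homogeneous regions", {
  g <- sn_region_graph(1)
  tr <- ground_truth(g, intercept = -1)
  rejections <- 0L
  for (seed in 1:20) {
    ds <- simulate_survey(tr, default_design(g, women_target = 3000), g, 1,
                          seed = seed)
    tab <- table(ds$region, ds$outcome)
    pval <- suppressWarnings(chisq.test(tab)$p.value)
    rejections <- rejections + (pval < 0.05)
  }
  expect_lte(rejections, 3L) # nominal 5%, allow <= 15% of 20 seeds
})

test_that("dataset CSV round trip is exact", {
  g <- sn_region_graph(1)
  ds <- small_survey(seed = 7, women_target = 900)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, f)
  back <- read_dataset(f, g)
  expect_equal(as.data.frame(back), as.data.frame(ds), ignore_attr = TRUE)
  expect_true(anyNA(back$partner_age)) # missing encoded as empty, restored

  # validation catches bad outcome values
  bad <- as.data.frame(ds)
  bad$outcome[3] <- 2L
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(bad, f2, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  expect_error(read_dataset(f2), "outcome must be 0/1")

  # unknown region vs supplied graph
  bad2 <- as.data.frame(ds)
  bad2$region[1] <- "Atlantis"
  bad2$cluster[1] <- "Atlantis_c001"
  expect_error(validate_dataset(bad2, g), "Atlantis")

  # 1-row dataset round trip
  one <- as.data.frame(ds)[1, ]
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(validate_dataset(one), f3)
  expect_equal(as.data.frame(read_dataset(f3)), one, ignore_attr = TRUE)
})

test_that("empirical prevalence matches truth-implied prevalence", {
  g <- sn_region_graph(1)
  tr <- default_truth(g, seed = 11)
  ds <- simulate_survey(tr, default_design(g, women_target = 100000), g, 1,
                        seed = 12)
  # truth-implied: recompute eta from the stored truth on the realized rows
  eta <- rep(tr$intercept, nrow(ds))
  fa <- tr$f_age(ds$age)
  eta <- eta + (fa - mean(fa)) + tr$f_str[ds$region] + tr$f_unstr[ds$region]
  for (nm in names(tr$beta)) {
    v <- as.character(ds[[nm]])
    contrib <- ifelse(is.na(v), 0, tr$beta[[nm]][v])
    contrib[is.na(contrib)] <- 0
    eta <- eta + contrib
  }
  p_implied <- mean(plogis(unname(eta)))
  se <- sqrt(p_implied * (1 - p_implied) / nrow(ds))
  expect_lt(abs(mean(ds$outcome) - p_implied), 3 * se)
})
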