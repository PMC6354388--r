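#' Posterior odds ratios for the fixed effects
#'
#' Per dummy-coded term: exponentiate the draws, take the posterior median
#' (invariant to the log transform) and the equal-tailed credible interval.
#' Reference levels are emitted as POR = 1 with no interval.
#'
#' @param samples a `geofgm_fit`.
#' @param level credibility level in (0, 1), default 0.95.
#' @return data.frame `term`, `por`, `ci_low`, `ci_high`, `level`;
#'   reference-level rows have NA intervals.
#' @export
fixed_effect_por <- function(samples, level = 0.95) {
  stopifnot(inherits(samples, "geofgm_fit"))
  if (!samples$n_stored) stop("no stored draws")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  terms <- colnames(samples$gamma)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- lapply(terms, function(tm) {
    ex <- exp(samples$gamma[, tm])
    q <- unname(stats::quantile(ex, qs))
    data.frame(term = tm, por = stats::median(ex), ci_low = q[1L],
               ci_high = q[2L], level = level, stringsAsFactors = FALSE)
  })
  # reference rows: one per fixed covariate
  refs <- samples$spec$fixed
  ref_rows <- lapply(names(refs), function(nm) {
    data.frame(term = paste0(nm, ":", refs[[nm]], " (ref)"), por = 1,
               ci_low = NA_real_, ci_high = NA_real_, level = level,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, ref_rows))
  rownames(out) <- NULL
  out
}

#' Total residual spatial effect draws
#'
#' The mapped quantity: per draw and region, the sum of the structured and
#' unstructured effects (whichever blocks were fitted).
#'
#' @param samples a `geofgm_fit`.
#' @return matrix draws x regions on the log-odds scale.
#' @export
total_spatial_effect <- function(samples) {
  stopifnot(inherits(samples, "geofgm_fit"))
  if (!samples$include_structured && !samples$include_unstructured) {
    stop("no spatial block was fitted")
  }
  tot <- matrix(0, samples$n_stored, length(samples$labels),
                dimnames = list(NULL, samples$labels))
  if (samples$include_structured) tot <- tot + samples$f_str
  if (samples$include_unstructured) tot <- tot + samples$f_unstr
  tot
}

#' Classify regions by the significance of their total spatial effect
#'
#' Per region: posterior median of exp(total effect) (the region's posterior
#' odds ratio), the equal-tailed interval at `nominal_level`, and the
#' three-way category of the usual white/grey/black significance map:
#' "negative" (white, interval entirely below 1, reduced risk), "positive"
#' (black, entirely above 1, increased risk), else "not_significant" (grey).
#'
#' @param total_draws matrix draws x regions (log-odds scale), e.g. from
#'   [total_spatial_effect].
#' @param nominal_level credibility level, default 0.95 (0.90 is the usual
#'   alternative preset).
#' @return data.frame `region`, `por`, `ci_low`, `ci_high`, `category`,
#'   `nominal_level`.
#' @export
classify_regions <- function(total_draws, nominal_level = 0.95) {
  if (nominal_level <= 0 || nominal_level >= 1) {
    stop("nominal_level must be in (0, 1)")
  }
  qs <- c((1 - nominal_level) / 2, 1 - (1 - nominal_level) / 2)
  regions <- colnames(total_draws)
  rows <- lapply(regions, function(r) {
    ex <- exp(total_draws[, r])
    q <- unname(stats::quantile(ex, qs))
    cat <- if (q[1L] > 1) "positive" else if (q[2L] < 1) "negative" else
      "not_significant"
    data.frame(region = r, por = stats::median(ex), ci_low = q[1L],
               ci_high = q[2L], category = cat,
               nominal_level = nominal_level, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior summary of a nonlinear curve
#'
#' Evaluates the fitted spline on a grid for every stored draw and returns
#' the pointwise posterior mean with an equal-tailed credible band (80\% by
#' convention for curves). No extrapolation: the grid must lie within the
#' fitted range. Also reports a crude shape flag: "decreasing",
#' "increasing", "unimodal" or "other", from the sign pattern of the
#' posterior-mean curve's differences.
#'
#' @param samples a `geofgm_fit`.
#' @param field name of a fitted nonlinear term.
#' @param grid numeric grid within the fitted range; default 200 points over
#'   the range.
#' @param level band level, default 0.80.
#' @return list of class `curve_summary`: `grid`, `mean`, `band_low`,
#'   `band_high`, `level`, `shape`, `draws` (draws x grid matrix).
#' @export
curve_summary <- function(samples, field, grid = NULL, level = 0.80) {
  stopifnot(inherits(samples, "geofgm_fit"))
  if (!field %in% names(samples$alpha)) {
    stop("'", field, "' is not a fitted nonlinear term")
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  meta <- samples$spline_meta[[field]]
  if (is.null(grid)) grid <- seq(meta$xl, meta$xr, length.out = 200L)
  if (any(grid < meta$xl - 1e-9) || any(grid > meta$xr + 1e-9)) {
    stop("grid outside fitted range [", meta$xl, ", ", meta$xr, "]")
  }
  Bg <- splines::splineDesign(meta$knots, pmin(pmax(grid, meta$xl), meta$xr),
                              ord = meta$degree + 1L)
  draws <- samples$alpha[[field]] %*% t(Bg) # draws x grid
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  m <- colMeans(draws)
  lo <- apply(draws, 2L, stats::quantile, probs = qs[1L])
  hi <- apply(draws, 2L, stats::quantile, probs = qs[2L])
  d <- diff(m)
  eps <- 1e-9
  shape <- if (all(d <= eps)) "decreasing" else if (all(d >= -eps)) {
    "increasing"
  } else {
    r <- rle(sign(d[abs(d) > eps]))
    if (length(r$values) == 2L && r$values[1L] == 1) "unimodal" else "other"
  }
  structure(list(grid = grid, mean = m, band_low = lo, band_high = hi,
                 level = level, shape = shape, draws = draws),
            class = "curve_summary")
}

#' Harmonize wave-2 summaries onto the wave-1 region frame
#'
#' Wave-2 regions that subdivide a wave-1 region are merged by unweighted
#' averaging of their per-region statistic (the convention for comparing
#' trends across a frame change); a population-weighted alternative is
#' available through `weights`. Output rows are wave-1 regions with both
#' waves' values and the wave-2-minus-wave-1 difference.
#'
#' @param summary_w1 named numeric vector (or 2-column data.frame
#'   region/value) of wave-1 per-region statistics.
#' @param summary_w2 same, on the wave-2 frame.
#' @param wave_region_map named character: wave-2 label -> wave-1 parent
#'   (identity names for unsplit regions), as from [split_region_map].
#' @param weights optional named numeric vector over wave-2 regions for
#'   weighted merging; default NULL = unweighted.
#' @return data.frame `region` (wave-1 frame), `wave1`, `wave2`, `difference`.
#' @export
harmonize_waves <- function(summary_w1, summary_w2, wave_region_map,
                            weights = NULL) {
  as_named <- function(x) {
    if (is.data.frame(x)) {
      stats::setNames(as.numeric(x[[2L]]), as.character(x[[1L]]))
    } else {
      x
    }
  }
  s1 <- as_named(summary_w1)
  s2 <- as_named(summary_w2)
  unmapped <- setdiff(names(s2), names(wave_region_map))
  if (length(unmapped)) stop("unmapped wave-2 regions: ",
                             paste(unmapped, collapse = ", "))
  parents <- unique(unname(wave_region_map[names(s2)]))
  merged <- vapply(parents, function(p) {
    kids <- names(s2)[wave_region_map[names(s2)] == p]
    if (is.null(weights)) {
      mean(s2[kids])
    } else {
      sum(s2[kids] * weights[kids]) / sum(weights[kids])
    }
  }, 0)
  regions <- names(s1)[names(s1) %in% parents]
  data.frame(region = regions, wave1 = unname(s1[regions]),
             wave2 = unname(merged[regions]),
             difference = unname(merged[regions] - s1[regions]),
             stringsAsFactors = FALSE)
}

#' Stepwise sensitivity of the nonlinear age curve
#'
#' Refits the model adding one candidate factor at a time to the base
#' specification and reports, per step, the maximum absolute change of the
#' posterior-mean age curve on a fixed grid relative to the previous step,
#' plus the curve's shape flag — the diagnostic for which adjustments are
#' responsible for a change in the fitted age effect.
#'
#' @param dataset a survey dataset.
#' @param base_spec a [model_spec] containing the nonlinear term `field`.
#' @param candidate_factors ordered character vector of covariates to add
#'   (reference level = first canonical level unless given as a named
#'   vector covariate -> reference).
#' @param config an [mcmc_config]; each refit bumps the seed by the step
#'   index so steps are independent but reproducible.
#' @param graph a [region_graph].
#' @param field the nonlinear term to monitor (default "age").
#' @param grid evaluation grid (default 35 points over the fitted range).
#' @return data.frame `step`, `added`, `max_abs_change`, `shape`; step 0 is
#'   the base fit with change NA.
#' @export
stepwise_sensitivity <- function(dataset, base_spec, candidate_factors,
                                 config, graph, field = "age", grid = NULL) {
  stopifnot(inherits(base_spec, "model_spec"))
  if (!field %in% names(base_spec$nonlinear)) {
    stop("base_spec must include nonlinear term '", field, "'")
  }
  if (is.null(names(candidate_factors))) {
    refs <- vapply(candidate_factors, function(nm) {
      if (nm %in% names(covariate_levels)) covariate_levels[[nm]][1L] else "0"
    }, "")
    candidate_factors <- stats::setNames(refs, candidate_factors)
  }
  bad <- setdiff(names(candidate_factors), names(dataset))
  if (length(bad)) stop("candidate factors not in dataset: ",
                        paste(bad, collapse = ", "))
  spec <- base_spec
  fit_step <- function(spec, step) {
    cfg <- mcmc_config(config$iterations, config$burn_in, config$thin,
                       seed = config$seed + step, init = config$init)
    blocks <- build_design(dataset, spec, graph)
    fit <- tryCatch(gibbs_fit(blocks, config = cfg),
                    error = function(e) stop("step ", step, " (",
                                             paste(names(spec$fixed),
                                                   collapse = "+"),
                                             "): ", conditionMessage(e)))
    fit
  }
  fit0 <- fit_step(spec, 0L)
  meta <- fit0$spline_meta[[field]]
  if (is.null(grid)) grid <- seq(meta$xl, meta$xr, length.out = 35L)
  cs <- curve_summary(fit0, field, grid)
  prev_mean <- cs$mean
  out <- data.frame(step = 0L, added = "(base)", max_abs_change = NA_real_,
                    shape = cs$shape, stringsAsFactors = FALSE)
  step <- 0L
  for (nm in names(candidate_factors)) {
    step <- step + 1L
    if (nm %in% names(spec$fixed)) {
      out <- rbind(out, data.frame(step = step, added = paste0(nm, " (no-op)"),
                                   max_abs_change = 0, shape = cs$shape,
                                   stringsAsFactors = FALSE))
      next
    }
    spec$fixed <- c(spec$fixed, stats::setNames(candidate_factors[[nm]], nm))
    fit <- fit_step(spec, step)
    cs <- curve_summary(fit, field, grid)
    out <- rbind(out, data.frame(
      step = step, added = nm,
      max_abs_change = max(abs(cs$mean - prev_mean)), shape = cs$shape,
      stringsAsFactors = FALSE))
    prev_mean <- cs$mean
  }
  rownames(out) <- NULL
  out
}

#' Render or tabulate a significance map
#'
#' With a geometry file (CSV columns `region`, `x`, `y`, one polygon vertex
#' per row, vertices in drawing order) the classification is rendered as a
#' white/grey/black choropleth to `file` (PNG or SVG by extension). Without
#' geometry a tabular fallback is returned with a warning. Colors follow the
#' usual convention: white = significantly negative (reduced risk), black =
#' significantly positive (increased risk), grey = not significant.
#'
#' @param classification a [classify_regions] result.
#' @param geometry optional path to the polygon CSV.
#' @param file output image path (required when geometry is given).
#' @return the classification table (invisibly when a map was drawn).
#' @export
export_choropleth <- function(classification, geometry = NULL, file = NULL) {
  if (is.null(geometry)) {
    warning("no geometry supplied; returning tabular fallback")
    return(classification)
  }
  geo <- utils::read.csv(geometry, stringsAsFactors = FALSE)
  need <- c("region", "x", "y")
  if (!all(need %in% names(geo))) stop("geometry needs columns region, x, y")
  missing_geo <- setdiff(classification$region, unique(geo$region))
  if (length(missing_geo)) stop("geometry missing regions: ",
                                paste(missing_geo, collapse = ", "))
  if (is.null(file)) stop("file required when rendering geometry")
  cols <- c(negative = "white", not_significant = "grey70", positive = "black")
  ext <- tolower(tools::file_ext(file))
  if (ext == "svg") grDevices::svg(file) else grDevices::png(file, 700, 700)
  on.exit(grDevices::dev.off())
  plot(NA, xlim = range(geo$x), ylim = range(geo$y), asp = 1,
       xlab = "", ylab = "", axes = FALSE,
       main = sprintf("total spatial effect, %.0f%% nominal level",
                      100 * classification$nominal_level[1L]))
  for (r in classification$region) {
    poly <- geo[geo$region == r, ]
    cat_r <- classification$category[classification$region == r]
    graphics::polygon(poly$x, poly$y, col = cols[[cat_r]], border = "black")
    graphics::text(mean(poly$x), mean(poly$y), r, cex = 0.6,
                   col = if (cat_r == "positive") "white" else "black")
  }
  invisible(classification)
}
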