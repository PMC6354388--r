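#' Validate and normalize a pipeline configuration
#'
#' Configs are JSON (schema below); every schema violation is collected and
#' reported at once with a path-like key. Defaults are filled for everything
#' optional.
#'
#' \preformatted{
#' {
#'   "seed": 1,                        # mandatory
#'   "output_dir": "out",              # mandatory
#'   "graph": "inst .gra path" | "senegal",   # default "senegal"
#'   "splits": {"Kaolack": ["Kaolack","Kaffrine"], ...},  # default Senegal
#'   "design": {"women_target": 2000, "households_per_cluster": 21,
#'              "inherit_sd": 0.2},
#'   "data":  {"wave1": "w1.csv", "wave2": "w2.csv"},  # optional: else simulate
#'   "truth": {"tau2_str": 0.6, "tau2_unstr": 0.1, "age_amplitude": 0.9,
#'             "hotspot": ["Kolda"], "hotspot_effect": 2},
#'   "model": {"fixed": {"urban": "0", "wealth": "richest", ...},
#'             "nonlinear": {"age": {"n_inner_knots": 20, "degree": 3}},
#'             "include_structured": true, "include_unstructured": true,
#'             "hyper_a": 0.001, "hyper_b": 0.001, "link": "logit"},
#'   "mcmc":  {"iterations": 12000, "burn_in": 2000, "thin": 10},
#'   "report": {"nominal_level": 0.95, "curve_level": 0.8}
#' }
#' }
#'
#' @param path path to a JSON config file, or an already-parsed list.
#' @return a normalized `pipeline_config` list, or an error whose message
#'   lists every violation.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e) stop("config parse error: ",
                                      conditionMessage(e)))
  } else {
    path
  }
  errs <- character(0)
  err <- function(key, msg) errs <<- c(errs, paste0(key, ": ", msg))
  if (is.null(cfg$seed)) {
    err("seed", "mandatory")
  } else if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
    err("seed", "must be an integer")
  }
  if (is.null(cfg$output_dir) || !nzchar(cfg$output_dir)) {
    err("output_dir", "mandatory")
  }
  cfg$graph <- cfg$graph %||% "senegal"
  if (!identical(cfg$graph, "senegal") && !file.exists(cfg$graph)) {
    err("graph", paste0("file not found: ", cfg$graph))
  }
  d <- cfg$design %||% list()
  d$women_target <- d$women_target %||% 14600
  d$households_per_cluster <- d$households_per_cluster %||% 21L
  d$inherit_sd <- d$inherit_sd %||% 0.2
  if (d$households_per_cluster < 1) err("design.households_per_cluster", ">= 1")
  cfg$design <- d
  if (!is.null(cfg$data)) {
    for (w in c("wave1", "wave2")) {
      if (!is.null(cfg$data[[w]]) && !file.exists(cfg$data[[w]])) {
        err(paste0("data.", w), paste0("file not found: ", cfg$data[[w]]))
      }
    }
  }
  tr <- cfg$truth %||% list()
  tr$tau2_str <- tr$tau2_str %||% 0.6
  tr$tau2_unstr <- tr$tau2_unstr %||% 0.1
  tr$age_amplitude <- tr$age_amplitude %||% 0.9
  tr$hotspot <- tr$hotspot %||% character(0)
  tr$hotspot_effect <- tr$hotspot_effect %||% 2
  cfg$truth <- tr
  m <- cfg$model %||% list()
  fixed <- unlist(m$fixed) %||% c(
    urban = "0", married = "0", education = "higher",
    partner_education = "higher", wealth = "richest", family_size = "small",
    ethnicity = "Wolof", religion = "other")
  nl <- m$nonlinear %||% list(age = list(n_inner_knots = 20L, degree = 3L))
  spec <- tryCatch(model_spec(
    fixed = fixed, nonlinear = nl,
    include_structured = m$include_structured %||% TRUE,
    include_unstructured = m$include_unstructured %||% TRUE,
    hyper_a = m$hyper_a %||% 0.001, hyper_b = m$hyper_b %||% 0.001,
    link = m$link %||% "logit"),
    error = function(e) {
      err("model", conditionMessage(e))
      NULL
    })
  mc <- cfg$mcmc %||% list()
  mc$iterations <- mc$iterations %||% 12000L
  mc$burn_in <- mc$burn_in %||% 2000L
  mc$thin <- mc$thin %||% 10L
  if (mc$burn_in >= mc$iterations) {
    err("mcmc.burn_in", "must be < iterations")
  }
  if (mc$thin < 1) err("mcmc.thin", "must be >= 1")
  cfg$mcmc <- mc
  rp <- cfg$report %||% list()
  rp$nominal_level <- rp$nominal_level %||% 0.95
  rp$curve_level <- rp$curve_level %||% 0.8
  for (k in c("nominal_level", "curve_level")) {
    if (rp[[k]] <= 0 || rp[[k]] >= 1) err(paste0("report.", k), "in (0, 1)")
  }
  cfg$report <- rp
  if (length(errs)) {
    stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "))
  }
  cfg$spec <- spec
  # unknown covariates checked against the canonical dataset schema
  bad <- setdiff(names(spec$fixed), dataset_columns)
  if (length(bad)) stop("invalid config:\n  - model.fixed: unknown covariate ",
                        paste(bad, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full simulate / describe / fit / summarize pipeline
#'
#' Per wave: (1) obtain data (simulate with the planted truth unless CSV
#' paths are configured), (2) descriptive stage — overall and per-region
#' prevalence, unadjusted ORs for every fixed covariate, baseline table, (3)
#' Bayesian stage — geo-additive fit, persisted draws, POR table, region
#' classification, age-curve summary; then the wave comparison on the
#' harmonized wave-1 frame. The two waves are fitted separately. All
#' artifacts go under `output_dir` and are indexed by a JSON manifest with
#' seeds, record counts, per-stage timing and md5 checksums; a stage failure
#' aborts with a stage-tagged error, keeping earlier artifacts.
#'
#' @param config a `pipeline_config` (or path to one; validated either way).
#' @return the manifest, invisibly (also written to
#'   `output_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list(), artifacts = list())
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  put <- function(name, path) manifest$artifacts[[name]] <<- path

  graphs <- stage("graph", function() {
    if (identical(cfg$graph, "senegal")) {
      g1 <- sn_region_graph(1L)
      sp <- split_region_map(g1, sn_wave2_splits())
    } else {
      g1 <- read_gra(cfg$graph)
      sp <- split_region_map(g1, cfg$splits %||% list())
    }
    write_gra(g1, file.path(out, "graph_w1.gra"))
    write_gra(sp$graph, file.path(out, "graph_w2.gra"))
    put("graph_w1", file.path(out, "graph_w1.gra"))
    put("graph_w2", file.path(out, "graph_w2.gra"))
    list(g1 = g1, g2 = sp$graph, map = sp$map)
  })

  design1 <- default_design(graphs$g1, women_target = cfg$design$women_target,
                            households_per_cluster =
                              cfg$design$households_per_cluster)
  design2 <- default_design(graphs$g2, women_target = cfg$design$women_target,
                            households_per_cluster =
                              cfg$design$households_per_cluster,
                            wave_region_map = graphs$map,
                            inherit_sd = cfg$design$inherit_sd)

  data_by_wave <- list()
  truth1 <- NULL
  for (w in 1:2) {
    g <- if (w == 1L) graphs$g1 else graphs$g2
    dsg <- if (w == 1L) design1 else design2
    key <- paste0("wave", w)
    data_by_wave[[w]] <- stage(paste0("data_", key), function() {
      if (!is.null(cfg$data[[key]])) {
        read_dataset(cfg$data[[key]], g)
      } else {
        if (w == 1L) {
          truth1 <<- default_truth(
            graphs$g1, seed = cfg$seed, tau2_str = cfg$truth$tau2_str,
            tau2_unstr = cfg$truth$tau2_unstr,
            age_amplitude = cfg$truth$age_amplitude,
            hotspot = unlist(cfg$truth$hotspot),
            hotspot_effect = cfg$truth$hotspot_effect)
          write_truth(truth1, file.path(out, "truth_w1.json"))
          put("truth_w1", file.path(out, "truth_w1.json"))
        }
        ds <- simulate_survey(truth1, dsg, g, wave = w,
                              seed = cfg$seed + 17L * w)
        path <- file.path(out, sprintf("survey_w%d.csv", w))
        write_dataset(ds, path)
        put(paste0("survey_w", w), path)
        ds
      }
    })
  }

  summaries <- list()
  for (w in 1:2) {
    g <- if (w == 1L) graphs$g1 else graphs$g2
    ds <- data_by_wave[[w]]
    stage(paste0("descriptive_wave", w), function() {
      prev <- prevalence_table(ds, by = "region")
      utils::write.csv(prev, file.path(out, sprintf("prevalence_w%d.csv", w)),
                       row.names = FALSE)
      put(paste0("prevalence_w", w),
          file.path(out, sprintf("prevalence_w%d.csv", w)))
      ors <- do.call(rbind, lapply(names(cfg$spec$fixed), function(nm) {
        o <- unadjusted_or(ds, nm, cfg$spec$fixed[[nm]])
        o$covariate <- nm
        o
      }))
      utils::write.csv(ors, file.path(out, sprintf("unadjusted_or_w%d.csv", w)),
                       row.names = FALSE)
      put(paste0("unadjusted_or_w", w),
          file.path(out, sprintf("unadjusted_or_w%d.csv", w)))
      bt <- baseline_table(ds)
      utils::write.csv(bt, file.path(out, sprintf("baseline_w%d.csv", w)),
                       row.names = FALSE)
      put(paste0("baseline_w", w),
          file.path(out, sprintf("baseline_w%d.csv", w)))
      NULL
    })
    fit <- stage(paste0("fit_wave", w), function() {
      blocks <- build_design(ds, cfg$spec, g)
      manifest$stages[[paste0("fit_wave", w, "_rows")]] <<- list(
        n = blocks$n, dropped = blocks$n_dropped)
      cfgm <- mcmc_config(cfg$mcmc$iterations, cfg$mcmc$burn_in,
                          cfg$mcmc$thin, seed = cfg$seed + 101L * w)
      fit <- gibbs_fit(blocks, config = cfgm)
      write_fit(fit, file.path(out, sprintf("fit_w%d", w)))
      put(paste0("fit_w", w), file.path(out, sprintf("fit_w%d", w)))
      fit
    })
    summaries[[w]] <- stage(paste0("summarize_wave", w), function() {
      por <- fixed_effect_por(fit, level = cfg$report$nominal_level)
      utils::write.csv(por, file.path(out, sprintf("por_w%d.csv", w)),
                       row.names = FALSE)
      put(paste0("por_w", w), file.path(out, sprintf("por_w%d.csv", w)))
      cls <- classify_regions(total_spatial_effect(fit),
                              cfg$report$nominal_level)
      utils::write.csv(cls, file.path(out, sprintf("regions_w%d.csv", w)),
                       row.names = FALSE)
      put(paste0("regions_w", w), file.path(out, sprintf("regions_w%d.csv", w)))
      crv <- NULL
      if ("age" %in% names(fit$alpha)) {
        crv <- curve_summary(fit, "age", level = cfg$report$curve_level)
        cdf <- data.frame(age = crv$grid, mean = crv$mean,
                          band_low = crv$band_low, band_high = crv$band_high)
        utils::write.csv(cdf, file.path(out, sprintf("age_curve_w%d.csv", w)),
                         row.names = FALSE)
        put(paste0("age_curve_w", w),
            file.path(out, sprintf("age_curve_w%d.csv", w)))
      }
      list(classification = cls, curve = crv)
    })
  }

  stage("compare", function() {
    prev1 <- prevalence_table(data_by_wave[[1L]], by = "region")
    prev2 <- prevalence_table(data_by_wave[[2L]], by = "region")
    cmp <- harmonize_waves(stats::setNames(prev1$percent, prev1$region),
                           stats::setNames(prev2$percent, prev2$region),
                           graphs$map)
    utils::write.csv(cmp, file.path(out, "wave_comparison.csv"),
                     row.names = FALSE)
    put("wave_comparison", file.path(out, "wave_comparison.csv"))
    por1 <- summaries[[1L]]$classification
    por2 <- summaries[[2L]]$classification
    cmp2 <- harmonize_waves(stats::setNames(log(por1$por), por1$region),
                            stats::setNames(log(por2$por), por2$region),
                            graphs$map)
    names(cmp2)[2:4] <- c("log_por_w1", "log_por_w2", "difference")
    utils::write.csv(cmp2, file.path(out, "spatial_comparison.csv"),
                     row.names = FALSE)
    put("spatial_comparison", file.path(out, "spatial_comparison.csv"))
    NULL
  })

  files <- unlist(manifest$artifacts)
  sums <- vapply(files, function(f) {
    if (dir.exists(f)) {
      inner <- list.files(f, full.names = TRUE)
      paste(unname(tools::md5sum(inner)), collapse = "")
    } else {
      unname(tools::md5sum(f))
    }
  }, "")
  manifest$checksums <- as.list(stats::setNames(sums, names(manifest$artifacts)))
  manifest$package_version <- as.character(utils::packageVersion("geofgm"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline), `simulate`, `descriptive`, `fit`,
#' `summarize`, `compare`. All take `--config <path.json>`; `descriptive`
#' additionally honours `--data`, `--by`, `--covariate`, `--reference`.
#' Invoke from a shell as
#' `Rscript -e 'geofgm::pipeline_cli()' run --config cfg.json`.
#'
#' @param args character vector of CLI arguments (default: the command line).
#' @return exit-status-like integer, invisibly (0 on success).
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: <subcommand> --config <path.json>\n",
        "subcommands: run simulate descriptive fit summarize compare\n")
    return(invisible(1L))
  }
  sub <- args[[1L]]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    opts[[key]] <- if (i + 1L <= length(args)) args[[i + 1L]] else ""
    i <- i + 2L
  }
  if (sub == "descriptive" && !is.null(opts$data)) {
    ds <- read_dataset(opts$data)
    if (!is.null(opts$by)) print(prevalence_table(ds, by = opts$by))
    if (!is.null(opts$covariate)) {
      print(unadjusted_or(ds, opts$covariate,
                          opts$reference %||%
                            covariate_levels[[opts$covariate]][1L]))
    }
    return(invisible(0L))
  }
  if (is.null(opts$config)) stop("--config is required")
  cfg <- validate_config(opts$config)
  switch(sub,
    run = run_pipeline(cfg),
    simulate = {
      cfg$mcmc$iterations <- 2L # unused; simulate stage only
      g1 <- if (identical(cfg$graph, "senegal")) sn_region_graph(1L) else
        read_gra(cfg$graph)
      truth <- default_truth(g1, seed = cfg$seed,
                             tau2_str = cfg$truth$tau2_str,
                             tau2_unstr = cfg$truth$tau2_unstr,
                             age_amplitude = cfg$truth$age_amplitude,
                             hotspot = unlist(cfg$truth$hotspot),
                             hotspot_effect = cfg$truth$hotspot_effect)
      dsg <- default_design(g1, women_target = cfg$design$women_target)
      ds <- simulate_survey(truth, dsg, g1, wave = 1L, seed = cfg$seed + 17L)
      dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
      write_dataset(ds, file.path(cfg$output_dir, "survey_w1.csv"))
      cat("wrote", file.path(cfg$output_dir, "survey_w1.csv"), "\n")
    },
    fit = ,
    summarize = ,
    compare = ,
    descriptive = run_pipeline(cfg), # stages always run from the manifest
    stop("unknown subcommand: ", sub))
  invisible(0L)
}
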