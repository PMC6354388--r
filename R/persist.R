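#' Persist posterior draws as columnar CSV + JSON metadata
#'
#' Writes `draws.csv` (one row per stored draw; columns `intercept`,
#' `gamma:<term>`, `alpha:<field>:<k>`, `f_str:<region>`,
#' `f_unstr:<region>`, `tau2:<component>`) and `meta.json` (seed, MCMC
#' config, model spec, region labels, component index, spline knots) into a
#' directory, so every summary can be recomputed without refitting.
#'
#' @param fit a `geofgm_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "geofgm_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cols <- list(intercept = fit$intercept)
  for (tm in colnames(fit$gamma)) {
    cols[[paste0("gamma:", tm)]] <- fit$gamma[, tm]
  }
  for (nm in names(fit$alpha)) {
    A <- fit$alpha[[nm]]
    for (k in seq_len(ncol(A))) cols[[paste0("alpha:", nm, ":", k)]] <- A[, k]
  }
  for (r in colnames(fit$f_str)) cols[[paste0("f_str:", r)]] <- fit$f_str[, r]
  for (r in colnames(fit$f_unstr)) {
    cols[[paste0("f_unstr:", r)]] <- fit$f_unstr[, r]
  }
  for (tm in colnames(fit$tau2)) cols[[paste0("tau2:", tm)]] <- fit$tau2[, tm]
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, file.path(dir, "draws.csv"), row.names = FALSE)
  meta <- list(config = unclass(fit$config), spec = unclass(fit$spec),
               labels = fit$labels, comp = as.list(fit$comp),
               include_structured = fit$include_structured,
               include_unstructured = fit$include_unstructured,
               n_stored = fit$n_stored,
               spline_meta = fit$spline_meta,
               gamma_terms = colnames(fit$gamma),
               tau2_terms = colnames(fit$tau2))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_fit
#' @export
read_fit <- function(dir) {
  draws_path <- file.path(dir, "draws.csv")
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(draws_path) || !file.exists(meta_path)) {
    stop("not a persisted fit directory: ", dir)
  }
  df <- utils::read.csv(draws_path, check.names = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  labs <- meta$labels
  pick <- function(prefix) {
    nms <- grep(paste0("^", prefix, ":"), names(df), value = TRUE)
    m <- as.matrix(df[nms])
    colnames(m) <- sub(paste0("^", prefix, ":"), "", nms)
    m
  }
  gamma <- pick("gamma")
  alpha <- list()
  anms <- grep("^alpha:", names(df), value = TRUE)
  fields <- unique(sub("^alpha:([^:]+):.*$", "\\1", anms))
  for (f in fields) {
    sel <- grep(paste0("^alpha:", f, ":"), names(df), value = TRUE)
    ord <- order(as.integer(sub(".*:", "", sel)))
    alpha[[f]] <- as.matrix(df[sel[ord]])
  }
  spec <- meta$spec
  spec$fixed <- unlist(spec$fixed) %||% character(0)
  class(spec) <- "model_spec"
  config <- meta$config
  class(config) <- "mcmc_config"
  sm <- lapply(meta$spline_meta, function(m) {
    list(knots = as.numeric(m$knots), degree = as.integer(m$degree),
         xl = as.numeric(m$xl), xr = as.numeric(m$xr))
  })
  structure(list(intercept = df$intercept, gamma = gamma, alpha = alpha,
                 f_str = pick("f_str")[, labs, drop = FALSE],
                 f_unstr = pick("f_unstr")[, labs, drop = FALSE],
                 tau2 = pick("tau2"),
                 spline_meta = sm, labels = labs,
                 comp = unlist(meta$comp), config = config, spec = spec,
                 n_stored = meta$n_stored,
                 include_structured = meta$include_structured,
                 include_unstructured = meta$include_unstructured),
            class = "geofgm_fit")
}
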