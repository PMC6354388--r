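#' Unweighted prevalence table
#'
#' Counts and percent cut, optionally grouped (e.g. by region or wave).
#' Percent is 100 * cut / n, unweighted; empty groups are omitted.
#'
#' @param dataset a survey dataset (see [validate_dataset]).
#' @param by character vector of grouping columns, or NULL for the overall
#'   prevalence.
#' @return data.frame with the grouping columns plus `n`, `cut`, `percent`.
#' @export
prevalence_table <- function(dataset, by = NULL) {
  if (!nrow(dataset)) stop("empty dataset")
  if (is.null(by) || !length(by)) {
    n <- nrow(dataset)
    cut <- sum(dataset$outcome)
    return(data.frame(n = n, cut = cut, percent = 100 * cut / n))
  }
  miss <- setdiff(by, names(dataset))
  if (length(miss)) stop("unknown grouping fields: ",
                         paste(miss, collapse = ", "))
  key <- interaction(dataset[by], drop = TRUE, sep = "\r")
  n <- as.vector(table(key))
  cut <- as.vector(tapply(dataset$outcome, key, sum))
  parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  out <- as.data.frame(parts, stringsAsFactors = FALSE)
  names(out) <- by
  out$n <- n
  out$cut <- cut
  out$percent <- 100 * cut / n
  out[order(out[[1L]]), , drop = FALSE]
}

#' Cumulative age-at-cutting percentages
#'
#' Turns per-age-band percentages (ordered youngest first) into the running
#' cumulative percentages a report prints next to them, rounded to 1 decimal.
#'
#' @param category_percents non-negative numeric vector ordered by age band.
#' @return numeric vector of cumulative percentages, same length, rounded to
#'   1 decimal; monotone nondecreasing.
#' @export
cumulative_age_at_cutting <- function(category_percents) {
  if (any(is.na(category_percents)) || any(category_percents < 0)) {
    stop("percentages must be non-negative")
  }
  round(cumsum(category_percents), 1L)
}

#' 2x2 contingency table
#'
#' @param a,b,c,d non-negative counts: exposed-cut, exposed-uncut,
#'   unexposed-cut, unexposed-uncut.
#' @return object of class `contingency_2x2`.
#' @keywords internal
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("empty table")
  structure(as.list(counts), class = "contingency_2x2")
}

# cross-product OR with Wald CI; Haldane-Anscombe 0.5 added to all cells when
# any is zero (flagged)
or_from_2x2 <- function(tab, alpha = 0.05) {
  x <- unlist(tab[c("a", "b", "c", "d")])
  corrected <- any(x == 0)
  if (corrected) x <- x + 0.5
  or <- (x["a"] * x["d"]) / (x["b"] * x["c"])
  se <- sqrt(sum(1 / x))
  z <- stats::qnorm(1 - alpha / 2)
  list(or = unname(or), ci_low = unname(exp(log(or) - z * se)),
       ci_high = unname(exp(log(or) + z * se)), corrected = corrected)
}

#' Unadjusted marginal odds ratios
#'
#' For each non-reference level of a categorical covariate, the
#' level-vs-reference 2x2 cross-product odds ratio with a Wald interval
#' exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). This coincides with the
#' coefficient-exponential of a marginal logistic regression of the outcome
#' on that contrast. Zero cells get the Haldane-Anscombe 0.5 correction on
#' all four cells and are flagged.
#'
#' @param dataset a survey dataset.
#' @param covariate name of a categorical (or pre-binned) column.
#' @param reference reference level (reported as OR = 1, no interval).
#' @param alpha nominal level, default 0.05 for 95\% intervals.
#' @return data.frame: `level`, `reference`, `or`, `ci_low`, `ci_high`,
#'   `corrected` (zero-cell flag); first row is the reference.
#' @export
unadjusted_or <- function(dataset, covariate, reference, alpha = 0.05) {
  if (!covariate %in% names(dataset)) stop("unknown covariate: ", covariate)
  v <- as.character(dataset[[covariate]])
  keep <- !is.na(v)
  v <- v[keep]
  y <- dataset$outcome[keep]
  levs <- unique(v)
  if (length(levs) < 2L) stop("covariate has a single level: ", covariate)
  if (!reference %in% levs) stop("reference level not present: ", reference)
  others <- setdiff(levs, reference)
  ref_cut <- sum(y[v == reference])
  ref_uncut <- sum(v == reference) - ref_cut
  rows <- lapply(others, function(lv) {
    a <- sum(y[v == lv])
    b <- sum(v == lv) - a
    res <- or_from_2x2(contingency_2x2(a, b, ref_cut, ref_uncut), alpha)
    data.frame(level = lv, reference = reference, or = res$or,
               ci_low = res$ci_low, ci_high = res$ci_high,
               corrected = res$corrected, stringsAsFactors = FALSE)
  })
  out <- rbind(
    data.frame(level = reference, reference = reference, or = 1,
               ci_low = NA_real_, ci_high = NA_real_, corrected = FALSE,
               stringsAsFactors = FALSE),
    do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Baseline characteristics table
#'
#' Mirrors the usual survey "Table 2" layout: mean (SD, n-1 denominator) for
#' the age variables, percent per level for categoricals, with an overall
#' column and a cut/uncut split. Percentages are computed over non-missing
#' values of each variable.
#'
#' @param dataset a survey dataset.
#' @return data.frame with `variable`, `level`, `overall`, `cut`, `uncut`
#'   (means or percents) and `stat` ("mean_sd" or "percent"); SDs are in
#'   `overall_sd`, `cut_sd`, `uncut_sd` for the mean rows.
#' @export
baseline_table <- function(dataset) {
  validate_dataset(dataset)
  y <- dataset$outcome
  num_row <- function(var) {
    x <- dataset[[var]]
    data.frame(variable = var, level = "", stat = "mean_sd",
               overall = mean(x, na.rm = TRUE),
               overall_sd = stats::sd(x, na.rm = TRUE),
               cut = mean(x[y == 1], na.rm = TRUE),
               cut_sd = stats::sd(x[y == 1], na.rm = TRUE),
               uncut = mean(x[y == 0], na.rm = TRUE),
               uncut_sd = stats::sd(x[y == 0], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  pct <- function(x, levs) {
    x <- x[!is.na(x)]
    if (!length(x)) return(stats::setNames(rep(NA_real_, length(levs)), levs))
    100 * as.vector(table(factor(x, levels = levs))) / length(x)
  }
  cat_row <- function(var, levs) {
    x <- as.character(dataset[[var]])
    data.frame(variable = var, level = levs, stat = "percent",
               overall = pct(x, levs), overall_sd = NA_real_,
               cut = pct(x[y == 1], levs), cut_sd = NA_real_,
               uncut = pct(x[y == 0], levs), uncut_sd = NA_real_,
               stringsAsFactors = FALSE)
  }
  cats <- list(
    urban = c("0", "1"), married = c("0", "1"),
    education = covariate_levels$education,
    partner_education = covariate_levels$partner_education,
    wealth = covariate_levels$wealth,
    family_size = covariate_levels$family_size,
    ethnicity = covariate_levels$ethnicity,
    religion = covariate_levels$religion,
    region = sort(unique(dataset$region)))
  out <- rbind(num_row("age"), num_row("partner_age"),
               do.call(rbind, Map(cat_row, names(cats), cats)))
  rownames(out) <- NULL
  out
}
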