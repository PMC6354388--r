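#' @useDynLib geofgm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Canonical covariate level sets for the simulated survey. Order matters:
# the first level of each set is the generator's reference (effect 0) unless
# a truth object says otherwise.
covariate_levels <- list(
  education = c("none", "primary", "secondary", "higher"),
  partner_education = c("none", "primary", "secondary", "higher"),
  wealth = c("poorest", "poorer", "middle", "richer", "richest"),
  family_size = c("small", "middle", "large"),
  ethnicity = c("Wolof", "Poular", "Serer", "Mandingu", "Diola", "Soninke",
                "NotSenegalese", "Other"),
  religion = c("muslim", "other")
)

dataset_columns <- c("outcome", "wave", "region", "cluster", "household",
                     "age", "urban", "married", "education",
                     "partner_education", "wealth", "family_size",
                     "ethnicity", "religion", "partner_age")

#' Stylized Senegal region graphs
#'
#' Adjacency fixtures for the 11 administrative regions (wave 1, 2005 frame)
#' and the 14-region frame after the 2008 subdivisions (Kaffrine out of
#' Kaolack, Kedougou out of Tambacounda, Sedhiou out of Kolda). The adjacency
#' is a stylized reading of the political map, not authoritative geography;
#' labels are ASCII-fied.
#'
#' @param wave 1 (11 regions) or 2 (14 regions).
#' @return a [region_graph].
#' @export
sn_region_graph <- function(wave = 1L) {
  edges <- rbind(
    c("Dakar", "Thies"),
    c("Thies", "Diourbel"), c("Thies", "Fatick"), c("Thies", "Louga"),
    c("Diourbel", "Louga"), c("Diourbel", "Fatick"), c("Diourbel", "Kaolack"),
    c("Louga", "Saint-Louis"), c("Louga", "Matam"),
    c("Saint-Louis", "Matam"),
    c("Matam", "Tambacounda"),
    c("Fatick", "Kaolack"),
    c("Kaolack", "Tambacounda"),
    c("Tambacounda", "Kolda"),
    c("Kolda", "Ziguinchor")
  )
  labels <- c("Dakar", "Diourbel", "Fatick", "Kaolack", "Kolda", "Louga",
              "Matam", "Saint-Louis", "Tambacounda", "Thies", "Ziguinchor")
  g1 <- region_graph(labels, edges)
  if (wave == 1L) return(g1)
  if (wave != 2L) stop("wave must be 1 or 2")
  split_region_map(g1, sn_wave2_splits())$graph
}

#' The 2008 region subdivisions
#'
#' @return named list mapping each subdivided wave-1 region to its wave-2
#'   parts (parent label retained as the first part).
#' @export
sn_wave2_splits <- function() {
  list(Kaolack = c("Kaolack", "Kaffrine"),
       Tambacounda = c("Tambacounda", "Kedougou"),
       Kolda = c("Kolda", "Sedhiou"))
}

#' Subdivide regions of a graph for a later survey wave
#'
#' Each split region is replaced by its parts; the parts are mutually
#' adjacent and inherit all the parent's external adjacencies (a stylized
#' rule: real subdivisions share only some of the parent's borders).
#' Unsplit regions map to themselves.
#'
#' @param graph_w1 wave-1 [region_graph].
#' @param splits named list: wave-1 label -> character vector of wave-2 part
#'   labels (length 1 = rename). Part labels must not collide with any
#'   retained wave-1 label, except that a part may reuse its own parent's
#'   label.
#' @return list with `graph` (wave-2 [region_graph], parts inserted at the
#'   parent's position) and `map` (named character: wave-2 label -> wave-1
#'   parent label, covering every wave-2 region).
#' @export
split_region_map <- function(graph_w1, splits = list()) {
  stopifnot(inherits(graph_w1, "region_graph"))
  if (!length(splits)) {
    map <- stats::setNames(graph_w1$labels, graph_w1$labels)
    return(list(graph = graph_w1, map = map))
  }
  if (is.null(names(splits)) || any(!nzchar(names(splits)))) {
    stop("splits must be a named list keyed by wave-1 labels")
  }
  unknown <- setdiff(names(splits), graph_w1$labels)
  if (length(unknown)) stop("splits name unknown regions: ",
                            paste(unknown, collapse = ", "))
  kept <- setdiff(graph_w1$labels, names(splits))
  new_labels <- character(0)
  map <- character(0)
  for (lab in graph_w1$labels) {
    if (lab %in% names(splits)) {
      parts <- as.character(splits[[lab]])
      if (anyDuplicated(parts)) stop("duplicate part labels for ", lab)
      clash <- intersect(setdiff(parts, lab), c(kept, new_labels))
      if (length(clash)) stop("split label collides with existing label: ",
                              paste(clash, collapse = ", "))
      new_labels <- c(new_labels, parts)
      map <- c(map, stats::setNames(rep(lab, length(parts)), parts))
    } else {
      new_labels <- c(new_labels, lab)
      map <- c(map, stats::setNames(lab, lab))
    }
  }
  parent_of <- function(lab2) map[[lab2]]
  nbrs1 <- neighbour_list(graph_w1)
  pairs <- list()
  add <- function(a, b) pairs[[length(pairs) + 1L]] <<- c(a, b)
  for (i in seq_along(new_labels)) {
    for (j in seq_along(new_labels)) {
      if (j <= i) next
      a <- new_labels[i]; b <- new_labels[j]
      pa <- parent_of(a); pb <- parent_of(b)
      if (pa == pb || pb %in% nbrs1[[pa]]) add(a, b)
    }
  }
  g2 <- region_graph(new_labels, do.call(rbind, pairs))
  list(graph = g2, map = map)
}

#' Survey design for the synthetic generator
#'
#' Describes the two-stage sample: how many clusters per region (stage 1),
#' 21 households per cluster (stage 2), a truncated-Poisson(2) number of
#' women aged 15-49 per household on \{0,...,4\}, per-region urban fractions
#' and per-region ethnicity mixing (the generator's region-ethnicity
#' confounding). For the Senegal fixture labels the defaults are calibrated
#' to the published sample composition (region shares, 377 clusters,
#' ~14.6k women); for other graphs shares are uniform.
#'
#' @param graph a [region_graph] for the wave being simulated.
#' @param women_target approximate number of respondents wanted; scales the
#'   cluster counts. Default 14600 for the Senegal fixture, 40 per region
#'   otherwise.
#' @param households_per_cluster stage-2 take, default 21.
#' @param wave_region_map named character (wave-2 label -> wave-1 parent), as
#'   produced by [split_region_map]; required downstream for harmonization
#'   and for inheriting wave-1 spatial effects.
#' @param inherit_sd standard deviation of the perturbation added to a
#'   parent's spatial effect when its parts inherit it (default 0.2).
#' @return an object of class `survey_design`.
#' @export
default_design <- function(graph, women_target = NULL,
                           households_per_cluster = 21L,
                           wave_region_map = NULL, inherit_sd = 0.2) {
  stopifnot(inherits(graph, "region_graph"))
  labs <- graph$labels
  sn_shares <- c(Dakar = 26.5, Diourbel = 10.6, Fatick = 4.8, Kaffrine = 3.7,
                 Kaolack = 11.3, Kedougou = 0.7, Kolda = 7.2, Louga = 6.3,
                 Matam = 3.7, "Saint-Louis" = 6.5, Sedhiou = 2.9,
                 Tambacounda = 5.8, Thies = 13.5, Ziguinchor = 3.9)
  sn_urban <- c(Dakar = 0.93, Diourbel = 0.25, Fatick = 0.2, Kaffrine = 0.2,
                Kaolack = 0.35, Kedougou = 0.2, Kolda = 0.3, Louga = 0.25,
                Matam = 0.25, "Saint-Louis" = 0.45, Sedhiou = 0.25,
                Tambacounda = 0.3, Thies = 0.5, Ziguinchor = 0.45)
  is_sn <- all(labs %in% names(sn_shares))
  if (is_sn) {
    shares <- sn_shares[labs] / sum(sn_shares[labs])
    urban <- sn_urban[labs]
    if (is.null(women_target)) women_target <- 14600
  } else {
    shares <- stats::setNames(rep(1 / length(labs), length(labs)), labs)
    urban <- stats::setNames(rep(0.4, length(labs)), labs)
    if (is.null(women_target)) women_target <- 40 * length(labs)
  }
  women_per_cluster <- households_per_cluster * 1.86 # E[truncPois(2) on 0..4]
  total_clusters <- max(length(labs), round(women_target / women_per_cluster))
  clusters <- pmax(1L, as.integer(round(shares * total_clusters)))
  names(clusters) <- labs
  structure(list(
    clusters_per_region = clusters,
    households_per_cluster = as.integer(households_per_cluster),
    urban_fraction = urban,
    ethnicity_probs = ethnicity_mixing(labs),
    wave_region_map = wave_region_map,
    inherit_sd = inherit_sd
  ), class = "survey_design")
}

# Per-region ethnicity distributions. For Senegal labels a hand-coded tilt
# reflecting the broad geography (Poular/Mandingu in the south-east, Wolof in
# the centre-west, Serer around Fatick, Diola in Ziguinchor); elsewhere a
# deterministic tilt so region-ethnicity confounding is always present.
ethnicity_mixing <- function(labels) {
  eth <- covariate_levels$ethnicity
  base <- c(0.397, 0.252, 0.159, 0.046, 0.049, 0.028, 0.017, 0.052)
  tilt <- matrix(0, length(labels), length(eth),
                 dimnames = list(labels, eth))
  sn_tilt <- list(
    Dakar = c(Wolof = 0.6), Diourbel = c(Wolof = 1), Louga = c(Wolof = 1),
    Thies = c(Wolof = 0.5, Serer = 0.5),
    Fatick = c(Serer = 1.6), Kaolack = c(Serer = 0.8, Wolof = 0.4),
    Kaffrine = c(Wolof = 0.6, Poular = 0.4),
    Matam = c(Poular = 2.2, Soninke = 1),
    "Saint-Louis" = c(Poular = 1.4, Wolof = 0.3),
    Tambacounda = c(Poular = 1.2, Mandingu = 1.4, Soninke = 1.6),
    Kedougou = c(Mandingu = 1.8, Poular = 1, Other = 1),
    Kolda = c(Poular = 1.8, Mandingu = 1.2),
    Sedhiou = c(Mandingu = 1.6, Diola = 1, Poular = 0.8),
    Ziguinchor = c(Diola = 2.4, Mandingu = 0.8)
  )
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab %in% names(sn_tilt)) {
      tl <- sn_tilt[[lab]]
      tilt[i, names(tl)] <- tl
    } else {
      # deterministic non-trivial mixing for arbitrary graphs
      tilt[i, ] <- 0.8 * sin(i * seq_along(eth))
    }
  }
  probs <- sweep(exp(tilt), 2L, base, `*`)
  sweep(probs, 1L, rowSums(probs), `/`)
}

#' Ground truth of a simulation run
#'
#' Validates and stores the generative parameters on the log-odds scale:
#' intercept, per-covariate level effects (reference level 0), the nonlinear
#' age effect as a function on [15, 49], and per-region structured and
#' unstructured spatial effects. Spatial vectors are centered to sum to zero
#' per connected component of the graph (the identifiability convention the
#' fitted model also uses).
#'
#' @param graph the [region_graph] the spatial effects live on.
#' @param intercept scalar log-odds intercept.
#' @param beta named list of named numeric vectors, one entry per categorical
#'   covariate, one coefficient per level (reference 0).
#' @param f_age function of age in years returning a log-odds offset; it is
#'   re-centered empirically by the simulator so only its shape matters.
#' @param f_str,f_unstr named per-region numeric vectors.
#' @param tau2_str,tau2_unstr,tau2_age positive variance components (recorded
#'   for reference; the drawn vectors carry the actual effects).
#' @param hotspot optional label(s) recorded as the planted hotspot(s).
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(graph, intercept = 0, beta = list(),
                         f_age = function(age) rep(0, length(age)),
                         f_str = NULL, f_unstr = NULL,
                         tau2_str = 1, tau2_unstr = 1, tau2_age = 1,
                         hotspot = character(0)) {
  stopifnot(inherits(graph, "region_graph"))
  labs <- graph$labels
  zero <- stats::setNames(rep(0, length(labs)), labs)
  if (is.null(f_str)) f_str <- zero
  if (is.null(f_unstr)) f_unstr <- zero
  if (!setequal(names(f_str), labs) || !setequal(names(f_unstr), labs)) {
    stop("f_str/f_unstr must be named by the graph's region labels")
  }
  f_str <- center_by_component(f_str[labs], graph)
  f_unstr <- center_by_component(f_unstr[labs], graph)
  if (any(c(tau2_str, tau2_unstr, tau2_age) <= 0)) {
    stop("variance components must be > 0")
  }
  for (nm in names(beta)) {
    if (is.null(names(beta[[nm]]))) stop("beta$", nm, " must be named by level")
  }
  structure(list(graph = graph, intercept = intercept, beta = beta,
                 f_age = f_age, f_str = f_str, f_unstr = f_unstr,
                 tau2_str = tau2_str, tau2_unstr = tau2_unstr,
                 tau2_age = tau2_age, hotspot = hotspot),
            class = "ground_truth")
}

center_by_component <- function(v, graph) {
  for (comp in connected_components(graph)) {
    v[comp] <- v[comp] - mean(v[comp])
  }
  v
}

#' Default generative truth
#'
#' Draws a complete ground truth on a graph: the structured effect from the
#' intrinsic-CAR distribution (scaled by `tau2_str`, centered per component),
#' the unstructured effect i.i.d. normal (centered), a smooth declining age
#' curve (prevalence highest under age 20, declining thereafter), and fixed
#' effects loosely echoing the published adjusted odds ratios (large
#' ethnicity contrasts, graded wealth contrasts, modest residence/religion
#' effects). All magnitudes are overridable; the defaults are the package's
#' stated world, not tuning knobs.
#'
#' @param graph a [region_graph].
#' @param seed integer seed; mandatory, all generation is reproducible.
#' @param intercept log-odds intercept (default -5.6, giving a marginal
#'   prevalence near 30\% under the default covariate mix).
#' @param tau2_str,tau2_unstr variances of the spatial draws (defaults 0.6
#'   and 0.1: structure dominates heterogeneity).
#' @param age_amplitude size of the declining age effect on the log-odds
#'   scale (default 0.9; ~0.85 drop from age 15 to 49).
#' @param beta named list overriding any default fixed-effect vectors.
#' @param hotspot optional region label(s) given an extra `hotspot_effect`
#'   split equally between the structured and unstructured components.
#' @param hotspot_effect log-odds bump for hotspot regions (default 2).
#' @return a [ground_truth].
#' @export
default_truth <- function(graph, seed, intercept = -5.6,
                          tau2_str = 0.6, tau2_unstr = 0.1,
                          age_amplitude = 0.9, beta = NULL,
                          hotspot = character(0), hotspot_effect = 2) {
  stopifnot(inherits(graph, "region_graph"))
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  set.seed(seed)
  labs <- graph$labels
  f_str <- ricar(graph, tau2_str)
  f_unstr <- stats::rnorm(length(labs), 0, sqrt(tau2_unstr))
  names(f_unstr) <- labs
  if (length(hotspot)) {
    bad <- setdiff(hotspot, labs)
    if (length(bad)) stop("hotspot not in graph: ", paste(bad, collapse = ", "))
    f_str[hotspot] <- f_str[hotspot] + hotspot_effect / 2
    f_unstr[hotspot] <- f_unstr[hotspot] + hotspot_effect / 2
  }
  f_age <- local({
    amp <- age_amplitude
    function(age) amp * exp(-(age - 15) / 12)
  })
  b <- list(
    urban = c("0" = 0, "1" = -0.3),
    married = c("0" = 0, "1" = 0.35),
    education = c(none = 0.6, primary = 0.5, secondary = 0.3, higher = 0),
    partner_education = c(none = 0.25, primary = 0.45, secondary = 0.35,
                          higher = 0),
    wealth = c(poorest = 1.5, poorer = 1.45, middle = 0.9, richer = 0.55,
               richest = 0),
    family_size = c(small = 0, middle = 0.15, large = 0.1),
    ethnicity = c(Wolof = 0, Poular = 3.1, Serer = -1.5, Mandingu = 4.4,
                  Diola = 3.0, Soninke = 4.3, NotSenegalese = 3.5,
                  Other = 2.4),
    religion = c(muslim = 1.1, other = 0)
  )
  if (!is.null(beta)) b[names(beta)] <- beta
  ground_truth(graph, intercept = intercept, beta = b, f_age = f_age,
               f_str = f_str, f_unstr = f_unstr, tau2_str = tau2_str,
               tau2_unstr = tau2_unstr, tau2_age = 1, hotspot = hotspot)
}

# one draw from the (improper) intrinsic-CAR prior, projected onto the
# per-component sum-to-zero subspace: N(0, tau2 * Q^+) via eigendecomposition
ricar <- function(graph, tau2) {
  labs <- graph$labels
  if (tau2 == 0) return(stats::setNames(rep(0, length(labs)), labs))
  Q <- unclass(icar_precision(graph))
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-9
  if (!any(pos)) return(stats::setNames(rep(0, length(labs)), labs))
  z <- stats::rnorm(sum(pos))
  f <- e$vectors[, pos, drop = FALSE] %*% (z * sqrt(tau2 / e$values[pos]))
  center_by_component(stats::setNames(drop(f), labs), graph)
}

#' Derive a wave-2 truth from a wave-1 truth
#'
#' Each wave-2 region inherits its wave-1 parent's structured and
#' unstructured effects plus independent N(0, sd^2) perturbations, then both
#' vectors are re-centered; fixed effects, age curve and intercept carry over
#' unchanged.
#'
#' @param truth wave-1 [ground_truth].
#' @param graph_w2 wave-2 [region_graph].
#' @param map named character wave-2 label -> wave-1 parent.
#' @param seed integer seed for the perturbations.
#' @param sd perturbation standard deviation (default 0.2).
#' @return a [ground_truth] on `graph_w2`.
#' @export
wave2_truth <- function(truth, graph_w2, map, seed, sd = 0.2) {
  stopifnot(inherits(truth, "ground_truth"), inherits(graph_w2, "region_graph"))
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  labs2 <- graph_w2$labels
  miss <- setdiff(labs2, names(map))
  if (length(miss)) stop("wave_region_map misses regions: ",
                         paste(miss, collapse = ", "))
  set.seed(seed)
  f_str <- truth$f_str[map[labs2]] + stats::rnorm(length(labs2), 0, sd)
  f_unstr <- truth$f_unstr[map[labs2]] + stats::rnorm(length(labs2), 0, sd)
  names(f_str) <- names(f_unstr) <- labs2
  hot2 <- names(map)[map %in% truth$hotspot]
  ground_truth(graph_w2, intercept = truth$intercept, beta = truth$beta,
               f_age = truth$f_age, f_str = f_str, f_unstr = f_unstr,
               tau2_str = truth$tau2_str, tau2_unstr = truth$tau2_unstr,
               tau2_age = truth$tau2_age, hotspot = hot2)
}

#' Simulate one survey wave
#'
#' Two-stage sample: stage 1 lays down `clusters_per_region[r]` clusters in
#' each region (each cluster urban with the region's urban fraction); stage 2
#' takes `households_per_cluster` households per cluster and interviews all
#' women aged 15-49 in them (a truncated-Poisson(2) count on 0-4 per
#' household). Covariates are drawn from region-dependent multinomials
#' (ethnicity mixing per region, wealth shifted by urbanicity, marriage
#' age-dependent); partner covariates exist only for married women. The
#' outcome is Bernoulli with
#' logit p = intercept + covariate effects + f_age(age) + f_str + f_unstr,
#' where f_age is centered over the realized ages so the intercept keeps its
#' meaning.
#'
#' @param truth a [ground_truth]. Its graph must match `graph`; for `wave = 2`
#'   a wave-1 truth is accepted and converted via [wave2_truth] using
#'   `design$wave_region_map` (perturbation sd `design$inherit_sd`).
#' @param design a `survey_design` covering `graph`'s regions.
#' @param graph the wave's [region_graph].
#' @param wave 1 or 2 (recorded in the data; drives truth inheritance).
#' @param seed integer seed; mandatory.
#' @return a `data.frame` of class `survey_dataset`, one row per respondent,
#'   columns as documented in [validate_dataset]; the truth actually used is
#'   attached as attribute `truth`.
#' @export
simulate_survey <- function(truth, design, graph, wave = 1L, seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "survey_design"),
            inherits(graph, "region_graph"))
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  wave <- as.integer(wave)
  if (!wave %in% c(1L, 2L)) stop("wave must be 1 or 2")
  if (!setequal(truth$graph$labels, graph$labels)) {
    if (wave == 2L) {
      if (is.null(design$wave_region_map)) {
        stop("wave = 2 with a wave-1 truth requires design$wave_region_map")
      }
      truth <- wave2_truth(truth, graph, design$wave_region_map,
                           seed = seed + 1000003L, sd = design$inherit_sd)
    } else {
      stop("truth regions do not match graph regions")
    }
  }
  labs <- graph$labels
  miss <- setdiff(labs, names(design$clusters_per_region))
  if (length(miss)) stop("design does not cover regions: ",
                         paste(miss, collapse = ", "))
  set.seed(seed)
  eth_probs <- design$ethnicity_probs
  if (!all(labs %in% rownames(eth_probs))) {
    eth_probs <- ethnicity_mixing(labs)
  }
  rows <- vector("list", length(labs))
  for (ri in seq_along(labs)) {
    reg <- labs[ri]
    n_cl <- design$clusters_per_region[[reg]]
    reg_rows <- vector("list", n_cl)
    for (cl in seq_len(n_cl)) {
      cl_id <- sprintf("%s_c%03d", reg, cl)
      cl_urban <- stats::rbinom(1L, 1L, design$urban_fraction[[reg]])
      n_women_hh <- rtrunc_pois(design$households_per_cluster, 2, 4L)
      n_w <- sum(n_women_hh)
      if (n_w == 0L) next
      hh_id <- rep(sprintf("%s_h%02d", cl_id,
                           seq_len(design$households_per_cluster)),
                   times = n_women_hh)
      age <- sample(15:49, n_w, replace = TRUE,
                    prob = exp(-0.045 * (0:34)))
      married <- stats::rbinom(n_w, 1L, stats::plogis(-4 + 0.2 * age))
      educ_p <- c(0.596, 0.252, 0.142, 0.010)
      if (cl_urban == 1L) educ_p <- c(0.45, 0.28, 0.24, 0.03)
      education <- sample(covariate_levels$education, n_w, TRUE, educ_p)
      wealth_p <- if (cl_urban == 1L) c(0.05, 0.08, 0.17, 0.3, 0.4) else
        c(0.26, 0.26, 0.22, 0.16, 0.10)
      wealth <- sample(covariate_levels$wealth, n_w, TRUE, wealth_p)
      family_size <- sample(covariate_levels$family_size, n_w, TRUE,
                            c(0.846, 0.130, 0.024))
      ethnicity <- sample(covariate_levels$ethnicity, n_w, TRUE,
                          eth_probs[reg, ])
      rel_p <- ifelse(ethnicity == "Serer", 0.85, 0.97)
      religion <- ifelse(stats::runif(n_w) < rel_p, "muslim", "other")
      partner_education <- rep(NA_character_, n_w)
      partner_age <- rep(NA_integer_, n_w)
      m <- married == 1L
      if (any(m)) {
        partner_education[m] <- sample(covariate_levels$partner_education,
                                       sum(m), TRUE,
                                       c(0.703, 0.126, 0.129, 0.042))
        pa <- age[m] + round(stats::rnorm(sum(m), 14, 6))
        partner_age[m] <- pmin(pmax(pa, 18L), 97L)
      }
      reg_rows[[cl]] <- data.frame(
        wave = wave, region = reg, cluster = cl_id, household = hh_id,
        age = as.integer(age), urban = cl_urban, married = married,
        education = education, partner_education = partner_education,
        wealth = wealth, family_size = family_size, ethnicity = ethnicity,
        religion = religion, partner_age = partner_age,
        stringsAsFactors = FALSE)
    }
    rows[[ri]] <- do.call(rbind, reg_rows)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  # linear predictor from the truth
  eta <- rep(truth$intercept, nrow(df))
  fa <- truth$f_age(df$age)
  eta <- eta + (fa - mean(fa))
  eta <- eta + truth$f_str[df$region] + truth$f_unstr[df$region]
  for (nm in names(truth$beta)) {
    vals <- truth$beta[[nm]]
    col <- as.character(df[[nm]])
    contrib <- ifelse(is.na(col), 0, vals[col])
    contrib[is.na(contrib)] <- 0
    eta <- eta + contrib
  }
  df$outcome <- stats::rbinom(nrow(df), 1L, stats::plogis(unname(eta)))
  df <- df[, dataset_columns]
  class(df) <- c("survey_dataset", "data.frame")
  attr(df, "truth") <- truth
  validate_dataset(df, graph)
  df
}

# truncated Poisson(lambda) on {0, ..., kmax}, vector of n draws
rtrunc_pois <- function(n, lambda, kmax) {
  k <- 0:kmax
  p <- stats::dpois(k, lambda)
  sample(k, n, replace = TRUE, prob = p / sum(p))
}

#' Validate a respondent-level survey dataset
#'
#' Columns (in order): `outcome` (0/1), `wave` (1/2), `region`, `cluster`,
#' `household`, `age` (integer 15-49), `urban` (0/1), `married` (0/1),
#' `education`, `partner_education` (4 levels, may be missing),
#' `wealth` (5 levels), `family_size` (3 levels), `ethnicity`, `religion`,
#' `partner_age` (integer or missing). Checks the value ranges, that cluster
#' ids never span regions and (when a graph is given) that every region label
#' is in the graph.
#'
#' @param dataset a data.frame.
#' @param graph optional [region_graph] to check region labels against.
#' @return the dataset, invisibly, with class `survey_dataset`.
#' @export
validate_dataset <- function(dataset, graph = NULL) {
  miss <- setdiff(dataset_columns, names(dataset))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(dataset)) stop("empty dataset")
  if (!all(dataset$outcome %in% c(0L, 1L))) {
    stop("outcome must be 0/1; offending rows: ",
         paste(utils::head(which(!dataset$outcome %in% c(0L, 1L))),
               collapse = ", "))
  }
  if (!all(dataset$wave %in% c(1L, 2L))) stop("wave must be 1 or 2")
  if (any(dataset$age < 15L | dataset$age > 49L)) {
    stop("age outside [15, 49]")
  }
  if (!all(dataset$urban %in% c(0L, 1L))) stop("urban must be 0/1")
  if (!all(dataset$married %in% c(0L, 1L))) stop("married must be 0/1")
  spans <- tapply(dataset$region, dataset$cluster,
                  function(r) length(unique(r)))
  if (any(spans > 1L)) {
    stop("cluster ids span regions: ",
         paste(names(spans)[spans > 1L], collapse = ", "))
  }
  if (!is.null(graph)) {
    bad <- setdiff(unique(dataset$region), graph$labels)
    if (length(bad)) stop("regions not in graph: ", paste(bad, collapse = ", "))
  }
  if (!inherits(dataset, "survey_dataset")) {
    class(dataset) <- c("survey_dataset", "data.frame")
  }
  invisible(dataset)
}

#' Write / read a survey dataset as CSV
#'
#' Fixed documented header, UTF-8, "." decimal, missing `partner_age` /
#' `partner_education` written as empty fields. The round trip is exact and
#' identical seeds give byte-identical files.
#'
#' @param dataset a validated survey dataset.
#' @param path CSV path.
#' @return `path` invisibly (write); the dataset (read).
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  df <- as.data.frame(dataset)[, dataset_columns]
  utils::write.table(df, path, sep = ",", row.names = FALSE, col.names = TRUE,
                     qmethod = "double", quote = FALSE, na = "",
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname write_dataset
#' @param graph optional [region_graph] passed to [validate_dataset].
#' @export
read_dataset <- function(path, graph = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = c(
                          outcome = "integer", wave = "integer",
                          region = "character", cluster = "character",
                          household = "character", age = "integer",
                          urban = "integer", married = "integer",
                          education = "character",
                          partner_education = "character",
                          wealth = "character", family_size = "character",
                          ethnicity = "character", religion = "character",
                          partner_age = "integer"))
  out <- validate_dataset(df, graph)
  class(df) <- c("survey_dataset", "data.frame")
  df
}

#' Dump a ground truth to JSON
#'
#' All planted parameters (intercept, fixed effects, age curve on the 15-49
#' grid, spatial vectors, variances, hotspot labels) for recovery tests.
#'
#' @param truth a [ground_truth].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  grid <- 15:49
  fa <- truth$f_age(grid)
  obj <- list(intercept = truth$intercept, beta = truth$beta,
              age_grid = grid, f_age = fa - mean(fa),
              f_str = as.list(truth$f_str), f_unstr = as.list(truth$f_unstr),
              tau2_str = truth$tau2_str, tau2_unstr = truth$tau2_unstr,
              tau2_age = truth$tau2_age, hotspot = truth$hotspot,
              labels = truth$graph$labels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
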