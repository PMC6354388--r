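#' Model specification for the geo-additive regression
#'
#' Declares the terms of the predictor
#' eta = intercept + W gamma + sum_j B_j alpha_j + f_str(region) +
#' f_unstr(region): which categorical covariates enter as dummy-coded fixed
#' effects (with their reference levels), which continuous covariates get a
#' penalized-spline nonlinear effect, and whether the structured (intrinsic
#' CAR) and unstructured (exchangeable) region effects are included.
#'
#' @param fixed named character vector: covariate name -> reference level.
#'   May be empty.
#' @param nonlinear named list: continuous covariate name -> list/vector with
#'   `n_inner_knots` and `degree` (defaults 20 and 3).
#' @param spatial_field name of the region column (default "region").
#' @param include_structured,include_unstructured logical switches for the
#'   two spatial blocks.
#' @param hyper_a,hyper_b inverse-gamma hyperparameters shared by every
#'   variance component (default 0.001/0.001; 0.01 or 0.1 are the documented
#'   sensitivity settings).
#' @param link "logit" (Polya-Gamma augmentation; odds-ratio reporting) or
#'   "probit" (latent-Gaussian augmentation).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(fixed = character(0), nonlinear = list(),
                       spatial_field = "region",
                       include_structured = TRUE, include_unstructured = TRUE,
                       hyper_a = 0.001, hyper_b = 0.001, link = "logit") {
  link <- match.arg(link, c("logit", "probit"))
  if (hyper_a <= 0 || hyper_b <= 0) stop("hyperparameters must be > 0")
  if (length(fixed) && is.null(names(fixed))) {
    stop("fixed must be a named vector: covariate -> reference level")
  }
  nl <- list()
  for (nm in names(nonlinear)) {
    v <- as.list(nonlinear[[nm]])
    nl[[nm]] <- list(
      n_inner_knots = as.integer(v$n_inner_knots %||% 20L),
      degree = as.integer(v$degree %||% 3L))
  }
  if (!length(fixed) && !length(nl) && !include_structured &&
      !include_unstructured) {
    # intercept-only is permitted; flag only a fully term-free misuse
    # (intercept always present, so this is fine)
  }
  structure(list(fixed = fixed, nonlinear = nl, spatial_field = spatial_field,
                 include_structured = include_structured,
                 include_unstructured = include_unstructured,
                 hyper_a = hyper_a, hyper_b = hyper_b, link = link),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' MCMC configuration
#'
#' @param iterations total Gibbs iterations (default 12000).
#' @param burn_in discarded initial iterations (default 2000; must be <
#'   `iterations`, equality gives a valid empty chain).
#' @param thin keep every `thin`-th post-burn-in draw (default 10).
#' @param seed integer seed; mandatory.
#' @param init "zeros" or "mle-jitter" (fixed-effect start at a quick IRLS
#'   fit plus small noise).
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 12000L, burn_in = 2000L, thin = 10L,
                        seed, init = "zeros") {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  init <- match.arg(init, c("zeros", "mle-jitter"))
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in > iterations) stop("burn_in must be <= iterations")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), init = init),
            class = "mcmc_config")
}

#' Build the design blocks of the geo-additive model
#'
#' Dummy-codes the fixed effects (declared reference dropped), builds one
#' B-spline basis and RW2 penalty per nonlinear term, indexes observations
#' to regions, and attaches the intrinsic-CAR precision of the graph. Rows
#' with missing values in any used field are dropped with a message (the
#' count is recorded in attribute `n_dropped`).
#'
#' @param dataset a survey dataset.
#' @param spec a [model_spec].
#' @param graph a [region_graph]; every dataset region must be in it.
#' @return an object of class `design_blocks`: `y`, `W`, `B` (list), `K`
#'   (list), `region_idx`, `labels`, `Q`, `comp` (component index per
#'   region), `graph`, `spec`, `n`, plus per-term spline metadata.
#' @export
build_design <- function(dataset, spec, graph) {
  stopifnot(inherits(spec, "model_spec"), inherits(graph, "region_graph"))
  used <- unique(c("outcome", spec$spatial_field, names(spec$fixed),
                   names(spec$nonlinear)))
  miss_cols <- setdiff(used, names(dataset))
  if (length(miss_cols)) stop("fields not in dataset: ",
                              paste(miss_cols, collapse = ", "))
  cc <- stats::complete.cases(dataset[used])
  n_dropped <- sum(!cc)
  if (n_dropped) {
    message("dropping ", n_dropped, " rows with missing values in model fields")
  }
  df <- dataset[cc, , drop = FALSE]
  if (!nrow(df)) stop("no complete rows")
  bad <- setdiff(unique(as.character(df[[spec$spatial_field]])), graph$labels)
  if (length(bad)) stop("regions in data but not in graph: ",
                        paste(bad, collapse = ", "))
  y <- as.numeric(df$outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  # fixed-effect dummies, reference dropped
  Wcols <- list()
  for (nm in names(spec$fixed)) {
    ref <- spec$fixed[[nm]]
    v <- as.character(df[[nm]])
    levs <- if (nm %in% names(covariate_levels)) {
      covariate_levels[[nm]]
    } else if (nm %in% c("urban", "married")) {
      c("0", "1")
    } else {
      sort(unique(v))
    }
    unseen <- setdiff(unique(v), levs)
    if (length(unseen)) stop("unseen level(s) in ", nm, ": ",
                             paste(unseen, collapse = ", "))
    if (!ref %in% levs) stop("reference level '", ref, "' not a level of ", nm)
    for (lv in setdiff(levs, ref)) {
      if (!any(v == lv)) next # absent level: no column (logged by dimnames)
      Wcols[[paste0(nm, ":", lv)]] <- as.numeric(v == lv)
    }
  }
  W <- if (length(Wcols)) {
    do.call(cbind, Wcols)
  } else {
    matrix(numeric(0), nrow = nrow(df), ncol = 0L)
  }
  # spline blocks
  B <- list()
  K <- list()
  for (nm in names(spec$nonlinear)) {
    cfg <- spec$nonlinear[[nm]]
    x <- as.numeric(df[[nm]])
    Bj <- bspline_design(x, cfg$n_inner_knots, cfg$degree)
    B[[nm]] <- Bj
    K[[nm]] <- rw2_penalty(ncol(Bj))
  }
  region_idx <- match(as.character(df[[spec$spatial_field]]), graph$labels)
  Q <- unclass(icar_precision(graph))
  structure(list(y = y, W = W, B = B, K = K, region_idx = region_idx,
                 labels = graph$labels, Q = Q,
                 comp = component_index(graph), graph = graph, spec = spec,
                 n = nrow(df), n_dropped = n_dropped,
                 data = df),
            class = "design_blocks")
}

# draw from N(prec^{-1} rhs, prec^{-1}) via Cholesky; adds jitter on failure
draw_gaussian <- function(prec, rhs) {
  R <- tryCatch(chol(prec), error = function(e) {
    chol(prec + diag(1e-8 * max(diag(prec)), nrow(prec)))
  })
  mu <- backsolve(R, forwardsolve(t(R), rhs))
  mu + backsolve(R, stats::rnorm(length(rhs)))
}

#' Fit the Bayesian geo-additive binary regression by Gibbs sampling
#'
#' Data-augmentation Gibbs sampler. For the logit link every iteration draws
#' Polya-Gamma latent weights omega_i | eta_i ~ PG(1, eta_i), after which
#' each coefficient block (intercept + fixed effects jointly, each spline
#' block, the structured and the unstructured region block) has a conjugate
#' Gaussian full conditional, and each variance component an inverse-gamma
#' one: tau2 ~ IG(a + rank(P)/2, b + theta' P theta / 2). For the probit
#' link the same machinery runs with unit weights and truncated-normal
#' latent responses. After its draw every penalized block is re-centered to
#' its sum-to-zero constraint (empirical mean over observations for splines,
#' per-component mean for the spatial blocks) with the removed mean absorbed
#' into the intercept, keeping the predictor invariant and the blocks
#' identified against the improper RW2/ICAR priors.
#'
#' Fixed effects and intercept carry a diffuse N(0, 1e6) prior. The sampler
#' never inverts the rank-deficient ICAR precision: it works with the full
#' conditional precision (data + prior), which is positive definite whenever
#' every connected component has observations.
#'
#' @param blocks a [build_design] result.
#' @param y binary outcome vector; defaults to `blocks$y`.
#' @param config an [mcmc_config].
#' @param spec optional [model_spec] override; defaults to `blocks$spec`.
#' @return object of class `geofgm_fit`: `intercept` (vector of stored
#'   draws), `gamma` (draws x fixed effects), `alpha` (list of draws x basis
#'   matrices), `f_str`, `f_unstr` (draws x regions), `tau2` (draws x
#'   components), `spline_meta`, `labels`, `comp`, `config`, `spec`,
#'   `n_stored`.
#' @export
gibbs_fit <- function(blocks, y = blocks$y, config, spec = blocks$spec) {
  stopifnot(inherits(blocks, "design_blocks"), inherits(config, "mcmc_config"))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  n <- length(y)
  if (n != blocks$n) stop("y length does not match design")
  W <- blocks$W
  p <- ncol(W)
  X0 <- cbind(`(Intercept)` = rep(1, n), W)
  B <- blocks$B
  K <- blocks$K
  labs <- blocks$labels
  R <- length(labs)
  ridx <- blocks$region_idx
  comp <- blocks$comp
  ncomp <- max(comp)
  use_str <- spec$include_structured
  use_unstr <- spec$include_unstructured
  Q <- blocks$Q
  a0 <- spec$hyper_a
  b0 <- spec$hyper_b
  probit <- spec$link == "probit"

  set.seed(config$seed)
  # state
  beta <- rep(0, p + 1L) # intercept first
  alpha <- lapply(B, function(Bj) rep(0, ncol(Bj)))
  fs <- rep(0, R)
  fu <- rep(0, R)
  tau2_age <- stats::setNames(rep(1, length(B)), names(B))
  tau2_str <- 1
  tau2_unstr <- 1
  if (config$init == "mle-jitter" && p >= 0L) {
    fit0 <- suppressWarnings(stats::glm.fit(X0, y,
                                            family = stats::binomial()))
    cf <- fit0$coefficients
    cf[!is.finite(cf)] <- 0
    beta <- cf + stats::rnorm(length(cf), 0, 0.1)
  }
  eta_fixed <- drop(X0 %*% beta)
  eta_spl <- lapply(B, function(Bj) rep(0, n))
  eta <- eta_fixed + fs[ridx] + fu[ridx]

  n_stored <- max(0L, (config$iterations - config$burn_in) %/% config$thin)
  st_int <- numeric(n_stored)
  st_gamma <- matrix(NA_real_, n_stored, p,
                     dimnames = list(NULL, colnames(W)))
  st_alpha <- lapply(B, function(Bj) matrix(NA_real_, n_stored, ncol(Bj)))
  st_fs <- matrix(NA_real_, n_stored, R, dimnames = list(NULL, labs))
  st_fu <- matrix(NA_real_, n_stored, R, dimnames = list(NULL, labs))
  tau_names <- c(if (length(B)) paste0("tau2_", names(B)),
                 if (use_str) "tau2_str", if (use_unstr) "tau2_unstr")
  st_tau <- matrix(NA_real_, n_stored, length(tau_names),
                   dimnames = list(NULL, tau_names))
  prior_prec_fixed <- 1e-6

  slot <- 0L
  for (it in seq_len(config$iterations)) {
    # latent augmentation
    if (probit) {
      omega <- rep(1, n)
      u <- stats::runif(n)
      plo <- stats::pnorm(-eta)
      # truncated normal via inverse cdf: y=1 -> (0, Inf), y=0 -> (-Inf, 0)
      z <- stats::qnorm(ifelse(y == 1, plo + u * (1 - plo), u * plo))
      z <- pmin(pmax(z, -8), 8) + eta
      s <- z * omega
    } else {
      omega <- .rpg_devroye(eta)
      s <- y - 0.5
    }

    # intercept + fixed effects
    eta_rest <- eta - eta_fixed
    Xw <- X0 * omega
    prec <- crossprod(X0, Xw)
    diag(prec) <- diag(prec) + prior_prec_fixed
    rhs <- drop(crossprod(X0, s - omega * eta_rest))
    beta <- draw_gaussian(prec, rhs)
    eta_fixed <- drop(X0 %*% beta)
    eta <- eta_rest + eta_fixed

    # spline blocks
    for (j in seq_along(B)) {
      Bj <- B[[j]]
      eta_rest <- eta - eta_spl[[j]]
      prec <- crossprod(Bj, Bj * omega) + K[[j]] / tau2_age[j]
      rhs <- drop(crossprod(Bj, s - omega * eta_rest))
      aj <- draw_gaussian(prec, rhs)
      fit <- drop(Bj %*% aj)
      ctr <- mean(fit) # basis rows sum to 1: shifting aj shifts fit
      aj <- aj - ctr
      fit <- fit - ctr
      beta[1L] <- beta[1L] + ctr
      eta_fixed <- eta_fixed + ctr
      alpha[[j]] <- aj
      eta_spl[[j]] <- fit
      eta <- eta_rest + fit + ctr
      quad <- drop(crossprod(aj, K[[j]] %*% aj))
      tau2_age[j] <- 1 / stats::rgamma(1, a0 + (ncol(Bj) - 2) / 2,
                                       rate = b0 + quad / 2)
    }

    # unstructured region block: independent normals given omega
    if (use_unstr) {
      eta_rest <- eta - fu[ridx]
      wsum <- vapply(seq_len(R), function(r) sum(omega[ridx == r]), 0)
      rsum <- vapply(seq_len(R), function(r) {
        sum((s - omega * eta_rest)[ridx == r])
      }, 0)
      precs <- wsum + 1 / tau2_unstr
      fu <- rsum / precs + stats::rnorm(R) / sqrt(precs)
      adj <- center_spatial(fu, comp)
      fu <- adj$f
      beta[1L] <- beta[1L] + adj$shift
      eta_fixed <- eta_fixed + adj$shift
      eta <- eta_rest + fu[ridx] + adj$shift
      tau2_unstr <- 1 / stats::rgamma(1, a0 + (R - ncomp) / 2,
                                      rate = b0 + sum(fu^2) / 2)
      if (tau2_unstr > 1e8) stop("divergent unstructured variance (tau2 > 1e8)")
    }

    # structured (ICAR) region block: joint Gaussian, precision = data + Q/tau2
    if (use_str) {
      eta_rest <- eta - fs[ridx]
      wsum <- vapply(seq_len(R), function(r) sum(omega[ridx == r]), 0)
      rsum <- vapply(seq_len(R), function(r) {
        sum((s - omega * eta_rest)[ridx == r])
      }, 0)
      prec <- Q / tau2_str
      diag(prec) <- diag(prec) + wsum
      fs <- draw_gaussian(prec, rsum)
      adj <- center_spatial(fs, comp)
      fs <- adj$f
      beta[1L] <- beta[1L] + adj$shift
      eta_fixed <- eta_fixed + adj$shift
      eta <- eta_rest + fs[ridx] + adj$shift
      quad <- drop(crossprod(fs, Q %*% fs))
      tau2_str <- 1 / stats::rgamma(1, a0 + (R - ncomp) / 2,
                                    rate = b0 + quad / 2)
      if (tau2_str > 1e8) stop("divergent structured variance (tau2 > 1e8)")
    }

    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      slot <- slot + 1L
      st_int[slot] <- beta[1L]
      if (p) st_gamma[slot, ] <- beta[-1L]
      for (j in seq_along(B)) st_alpha[[j]][slot, ] <- alpha[[j]]
      st_fs[slot, ] <- fs
      st_fu[slot, ] <- fu
      if (length(tau_names)) {
        st_tau[slot, ] <- c(tau2_age, if (use_str) tau2_str,
                            if (use_unstr) tau2_unstr)
      }
    }
  }

  spline_meta <- lapply(B, function(Bj) {
    list(knots = attr(Bj, "knots"), degree = attr(Bj, "degree"),
         xl = attr(Bj, "xl"), xr = attr(Bj, "xr"))
  })
  structure(list(intercept = st_int, gamma = st_gamma, alpha = st_alpha,
                 f_str = st_fs, f_unstr = st_fu, tau2 = st_tau,
                 spline_meta = spline_meta, labels = labs, comp = comp,
                 config = config, spec = spec, n_stored = n_stored,
                 include_structured = use_str,
                 include_unstructured = use_unstr),
            class = "geofgm_fit")
}

# subtract per-component means; report the observation-agnostic overall shift
# to absorb into the intercept (exact when the graph is connected)
center_spatial <- function(f, comp) {
  shift <- 0
  for (k in unique(comp)) {
    m <- mean(f[comp == k])
    f[comp == k] <- f[comp == k] - m
    shift <- shift + m * mean(comp == k)
  }
  list(f = f, shift = shift)
}

#' @export
print.geofgm_fit <- function(x, ...) {
  cat("geofgm_fit:", x$n_stored, "stored draws (",
      x$config$iterations, "iterations, burn-in", x$config$burn_in,
      ", thin", x$config$thin, ")\n")
  cat("fixed effects:", ncol(x$gamma), "| nonlinear terms:",
      length(x$alpha), "| regions:", length(x$labels), "\n")
  invisible(x)
}

#' Posterior-predictive prevalence by region
#'
#' For every stored draw, the mean fitted probability within each region: a
#' cheap model-checking aid (the null model should reproduce the observed
#' prevalence; a planted hotspot should rank first).
#'
#' @param samples a `geofgm_fit`.
#' @param blocks the [build_design] object the fit used.
#' @return matrix draws x regions of predicted prevalences.
#' @export
posterior_predictive_prevalence <- function(samples, blocks) {
  stopifnot(inherits(samples, "geofgm_fit"), inherits(blocks, "design_blocks"))
  if (!samples$n_stored) stop("no stored draws")
  n <- blocks$n
  X0 <- cbind(1, blocks$W)
  ridx <- blocks$region_idx
  R <- length(samples$labels)
  out <- matrix(NA_real_, samples$n_stored, R,
                dimnames = list(NULL, samples$labels))
  linkinv <- if (samples$spec$link == "probit") stats::pnorm else stats::plogis
  for (d in seq_len(samples$n_stored)) {
    eta <- drop(X0 %*% c(samples$intercept[d],
                         if (ncol(blocks$W)) samples$gamma[d, ]))
    for (j in seq_along(blocks$B)) {
      eta <- eta + drop(blocks$B[[j]] %*% samples$alpha[[j]][d, ])
    }
    eta <- eta + samples$f_str[d, ridx] + samples$f_unstr[d, ridx]
    pr <- linkinv(eta)
    out[d, ] <- vapply(seq_len(R), function(r) mean(pr[ridx == r]), 0)
  }
  out
}
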