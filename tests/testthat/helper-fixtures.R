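# shared fixtures, built in code

# Erdos-Renyi-ish random region graph with deterministic labels
random_graph <- function(n_regions, seed, p_edge = 0.35) {
  set.seed(seed)
  labs <- paste0("R", sprintf("%02d", seq_len(n_regions)))
  pairs <- t(combn(labs, 2L))
  keep <- runif(nrow(pairs)) < p_edge
  region_graph(labs, pairs[keep, , drop = FALSE])
}

chain_graph <- function(labels) {
  n <- length(labels)
  region_graph(labels, cbind(labels[-n], labels[-1L]))
}

# tiny simulated survey reused across tests
small_survey <- function(seed = 42, women_target = 800,
                         graph = sn_region_graph(1), ...) {
  truth <- default_truth(graph, seed = seed, ...)
  design <- default_design(graph, women_target = women_target)
  simulate_survey(truth, design, graph, wave = 1L, seed = seed + 1L)
}

# independent de Boor recursion (oracle for bspline_design)
deboor_basis <- function(x, knots, degree) {
  m <- length(knots) - degree - 1L
  B <- sapply(seq_len(m), function(i) {
    vapply(x, function(xx) deboor_one(i, degree, xx, knots), 0)
  })
  matrix(B, nrow = length(x))
}

deboor_one <- function(i, d, x, t) {
  if (d == 0L) {
    return(as.numeric(x >= t[i] && x < t[i + 1L]))
  }
  left <- 0
  if (t[i + d] > t[i]) {
    left <- (x - t[i]) / (t[i + d] - t[i]) * deboor_one(i, d - 1L, x, t)
  }
  right <- 0
  if (t[i + d + 1L] > t[i + 1L]) {
    right <- (t[i + d + 1L] - x) / (t[i + d + 1L] - t[i + 1L]) *
      deboor_one(i + 1L, d - 1L, x, t)
  }
  left + right
}

# IRLS logistic regression (oracle, no glm)
irls_logit <- function(X, y, tol = 1e-12, maxit = 100L) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / w
    beta_new <- solve(crossprod(X, X * w), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

# crude effective sample size from the initial positive autocorrelations
coda_ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1] - 1 else length(ac)
  max(1, n / (1 + 2 * sum(ac[seq_len(cut)])))
}

# grid-quadrature posterior for an intercept-only Bernoulli-logit model with
# N(0, v) prior: returns posterior mean and sd of the intercept
quad_intercept_posterior <- function(y, v = 1e6, lim = 12, n_grid = 20001L) {
  g <- seq(-lim, lim, length.out = n_grid)
  s <- sum(y)
  n <- length(y)
  loglik <- s * g - n * log1p(exp(g)) - g^2 / (2 * v)
  w <- exp(loglik - max(loglik))
  w <- w / sum(w)
  list(mean = sum(g * w), sd = sqrt(sum(g^2 * w) - sum(g * w)^2))
}
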