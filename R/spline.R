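#' Equidistant B-spline design matrix
#'
#' Builds the penalized-spline basis: `n_inner_knots` equidistant interior
#' knots over `[xl, xr]` (defaults to the range of `x`), extended by `degree`
#' equally spaced boundary knots on each side, evaluated with the de
#' Boor recursion (via `splines::splineDesign`). On `[xl, xr]` the basis is a
#' partition of unity: every row sums to 1 and entries are non-negative. The
#' number of basis functions is `n_inner_knots + degree + 1`.
#'
#' @param x numeric vector of evaluation points within `[xl, xr]`.
#' @param n_inner_knots number of interior knots, at least 2.
#' @param degree spline degree, at least 1 (3 = cubic, the default elsewhere).
#' @param xl,xr domain limits; default the range of `x`.
#' @return matrix with `length(x)` rows; attributes `knots` (the full
#'   extended knot vector), `degree`, `xl`, `xr`.
#' @export
bspline_design <- function(x, n_inner_knots, degree = 3L,
                           xl = min(x), xr = max(x)) {
  if (n_inner_knots < 2L) stop("n_inner_knots must be >= 2")
  if (degree < 1L) stop("degree must be >= 1")
  if (!is.finite(xl) || !is.finite(xr) || xr <= xl) {
    stop("constant x (or empty range): nothing to smooth over")
  }
  if (any(x < xl - 1e-9) || any(x > xr + 1e-9)) {
    stop("x outside [", xl, ", ", xr, "]")
  }
  h <- (xr - xl) / (n_inner_knots + 1L)
  knots <- seq(xl - degree * h, xr + degree * h, by = h)
  # guard against fp drift at the right boundary
  knots[length(knots)] <- xr + degree * h
  B <- splines::splineDesign(knots, pmin(pmax(x, xl), xr), ord = degree + 1L,
                             outer.ok = FALSE)
  attr(B, "knots") <- knots
  attr(B, "degree") <- degree
  attr(B, "xl") <- xl
  attr(B, "xr") <- xr
  B
}

#' Second-order random-walk penalty matrix
#'
#' `K = D'D` with `D` the (m-2) x m second-difference matrix: the smoothness
#' prior for P-spline coefficients. Symmetric, positive semidefinite, rank
#' m - 2; its null space is spanned by constant and linear coefficient
#' vectors, which is why the spline block needs its own centering constraint.
#'
#' @param m number of basis coefficients, at least 3.
#' @return m x m integer penalty matrix.
#' @export
rw2_penalty <- function(m) {
  if (m < 3L) stop("m must be >= 3")
  D <- diff(diag(m), differences = 2L)
  crossprod(D)
}
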