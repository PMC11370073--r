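# Restricted cubic splines (natural splines in Harrell's truncated-power
# parameterisation): piecewise cubic between the knots, constrained to be
# linear beyond the boundary knots. With k knots the basis has one linear
# term and k - 2 nonlinear terms.

#' Restricted-cubic-spline specification
#'
#' @param knots Strictly increasing numeric vector of knot locations
#'   (ages in years), length >= 3.
#'
#' @return Object of class `rcs_spec`.
#' @export
rcs_spec <- function(knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3 || any(diff(knots) <= 0)) {
    abort_arg("knots must be strictly increasing, length >= 3.")
  }
  structure(list(knots = knots), class = "rcs_spec")
}

#' @export
print.rcs_spec <- function(x, ...) {
  cat(
    "<rcs_spec>", length(x$knots), "knots at",
    paste(signif(x$knots, 4), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Place knots at Harrell's default quantiles
#'
#' For four knots the default placement quantiles are 0.05, 0.35, 0.65 and
#' 0.95 of the observed ages, with linear-interpolation (type 7) quantiles
#' so repeated runs agree exactly.
#'
#' @param ages Numeric vector of observed ages.
#' @param quantiles Placement quantiles (default `c(0.05, 0.35, 0.65, 0.95)`).
#'
#' @return An [rcs_spec()].
#' @export
place_knots <- function(ages, quantiles = c(0.05, 0.35, 0.65, 0.95)) {
  ages <- ages[is.finite(ages)]
  if (length(unique(ages)) < 20) {
    abort_arg("need >= 20 distinct ages to place knots.")
  }
  k <- unname(quantile(ages, quantiles, type = 7))
  if (any(diff(k) <= 0)) abort_arg("degenerate age distribution: knots not distinct.")
  rcs_spec(k)
}

#' Evaluate the restricted-cubic-spline basis
#'
#' For knots `t1 < ... < tk`, column 1 is `x` itself and nonlinear column
#' `j` (j = 1..k-2) is
#' \deqn{[(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'   + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2,}
#' which makes the fitted function linear beyond the boundary knots with
#' continuous first and second derivatives throughout.
#'
#' @param x Numeric vector of evaluation points.
#' @param spec An [rcs_spec()].
#'
#' @return Matrix with `length(x)` rows and `length(knots) - 1` columns
#'   named `lin`, `nl1`, `nl2`, ...
#' @export
rcs_basis <- function(x, spec) {
  stopifnot(inherits(spec, "rcs_spec"))
  t <- spec$knots
  k <- length(t)
  norm <- (t[k] - t[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  nl <- vapply(seq_len(k - 2), function(j) {
    (pos3(x - t[j]) -
      pos3(x - t[k - 1]) * (t[k] - t[j]) / (t[k] - t[k - 1]) +
      pos3(x - t[k]) * (t[k - 1] - t[j]) / (t[k] - t[k - 1])) / norm
  }, numeric(length(x)))
  out <- cbind(x, matrix(nl, nrow = length(x)))
  colnames(out) <- c("lin", paste0("nl", seq_len(k - 2)))
  out
}

# Coefficients of the RCS interpolant through (x_i, y_i) anchor points —
# used by the cohort generator to define smooth true curves that lie
# exactly in the model's function space.
rcs_interpolant <- function(anchors_x, anchors_y, spec) {
  B <- cbind(1, rcs_basis(anchors_x, spec))
  if (nrow(B) != ncol(B)) {
    abort_arg("need exactly length(knots) anchor points for interpolation.")
  }
  beta <- solve(B, anchors_y)
  function(x) as.numeric(cbind(1, rcs_basis(x, spec)) %*% beta)
}
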