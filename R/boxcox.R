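#' Box-Cox power transformation
#'
#' The one-parameter power family \eqn{(x^\lambda - 1)/\lambda} for
#' \eqn{\lambda \neq 0} and \eqn{\ln x} for \eqn{\lambda = 0}. It contains the
#' identity (up to an affine shift, \eqn{\lambda = 1}) and the logarithm
#' (\eqn{\lambda = 0}) as special cases and is continuous in \eqn{\lambda}
#' at 0.
#'
#' @param x Numeric vector of strictly positive values.
#' @param lambda Single transformation parameter.
#' @return Numeric vector of transformed values.
#' @examples
#' boxcox_transform(2, 1)     # 1
#' boxcox_transform(exp(1), 0) # 1
#' boxcox_transform(4, 0.5)   # 2
#' @export
boxcox_transform <- function(x, lambda) {
  stopifnot(is.numeric(x), length(lambda) == 1L, is.finite(lambda))
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("boxcox_transform() requires strictly positive finite values", call. = FALSE)
  }
  if (lambda == 0) log(x) else (x^lambda - 1) / lambda
}

#' Inverse Box-Cox transformation
#'
#' Maps a value on the transformed scale back to the positive raw scale.
#' Requires \eqn{1 + \lambda y > 0} for \eqn{\lambda \neq 0}.
#'
#' @param y Numeric vector on the transformed scale.
#' @param lambda Single transformation parameter.
#' @return Numeric vector of positive raw-scale values.
#' @examples
#' boxcox_inverse(1, 1) # 2
#' boxcox_inverse(1, 0) # e
#' @export
boxcox_inverse <- function(y, lambda) {
  stopifnot(is.numeric(y), length(lambda) == 1L, is.finite(lambda))
  if (lambda == 0) return(exp(y))
  base <- 1 + lambda * y
  if (any(!is.finite(base)) || any(base <= 0)) {
    stop("boxcox_inverse(): 1 + lambda*y must be positive (domain violation)",
         call. = FALSE)
  }
  base^(1 / lambda)
}

#' Variance-ratio stabilization objective
#'
#' The objective minimized to choose the variance-stabilizing parameter:
#' \eqn{|\log(\mathrm{Var}[Y'] / \mathrm{Var}[X'])|} where \eqn{X'} and
#' \eqn{Y'} are the Box-Cox transformed baseline and on-drug samples.
#' Sample variances use the unbiased (n-1) denominator.
#'
#' @param x,y Positive numeric samples (baseline and on-drug levels), each of
#'   length >= 2. They need not be the same length, although in the intended
#'   paired-response use they are.
#' @param lambda Transformation parameter at which to evaluate.
#' @return Non-negative scalar objective value.
#' @export
variance_objective <- function(x, y, lambda) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("variance_objective() needs samples of size >= 2", call. = FALSE)
  }
  vx <- stats::var(boxcox_transform(x, lambda))
  vy <- stats::var(boxcox_transform(y, lambda))
  if (!is.finite(vx) || !is.finite(vy) || vx == 0 || vy == 0) {
    stop("degenerate sample: zero or non-finite variance after transform",
         call. = FALSE)
  }
  abs(log(vy / vx))
}

#' Find the variance-stabilizing Box-Cox parameter
#'
#' Grid search for the \eqn{\lambda} minimizing
#' \eqn{|\log(\mathrm{Var}[Y']/\mathrm{Var}[X'])|}. When several grid points
#' tie within `tie_tol`, the point nearest 1 is returned (nearest 0 as a
#' second key), preferring the least-transformed scale when the data do not
#' discriminate. `boundary_hit` flags a minimizer at a grid endpoint, which
#' usually means the grid should be widened.
#'
#' @param x,y Positive numeric samples (baseline and on-drug levels).
#' @param grid Numeric vector of candidate lambda values; default
#'   `seq(-2, 2, by = 0.05)`.
#' @param tie_tol Objective values within this of the minimum count as tied.
#' @return An object of class `boxcox_param`: list with elements `lambda`,
#'   `objective` (value at the minimizer), `profile` (data.frame with columns
#'   `lambda`, `objective`), and `boundary_hit`.
#' @examples
#' x <- exp(rnorm(500))
#' find_lambda(x, 0.6 * x)$lambda # 0: a multiplicative effect is log-additive
#' @export
find_lambda <- function(x, y, grid = seq(-2, 2, by = 0.05), tie_tol = 1e-12) {
  stopifnot(length(grid) >= 1L, !anyNA(grid))
  grid <- sort(grid)
  obj <- vapply(grid, function(l) variance_objective(x, y, l), numeric(1))
  tied <- which(obj <= min(obj) + tie_tol)
  # ties: nearest to 1, then nearest to 0, then smallest lambda (stable)
  ord <- order(abs(grid[tied] - 1), abs(grid[tied]), grid[tied])
  pick <- tied[ord[1L]]
  structure(
    list(
      lambda = grid[pick],
      objective = obj[pick],
      profile = data.frame(lambda = grid, objective = obj),
      boundary_hit = pick == 1L || pick == length(grid)
    ),
    class = "boxcox_param"
  )
}

#' @export
print.boxcox_param <- function(x, ...) {
  cat(sprintf("Variance-stabilizing Box-Cox parameter\n  lambda = %.2f  (objective %.4g over %d grid points%s)\n",
              x$lambda, x$objective, nrow(x$profile),
              if (x$boundary_hit) "; boundary hit" else ""))
  invisible(x)
}

#' Drug-response change metrics
#'
#' Computes the three change scores compared throughout the package for each
#' subject: absolute change \eqn{Y - X} (raw scale), relative change
#' \eqn{\log(Y/X)} (log scale), and the variance-stabilized change
#' \eqn{bc(Y, \lambda) - bc(X, \lambda)}. At \eqn{\lambda = 1} the stabilized
#' metric equals the absolute change; at \eqn{\lambda = 0} it equals the
#' relative change.
#'
#' @param phenotypes Data frame with columns `subject_id`, `baseline`,
#'   `ondrug` (as produced by [derive_response_phenotypes()]), or any data
#'   frame with positive `baseline`/`ondrug` columns.
#' @param lambda Stabilizing parameter, typically from [find_lambda()].
#' @return Data frame with columns `subject_id`, `baseline`, `ondrug`,
#'   `absolute`, `relative`, `stabilized`, and attribute `lambda`.
#' @export
compute_response_metrics <- function(phenotypes, lambda) {
  stopifnot(all(c("baseline", "ondrug") %in% names(phenotypes)))
  x <- phenotypes$baseline
  y <- phenotypes$ondrug
  bad <- !is.finite(x) | !is.finite(y) | x <= 0 | y <= 0
  if (any(bad)) {
    stop(sprintf("%d subject(s) have non-positive or non-finite baseline/on-drug values (e.g. row %d)",
                 sum(bad), which(bad)[1L]), call. = FALSE)
  }
  out <- data.frame(
    subject_id = if ("subject_id" %in% names(phenotypes)) phenotypes$subject_id else seq_along(x),
    baseline = x,
    ondrug = y,
    absolute = y - x,
    relative = log(y / x),
    stabilized = boxcox_transform(y, lambda) - boxcox_transform(x, lambda)
  )
  attr(out, "lambda") <- lambda
  out
}
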