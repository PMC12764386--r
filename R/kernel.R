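# Squared exponential (RBF) kernel and its hyperparameters.

#' Kernel hyperparameters
#'
#' Bundles the hyperparameters of the squared exponential covariance
#' \eqn{K(x, x') = \sigma^2 \exp(-d^2(x, x') / (2b))}: the spatial variance
#' `sigma2` (response units squared), the length scale `b` (units of squared
#' feature distance, since it divides \eqn{d^2} directly), and the nugget
#' `tau2`, the observation-noise variance added to the Gram diagonal.
#'
#' @param sigma2 Spatial variance, > 0.
#' @param b Length scale, > 0.
#' @param tau2 Nugget (noise) variance, >= 0. Default 0.
#' @return An object of class `"kernel_params"`.
#' @examples
#' kernel_params(sigma2 = 1, b = 1)
#' @export
kernel_params <- function(sigma2, b, tau2 = 0) {
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 <= 0) {
    stop("'sigma2' must be a single finite positive number", call. = FALSE)
  }
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    stop("'b' must be a single finite positive number", call. = FALSE)
  }
  if (!is.numeric(tau2) || length(tau2) != 1L || !is.finite(tau2) || tau2 < 0) {
    stop("'tau2' must be a single finite non-negative number", call. = FALSE)
  }
  structure(list(sigma2 = as.numeric(sigma2), b = as.numeric(b),
                 tau2 = as.numeric(tau2)),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("RBF kernel parameters: sigma2 = %.6g, b = %.6g, tau2 = %.6g\n",
              x$sigma2, x$b, x$tau2))
  invisible(x)
}

# Pairwise squared Euclidean distances between rows of A and rows of B.
# Clipped at 0 to absorb round-off from the expansion.
sqdist <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    stop("designs must have the same number of columns", call. = FALSE)
  }
  D <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

#' Squared exponential kernel matrix
#'
#' Evaluates the RBF kernel between the rows of two design matrices:
#' entry (i, k) is \eqn{\sigma^2 \exp(-\|A_i - B_k\|^2 / (2b))}. By default
#' the length scale divides the squared distance directly (`convention =
#' "2b"`); `convention = "2b2"` uses the more common \eqn{2b^2} denominator.
#' The two are reparameterisations of one another, so fitted models are
#' unaffected by the choice; it only changes how a given `b` is read.
#'
#' @param A m x q numeric matrix (rows are points).
#' @param B r x q numeric matrix.
#' @param params A [kernel_params()] object.
#' @param convention `"2b"` (default) or `"2b2"`: denominator of the squared
#'   distance in the exponent.
#' @return An m x r kernel matrix with entries in (0, sigma2].
#' @examples
#' A <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
#' rbf_kernel(A, A, kernel_params(1, 1))
#' @export
rbf_kernel <- function(A, B, params, convention = c("2b", "2b2")) {
  convention <- match.arg(convention)
  if (!inherits(params, "kernel_params")) {
    params <- do.call(kernel_params, as.list(params)[c("sigma2", "b", "tau2")])
  }
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    stop("'A' and 'B' must have the same number of columns", call. = FALSE)
  }
  if (ncol(A) < 1L) stop("designs need at least one column", call. = FALSE)
  denom <- if (convention == "2b") 2 * params$b else 2 * params$b^2
  params$sigma2 * exp(-sqdist(A, B) / denom)
}
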