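# Gaussian process regression: marginal likelihood, bounded MLE, BLUP.

# Relative jitter added to the Gram diagonal for numerical stability.
# The effective diagonal is K + (tau2 + JITTER_REL * sigma2) I, so residuals
# stay non-degenerate even when tau2 is driven to its lower bound.
JITTER_REL <- 1e-8

# Cholesky of K(X,X) + (tau2 + jitter) I, escalating the jitter a few times
# if the factorization fails. Returns NULL when even the largest jitter fails.
chol_gram <- function(D, params) {
  K <- params$sigma2 * exp(-D / (2 * params$b))
  for (mult in c(1, 1e2, 1e4)) {
    Ky <- K
    diag(Ky) <- diag(Ky) + params$tau2 + mult * JITTER_REL * params$sigma2
    L <- tryCatch(chol(Ky), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, K = K))
  }
  NULL
}

#' Log marginal likelihood of a zero-mean GP
#'
#' Computes \eqn{\log N(Y \mid 0, K_\theta(X,X) + \tau^2 I)} for the RBF
#' kernel. `Y` is used as given; callers following the zero-mean convention
#' should center it first (the fitter does this internally and stores the
#' offset).
#'
#' @param X n x q design matrix.
#' @param Y Numeric response vector of length n.
#' @param params A [kernel_params()] object.
#' @return The log density (scalar).
#' @examples
#' log_marginal_likelihood(matrix(0), 0, kernel_params(1, 1)) # ~ -0.9189
#' @export
log_marginal_likelihood <- function(X, Y, params) {
  X <- as.matrix(X)
  Y <- as.numeric(Y)
  n <- nrow(X)
  if (n < 1L || length(Y) != n) {
    stop("'X' must have as many rows as 'Y' has elements (n >= 1)",
         call. = FALSE)
  }
  cg <- chol_gram(sqdist(X, X), params)
  if (is.null(cg)) {
    stop(sprintf(paste0("Gram matrix not positive definite after maximal ",
                        "jitter (sigma2 = %g, b = %g, tau2 = %g)"),
                 params$sigma2, params$b, params$tau2), call. = FALSE)
  }
  alpha <- backsolve(cg$L, forwardsolve(t(cg$L), Y))
  -0.5 * sum(Y * alpha) - sum(log(diag(cg$L))) - 0.5 * n * log(2 * pi)
}

# Negative log marginal likelihood and its gradient in u = log(sigma2, b,
# tau2). D is the precomputed squared-distance matrix of the training design.
neg_lml_obj <- function(u, D, Y) {
  params <- list(sigma2 = exp(u[1]), b = exp(u[2]), tau2 = exp(u[3]))
  cg <- chol_gram(D, params)
  if (is.null(cg)) return(list(value = Inf, gradient = rep(0, 3)))
  n <- length(Y)
  L <- cg$L
  alpha <- backsolve(L, forwardsolve(t(L), Y))
  value <- 0.5 * sum(Y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  if (!is.finite(value)) return(list(value = Inf, gradient = rep(0, 3)))
  # d(-lml)/d theta = -0.5 * (alpha' dK alpha - tr(Kinv dK))
  Kinv <- chol2inv(L)
  A <- tcrossprod(alpha) - Kinv
  # dK/dlog sigma2 = K; dK/dlog b = K * D/(2b); dK/dlog tau2 = tau2 I
  g1 <- -0.5 * sum(A * cg$K)
  g2 <- -0.5 * sum(A * (cg$K * D / (2 * params$b)))
  g3 <- -0.5 * sum(diag(A)) * params$tau2
  list(value = value, gradient = c(g1, g2, g3))
}

#' Default hyperparameter bounds
#'
#' Optimization box for the bounded MLE, scaled by the response variance:
#' `b` in \[1e-2, 1e3\], `sigma2` in \[1e-3, 1e3\] * var(y), `tau2` in
#' \[1e-8, 1\] * var(y). Bounding the kernel parameters during optimization
#' guards against degenerate interpolating fits.
#'
#' @param var_y Response variance used as the scale; a non-finite or
#'   near-zero value falls back to 1.
#' @return A list with elements `sigma2`, `b`, `tau2`, each a (lower, upper)
#'   pair.
#' @export
gp_default_bounds <- function(var_y = 1) {
  if (!is.finite(var_y) || var_y < 1e-12) var_y <- 1
  list(sigma2 = c(1e-3, 1e3) * var_y,
       b      = c(1e-2, 1e3),
       tau2   = c(1e-8, 1) * var_y)
}

check_bounds <- function(bounds) {
  for (nm in c("sigma2", "b", "tau2")) {
    bd <- bounds[[nm]]
    if (is.null(bd) || length(bd) != 2L || !all(is.finite(bd)) ||
        bd[1] <= 0 || bd[2] < bd[1]) {
      stop(sprintf("bounds for '%s' must be a finite positive interval", nm),
           call. = FALSE)
    }
  }
  bounds[c("sigma2", "b", "tau2")]
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run an expression with a temporary RNG state seeded at `seed`, restoring
# the caller's state afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a GP model with fixed hyperparameters
#'
#' Builds a ready-to-predict GP (centered response, cached Cholesky
#' factorization and weight vector) at given kernel parameters, without any
#' optimization. [fit_gp_mle()] uses this after choosing the parameters; it
#' is also the workhorse of the annealed early iterations of [gpsc_fit()],
#' where the hyperparameters are pinned.
#'
#' @param X n x q design matrix.
#' @param Y Numeric response vector of length n.
#' @param params A [kernel_params()] object.
#' @return An object of class `"gp_model"`.
#' @export
gp_model <- function(X, Y, params) {
  X <- as.matrix(X)
  Y <- as.numeric(Y)
  n <- nrow(X)
  if (n == 0L) stop("cannot build a GP on an empty cluster", call. = FALSE)
  if (length(Y) != n) stop("'X' and 'Y' sizes disagree", call. = FALSE)
  y_center <- mean(Y)
  Yc <- Y - y_center
  D <- sqdist(X, X)
  cg <- chol_gram(D, params)
  if (is.null(cg)) {
    stop("Gram matrix not positive definite after maximal jitter",
         call. = FALSE)
  }
  alpha <- backsolve(cg$L, forwardsolve(t(cg$L), Yc))
  loglik <- -0.5 * sum(Yc * alpha) - sum(log(diag(cg$L))) -
    0.5 * n * log(2 * pi)
  structure(list(params = params, X = X, Y = Yc, y_center = y_center,
                 L = cg$L, alpha = alpha, n = n, loglik = loglik,
                 bounds = NULL, starts = NULL),
            class = "gp_model")
}

#' Fit a GP by bounded maximum marginal likelihood
#'
#' Multi-start bounded quasi-Newton (L-BFGS-B on log parameters) maximization
#' of the log marginal likelihood. The response is centered internally and
#' the offset stored, consistent with the zero-mean prior. Starts are: an
#' optional warm start, a heuristic start (length scale at the median pairwise
#' squared distance, nugget at a tenth of the response variance), and
#' `restarts` points drawn log-uniformly inside the bounds. The best local
#' optimum by likelihood wins; ties go to the earliest start.
#'
#' @param X n x q design matrix, n >= 1.
#' @param Y Numeric response vector of length n.
#' @param bounds Per-parameter (lower, upper) intervals as in
#'   [gp_default_bounds()]; `NULL` uses the defaults scaled by `var(Y)`.
#' @param restarts Number of random restarts (>= 0). Default 3.
#' @param seed Integer seed making the random restarts reproducible.
#' @param warm_start Optional [kernel_params()] used as the first start
#'   (clipped into the bounds).
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @param factr L-BFGS-B convergence tolerance (see [stats::optim()]); the
#'   clustering loop uses a looser value than the default, since label
#'   assignment is insensitive to the last digits of the hyperparameters.
#' @return An object of class `"gp_model"`: fitted `params`, training design
#'   `X`, centered targets `Y`, response offset `y_center`, cached Cholesky
#'   factor and weight vector `alpha`, and the achieved `loglik`. The
#'   `starts` element records each start's initial and final objective for
#'   diagnostics.
#' @seealso [blup_predict()], [log_marginal_likelihood()]
#' @export
fit_gp_mle <- function(X, Y, bounds = NULL, restarts = 3, seed = NULL,
                       warm_start = NULL, maxit = 100, factr = 1e7) {
  X <- as.matrix(X)
  Y <- as.numeric(Y)
  n <- nrow(X)
  if (n == 0L) stop("cannot fit a GP to an empty cluster", call. = FALSE)
  if (length(Y) != n) stop("'X' and 'Y' sizes disagree", call. = FALSE)
  if (anyNA(X) || anyNA(Y)) stop("missing values in GP inputs", call. = FALSE)

  y_center <- mean(Y)
  Yc <- Y - y_center
  var_y <- if (n >= 2) stats::var(Y) else 1
  if (is.null(bounds)) bounds <- gp_default_bounds(var_y)
  bounds <- check_bounds(bounds)
  lower <- log(c(bounds$sigma2[1], bounds$b[1], bounds$tau2[1]))
  upper <- log(c(bounds$sigma2[2], bounds$b[2], bounds$tau2[2]))

  D <- sqdist(X, X)
  scale_var <- if (is.finite(var_y) && var_y > 1e-12) var_y else 1

  b_med <- if (n >= 2) stats::median(D[upper.tri(D)]) else 1
  if (!is.finite(b_med) || b_med <= 0) b_med <- 1
  starts <- list()
  if (!is.null(warm_start)) {
    starts <- c(starts, list(c(warm_start$sigma2, warm_start$b,
                               max(warm_start$tau2, bounds$tau2[1]))))
  }
  starts <- c(starts, list(c(0.5 * scale_var, b_med, 0.1 * scale_var)))
  if (restarts > 0) {
    draws <- with_seed(seed, matrix(stats::runif(3 * restarts), restarts, 3))
    for (r in seq_len(restarts)) {
      starts <- c(starts, list(exp(lower + draws[r, ] * (upper - lower))))
    }
  }

  obj_env <- new.env()
  fn <- function(u) {
    res <- neg_lml_obj(u, D, Yc)
    obj_env$grad <- res$gradient
    res$value
  }
  gr <- function(u) obj_env$grad

  best <- NULL
  info <- data.frame(start = integer(0), init = numeric(0), final = numeric(0))
  for (k in seq_along(starts)) {
    u0 <- log(clip(starts[[k]], exp(lower), exp(upper)))
    init_val <- neg_lml_obj(u0, D, Yc)$value
    fit <- tryCatch(
      stats::optim(u0, fn, gr, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = maxit, factr = factr)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    info <- rbind(info, data.frame(start = k, init = init_val,
                                   final = fit$value))
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (is.null(best)) {
    stop("all optimization restarts failed for the GP fit", call. = FALSE)
  }

  par <- exp(clip(best$par, lower, upper))
  model <- gp_model(X, Y, kernel_params(par[1], par[2], par[3]))
  model$bounds <- bounds
  model$starts <- info
  model
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("GP model: n = %d, q = %d, loglik = %.4f\n", x$n, ncol(x$X),
              x$loglik))
  print(x$params)
  invisible(x)
}

#' BLUP prediction from a fitted GP
#'
#' The best linear unbiased predictor
#' \eqn{\hat y_* = K(X_*, X) (K(X,X) + \tau^2 I)^{-1} Y} evaluated with the
#' cached Cholesky factor, plus the stored response offset. Far from the
#' training data the prediction reverts to the training-response mean (the
#' zero-mean prior after un-centering).
#'
#' @param model A fitted `"gp_model"` from [fit_gp_mle()].
#' @param Xstar m x q matrix of prediction points.
#' @return Numeric vector of m predictions.
#' @export
blup_predict <- function(model, Xstar) {
  if (!inherits(model, "gp_model")) stop("'model' must be a gp_model",
                                         call. = FALSE)
  Xstar <- as.matrix(Xstar)
  if (nrow(Xstar) == 0L) return(numeric(0))
  if (ncol(Xstar) != ncol(model$X)) {
    stop(sprintf("prediction design has %d columns but the model was trained on %d",
                 ncol(Xstar), ncol(model$X)), call. = FALSE)
  }
  kstar <- rbf_kernel(Xstar, model$X, model$params)
  drop(kstar %*% model$alpha) + model$y_center
}
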