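# Ridge-regression BLUP: beta_hat = (X'X + lambda I)^-1 X'y, computed through
# the dual form beta_hat = X' V^-1 y with V = XX' + lambda I (an nTRN x nTRN
# solve), which is the cheap route when p >> n. The regularisation parameter
# lambda = sigma_eps2 / sigma_beta2 is either estimated by REML or deduced
# from the heritability.

eigen_K <- function(X) {
  K <- tcrossprod(X)
  ev <- eigen(K, symmetric = TRUE)
  # guard tiny negative eigenvalues from finite precision
  ev$values <- pmax(ev$values, 0)
  ev
}

#' Estimate the ridge parameter by REML
#'
#' Fits the one-random-effect model `y = X beta + eps`,
#' `beta ~ N(0, sigma_beta2 I)`, `eps ~ N(0, sigma_eps2 I)` to centered data
#' (no fixed effects, so REML coincides with maximum likelihood on the
#' zero-mean model) and returns `lambda = sigma_eps2 / sigma_beta2`. The
#' likelihood is profiled over `sigma_beta2` on the spectrum of `K = XX'`
#' and maximised over `log(lambda)` by 1-D bounded optimisation. When the
#' marker variance collapses to zero (null trait), `lambda` is capped at
#' `1e8 * tr(K) / n` with a warning.
#'
#' @param X Centered training marker matrix (n x p).
#' @param y Centered training phenotypes (length n).
#' @param eigen_k Optional precomputed `eigen(tcrossprod(X))` (reused across
#'   replicates when `X` is fixed).
#' @return A list with `sigma_eps2`, `sigma_beta2`, `lambda`, `logLik`,
#'   `capped` (logical) and the eigendecomposition `eigen_k`.
#' @export
estimate_lambda_reml <- function(X, y, eigen_k = NULL) {
  n <- nrow(X)
  stopifnot(n >= 2, length(y) == n)
  if (all(abs(X) < .Machine$double.eps)) stop("X is degenerate (all zero)")
  ev <- eigen_k %||% eigen_K(X)
  d <- ev$values
  cc <- drop(crossprod(ev$vectors, y))^2
  # profiled negative log-likelihood: sigma_beta2_hat(lambda) = mean(cc/(d+lambda))
  nll <- function(loglam) {
    lam <- exp(loglam)
    sb2 <- sum(cc / (d + lam)) / n
    0.5 * (n * log(sb2) + sum(log(d + lam)))
  }
  # Search lambda over a wide bracket scaled by tr(K)/n.
  scale <- sum(d) / n
  lam_cap <- 1e8 * scale
  opt <- stats::optimize(nll, interval = log(c(1e-8 * scale, lam_cap)), tol = 1e-8)
  lambda <- exp(opt$minimum)
  capped <- FALSE
  if (lambda > 0.99 * lam_cap) {
    warning("sigma_beta2 is numerically 0; lambda capped at 1e8 * tr(XX')/n")
    lambda <- lam_cap
    capped <- TRUE
  }
  sigma_beta2 <- sum(cc / (d + lambda)) / n
  list(sigma_eps2 = lambda * sigma_beta2, sigma_beta2 = sigma_beta2,
       lambda = lambda, logLik = -nll(log(lambda)), capped = capped,
       eigen_k = ev)
}

#' Ridge parameter from the heritability
#'
#' `lambda_h2 = (1 - h2) / (n h2) * sum(X^2)`, i.e. the genetic variance is
#' assumed spread uniformly over the (filtered) markers.
#'
#' @param X Centered training marker matrix.
#' @param h2 Heritability in (0, 1).
#' @return The scalar `lambda_h2`.
#' @export
estimate_lambda_h2 <- function(X, h2) {
  if (!is.finite(h2) || h2 <= 0 || h2 >= 1) stop("h2 must lie strictly in (0, 1)")
  (1 - h2) / (nrow(X) * h2) * sum(X^2)
}

#' Fit ridge-regression BLUP
#'
#' Computes `V = XX' + lambda I`, its solve against `y`, and the marker
#' effects `beta_hat = X' V^-1 y` (identical to the primal
#' `(X'X + lambda I)^-1 X' y` by the Woodbury identity).
#'
#' @param X Centered training marker matrix (n x p).
#' @param y Centered training phenotypes.
#' @param lambda Ridge parameter (> 0; `lambda = 0` is only allowed when
#'   `XX'` is non-singular).
#' @param eigen_k Optional precomputed `eigen(tcrossprod(X))`; when supplied
#'   the solve is done on the spectrum, which is cheap to repeat for many
#'   `lambda` or `y`.
#' @return An object of class `rr_fit` with elements `lambda`, `beta_hat`,
#'   `v_inv_y`, `n`, `p`.
#' @export
rr_fit <- function(X, y, lambda, eigen_k = NULL) {
  n <- nrow(X)
  stopifnot(length(y) == n, lambda >= 0)
  if (!is.null(eigen_k)) {
    d <- eigen_k$values + lambda
    if (any(d <= 0)) stop("V = XX' + lambda I is singular (lambda = 0 with rank-deficient XX')")
    v_inv_y <- ev_solve(eigen_k, lambda, y)
  } else {
    V <- tcrossprod(X)
    diag(V) <- diag(V) + lambda
    R <- tryCatch(chol(V), error = function(e) {
      stop("V = XX' + lambda I is singular (lambda = 0 with rank-deficient XX')")
    })
    v_inv_y <- backsolve(R, backsolve(R, y, transpose = TRUE))
  }
  beta_hat <- drop(crossprod(X, v_inv_y))
  structure(list(lambda = lambda, beta_hat = beta_hat, v_inv_y = v_inv_y,
                 n = n, p = ncol(X)),
            class = "rr_fit")
}

ev_solve <- function(ev, lambda, b) {
  drop(ev$vectors %*% ((crossprod(ev$vectors, b)) / (ev$values + lambda)))
}

#' Predict from a ridge-regression BLUP fit
#'
#' @param object An `rr_fit`.
#' @param X_new Centered marker matrix of new individuals (same columns as
#'   the training matrix).
#' @param ... Unused.
#' @return Predicted (centered) phenotypic values `X_new %*% beta_hat`.
#' @export
predict.rr_fit <- function(object, X_new, ...) {
  if (ncol(X_new) != object$p) {
    stop(sprintf("X_new has %d columns but the fit used %d markers",
                 ncol(X_new), object$p))
  }
  drop(X_new %*% object$beta_hat)
}

#' @export
print.rr_fit <- function(x, ...) {
  cat(sprintf("<rr_fit> n = %d, p = %d, lambda = %.6g\n", x$n, x$p, x$lambda))
  invisible(x)
}

#' Tidy a ridge-regression BLUP fit
#'
#' @param x An `rr_fit`.
#' @param ... Unused.
#' @return A tibble with one row per marker: `term` and `estimate`.
#' @method tidy rr_fit
#' @export
tidy.rr_fit <- function(x, ...) {
  tibble::tibble(term = paste0("marker_", seq_along(x$beta_hat)),
                 estimate = x$beta_hat)
}

#' Glance at a ridge-regression BLUP fit
#'
#' @param x An `rr_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `p`, `lambda`.
#' @method glance rr_fit
#' @export
glance.rr_fit <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, lambda = x$lambda)
}
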