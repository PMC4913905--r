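# Accuracy of RRBLUP prediction: the exact theoretical phenotypic accuracy
# conditional on the training design, its plug-in estimators over a test
# sample, the empirical accuracy, the oracle accuracy, and the classical
# closed form for independent causal loci.
#
# Notation: X / Q are the centered training marker / causal matrices,
# X_tst / Q_tst their test counterparts, theta the causal effects,
# V = XX' + lambda I. Predictions are x' X' V^-1 y for a test genome x.

#' Plug-in estimators of the theoretical-accuracy components
#'
#' Estimates, by averaging over the test sample, the four quantities
#' entering the theoretical accuracy:
#' 1. `e_norm2`: mean over test rows of `|| x_i' X' V^-1 ||^2`;
#' 2. `cross_term`: `theta' (mean_i q_i x_i') X' V^-1 Q theta`;
#' 3. the variance term `theta' Q' V^-1 X Var(x) X' V^-1 Q theta`, with
#'    `Var(x)` the uncentered test cross-product matrix
#'    `X_tst' X_tst / n_tst`;
#' 4. `sigma_G2`: the (mean-subtracted) empirical variance of the test
#'    genetic values `q_i' theta`, with divisor `n_tst`.
#'
#' The variance term is evaluated as `mean((X_tst u)^2)` with
#' `u = X' V^-1 Q theta`, which is algebraically identical to forming the
#' p x p matrix `Var(x)` and never materialises it; set
#' `return_var_x = TRUE` to also get the explicit matrix (small panels
#' only).
#'
#' With `lambda = 0` the dual matrix `XX'` is singular whenever p < n, so
#' the components are then computed through the primal operator
#' `(X'X)^-1 X'`, which requires `X'X` to be invertible.
#'
#' @param X,Q Centered training marker (n x p) and causal (n x C) matrices.
#' @param X_tst,Q_tst Centered test counterparts (n_tst rows each).
#' @param theta Causal effect vector (length C).
#' @param lambda Ridge parameter (>= 0).
#' @param return_var_x Also return the explicit `Var(x)` matrix?
#' @return A list with `e_norm2`, `cross_term`, `var_term`, `sigma_G2`,
#'   `n_tst` (and `var_x` if requested).
#' @export
estimate_components <- function(X, Q, X_tst, Q_tst, theta, lambda,
                                return_var_x = FALSE) {
  n_tst <- nrow(X_tst)
  if (n_tst < 2) stop("need at least 2 test individuals")
  stopifnot(nrow(X) == nrow(Q), nrow(X_tst) == nrow(Q_tst),
            ncol(Q) == length(theta), ncol(X) == ncol(X_tst),
            lambda >= 0)
  g_trn <- drop(Q %*% theta)
  g_tst <- drop(Q_tst %*% theta)
  if (lambda > 0) {
    V <- tcrossprod(X)
    diag(V) <- diag(V) + lambda
    R <- chol(V)
    v_solve <- function(b) backsolve(R, backsolve(R, b, transpose = TRUE))
    A <- X_tst %*% t(X)                     # n_tst x n rows x_i' X'
    A <- t(v_solve(t(A)))                   # rows x_i' X' V^-1
    u <- drop(crossprod(X, v_solve(g_trn))) # X' V^-1 Q theta
  } else {
    M <- crossprod(X)
    B <- tryCatch(solve(M, t(X)), error = function(e) {
      stop("lambda = 0 requires an invertible X'X")
    })                                      # (X'X)^-1 X'
    A <- X_tst %*% B
    u <- drop(B %*% g_trn)
  }
  s <- drop(X_tst %*% u)
  out <- list(
    e_norm2 = mean(rowSums(A^2)),
    cross_term = mean(g_tst * s),
    var_term = mean(s^2),
    sigma_G2 = mean((g_tst - mean(g_tst))^2),
    n_tst = n_tst
  )
  if (return_var_x) out$var_x <- crossprod(X_tst) / n_tst
  out
}

#' Theoretical accuracy of the RRBLUP predictor
#'
#' The exact phenotypic accuracy, conditional on the training marker and
#' causal matrices:
#' \deqn{\rho_{RR} = \frac{\theta' E(q x') X' V^{-1} Q \theta}
#'   {\{\sigma_e^2 E\|x' X' V^{-1}\|^2 +
#'     \theta' Q' V^{-1} X \mathrm{Var}(x) X' V^{-1} Q \theta\}^{1/2}
#'    \{\sigma_G^2 + \sigma_e^2\}^{1/2}}}
#' with expectations over the test genome replaced by their test-sample
#' plug-ins (see [estimate_components()]). The environmental variance is
#' taken as known (`sigma_e2 = 1` in the simulation study).
#'
#' @inheritParams estimate_components
#' @param sigma_e2 Environmental variance (its true/configured value).
#' @param components Optional precomputed [estimate_components()] output.
#' @return The scalar accuracy estimate.
#' @export
theoretical_accuracy <- function(X, Q, X_tst, Q_tst, theta, lambda, sigma_e2,
                                 components = NULL) {
  stopifnot(sigma_e2 > 0)
  comp <- components %||%
    estimate_components(X, Q, X_tst, Q_tst, theta, lambda)
  den <- sqrt(sigma_e2 * comp$e_norm2 + comp$var_term) *
    sqrt(comp$sigma_G2 + sigma_e2)
  if (den == 0) stop("zero denominator in theoretical accuracy")
  comp$cross_term / den
}

#' Empirical accuracy
#'
#' Pearson correlation between predictions and realised values, the usual
#' empirical measure of prediction accuracy.
#'
#' @param predictions,truths Equal-length numeric vectors (>= 3 pairs).
#' @return The correlation.
#' @export
empirical_accuracy <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths), length(truths) >= 3)
  if (stats::sd(predictions) == 0 || stats::sd(truths) == 0) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(predictions, truths)
}

#' Oracle accuracy
#'
#' If causal positions and effects were known, the best predictor is the
#' genetic value itself: the phenotypic accuracy is then `h` (the square
#' root of the heritability) and the genotypic accuracy is 1.
#'
#' @param h2 Heritability in `[0, 1]`.
#' @return Named vector `c(rho = sqrt(h2), rho_tilde = 1)`.
#' @export
oracle_accuracy <- function(h2) {
  stopifnot(h2 >= 0, h2 <= 1)
  c(rho = sqrt(h2), rho_tilde = 1)
}

#' Closed-form accuracy for independent causal loci
#'
#' The classical accuracy formula for a known set of `C` mutually
#' independent causal loci (ordinary least squares locus by locus):
#' \deqn{\tilde\rho = \sqrt{\frac{h^2/(1-h^2)}{C/n_{TRN} + h^2/(1-h^2)}},
#'   \qquad \rho = h \tilde\rho.}
#' Substituting an effective number of independent loci for `C` turns this
#' into the familiar family of accuracy proxies.
#'
#' @param C_or_Me Number of independent causal loci, or an effective number
#'   of segments plugged in its place (> 0).
#' @param n_trn Number of training individuals.
#' @param h2 Heritability in (0, 1).
#' @return Named vector `c(rho_tilde = , rho = )`.
#' @export
daetwyler_accuracy <- function(C_or_Me, n_trn, h2) {
  if (!is.finite(h2) || h2 <= 0 || h2 >= 1) stop("h2 must lie strictly in (0, 1)")
  stopifnot(C_or_Me > 0, n_trn > 0)
  g <- h2 / (1 - h2)
  rho_tilde <- sqrt(g / (C_or_Me / n_trn + g))
  c(rho_tilde = rho_tilde, rho = sqrt(h2) * rho_tilde)
}
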