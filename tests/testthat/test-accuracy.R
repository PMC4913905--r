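# Independent dense evaluation of the accuracy components: explicit V
# inverse, elementwise sums, materialised Var(x). Deliberately coded apart
# from the package path.
dense_components <- function(X, Q, X_tst, Q_tst, theta, lambda) {
  n <- nrow(X)
  Vinv <- solve(tcrossprod(X) + lambda * diag(n))
  n_tst <- nrow(X_tst)
  e2 <- 0; cross <- 0
  for (i in seq_len(n_tst)) {
    w <- drop(t(X_tst[i, ]) %*% t(X) %*% Vinv)
    e2 <- e2 + sum(w^2)
    cross <- cross + drop(Q_tst[i, ] %*% theta) *
      drop(w %*% Q %*% theta)
  }
  var_x <- crossprod(X_tst) / n_tst
  u <- drop(t(X) %*% Vinv %*% Q %*% theta)
  g <- drop(Q_tst %*% theta)
  list(e_norm2 = e2 / n_tst,
       cross_term = cross / n_tst,
       var_term = drop(t(u) %*% var_x %*% u),
       sigma_G2 = mean((g - mean(g))^2))
}

dense_rho <- function(X, Q, X_tst, Q_tst, theta, lambda, sigma_e2) {
  cp <- dense_components(X, Q, X_tst, Q_tst, theta, lambda)
  cp$cross_term / (sqrt(sigma_e2 * cp$e_norm2 + cp$var_term) *
                     sqrt(cp$sigma_G2 + sigma_e2))
}

toy_inputs <- function(n = 5, p = 4, C = 2, n_tst = 3, seed = 10) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p),
       Q = matrix(rnorm(n * C), n, C),
       X_tst = matrix(rnorm(n_tst * p), n_tst, p),
       Q_tst = matrix(rnorm(n_tst * C), n_tst, C),
       theta = rnorm(C))
}

test_that("plug-in components match direct elementwise summation", {
  ti <- toy_inputs()
  got <- estimate_components(ti$X, ti$Q, ti$X_tst, ti$Q_tst, ti$theta, 0.8,
                             return_var_x = TRUE)
  want <- dense_components(ti$X, ti$Q, ti$X_tst, ti$Q_tst, ti$theta, 0.8)
  expect_equal(got$e_norm2, want$e_norm2, tolerance = 1e-10)
  expect_equal(got$cross_term, want$cross_term, tolerance = 1e-10)
  expect_equal(got$var_term, want$var_term, tolerance = 1e-10)
  expect_equal(got$sigma_G2, want$sigma_G2, tolerance = 1e-12)
  expect_equal(got$var_x, crossprod(ti$X_tst) / 3, tolerance = 1e-12)
})

test_that("components vanish on null test genomes or null effects", {
  ti <- toy_inputs()
  z <- estimate_components(ti$X, ti$Q, 0 * ti$X_tst, ti$Q_tst, ti$theta, 1,
                           return_var_x = TRUE)
  expect_equal(z$e_norm2, 0)
  expect_equal(z$var_x, matrix(0, 4, 4))
  z2 <- estimate_components(ti$X, ti$Q, ti$X_tst, ti$Q_tst, 0 * ti$theta, 1)
  expect_equal(z2$cross_term, 0)
  expect_equal(z2$sigma_G2, 0)
  expect_error(estimate_components(ti$X, ti$Q, ti$X_tst[1, , drop = FALSE],
                                   ti$Q_tst[1, , drop = FALSE], ti$theta, 1),
               "at least 2")
})

test_that("theoretical accuracy equals an independent dense evaluation", {
  ti <- toy_inputs(n = 6, p = 4, C = 1, n_tst = 3, seed = 77)
  got <- theoretical_accuracy(ti$X, ti$Q, ti$X_tst, ti$Q_tst, ti$theta,
                              lambda = 0.4, sigma_e2 = 1)
  want <- dense_rho(ti$X, ti$Q, ti$X_tst, ti$Q_tst, ti$theta, 0.4, 1)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("theoretical accuracy is invariant to column permutation and trait rescaling", {
  ti <- toy_inputs(n = 8, p = 6, C = 3, n_tst = 5, seed = 13)
  base <- theoretical_accuracy(ti$X, ti$Q, ti$X_tst, ti$Q_tst, ti$theta,
                               lambda = 1.3, sigma_e2 = 1)
  perm <- sample(6)
  permed <- theoretical_accuracy(ti$X[, perm], ti$Q, ti$X_tst[, perm],
                                 ti$Q_tst, ti$theta, 1.3, 1)
  expect_equal(permed, base, tolerance = 1e-12)
  # theta -> c theta with sigma_e -> c sigma_e leaves rho unchanged
  scaled <- theoretical_accuracy(ti$X, ti$Q, ti$X_tst, ti$Q_tst,
                                 2.5 * ti$theta, 1.3, 2.5^2 * 1)
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("the closed form for independent causal loci is recovered on an orthogonal design", {
  toy <- orthogonal_toy()
  theta <- c(0.8, -0.4)
  sigma_e2 <- 1.7
  rho5 <- theoretical_accuracy(toy$Q, toy$Q, toy$Q_tst, toy$Q_tst, theta,
                               lambda = 0, sigma_e2 = sigma_e2)
  sigma_G2 <- mean(drop(toy$Q_tst %*% theta)^2)  # columns centered, orthonormal*2
  h2 <- sigma_G2 / (sigma_G2 + sigma_e2)
  rho7 <- daetwyler_accuracy(2, nrow(toy$Q), h2)[["rho"]]
  expect_equal(rho5, rho7, tolerance = 1e-10)
})

test_that("empirical accuracy is the Pearson correlation with guarded edges", {
  x <- c(1, 2, 3, 5)
  expect_equal(empirical_accuracy(x, x), 1)
  expect_equal(empirical_accuracy(x, -x), -1)
  expect_error(empirical_accuracy(rep(1, 4), x), "constant")
  expect_error(empirical_accuracy(x[1:2], x[1:2]), "length")
})

test_that("oracle accuracy is (h, 1)", {
  expect_equal(oracle_accuracy(0), c(rho = 0, rho_tilde = 1))
  expect_equal(oracle_accuracy(1), c(rho = 1, rho_tilde = 1))
  expect_equal(oracle_accuracy(0.45)[["rho"]], 0.6708, tolerance = 1e-4)
  expect_error(oracle_accuracy(1.2))
})

test_that("independent-loci closed form matches hand arithmetic and its limits", {
  expect_equal(daetwyler_accuracy(500, 500, 0.5)[["rho_tilde"]],
               sqrt(1 / 2), tolerance = 1e-10)
  expect_equal(daetwyler_accuracy(100, 500, 0.5)[["rho_tilde"]],
               sqrt(1 / 1.2), tolerance = 1e-10)
  tiny <- daetwyler_accuracy(1e-9, 500, 0.6)
  expect_equal(tiny[["rho_tilde"]], 1, tolerance = 1e-6)
  expect_equal(tiny[["rho"]], sqrt(0.6), tolerance = 1e-6)
  expect_error(daetwyler_accuracy(100, 500, 1), "h2")
  # rho = h * rho_tilde exactly, for the closed form and the oracle
  for (h2 in c(0.2, 0.5, 0.8)) {
    d <- daetwyler_accuracy(37, 500, h2)
    expect_equal(d[["rho"]], sqrt(h2) * d[["rho_tilde"]], tolerance = 1e-14)
    o <- oracle_accuracy(h2)
    expect_equal(o[["rho"]], sqrt(h2) * o[["rho_tilde"]], tolerance = 1e-14)
  }
})
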