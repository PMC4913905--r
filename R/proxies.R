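# Computable proxies for genomic-prediction accuracy.
#
# The effective-dimension proxy replaces the number of independent causal
# loci in the classical closed form by n_trn * E||x' X' V^-1||^2, a quantity
# that depends only on the marker data and lambda (never on the causal
# architecture). The competitors replace it by an effective number of
# chromosome segments Me (a function of the effective population size
# estimated from LD decay) or by the effective number of independent tests
# (Li & Ji eigenvalue rule).

#' Effective-dimension accuracy proxy (perfect LD)
#'
#' \deqn{\rho_{pLD} = h \sqrt{\frac{h^2/(1-h^2)}
#'   {E\|x' X' V^{-1}\|^2 + h^2/(1-h^2)}}}
#' with the expectation replaced by its test-sample mean. Free of the
#' causal parameters; assumes each causal locus is in perfect LD with one
#' marker. Always bounded above by the oracle accuracy `h`.
#'
#' @param h2 Heritability in (0, 1).
#' @param effective_term Test-sample mean of `||x' X' V^-1||^2` (>= 0), the
#'   `e_norm2` component of [estimate_components()].
#' @return The proxy value.
#' @export
new_proxy <- function(h2, effective_term) {
  if (!is.finite(h2) || h2 <= 0 || h2 >= 1) stop("h2 must lie strictly in (0, 1)")
  stopifnot(effective_term >= 0)
  g <- h2 / (1 - h2)
  sqrt(h2) * sqrt(g / (effective_term + g))
}

#' Effective-dimension proxy under imperfect LD
#'
#' Generalises [new_proxy()] to a constant squared correlation `r2` between
#' each causal locus and its associated marker:
#' \deqn{\rho_{pLD}^{(r^2)} = r^2 h \sqrt{\frac{h^2/(1-h^2)}
#'   {E\|x' X' V^{-1}\|^2 + r^2 h^2/(1-h^2)}}.}
#' Reduces to [new_proxy()] at `r2 = 1` and to 0 at `r2 = 0`.
#'
#' @inheritParams new_proxy
#' @param r2 Marker-QTL squared correlation in `[0, 1]`.
#' @return The proxy value.
#' @export
new_proxy_imperfect <- function(h2, effective_term, r2) {
  if (!is.finite(r2) || r2 < 0 || r2 > 1) stop("r2 must lie in [0, 1]")
  if (!is.finite(h2) || h2 <= 0 || h2 >= 1) stop("h2 must lie strictly in (0, 1)")
  g <- h2 / (1 - h2)
  r2 * sqrt(h2) * sqrt(g / (effective_term + r2 * g))
}

#' Effective dimension of the ridge prediction operator
#'
#' `n_trn * mean_i ||x_i' X' V^-1||^2` over the test sample: the quantity
#' that should replace the effective number of independent loci in the
#' classical accuracy formula. Unlike Me it reflects both the training
#' design and the test population.
#'
#' @param X Centered training marker matrix.
#' @param lambda Ridge parameter.
#' @param X_tst Centered test marker matrix.
#' @return The scalar effective dimension.
#' @export
effective_dimension <- function(X, lambda, X_tst) {
  n <- nrow(X)
  dummyQ <- matrix(0, n, 1)
  dummyQt <- matrix(0, nrow(X_tst), 1)
  comp <- estimate_components(X, dummyQ, X_tst, dummyQt, 0, lambda)
  n * comp$e_norm2
}

#' Pairwise LD summary of a marker panel
#'
#' Squared Pearson correlations between all marker pairs together with
#' their map distances, the input to [estimate_ne()]. For large panels a
#' random subset of pairs can be taken.
#'
#' @param genotypes 0/1 (or dosage) matrix, individuals x markers; columns
#'   must be polymorphic.
#' @param positions Marker positions in Morgans.
#' @param max_pairs Optional cap on the number of pairs (random subsample).
#' @return A tibble with columns `distance` (Morgans) and `r2`.
#' @export
ld_pairs <- function(genotypes, positions, max_pairs = NULL) {
  stopifnot(ncol(genotypes) == length(positions), ncol(genotypes) >= 2)
  r2 <- stats::cor(genotypes)^2
  keep <- upper.tri(r2)
  d <- abs(outer(positions, positions, "-"))[keep]
  r2 <- r2[keep]
  if (!is.null(max_pairs) && length(r2) > max_pairs) {
    idx <- sample.int(length(r2), max_pairs)
    d <- d[idx]
    r2 <- r2[idx]
  }
  tibble::tibble(distance = d, r2 = r2)
}

#' Estimate the effective population size from LD decay
#'
#' Least-squares fit of observed pairwise `r2` against the expected decay
#' curve `E[r2] = 1/(a + b * Ne * c) + 1/n`, where `c` is the map distance
#' in Morgans and `1/n` the finite-sample inflation. The default constants
#' `a = 1, b = 4` are the classical Sved/Hill-Weir convention used by the
#' segment-count literature (and are what the benchmark's printed Me values
#' back-solve to); `b = 2` is the pure-haploid recombination rate variant.
#' Both are exposed. With a single free parameter the least-squares problem
#' is solved by bounded 1-D optimisation on `log(Ne)`.
#'
#' @param ld A data frame with columns `distance` (Morgans) and `r2`
#'   (e.g. from [ld_pairs()]), at least 10 pairs over distinct distances.
#' @param n_sample Number of individuals used to compute `r2`.
#' @param a,b Decay-curve constants.
#' @return Estimated `Ne` (> 0). Warns and returns the boundary value when
#'   the fit diverges (r2 carrying no distance signal).
#' @export
estimate_ne <- function(ld, n_sample, a = 1, b = 4) {
  stopifnot(all(c("distance", "r2") %in% names(ld)), n_sample > 1)
  d <- ld$distance
  r2 <- ld$r2
  if (length(r2) < 10 || length(unique(d)) < 3) {
    stop("need at least 10 pairs spanning at least 3 distinct distances")
  }
  sse <- function(logne) {
    ne <- exp(logne)
    sum((r2 - 1 / (a + b * ne * d) - 1 / n_sample)^2)
  }
  lo <- log(1e-3)
  hi <- log(1e8)
  opt <- stats::optimize(sse, interval = c(lo, hi), tol = 1e-10)
  ne <- exp(opt$minimum)
  if (opt$minimum > hi - 0.01) {
    warning("Ne estimate diverged (r2 shows no decay with distance)")
  }
  ne
}

#' Effective number of chromosome segments
#'
#' The three classical representations, all with natural logarithms:
#' `Me1 = 2 Ne L / log(4 Ne l)`, `Me2 = 2 Ne L / log(2 Ne l)`,
#' `Me3 = 2 Ne L / log(Ne l)`, where `L` is genome length and `l` the
#' average chromosome length (Morgans). `Me1 < Me2 < Me3` whenever all
#' three are defined.
#'
#' @param Ne Effective population size (> 0).
#' @param L Genome length in Morgans.
#' @param l Average chromosome length in Morgans.
#' @return Named vector `c(Me1 = , Me2 = , Me3 = )`.
#' @export
me_formulas <- function(Ne, L, l) {
  stopifnot(Ne > 0, L > 0, l > 0)
  if (Ne * l <= 1) stop("Ne * l must exceed 1 for the Me denominators")
  c(Me1 = 2 * Ne * L / log(4 * Ne * l),
    Me2 = 2 * Ne * L / log(2 * Ne * l),
    Me3 = 2 * Ne * L / log(Ne * l))
}

#' Effective number of independent tests (Li & Ji)
#'
#' Eigenvalue-based count of independent markers: for each eigenvalue
#' `ev` of the marker correlation matrix, contribute
#' `1(ev >= 1) + (ev - floor(ev))`; sum over eigenvalues. The method needs
#' more individuals than markers, so dense panels are split into
#' equal-width position intervals along the chromosome and the per-split
#' counts are summed.
#'
#' @param genotypes Pooled training + test genotype matrix (polymorphic
#'   columns).
#' @param positions Marker positions in Morgans (for splitting).
#' @param n_splits Number of equal-width splits; see [lj_splits_rule()].
#' @param chrom_length Chromosome length in Morgans.
#' @return The summed effective number of independent tests.
#' @export
m_li_ji <- function(genotypes, positions, n_splits = 1, chrom_length = 1) {
  stopifnot(ncol(genotypes) == length(positions), n_splits >= 1)
  breaks <- seq(0, chrom_length, length.out = n_splits + 1)
  part <- cut(positions, breaks, include.lowest = TRUE, labels = FALSE)
  total <- 0
  for (s in unique(part)) {
    cols <- which(part == s)
    if (length(cols) >= nrow(genotypes)) {
      stop("markers in a split must be fewer than individuals; increase n_splits")
    }
    if (length(cols) == 1L) {
      total <- total + 1
      next
    }
    ev <- eigen(stats::cor(genotypes[, cols, drop = FALSE]),
                symmetric = TRUE, only.values = TRUE)$values
    ev[ev < 1e-10] <- 0
    # round before flooring so integer eigenvalues are not split by one ulp
    ev <- round(ev, 9)
    total <- total + sum((ev >= 1) + (ev - floor(ev)))
  }
  total
}

#' Split rule for the Li & Ji computation
#'
#' The benchmark convention: no split below 1,000 markers, 2 splits for
#' 1,000-marker panels, 3 splits for 5,000 or more.
#'
#' @param n_markers Initial panel density (before filtering).
#' @return Number of splits.
#' @export
lj_splits_rule <- function(n_markers) {
  if (n_markers < 1000) 1L else if (n_markers < 5000) 2L else 3L
}

#' Mean squared error of a proxy against empirical accuracy
#'
#' `MSE = mean((proxy_a - empirical_a)^2)` over per-architecture means.
#'
#' @param proxy_values,empirical_values Equal-length vectors of
#'   per-architecture mean accuracies.
#' @return The mean squared difference.
#' @export
proxy_mse <- function(proxy_values, empirical_values) {
  if (length(proxy_values) != length(empirical_values)) {
    stop("proxy and empirical vectors must have equal length")
  }
  mean((proxy_values - empirical_values)^2)
}
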