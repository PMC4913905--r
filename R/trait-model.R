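# Sparse causal trait model: y_i = q_i' theta + e_i with a handful of causal
# loci carrying fixed effects, environmental noise N(0, sigma_e2), and all
# genotype codes centered before any model fitting.

#' Construct a trait architecture
#'
#' @param qtl_positions Causal locus positions in Morgans (must be locus
#'   positions of the map in use; the equally spaced grid makes every whole
#'   centimorgan exact).
#' @param effects Fixed causal effects, one per causal locus.
#' @param sigma_e2 Environmental variance (> 0).
#' @param name Optional scenario label.
#' @return An object of class `trait_arch`.
#' @export
trait_architecture <- function(qtl_positions, effects, sigma_e2 = 1, name = NULL) {
  stopifnot(length(qtl_positions) == length(effects), length(effects) >= 1,
            sigma_e2 > 0)
  structure(
    list(qtl_positions = as.numeric(qtl_positions),
         effects = as.numeric(effects),
         sigma_e2 = sigma_e2,
         name = name %||% "custom"),
    class = "trait_arch"
  )
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf("<trait_arch> '%s': %d causal loci, sigma_e2 = %.3g\n",
              x$name, length(x$effects), x$sigma_e2))
  invisible(x)
}

#' Named QTL scenarios of the benchmark study
#'
#' Five architectures on a 1-Morgan chromosome, all with environmental
#' variance 1:
#' * `two_qtl`: 2 QTLs at 3 cM and 80 cM with effects +1 and -2;
#' * `hundred_qtl`: 100 QTLs, one every centimorgan, all with effect +0.15;
#' * `mixture_a`: large QTLs +0.5 / -0.6 at 3 and 80 cM plus 98 small QTLs
#'   of +0.07 at the remaining centimorgans;
#' * `mixture_b`: +1 / -0.7 plus 98 effects of +0.1;
#' * `mixture_c`: +2 / -2 plus 98 effects of +0.1.
#'
#' @param scenario One of `"two_qtl"`, `"hundred_qtl"`, `"mixture_a"`,
#'   `"mixture_b"`, `"mixture_c"`.
#' @return A [trait_architecture()] object.
#' @export
qtl_scenarios <- function(scenario) {
  every_cm <- (0:99) / 100
  big <- c(0.03, 0.80)
  small <- setdiff(every_cm, big)
  mix <- function(eff_big, eff_small, name) {
    trait_architecture(c(big, small),
                       c(eff_big, rep(eff_small, length(small))),
                       sigma_e2 = 1, name = name)
  }
  switch(match.arg(scenario,
                   c("two_qtl", "hundred_qtl", "mixture_a", "mixture_b", "mixture_c")),
    two_qtl = trait_architecture(big, c(1, -2), 1, "two_qtl"),
    hundred_qtl = trait_architecture(every_cm, rep(0.15, 100), 1, "hundred_qtl"),
    mixture_a = mix(c(0.5, -0.6), 0.07, "mixture_a"),
    mixture_b = mix(c(1, -0.7), 0.1, "mixture_b"),
    mixture_c = mix(c(2, -2), 0.1, "mixture_c")
  )
}

#' Map causal positions to locus columns
#'
#' Returns the column index of the locus nearest to each causal position
#' (exact on the standard grids). Errors if a causal position falls further
#' than half the marker spacing from every locus.
#'
#' @param map A [genetic_map()].
#' @param arch A `trait_arch`.
#' @return Integer column indices, one per causal locus.
#' @export
qtl_indices <- function(map, arch) {
  idx <- vapply(arch$qtl_positions, function(p) which.min(abs(map$positions - p)),
                integer(1))
  spacing <- map$chrom_length / n_loci(map)
  off <- abs(map$positions[idx] - arch$qtl_positions)
  if (any(off > spacing / 2 + 1e-12)) {
    stop("some causal positions do not lie on (or near) the locus grid")
  }
  idx
}

#' Center matrix columns against reference means
#'
#' @param m Numeric matrix.
#' @param reference_means One mean per column; defaults to the matrix's own
#'   column means. Test genotypes are typically centered by training (or
#'   pooled) means, so their column means need not be zero afterwards.
#' @return The centered matrix.
#' @export
center_columns <- function(m, reference_means = colMeans(m)) {
  if (length(reference_means) != ncol(m)) {
    stop("reference_means must have one entry per column")
  }
  sweep(m, 2L, reference_means, "-")
}

#' Simulate phenotypes under the sparse causal model
#'
#' `y_i = q_i' theta + e_i` with `e_i ~ N(0, sigma_e2)`. When `center =
#' TRUE` (the default, matching the convention that phenotypic observations
#' are centered) the overall mean of `y` is subtracted; genetic values and
#' residuals are returned uncentered so that `y + mean = genetic + e`.
#'
#' @param Q Centered causal genotype matrix (n x C).
#' @param arch A `trait_arch` providing effects and `sigma_e2`.
#' @param center Subtract the sample mean from `y`?
#' @return A list with `y`, `genetic_values`, `residuals`.
#' @export
simulate_phenotypes <- function(Q, arch, center = TRUE) {
  stopifnot(ncol(Q) == length(arch$effects))
  g <- drop(Q %*% arch$effects)
  e <- stats::rnorm(nrow(Q), 0, sqrt(arch$sigma_e2))
  y <- g + e
  if (center) y <- y - mean(y)
  list(y = y, genetic_values = g, residuals = e)
}

#' Estimate heritability from realised genetic values
#'
#' `h2 = Var(g) / (Var(g) + sigma_e2)` with the unbiased empirical variance
#' of the genetic values `g = q' theta`, computed over the pooled
#' training + test sample.
#'
#' @param genetic_values Vector of realised genetic values.
#' @param sigma_e2 Environmental variance.
#' @return Estimated narrow-sense heritability in `[0, 1)`.
#' @export
estimate_heritability <- function(genetic_values, sigma_e2) {
  stopifnot(length(genetic_values) >= 2, sigma_e2 > 0)
  v <- stats::var(genetic_values)
  if (!is.finite(v) || v <= 0) return(0)
  v / (v + sigma_e2)
}
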