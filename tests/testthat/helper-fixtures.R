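# Shared fixtures, all built in code.

# Tiny two-locus map at a chosen distance, for recombination-fraction checks.
two_locus_map <- function(d, start = 0.25, L = 1) {
  genetic_map(2, chrom_length = L, positions = c(start, start + d))
}

# Empirical recombination fraction between the two loci of `map` over
# n gametes of fully divergent parents.
recomb_fraction <- function(map, n) {
  a <- c(0L, 0L)
  b <- c(1L, 1L)
  rec <- vapply(seq_len(n), function(i) {
    g <- meiosis(a, b, map)
    g[1L] != g[2L]
  }, logical(1))
  mean(rec)
}

# Haldane map function.
haldane_r <- function(d) (1 - exp(-2 * d)) / 2

# An 8 x 2 orthogonal +/-1 causal design with Q'Q = 8 I and a matching
# centered orthogonal 4 x 2 test matrix; used for the closed-form reduction.
orthogonal_toy <- function() {
  Q <- cbind(rep(c(1, -1), 4), rep(c(1, 1, -1, -1), 2))
  Q_tst <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  list(Q = Q, Q_tst = Q_tst)
}

# Subset a haploid population's rows, keeping the class structure.
new_haploid_pop_for_test <- function(pop, rows) {
  structure(list(alleles = pop$alleles[rows, , drop = FALSE], map = pop$map,
                 generation = pop$generation), class = "haploid_pop")
}

# Small random regression instance.
random_instance <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  list(X = X, y = y)
}

# Minimal simulated design for runner tests.
tiny_arch <- function(n_markers = 100, n_generations = 10, scenario = "two_qtl",
                      n_trn = 500) {
  gs_architecture(n_markers, n_generations, scenario, n_trn = n_trn)
}
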