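# Forward-in-time haploid random-mating simulator on a single chromosome.
# Recombination follows Haldane's model (Poisson crossovers, no interference,
# no mutation), so all linkage disequilibrium in the simulated populations is
# generated by the two-founder bottleneck, drift and recombination alone.

#' Create a genetic map of equally spaced loci on one chromosome
#'
#' Loci are placed on the grid `(0:(n_loci-1)) * chrom_length / n_loci`
#' Morgans, so that for the standard panel densities (100, 1,000, 5,000,
#' 10,000 loci on a 1-Morgan chromosome) every whole centimorgan is an exact
#' locus position. This matters for the perfect-LD analyses, where causal
#' loci must sit exactly on markers.
#'
#' @param n_loci Number of loci (columns of the allele matrix).
#' @param chrom_length Chromosome length `L` in Morgans.
#' @param avg_chrom_length Average chromosome length `l` in Morgans, used by
#'   the effective-number-of-segments formulas. Defaults to `chrom_length`
#'   (single-chromosome genome).
#' @param positions Optional explicit locus positions (Morgans); overrides
#'   the equally spaced grid. Must be sorted and lie in `[0, chrom_length]`.
#' @return An object of class `genetic_map`: a list with `positions`,
#'   `chrom_length` and `avg_chrom_length`.
#' @examples
#' map <- genetic_map(100)
#' map$positions[c(4, 81)] # 3 cM and 80 cM are exact grid points
#' @export
genetic_map <- function(n_loci, chrom_length = 1, avg_chrom_length = chrom_length,
                        positions = NULL) {
  stopifnot(chrom_length > 0)
  if (is.null(positions)) {
    stopifnot(n_loci >= 1)
    positions <- (seq_len(n_loci) - 1) * (chrom_length / n_loci)
  } else {
    if (is.unsorted(positions)) stop("map positions must be sorted non-decreasing")
    if (any(positions < 0 | positions > chrom_length)) {
      stop("map positions must lie within [0, chrom_length]")
    }
  }
  structure(
    list(positions = as.numeric(positions),
         chrom_length = chrom_length,
         avg_chrom_length = avg_chrom_length),
    class = "genetic_map"
  )
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %d loci on %.4g Morgan(s)\n",
              length(x$positions), x$chrom_length))
  invisible(x)
}

n_loci <- function(map) length(map$positions)

new_haploid_pop <- function(alleles, map, generation) {
  structure(list(alleles = alleles, map = map, generation = as.integer(generation)),
            class = "haploid_pop")
}

#' @export
print.haploid_pop <- function(x, ...) {
  cat(sprintf("<haploid_pop> %d individuals x %d loci, generation %d\n",
              nrow(x$alleles), ncol(x$alleles), x$generation))
  invisible(x)
}

#' Two fully divergent haploid founder lines
#'
#' Founder 1 carries allele 0 at every locus and founder 2 allele 1, so the
#' base cross starts from complete polymorphism (frequency 1/2 everywhere)
#' and complete positive linkage disequilibrium between all locus pairs.
#'
#' @param map A [genetic_map()].
#' @return A `haploid_pop` with 2 individuals at generation 0.
#' @export
make_founders <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  p <- n_loci(map)
  if (p < 1L) stop("empty genetic map")
  alleles <- rbind(rep(0L, p), rep(1L, p))
  new_haploid_pop(alleles, map, 0L)
}

#' Single meiosis between two haploid parents (Haldane model)
#'
#' Crossover count is Poisson with mean equal to the chromosome length in
#' Morgans; crossover locations are uniform on the chromosome; the starting
#' parental strand is chosen with probability 1/2 and strands alternate at
#' each crossover. There is no mutation: every output allele is copied from
#' one of the parents.
#'
#' @param parent_a,parent_b Haplotypes (0/1 vectors) of equal length,
#'   matching the map.
#' @param map A [genetic_map()].
#' @return A gamete: 0/1 integer vector of the same length.
#' @export
meiosis <- function(parent_a, parent_b, map) {
  p <- n_loci(map)
  if (length(parent_a) != p || length(parent_b) != p) {
    stop("parent haplotype length does not match the map")
  }
  L <- map$chrom_length
  k <- stats::rpois(1L, L)
  start <- if (stats::runif(1L) < 0.5) 0L else 1L
  if (k == 0L) {
    return(if (start == 0L) parent_a else parent_b)
  }
  xo <- sort(stats::runif(k, 0, L))
  # segment index (number of crossovers left of each locus) + start, mod 2
  src <- (findInterval(map$positions, xo) + start) %% 2L
  gamete <- parent_a
  swap <- src == 1L
  gamete[swap] <- parent_b[swap]
  gamete
}

# Fast gamete formation on a locus-major (transposed) allele matrix: each
# gamete is assembled from k+1 contiguous chromosome segments (k ~ Poisson(L)
# crossovers), so a column copy is a handful of memcpy-like slice
# assignments instead of per-locus work. Distributionally identical to
# meiosis(); parents for column o are pairs[o, 1:2], starting strand random.
mate_t <- function(tA, pairs, map) {
  p <- nrow(tA)
  pos <- map$positions
  L <- map$chrom_length
  n_off <- nrow(pairs)
  out <- matrix(0L, p, n_off)
  k_all <- stats::rpois(n_off, L)
  swap <- stats::runif(n_off) < 0.5
  for (o in seq_len(n_off)) {
    a <- pairs[o, 1L]
    b <- pairs[o, 2L]
    if (swap[o]) { tmp <- a; a <- b; b <- tmp }
    k <- k_all[o]
    if (k == 0L) {
      out[, o] <- tA[, a]
      next
    }
    xo <- sort.int(stats::runif(k, 0, L))
    bounds <- c(0L, findInterval(xo, pos), p)
    cur <- a
    for (j in seq_len(k + 1L)) {
      lo <- bounds[j] + 1L
      hi <- bounds[j + 1L]
      if (lo <= hi) out[lo:hi, o] <- tA[lo:hi, cur]
      cur <- if (cur == a) b else a
    }
  }
  out
}

# Uniform distinct parent pairs (no selfing), with replacement across
# offspring.
draw_pairs <- function(n_parents, n_offspring) {
  p1 <- sample.int(n_parents, n_offspring, replace = TRUE)
  p2 <- sample.int(n_parents - 1L, n_offspring, replace = TRUE)
  p2 <- p2 + (p2 >= p1)
  cbind(p1, p2)
}

# One round of random mating: n_offspring gametes, each from two distinct
# parents drawn uniformly (no selfing), sampled with replacement across
# offspring. Individual-major in, individual-major out.
random_mating <- function(alleles, n_offspring, map) {
  n <- nrow(alleles)
  if (n < 2L) stop("random mating needs at least 2 parents")
  t(mate_t(t(alleles), draw_pairs(n, n_offspring), map))
}

#' Evolve a population by discrete-generation random mating
#'
#' Each generation consists of `pop_size` offspring; each offspring is a
#' single gamete from two distinct parents drawn uniformly at random from
#' the previous generation (generations do not overlap). Applied to the
#' two-founder population this makes generation 1 a set of `pop_size`
#' gametes of the founder pair.
#'
#' @param pop A `haploid_pop`.
#' @param n_generations Number of generations to advance (0 returns the
#'   input unchanged).
#' @param pop_size Constant population size per generation.
#' @return The evolved `haploid_pop` with its generation counter advanced.
#' @export
evolve <- function(pop, n_generations, pop_size) {
  stopifnot(inherits(pop, "haploid_pop"), n_generations >= 0)
  if (pop_size < 2) stop("pop_size must be at least 2")
  if (nrow(pop$alleles) < 2L) stop("population must contain at least 2 individuals")
  if (n_generations == 0) return(pop)
  tA <- t(pop$alleles)
  for (g in seq_len(n_generations)) {
    tA <- mate_t(tA, draw_pairs(ncol(tA), pop_size), pop$map)
  }
  new_haploid_pop(t(tA), pop$map, pop$generation + n_generations)
}

#' Generate full sibs from one randomly chosen parent pair
#'
#' Two distinct individuals are drawn from the population and `n_sibs`
#' independent gametes of that single pair are produced. Used to enrich the
#' training set with closely related individuals.
#'
#' @param pop A `haploid_pop` (the final generation).
#' @param n_sibs Number of full sibs to generate.
#' @param parents Optional length-2 vector of parent row indices; drawn at
#'   random when `NULL`.
#' @return A `haploid_pop` of the sibs (same generation counter + 1).
#' @export
make_full_sibs <- function(pop, n_sibs, parents = NULL) {
  stopifnot(inherits(pop, "haploid_pop"), n_sibs >= 1)
  n <- nrow(pop$alleles)
  if (n < 2L) stop("need at least 2 individuals to pick a sib parent pair")
  if (is.null(parents)) parents <- sample.int(n, 2L)
  tA <- t(pop$alleles[parents, , drop = FALSE])
  pairs <- matrix(rep(c(1L, 2L), each = n_sibs), ncol = 2L)
  out <- t(mate_t(tA, pairs, pop$map))
  new_haploid_pop(out, pop$map, pop$generation + 1L)
}

#' Filter monomorphic and duplicated marker columns
#'
#' Removes columns without polymorphism, then among groups of exactly
#' identical columns keeps only the left-most occurrence (smallest map
#' position). Filtering is defined on the training genotypes; the returned
#' index set is then applied to any other matrix over the same panel.
#'
#' @param genotypes 0/1 matrix (individuals x loci), typically the TRN set.
#' @return Integer vector of kept column indices, ascending.
#' @export
filter_markers <- function(genotypes) {
  if (!is.matrix(genotypes) || nrow(genotypes) == 0L || ncol(genotypes) == 0L) {
    stop("genotypes must be a non-empty matrix")
  }
  cmin <- apply(genotypes, 2L, min)
  cmax <- apply(genotypes, 2L, max)
  poly <- cmin != cmax
  dup <- duplicated(genotypes, MARGIN = 2L)
  which(poly & !dup)
}

#' Branch a test population from a checkpoint generation
#'
#' Continues random mating from `pop` for `extra_generations` further
#' generations, then samples `n_tst` individuals uniformly without
#' replacement from the resulting generation. With `extra_generations = 0`
#' the sample is drawn from the checkpoint itself. Used to study prediction
#' on test material that kept evolving after the training population was
#' fixed.
#'
#' @param pop Checkpoint `haploid_pop`.
#' @param extra_generations Further generations of random mating (>= 0).
#' @param n_tst Number of test individuals to sample.
#' @return A `haploid_pop` of the sampled test individuals.
#' @export
branch_tst <- function(pop, extra_generations, n_tst) {
  stopifnot(extra_generations >= 0)
  evolved <- if (extra_generations > 0) {
    evolve(pop, extra_generations, nrow(pop$alleles))
  } else {
    pop
  }
  n <- nrow(evolved$alleles)
  if (n_tst > n) stop("n_tst exceeds population size")
  idx <- sample.int(n, n_tst)
  new_haploid_pop(evolved$alleles[idx, , drop = FALSE], pop$map, evolved$generation)
}

#' Simulate a complete training/test design
#'
#' Runs the full base-population pipeline: cross two divergent founders,
#' evolve `n_generations` of random mating at size `pop_size`, produce the
#' final generation together with `n_tst` extra offspring of the penultimate
#' generation (the test set), and add `n_fullsibs` full sibs of one random
#' final-generation pair to the training set. The training set pools the
#' `pop_size` final-generation individuals with the sibs.
#'
#' @param map A [genetic_map()].
#' @param n_generations Generations of random mating.
#' @param pop_size Constant population size (e.g. 400 or 800).
#' @param n_fullsibs Number of full sibs added to the training set
#'   (e.g. 100 or 200; the classical design uses `pop_size / 4`).
#' @param n_tst Number of test individuals (e.g. 100).
#' @return A list with `trn` (n_trn x p matrix, sibs last), `tst`
#'   (n_tst x p matrix), `map`, `penultimate` (`haploid_pop`, used to
#'   regenerate test sets), `final` (`haploid_pop`), and `is_sib` (logical
#'   over TRN rows).
#' @export
simulate_design <- function(map, n_generations, pop_size, n_fullsibs, n_tst) {
  stopifnot(n_generations >= 1)
  founders <- make_founders(map)
  pen <- evolve(founders, n_generations - 1L, pop_size)
  # final mating step: pop_size TRN-base offspring plus n_tst TST offspring,
  # all children of the penultimate generation
  off <- random_mating(pen$alleles, pop_size + n_tst, map)
  tst_idx <- sample.int(pop_size + n_tst, n_tst)
  final <- new_haploid_pop(off[-tst_idx, , drop = FALSE], map, pen$generation + 1L)
  tst <- off[tst_idx, , drop = FALSE]
  sibs <- make_full_sibs(final, n_fullsibs)
  trn <- rbind(final$alleles, sibs$alleles)
  list(
    trn = trn,
    tst = tst,
    map = map,
    penultimate = pen,
    final = final,
    is_sib = c(rep(FALSE, pop_size), rep(TRUE, n_fullsibs))
  )
}
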