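# Experiment runner: architecture grid, replicate loops, fixed-vs-varying
# training designs, causal-markers-removed mode. Each replicate runs the
# full pipeline (simulate -> sibs -> TRN/TST -> filter -> phenotypes ->
# lambda -> fit -> predict -> accuracies and proxies) and contributes one
# tibble row; summaries and proxy mean-squared errors are tibble views.

#' Define a simulation architecture
#'
#' An architecture fixes the marker density, number of generations, causal
#' scenario and training-set size. The classical design couples the sizes:
#' `n_trn = pop_size + n_fullsibs` with `n_fullsibs = pop_size / 4`, so
#' `n_trn = 500` means 400 random-mating individuals plus 100 full sibs.
#'
#' @param n_markers Marker panel density (e.g. 100, 1000, 5000, 10000).
#' @param n_generations Generations of random mating (e.g. 30, 50, 70).
#' @param qtl_scenario Scenario name, see [qtl_scenarios()], or a
#'   `trait_arch` object.
#' @param n_trn Training-set size (500 or 1000 in the classical grid).
#' @param n_tst Test-set size (default 100).
#' @param chrom_length Chromosome length in Morgans.
#' @return An object of class `gs_arch`.
#' @export
gs_architecture <- function(n_markers, n_generations, qtl_scenario,
                            n_trn = 500, n_tst = 100, chrom_length = 1) {
  pop_size <- n_trn * 4 / 5
  n_fullsibs <- n_trn / 5
  if (pop_size != round(pop_size) || pop_size + n_fullsibs != n_trn) {
    stop("n_trn must decompose as pop_size + pop_size/4")
  }
  arch <- if (inherits(qtl_scenario, "trait_arch")) qtl_scenario
          else qtl_scenarios(qtl_scenario)
  structure(
    list(n_markers = n_markers, n_generations = n_generations,
         pop_size = as.integer(pop_size), n_fullsibs = as.integer(n_fullsibs),
         n_trn = as.integer(n_trn), n_tst = as.integer(n_tst),
         trait = arch, chrom_length = chrom_length,
         id = sprintf("%s_m%d_g%d_n%d", arch$name, n_markers, n_generations, n_trn)),
    class = "gs_arch"
  )
}

#' @export
print.gs_arch <- function(x, ...) {
  cat(sprintf("<gs_arch> %s: %d markers, %d generations, n_trn = %d (%d sibs), n_tst = %d\n",
              x$trait$name, x$n_markers, x$n_generations, x$n_trn,
              x$n_fullsibs, x$n_tst))
  invisible(x)
}

# Deterministic per-replicate seed stream; master seeds are small integers,
# so the arithmetic stays exact in doubles and the result fits in 32 bits.
derive_seeds <- function(master_seed, n, stream = 0L) {
  base <- (abs(as.numeric(master_seed)) * 48271 + as.numeric(stream) * 69621) %%
    2147483629
  as.integer((base + 999983 * seq_len(n)) %% 2147483629 + 1)
}

# Build centered X, Q and phenotypes for an assembled design.
# Returns everything a fit/accuracy evaluation needs.
prepare_replicate_data <- function(design, arch, qtl_in_markers, center) {
  map <- design$map
  trait <- arch$trait
  qidx <- qtl_indices(map, trait)
  geno_all <- rbind(design$trn, design$tst)
  n_trn <- nrow(design$trn)
  idx_trn <- seq_len(n_trn)
  idx_tst <- n_trn + seq_len(nrow(design$tst))

  Q_raw <- geno_all[, qidx, drop = FALSE]
  marker_cols <- seq_len(ncol(geno_all))
  if (qtl_in_markers == "removed") marker_cols <- setdiff(marker_cols, qidx)
  kept <- filter_markers(design$trn[, marker_cols, drop = FALSE])
  kept_cols <- marker_cols[kept]
  X_raw <- geno_all[, kept_cols, drop = FALSE]

  ref_rows <- if (center == "pooled") seq_len(nrow(geno_all)) else idx_trn
  Xc <- center_columns(X_raw, colMeans(X_raw[ref_rows, , drop = FALSE]))
  Qc <- center_columns(Q_raw, colMeans(Q_raw[ref_rows, , drop = FALSE]))

  list(
    X = Xc[idx_trn, , drop = FALSE], X_tst = Xc[idx_tst, , drop = FALSE],
    Q = Qc[idx_trn, , drop = FALSE], Q_tst = Qc[idx_tst, , drop = FALSE],
    theta = trait$effects, sigma_e2 = trait$sigma_e2,
    n_kept = length(kept_cols), kept_cols = kept_cols,
    positions = map$positions[kept_cols],
    idx_trn = idx_trn, idx_tst = idx_tst
  )
}

# Phenotypes + lambda + fit + all accuracy quantities for prepared data.
evaluate_replicate <- function(dat, arch, lambda_route, compute_proxies,
                               eigen_k = NULL, ld_max_pairs = 200000) {
  trait <- arch$trait
  Q_all <- rbind(dat$Q, dat$Q_tst)
  ph <- simulate_phenotypes(Q_all, trait, center = TRUE)
  y_trn <- ph$y[dat$idx_trn]
  y_tst <- ph$y[dat$idx_tst]
  g_tst <- ph$genetic_values[dat$idx_tst]
  h2_hat <- estimate_heritability(ph$genetic_values, trait$sigma_e2)

  ev <- eigen_k
  if (lambda_route == "reml") {
    ev <- ev %||% eigen_K(dat$X)
    reml <- estimate_lambda_reml(dat$X, y_trn, eigen_k = ev)
    lambda <- reml$lambda
  } else {
    h2_for_lambda <- if (lambda_route == "h2_mis") 0.9 * h2_hat else h2_hat
    lambda <- estimate_lambda_h2(dat$X, h2_for_lambda)
  }

  fit <- rr_fit(dat$X, y_trn, lambda, eigen_k = ev)
  pred <- predict(fit, dat$X_tst)

  comp <- estimate_components(dat$X, dat$Q, dat$X_tst, dat$Q_tst,
                              dat$theta, lambda)
  rho_theo <- theoretical_accuracy(sigma_e2 = trait$sigma_e2, components = comp)
  eff_dim <- arch$n_trn * comp$e_norm2

  row <- tibble::tibble(
    h2_hat = h2_hat, lambda = lambda, n_markers_kept = dat$n_kept,
    rho_empirical = empirical_accuracy(pred, y_tst),
    rho_empirical_genotypic = empirical_accuracy(pred, g_tst),
    rho_theoretical = rho_theo,
    rho_oracle = sqrt(h2_hat),
    rho_pld = new_proxy(h2_hat, comp$e_norm2),
    effective_dimension = eff_dim,
    e_norm2 = comp$e_norm2, cross_term = comp$cross_term,
    var_term = comp$var_term, sigma_G2_hat = comp$sigma_G2
  )

  if (compute_proxies) {
    # pairwise r2 is invariant to the column centering of X
    ld <- ld_pairs(dat$X, dat$positions, max_pairs = ld_max_pairs)
    ne <- estimate_ne(ld, n_sample = arch$n_trn)
    me <- me_formulas(ne, L = arch$chrom_length, l = arch$chrom_length)
    pooled <- rbind(dat$X, dat$X_tst)
    mlj <- m_li_ji(pooled, dat$positions,
                   n_splits = lj_splits_rule(arch$n_markers),
                   chrom_length = arch$chrom_length)
    row <- dplyr::mutate(
      row,
      Ne_hat = ne, Me1 = me[["Me1"]], Me2 = me[["Me2"]], Me3 = me[["Me3"]],
      M_LJ = mlj,
      rho_me1 = daetwyler_accuracy(me[["Me1"]], arch$n_trn, h2_hat)[["rho"]],
      rho_me2 = daetwyler_accuracy(me[["Me2"]], arch$n_trn, h2_hat)[["rho"]],
      rho_me3 = daetwyler_accuracy(me[["Me3"]], arch$n_trn, h2_hat)[["rho"]],
      rho_mlj = daetwyler_accuracy(mlj, arch$n_trn, h2_hat)[["rho"]]
    )
  }
  row
}

#' Run one simulation replicate end to end
#'
#' Simulates a population for the architecture, assembles the training and
#' test sets, filters markers on the training genotypes, builds centered
#' incidence matrices, draws phenotypes, estimates the ridge parameter,
#' fits RRBLUP, and returns one row with empirical, theoretical, oracle and
#' proxy accuracies.
#'
#' @param arch A [gs_architecture()].
#' @param lambda_route `"reml"`, `"h2"`, or `"h2_mis"` (the last multiplies
#'   the estimated heritability by 0.9 before the lambda formula, to probe
#'   robustness to a misspecified heritability; accuracy formulas still use
#'   the unperturbed estimate).
#' @param qtl_in_markers `"included"` (causal loci are observed markers) or
#'   `"removed"` (causal columns are deleted from the marker panel before
#'   filtering; the causal matrix and phenotypes are unchanged — the
#'   imperfect-LD mode).
#' @param compute_proxies Also compute Ne/Me/Li-Ji proxies (adds the LD fit
#'   and an eigendecomposition; off by default).
#' @param center Column-centering reference: pooled TRN+TST means
#'   (default) or TRN-only means.
#' @param seed Integer seed for the replicate.
#' @return A one-row tibble.
#' @export
run_replicate <- function(arch, lambda_route = c("reml", "h2", "h2_mis"),
                          qtl_in_markers = c("included", "removed"),
                          compute_proxies = FALSE,
                          center = c("pooled", "trn"), seed = 1L) {
  lambda_route <- match.arg(lambda_route)
  qtl_in_markers <- match.arg(qtl_in_markers)
  center <- match.arg(center)
  set.seed(seed)
  map <- genetic_map(arch$n_markers, arch$chrom_length)
  design <- simulate_design(map, arch$n_generations, arch$pop_size,
                            arch$n_fullsibs, arch$n_tst)
  dat <- prepare_replicate_data(design, arch, qtl_in_markers, center)
  row <- evaluate_replicate(dat, arch, lambda_route, compute_proxies)
  dplyr::bind_cols(
    tibble::tibble(architecture = arch$id, scenario = arch$trait$name,
                   n_markers = arch$n_markers,
                   n_generations = arch$n_generations,
                   n_trn = arch$n_trn, seed = seed),
    row
  )
}

#' Run replicates of one architecture (training design varies)
#'
#' A fresh population (hence a fresh training incidence matrix) is
#' simulated for every replicate; per-replicate seeds are derived
#' deterministically from the master seed. Failed replicates are recorded
#' with their stage and excluded from summaries; more than 5% failures
#' aborts the run.
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of replicates.
#' @param master_seed Master seed for the architecture.
#' @param stream Integer stream offset separating architectures sharing a
#'   master seed.
#' @return A tibble with one row per replicate (column `failed` flags
#'   failures).
#' @export
run_architecture <- function(arch, n_replicates = 100, master_seed = 1L,
                             lambda_route = "reml",
                             qtl_in_markers = "included",
                             compute_proxies = FALSE,
                             center = "pooled", stream = 0L) {
  seeds <- derive_seeds(master_seed, n_replicates, stream)
  rows <- purrr::map(seq_len(n_replicates), function(r) {
    out <- tryCatch(
      dplyr::mutate(
        run_replicate(arch, lambda_route, qtl_in_markers, compute_proxies,
                      center, seed = seeds[r]),
        replicate = r, failed = FALSE, .before = 1),
      error = function(e) {
        tibble::tibble(replicate = r, failed = TRUE,
                       architecture = arch$id, scenario = arch$trait$name,
                       n_markers = arch$n_markers,
                       n_generations = arch$n_generations,
                       n_trn = arch$n_trn, seed = seeds[r],
                       stage = conditionMessage(e))
      })
    out
  })
  res <- dplyr::bind_rows(rows)
  if (mean(res$failed) > 0.05) {
    stop(sprintf("%.0f%% of replicates failed for %s",
                 100 * mean(res$failed), arch$id))
  }
  res
}

#' Run replicates with a fixed training incidence matrix
#'
#' The training population (and hence X and Q over the training rows) is
#' generated once; each replicate regenerates only the test individuals —
#' by random mating from the penultimate generation, or, when
#' `tst_extra_generations > 0`, by evolving the final population further
#' before sampling the test set — and fresh phenotypes for everyone.
#' Centering uses training means so that the training matrix is literally
#' constant across replicates, and the eigendecomposition of `XX'` is
#' computed once and reused.
#'
#' @inheritParams run_architecture
#' @param tst_extra_generations Extra generations of random mating for the
#'   test population beyond the training generation count.
#' @return A tibble with one row per replicate.
#' @export
run_fixed_trn <- function(arch, n_replicates = 100, master_seed = 1L,
                          lambda_route = "h2",
                          qtl_in_markers = "included",
                          compute_proxies = FALSE,
                          tst_extra_generations = 0, stream = 0L) {
  seeds <- derive_seeds(master_seed, n_replicates + 1L, stream)
  set.seed(seeds[1L])
  map <- genetic_map(arch$n_markers, arch$chrom_length)
  base <- simulate_design(map, arch$n_generations, arch$pop_size,
                          arch$n_fullsibs, arch$n_tst)
  ev_cache <- new.env(parent = emptyenv())
  rows <- purrr::map(seq_len(n_replicates), function(r) {
    set.seed(seeds[r + 1L])
    tst <- if (tst_extra_generations > 0) {
      branch_tst(base$final, tst_extra_generations, arch$n_tst)$alleles
    } else {
      random_mating(base$penultimate$alleles, arch$n_tst, map)
    }
    design <- list(trn = base$trn, tst = tst, map = map)
    dat <- prepare_replicate_data(design, arch, qtl_in_markers, center = "trn")
    if (is.null(ev_cache$ev) && lambda_route == "reml") {
      ev_cache$ev <- eigen_K(dat$X)
    }
    out <- evaluate_replicate(dat, arch, lambda_route, compute_proxies,
                              eigen_k = ev_cache$ev)
    dplyr::bind_cols(
      tibble::tibble(replicate = r, failed = FALSE, architecture = arch$id,
                     scenario = arch$trait$name, n_markers = arch$n_markers,
                     n_generations = arch$n_generations,
                     n_trn = arch$n_trn, seed = seeds[r + 1L],
                     tst_extra_generations = tst_extra_generations),
      out
    )
  })
  dplyr::bind_rows(rows)
}

#' Summarise replicate rows per architecture
#'
#' Per-architecture means and variances of every accuracy / proxy column,
#' excluding failed replicates.
#'
#' @param rows Output of [run_architecture()] / [run_fixed_trn()]
#'   (possibly row-bound over architectures).
#' @return A tibble with one row per architecture; columns `<name>_mean`
#'   and `<name>_var`.
#' @export
summarize_runs <- function(rows) {
  metric_cols <- intersect(
    c("h2_hat", "lambda", "n_markers_kept", "rho_empirical",
      "rho_empirical_genotypic", "rho_theoretical", "rho_oracle", "rho_pld",
      "effective_dimension", "Ne_hat", "Me1", "Me2", "Me3", "M_LJ",
      "rho_me1", "rho_me2", "rho_me3", "rho_mlj"),
    names(rows))
  ok <- dplyr::filter(rows, !.data$failed)
  dplyr::summarise(
    dplyr::group_by(ok, .data$architecture, .data$scenario, .data$n_markers,
                    .data$n_generations, .data$n_trn),
    n_replicates = dplyr::n(),
    dplyr::across(dplyr::all_of(metric_cols),
                  list(mean = mean, var = stats::var)),
    .groups = "drop")
}

#' Proxy mean-squared-error table
#'
#' Compares each proxy's per-architecture mean against the mean empirical
#' accuracy over the same architectures, the headline benchmark of the
#' proxy comparison.
#'
#' @param summary_tbl Output of [summarize_runs()] with proxies computed.
#' @return A tibble with columns `method` and `mse`, sorted ascending.
#' @export
proxy_mse_table <- function(summary_tbl) {
  methods <- c(theoretical = "rho_theoretical_mean",
               new_proxy = "rho_pld_mean",
               me1 = "rho_me1_mean", me2 = "rho_me2_mean",
               me3 = "rho_me3_mean", mlj = "rho_mlj_mean")
  methods <- methods[methods %in% names(summary_tbl)]
  emp <- summary_tbl$rho_empirical_mean
  out <- tibble::tibble(
    method = names(methods),
    mse = vapply(methods, function(col) proxy_mse(summary_tbl[[col]], emp),
                 numeric(1))
  )
  dplyr::arrange(out, .data$mse)
}

#' Read an experiment configuration file
#'
#' YAML file with fields `architectures` (list of entries with `n_markers`,
#' `n_generations`, `qtl_scenario`, `n_trn`), plus optional `n_replicates`,
#' `lambda_route`, `trn_matrix_mode` (`vary`/`fixed`), `qtl_in_markers`,
#' `tst_extra_generations`, `master_seed`.
#'
#' @param path Path to the YAML file.
#' @return A list with `architectures` (list of `gs_arch`) and the scalar
#'   settings, defaults filled in.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(length(cfg$architectures) >= 1)
  archs <- lapply(cfg$architectures, function(a) {
    gs_architecture(a$n_markers, a$n_generations, a$qtl_scenario,
                    n_trn = a$n_trn %||% 500, n_tst = a$n_tst %||% 100)
  })
  list(architectures = archs,
       n_replicates = cfg$n_replicates %||% 100L,
       lambda_route = cfg$lambda_route %||% "reml",
       trn_matrix_mode = cfg$trn_matrix_mode %||% "vary",
       qtl_in_markers = cfg$qtl_in_markers %||% "included",
       tst_extra_generations = cfg$tst_extra_generations %||% 0L,
       master_seed = cfg$master_seed %||% 1L)
}

#' Run a whole architecture grid
#'
#' Convenience driver looping [run_architecture()] (or [run_fixed_trn()])
#' over a list of architectures with per-architecture seed streams.
#'
#' @param architectures List of [gs_architecture()] objects.
#' @param n_replicates Replicates per architecture.
#' @param master_seed Master seed.
#' @param trn_matrix_mode `"vary"` or `"fixed"`.
#' @param ... Passed to the per-architecture runner.
#' @return Row-bound replicate tibble over all architectures.
#' @export
run_architecture_grid <- function(architectures, n_replicates = 100,
                                  master_seed = 1L,
                                  trn_matrix_mode = c("vary", "fixed"), ...) {
  trn_matrix_mode <- match.arg(trn_matrix_mode)
  runner <- if (trn_matrix_mode == "vary") run_architecture else run_fixed_trn
  dplyr::bind_rows(purrr::imap(architectures, function(a, i) {
    runner(a, n_replicates = n_replicates, master_seed = master_seed,
           stream = i, ...)
  }))
}
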