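test_that("architecture constructor enforces the coupled design sizes", {
  a <- gs_architecture(100, 30, "two_qtl", n_trn = 500)
  expect_equal(a$pop_size, 400L)
  expect_equal(a$n_fullsibs, 100L)
  expect_error(gs_architecture(100, 30, "two_qtl", n_trn = 499))
  b <- gs_architecture(100, 30, qtl_scenarios("mixture_b"), n_trn = 1000)
  expect_equal(b$pop_size, 800L)
  expect_equal(b$trait$name, "mixture_b")
})

test_that("replicates are bit-reproducible under a fixed seed", {
  a <- tiny_arch(n_markers = 100, n_generations = 8)
  r1 <- run_replicate(a, "h2", seed = 99)
  r2 <- run_replicate(a, "h2", seed = 99)
  expect_identical(r1, r2)
  r3 <- run_replicate(a, "h2", seed = 100)
  expect_false(identical(r3$rho_empirical, r1$rho_empirical))
})

test_that("derived seed streams do not collide across architectures", {
  s1 <- gsaccuracy:::derive_seeds(1L, 50, stream = 1L)
  s2 <- gsaccuracy:::derive_seeds(1L, 50, stream = 2L)
  expect_length(intersect(s1, s2), 0)
  expect_identical(s1, gsaccuracy:::derive_seeds(1L, 50, stream = 1L))
  expect_true(all(s1 > 0 & s1 < 2^31))
})

test_that("summaries recompute exactly from the replicate rows", {
  a <- tiny_arch(n_markers = 100, n_generations = 6)
  rows <- run_architecture(a, n_replicates = 4, master_seed = 2,
                           lambda_route = "h2")
  expect_equal(nrow(rows), 4L)
  expect_false(any(rows$failed))
  s <- summarize_runs(rows)
  expect_equal(nrow(s), 1L)
  expect_equal(s$rho_empirical_mean, mean(rows$rho_empirical))
  expect_equal(s$h2_hat_var, var(rows$h2_hat))
  expect_equal(s$n_replicates, 4L)
})

test_that("fixed-TRN mode keeps the training design constant across replicates", {
  a <- tiny_arch(n_markers = 100, n_generations = 8)
  rows <- run_fixed_trn(a, n_replicates = 4, master_seed = 7,
                        lambda_route = "h2")
  # same filtered panel every replicate; phenotype-driven quantities vary
  expect_equal(length(unique(rows$n_markers_kept)), 1L)
  expect_gt(length(unique(rows$h2_hat)), 1L)
  expect_gt(length(unique(rows$rho_theoretical)), 1L)
  rows2 <- run_fixed_trn(a, n_replicates = 4, master_seed = 7,
                         lambda_route = "h2")
  expect_identical(rows$rho_theoretical, rows2$rho_theoretical)
})

test_that("test sets evolved further increase the effective dimension", {
  a <- tiny_arch(n_markers = 100, n_generations = 15)
  base <- run_fixed_trn(a, n_replicates = 6, master_seed = 11,
                        lambda_route = "h2")
  far <- run_fixed_trn(a, n_replicates = 6, master_seed = 11,
                       lambda_route = "h2", tst_extra_generations = 25)
  expect_gt(mean(far$effective_dimension), mean(base$effective_dimension))
})

test_that("heritability declines with generations for the polygenic scenario", {
  early <- run_architecture(gs_architecture(100, 10, "hundred_qtl"),
                            n_replicates = 6, master_seed = 4,
                            lambda_route = "h2")
  late <- run_architecture(gs_architecture(100, 40, "hundred_qtl"),
                           n_replicates = 6, master_seed = 4,
                           lambda_route = "h2")
  expect_gt(mean(early$h2_hat), mean(late$h2_hat))
})

test_that("the two lambda routes give closely agreeing theoretical accuracy", {
  a <- tiny_arch(n_markers = 100, n_generations = 10)
  reml <- run_architecture(a, n_replicates = 6, master_seed = 8,
                           lambda_route = "reml")
  h2 <- run_architecture(a, n_replicates = 6, master_seed = 8,
                         lambda_route = "h2")
  # paired replicates (same seeds) so the comparison is variance-reduced
  expect_lt(abs(mean(reml$rho_theoretical) - mean(h2$rho_theoretical)), 0.03)
  mis <- run_architecture(a, n_replicates = 6, master_seed = 8,
                          lambda_route = "h2_mis")
  expect_lt(abs(mean(mis$rho_theoretical) - mean(h2$rho_theoretical)), 0.03)
})

test_that("removing causal markers lowers accuracy on sparse panels", {
  a <- tiny_arch(n_markers = 100, n_generations = 12)
  incl <- run_architecture(a, n_replicates = 6, master_seed = 14,
                           lambda_route = "h2")
  rem <- run_architecture(a, n_replicates = 6, master_seed = 14,
                          lambda_route = "h2", qtl_in_markers = "removed")
  expect_gt(mean(incl$rho_theoretical), mean(rem$rho_theoretical))
  # causal columns really left the panel
  expect_equal(unique(incl$n_markers_kept - rem$n_markers_kept), 2L)
})

test_that("accuracy grows with the training-set size", {
  small <- run_architecture(tiny_arch(100, 10, n_trn = 500),
                            n_replicates = 6, master_seed = 16,
                            lambda_route = "h2")
  large <- run_architecture(tiny_arch(100, 10, n_trn = 1000),
                            n_replicates = 6, master_seed = 16,
                            lambda_route = "h2")
  se <- sd(small$rho_theoretical) / sqrt(6)
  expect_gte(mean(large$rho_theoretical),
             mean(small$rho_theoretical) - 2 * se)
})

test_that("experiment configuration round-trips through YAML", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_replicates: 7",
    "lambda_route: h2",
    "trn_matrix_mode: fixed",
    "master_seed: 42",
    "architectures:",
    "  - n_markers: 100",
    "    n_generations: 30",
    "    qtl_scenario: two_qtl",
    "    n_trn: 500",
    "  - n_markers: 1000",
    "    n_generations: 50",
    "    qtl_scenario: mixture_c",
    "    n_trn: 1000"
  ), cfg_path)
  cfg <- read_experiment_config(cfg_path)
  expect_length(cfg$architectures, 2)
  expect_equal(cfg$n_replicates, 7)
  expect_equal(cfg$architectures[[2]]$n_trn, 1000L)
  expect_equal(cfg$architectures[[2]]$trait$name, "mixture_c")
  expect_equal(cfg$trn_matrix_mode, "fixed")
})

test_that("plot helpers return ggplot objects", {
  a <- tiny_arch(n_markers = 100, n_generations = 6)
  rows <- run_architecture(a, n_replicates = 3, master_seed = 2,
                           lambda_route = "h2", compute_proxies = TRUE)
  s <- summarize_runs(rows)
  expect_s3_class(plot_accuracy_comparison(s), "ggplot")
  expect_s3_class(plot_proxy_comparison(s), "ggplot")
})
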