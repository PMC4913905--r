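# ggplot2 views of the benchmark tables. Convenience surface: every plot is
# a straightforward mapping of a summarize_runs() tibble.

#' Empirical versus theoretical accuracy, one point per architecture
#'
#' @param summary_tbl Output of [summarize_runs()].
#' @return A ggplot.
#' @export
plot_accuracy_comparison <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = .data$rho_empirical_mean,
                               y = .data$rho_theoretical_mean,
                               colour = .data$scenario,
                               shape = factor(.data$n_trn))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "Empirical accuracy", y = "Theoretical accuracy",
                  colour = "Scenario", shape = "n_TRN") +
    ggplot2::theme_minimal()
}

#' Proxy values against empirical accuracy
#'
#' @param summary_tbl Output of [summarize_runs()] with proxies computed.
#' @return A ggplot with one panel-free layer per proxy.
#' @export
plot_proxy_comparison <- function(summary_tbl) {
  proxy_cols <- intersect(
    c("rho_theoretical_mean", "rho_pld_mean", "rho_me1_mean",
      "rho_me2_mean", "rho_me3_mean", "rho_mlj_mean"),
    names(summary_tbl))
  long <- tidyr_pivot(summary_tbl, proxy_cols)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rho_empirical_mean,
                                     y = .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Empirical accuracy", y = "Proxy value",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

# small local reshape to avoid importing tidyr for one call
tidyr_pivot <- function(tbl, cols) {
  dplyr::bind_rows(lapply(cols, function(cl) {
    tibble::tibble(rho_empirical_mean = tbl$rho_empirical_mean,
                   method = sub("_mean$", "", cl),
                   value = tbl[[cl]])
  }))
}
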