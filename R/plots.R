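# Plotting helpers for the experiment drivers (requires ggplot2).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}

#' Plot posterior s.d. of d against training sample size
#'
#' One line per polygenicity value, on a log-10 x axis — the standard view
#' of how uncertainty in the relative-risk estimate decays with GWAS
#' training size.
#'
#' @param result Data frame from [run_sd_experiment()].
#' @return A ggplot object.
#' @export
plot_sd_experiment <- function(result) {
  need_ggplot()
  ggplot2::ggplot(result,
                  ggplot2::aes(x = .data$n_eff, y = .data$sd_d,
                               colour = factor(.data$p_causal))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "training sample size N", y = "posterior s.d.(d)",
                  colour = "p_causal") +
    ggplot2::theme_minimal()
}

#' Plot rejection rates from a frequentist experiment
#'
#' For null grids (`rr = 1`) this shows type-1 error for the Wald and t
#' tests with a horizontal reference at the nominal size; for power grids it
#' shows Wald power per relative risk.
#'
#' @param result Data frame from [run_frequentist_experiment()].
#' @param alpha Nominal size drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_rejection_rates <- function(result, alpha = 0.05) {
  need_ggplot()
  is_null <- all(result$rr == 1)
  if (is_null) {
    long <- rbind(
      data.frame(result[c("p_causal", "n_eff")], test = "wald",
                 reject = result$wald_reject),
      data.frame(result[c("p_causal", "n_eff")], test = "t_test",
                 reject = result$t_reject)
    )
    ggplot2::ggplot(long,
                    ggplot2::aes(x = .data$n_eff, y = .data$reject,
                                 colour = .data$test,
                                 linetype = factor(.data$p_causal))) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = alpha, colour = "grey50") +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "training sample size N", y = "type-1 error",
                    linetype = "p_causal") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(result,
                    ggplot2::aes(x = .data$n_eff, y = .data$wald_reject,
                                 colour = factor(.data$rr),
                                 linetype = factor(.data$p_causal))) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "training sample size N", y = "power",
                    colour = "relative risk", linetype = "p_causal") +
      ggplot2::theme_minimal()
  }
}

#' Plot the bias-variance decomposition of the estimator of d
#'
#' Squared bias, sampling variance and MSE of the posterior-mean estimator
#' against training sample size.
#'
#' @param result Data frame from [run_frequentist_experiment()].
#' @return A ggplot object.
#' @export
plot_bias_mse <- function(result) {
  need_ggplot()
  long <- rbind(
    data.frame(result[c("p_causal", "n_eff")], metric = "bias^2",
               value = result$bias^2),
    data.frame(result[c("p_causal", "n_eff")], metric = "sampling variance",
               value = result$sampling_var),
    data.frame(result[c("p_causal", "n_eff")], metric = "MSE",
               value = result$mse)
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$n_eff, y = .data$value,
                               colour = .data$metric,
                               linetype = factor(.data$p_causal))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "training sample size N", y = NULL,
                  linetype = "p_causal") +
    ggplot2::theme_minimal()
}
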