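#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.scmtf_solution <- function(x, ...) {
  cat("sCMTF solution: R =", ncol(x$S), "sources, K =",
      nrow(x$basis$waveforms), "HRF basis functions, Q =", ncol(x$N),
      "nuisance components\n")
  cat(sprintf("  cost J = %.6g | EEG rel. error %.3f | fMRI rel. error %.3f\n",
              x$cost, x$relerr_x, x$relerr_y))
  cat("  amplitudes lambda_x:", signif(x$lambda_x, 3), "\n")
  cat("  amplitudes lambda_y:", signif(x$lambda_y, 3), "\n")
  if (!x$converged) cat("  (not converged)\n")
  invisible(x)
}

#' @export
print.scmtf_fit <- function(x, ...) {
  cat("sCMTF fit: R =", x$config$R, "|", length(x$solutions),
      "solution(s) from", x$config$n_inits, "initialization(s)\n")
  cat("  best cost:", signif(x$solutions[[1L]]$cost, 6), "\n")
  invisible(x)
}

#' @export
print.snpm_result <- function(x, ...) {
  cat("SnPM (", x$statistic, ", ", x$n_surrogates, " surrogates, alpha = ",
      x$alpha, ", ", x$tail, " tails)\n", sep = "")
  for (r in seq_len(nrow(x$t))) {
    cat(sprintf("  source %d: %d activated, %d deactivated of %d ROIs\n",
                r, sum(x$act_mask[r, ]), sum(x$deact_mask[r, ]), ncol(x$t)))
  }
  invisible(x)
}

#' @export
print.hrf_variability_map <- function(x, ...) {
  cat("HRF variability over", nrow(x$table), "ROIs (top", x$k, "flagged)\n")
  if (!is.null(x$enrichment)) print(x$enrichment)
  invisible(x)
}

#' @export
print.scmtf_report <- function(x, ...) {
  cat("sCMTF pipeline report\n")
  cat("  selected rank:", x$selected_R, "\n")
  cat(sprintf("  IED component: %d (r = %.3f with the EEG envelope)\n",
              x$ied$index, x$ied$correlation))
  print(x$mask_summary)
  if (!is.null(x$hrf_variability$enrichment)) {
    print(x$hrf_variability$enrichment)
  }
  invisible(x)
}

#' Tidy an sCMTF solution into a per-source tibble
#'
#' @param x an `scmtf_solution`.
#' @param ... unused.
#' @return tibble with one row per source: amplitudes in both modalities
#'   and convergence info.
#' @export
tidy.scmtf_solution <- function(x, ...) {
  tibble::tibble(source = seq_along(x$lambda_x),
                 lambda_x = x$lambda_x, lambda_y = x$lambda_y)
}

#' @export
glance.scmtf_solution <- function(x, ...) {
  tibble::tibble(R = ncol(x$S), K = nrow(x$basis$waveforms),
                 Q = ncol(x$N), cost = x$cost, relerr_x = x$relerr_x,
                 relerr_y = x$relerr_y, converged = x$converged,
                 calibrated = x$calibrated, degenerate = x$degenerate)
}

#' Tidy an SnPM result into a long per-ROI tibble
#'
#' @param x an `snpm_result`.
#' @param ... unused.
#' @export
tidy.snpm_result <- function(x, ...) {
  R <- nrow(x$t); Iv <- ncol(x$t)
  tibble::tibble(
    source = rep(seq_len(R), each = Iv),
    roi = rep(seq_len(Iv), R),
    t = as.numeric(t(x$t)),
    v = as.numeric(t(x$v)),
    thresh_hi = rep(x$thresh_hi, each = Iv),
    thresh_lo = rep(x$thresh_lo, each = Iv),
    activated = as.logical(t(x$act_mask)),
    deactivated = as.logical(t(x$deact_mask)))
}

#' @export
tidy.hrf_variability_map <- function(x, ...) x$table

#' @export
glance.scmtf_report <- function(x, ...) {
  tibble::tibble(selected_R = x$selected_R, ied_component = x$ied$index,
                 ied_correlation = x$ied$correlation,
                 n_activated = sum(x$snpm$act_mask[x$ied$index, ]),
                 n_deactivated = sum(x$snpm$deact_mask[x$ied$index, ]))
}

#' Plot the observed statistic map of an SnPM result
#'
#' Per-ROI statistic with the familywise thresholds per source.
#'
#' @param object an `snpm_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.snpm_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi, y = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$activated |
                                       .data$deactivated)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$thresh_hi),
                        linetype = "dashed") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$thresh_lo),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~source, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "ROI", y = object$statistic, colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot the temporal signatures of a solution
#'
#' @param object an `scmtf_solution`.
#' @param ... unused.
#' @export
autoplot.scmtf_solution <- function(object, ...) {
  S <- object$S
  df <- tibble::tibble(
    time = rep(seq_len(nrow(S)), ncol(S)),
    source = rep(seq_len(ncol(S)), each = nrow(S)),
    value = as.numeric(S))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~source, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "volume", y = "temporal signature") +
    ggplot2::theme_minimal()
}

#' Plot per-ROI HRF waveforms
#'
#' @param sol an `scmtf_solution`.
#' @param highlight optional logical/integer ROI subset drawn in colour.
#' @return a ggplot.
#' @export
plot_hrfs <- function(sol, highlight = NULL) {
  H <- roi_hrfs(sol)
  lags <- sol$basis$grid$lags
  df <- tibble::tibble(
    lag = rep(lags, each = nrow(H)),
    roi = rep(seq_len(nrow(H)), length(lags)),
    value = as.numeric(H))
  hl <- rep(FALSE, nrow(H))
  if (!is.null(highlight)) hl[highlight] <- TRUE
  df$highlight <- hl[df$roi]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$value,
                                   group = .data$roi,
                                   colour = .data$highlight)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c("grey40", "firebrick")) +
    ggplot2::labs(x = "lag (s)", y = "HRF", colour = "highlighted") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
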