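#' Plot a ROC curve
#'
#' FAR against FRR over the swept thresholds, log-scaled FAR axis —
#' the standard biometric verification view.
#'
#' @param result a `verification_result` from [compute_eer()], or a
#'   named list of them for overlayed comparison.
#' @return a ggplot object.
#' @export
plot_roc <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    vp_stop("invalid_input", "plotting needs the ggplot2 package")
  }
  if (inherits(result, "verification_result")) result <- list(matcher = result)
  df <- do.call(rbind, lapply(names(result), function(nm) {
    cbind(result[[nm]]$roc, matcher = nm)
  }))
  df <- df[df$far > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = far, y = frr, color = matcher)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "false acceptance rate", y = "false rejection rate") +
    ggplot2::theme_minimal()
}

#' Plot a cumulative match characteristic curve
#'
#' Cumulative recognition rate by rank for one or more identification
#' results.
#'
#' @param result an `identification_result`, or a named list of them.
#' @param max_rank truncate the rank axis (default: full).
#' @return a ggplot object.
#' @export
plot_cmc <- function(result, max_rank = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    vp_stop("invalid_input", "plotting needs the ggplot2 package")
  }
  if (inherits(result, "identification_result")) result <- list(matcher = result)
  df <- do.call(rbind, lapply(names(result), function(nm) {
    cmc <- result[[nm]]$cmc
    data.frame(rank = seq_along(cmc), rate = cmc, matcher = nm)
  }))
  if (!is.null(max_rank)) df <- df[df$rank <= max_rank, ]
  ggplot2::ggplot(df, ggplot2::aes(x = rank, y = rate, color = matcher)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "rank", y = "cumulative recognition rate") +
    ggplot2::theme_minimal()
}
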