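# Report rendering: selection-frequency bars, per-feature nonzero
# coefficient distributions, and the elimination overview (VIMP bars +
# AUROC boxes + cutoff line).

#' Selection-frequency bar plot
#'
#' Bars of how often each feature had a nonzero coefficient across the
#' ensemble; only features selected at least once are shown.
#'
#' @param result A `sivs_result`.
#' @param top_n Show at most this many features (highest frequency first).
#' @return A ggplot object.
#' @export
plot_selection_frequency <- function(result, top_n = 50) {
  tab <- result$vimp_table
  d <- tab[tab$count > 0, c("feature", "count")]
  d <- d[order(-d$count, d$feature), ][seq_len(min(top_n, nrow(d))), ]
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "runs with nonzero coefficient", y = NULL,
                  title = "Selection frequency across ensemble runs") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Per-feature nonzero-coefficient distributions
#'
#' Box summaries of each feature's nonzero coefficients across the
#' ensemble, ordered by their median from high to low.
#'
#' @inheritParams plot_selection_frequency
#' @return A ggplot object.
#' @export
plot_coefficient_distributions <- function(result, top_n = 50) {
  nz <- attr(result$vimp_table, "nonzero_coefs")
  nz <- nz[vapply(nz, length, integer(1)) > 0]
  med <- vapply(nz, median, numeric(1))
  ord <- names(sort(med, decreasing = TRUE))
  ord <- ord[seq_len(min(top_n, length(ord)))]
  d <- data.frame(
    feature = factor(rep(ord, vapply(nz[ord], length, integer(1))),
                     levels = ord),
    coefficient = unlist(nz[ord], use.names = FALSE))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$coefficient)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "nonzero coefficient",
                  title = "Nonzero-coefficient distributions (median-ordered)") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Elimination overview plot
#'
#' For each elimination step: the VIMP of the feature removed at that step
#' (bars, log-ready scale) and the distribution of ensemble AUROCs after
#' the removal (boxes), with horizontal lines at the suggested cutoff.
#'
#' @param result A `sivs_result` containing an elimination trace.
#' @param gammas Strictness values whose cutoffs are drawn.
#' @return A ggplot object.
#' @export
plot_rfe <- function(result, gammas = c(0.01, 0.05)) {
  trace <- result$rfe_trace
  if (is.null(trace))
    sivs_stop("result has no elimination trace", class = "sivsel_data_error")
  steps <- trace$steps
  lab <- vapply(steps, function(s)
    if (is.na(s$removed_feature)) "(none)" else s$removed_feature,
    character(1))
  d <- do.call(rbind, lapply(seq_along(steps), function(i)
    data.frame(step = steps[[i]]$step, removed = lab[i],
               auroc = steps[[i]]$auroc_samples)))
  d$removed <- factor(d$removed, levels = lab)
  vt <- result$vimp_table
  vd <- data.frame(step = vapply(steps, `[[`, numeric(1), "step"),
                   removed = factor(lab, levels = lab),
                   vimp = vt$vimp[match(lab, vt$feature)])
  vd$vimp[is.na(vd$vimp)] <- 0
  vmax <- max(vd$vimp, 1e-9)
  cuts <- data.frame(gamma = gammas,
                     cutoff = vapply(gammas, function(g)
                       suggest_cutoff(trace, g)$cutoff, numeric(1)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$removed, y = .data$auroc)) +
    ggplot2::geom_col(data = vd,
                      ggplot2::aes(y = .data$vimp / vmax),
                      fill = "grey80", width = 0.7) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "lightsteelblue") +
    ggplot2::geom_hline(data = cuts,
                        ggplot2::aes(yintercept = .data$cutoff),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "feature removed (increasing VIMP scaled to bars)",
                  y = "training AUROC after removal",
                  title = "Recursive elimination overview") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Render a report directory for a result
#'
#' Writes the elimination overview, the selection-frequency plot, the
#' coefficient-distribution plot (PDF) and a plain-text summary listing
#' the selected features in VIMP-descending order.
#'
#' @param result A `sivs_result` containing an elimination trace.
#' @param outdir Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
render_report <- function(result, outdir) {
  stopifnot(inherits(result, "sivs_result"))
  if (is.null(result$rfe_trace))
    sivs_stop("result has no elimination trace; nothing to render",
              class = "sivsel_data_error")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(outdir, c("rfe_overview.pdf", "selection_frequency.pdf",
                               "coefficient_distributions.pdf",
                               "summary.txt"))
  ggplot2::ggsave(files[1], plot_rfe(result), width = 8, height = 5)
  ggplot2::ggsave(files[2], plot_selection_frequency(result),
                  width = 6, height = 7)
  ggplot2::ggsave(files[3], plot_coefficient_distributions(result),
                  width = 8, height = 5)
  vt <- result$vimp_table
  sel <- vt[vt$feature %in% result$selected_features, ]
  sel <- sel[order(-sel$vimp, -sel$count, sel$feature), ]
  lines <- c("stable feature selection summary",
             sprintf("status: %s", result$status),
             sprintf("iterations: %d | elimination repeats: %d | folds: %d",
                     result$config$iterations, result$config$rfe_repeats,
                     result$config$cv_folds),
             if (!is.null(result$cutoff))
               sprintf("gamma: %g | AUROC cutoff: %.4f (range %.4f-%.4f)",
                       result$cutoff$gamma, result$cutoff$cutoff,
                       result$cutoff$x_min, result$cutoff$x_max),
             sprintf("selected features (%d), VIMP-descending:", nrow(sel)),
             sprintf("  %-24s vimp=%-10.4g count=%-4d mabs=%.4g",
                     sel$feature, sel$vimp, sel$count, sel$mabs))
  writeLines(lines, files[4])
  files
}

#' @importFrom ggplot2 .data
NULL
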