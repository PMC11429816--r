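#' Normalized histogram over fixed bin edges
#'
#' Counts are divided by the total number of in-range values, so the bins
#' sum to 1; out-of-range values are counted separately, not silently
#' dropped into edge bins.
#'
#' @param values Numeric vector (NAs are removed).
#' @param bin_edges Strictly increasing numeric vector of edges; bins are
#'   left-open, right-closed except the first, which includes its left edge
#'   (the [cut()] convention with `include.lowest`).
#' @return List of class `normalized_histogram`: `counts`, `proportions`,
#'   `edges`, `n`, `n_out`.
#' @examples
#' normalized_histogram(c(1, 1, 2), c(0.5, 1.5, 2.5))$proportions  # 2/3, 1/3
#' @export
normalized_histogram <- function(values, bin_edges) {
  values <- values[is.finite(values)]
  if (!length(values))
    stop("normalized_histogram: no finite values", call. = FALSE)
  if (any(diff(bin_edges) <= 0))
    stop("normalized_histogram: bin edges must be strictly increasing", call. = FALSE)
  inside <- values >= bin_edges[1] & values <= bin_edges[length(bin_edges)]
  counts <- as.vector(table(cut(values[inside], bin_edges, include.lowest = TRUE)))
  n <- sum(counts)
  structure(list(counts = counts,
                 proportions = if (n > 0) counts / n else counts,
                 edges = bin_edges, n = n, n_out = sum(!inside)),
            class = "normalized_histogram")
}

# Freedman-Diaconis edges on the pooled sample (shared across groups).
fd_bin_edges <- function(values, min_bins = 5L) {
  values <- values[is.finite(values)]
  nb <- max(min_bins, grDevices::nclass.FD(values))
  r <- range(values)
  if (diff(r) == 0) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = nb + 1L)
}

#' Single-feature ROC curve and AUC
#'
#' The implicit classifier calls a sample positive when its descriptor value
#' exceeds a threshold; sweeping the threshold over all distinct observed
#' values traces the ROC curve from (0, 0) to (1, 1). The area under the
#' curve is computed by the trapezoid rule and equals the Mann--Whitney
#' probability `P(X_pos > X_neg) + P(X_pos = X_neg) / 2`: 0.5 is the
#' no-discrimination (random classifier) reference, 1.0 perfect separation.
#'
#' @param values_neg,values_pos Descriptor values for the negative (control)
#'   and positive (treated) group; NAs are dropped.
#' @param name Optional descriptor name carried in the result.
#' @return Object of class `roc_curve`: `descriptor`, `thresholds`, `fpr`,
#'   `tpr`, `auc`, `n_neg`, `n_pos`.
#' @examples
#' roc_curve(c(1, 2, 3), c(4, 5, 6))$auc   # 1
#' roc_curve(c(1, 3), c(2, 4))$auc         # 0.75
#' @export
roc_curve <- function(values_neg, values_pos, name = NA_character_) {
  values_neg <- values_neg[!is.na(values_neg)]
  values_pos <- values_pos[!is.na(values_pos)]
  if (!length(values_neg) || !length(values_pos))
    stop("roc_curve: a group is empty after dropping missing values",
         if (!is.na(name)) paste0(" (", name, ")"), call. = FALSE)
  thr <- c(Inf, sort(unique(c(values_neg, values_pos)), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(s) mean(values_pos > s), 0)
  fpr <- vapply(thr, function(s) mean(values_neg > s), 0)
  # thr = Inf anchors (0, 0); thr = -Inf anchors (1, 1)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(descriptor = name, thresholds = thr, fpr = fpr, tpr = tpr,
                 auc = auc, n_neg = length(values_neg),
                 n_pos = length(values_pos)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %s: AUC = %.4f (n_neg = %d, n_pos = %d)\n",
              if (is.na(x$descriptor)) "feature" else x$descriptor,
              x$auc, x$n_neg, x$n_pos))
  invisible(x)
}

#' Two-group separability report over all kinematic descriptors
#'
#' For each descriptor column shared by the two tables, builds the
#' normalized histogram pair (Freedman--Diaconis edges on the pooled
#' sample, shared between groups) and the single-feature ROC curve with the
#' treated group as the positive class, and reports the separability index
#' `|AUC - 0.5|` against the random-classifier reference AUC of 0.5.
#'
#' @param descriptors_ctrl,descriptors_treated Descriptor tables
#'   ([summarize_tracks()] output or CSV re-read).
#' @param descriptors Columns to compare; defaults to the four kinematic
#'   descriptors.
#' @return Object of class `separability_report`: per-descriptor list with
#'   `roc`, `hist_ctrl`, `hist_treated`, `separability`; plus `n_ctrl`,
#'   `n_treated`, `reference_auc = 0.5`.
#' @export
compare_groups <- function(descriptors_ctrl, descriptors_treated,
                           descriptors = c("mean_speed_um_min",
                                           "mean_curvature_per_um",
                                           "mean_turning_angle_rad",
                                           "diffusion_um2_min")) {
  if (!nrow(descriptors_ctrl) || !nrow(descriptors_treated))
    stop("compare_groups: both descriptor tables must be non-empty", call. = FALSE)
  missing_cols <- setdiff(descriptors,
                          intersect(names(descriptors_ctrl),
                                    names(descriptors_treated)))
  if (length(missing_cols))
    stop("compare_groups: descriptor columns missing from input: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  per <- lapply(descriptors, function(d) {
    vn <- descriptors_ctrl[[d]]
    vp <- descriptors_treated[[d]]
    pooled <- c(vn, vp)
    if (all(is.na(pooled)))
      stop("compare_groups: descriptor '", d, "' is entirely missing", call. = FALSE)
    edges <- fd_bin_edges(pooled)
    roc <- roc_curve(vn, vp, name = d)
    list(roc = roc,
         hist_ctrl = normalized_histogram(vn, edges),
         hist_treated = normalized_histogram(vp, edges),
         separability = abs(roc$auc - 0.5))
  })
  names(per) <- descriptors
  structure(list(descriptors = per,
                 n_ctrl = nrow(descriptors_ctrl),
                 n_treated = nrow(descriptors_treated),
                 reference_auc = 0.5),
            class = "separability_report")
}

#' @export
print.separability_report <- function(x, ...) {
  cat(sprintf("<separability_report> %d control vs %d treated tracks\n",
              x$n_ctrl, x$n_treated))
  for (d in names(x$descriptors))
    cat(sprintf("  %-24s AUC = %.4f  |AUC - 0.5| = %.4f\n", d,
                x$descriptors[[d]]$roc$auc, x$descriptors[[d]]$separability))
  invisible(x)
}

#' Summarize a separability report as a data frame
#' @param report A `separability_report`.
#' @return Data frame with one row per descriptor: `descriptor`, `auc`,
#'   `separability`, `n_ctrl`, `n_treated`.
#' @export
separability_table <- function(report) {
  data.frame(descriptor = names(report$descriptors),
             auc = vapply(report$descriptors, function(d) d$roc$auc, 0),
             separability = vapply(report$descriptors,
                                   function(d) d$separability, 0),
             n_ctrl = report$n_ctrl, n_treated = report$n_treated,
             row.names = NULL)
}

#' Serialize a separability report to JSON
#' @param report A `separability_report`.
#' @param path Output path.
#' @export
write_separability_report <- function(report, path) {
  out <- list(n_ctrl = report$n_ctrl, n_treated = report$n_treated,
              reference_auc = report$reference_auc,
              descriptors = lapply(report$descriptors, function(d) {
                list(auc = d$roc$auc,
                     separability = d$separability,
                     fpr = d$roc$fpr, tpr = d$roc$tpr,
                     hist_edges = d$hist_ctrl$edges,
                     hist_ctrl = d$hist_ctrl$proportions,
                     hist_treated = d$hist_treated$proportions)
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot ROC curves of a separability report
#'
#' One panel per descriptor with the random-classifier diagonal as
#' reference.
#'
#' @param report A `separability_report`.
#' @return A ggplot object.
#' @export
plot_roc_curves <- function(report) {
  df <- do.call(rbind, lapply(names(report$descriptors), function(d) {
    r <- report$descriptors[[d]]$roc
    data.frame(descriptor = sprintf("%s (AUC = %.2f)", d, r$auc),
               fpr = r$fpr, tpr = r$tpr)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_step(color = "#2166ac") +
    ggplot2::facet_wrap(~descriptor) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "True positive rate (sensitivity)") +
    ggplot2::theme_bw()
}

#' Plot normalized descriptor histograms of a separability report
#'
#' @param report A `separability_report`.
#' @return A ggplot object.
#' @export
plot_histograms <- function(report) {
  df <- do.call(rbind, lapply(names(report$descriptors), function(d) {
    p <- report$descriptors[[d]]
    mid <- function(e) (e[-1] + e[-length(e)]) / 2
    rbind(data.frame(descriptor = d, group = "control",
                     mid = mid(p$hist_ctrl$edges),
                     proportion = p$hist_ctrl$proportions),
          data.frame(descriptor = d, group = "treated",
                     mid = mid(p$hist_treated$edges),
                     proportion = p$hist_treated$proportions))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$proportion,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "identity", alpha = 0.55) +
    ggplot2::facet_wrap(~descriptor, scales = "free") +
    ggplot2::labs(x = "descriptor value", y = "normalized frequency") +
    ggplot2::theme_bw()
}
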