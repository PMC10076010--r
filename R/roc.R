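check_binary_labels <- function(labels, positive) {
  labels <- as.vector(labels)
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("both classes must be present in the labels")
  pos
}

#' ROC curve points
#'
#' Sweeps thresholds over the unique scores in descending order, grouping
#' ties at a single threshold. Orientation is fixed by the declared positive
#' class with higher score = more positive by default (set
#' \code{flip = TRUE} for markers where lower scores indicate the positive
#' class); the curve is never auto-flipped to force AUC >= 0.5.
#'
#' @param scores numeric per-sample scores.
#' @param labels class labels.
#' @param positive the positive-class label (default: the larger of the two
#'   sorted unique labels).
#' @param flip if TRUE, lower scores indicate the positive class.
#' @return data.frame with columns fpr, tpr, threshold; starts at (0, 0)
#'   and ends at (1, 1).
#' @export
roc_points <- function(scores, labels,
                       positive = sort(unique(labels))[2], flip = FALSE) {
  pos <- check_binary_labels(labels, positive)
  if (flip) scores <- -scores
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  n1 <- sum(pos); n0 <- sum(!pos)
  # group tied scores at one threshold
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1),
             threshold = c(Inf, rle(s)$values) * if (flip) -1 else 1)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under \code{\link{roc_points}}; identical to the
#' Mann-Whitney statistic U/(n1*n0) with ties counted one half.
#'
#' @inheritParams roc_points
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels,
                    positive = sort(unique(labels))[2], flip = FALSE) {
  pts <- roc_points(scores, labels, positive = positive, flip = flip)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

# DeLong placement values: for each positive, the fraction of negatives it
# outscores (ties = 1/2), and symmetrically for negatives.
delong_placements <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yi) mean((x > yi) + 0.5 * (x == yi)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance of the AUC from placement values with a
#' normal-approximation interval, clipped to [0, 1]. Under perfect
#' separation the variance is zero and a degenerate interval at the point
#' AUC is returned with a warning.
#'
#' @inheritParams roc_points
#' @param level confidence level (default 0.95).
#' @return list with \code{auc}, \code{ci_low}, \code{ci_high},
#'   \code{se}.
#' @export
auc_ci <- function(scores, labels, level = 0.95,
                   positive = sort(unique(labels))[2], flip = FALSE) {
  pos <- check_binary_labels(labels, positive)
  sc <- if (flip) -scores else scores
  pl <- delong_placements(sc, pos)
  auc <- mean(pl$v10)
  s10 <- stats::var(pl$v10); s01 <- stats::var(pl$v01)
  v <- s10 / length(pl$v10) + s01 / length(pl$v01)
  if (v <= 0) {
    warning("zero DeLong variance (perfect separation); degenerate interval")
    return(list(auc = auc, ci_low = auc, ci_high = min(1, auc), se = 0))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = auc,
       ci_low = max(0, auc - z * sqrt(v)),
       ci_high = min(1, auc + z * sqrt(v)),
       se = sqrt(v))
}

#' Evaluate markers as diagnostic classifiers
#'
#' Builds ROC curves with AUC and DeLong confidence intervals for each
#' marker column of a per-sample score matrix (e.g. TMM-normalized
#' expression, or subpopulation proportions).
#'
#' @param score_matrix samples x markers numeric matrix.
#' @param labels per-sample class labels.
#' @param positive positive-class label.
#' @param level confidence level for the AUC interval.
#' @return a \code{roc_result} data.frame: marker, auc, ci_low, ci_high,
#'   n_pos, n_neg; attribute \code{curves} holds the per-marker
#'   \code{\link{roc_points}} data.frames.
#' @export
marker_roc <- function(score_matrix, labels,
                       positive = sort(unique(labels))[2], level = 0.95) {
  score_matrix <- as.matrix(score_matrix)
  pos <- check_binary_labels(labels, positive)
  markers <- colnames(score_matrix) %||%
    as.character(seq_len(ncol(score_matrix)))
  curves <- list()
  rows <- lapply(seq_len(ncol(score_matrix)), function(j) {
    s <- score_matrix[, j]
    ci <- suppressWarnings(auc_ci(s, labels, level = level,
                                  positive = positive))
    curves[[markers[j]]] <<- roc_points(s, labels, positive = positive)
    data.frame(marker = markers[j], auc = ci$auc, ci_low = ci$ci_low,
               ci_high = ci$ci_high, n_pos = sum(pos), n_neg = sum(!pos),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  attr(out, "positive") <- positive
  class(out) <- c("roc_result", "data.frame")
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC evaluation (positive class: %s)\n", attr(x, "positive")))
  df <- as.data.frame(x)
  df$auc <- sprintf("%.4f", df$auc)
  df$ci <- sprintf("%.4f-%.4f", x$ci_low, x$ci_high)
  print(df[order(-x$auc), c("marker", "auc", "ci", "n_pos", "n_neg")],
        row.names = FALSE)
  invisible(x)
}
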