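#' Per-sample protein totals
#'
#' Sums molecule counts over all exosomes of a sample, giving the sample's
#' bulk-style protein expression vector.
#'
#' @param matrix an \code{exo_matrix}.
#' @return named numeric vector of per-protein molecule totals.
#' @export
aggregate_counts <- function(matrix) {
  stopifnot(inherits(matrix, "exo_matrix"))
  v <- Matrix::colSums(matrix$counts)
  stats::setNames(as.numeric(v), colnames(matrix$counts))
}

#' Assemble a sample-by-protein expression table
#'
#' @param matrices named list of \code{exo_matrix} objects (names = sample
#'   ids), or a pre-built samples x proteins count matrix.
#' @param groups character/factor of group labels, one per sample.
#' @return an \code{expr_table}: list with \code{counts} (samples x
#'   proteins), \code{groups} (factor).
#' @export
expression_table <- function(matrices, groups) {
  if (is.list(matrices)) {
    counts <- do.call(rbind, lapply(matrices, aggregate_counts))
    rownames(counts) <- if (!is.null(names(matrices))) names(matrices)
      else vapply(matrices, `[[`, "", "sample_id")
  } else counts <- as.matrix(matrices)
  if (length(groups) != nrow(counts))
    stop("one group label per sample is required")
  structure(list(counts = counts, groups = factor(groups)),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat(sprintf("expr_table: %d samples x %d proteins; groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s (n=%d)", levels(x$groups),
                            table(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes per-sample scaling factors by the trimmed mean of M-values: the
#' reference sample is the one whose upper-quartile-to-total ratio is
#' closest to the mean of that statistic; for every sample, log2 ratios (M)
#' and average log2 abundances (A) versus the reference are formed over
#' proteins positive in both, doubly trimmed (30\% on M, 5\% on A by default),
#' and combined by an inverse-asymptotic-variance weighted mean. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param table an \code{expr_table} or samples x proteins count matrix.
#' @param logratio_trim two-sided trim fraction on M values (default 0.30).
#' @param sum_trim two-sided trim fraction on A values (default 0.05).
#' @return a \code{tmm_factors} object: numeric factors named by sample,
#'   with attributes \code{reference}, \code{logratio_trim}, \code{sum_trim}.
#' @export
tmm_factors <- function(table, logratio_trim = 0.30, sum_trim = 0.05) {
  counts <- if (inherits(table, "expr_table")) table$counts else as.matrix(table)
  if (nrow(counts) < 2L) stop("TMM needs at least 2 samples")
  lib <- rowSums(counts)
  if (any(lib <= 0)) stop("every sample must have a positive total count")

  f75 <- apply(counts, 1L, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  r <- counts[ref, ]
  lr <- lib[ref]

  f <- vapply(seq_len(nrow(counts)), function(s) {
    tmm_pair_factor(counts[s, ], r, lib[s], lr, logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(stats::setNames(f, rownames(counts)),
            reference = rownames(counts)[ref] %||% ref,
            logratio_trim = logratio_trim, sum_trim = sum_trim,
            class = "tmm_factors")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TMM factor of one observation vector against the reference vector
tmm_pair_factor <- function(x, r, lx, lr, logratio_trim, sum_trim) {
  keep <- x > 0 & r > 0
  if (!any(keep)) {
    warning("sample shares no positive protein with the reference; factor 1")
    return(1)
  }
  x <- x[keep]; r <- r[keep]
  M <- log2((x / lx) / (r / lr))
  A <- 0.5 * log2((x / lx) * (r / lr))
  w <- 1 / ((lx - x) / (lx * x) + (lr - r) / (lr * r))

  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  lf <- sum(w[keep2] * M[keep2]) / sum(w[keep2])
  if (!is.finite(lf) || abs(lf) < 1e-10) lf <- 0
  2^lf
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat(sprintf("TMM factors (reference: %s):\n", attr(x, "reference")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Apply normalization factors
#'
#' Scales counts to a counts-per-million-style unit using effective library
#' sizes: value(s, p) = counts(s, p) / (total(s) * f_s) * 1e6.
#'
#' @param table an \code{expr_table} or samples x proteins count matrix.
#' @param factors \code{tmm_factors} computed on the same table.
#' @return samples x proteins numeric matrix of normalized expression.
#' @export
normalize_expression <- function(table, factors) {
  counts <- if (inherits(table, "expr_table")) table$counts else as.matrix(table)
  eff <- rowSums(counts) * as.numeric(factors)
  sweep(counts, 1L, eff, "/") * 1e6
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment. Missing p-values are excluded from the family and
#' returned as NA.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Differential protein expression between two groups
#'
#' Implements a normality-routed testing scheme on normalized expression:
#' Shapiro-Wilk is applied per group; when both groups look normal at
#' \code{alpha_normality}, an F test on the variance ratio routes to the
#' Student t test (equal variances) or Welch's t test (unequal); when
#' normality is rejected in either group (or a group is constant, where
#' Shapiro-Wilk is undefined), the Wilcoxon rank-sum test is used (set
#' \code{nonnormal = "t"} to force the t/Welch route instead). P-values are
#' Benjamini-Hochberg adjusted over all proteins with a defined p.
#'
#' @param normalized samples x proteins matrix of normalized expression.
#' @param groups two-level factor, each level with n >= 3.
#' @param alpha_normality Shapiro-Wilk significance level (default 0.05).
#' @param alpha_var variance-ratio F-test level for t vs Welch routing.
#' @param nonnormal fallback test when normality fails: "wilcoxon" or "t".
#' @param pseudocount added to group means for fold changes (default 0.5).
#' @return data.frame (class \code{diff_result}) with columns protein,
#'   log2fc (second group level over first), test, p, q, significant
#'   (q < 0.05).
#' @export
diff_expression <- function(normalized, groups, alpha_normality = 0.05,
                            alpha_var = 0.05,
                            nonnormal = c("wilcoxon", "t"),
                            pseudocount = 0.5) {
  nonnormal <- match.arg(nonnormal)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (any(table(groups) < 3L)) stop("each group needs at least 3 samples")
  ga <- levels(groups)[1]; gb <- levels(groups)[2]

  res <- lapply(seq_len(ncol(normalized)), function(j) {
    x <- normalized[groups == ga, j]
    y <- normalized[groups == gb, j]
    ratio <- (mean(y) + pseudocount) / (mean(x) + pseudocount)
    l2fc <- if (is.finite(ratio) && ratio > 0) log2(ratio) else NA_real_
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(list(log2fc = l2fc, test = NA_character_, p = NA_real_))
    normal <- stats::sd(x) > 0 && stats::sd(y) > 0 &&
      stats::shapiro.test(x)$p.value > alpha_normality &&
      stats::shapiro.test(y)$p.value > alpha_normality
    if (normal) {
      equal_var <- stats::var.test(x, y)$p.value >= alpha_var
      tt <- stats::t.test(x, y, var.equal = equal_var)
      list(log2fc = l2fc, test = if (equal_var) "t" else "welch",
           p = tt$p.value)
    } else if (nonnormal == "wilcoxon") {
      list(log2fc = l2fc, test = "wilcoxon",
           p = stats::wilcox.test(x, y, exact = FALSE)$p.value)
    } else {
      equal_var <- stats::sd(x) > 0 && stats::sd(y) > 0 &&
        stats::var.test(x, y)$p.value >= alpha_var
      tt <- stats::t.test(x, y, var.equal = equal_var)
      list(log2fc = l2fc, test = if (equal_var) "t" else "welch",
           p = tt$p.value)
    }
  })
  out <- data.frame(
    protein = colnames(normalized) %||% as.character(seq_len(ncol(normalized))),
    log2fc = vapply(res, `[[`, 0, "log2fc"),
    test = vapply(res, `[[`, "", "test"),
    p = vapply(res, `[[`, 0, "p"),
    stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out$significant <- !is.na(out$q) & out$q < 0.05
  class(out) <- c("diff_result", "data.frame")
  attr(out, "comparison") <- paste(gb, "vs", ga)
  out
}

#' @export
print.diff_result <- function(x, n = 10L, ...) {
  cat(sprintf("Differential expression (%s): %d proteins, %d significant at q < 0.05\n",
              attr(x, "comparison"), nrow(x), sum(x$significant)))
  print.data.frame(utils::head(x[order(x$q), ], n), row.names = FALSE)
  invisible(x)
}
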