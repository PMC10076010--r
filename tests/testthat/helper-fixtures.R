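# Shared fixtures and independent oracles for the test suite.

# small panel with well-separated tags
tiny_panel <- function(n = 6L, len = 6L) {
  tags <- exopba:::generate_separated_tags(n, len, min_dist = 3L,
                                           seed = 1234L)
  pba_panel(paste0("AB", seq_len(n)), tags)
}

# write a FASTQ file from parallel sequence/quality character vectors
write_test_fastq <- function(seqs, quals, path = tempfile(fileext = ".fastq")) {
  stopifnot(length(seqs) == length(quals))
  lines <- character(4L * length(seqs))
  lines[seq(1, by = 4, length.out = length(seqs))] <-
    paste0("@read", seq_along(seqs))
  lines[seq(2, by = 4, length.out = length(seqs))] <- seqs
  lines[seq(3, by = 4, length.out = length(seqs))] <- "+"
  lines[seq(4, by = 4, length.out = length(seqs))] <- quals
  writeLines(lines, path)
  path
}

# Phred+33 quality string of a given integer score
qstr <- function(q, len) strrep(rawToChar(as.raw(q + 33L)), len)

# small two-group/one-cluster-contrast design used by several tests
tiny_design <- function(panel, n_exo = 300L, n_samples = c(3L, 3L, 3L),
                        ...) {
  d <- crc_cohort_design(panel = panel, exosomes_per_sample = n_exo, ...)
  d$groups$n_samples <- as.integer(n_samples)
  d
}

# --- independent oracles -------------------------------------------------

# TMM factors recomputed directly from the definition, scalar loops only
oracle_tmm <- function(counts, logratio_trim = 0.30, sum_trim = 0.05) {
  lib <- apply(counts, 1, sum)
  uq <- numeric(nrow(counts))
  for (s in seq_len(nrow(counts)))
    uq[s] <- as.numeric(stats::quantile(counts[s, ], 0.75)) / lib[s]
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(nrow(counts))
  for (s in seq_len(nrow(counts))) {
    M <- c(); A <- c(); w <- c()
    for (p in seq_len(ncol(counts))) {
      x <- counts[s, p]; r <- counts[ref, p]
      if (x > 0 && r > 0) {
        M <- c(M, log2((x / lib[s]) / (r / lib[ref])))
        A <- c(A, 0.5 * log2((x / lib[s]) * (r / lib[ref])))
        w <- c(w, 1 / ((lib[s] - x) / (lib[s] * x) +
                         (lib[ref] - r) / (lib[ref] * r)))
      }
    }
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    lf <- sum(w[keep] * M[keep]) / sum(w[keep])
    if (!is.finite(lf) || abs(lf) < 1e-10) lf <- 0
    f[s] <- 2^lf
  }
  f / exp(mean(log(f)))
}

# AUC by exhaustive positive/negative pair enumeration, ties counted 1/2
oracle_auc_pairs <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# directional UMI collapse recomputed from the adjacency definition:
# explicit O(n^2) absorption matrix, processed in (count desc, umi) order
oracle_directional <- function(umis, counts) {
  o <- order(-counts, umis)
  umis <- umis[o]; counts <- counts[o]
  n <- length(umis)
  hd <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    hd[i, j] <- sum(strsplit(umis[i], "")[[1]] != strsplit(umis[j], "")[[1]])
  taken <- rep(FALSE, n)
  roots <- 0L
  for (i in seq_len(n)) {
    if (taken[i]) next
    roots <- roots + 1L
    frontier <- i; taken[i] <- TRUE
    while (length(frontier)) {
      nxt <- c()
      for (u in frontier) for (v in seq_len(n))
        if (!taken[v] && hd[u, v] <= 1L && counts[u] >= 2L * counts[v] - 1L) {
          taken[v] <- TRUE; nxt <- c(nxt, v)
        }
      frontier <- nxt
    }
  }
  roots
}

# sorted (exosome, protein, count) triplet data.frame for matrix comparison
matrix_triplets <- function(counts) {
  tr <- Matrix::summary(methods::as(counts, "TsparseMatrix"))
  df <- data.frame(exosome = rownames(counts)[tr$i],
                   protein = colnames(counts)[tr$j],
                   count = tr$x, stringsAsFactors = FALSE)
  df[order(df$exosome, df$protein), , drop = FALSE]
}

# truth molecule table -> per-exosome-tag triplets via the emitted tag map
truth_triplets <- function(truth, tags, panel, sample) {
  mol <- truth$molecules[truth$molecules$sample_id == sample, ]
  tg <- tags[tags$sample_id == sample, ]
  agg <- stats::aggregate(list(count = rep(1L, nrow(mol))),
                          by = list(exosome = tg$exosome_tag[mol$exosome],
                                    protein = panel$antibody_name[mol$protein]),
                          FUN = sum)
  agg <- agg[order(agg$exosome, agg$protein), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
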