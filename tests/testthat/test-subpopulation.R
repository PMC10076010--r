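# build an exo_matrix directly from a dense count matrix
as_exo_matrix <- function(counts, sample_id = "s") {
  structure(list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                      "CsparseMatrix"),
                 sample_id = sample_id),
            class = "exo_matrix")
}

# noiseless planted fixture: k pure marker blocks, one protein pair per block
planted_block <- function(n_per_cluster, k = 3L, p_per_block = 2L,
                          sample_id = "s") {
  P <- k * p_per_block
  rows <- do.call(rbind, lapply(seq_len(k), function(cl) {
    prof <- rep(0L, P)
    prof[(cl - 1L) * p_per_block + seq_len(p_per_block)] <- 1L
    matrix(prof, nrow = n_per_cluster[cl], ncol = P, byrow = TRUE)
  }))
  colnames(rows) <- paste0("P", seq_len(P))
  rownames(rows) <- paste0("E", seq_len(nrow(rows)))
  list(matrix = as_exo_matrix(rows, sample_id),
       truth = rep(seq_len(k), n_per_cluster))
}

test_that("downsampling keeps n rows, is reproducible, and keeps small samples", {
  m <- planted_block(c(40, 40, 20))$matrix
  d1 <- downsample_exosomes(m, 30L, seed = 1L)
  expect_equal(nrow(d1$counts), 30L)
  expect_true(all(rownames(d1$counts) %in% rownames(m$counts)))
  d2 <- downsample_exosomes(m, 30L, seed = 1L)
  expect_identical(rownames(d1$counts), rownames(d2$counts))
  expect_equal(nrow(downsample_exosomes(m, 500L, seed = 1L)$counts), 100L)
})

test_that("binarization thresholds counts and is idempotent", {
  m <- as_exo_matrix(rbind(E1 = c(0, 2, 1), E2 = c(3, 0, 0)))
  b <- binarize_features(m)
  expect_equal(as.vector(b$features[1, ]), c(0, 1, 1))
  b2 <- binarize_features(list(structure(list(counts = b$features,
                                              sample_id = "s"),
                                         class = "exo_matrix")))
  expect_equal(as.matrix(b2$features), as.matrix(b$features))
  # row nonzero count equals the QC proteins-per-exosome numerator
  qc <- qc_metrics(10L, 10L, 10L, 10L, m)
  expect_equal(mean(Matrix::rowSums(b$features)),
               qc$mean_proteins_per_exosome)
})

test_that("SOM maps vectors to their brute-force nearest node", {
  set.seed(8)
  pb <- planted_block(c(60, 60, 60))
  block <- binarize_features(pb$matrix)
  som <- train_som(block, grid = c(3L, 3L), epochs = 5L, seed = 2L)
  X <- matrix(runif(50 * ncol(som$codebook)), nrow = 50)
  got <- exopba:::nearest_node(X, som$codebook)
  brute <- apply(X, 1L, function(x)
    which.min(colSums((t(som$codebook) - x)^2)))
  expect_equal(got, unname(brute))
})

test_that("SOM separates well-separated clouds and reduces quantization error", {
  set.seed(9)
  cloud1 <- matrix(rnorm(200 * 5, 0, 0.05), ncol = 5)
  cloud2 <- matrix(rnorm(200 * 5, 3, 0.05), ncol = 5)
  X <- Matrix::Matrix(rbind(cloud1, cloud2), sparse = TRUE)
  block <- structure(list(features = X,
                          sample_id = rep("s", 400),
                          exosome_tag = paste0("E", 1:400),
                          transform = "binary"),
                     class = "feature_block")
  som <- train_som(block, grid = c(2L, 2L), epochs = 8L, seed = 3L)
  bmu <- exopba:::nearest_node(X, som$codebook)
  truth <- rep(1:2, each = 200)
  mix <- vapply(unique(bmu), function(j)
    length(unique(truth[bmu == j])), integer(1))
  expect_true(all(mix == 1L))
  # training does not worsen the quantization error of the seeded init
  W0 <- exopba:::with_preserved_seed(3L,
    as.matrix(X[sample.int(nrow(X), 4L), , drop = FALSE]))
  expect_lte(exopba:::quantization_error(X, som$codebook),
             exopba:::quantization_error(X, W0) + 1e-12)
  expect_error(train_som(block, grid = c(30L, 30L), seed = 1L),
               "smaller grid")
})

test_that("consensus metaclustering recovers separated clouds at K = 2", {
  set.seed(10)
  codebook <- rbind(matrix(rnorm(10 * 4, 0, 0.05), ncol = 4),
                    matrix(rnorm(10 * 4, 5, 0.05), ncol = 4))
  model <- metacluster_consensus(codebook, K = 2L, reps = 50L, seed = 4L,
                                 normalize_rows = FALSE)
  expect_equal(length(unique(model$node_cluster[1:10])), 1L)
  expect_equal(length(unique(model$node_cluster[11:20])), 1L)
  expect_false(model$node_cluster[1] == model$node_cluster[11])
  # consensus matrix is symmetric with unit diagonal in [0, 1]
  expect_equal(model$consensus, t(model$consensus))
  expect_true(all(diag(model$consensus) == 1))
  expect_true(all(model$consensus >= 0 & model$consensus <= 1))
  expect_error(metacluster_consensus(codebook, K = 25L), "exceed")
})

test_that("delta-area auto_k finds the cloud count on well-separated data", {
  set.seed(12)
  codebook <- do.call(rbind, lapply(1:3, function(i)
    matrix(rnorm(8 * 4, 4 * i, 0.05), ncol = 4)))
  model <- metacluster_consensus(codebook, reps = 50L, k_range = 2:8,
                                 auto_k = TRUE, normalize_rows = FALSE,
                                 seed = 5L)
  expect_equal(model$selected_k, 3L)
  expect_equal(model$K, 3L)
})

test_that("marker co-detection K estimator counts planted blocks", {
  set.seed(13)
  pb <- planted_block(c(80, 60, 40, 40), k = 4L)
  block <- binarize_features(pb$matrix)
  k <- estimate_k_markers(block)
  expect_equal(as.integer(k), 4L)
  expect_equal(lengths(attr(k, "communities")), rep(2L, 4))
})

test_that("assignment recovers noiseless planted proportions exactly", {
  pb <- planted_block(c(100, 60, 40))
  block <- binarize_features(pb$matrix)
  som <- train_som(block, grid = c(2L, 2L), epochs = 6L, seed = 6L)
  model <- metacluster_consensus(som, K = 3L, reps = 50L, seed = 6L)
  tab <- assign_and_summarize(block, model)
  expect_equal(rowSums(tab$proportions), c(s = 1))
  # labels ordered by decreasing abundance
  expect_equal(as.vector(tab$proportions), c(0.5, 0.3, 0.2))
  # signatures rank the true block markers on top
  for (k in 1:3) {
    top <- names(sort(tab$signatures[k, ], decreasing = TRUE)[1:2])
    expect_setequal(top, paste0("P", (2 * k - 1):(2 * k)))
  }
  # assignment is invariant to exosome row order
  perm <- sample(nrow(block$features))
  block2 <- block
  block2$features <- block$features[perm, ]
  block2$sample_id <- block$sample_id[perm]
  block2$exosome_tag <- block$exosome_tag[perm]
  tab2 <- assign_and_summarize(block2, model)
  expect_equal(tab2$proportions, tab$proportions)
  expect_equal(tab2$cluster, tab$cluster[perm])
})

test_that("differential abundance flags planted shifts and respects symmetry", {
  set.seed(14)
  make_props <- function(p1, n) {
    p <- cbind(rnorm(n, p1, 0.01), 0)
    p[, 2] <- 1 - p[, 1]
    rownames(p) <- paste0("s", seq_len(n))
    colnames(p) <- c("C1", "C2")
    p
  }
  props <- rbind(make_props(0.1347, 13), make_props(0.0113, 10))
  rownames(props) <- paste0("s", 1:23)
  tab <- structure(list(proportions = props,
                        counts = round(props * 3000)),
                   class = "subpop_table")
  groups <- rep(c("HC", "CRC"), c(13, 10))
  res <- diff_abundance(tab, groups)
  expect_true(all(res$significant))
  # label swap flips the sign of the difference, not the p-value
  res2 <- diff_abundance(tab, factor(groups, levels = c("HC", "CRC")))
  expect_equal(res2$diff, -res$diff)
  expect_equal(res2$p, res$p)
  # identical groups: no flags
  null_props <- make_props(0.3, 20)
  tabn <- structure(list(proportions = null_props,
                         counts = round(null_props * 3000)),
                    class = "subpop_table")
  resn <- diff_abundance(tabn, rep(c("a", "b"), 10))
  expect_false(any(resn$significant))
  # degenerate equal proportions: missing p
  const <- matrix(0.5, 8, 2, dimnames = list(paste0("s", 1:8), c("C1", "C2")))
  tabc <- structure(list(proportions = const, counts = const * 100),
                    class = "subpop_table")
  expect_true(all(is.na(diff_abundance(tabc, rep(c("a", "b"), 4))$p)))
})

test_that("2-D embedding is deterministic and separates planted clusters", {
  pb <- planted_block(c(150, 150), k = 2L)
  block <- binarize_features(pb$matrix)
  y1 <- embed_2d(block, seed = 3L)
  y2 <- embed_2d(block, seed = 3L)
  expect_identical(y1, y2)
  expect_equal(nrow(y1), 300L)
  truth <- pb$truth
  cent <- rbind(colMeans(y1[truth == 1, ]), colMeans(y1[truth == 2, ]))
  between <- sqrt(sum((cent[1, ] - cent[2, ])^2))
  within <- mean(c(sd(y1[truth == 1, 1]), sd(y1[truth == 2, 1]),
                   sd(y1[truth == 1, 2]), sd(y1[truth == 2, 2])))
  expect_gt(between, 3 * within)
})
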