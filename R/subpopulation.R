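#' Downsample exosomes per sample
#'
#' Uniform sampling without replacement of exosome rows; samples with at
#' most \code{n} exosomes are kept whole.
#'
#' @param matrix an \code{exo_matrix}.
#' @param n target exosome count (default 3000).
#' @param seed integer seed.
#' @return an \code{exo_matrix} with at most \code{n} rows.
#' @export
downsample_exosomes <- function(matrix, n = 3000L, seed = 1L) {
  stopifnot(inherits(matrix, "exo_matrix"), n > 0L)
  n_rows <- nrow(matrix$counts)
  if (n_rows <= n) return(matrix)
  keep <- with_preserved_seed(seed, sort(sample.int(n_rows, n)))
  structure(list(counts = matrix$counts[keep, , drop = FALSE],
                 sample_id = matrix$sample_id), class = "exo_matrix")
}

#' Binarize single-exosome profiles into a feature block
#'
#' Converts molecule counts into detection indicators (1 iff count > 0) and
#' pools exosomes across samples. With ~2.4 proteins per exosome the count
#' matrix is near-binary, so presence/absence is the default clustering
#' feature; \code{transform = "log1p"} keeps graded counts instead.
#'
#' @param matrices an \code{exo_matrix} or list of them.
#' @param transform "binary" (default) or "log1p".
#' @return a \code{feature_block}: list with \code{features} (sparse
#'   exosomes x proteins matrix), \code{sample_id}, \code{exosome_tag},
#'   \code{transform}.
#' @export
binarize_features <- function(matrices, transform = c("binary", "log1p")) {
  transform <- match.arg(transform)
  if (inherits(matrices, "exo_matrix")) matrices <- list(matrices)
  feats <- lapply(matrices, function(m) {
    x <- m$counts
    if (transform == "binary") {
      x@x <- rep(1, length(x@x))
      x
    } else {
      x@x <- log1p(x@x)
      x
    }
  })
  features <- do.call(rbind, feats)
  structure(list(features = features,
                 sample_id = rep(vapply(matrices, `[[`, "", "sample_id"),
                                 vapply(matrices, function(m) nrow(m$counts),
                                        0L)),
                 exosome_tag = unlist(lapply(matrices,
                                             function(m) rownames(m$counts))),
                 transform = transform),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("feature_block (%s): %d exosomes x %d proteins, %d samples\n",
              x$transform, nrow(x$features), ncol(x$features),
              length(unique(x$sample_id))))
  invisible(x)
}

# squared Euclidean distances from every row of (possibly sparse) X to every
# row of dense codebook W; returns n x nodes matrix
dist2_to_codebook <- function(X, W) {
  xn <- Matrix::rowSums(X^2)
  wn <- rowSums(W^2)
  cross <- as.matrix(X %*% t(W))
  outer(xn, wn, "+") - 2 * cross
}

# nearest codebook row for every row of X
nearest_node <- function(X, W) max.col(-dist2_to_codebook(X, W),
                                       ties.method = "first")

#' Train a self-organizing map on exosome features
#'
#' Batch SOM on a rectangular grid: codebook rows are initialized from
#' randomly drawn data rows, and each epoch assigns every exosome to its
#' nearest node (Euclidean) and replaces each codebook row by the
#' neighborhood-weighted mean of the assigned data, with a Gaussian
#' neighborhood whose radius shrinks linearly across epochs.
#'
#' @param block a \code{feature_block}.
#' @param grid integer c(rows, cols) of the node grid (default 10 x 10).
#' @param epochs training epochs (default 10).
#' @param seed integer seed for codebook initialization.
#' @param radius c(start, end) neighborhood sigmas; default half the larger
#'   grid dimension down to 0.2, so that final codebook rows are sharp
#'   centroids of their assigned exosomes.
#' @return a \code{som_model}: list with \code{codebook} (nodes x proteins),
#'   \code{grid}, \code{grid_xy} (node coordinates).
#' @export
train_som <- function(block, grid = c(10L, 10L), epochs = 10L, seed = 1L,
                      radius = NULL) {
  X <- block$features
  n_nodes <- prod(grid)
  if (nrow(X) < n_nodes)
    stop("fewer exosomes (", nrow(X), ") than SOM nodes (", n_nodes,
         "); use a smaller grid")
  if (is.null(radius)) radius <- c(max(grid) / 2, 0.2)
  grid_xy <- cbind(rep(seq_len(grid[1]), times = grid[2]),
                   rep(seq_len(grid[2]), each = grid[1]))
  gd2 <- as.matrix(stats::dist(grid_xy))^2

  W <- with_preserved_seed(seed, {
    as.matrix(X[sample.int(nrow(X), n_nodes), , drop = FALSE])
  })
  sigmas <- if (epochs == 1L) radius[1] else
    seq(radius[1], radius[2], length.out = epochs)
  for (e in seq_len(epochs)) {
    bmu <- nearest_node(X, W)
    ind <- Matrix::sparseMatrix(i = seq_along(bmu), j = bmu, x = 1,
                                dims = c(nrow(X), n_nodes))
    S <- as.matrix(Matrix::crossprod(ind, X))       # nodes x proteins sums
    cnt <- Matrix::colSums(ind)
    H <- exp(-gd2 / (2 * sigmas[e]^2))
    denom <- as.numeric(H %*% cnt)
    num <- H %*% S
    upd <- denom > 1e-12
    W[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
  }
  dimnames(W) <- list(NULL, colnames(X))
  # node occupancy and coherence (mean cosine of member profiles to the
  # codebook row): incoherent nodes hold heterogeneous background-only
  # profiles and are treated as noise during metaclustering
  bmu <- nearest_node(X, W)
  Wn <- W / pmax(sqrt(rowSums(W^2)), 1e-12)
  xnorm <- sqrt(Matrix::rowSums(X^2))
  cosm <- Matrix::rowSums(X * Wn[bmu, , drop = FALSE]) / pmax(xnorm, 1e-12)
  size <- tabulate(bmu, nbins = n_nodes)
  coherence <- rep(0, n_nodes)
  occ <- which(size > 0L)
  coherence[occ] <- vapply(occ, function(j) mean(cosm[bmu == j]), numeric(1))
  structure(list(codebook = W, grid = grid, grid_xy = grid_xy,
                 node_size = size, node_coherence = coherence),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %d x %d grid (%d nodes), %d features\n",
              x$grid[1], x$grid[2], nrow(x$codebook), ncol(x$codebook)))
  invisible(x)
}

# mean distance of rows of X to their assigned codebook rows
quantization_error <- function(X, W) {
  d2 <- dist2_to_codebook(X, W)
  mean(sqrt(pmax(apply(d2, 1L, min), 0)))
}

# area under the empirical CDF of the upper-triangle consensus values
consensus_cdf_area <- function(cons) {
  v <- sort(cons[upper.tri(cons)])
  if (!length(v)) return(0)
  xs <- unique(c(0, v, 1))
  cdf <- stats::ecdf(v)
  sum(diff(xs) * cdf(xs[-length(xs)]))
}

#' Consensus metaclustering of SOM nodes
#'
#' Groups SOM codebook rows into K metaclusters by resampled consensus:
#' each of \code{reps} replicates subsamples a fraction of the nodes,
#' clusters them by average-linkage hierarchical clustering on Euclidean
#' distances and cuts at k; consensus(i, j) is the fraction of co-sampled
#' replicates in which i and j co-cluster. The final partition cuts an
#' average-linkage tree on (1 - consensus) at K.
#'
#' By default codebook rows are L2-normalized before distances are taken
#' (Euclidean distance on unit rows is monotone in cosine similarity).
#' Detection profiles are sparse and near-binary, so what makes two nodes
#' belong to the same subpopulation is the direction of their marker
#' content, not its magnitude; in raw Euclidean geometry, low-occupancy
#' "mixed" nodes sit between every subpopulation and chain unrelated
#' blocks together under average linkage.
#'
#' With \code{auto_k}, K is selected by the consensus-CDF delta-area
#' criterion: Delta(k) is the relative increase in consensus-CDF area from
#' k-1 to k, and the selected K is the elbow, the k at which Delta drops
#' most sharply (maximal Delta(k)/Delta(k+1)). For sparse detection
#' profiles whose subpopulations are near-orthogonal this criterion
#' carries little signal (the consensus hierarchy is stable at every k, so
#' the CDF area grows smoothly); \code{\link{estimate_k_markers}} is the
#' recommended K-selection route and is what \code{\link{cluster_exosomes}}
#' uses by default.
#'
#' @param som a \code{som_model} (or a plain codebook matrix).
#' @param K number of metaclusters when \code{auto_k = FALSE} (default 12).
#' @param reps subsampling replicates (default 100).
#' @param subsample fraction of nodes per replicate (default 0.8).
#' @param k_range candidate k values scanned for consensus (default 2:20).
#' @param auto_k select K by the delta-area criterion (default FALSE).
#' @param normalize_rows L2-normalize codebook rows before clustering
#'   (default TRUE). Exosome assignment is unaffected: it always uses the
#'   raw codebook.
#' @param min_node_coherence when the input is a \code{som_model} carrying
#'   node statistics, nodes whose member profiles have mean cosine to the
#'   codebook row below this value (or no members at all) are set aside as
#'   a noise bucket (metacluster 0) instead of being forced into one of the
#'   K subpopulations (default 0.5; set to 0 to disable). Such nodes
#'   collect heterogeneous background-detection profiles that would
#'   otherwise chain onto an arbitrary subpopulation.
#' @param seed integer seed for subsampling.
#' @return an \code{exo_clusters} model: list with \code{som},
#'   \code{node_cluster} (node to metacluster map), \code{K},
#'   \code{consensus} (nodes x nodes for the selected K), \code{cdf_area}
#'   and \code{delta_area} (per candidate k), \code{selected_k}.
#' @export
metacluster_consensus <- function(som, K = 12L, reps = 100L,
                                  subsample = 0.8, k_range = 2:20,
                                  auto_k = FALSE,
                                  normalize_rows = TRUE,
                                  min_node_coherence = 0.5, seed = 1L) {
  codebook <- if (inherits(som, "som_model")) som$codebook else as.matrix(som)
  n_all <- nrow(codebook)
  keep <- if (inherits(som, "som_model") &&
                !is.null(som$node_coherence) && min_node_coherence > 0)
    which(som$node_size > 0L & som$node_coherence >= min_node_coherence)
  else seq_len(n_all)
  if (length(keep) < 2L) keep <- seq_len(n_all)
  codebook_all <- codebook
  codebook <- codebook[keep, , drop = FALSE]
  n <- nrow(codebook)
  if (!auto_k && K > n) stop("K cannot exceed the number of SOM nodes")
  cb <- if (normalize_rows)
    codebook / pmax(sqrt(rowSums(codebook^2)), 1e-12)
  else codebook
  k_range <- k_range[k_range <= n - 1L]
  ks <- sort(unique(c(k_range, if (!auto_k) K)))
  m <- max(2L, floor(subsample * n))

  co <- lapply(ks, function(k) matrix(0, n, n))
  names(co) <- as.character(ks)
  pair_n <- matrix(0, n, n)
  with_preserved_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sample.int(n, m)
      pair_n[idx, idx] <- pair_n[idx, idx] + 1
      hc <- stats::hclust(stats::dist(cb[idx, , drop = FALSE]),
                          method = "average")
      for (k in ks) {
        if (k > m) next
        lab <- stats::cutree(hc, k)
        same <- outer(lab, lab, "==") * 1
        co[[as.character(k)]][idx, idx] <- co[[as.character(k)]][idx, idx] + same
      }
    }
  })
  consensus_for <- function(k) {
    cons <- co[[as.character(k)]] / pmax(pair_n, 1)
    diag(cons) <- 1
    cons
  }
  areas <- vapply(ks, function(k) consensus_cdf_area(consensus_for(k)),
                  numeric(1))
  names(areas) <- as.character(ks)
  delta <- c(areas[1], diff(areas) / utils::head(areas, -1))
  names(delta) <- as.character(ks)

  selected_k <- NA_integer_
  if (auto_k) {
    # elbow: the k after which the relative area gain collapses
    drop_ratio <- delta[-length(delta)] / pmax(delta[-1], 1e-12)
    selected_k <- ks[which.max(drop_ratio)]
    K <- selected_k
  }
  cons <- consensus_for(K)
  hc_final <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  node_cluster <- integer(n_all)        # 0 = noise bucket
  node_cluster[keep] <- stats::cutree(hc_final, K)

  structure(list(som = if (inherits(som, "som_model")) som else NULL,
                 codebook = codebook_all,
                 node_cluster = node_cluster,
                 n_noise_nodes = n_all - n,
                 K = as.integer(K),
                 consensus = cons,
                 cdf_area = areas,
                 delta_area = delta,
                 selected_k = selected_k,
                 seed = seed),
            class = "exo_clusters")
}

#' @export
print.exo_clusters <- function(x, ...) {
  cat(sprintf("exo_clusters: %d SOM nodes -> %d metaclusters%s\n",
              nrow(x$codebook), x$K,
              if (!is.na(x$selected_k))
                sprintf(" (auto-selected k = %d)", x$selected_k) else ""))
  print(table(metacluster = x$node_cluster))
  invisible(x)
}

#' Estimate the number of subpopulations from marker co-detection
#'
#' A subpopulation in a single-EV surface-protein assay manifests as a
#' block of markers that are repeatedly detected together on the same
#' vesicles. This estimator builds a marker association graph: the edge
#' weight between proteins u and v is the cosine between their detection
#' indicator vectors, co-detections / sqrt(n_u * n_v), which unlike a lift
#' (observed/expected) ratio does not shrink for abundant subpopulations.
#' Edges with cosine at or above \code{min_cosine} are kept and K is the
#' number of connected components with at least \code{min_size} proteins.
#' Markers whose only association is the uniform background co-occurrence
#' floor (cosine well below 0.1 in practice) remain isolated and are not
#' counted.
#'
#' The estimate assumes each subpopulation carries at least two associated
#' markers; a subpopulation defined by a single protein, or two
#' subpopulations sharing their full marker block, would not be resolved.
#'
#' @param block a \code{feature_block}.
#' @param min_cosine association threshold on the detection-vector cosine
#'   (default 0.15).
#' @param min_detections proteins detected on fewer exosomes are excluded
#'   from the graph (default 10; their cosines are unstable).
#' @param min_size minimum component size counted as a subpopulation
#'   (default 2).
#' @return integer K; attribute \code{communities} lists the member
#'   proteins of each counted component.
#' @export
estimate_k_markers <- function(block, min_cosine = 0.15,
                               min_detections = 10L, min_size = 2L) {
  X <- block$features
  C <- as.matrix(Matrix::crossprod(X))
  nu <- diag(C)
  keep <- nu >= min_detections
  cs <- C / sqrt(outer(pmax(nu, 1), pmax(nu, 1)))
  diag(cs) <- 0
  cs[!keep, ] <- 0
  cs[, !keep] <- 0
  g <- igraph::graph_from_adjacency_matrix(cs >= min_cosine, mode = "max")
  comp <- igraph::components(g)
  sizes <- table(comp$membership)
  counted <- as.integer(names(sizes)[sizes >= min_size])
  communities <- lapply(counted, function(cc)
    colnames(X)[comp$membership == cc])
  structure(length(counted), communities = communities)
}

#' Assign exosomes to metaclusters and summarize subpopulations
#'
#' Each exosome is mapped to its nearest SOM node and inherits the node's
#' metacluster. Exosomes landing on noise-bucket nodes (metacluster 0, see
#' \code{\link{metacluster_consensus}}) are reported as unassigned and
#' excluded from the proportion denominators; because every subpopulation
#' sheds background-detection profiles at a similar per-exosome rate, this
#' exclusion leaves the mixing proportions unbiased. Metacluster labels are
#' re-ordered by decreasing overall abundance (cluster 1 = most exosomes).
#' Per-sample subpopulation proportions and per-cluster signatures (mean
#' feature value, i.e. detection frequency for binary features, among
#' member exosomes) are computed.
#'
#' @param block a \code{feature_block}.
#' @param model an \code{exo_clusters} model.
#' @return a \code{subpop_table}: list with \code{cluster} (per-exosome
#'   label, 0 = unassigned), \code{proportions} (samples x K, over assigned
#'   exosomes), \code{counts} (samples x K), \code{n_unassigned} (per
#'   sample), \code{signatures} (K x proteins), \code{sample_id},
#'   \code{exosome_tag}.
#' @export
assign_and_summarize <- function(block, model) {
  stopifnot(inherits(block, "feature_block"), inherits(model, "exo_clusters"))
  node <- nearest_node(block$features, model$codebook)
  cl <- model$node_cluster[node]
  sizes <- tabulate(cl, nbins = model$K)
  relabel <- order(order(sizes, decreasing = TRUE))
  assigned <- cl > 0L
  cl[assigned] <- relabel[cl[assigned]]

  samples <- unique(block$sample_id)
  counts <- t(vapply(samples, function(s)
    tabulate(cl[block$sample_id == s], nbins = model$K),
    integer(model$K)))
  rownames(counts) <- samples
  colnames(counts) <- paste0("C", seq_len(model$K))
  n_unassigned <- vapply(samples, function(s)
    sum(cl[block$sample_id == s] == 0L), integer(1))
  proportions <- counts / rowSums(counts)

  signatures <- matrix(0, model$K, ncol(block$features),
                       dimnames = list(paste0("C", seq_len(model$K)),
                                       colnames(block$features)))
  for (k in seq_len(model$K)) {
    mem <- cl == k
    if (any(mem))
      signatures[k, ] <- Matrix::colMeans(block$features[mem, , drop = FALSE])
  }
  structure(list(cluster = cl, proportions = proportions, counts = counts,
                 n_unassigned = n_unassigned,
                 signatures = signatures, sample_id = block$sample_id,
                 exosome_tag = block$exosome_tag,
                 relabel = relabel),
            class = "subpop_table")
}

#' @export
print.subpop_table <- function(x, ...) {
  cat(sprintf("subpop_table: %d samples x %d clusters (%d exosomes unassigned)\n",
              nrow(x$proportions), ncol(x$proportions), sum(x$n_unassigned)))
  cat("overall proportions:\n")
  print(round(colSums(x$counts) / sum(x$counts), 4))
  invisible(x)
}

#' Find the cluster matching a marker signature
#'
#' Returns the cluster whose signature ranks the given markers highest
#' (smallest sum of within-cluster frequency ranks), used to identify a
#' planted or biologically named subpopulation.
#'
#' @param table a \code{subpop_table}.
#' @param markers character vector of protein names.
#' @return integer cluster label.
#' @export
match_signature_cluster <- function(table, markers) {
  stopifnot(all(markers %in% colnames(table$signatures)))
  score <- apply(table$signatures, 1L, function(s)
    sum(rank(-s)[markers]))
  which.min(score)
}

#' Differential subpopulation abundance between two groups
#'
#' Two-sample t tests on per-sample cluster proportions, BH-adjusted.
#'
#' @param table a \code{subpop_table}.
#' @param groups two-level factor of group labels, one per sample (in the
#'   row order of \code{table$proportions}).
#' @return data.frame cluster, mean_a, mean_b, diff, p, q, significant.
#' @export
diff_abundance <- function(table, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (any(table(groups) < 3L)) stop("each group needs at least 3 samples")
  ga <- levels(groups)[1]; gb <- levels(groups)[2]
  res <- lapply(seq_len(ncol(table$proportions)), function(k) {
    x <- table$proportions[groups == ga, k]
    y <- table$proportions[groups == gb, k]
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) NA_real_
    else stats::t.test(x, y)$p.value
    list(mean_a = mean(x), mean_b = mean(y), p = p)
  })
  out <- data.frame(cluster = colnames(table$proportions),
                    mean_a = vapply(res, `[[`, 0, "mean_a"),
                    mean_b = vapply(res, `[[`, 0, "mean_b"),
                    p = vapply(res, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  out$diff <- out$mean_b - out$mean_a
  out$q <- bh_adjust(out$p)
  out$significant <- !is.na(out$q) & out$q < 0.05
  attr(out, "comparison") <- paste(gb, "vs", ga)
  out
}

#' 2-D embedding of exosome profiles for visualization
#'
#' Projects exosome feature profiles onto their first two principal
#' components and adds a small seeded jitter so that exosomes with
#' identical (binary) profiles do not collapse onto a single plotted point.
#' The embedding is deterministic under a fixed seed and is intended for
#' visualization only; no downstream computation consumes the coordinates.
#'
#' @param block a \code{feature_block}.
#' @param seed integer seed for the jitter.
#' @param jitter_sd jitter standard deviation as a fraction of each
#'   component's spread (default 0.02; 0 disables).
#' @return n x 2 matrix of coordinates.
#' @export
embed_2d <- function(block, seed = 1L, jitter_sd = 0.02) {
  X <- block$features
  n <- nrow(X)
  if (n == 0L) stop("feature block is empty")
  mu <- Matrix::colMeans(X)
  cov <- as.matrix(Matrix::crossprod(X)) / n - tcrossprod(mu)
  eig <- eigen(cov, symmetric = TRUE)
  V <- eig$vectors[, 1:2, drop = FALSE]
  # fix sign convention for determinism across platforms
  for (j in 1:2) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  Y <- as.matrix(X %*% V) - rep(as.numeric(crossprod(mu, V)), each = n)
  if (jitter_sd > 0) {
    spread <- pmax(apply(Y, 2L, stats::sd), 1e-8)
    Y <- Y + with_preserved_seed(seed,
      matrix(stats::rnorm(2L * n, sd = rep(jitter_sd * spread, each = n)),
             ncol = 2L))
  }
  colnames(Y) <- c("dim1", "dim2")
  Y
}

#' End-to-end subpopulation discovery
#'
#' Downsamples each sample, binarizes and pools features, trains the SOM,
#' metaclusters its nodes by consensus, and assigns every retained exosome.
#'
#' @param matrices list of \code{exo_matrix} objects (one per sample).
#' @param n_per_sample downsampling depth (default 3000).
#' @param grid,epochs SOM settings.
#' @param K,reps,subsample,k_range consensus settings.
#' @param auto_k select K from the data instead of using \code{K}.
#' @param auto_k_method "markers" (default; marker co-detection communities
#'   via \code{\link{estimate_k_markers}}) or "delta_area" (consensus-CDF
#'   criterion inside \code{\link{metacluster_consensus}}).
#' @param transform feature transform ("binary" or "log1p").
#' @param seed integer seed (drives downsampling, SOM init and consensus
#'   subsampling).
#' @return list with \code{block}, \code{som}, \code{model},
#'   \code{table} (a \code{subpop_table}), and \code{selected_k} when
#'   \code{auto_k} is used.
#' @export
cluster_exosomes <- function(matrices, n_per_sample = 3000L,
                             grid = c(10L, 10L), epochs = 10L,
                             K = 12L, auto_k = FALSE,
                             auto_k_method = c("markers", "delta_area"),
                             reps = 100L,
                             subsample = 0.8, k_range = 2:20,
                             transform = "binary", seed = 1L) {
  auto_k_method <- match.arg(auto_k_method)
  if (inherits(matrices, "exo_matrix")) matrices <- list(matrices)
  down <- lapply(seq_along(matrices), function(i)
    downsample_exosomes(matrices[[i]], n = n_per_sample, seed = seed + i))
  block <- binarize_features(down, transform = transform)
  som <- train_som(block, grid = grid, epochs = epochs, seed = seed)
  selected_k <- NA_integer_
  if (auto_k && auto_k_method == "markers") {
    selected_k <- as.integer(estimate_k_markers(block))
    K <- max(2L, selected_k)
    auto_k <- FALSE
  }
  model <- metacluster_consensus(som, K = K, reps = reps,
                                 subsample = subsample, k_range = k_range,
                                 auto_k = auto_k,
                                 seed = seed)
  if (!is.na(selected_k)) model$selected_k <- selected_k
  table <- assign_and_summarize(block, model)
  list(block = block, som = som, model = model, table = table,
       selected_k = model$selected_k)
}
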