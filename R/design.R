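#' Cohort simulation design
#'
#' Ground truth for the synthetic-cohort generator: the study groups and
#' their sample counts, the number of exosome subpopulations (clusters),
#' per-cluster protein signatures, per-group cluster mixing proportions, and
#' the sequencing error model applied when reads are rendered.
#'
#' @param groups data.frame with columns \code{group_name}, \code{n_samples}.
#' @param signatures K x P non-negative matrix of per-cluster protein
#'   detection weights; rows are clusters, columns named by protein.
#' @param mixing G x K matrix of per-group cluster mixing proportions; each
#'   row must sum to 1 (tolerance 1e-9). Row names must match
#'   \code{groups$group_name}.
#' @param exosomes_per_sample number of detected exosomes simulated per
#'   sample.
#' @param molecules_per_exosome_mean mean number of detected protein
#'   molecules per exosome (shifted-Poisson mean, so every exosome carries at
#'   least one molecule). Default 2.4.
#' @param duplication_rate mean number of extra sequenced copies per
#'   molecule; copies ~ 1 + Poisson(duplication_rate). Default 0.5.
#' @param substitution_rate per-base substitution probability in rendered
#'   reads. Default 5e-4.
#' @param low_quality_read_fraction fraction of reads rendered with quality
#'   strings that fail the downstream quality filter. Default 0.01.
#' @return an object of class \code{cohort_design}.
#' @export
cohort_design <- function(groups, signatures, mixing,
                          exosomes_per_sample,
                          molecules_per_exosome_mean = 2.4,
                          duplication_rate = 0.5,
                          substitution_rate = 5e-4,
                          low_quality_read_fraction = 0.01) {
  groups <- as.data.frame(groups)
  if (!all(c("group_name", "n_samples") %in% names(groups)))
    stop("groups needs columns group_name and n_samples")
  signatures <- as.matrix(signatures)
  mixing <- as.matrix(mixing)
  K <- nrow(signatures)
  if (K < 1L) stop("at least one cluster is required")
  if (ncol(mixing) != K)
    stop("mixing must have one column per cluster")
  if (nrow(mixing) != nrow(groups))
    stop("mixing must have one row per group")
  if (is.null(rownames(mixing))) rownames(mixing) <- groups$group_name
  if (!identical(rownames(mixing), as.character(groups$group_name)))
    stop("mixing row names must match group names")
  if (any(signatures < 0)) stop("signature weights must be >= 0")
  if (any(rowSums(signatures > 0) < 1L))
    stop("every signature row needs at least one positive weight")
  if (any(abs(rowSums(mixing) - 1) > 1e-9))
    stop("each group's mixing proportions must sum to 1")
  if (any(mixing < 0)) stop("mixing proportions must be >= 0")
  if (molecules_per_exosome_mean < 1)
    stop("molecules_per_exosome_mean must be >= 1 (an exosome is detected via at least one molecule)")
  stopifnot(duplication_rate >= 0, substitution_rate >= 0,
            substitution_rate <= 1, low_quality_read_fraction >= 0,
            low_quality_read_fraction <= 1)
  structure(list(groups = groups,
                 n_clusters = K,
                 signatures = signatures,
                 mixing = mixing,
                 exosomes_per_sample = as.integer(exosomes_per_sample),
                 molecules_per_exosome_mean = molecules_per_exosome_mean,
                 duplication_rate = duplication_rate,
                 substitution_rate = substitution_rate,
                 low_quality_read_fraction = low_quality_read_fraction),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("Cohort simulation design\n")
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", x$groups$group_name,
                            x$groups$n_samples), collapse = ", ")))
  cat(sprintf("  clusters: %d | proteins: %d | exosomes/sample: %d\n",
              x$n_clusters, ncol(x$signatures), x$exosomes_per_sample))
  cat(sprintf("  molecules/exosome mean: %.2f | dup rate: %.2f | sub rate: %.2g | low-Q frac: %.2g\n",
              x$molecules_per_exosome_mean, x$duplication_rate,
              x$substitution_rate, x$low_quality_read_fraction))
  invisible(x)
}

#' Packaged CRC-study-style cohort design
#'
#' The packaged fixture emulating a plasma-exosome colorectal-cancer study:
#' three groups (healthy controls n=13, primary CRC n=10, metastatic CRC
#' n=11), twelve exosome subpopulations, a tumor-like cluster carrying an
#' ITGA6/ITGB3/ADAM10/CD151/CD9 signature whose mixing proportion rises from
#' 13.61% (HC) to 23.03% (primary) and 52.06% (metastatic), an
#' immune-(monocyte/macrophage-)like cluster carrying an ITGAM/ITGAL/ITGB2
#' signature falling from 13.47% (HC) to 1.13%/1.13%, and ten background
#' clusters sharing the residual mass equally. Each cluster's signature puts
#' 95% of its detection mass on a sparse 3-5-marker block and spreads 5%
#' uniformly over the whole panel.
#'
#' @param panel antibody panel (default \code{crc_panel()}).
#' @param exosomes_per_sample exosomes per sample (default 3000, the
#'   per-sample downsampling depth used for subpopulation analysis).
#' @param ... overrides passed to \code{\link{cohort_design}} error-model
#'   arguments.
#' @return a \code{cohort_design} with attributes \code{tumor_cluster} and
#'   \code{immune_cluster} giving the planted cluster indices.
#' @export
crc_cohort_design <- function(panel = crc_panel(),
                              exosomes_per_sample = 3000L, ...) {
  proteins <- panel$antibody_name
  P <- length(proteins)
  K <- 12L
  tumor_markers <- c("ITGA6", "ITGB3", "ADAM10", "CD151", "CD9")
  immune_markers <- c("ITGAM", "ITGAL", "ITGB2")
  if (!all(c(tumor_markers, immune_markers) %in% proteins))
    stop("panel must contain the planted signature markers")

  background <- 0.05 / P
  sig <- matrix(background, nrow = K, ncol = P,
                dimnames = list(NULL, proteins))
  block <- function(markers, w) {
    stopifnot(abs(sum(w) - 1) < 1e-12)
    v <- rep(0, P); names(v) <- proteins
    v[markers] <- 0.95 * w
    v
  }
  # ITGA6/ITGB3 dominate the tumor-like signature; ADAM10/CD151/CD9 are a
  # minor tail so the block stays effectively 2-3 markers deep
  sig[1, ] <- sig[1, ] + block(tumor_markers, c(0.40, 0.34, 0.10, 0.08, 0.08))
  sig[2, ] <- sig[2, ] + block(immune_markers, c(0.40, 0.35, 0.25))
  pool <- setdiff(proteins, c(tumor_markers, immune_markers))
  for (k in 3:K) {
    m <- pool[(3 * (k - 3) + 1):(3 * (k - 3) + 3)]
    sig[k, ] <- sig[k, ] + block(m, c(0.50, 0.30, 0.20))
  }

  tumor_pi <- c(0.1361, 0.2303, 0.5206)
  immune_pi <- c(0.1347, 0.0113, 0.0113)
  resid <- (1 - tumor_pi - immune_pi) / 10
  mixing <- cbind(tumor_pi, immune_pi,
                  matrix(rep(resid, 10), nrow = 3))
  colnames(mixing) <- NULL
  rownames(mixing) <- c("HC", "primary", "metastatic")

  design <- cohort_design(
    groups = data.frame(group_name = c("HC", "primary", "metastatic"),
                        n_samples = c(13L, 10L, 11L)),
    signatures = sig,
    mixing = mixing,
    exosomes_per_sample = exosomes_per_sample,
    ...)
  attr(design, "tumor_cluster") <- 1L
  attr(design, "immune_cluster") <- 2L
  attr(design, "tumor_markers") <- tumor_markers
  attr(design, "immune_markers") <- immune_markers
  design
}
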