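pipeline_stages <- c("simulate", "process", "expression", "cluster", "roc")

config_defaults <- function() {
  list(panel = NULL, fastq_dir = NULL, outdir = "pba_out", metadata = NULL,
       design = list(type = "crc"),
       seeds = list(simulate = 1L, cluster = 1L, embed = 1L),
       quality = list(min_q = 20L, min_fraction = 0.75),
       match = list(max_mismatch = 1L),
       umi = list(method = "directional"),
       cluster = list(n_per_sample = 3000L, grid = c(10L, 10L),
                      epochs = 10L, K = 12L, auto_k = FALSE,
                      reps = 100L, subsample = 0.8),
       roc = list(positive = NULL))
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stop("unknown config key: ", paste0(path, nm))
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && nm != "design")
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, nm, "."))
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read and validate a pipeline run configuration
#'
#' Configuration is YAML; unknown keys are rejected. Defaults cover the
#' packaged CRC-style design, a 10x10 SOM with K = 12, 3000 exosomes per
#' sample, and the standard quality/matching/UMI parameters.
#'
#' @param path YAML file path, or a list of overrides.
#' @return a validated \code{run_config} list.
#' @export
read_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
  else if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else as.list(path)
  cfg <- merge_config(config_defaults(), user)
  cfg$seeds <- lapply(cfg$seeds, as.integer)
  structure(cfg, class = "run_config")
}

# resolve the design entry of a config into a cohort_design
config_design <- function(cfg, panel) {
  d <- cfg$design
  if (is.character(d)) d <- list(type = d)
  type <- d$type %||% "crc"
  if (type != "crc")
    stop("unknown design type: ", type)
  args <- d[setdiff(names(d), "type")]
  do.call(crc_cohort_design, c(list(panel = panel), args))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# polynomial rolling hash of the serialized config, for the run manifest
config_hash <- function(cfg) {
  bytes <- as.integer(charToRaw(paste(utils::capture.output(utils::str(cfg)),
                                      collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# write an exo_matrix as MatrixMarket triplets + axis TSVs
write_exo_matrix <- function(mat, dir) {
  base <- file.path(dir, mat$sample_id)
  Matrix::writeMM(mat$counts, paste0(base, ".mtx"))
  writeLines(rownames(mat$counts), paste0(base, ".exosome_tags.tsv"))
  writeLines(colnames(mat$counts), paste0(base, ".proteins.tsv"))
  invisible(base)
}

#' Read an exosome-protein matrix written by the pipeline
#' @param base path prefix (without extension) of the .mtx artifact.
#' @return an \code{exo_matrix}.
#' @export
read_exo_matrix <- function(base) {
  counts <- Matrix::readMM(paste0(base, ".mtx"))
  # writeMM may have used pattern/symmetric storage for binary matrices
  counts <- methods::as(methods::as(methods::as(
    counts, "generalMatrix"), "dMatrix"), "CsparseMatrix")
  dimnames(counts) <- list(readLines(paste0(base, ".exosome_tags.tsv")),
                           readLines(paste0(base, ".proteins.tsv")))
  sample_id <- basename(base)
  structure(list(counts = counts, sample_id = sample_id),
            class = "exo_matrix")
}

#' Run the PBA analysis pipeline
#'
#' Orchestrates simulate -> process -> expression -> cluster -> roc over a
#' validated configuration, writing every stage artifact (FASTQ + truth
#' sidecar, MatrixMarket matrices + QC JSON, expression/differential TSVs,
#' cluster assignment/proportion/signature/embedding TSVs, ROC summaries)
#' and a run manifest JSON recording the config hash, seeds, package
#' version and per-stage counts.
#'
#' @param config a \code{run_config}, a YAML path, or a list of overrides.
#' @param stages subset of \code{c("simulate", "process", "expression",
#'   "cluster", "roc")}, executed in pipeline order.
#' @return (invisibly) list of artifact paths and in-memory results.
#' @export
run_pipeline <- function(config = NULL, stages = pipeline_stages) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  panel <- if (is.null(cfg$panel)) crc_panel() else {
    if (!file.exists(cfg$panel)) stop("panel file not found: ", cfg$panel)
    read_panel_tsv(cfg$panel)
  }
  layout <- read_layout()
  manifest <- list(config_hash = config_hash(cfg), seeds = cfg$seeds,
                   package_version = as.character(utils::packageVersion("exopba")),
                   stages = list())
  artifacts <- list()
  fastq_dir <- cfg$fastq_dir %||% file.path(outdir, "fastq")
  metadata_path <- cfg$metadata %||% file.path(outdir, "metadata.tsv")

  if ("simulate" %in% stages) {
    design <- config_design(cfg, panel)
    truth <- simulate_exosomes(design, seed = cfg$seeds$simulate)
    emitted <- write_pba_reads(truth, panel, layout, dir = fastq_dir,
                               seed = cfg$seeds$simulate + 1L)
    meta <- unique(truth$exosomes[, c("sample_id", "group")])
    write_tsv(meta, metadata_path)
    write_panel_tsv(panel, file.path(outdir, "panel.tsv"))
    manifest$stages$simulate <- list(n_samples = length(emitted$fastq),
                                     n_exosomes = nrow(truth$exosomes),
                                     n_molecules = nrow(truth$molecules))
    stage_log("simulate", "%d samples, %d exosomes, %d molecules",
              length(emitted$fastq), nrow(truth$exosomes),
              nrow(truth$molecules))
    artifacts$fastq <- emitted$fastq
    artifacts$sidecar <- emitted$sidecar
    artifacts$truth <- truth
  }

  matrix_dir <- file.path(outdir, "matrices")
  if ("process" %in% stages) {
    if (!dir.exists(fastq_dir))
      stop("FASTQ directory not found: ", fastq_dir)
    fq <- sort(list.files(fastq_dir, pattern = "\\.(fastq|fq)$",
                          full.names = TRUE))
    if (!length(fq)) stop("no FASTQ files in ", fastq_dir)
    dir.create(matrix_dir, showWarnings = FALSE)
    processed <- lapply(fq, function(f) {
      res <- process_sample(f, panel, layout,
                            min_q = cfg$quality$min_q,
                            min_fraction = cfg$quality$min_fraction,
                            max_mismatch = cfg$match$max_mismatch,
                            umi_method = cfg$umi$method)
      write_exo_matrix(res$matrix, matrix_dir)
      stage_log("process", "%s: %d reads -> %d exosomes, %d molecules",
                res$matrix$sample_id, res$qc$n_reads_in, res$qc$n_exosomes,
                res$qc$n_molecules)
      res
    })
    names(processed) <- vapply(processed, function(r) r$matrix$sample_id, "")
    qc <- lapply(processed, function(r) unclass(r$qc))
    jsonlite::write_json(qc, file.path(outdir, "qc_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$process <- list(
      n_samples = length(processed),
      n_reads_in = sum(vapply(qc, `[[`, 0, "n_reads_in")),
      n_reads_pass_quality = sum(vapply(qc, `[[`, 0, "n_reads_pass_quality")),
      n_parsed = sum(vapply(qc, `[[`, 0, "n_parsed")),
      n_matched = sum(vapply(qc, `[[`, 0, "n_matched")),
      n_exosomes = sum(vapply(qc, `[[`, 0, "n_exosomes")),
      n_molecules = sum(vapply(qc, `[[`, 0, "n_molecules")),
      mean_proteins_per_exosome =
        sum(vapply(qc, function(x) x$mean_proteins_per_exosome * x$n_exosomes,
                   0)) / sum(vapply(qc, `[[`, 0, "n_exosomes")))
    artifacts$matrices <- lapply(processed, `[[`, "matrix")
    artifacts$qc <- lapply(processed, `[[`, "qc")
  }

  load_matrices <- function() {
    if (!is.null(artifacts$matrices)) return(artifacts$matrices)
    bases <- sub("\\.mtx$", "",
                 list.files(matrix_dir, pattern = "\\.mtx$",
                            full.names = TRUE))
    if (!length(bases))
      stop("no matrix artifacts in ", matrix_dir,
           "; run the process stage first")
    mats <- lapply(sort(bases), read_exo_matrix)
    names(mats) <- vapply(mats, `[[`, "", "sample_id")
    mats
  }
  load_metadata <- function(samples) {
    if (!file.exists(metadata_path))
      stop("metadata file not found: ", metadata_path)
    meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
    meta$group[match(samples, meta$sample_id)]
  }

  if ("expression" %in% stages) {
    mats <- load_matrices()
    groups <- load_metadata(names(mats))
    tab <- expression_table(mats, groups)
    factors <- tmm_factors(tab)
    norm <- normalize_expression(tab, factors)
    write_tsv(data.frame(sample_id = rownames(tab$counts),
                         group = as.character(tab$groups),
                         tmm_factor = as.numeric(factors)),
              file.path(outdir, "tmm_factors.tsv"))
    write_tsv(cbind(data.frame(sample_id = rownames(norm)),
                    as.data.frame(norm)),
              file.path(outdir, "normalized_expression.tsv"))
    pairs <- utils::combn(levels(tab$groups), 2L, simplify = FALSE)
    de <- lapply(pairs, function(pr) {
      sel <- tab$groups %in% pr
      res <- diff_expression(norm[sel, , drop = FALSE],
                             droplevels(tab$groups[sel]))
      write_tsv(as.data.frame(res),
                file.path(outdir, sprintf("diff_expression_%s_vs_%s.tsv",
                                          pr[2], pr[1])))
      stage_log("expression", "%s vs %s: %d/%d proteins at q < 0.05",
                pr[2], pr[1], sum(res$significant), nrow(res))
      res
    })
    names(de) <- vapply(pairs, paste, "", collapse = "_vs_")
    manifest$stages$expression <- list(
      n_samples = nrow(tab$counts), n_proteins = ncol(tab$counts),
      comparisons = names(de))
    artifacts$expression <- list(table = tab, factors = factors,
                                 normalized = norm, diff = de)
  }

  if ("cluster" %in% stages) {
    mats <- load_matrices()
    cl <- cluster_exosomes(mats,
                           n_per_sample = cfg$cluster$n_per_sample,
                           grid = cfg$cluster$grid,
                           epochs = cfg$cluster$epochs,
                           K = cfg$cluster$K,
                           auto_k = isTRUE(cfg$cluster$auto_k),
                           reps = cfg$cluster$reps,
                           subsample = cfg$cluster$subsample,
                           seed = cfg$seeds$cluster)
    emb <- embed_2d(cl$block, seed = cfg$seeds$embed)
    write_tsv(data.frame(exosome_tag = cl$block$exosome_tag,
                         sample_id = cl$block$sample_id,
                         cluster = cl$table$cluster),
              file.path(outdir, "cluster_assignments.tsv"))
    write_tsv(cbind(data.frame(sample_id = rownames(cl$table$proportions)),
                    as.data.frame(cl$table$proportions)),
              file.path(outdir, "cluster_proportions.tsv"))
    write_tsv(cbind(data.frame(cluster = rownames(cl$table$signatures)),
                    as.data.frame(cl$table$signatures)),
              file.path(outdir, "cluster_signatures.tsv"))
    write_tsv(cbind(data.frame(exosome_tag = cl$block$exosome_tag,
                               sample_id = cl$block$sample_id),
                    as.data.frame(emb)),
              file.path(outdir, "embedding.tsv"))
    stage_log("cluster", "%d exosomes -> %d metaclusters",
              nrow(cl$block$features), cl$model$K)
    manifest$stages$cluster <- list(n_exosomes = nrow(cl$block$features),
                                    K = cl$model$K,
                                    selected_k = cl$model$selected_k)
    artifacts$cluster <- cl
    artifacts$embedding <- emb
  }

  if ("roc" %in% stages) {
    mats <- load_matrices()
    groups <- load_metadata(names(mats))
    norm <- if (!is.null(artifacts$expression))
      artifacts$expression$normalized
    else {
      tab <- expression_table(mats, groups)
      normalize_expression(tab, tmm_factors(tab))
    }
    props <- if (!is.null(artifacts$cluster))
      artifacts$cluster$table$proportions
    else {
      pf <- file.path(outdir, "cluster_proportions.tsv")
      if (!file.exists(pf))
        stop("cluster proportions not found: ", pf,
             "; run the cluster stage first")
      pm <- utils::read.delim(pf, stringsAsFactors = FALSE)
      as.matrix(pm[, -1, drop = FALSE])
    }
    lv <- sort(unique(groups))
    pairs <- utils::combn(lv, 2L, simplify = FALSE)
    roc_all <- lapply(pairs, function(pr) {
      sel <- groups %in% pr
      positive <- cfg$roc$positive %||% pr[2]
      if (!positive %in% pr) positive <- pr[2]
      scores <- cbind(norm[sel, , drop = FALSE],
                      props[sel, , drop = FALSE])
      res <- marker_roc(scores, groups[sel], positive = positive)
      write_tsv(as.data.frame(res),
                file.path(outdir, sprintf("roc_summary_%s_vs_%s.tsv",
                                          pr[2], pr[1])))
      curves <- attr(res, "curves")
      long <- do.call(rbind, lapply(names(curves), function(mk)
        cbind(data.frame(marker = mk), curves[[mk]])))
      write_tsv(long, file.path(outdir, sprintf("roc_curves_%s_vs_%s.tsv",
                                                pr[2], pr[1])))
      stage_log("roc", "%s vs %s: best AUC %.4f (%s)", pr[2], pr[1],
                max(res$auc), res$marker[which.max(res$auc)])
      res
    })
    names(roc_all) <- vapply(pairs, paste, "", collapse = "_vs_")
    manifest$stages$roc <- list(comparisons = names(roc_all),
                                n_markers = ncol(norm) + ncol(props))
    artifacts$roc <- roc_all
  }

  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  artifacts$manifest <- manifest
  invisible(artifacts)
}
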