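DNA_BASES4 <- c("A", "C", "G", "T")

# n random DNA strings of the given length, vectorized column-wise
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  do.call(paste0, lapply(seq_len(len),
                         function(i) DNA_BASES4[sample.int(4L, n, replace = TRUE)]))
}

# random DNA strings guaranteed distinct (rejection sampling)
random_dna_unique <- function(n, len) {
  tags <- random_dna(n, len)
  repeat {
    dup <- duplicated(tags)
    if (!any(dup)) return(tags)
    tags[dup] <- random_dna(sum(dup), len)
  }
}

#' Simulate ground-truth single-exosome profiles
#'
#' Draws, for every sample of every group in the design, the configured
#' number of exosomes. Each exosome is assigned a subpopulation
#' (cluster ~ categorical of the group's mixing proportions), a molecule
#' count m ~ 1 + Poisson(mean - 1), and m distinct proteins drawn without
#' replacement with probabilities proportional to the cluster's signature
#' weights. Drawing without replacement makes the number of distinct
#' proteins per exosome equal the molecule count, matching how a
#' multiplexed antibody readout reports each detected surface protein once.
#'
#' @param design a \code{\link{cohort_design}}.
#' @param seed integer seed; the same seed reproduces the same truth.
#' @return an object of class \code{pba_truth}: list with \code{design},
#'   \code{exosomes} (sample_id, group, exosome, cluster) and
#'   \code{molecules} (sample_id, exosome, cluster, protein index).
#' @export
simulate_exosomes <- function(design, seed) {
  if (!inherits(design, "cohort_design")) stop("design must be a cohort_design")
  P <- ncol(design$signatures)
  n_exo <- design$exosomes_per_sample
  mu <- design$molecules_per_exosome_mean - 1

  sample_ids <- unlist(lapply(seq_len(nrow(design$groups)), function(g) {
    sprintf("%s_%02d", design$groups$group_name[g],
            seq_len(design$groups$n_samples[g]))
  }))
  sample_groups <- rep(design$groups$group_name, design$groups$n_samples)

  exo_list <- vector("list", length(sample_ids))
  mol_list <- vector("list", length(sample_ids))
  with_preserved_seed(seed, {
    for (s in seq_along(sample_ids)) {
      pi_g <- design$mixing[sample_groups[s], ]
      cluster <- sample.int(design$n_clusters, n_exo, replace = TRUE,
                            prob = pi_g)
      m <- 1L + stats::rpois(n_exo, mu)
      m <- pmin(m, P)
      proteins <- vector("list", n_exo)
      for (k in seq_len(design$n_clusters)) {
        idx <- which(cluster == k)
        if (!length(idx)) next
        w <- design$signatures[k, ]
        pos <- which(w > 0)
        # distinct proteins per exosome cannot exceed the cluster's support
        m[idx] <- pmin(m[idx], length(pos))
        singles <- idx[m[idx] == 1L]
        if (length(singles))
          proteins[singles] <- as.list(
            pos[sample.int(length(pos), length(singles), replace = TRUE,
                           prob = w[pos])])
        for (i in idx[m[idx] > 1L])
          proteins[[i]] <- pos[sample.int(length(pos), m[i], prob = w[pos])]
      }
      exo_list[[s]] <- data.frame(sample_id = sample_ids[s],
                                  group = sample_groups[s],
                                  exosome = seq_len(n_exo),
                                  cluster = cluster,
                                  stringsAsFactors = FALSE)
      mol_list[[s]] <- data.frame(sample_id = sample_ids[s],
                                  exosome = rep(seq_len(n_exo), m),
                                  cluster = rep(cluster, m),
                                  protein = unlist(proteins),
                                  stringsAsFactors = FALSE)
    }
  })
  structure(list(design = design,
                 exosomes = do.call(rbind, exo_list),
                 molecules = do.call(rbind, mol_list)),
            class = "pba_truth")
}

#' @export
print.pba_truth <- function(x, ...) {
  cat(sprintf("Simulated PBA truth: %d samples, %d exosomes, %d molecules\n",
              length(unique(x$exosomes$sample_id)), nrow(x$exosomes),
              nrow(x$molecules)))
  cat(sprintf("  mean molecules/exosome: %.3f\n",
              nrow(x$molecules) / nrow(x$exosomes)))
  invisible(x)
}

ANCHOR_SEQ <- "GTCAGTACGGCT"

# quality strings for the two-state model: good reads are uniformly Q37;
# bad reads carry Q2 over the final `n_low` cycles, enough to breach the
# 75%-of-bases-at-Q20 rule.
quality_strings <- function(n_reads, read_length, bad, q_good = 37L, q_bad = 2L) {
  n_low <- ceiling(0.26 * read_length)
  good_q <- strrep(rawToChar(as.raw(q_good + 33L)), read_length)
  bad_q <- paste0(strrep(rawToChar(as.raw(q_good + 33L)), read_length - n_low),
                  strrep(rawToChar(as.raw(q_bad + 33L)), n_low))
  ifelse(bad, bad_q, good_q)
}

# apply per-base substitutions at the given rate; returns modified seqs
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  len <- nchar(seqs[1])
  n_err <- stats::rbinom(length(seqs), len, rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(len, n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES4, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Render simulated truth as barcoded FASTQ reads
#'
#' Assigns each exosome a unique random exosome tag and each molecule a
#' random UMI, replicates molecules into sequenced copies
#' (copies ~ 1 + Poisson(duplication_rate)), applies per-base substitution
#' errors, marks a configured fraction of reads with filter-failing quality
#' strings, and writes one Phred+33 FASTQ per sample plus a truth sidecar
#' TSV mapping exosome tags to their planted cluster labels.
#'
#' @param truth a \code{pba_truth} from \code{\link{simulate_exosomes}}.
#' @param panel a \code{\link{pba_panel}}; must cover every protein index in
#'   the truth, and its tag length must equal the layout's protein-tag span.
#' @param layout a \code{\link{read_layout}}.
#' @param dir output directory (created if missing).
#' @param seed integer seed for tags, UMIs, duplication and errors.
#' @return (invisibly) list with \code{fastq} (named vector of per-sample
#'   paths), \code{sidecar} (path), and \code{tags} (data.frame exosome_tag,
#'   sample_id, cluster_label).
#' @export
write_pba_reads <- function(truth, panel, layout = read_layout(), dir, seed) {
  stopifnot(inherits(truth, "pba_truth"), inherits(panel, "pba_panel"),
            inherits(layout, "read_layout"))
  if (max(truth$molecules$protein) > nrow(panel))
    stop("panel has fewer antibodies than proteins present in the truth")
  if (span_len(layout$protein_tag) != tag_length(panel))
    stop("layout protein-tag span does not match panel tag length")
  if (layout_span(layout) > layout$read_length)
    stop("layout spans exceed read length")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- truth$design
  umi_len <- span_len(layout$umi)
  etag_len <- span_len(layout$exosome_tag)
  anchor <- substr(strrep(ANCHOR_SEQ, ceiling(span_len(layout$anchor) /
                                                nchar(ANCHOR_SEQ))),
                   1L, span_len(layout$anchor))
  pad_len <- layout$read_length - layout_span(layout)

  samples <- unique(truth$exosomes$sample_id)
  fastq <- stats::setNames(file.path(dir, paste0(samples, ".fastq")), samples)
  tag_list <- vector("list", length(samples))
  with_preserved_seed(seed, {
    for (s in seq_along(samples)) {
      sid <- samples[s]
      exo <- truth$exosomes[truth$exosomes$sample_id == sid, ]
      mol <- truth$molecules[truth$molecules$sample_id == sid, ]
      etags <- random_dna_unique(nrow(exo), etag_len)
      tag_list[[s]] <- data.frame(exosome_tag = etags, sample_id = sid,
                                  cluster_label = exo$cluster,
                                  stringsAsFactors = FALSE)
      umis <- random_dna(nrow(mol), umi_len)
      copies <- 1L + stats::rpois(nrow(mol), design$duplication_rate)
      rep_idx <- rep(seq_len(nrow(mol)), copies)
      seqs <- paste0(panel$protein_tag[mol$protein[rep_idx]],
                     umis[rep_idx], anchor, etags[mol$exosome[rep_idx]],
                     if (pad_len > 0) strrep("T", pad_len) else "")
      seqs <- apply_substitutions(seqs, design$substitution_rate)
      bad <- stats::runif(length(seqs)) < design$low_quality_read_fraction
      quals <- quality_strings(length(seqs), layout$read_length, bad)
      reads <- Biostrings::DNAStringSet(seqs)
      names(reads) <- sprintf("%s:%07d", sid, seq_along(seqs))
      withCallingHandlers(
        Biostrings::writeXStringSet(reads, fastq[s], format = "fastq",
                                    qualities = Biostrings::BStringSet(quals)),
        warning = function(w) {
          if (grepl("metadata columns", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    }
  })
  tags <- do.call(rbind, tag_list)
  sidecar <- file.path(dir, "truth_sidecar.tsv")
  utils::write.table(tags, sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fastq = fastq, sidecar = sidecar, tags = tags))
}
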