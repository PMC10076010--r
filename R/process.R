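#' Quality-filter FASTQ reads
#'
#' Keeps reads in which the fraction of bases at or above \code{min_q} is
#' strictly greater than \code{min_fraction} (the "more than 75\% of bases at
#' Q20" rule). Order is preserved.
#'
#' @param path path to a Phred+33 single-end FASTQ file.
#' @param min_q minimum Phred score counted as good (default 20).
#' @param min_fraction strict lower bound on the good-base fraction
#'   (default 0.75).
#' @return list with \code{sequences} (character vector of surviving reads),
#'   \code{n_in}, \code{n_pass}.
#' @export
quality_filter <- function(path, min_q = 20L, min_fraction = 0.75) {
  parsed <- withCallingHandlers(
    tryCatch({
      reads <- Biostrings::readQualityScaledDNAStringSet(path)
      list(reads = reads,
           q = as(Biostrings::quality(reads), "IntegerList"))
    }, error = function(e) stop("malformed FASTQ at ", path, ": ",
                                conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  reads <- parsed$reads
  q <- parsed$q
  if (length(reads)) {
    if (any(Biostrings::width(Biostrings::quality(reads)) !=
              Biostrings::width(reads)) ||
          min(min(q)) < 0L || max(max(q)) > 93L)
      stop("malformed FASTQ at ", path,
           ": quality strings do not match sequences", call. = FALSE)
  }
  good_frac <- sum(q >= min_q) / lengths(q)
  keep <- good_frac > min_fraction
  list(sequences = as.character(reads[keep]),
       n_in = length(reads), n_pass = sum(keep))
}

#' Parse reads into tag fields
#'
#' Slices protein tag, UMI and exosome tag out of each read at the layout's
#' offsets. Reads shorter than the layout span, or carrying an ambiguous
#' base (N) inside the UMI or exosome tag, are rejected; the UMI and exosome
#' tag are identifiers whose identity must be exact, whereas an N in the
#' protein tag is tolerated and simply counts as a mismatch during panel
#' matching.
#'
#' @param sequences character vector of read sequences.
#' @param layout a \code{\link{read_layout}}.
#' @return data.frame with columns protein_tag, umi, exosome_tag for parsed
#'   reads; attribute \code{n_in} gives the input count.
#' @export
parse_reads <- function(sequences, layout = read_layout()) {
  need <- layout_span(layout)
  long_enough <- nchar(sequences) >= need
  seqs <- sequences[long_enough]
  ptag <- slice_field(seqs, layout$protein_tag)
  umi <- slice_field(seqs, layout$umi)
  etag <- slice_field(seqs, layout$exosome_tag)
  ok <- !grepl("N", umi, fixed = TRUE) & !grepl("N", etag, fixed = TRUE)
  out <- data.frame(protein_tag = ptag[ok], umi = umi[ok],
                    exosome_tag = etag[ok], stringsAsFactors = FALSE)
  attr(out, "n_in") <- length(sequences)
  out
}

# Hamming distances between one tag and a matrix of panel tag characters
hamming_to_panel <- function(tag, panel_chars) {
  chars <- strsplit(tag, "", fixed = TRUE)[[1]]
  rowSums(panel_chars != rep(chars, each = nrow(panel_chars)))
}

#' Match protein tags against the antibody panel
#'
#' An exact match wins; otherwise a tag is assigned to the unique panel
#' entry within Hamming distance \code{max_mismatch}. Ties (two entries at
#' the minimal distance) and tags with no entry in range are rejected
#' (returned as NA). N bases count as mismatches.
#'
#' @param tags character vector of observed protein tags.
#' @param panel a \code{\link{pba_panel}}.
#' @param max_mismatch maximum tolerated Hamming distance (default 1).
#' @return integer vector of antibody indices into the panel, NA where
#'   rejected.
#' @export
match_protein_tags <- function(tags, panel, max_mismatch = 1L) {
  if (length(tags) && any(nchar(tags) != tag_length(panel)))
    stop("protein tags must have the panel tag length ", tag_length(panel))
  idx <- match(tags, panel$protein_tag)
  if (max_mismatch >= 1L && anyNA(idx)) {
    unmatched <- unique(tags[is.na(idx)])
    panel_chars <- do.call(rbind, strsplit(panel$protein_tag, "", fixed = TRUE))
    resolve <- vapply(unmatched, function(tg) {
      d <- hamming_to_panel(tg, panel_chars)
      dmin <- min(d)
      if (dmin > max_mismatch || sum(d == dmin) > 1L) NA_integer_
      else which.min(d)
    }, integer(1))
    miss <- is.na(idx)
    idx[miss] <- resolve[match(tags[miss], unmatched)]
  }
  idx
}

# brute-force directional UMI collapse within one (exosome, antibody) group.
# umis/counts must be sorted by (count desc, umi lexicographic). A root UMI u
# absorbs an unvisited v when Hamming(u, v) <= 1 and count(u) >= 2*count(v)-1;
# absorption spreads breadth-first so u's children can absorb their own.
collapse_group_directional <- function(umis, counts) {
  n <- length(umis)
  if (n == 1L) return(1L)
  chars <- do.call(rbind, strsplit(umis, "", fixed = TRUE))
  assigned <- rep(FALSE, n)
  n_roots <- 0L
  for (i in seq_len(n)) {
    if (assigned[i]) next
    n_roots <- n_roots + 1L
    queue <- i
    assigned[i] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      cand <- which(!assigned)
      if (!length(cand)) break
      hd <- colSums(t(chars[cand, , drop = FALSE]) != chars[u, ])
      absorb <- cand[hd <= 1L & counts[u] >= 2L * counts[cand] - 1L]
      if (length(absorb)) {
        assigned[absorb] <- TRUE
        queue <- c(queue, absorb)
      }
    }
  }
  n_roots
}

#' Collapse UMIs into unique molecules
#'
#' Deduplicates reads into molecules within each (exosome tag, antibody)
#' group. Method \code{"exact"} counts distinct UMIs. Method
#' \code{"directional"} (default) additionally merges sequencing-error UMI
#' variants: a UMI u absorbs v when they differ by at most one base and
#' count(u) >= 2*count(v) - 1, processed in deterministic
#' (count-descending, then lexicographic) order; the number of molecules is
#' the number of network roots.
#'
#' @param records data.frame with columns exosome_tag, antibody, umi (one
#'   row per surviving read).
#' @param method "directional" or "exact".
#' @return data.frame exosome_tag, antibody, n_molecules (one row per
#'   (exosome, antibody) pair).
#' @export
collapse_umis <- function(records, method = c("directional", "exact")) {
  method <- match.arg(method)
  if (!nrow(records))
    return(data.frame(exosome_tag = character(0), antibody = integer(0),
                      n_molecules = integer(0), stringsAsFactors = FALSE))
  # read counts per (exosome_tag, antibody, umi) via radix sort + run-length
  key3 <- paste(records$exosome_tag, records$antibody, records$umi,
                sep = "\r")
  o3 <- order(key3, method = "radix")
  r3 <- rle(key3[o3])
  first <- o3[cumsum(r3$lengths) - r3$lengths + 1L]
  cnt <- data.frame(exosome_tag = records$exosome_tag[first],
                    antibody = records$antibody[first],
                    umi = records$umi[first],
                    n_reads = r3$lengths, stringsAsFactors = FALSE)

  key <- paste(cnt$exosome_tag, cnt$antibody, sep = "\r")
  ord <- order(key, -cnt$n_reads, cnt$umi, method = "radix")
  cnt <- cnt[ord, ]
  runs <- rle(key[ord])
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  if (method == "exact") {
    n_mol <- runs$lengths
  } else {
    n_mol <- runs$lengths
    multi <- which(runs$lengths > 1L)
    for (g in multi) {
      ii <- starts[g]:ends[g]
      n_mol[g] <- collapse_group_directional(cnt$umi[ii], cnt$n_reads[ii])
    }
  }
  data.frame(exosome_tag = cnt$exosome_tag[starts],
             antibody = cnt$antibody[starts],
             n_molecules = n_mol,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the single-exosome protein-count matrix
#'
#' @param molecules data.frame from \code{\link{collapse_umis}}.
#' @param panel a \code{\link{pba_panel}} giving protein (column) order.
#' @param sample_id sample identifier stored with the matrix.
#' @return an \code{exo_matrix}: list with \code{counts} (sparse
#'   exosomes x proteins dgCMatrix, rownames = exosome tags, colnames =
#'   antibody names) and \code{sample_id}.
#' @export
build_matrix <- function(molecules, panel, sample_id = "sample") {
  etags <- sort(unique(molecules$exosome_tag))
  counts <- Matrix::sparseMatrix(
    i = match(molecules$exosome_tag, etags),
    j = molecules$antibody,
    x = molecules$n_molecules,
    dims = c(length(etags), nrow(panel)),
    dimnames = list(etags, panel$antibody_name))
  structure(list(counts = counts, sample_id = sample_id),
            class = "exo_matrix")
}

#' @export
print.exo_matrix <- function(x, ...) {
  cat(sprintf("exo_matrix '%s': %d exosomes x %d proteins, %d molecules\n",
              x$sample_id, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' QC metrics for one processed sample
#'
#' @param n_reads_in,n_reads_pass_quality,n_parsed,n_matched stage counters
#'   from the processing funnel.
#' @param matrix an \code{exo_matrix}.
#' @return a \code{qc_metrics} list; \code{mean_proteins_per_exosome} is the
#'   mean over exosomes of the number of proteins with nonzero deduplicated
#'   count (0 for an empty matrix).
#' @export
qc_metrics <- function(n_reads_in, n_reads_pass_quality, n_parsed,
                       n_matched, matrix) {
  counts <- matrix$counts
  n_exosomes <- nrow(counts)
  n_molecules <- sum(counts)
  stopifnot(n_reads_in >= n_reads_pass_quality,
            n_reads_pass_quality >= n_parsed,
            n_parsed >= n_matched,
            n_molecules <= n_matched)
  mean_ppe <- if (n_exosomes == 0L) 0 else
    mean(Matrix::rowSums(counts > 0))
  structure(list(n_reads_in = n_reads_in,
                 n_reads_pass_quality = n_reads_pass_quality,
                 n_parsed = n_parsed,
                 n_matched = n_matched,
                 n_exosomes = n_exosomes,
                 n_molecules = as.integer(n_molecules),
                 mean_proteins_per_exosome = mean_ppe),
            class = "qc_metrics")
}

#' @export
print.qc_metrics <- function(x, ...) {
  cat("PBA read-processing funnel:\n")
  cat(sprintf("  reads in          %d\n", x$n_reads_in))
  cat(sprintf("  pass quality      %d\n", x$n_reads_pass_quality))
  cat(sprintf("  parsed            %d\n", x$n_parsed))
  cat(sprintf("  panel-matched     %d\n", x$n_matched))
  cat(sprintf("  exosomes          %d\n", x$n_exosomes))
  cat(sprintf("  molecules         %d\n", x$n_molecules))
  cat(sprintf("  proteins/exosome  %.3f\n", x$mean_proteins_per_exosome))
  invisible(x)
}

#' Process one sample's FASTQ into an exosome-protein matrix
#'
#' Runs the full funnel: quality filter, field parsing, mismatch-tolerant
#' protein-tag matching, directional UMI collapse, matrix construction and
#' QC metric computation.
#'
#' @param path FASTQ path (one FASTQ = one sample).
#' @param panel a \code{\link{pba_panel}}.
#' @param layout a \code{\link{read_layout}}.
#' @param sample_id sample identifier (default: FASTQ basename).
#' @param min_q,min_fraction quality-filter parameters.
#' @param max_mismatch protein-tag matching tolerance.
#' @param umi_method UMI collapse method.
#' @return list with \code{matrix} (an \code{exo_matrix}) and \code{qc}
#'   (a \code{qc_metrics}).
#' @export
process_sample <- function(path, panel, layout = read_layout(),
                           sample_id = sub("\\.(fastq|fq)(\\.gz)?$", "",
                                           basename(path)),
                           min_q = 20L, min_fraction = 0.75,
                           max_mismatch = 1L,
                           umi_method = c("directional", "exact")) {
  qf <- quality_filter(path, min_q = min_q, min_fraction = min_fraction)
  parsed <- parse_reads(qf$sequences, layout)
  antibody <- match_protein_tags(parsed$protein_tag, panel,
                                 max_mismatch = max_mismatch)
  ok <- !is.na(antibody)
  records <- data.frame(exosome_tag = parsed$exosome_tag[ok],
                        antibody = antibody[ok],
                        umi = parsed$umi[ok], stringsAsFactors = FALSE)
  molecules <- collapse_umis(records, method = match.arg(umi_method))
  mat <- build_matrix(molecules, panel, sample_id)
  qc <- qc_metrics(qf$n_in, qf$n_pass, nrow(parsed), nrow(records), mat)
  list(matrix = mat, qc = qc)
}
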