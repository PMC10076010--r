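#' Antibody panel definition
#'
#' A PBA panel maps each antibody in the assay to the DNA protein tag carried
#' by its conjugated oligonucleotide. The protein tag is the read field that
#' identifies which antibody (hence which surface protein) a molecule reports.
#'
#' @param antibody_name character vector of unique antibody/protein names.
#' @param protein_tag character vector of DNA tags (A/C/G/T), one per
#'   antibody, all the same length and all distinct.
#' @return An object of class \code{pba_panel}: a data.frame with columns
#'   \code{antibody_name} and \code{protein_tag}, plus attribute
#'   \code{tag_length}.
#' @export
pba_panel <- function(antibody_name, protein_tag) {
  antibody_name <- as.character(antibody_name)
  protein_tag <- toupper(as.character(protein_tag))
  if (length(antibody_name) != length(protein_tag))
    stop("antibody_name and protein_tag must have equal length")
  if (length(antibody_name) < 2L)
    stop("a panel needs at least 2 entries")
  if (anyDuplicated(antibody_name))
    stop("antibody names must be unique")
  if (anyDuplicated(protein_tag))
    stop("protein tags must be unique")
  lens <- unique(nchar(protein_tag))
  if (length(lens) != 1L)
    stop("all protein tags must have the same length")
  if (any(grepl("[^ACGT]", protein_tag)))
    stop("protein tags must use alphabet {A,C,G,T}")
  panel <- data.frame(antibody_name = antibody_name,
                      protein_tag = protein_tag,
                      stringsAsFactors = FALSE)
  attr(panel, "tag_length") <- lens
  class(panel) <- c("pba_panel", "data.frame")
  panel
}

#' @export
print.pba_panel <- function(x, ...) {
  cat(sprintf("PBA antibody panel: %d antibodies, %d-nt protein tags\n",
              nrow(x), attr(x, "tag_length")))
  cat("  ", paste(utils::head(x$antibody_name, 8), collapse = ", "),
      if (nrow(x) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Tag length of a panel
#' @param panel a \code{pba_panel}.
#' @return integer tag length in nt.
#' @export
tag_length <- function(panel) attr(panel, "tag_length")

# Marker names used by the packaged CRC-style cohort fixture. The first
# entries are EV-surface / cancer / immune markers commonly profiled on
# plasma extracellular vesicles; the list is padded with generic names to
# the requested panel size.
ev_marker_names <- function(n) {
  known <- c(
    "ITGA6", "ITGB3", "ADAM10", "CD151", "CD9", "ERBB2", "EPS8", "ILK",
    "RIOX2", "ITGAM", "ITGAL", "ITGB2", "NT5E", "CCR2", "THY1", "TIMP1",
    "MMP2", "CD63", "CD81", "CD37", "CD82", "EPCAM", "EGFR", "CEACAM5",
    "MUC1", "CD44", "CD24", "CD47", "PDL1", "HLA-A", "CD3E", "CD4",
    "CD8A", "CD14", "CD19", "CD20", "CD31", "CD41", "CD45", "CD56",
    "GPC1", "FLOT1", "FLOT2", "TSG101", "SDCBP", "ANXA5", "LAMP1",
    "ICAM1", "VCAM1", "SELP", "ITGB1", "ITGA2", "ITGA4", "ITGAV",
    "TSPAN8", "CLDN3", "CDH1", "CDH2", "VIM", "FAP", "PDGFRB", "KIT",
    "MET", "AXL", "NOTCH1", "DLL4", "WNT5A", "FZD7", "LRP6", "TGFBR1"
  )
  if (n <= length(known)) return(known[seq_len(n)])
  c(known, sprintf("MARKER%03d", seq_len(n - length(known))))
}

#' Packaged CRC-study-style antibody panel
#'
#' Builds a deterministic panel of EV-surface markers with protein tags that
#' are mutually separated by Hamming distance >= 3, so that one-mismatch tag
#' matching is unambiguous.
#'
#' @param n_antibodies panel size (default 115 markers).
#' @param tag_length protein-tag length in nt (default 8).
#' @return a \code{pba_panel}.
#' @export
crc_panel <- function(n_antibodies = 115L, tag_length = 8L) {
  tags <- generate_separated_tags(n_antibodies, tag_length,
                                  min_dist = 3L, seed = 7041L)
  pba_panel(ev_marker_names(n_antibodies), tags)
}

# Greedy Gilbert-Varshamov-style tag design: draw random tags under a fixed
# local seed, keep those at Hamming distance >= min_dist from all kept tags.
generate_separated_tags <- function(n, len, min_dist = 3L, seed = 1L) {
  stopifnot(4^len > 50 * n)
  kept_mat <- matrix(integer(0), nrow = 0, ncol = len)
  with_preserved_seed(seed, {
    while (nrow(kept_mat) < n) {
      cand <- sample.int(4L, len, replace = TRUE)
      if (nrow(kept_mat) == 0L ||
          min(rowSums(kept_mat != rep(cand, each = nrow(kept_mat)))) >= min_dist) {
        kept_mat <- rbind(kept_mat, cand)
      }
    }
  })
  apply(kept_mat, 1L, function(r) paste(c("A", "C", "G", "T")[r], collapse = ""))
}

# Run code under a given RNG seed, restoring the caller's RNG state after.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Read an antibody panel from TSV
#'
#' Expects columns \code{antibody_name} and \code{protein_tag}.
#' @param path path to a tab-separated file.
#' @return a \code{pba_panel}.
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("antibody_name", "protein_tag") %in% names(df)))
    stop("panel TSV must have columns antibody_name and protein_tag: ", path)
  pba_panel(df$antibody_name, df$protein_tag)
}

#' Write an antibody panel to TSV
#' @param panel a \code{pba_panel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(as.data.frame(panel)[, c("antibody_name", "protein_tag")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
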