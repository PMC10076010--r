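#' Read field layout
#'
#' Describes where each field sits inside a single-end PBA read, as 0-based
#' half-open \code{[start, end)} offsets. The default layout places an 8-nt
#' protein tag, a 10-nt UMI, a 12-nt anchor (primer-binding) sequence and a
#' 15-nt exosome tag at the 5' end of a 75-nt read; the remainder is padding.
#'
#' @param protein_tag,umi,anchor,exosome_tag integer length-2 vectors
#'   \code{c(start, end)}, 0-based half-open.
#' @param read_length total read length in nt.
#' @return an object of class \code{read_layout}.
#' @export
read_layout <- function(protein_tag = c(0L, 8L),
                        umi = c(8L, 18L),
                        anchor = c(18L, 30L),
                        exosome_tag = c(30L, 45L),
                        read_length = 75L) {
  spans <- list(protein_tag = as.integer(protein_tag),
                umi = as.integer(umi),
                anchor = as.integer(anchor),
                exosome_tag = as.integer(exosome_tag))
  for (nm in names(spans)) {
    sp <- spans[[nm]]
    if (length(sp) != 2L || sp[1] < 0L || sp[2] <= sp[1])
      stop("invalid span for ", nm, ": must be c(start, end) with end > start >= 0")
    if (sp[2] > read_length)
      stop("span for ", nm, " exceeds read_length ", read_length)
  }
  ir <- do.call(rbind, spans)
  o <- order(ir[, 1])
  if (any(ir[o, 2][-nrow(ir)] > ir[o, 1][-1]))
    stop("read layout spans overlap")
  if (span_len(spans$umi) < 6L) stop("UMI must be at least 6 nt")
  if (span_len(spans$exosome_tag) < 10L) stop("exosome tag must be at least 10 nt")
  structure(c(spans, list(read_length = as.integer(read_length))),
            class = "read_layout")
}

span_len <- function(span) span[2] - span[1]

# total extent needed to parse a read under this layout
layout_span <- function(layout) {
  max(layout$protein_tag[2], layout$umi[2], layout$anchor[2],
      layout$exosome_tag[2])
}

#' @export
print.read_layout <- function(x, ...) {
  cat(sprintf("PBA read layout (%d nt):\n", x$read_length))
  for (nm in c("protein_tag", "umi", "anchor", "exosome_tag"))
    cat(sprintf("  %-12s [%2d, %2d)  %d nt\n", nm, x[[nm]][1], x[[nm]][2],
                span_len(x[[nm]])))
  invisible(x)
}

# slice a field out of a character vector of reads (vectorized)
slice_field <- function(seqs, span) substr(seqs, span[1] + 1L, span[2])
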