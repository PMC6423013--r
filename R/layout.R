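#' Single-end duplex-UMI read-1 layout
#'
#' Describes the fixed prefix of read 1 in a single-end duplex-UMI library:
#' a 12-nt random UMI, a constant spacer, the 2-nt strand barcode (`TT` =
#' original top strand; the bottom-strand `GG` barcode is read as `CC`
#' during sequencing), a second constant spacer, and then the genomic
#' insert. With the default geometry the insert begins at 0-based offset 35.
#'
#' @param umi_length UMI length in bases.
#' @param spacer1 Constant sequence between the UMI and the strand barcode.
#' @param barcode_top Barcode observed for reads from the original top strand.
#' @param barcode_bottom Barcode observed (as sequenced) for reads from the
#'   original bottom strand.
#' @param spacer2 Constant sequence between the strand barcode and the insert.
#' @return A `read_layout` object carrying the segment sequences and their
#'   0-based half-open offsets within read 1 (`umi` at `[0, umi_length)`,
#'   then spacer1, barcode, spacer2; `insert_offset` marks the first insert
#'   base).
#' @examples
#' layout <- read_layout()
#' layout$insert_offset  # 35
#' @export
read_layout <- function(umi_length = 12L,
                        spacer1 = "TTCTGAGCGA",
                        barcode_top = "TT",
                        barcode_bottom = "CC",
                        spacer2 = "ATAGGAGTCCT") {
  umi_length <- as.integer(umi_length)
  stopifnot(umi_length > 0L,
            nchar(barcode_top) == nchar(barcode_bottom),
            barcode_top != barcode_bottom)
  l <- list(umi_length = umi_length, spacer1 = spacer1,
            barcode_top = barcode_top, barcode_bottom = barcode_bottom,
            spacer2 = spacer2)
  l$umi_start <- 0L
  l$umi_end <- umi_length
  l$spacer1_start <- l$umi_end
  l$spacer1_end <- l$spacer1_start + nchar(spacer1)
  l$barcode_start <- l$spacer1_end
  l$barcode_end <- l$barcode_start + nchar(barcode_top)
  l$spacer2_start <- l$barcode_end
  l$spacer2_end <- l$spacer2_start + nchar(spacer2)
  l$insert_offset <- l$spacer2_end
  structure(l, class = "read_layout")
}

#' @export
print.read_layout <- function(x, ...) {
  cat("read 1 layout: UMI[0,", x$umi_end, ") + ", x$spacer1, " + ",
      x$barcode_top, "/", x$barcode_bottom, " + ", x$spacer2,
      " + insert (offset ", x$insert_offset, ")\n", sep = "")
  invisible(x)
}

# reverse complement of a character vector of DNA strings
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement of single-base characters, vectorised
comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

DNA_BASES <- c("A", "C", "G", "T")

#' The 12 base-substitution types
#'
#' All ordered (reference, alternative) base pairs, written `"A>G"` etc.
#' Types are in the polymerase frame: the reference base is the template
#' base the polymerase read, so a bottom-strand family observed as `G>T`
#' in reference coordinates contributes to the `C>A` type.
#' @return Character vector of length 12.
#' @export
substitution_types <- function() {
  g <- expand.grid(ref = DNA_BASES, alt = DNA_BASES, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, ]
  sort(paste0(g$ref, ">", g$alt))
}
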