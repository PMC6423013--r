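#' Define an amplicon panel
#'
#' A panel is a set of single-primer-extension loci on a reference sequence.
#' Each locus has a gene-specific primer and a target interval to be
#' analysed. All coordinates are 0-based half-open internally.
#'
#' For a `+` locus the primer anneals at `primer_start` and extends right;
#' the fragment's fixed end is the primer end and the random fragmentation
#' (adapter-ligated, UMI-bearing) end is on the right. For a `-` locus the
#' geometry is mirrored: the primer's 5' position is `primer_start`
#' (exclusive right end of the fragment) and the ligated end is on the left.
#'
#' @param loci data.frame with columns `locus_id`, `chrom`, `primer_start`,
#'   `primer_strand` (`"+"`/`"-"`), `target_start`, `target_end`.
#' @param reference Named character vector of chromosome sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return A `panel_design` object.
#' @export
panel_design <- function(loci, reference) {
  loci <- as.data.table(loci)
  need <- c("locus_id", "chrom", "primer_start", "primer_strand",
            "target_start", "target_end")
  if (!all(need %in% names(loci)))
    stop("panel loci must have columns: ", paste(need, collapse = ", "))
  if (nrow(loci) == 0L) stop("panel must contain at least one locus")
  if (anyDuplicated(loci$locus_id)) stop("locus_ids must be unique")
  if (inherits(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  if (is.null(names(reference)) || any(!nzchar(names(reference))))
    stop("reference sequences must be named by chromosome")
  if (!all(loci$chrom %in% names(reference)))
    stop("panel chromosomes missing from reference")
  chrlen <- nchar(reference)[loci$chrom]
  if (any(loci$target_end <= loci$target_start))
    stop("target intervals must be non-empty")
  if (any(loci$target_start < 0L) || any(loci$target_end > chrlen))
    stop("target intervals must lie within the reference")
  if (!all(loci$primer_strand %in% c("+", "-")))
    stop("primer_strand must be '+' or '-'")
  loci[, `:=`(primer_start = as.integer(primer_start),
              target_start = as.integer(target_start),
              target_end = as.integer(target_end))]
  structure(list(loci = loci[], reference = reference),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat("amplicon panel:", nrow(x$loci), "loci,",
      sum(x$loci$target_end - x$loci$target_start), "target bp on",
      length(x$reference), "reference sequence(s)\n")
  invisible(x)
}

#' Generate a random panel on a synthetic reference
#'
#' Convenience constructor used by the simulator and the test-suite: builds
#' a random reference sequence and evenly spaced single-primer loci.
#'
#' @param n_loci Number of loci.
#' @param target_length Target interval length per locus (bp).
#' @param target_offset Distance from the primer anchor to the target
#'   interval. With ~170 bp fragments sequenced 150 bp from the ligated
#'   end, read-1 inserts cover the band 90-140 bp beyond the primer with
#'   high probability, so the default target sits there.
#' @param primer_length Gene-specific primer length (bp).
#' @param spacing Distance between consecutive primer starts (bp).
#' @param strands Primer strands, recycled across loci.
#' @param chrom Chromosome name.
#' @param seed Optional RNG seed.
#' @return A [panel_design()] object.
#' @export
random_panel <- function(n_loci = 2L, target_length = 50L,
                         target_offset = 90L,
                         primer_length = 20L, spacing = 400L,
                         strands = "+", chrom = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  margin <- 320L
  ref_len <- 2L * margin + n_loci * spacing
  ref <- paste(sample(DNA_BASES, ref_len, replace = TRUE), collapse = "")
  strands <- rep_len(strands, n_loci)
  loci <- data.table(
    locus_id = sprintf("locus%02d", seq_len(n_loci)),
    chrom = chrom,
    primer_strand = strands
  )
  anchor <- margin + (seq_len(n_loci) - 1L) * spacing
  loci[, primer_start := anchor]
  loci[primer_strand == "+",
       `:=`(target_start = primer_start + target_offset,
            target_end = primer_start + target_offset + target_length)]
  loci[primer_strand == "-",
       `:=`(target_start = primer_start - target_offset - target_length,
            target_end = primer_start - target_offset)]
  panel_design(loci, setNames(ref, chrom))
}

#' All target sites of a panel
#'
#' @param panel A [panel_design()].
#' @return data.table with columns `chrom`, `pos` (0-based), `ref`.
#' @export
target_sites <- function(panel) {
  sites <- panel$loci[, .(pos = seq(target_start, target_end - 1L)),
                      by = .(locus_id, chrom)]
  sites <- unique(sites[, .(chrom, pos)])
  sites[, ref := ref_base_at(panel$reference, chrom, pos)]
  setkey(sites, chrom, pos)
  sites[]
}

# reference base at 0-based positions, vectorised
ref_base_at <- function(reference, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- substring(reference[[ch]], pos[i] + 1L, pos[i] + 1L)
  }
  out
}

#' Homopolymer runs of a reference
#'
#' @param reference Named character vector of sequences.
#' @param min_run Minimum run length to report.
#' @return data.table with `chrom`, `run_start`, `run_end` (0-based
#'   half-open) for every run of identical bases of length >= `min_run`.
#' @export
homopolymer_runs <- function(reference, min_run = 5L) {
  out <- lapply(names(reference), function(ch) {
    r <- rle(strsplit(reference[[ch]], "")[[1]])
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= min_run
    if (!any(keep)) return(NULL)
    data.table(chrom = ch,
               run_start = as.integer(ends[keep] - r$lengths[keep]),
               run_end = as.integer(ends[keep]))
  })
  out <- rbindlist(out)
  if (nrow(out) == 0L)
    out <- data.table(chrom = character(), run_start = integer(),
                      run_end = integer())
  out[]
}

#' Write / read a panel definition
#'
#' The panel is stored as a TSV of loci plus a FASTA reference; target
#' intervals can additionally be exported as BED.
#'
#' @param panel A [panel_design()].
#' @param loci_path Path of the loci TSV.
#' @param fasta_path Path of the reference FASTA.
#' @return `write_panel` returns the paths invisibly; `read_panel` returns
#'   a [panel_design()].
#' @export
write_panel <- function(panel, loci_path, fasta_path) {
  fwrite(panel$loci, loci_path, sep = "\t")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(panel$reference), fasta_path)
  invisible(c(loci_path, fasta_path))
}

#' @rdname write_panel
#' @export
read_panel <- function(loci_path, fasta_path) {
  loci <- fread(loci_path)
  ref <- Biostrings::readDNAStringSet(fasta_path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  panel_design(loci, ref)
}

#' Export the panel target intervals as BED
#'
#' @param panel A [panel_design()].
#' @param path Output BED path.
#' @export
write_target_bed <- function(panel, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = panel$loci$chrom,
    ranges = IRanges::IRanges(start = panel$loci$target_start + 1L,
                              end = panel$loci$target_end),
    name = panel$loci$locus_id)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# gene-specific primer sequence of each locus (reference orientation window)
locus_primer_seq <- function(panel, primer_length = 20L) {
  l <- panel$loci
  out <- character(nrow(l))
  for (i in seq_len(nrow(l))) {
    if (l$primer_strand[i] == "+") {
      out[i] <- substring(panel$reference[[l$chrom[i]]],
                          l$primer_start[i] + 1L,
                          l$primer_start[i] + primer_length)
    } else {
      s <- substring(panel$reference[[l$chrom[i]]],
                     l$primer_start[i] - primer_length + 1L,
                     l$primer_start[i])
      out[i] <- revcomp(s)
    }
  }
  out
}
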