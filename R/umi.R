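#' Family merging configuration
#'
#' A UMI family with a much smaller read count is merged into a much larger
#' family when their UMIs are within one edit distance and their random
#' fragmentation sites are within 5 bp; "much smaller" is quantified as a
#' configurable count ratio.
#'
#' @param max_umi_distance Maximum Hamming distance between UMIs (0 or 1;
#'   indels inside the fixed-length UMI slot shift the spacer and are
#'   rejected at decoding instead).
#' @param max_frag_pos_delta Maximum fragmentation-position difference (bp).
#' @param min_count_ratio Minimum large:small read count ratio for a merge.
#' @return A `merge_config` object.
#' @export
merge_config <- function(max_umi_distance = 1L, max_frag_pos_delta = 5L,
                         min_count_ratio = 5) {
  stopifnot(max_umi_distance %in% c(0L, 1L), max_frag_pos_delta >= 0,
            min_count_ratio > 1)
  structure(list(max_umi_distance = as.integer(max_umi_distance),
                 max_frag_pos_delta = as.integer(max_frag_pos_delta),
                 min_count_ratio = min_count_ratio),
            class = "merge_config")
}

# positionwise mismatch count between equal-length strings and one pattern
string_mismatches <- function(x, pattern) {
  mm <- integer(length(x))
  for (j in seq_len(nchar(pattern)))
    mm <- mm + (substr(x, j, j) != substr(pattern, j, j))
  mm
}

#' Decode UMI and strand barcode from read-1 sequences
#'
#' Splits the fixed read-1 prefix into UMI, spacers and strand barcode.
#' Each spacer tolerates at most one mismatch (sequencing-error robustness);
#' the 2-nt barcode must match exactly because it is the strand signal.
#' Failures are tallied, not raised: the `reject` column carries
#' `TOO_SHORT`, `BAD_SPACER` or `BAD_BARCODE`.
#'
#' @param read1 Character vector of read-1 sequences.
#' @param layout A [read_layout()].
#' @return data.table with one row per read: `umi`, `strand_label`
#'   (`"TOP"`/`"BOTTOM"`/NA), `insert_offset`, `reject` (NA when accepted).
#' @export
extract_umi_strand <- function(read1, layout = read_layout()) {
  n <- nchar(read1)
  out <- data.table(
    umi = substr(read1, layout$umi_start + 1L, layout$umi_end),
    strand_label = NA_character_,
    insert_offset = layout$insert_offset,
    reject = NA_character_)
  too_short <- n < layout$insert_offset + 1L
  sp1 <- substr(read1, layout$spacer1_start + 1L, layout$spacer1_end)
  sp2 <- substr(read1, layout$spacer2_start + 1L, layout$spacer2_end)
  bad_spacer <- string_mismatches(sp1, layout$spacer1) > 1L |
    string_mismatches(sp2, layout$spacer2) > 1L
  bc <- substr(read1, layout$barcode_start + 1L, layout$barcode_end)
  out[bc == layout$barcode_top, strand_label := "TOP"]
  out[bc == layout$barcode_bottom, strand_label := "BOTTOM"]
  bad_bc <- is.na(out$strand_label)
  out[bad_bc & !too_short & !bad_spacer, reject := "BAD_BARCODE"]
  out[bad_spacer & !too_short, reject := "BAD_SPACER"]
  out[too_short, reject := "TOO_SHORT"]
  out[!is.na(reject), `:=`(strand_label = NA_character_,
                           umi = NA_character_,
                           insert_offset = NA_integer_)]
  out[]
}

#' Tag reads with UMI, strand and alignment annotations
#'
#' Combines barcode decoding with read placements (the simulator truth
#' alignment table, or any table with the same columns derived from an
#' aligner) and compares each read's genomic insert with the reference to
#' produce per-read mismatch events. Alignment is consumed, not computed.
#'
#' @param reads data.table with `read_id`, `r1` and optionally `q1`
#'   (a `read_set` from [tag_and_sequence()] is accepted directly).
#' @param align data.table with `read_id`, `chrom`, `r1_start`, `r1_end`,
#'   `r1_orient` (`"+"` insert bases ascend the reference from `r1_start`,
#'   `"-"` the insert is the reverse complement), `locus_id`, `frag_pos`,
#'   and optionally `sample_id`, `mapq`.
#' @param panel A [panel_design()] supplying the reference.
#' @param layout A [read_layout()].
#' @param sample_id Used when `align` has no `sample_id` column.
#' @return A `tagged_reads` object: list with `reads` (one row per accepted
#'   read: key fields plus `start`/`end` insert coverage, `mapq`,
#'   `mismatch_count`, `median_qual`), `events` (per-read reference
#'   mismatches: `read_id`, `pos`, `base`, `qual`) and `rejects` (named
#'   count vector by reason).
#' @export
tag_reads <- function(reads, align, panel, layout = read_layout(),
                      sample_id = "S1") {
  if (inherits(reads, "read_set")) {
    if (missing(align)) align <- reads$truth_align
    reads <- reads$reads
  }
  reads <- as.data.table(reads)
  align <- as.data.table(align)
  if (!"q1" %in% names(reads)) reads[, qline := strrep("I", nchar(r1))]
  else setnames(copy(reads), "q1", "qline") -> reads
  dec <- extract_umi_strand(reads$r1, layout)
  rejects <- table(dec$reject)
  keep <- is.na(dec$reject)
  tg <- data.table(read_id = reads$read_id[keep],
                   umi = dec$umi[keep],
                   strand_label = dec$strand_label[keep],
                   r1 = reads$r1[keep], qline = reads$qline[keep])
  tg <- merge(tg, align, by = "read_id")
  if (!"sample_id" %in% names(tg)) tg[, sample_id := ..sample_id]
  if (!"mapq" %in% names(tg)) tg[, mapq := 60L]

  ## genomic insert in reference frame
  width <- pmin(tg$r1_end - tg$r1_start,
                nchar(tg$r1) - layout$insert_offset)
  tg[, `:=`(start = fifelse(r1_orient == "+", r1_start, r1_end - width),
            end = fifelse(r1_orient == "+", r1_start + width, r1_end))]
  ins <- substr(tg$r1, layout$insert_offset + 1L,
                layout$insert_offset + width)
  ins[tg$r1_orient == "-"] <- revcomp(ins[tg$r1_orient == "-"])
  refwin <- substring_by_chrom(panel$reference, tg$chrom, tg$start, tg$end)

  exact <- ins == refwin
  events <- NULL
  if (any(!exact)) {
    ix <- which(!exact)
    evl <- vector("list", length(ix))
    for (k in seq_along(ix)) {
      i <- ix[k]
      a <- strsplit(ins[i], "")[[1]]
      b <- strsplit(refwin[i], "")[[1]]
      d <- which(a != b)
      if (!length(d)) next
      ## read-frame position of each mismatched insert base, for quality
      w <- length(a)
      rp <- if (tg$r1_orient[i] == "+") layout$insert_offset + d
            else layout$insert_offset + (w - d + 1L)
      q <- utf8ToInt(tg$qline[i])[rp] - 33L
      evl[[k]] <- data.table(read_id = tg$read_id[i],
                             pos = tg$start[i] + d - 1L,
                             base = a[d], qual = as.integer(q))
    }
    events <- rbindlist(evl)
  }
  if (is.null(events) || nrow(events) == 0L)
    events <- data.table(read_id = character(), pos = integer(),
                         base = character(), qual = integer())
  mmc <- events[, .(mm = .N), by = read_id]
  tg <- merge(tg, mmc, by = "read_id", all.x = TRUE)
  tg[is.na(mm), mm := 0L]
  setnames(tg, "mm", "mismatch_count")
  ## representative base quality per read; quality strings are few in
  ## simulated data so compute per unique string
  uq <- unique(tg$qline)
  mq <- vapply(uq, function(s) as.integer(median(utf8ToInt(s) - 33L)), 1L)
  tg[, median_qual := mq[match(qline, uq)]]
  tagged <- tg[, .(read_id, sample_id, locus_id, chrom, frag_pos, umi,
                   strand_label, start, end, mapq, mismatch_count,
                   median_qual)]
  structure(list(reads = tagged, events = events,
                 rejects = rejects, panel = panel),
            class = "tagged_reads")
}

#' Group tagged reads into UMI families
#'
#' Partitions reads by the full family key
#' (`sample_id`, `locus_id`, `frag_pos`, `umi`, `strand_label`); the sample
#' index is part of the key to avoid barcode collisions between molecules
#' from different libraries.
#'
#' @param tagged A `tagged_reads` object from [tag_reads()].
#' @return A `umi_families` object: list with `families` (one row per
#'   family: key fields, `family_id`, `read_count`), `reads` (with
#'   `family_id` attached), `events`, `panel`.
#' @export
group_families <- function(tagged) {
  stopifnot(inherits(tagged, "tagged_reads"))
  rd <- copy(tagged$reads)
  setorder(rd, sample_id, locus_id, chrom, frag_pos, umi, strand_label,
           read_id)
  rd[, family_id := .GRP,
     by = .(sample_id, locus_id, chrom, frag_pos, umi, strand_label)]
  fams <- rd[, .(read_count = .N),
             by = .(family_id, sample_id, locus_id, chrom, frag_pos, umi,
                    strand_label)]
  structure(list(families = fams[], reads = rd[], events = tagged$events,
                 rejects = tagged$rejects, panel = tagged$panel),
            class = "umi_families")
}

hamming_ball <- function(umi) {
  k <- nchar(umi)
  out <- character(1L + 3L * k)
  out[1L] <- umi
  n <- 1L
  for (j in seq_len(k)) {
    old <- substr(umi, j, j)
    for (b in DNA_BASES) {
      if (b == old) next
      s <- umi
      substr(s, j, j) <- b
      n <- n + 1L
      out[n] <- s
    }
  }
  out[seq_len(n)]
}

#' Merge near-duplicate UMI families
#'
#' Within each (sample, locus, strand) stratum, families are visited in
#' descending read count (ties broken by UMI); a family is absorbed into an
#' already-retained family when their UMIs are within the configured Hamming
#' distance, their fragmentation positions differ by at most
#' `max_frag_pos_delta` bp, and the retained family is at least
#' `min_count_ratio` times larger. Merging is single pass: an absorbed
#' family never absorbs others, and the merged family keeps the larger
#' family's key (including its fragmentation position).
#'
#' @param ufams A `umi_families` object from [group_families()].
#' @param cfg A [merge_config()].
#' @return A `umi_families` object with updated `families` and read
#'   assignments; absorbed families are recorded in `merges`
#'   (`family_id` -> `merged_into`).
#' @export
merge_families <- function(ufams, cfg = merge_config()) {
  stopifnot(inherits(ufams, "umi_families"))
  fams <- copy(ufams$families)
  fams[, merged_into := NA_integer_]
  strata <- split(seq_len(nrow(fams)),
                  fams[, paste(sample_id, locus_id, chrom, strand_label,
                               sep = "\r")])
  for (rows in strata) {
    if (length(rows) < 2L) next
    f <- fams[rows]
    ord <- order(-f$read_count, f$umi)
    kept <- new.env(parent = emptyenv())
    for (i in ord) {
      cand <- if (cfg$max_umi_distance >= 1L) hamming_ball(f$umi[i])
              else f$umi[i]
      hits <- integer(0)
      for (u in cand) {
        v <- kept[[u]]
        if (!is.null(v)) hits <- c(hits, v)
      }
      hits <- hits[abs(f$frag_pos[hits] - f$frag_pos[i]) <=
                     cfg$max_frag_pos_delta &
                   f$read_count[hits] >= cfg$min_count_ratio * f$read_count[i]]
      if (length(hits)) {
        j <- hits[which.max(f$read_count[hits])]
        fams$merged_into[rows[i]] <- fams$family_id[rows[j]]
      } else {
        kept[[f$umi[i]]] <- c(kept[[f$umi[i]]], i)
      }
    }
  }
  merges <- fams[!is.na(merged_into), .(family_id, merged_into)]
  rd <- copy(ufams$reads)
  if (nrow(merges)) {
    rd[merges, family_id := i.merged_into, on = "family_id"]
    absorbed <- fams[!is.na(merged_into),
                     .(extra = sum(read_count)), by = .(merged_into)]
    fams[absorbed, read_count := read_count + i.extra,
         on = .(family_id = merged_into)]
    fams <- fams[is.na(merged_into)]
  }
  fams[, merged_into := NULL]
  structure(list(families = fams[], reads = rd[], events = ufams$events,
                 rejects = ufams$rejects, panel = ufams$panel,
                 merges = merges[]),
            class = "umi_families")
}

#' Pair UMI families into duplex groups
#'
#' Within (sample, locus, UMI), a TOP and a BOTTOM family whose
#' fragmentation positions differ by at most `max_frag_pos_delta` bp derive
#' from the two strands of one original molecule and form a DUPLEX group
#' (greedy nearest-position pairing). Unpaired families become SINGLEPLEX
#' groups; every family lands in exactly one group.
#'
#' @param ufams A `umi_families` object (post-merge).
#' @param max_frag_pos_delta Pairing tolerance in bp (the family-merge
#'   tolerance is reused by default).
#' @return A `duplex_groups` object: list with `groups` (`group_id`,
#'   `classification`, key fields, `top_family`, `bottom_family`),
#'   `families` (with `group_id`), `reads`, `events`, `panel`.
#' @export
pair_duplex <- function(ufams, max_frag_pos_delta = 5L) {
  stopifnot(inherits(ufams, "umi_families"))
  fams <- copy(ufams$families)
  if (nrow(fams) == 0L) stop("no families to pair")
  fams[, kid := .GRP, by = .(sample_id, locus_id, chrom, umi)]
  cnt <- fams[, .(n = .N, ntop = sum(strand_label == "TOP")), by = kid]
  simple <- cnt[n == 2L & ntop == 1L, kid]
  lone <- cnt[n == 1L, kid]
  complex_k <- cnt[!(kid %in% c(simple, lone)), kid]

  ## common case: exactly one family per strand
  sf <- fams[kid %in% simple]
  setorder(sf, kid, strand_label)  # BOTTOM then TOP
  wide <- sf[, .(bot = family_id[1L], top = family_id[2L],
                 bpos = frag_pos[1L], tpos = frag_pos[2L],
                 sample_id = sample_id[1L], locus_id = locus_id[1L],
                 chrom = chrom[1L], umi = umi[1L]), by = kid]
  wide[, ok := abs(tpos - bpos) <= max_frag_pos_delta]
  gsimple <- rbind(
    wide[ok == TRUE, .(classification = "DUPLEX", sample_id, locus_id,
                       chrom, umi, top_family = top, bottom_family = bot,
                       frag_pos = pmin(tpos, bpos))],
    wide[ok == FALSE, .(classification = "SINGLEPLEX", sample_id, locus_id,
                        chrom, umi, top_family = top,
                        bottom_family = NA_integer_, frag_pos = tpos)],
    wide[ok == FALSE, .(classification = "SINGLEPLEX", sample_id, locus_id,
                        chrom, umi, top_family = NA_integer_,
                        bottom_family = bot, frag_pos = bpos)])
  lf <- fams[kid %in% lone]
  glone <- lf[, .(classification = "SINGLEPLEX", sample_id, locus_id, chrom,
                  umi,
                  top_family = fifelse(strand_label == "TOP", family_id,
                                       NA_integer_),
                  bottom_family = fifelse(strand_label == "BOTTOM",
                                          family_id, NA_integer_),
                  frag_pos)]

  ## rare case: several families share a key; greedy nearest-position pairing
  glist <- list()
  for (k in complex_k) {
    f <- fams[kid == k]
    tops <- which(f$strand_label == "TOP")
    bots <- which(f$strand_label == "BOTTOM")
    paired_t <- logical(length(tops)); paired_b <- logical(length(bots))
    if (length(tops) && length(bots)) {
      cand <- CJ(ti = seq_along(tops), bi = seq_along(bots))
      cand[, d := abs(f$frag_pos[tops[ti]] - f$frag_pos[bots[bi]])]
      cand <- cand[d <= max_frag_pos_delta][order(d, ti, bi)]
      for (j in seq_len(nrow(cand))) {
        ti <- cand$ti[j]; bi <- cand$bi[j]
        if (paired_t[ti] || paired_b[bi]) next
        paired_t[ti] <- TRUE; paired_b[bi] <- TRUE
        glist[[length(glist) + 1L]] <- data.table(
          classification = "DUPLEX", sample_id = f$sample_id[1L],
          locus_id = f$locus_id[1L], chrom = f$chrom[1L], umi = f$umi[1L],
          top_family = f$family_id[tops[ti]],
          bottom_family = f$family_id[bots[bi]],
          frag_pos = min(f$frag_pos[tops[ti]], f$frag_pos[bots[bi]]))
      }
    }
    for (i in c(tops[!paired_t], bots[!paired_b])) {
      glist[[length(glist) + 1L]] <- data.table(
        classification = "SINGLEPLEX", sample_id = f$sample_id[1L],
        locus_id = f$locus_id[1L], chrom = f$chrom[1L], umi = f$umi[1L],
        top_family = if (f$strand_label[i] == "TOP") f$family_id[i]
                     else NA_integer_,
        bottom_family = if (f$strand_label[i] == "BOTTOM") f$family_id[i]
                        else NA_integer_,
        frag_pos = f$frag_pos[i])
    }
  }
  groups <- rbindlist(c(list(gsimple, glone), glist))
  groups[, group_id := .I]
  setcolorder(groups, "group_id")
  ## map families to their group
  gmap <- rbind(
    groups[!is.na(top_family), .(family_id = top_family, group_id)],
    groups[!is.na(bottom_family), .(family_id = bottom_family, group_id)])
  fams[, kid := NULL]
  fams[, group_id := NA_integer_]
  fams[gmap, group_id := i.group_id, on = "family_id"]
  structure(list(groups = groups[], families = fams[], reads = ufams$reads,
                 events = ufams$events, rejects = ufams$rejects,
                 panel = ufams$panel),
            class = "duplex_groups")
}

#' @export
print.duplex_groups <- function(x, ...) {
  nd <- sum(x$groups$classification == "DUPLEX")
  cat("duplex groups:", nrow(x$groups), "UMI groups (", nd, "duplex,",
      nrow(x$groups) - nd, "single-plex ), duplex fraction",
      round(duplex_fraction(x), 4), "\n")
  invisible(x)
}

#' Duplex share of observed UMIs
#'
#' The fraction of UMI groups (observed molecules) with evidence from both
#' strands. With independent per-strand capture probability `s` this
#' converges to `s / (2 - s)`.
#'
#' @param groups A `duplex_groups` object.
#' @return A single numeric fraction.
#' @export
duplex_fraction <- function(groups) {
  mean(groups$groups$classification == "DUPLEX")
}

#' Run UMI processing end to end
#'
#' Decode, tag, group, merge and pair: FASTQ-level input to duplex groups.
#'
#' @param reads A `read_set`, or a data.table of reads (see [tag_reads()]).
#' @param align Alignment table; defaults to the read set's truth table.
#' @param panel A [panel_design()].
#' @param layout A [read_layout()].
#' @param merge_cfg A [merge_config()].
#' @param sample_id Sample identifier.
#' @return A `duplex_groups` object.
#' @export
process_reads <- function(reads, align = NULL, panel,
                          layout = read_layout(),
                          merge_cfg = merge_config(), sample_id = "S1") {
  if (inherits(reads, "read_set") && is.null(align))
    align <- reads$truth_align
  tg <- tag_reads(reads, align, panel, layout, sample_id)
  uf <- group_families(tg)
  uf <- merge_families(uf, merge_cfg)
  pair_duplex(uf, merge_cfg$max_frag_pos_delta)
}

#' Load reads from FASTQ plus an alignment table
#'
#' @param fastq1 Read-1 FASTQ path (gzip accepted).
#' @param align_path TSV with the alignment columns of [tag_reads()].
#' @return list(`reads`, `align`) ready for [tag_reads()].
#' @export
read_fastq_input <- function(fastq1, align_path) {
  ## metadata-column drop warning from the quality container is benign
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq1))
  reads <- data.table(read_id = sub("\\s.*$", "", names(x)),
                      r1 = as.character(x),
                      q1 = as.character(Biostrings::quality(x)))
  list(reads = reads, align = fread(align_path))
}

#' Read pre-aligned reads carrying UMI and strand tags from BAM
#'
#' Consumes a coordinate-sorted BAM in which the UMI and strand label are
#' stored in the `UM` and `SL` tags (strand as `TOP`/`BOTTOM` or `T`/`B`)
#' and, optionally, the ligated fragmentation position in `FP` (0-based).
#' Without `FP`, the ligated end is taken as the right alignment end for
#' reverse-strand reads and the left end otherwise. Only simple
#' fully-aligned records (CIGAR `<n>M`) are used; others are tallied as
#' rejects. Requires the Rsamtools package.
#'
#' @param bam BAM path.
#' @param panel A [panel_design()].
#' @param locus_map Optional data.table (`chrom`, `start`, `end`,
#'   `locus_id`) assigning reads to loci; defaults to panel target
#'   intervals extended 200 bp.
#' @param sample_id Sample identifier.
#' @return A `tagged_reads` object.
#' @export
read_tagged_bam <- function(bam, panel, locus_map = NULL, sample_id = "S1") {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_tagged_bam requires the Rsamtools package")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "mapq", "seq", "qual",
             "cigar"),
    tag = c("UM", "SL", "FP"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  dt <- data.table(read_id = b$qname, chrom = as.character(b$rname),
                   pos1 = b$pos, strand = as.character(b$strand),
                   mapq = b$mapq, r1 = as.character(b$seq),
                   q1 = as.character(b$qual), cigar = b$cigar,
                   umi = b$tag$UM, sl = b$tag$SL)
  fp <- b$tag$FP
  dt[, frag_pos := if (is.null(fp)) NA_integer_ else as.integer(fp)]
  ok <- grepl("^[0-9]+M$", dt$cigar) & !is.na(dt$umi) & !is.na(dt$sl)
  rejects <- c(BAD_RECORD = sum(!ok))
  dt <- dt[ok]
  dt[, width := nchar(r1)]
  dt[, `:=`(start = pos1 - 1L, end = pos1 - 1L + width)]
  dt[is.na(frag_pos),
     frag_pos := fifelse(strand == "-", end, start)]
  dt[, strand_label := fifelse(sl %in% c("TOP", "T"), "TOP", "BOTTOM")]
  if (is.null(locus_map)) {
    locus_map <- panel$loci[, .(chrom, lstart = pmax(0L, target_start - 200L),
                                lend = target_end + 200L, locus_id)]
  } else {
    locus_map <- as.data.table(locus_map)
    setnames(locus_map, c("start", "end"), c("lstart", "lend"),
             skip_absent = TRUE)
  }
  dt <- locus_map[dt, on = .(chrom, lstart <= start, lend >= end),
                  nomatch = NA,
                  .(read_id, chrom, locus_id, frag_pos, umi, strand_label,
                    start = i.start, end = i.end, mapq, r1, q1)]
  dt <- dt[!is.na(locus_id)]
  ## reuse the mismatch machinery of tag_reads via a synthetic layout with
  ## no prefix (BAM sequences are already bare genomic inserts)
  bare <- read_layout()
  pre <- paste0(strrep("A", bare$umi_length), bare$spacer1,
                bare$barcode_top, bare$spacer2)
  reads <- dt[, .(read_id, r1 = paste0(pre, r1),
                  q1 = paste0(strrep("I", nchar(pre)), q1))]
  align <- dt[, .(read_id, chrom, r1_start = start, r1_end = end,
                  r1_orient = "+", locus_id, frag_pos,
                  sample_id = ..sample_id, mapq)]
  tg <- tag_reads(reads, align, panel, bare, sample_id)
  ## restore the tag-derived UMI and strand label
  tg$reads[dt, `:=`(umi = i.umi, strand_label = i.strand_label),
           on = "read_id"]
  tg$rejects <- c(tg$rejects, rejects)
  tg
}
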