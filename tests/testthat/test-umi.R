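layout <- read_layout()
mk_read1 <- function(umi = "ACGTACGTACGT", sp1 = layout$spacer1, bc = "TT",
                     sp2 = layout$spacer2, insert = "ACGTACGTACGTACGT") {
  paste0(umi, sp1, bc, sp2, insert)
}

test_that("UMI and strand barcode decode from the fixed read-1 prefix", {
  r <- c(mk_read1(bc = "TT"), mk_read1(bc = "CC"))
  x <- extract_umi_strand(r, layout)
  expect_equal(x$umi, rep("ACGTACGTACGT", 2))
  expect_equal(x$strand_label, c("TOP", "BOTTOM"))
  expect_equal(x$insert_offset, rep(35L, 2))
  expect_true(all(is.na(x$reject)))
})

test_that("decoding rejects are tallied with the right reason codes", {
  r <- c(mk_read1(bc = "TC"),                          # undefined barcode
         mk_read1(bc = "GG"),                          # pre-sequencing form
         mk_read1(sp1 = "AAAAAAAAAA"),                 # mangled spacer
         substr(mk_read1(), 1, 30),                    # too short
         mk_read1(sp1 = "TACTGAGCGA"),                 # 1 mismatch: accept
         mk_read1(sp2 = "ATAGGACTCCT"))                # 1 mismatch: accept
  x <- extract_umi_strand(r, layout)
  expect_equal(x$reject[1:4],
               c("BAD_BARCODE", "BAD_BARCODE", "BAD_SPACER", "TOO_SHORT"))
  expect_true(all(is.na(x$reject[5:6])))
  expect_equal(x$strand_label[5:6], c("TOP", "TOP"))
  ## two mismatches in one spacer is over the tolerance
  y <- extract_umi_strand(mk_read1(sp1 = "TAATGAGCGA"), layout)
  expect_equal(y$reject, "BAD_SPACER")
})

test_that("grouping partitions reads by the full family key", {
  panel <- fixture_panel()
  spec <- data.table(
    umi = c("A", "A", "A", "B", "B", "C")[c(1, 2, 3, 4, 5, 6)],
    strand_label = c("TOP", "TOP", "TOP", "TOP", "BOTTOM", "TOP"),
    frag_pos = c(500L, 500L, 500L, 500L, 500L, 510L),
    n_reads = 1L)
  spec[, umi := strrep(umi, 12)]
  tg <- synth_tagged(spec[c(1, 4, 5, 6)], panel)
  uf <- group_families(tg)
  expect_equal(nrow(uf$families), 4L)
  ## identical keys collapse
  tg3 <- synth_tagged(data.table(umi = strrep("A", 12), strand_label = "TOP",
                                 frag_pos = 500L, n_reads = 3L), panel)
  uf3 <- group_families(tg3)
  expect_equal(nrow(uf3$families), 1L)
  expect_equal(uf3$families$read_count, 3L)
  ## strand label alone separates families
  tg2 <- synth_tagged(data.table(umi = strrep("A", 12),
                                 strand_label = c("TOP", "BOTTOM"),
                                 frag_pos = 500L, n_reads = 1L), panel)
  expect_equal(nrow(group_families(tg2)$families), 2L)
})

test_that("grouping is invariant to read order", {
  panel <- fixture_panel()
  spec <- data.table(umi = replicate(6, paste(sample(c("A", "C", "G", "T"),
                                                     12, TRUE),
                                              collapse = "")),
                     strand_label = rep(c("TOP", "BOTTOM"), 3),
                     frag_pos = rep(c(500L, 502L, 510L), each = 2),
                     n_reads = c(3L, 1L, 2L, 5L, 1L, 4L))
  tg <- synth_tagged(spec, panel)
  uf1 <- group_families(tg)
  tg_shuf <- tg
  set.seed(1)
  tg_shuf$reads <- tg$reads[sample(.N)]
  uf2 <- group_families(tg_shuf)
  cols <- c("umi", "strand_label", "frag_pos", "read_count")
  expect_equal(setorderv(copy(uf1$families), cols)[, ..cols],
               setorderv(copy(uf2$families), cols)[, ..cols])
})

test_that("family merging follows distance, position and ratio rules", {
  panel <- fixture_panel()
  ham1 <- function(u) { substr(u, 3, 3) <- "T"; u }
  uA <- strrep("A", 12)
  spec <- data.table(
    umi = c(uA, ham1(uA)), strand_label = "TOP",
    frag_pos = c(1000L, 1003L), n_reads = c(20L, 2L))
  uf <- merge_families(group_families(synth_tagged(spec, panel)))
  expect_equal(nrow(uf$families), 1L)
  expect_equal(uf$families$read_count, 22L)
  expect_equal(uf$families$umi, uA)       # larger family keeps its key
  expect_equal(uf$families$frag_pos, 1000L)
  expect_equal(uniqueN(uf$reads$family_id), 1L)

  ## ratio 10:3 < 5 -> no merge
  spec2 <- copy(spec)[, n_reads := c(10L, 3L)]
  expect_equal(nrow(merge_families(group_families(
    synth_tagged(spec2, panel)))$families), 2L)

  ## position delta 6 > 5 -> no merge
  spec3 <- copy(spec)[, frag_pos := c(1000L, 1006L)]
  expect_equal(nrow(merge_families(group_families(
    synth_tagged(spec3, panel)))$families), 2L)

  ## Hamming distance 2 -> no merge
  ham2 <- function(u) { substr(u, 3, 4) <- "TT"; u }
  spec4 <- copy(spec)[, umi := c(uA, ham2(uA))]
  expect_equal(nrow(merge_families(group_families(
    synth_tagged(spec4, panel)))$families), 2L)

  ## different strand labels never merge
  spec5 <- copy(spec)[, strand_label := c("TOP", "BOTTOM")]
  expect_equal(nrow(merge_families(group_families(
    synth_tagged(spec5, panel)))$families), 2L)
})

test_that("merging is single pass and conserves reads", {
  panel <- fixture_panel()
  uA <- strrep("A", 12)
  h1 <- function(u, i, b) { substr(u, i, i) <- b; u }
  ## chain: C(2) could merge into B(12), B(12) into A(100); B merges into A
  ## first (visited in descending size), then C can only target retained A
  ## (distance 2 -> stays)
  spec <- data.table(
    umi = c(uA, h1(uA, 1, "C"), h1(h1(uA, 1, "C"), 2, "G")),
    strand_label = "TOP", frag_pos = 1000L,
    n_reads = c(100L, 12L, 2L))
  uf <- merge_families(group_families(synth_tagged(spec, panel)))
  expect_equal(sort(uf$families$read_count), c(2L, 112L))
  expect_equal(sum(uf$families$read_count), 114L)  # reads conserved
  expect_equal(nrow(uf$reads), 114L)
})

test_that("duplex pairing matches strands by UMI and nearby positions", {
  panel <- fixture_panel()
  uA <- strrep("A", 12); uB <- strrep("C", 12); uC <- strrep("G", 12)
  spec <- data.table(
    umi = c(uA, uA, uB, uC, uC),
    strand_label = c("TOP", "BOTTOM", "TOP", "TOP", "BOTTOM"),
    frag_pos = c(1000L, 1000L, 1000L, 1000L, 1002L),
    n_reads = 2L)
  dg <- pair_duplex(merge_families(group_families(synth_tagged(spec, panel))))
  cl <- dg$groups[order(umi), .(umi, classification)]
  expect_equal(cl$classification[cl$umi == uA], "DUPLEX")
  expect_equal(cl$classification[cl$umi == uB], "SINGLEPLEX")
  expect_equal(cl$classification[cl$umi == uC], "DUPLEX")  # delta 2 <= 5
  ## position delta beyond tolerance stays unpaired
  spec2 <- data.table(umi = uA, strand_label = c("TOP", "BOTTOM"),
                      frag_pos = c(1000L, 1007L), n_reads = 2L)
  dg2 <- pair_duplex(merge_families(group_families(
    synth_tagged(spec2, panel))))
  expect_equal(dg2$groups$classification, rep("SINGLEPLEX", 2))
  ## every family lands in exactly one group
  expect_equal(sort(unlist(dg$groups[, .(top_family, bottom_family)],
                           use.names = FALSE)),
               sort(dg$families$family_id))
})

test_that("two same-strand families with one bottom pair greedily by distance", {
  panel <- fixture_panel()
  uA <- strrep("A", 12)
  spec <- data.table(umi = uA,
                     strand_label = c("TOP", "TOP", "BOTTOM"),
                     frag_pos = c(1000L, 1004L, 1003L),
                     n_reads = c(30L, 30L, 10L))
  dg <- pair_duplex(merge_families(group_families(synth_tagged(spec, panel))))
  expect_equal(sort(dg$groups$classification), c("DUPLEX", "SINGLEPLEX"))
  dup <- dg$groups[classification == "DUPLEX"]
  top <- dg$families[family_id == dup$top_family]
  expect_equal(top$frag_pos, 1004L)  # nearest position wins
})

test_that("processing simulator output recovers the truth exactly at zero error", {
  panel <- fixture_panel()
  cfg <- sim_config(400, seed = 23)
  rs <- tag_and_sequence(simulate_molecules(panel, sample_profile(), cfg))
  dg <- process_reads(rs, panel = panel)
  ## no read lost: all simulated reads decode and group
  expect_equal(nrow(dg$reads), nrow(rs$reads))
  expect_equal(sum(dg$families$read_count), nrow(rs$reads))
  ## per-locus duplex/single-plex counts equal the truth table
  truth <- rs$truth_families[, .(n_strands = .N), by = .(mol_id, locus_id)]
  truth_counts <- truth[, .(duplex = sum(n_strands == 2L),
                            singleplex = sum(n_strands == 1L)),
                        by = locus_id]
  obs <- dg$groups[, .(duplex = sum(classification == "DUPLEX"),
                       singleplex = sum(classification == "SINGLEPLEX")),
                   by = locus_id]
  m <- merge(truth_counts, obs, by = "locus_id")
  expect_equal(m$duplex.x, m$duplex.y)
  expect_equal(m$singleplex.x, m$singleplex.y)
  ## decoded strand labels match the simulated strands for every read
  tagged <- merge(dg$reads, rs$truth_align[, .(read_id, fam_id)],
                  by = "read_id")
  tagged <- merge(tagged, rs$truth_families[, .(fam_id, strand)],
                  by = "fam_id")
  expect_true(all(tagged$strand_label ==
                    fifelse(tagged$strand == "T", "TOP", "BOTTOM")))
})

test_that("reads from BAM with UM/SL tags enter the same pipeline", {
  skip_if_not_installed("Rsamtools")
  panel <- fixture_panel(n_loci = 1L)
  loc <- panel$loci[1]
  pos1 <- loc$target_start - 5L  # 0-based insert start
  insert <- substring(panel$reference[[loc$chrom]], pos1 + 1L, pos1 + 60L)
  d <- withr::local_tempdir()
  sam <- file.path(d, "toy.sam")
  rec <- function(id, umi, sl) {
    paste(id, 0, loc$chrom, pos1 + 1L, 60, "60M", "*", 0, 0,
          insert, strrep("I", 60),
          paste0("UM:Z:", umi), paste0("SL:Z:", sl),
          paste0("FP:i:", pos1 + 60L), sep = "\t")
  }
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", loc$chrom, "\tLN:", nchar(panel$reference[[1]])),
    rec("q1", strrep("A", 12), "TOP"),
    rec("q2", strrep("A", 12), "TOP"),
    rec("q3", strrep("A", 12), "BOTTOM")), sam)
  bam <- Rsamtools::asBam(file.path(d, "toy.sam"),
                          file.path(d, "toy"), overwrite = TRUE)
  tg <- read_tagged_bam(bam, panel)
  expect_equal(nrow(tg$reads), 3L)
  expect_equal(sort(tg$reads$strand_label), c("BOTTOM", "TOP", "TOP"))
  dg <- pair_duplex(merge_families(group_families(tg)))
  expect_equal(dg$groups$classification, "DUPLEX")
})
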