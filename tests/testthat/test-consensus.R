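cfg <- consensus_config()

## small direct fixtures for the per-family rules
mk_family <- function(n, site, alt_base = NULL, n_alt = 0L,
                      mapq = 60L, qual = 40L, alt_qual = qual,
                      start = site - 40L, end = site + 40L,
                      mismatch_count = 0L) {
  reads <- data.table(
    read_id = sprintf("r%03d", seq_len(n)),
    start = start, end = end, mapq = mapq,
    mismatch_count = mismatch_count, median_qual = qual)
  events <- if (n_alt > 0L) {
    data.table(read_id = reads$read_id[seq_len(n_alt)], pos = site,
               base = alt_base, qual = alt_qual)
  } else {
    data.table(read_id = character(), pos = integer(), base = character(),
               qual = integer())
  }
  list(reads = reads, events = events)
}

test_that("family consensus applies the 80% all-read and 80% HQ rules", {
  ## 5 reads {A,A,A,A,G}, all HQ, ref A: majority 4/5 = 0.8 passes (>= is
  ## inclusive)
  f <- mk_family(5, site = 100L, alt_base = "G", n_alt = 1L)
  r <- family_consensus(f$reads, f$events, 100L, ref_base = "A", cfg)
  expect_equal(r$status, "CONSENSUS")
  expect_equal(r$allele, "A")
  ## 10 reads: 8 A of which 6 HQ, 2 G both HQ: all-read 8/10 = 0.8 passes
  ## but HQ 6/8 = 0.75 fails
  f <- mk_family(10, site = 100L, alt_base = "G", n_alt = 2L)
  f$reads[9:10, median_qual := 10L]  # two ref reads drop out of HQ
  r <- family_consensus(f$reads, f$events, 100L, "A", cfg)
  expect_equal(r$status, "NO_CONSENSUS")
  ## non-reference consensus: 5/5 alt
  f <- mk_family(5, site = 100L, alt_base = "T", n_alt = 5L)
  r <- family_consensus(f$reads, f$events, 100L, "C", cfg)
  expect_equal(r$status, "CONSENSUS")
  expect_equal(r$allele, "T")
})

test_that("singletons are excluded and uncovered sites are distinct", {
  f <- mk_family(1, site = 100L)
  expect_equal(family_consensus(f$reads, f$events, 100L, "A", cfg)$status,
               "EXCLUDED_SINGLETON")
  f <- mk_family(4, site = 100L)
  expect_equal(family_consensus(f$reads, f$events, 500L, "A", cfg)$status,
               "NOT_COVERED")
})

test_that("a family with no high-quality covering read has no consensus", {
  f <- mk_family(4, site = 100L, qual = 10L)
  expect_equal(family_consensus(f$reads, f$events, 100L, "A", cfg)$status,
               "NO_CONSENSUS")
  f <- mk_family(4, site = 100L, mapq = 10L)
  expect_equal(family_consensus(f$reads, f$events, 100L, "A", cfg)$status,
               "NO_CONSENSUS")
  f <- mk_family(4, site = 100L, mismatch_count = 5L)
  expect_equal(family_consensus(f$reads, f$events, 100L, "A", cfg)$status,
               "NO_CONSENSUS")
})

test_that("low-quality alt bases fail the HQ agreement, not the all-read one", {
  ## 10 reads all alt, but alt base qualities below threshold on 3 of 10:
  ## all-read 10/10, HQ 7/7 -> consensus
  f <- mk_family(10, site = 100L, alt_base = "T", n_alt = 10L)
  f$events[1:3, qual := 5L]
  r <- family_consensus(f$reads, f$events, 100L, "C", cfg)
  expect_equal(r$status, "CONSENSUS")
  expect_equal(r$allele, "T")
})

test_that("homopolymer sites demand reads spanning the run plus a flank", {
  hp <- data.table(chrom = "chr1", run_start = 95L, run_end = 101L)
  f <- mk_family(4, site = 98L, start = 60L, end = 120L)
  expect_equal(family_consensus(f$reads, f$events, 98L, "A", cfg,
                                hp_runs = hp)$status, "CONSENSUS")
  ## reads stop inside the run: no HQ read -> no consensus
  f2 <- mk_family(4, site = 98L, start = 60L, end = 100L)
  expect_equal(family_consensus(f2$reads, f2$events, 98L, "A", cfg,
                                hp_runs = hp)$status, "NO_CONSENSUS")
})

test_that("consensus is invariant to read order within a family", {
  set.seed(7)
  f <- mk_family(9, site = 100L, alt_base = "G", n_alt = 4L)
  r1 <- family_consensus(f$reads, f$events, 100L, "A", cfg)
  perm <- sample(nrow(f$reads))
  r2 <- family_consensus(f$reads[perm], f$events, 100L, "A", cfg)
  expect_identical(r1, r2)
})

test_that("raising the agreement threshold never creates a consensus", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    na <- sample(0:n, 1)
    f <- mk_family(n, site = 100L, alt_base = "G", n_alt = na)
    st <- vapply(c(0.6, 0.8, 0.95, 1.0), function(th) {
      c2 <- consensus_config(min_allele_fraction = th, min_hq_fraction = th)
      family_consensus(f$reads, f$events, 100L, "A", c2)$status
    }, "")
    reached <- st == "CONSENSUS"
    ## once lost at some threshold, never regained at a higher one
    expect_true(all(diff(reached) <= 0))
  }
})

test_that("duplex consensus confirms, rejects or abstains", {
  A <- list(status = "CONSENSUS", allele = "A")
  T_ <- list(status = "CONSENSUS", allele = "T")
  nc <- list(status = "NO_CONSENSUS", allele = NA_character_)
  sg <- list(status = "EXCLUDED_SINGLETON", allele = NA_character_)
  expect_equal(duplex_consensus(A, A),
               list(status = "CONSENSUS", allele = "A"))
  expect_equal(duplex_consensus(T_, A)$status, "DISCORDANT")
  expect_equal(duplex_consensus(A, nc)$status, "NO_CONSENSUS")
  expect_equal(duplex_consensus(sg, A)$status, "NO_CONSENSUS")
})

test_that("site counts tally duplex and single-plex evidence per the rules", {
  panel <- fixture_panel(n_loci = 1L)
  site <- target_sites(panel)[20]
  umis <- replicate(41, paste(sample(c("A", "C", "G", "T"), 12, TRUE),
                              collapse = ""))
  ## 10 duplex molecules (1 with a real alt on both strands),
  ## 30 single-plex families (2 alt), 1 discordant duplex (alt on one strand)
  spec <- rbind(
    data.table(umi = rep(umis[1:10], each = 2),
               strand_label = rep(c("TOP", "BOTTOM"), 10),
               frag_pos = 1000L, n_reads = 3L,
               n_alt = c(3L, 3L, rep(0L, 18))),
    data.table(umi = umis[11:40], strand_label = "TOP",
               frag_pos = 1004L, n_reads = 4L,
               n_alt = c(4L, 4L, rep(0L, 28))),
    data.table(umi = rep(umis[41], 2), strand_label = c("TOP", "BOTTOM"),
               frag_pos = 1000L, n_reads = 3L, n_alt = c(3L, 0L)))
  alt <- setdiff(c("A", "C", "G", "T"), site$ref)[1]
  spec[, `:=`(alt_base = alt, alt_pos = site$pos)]
  dg <- pair_duplex(group_families(synth_tagged(spec, panel)))
  sc <- site_counts(dg, site$chrom, site$pos)
  expect_equal(sc$N2, 10L)
  expect_equal(sc$n2, 1L)
  expect_equal(sc$N1, 30L)
  expect_equal(sc$n1, 2L)
  expect_equal(sc$discordant, 1L)
  expect_equal(sc$alt, alt)
})

test_that("all-singleton coverage leaves a site uncallable", {
  panel <- fixture_panel(n_loci = 1L)
  site <- target_sites(panel)[20]
  umis <- replicate(6, paste(sample(c("A", "C", "G", "T"), 12, TRUE),
                             collapse = ""))
  spec <- data.table(umi = umis, strand_label = "TOP", frag_pos = 1000L,
                     n_reads = 1L)
  dg <- pair_duplex(group_families(synth_tagged(spec, panel)))
  sc <- site_counts(dg, site$chrom, site$pos)
  expect_equal(sc$N1 + sc$N2, 0L)
  em <- error_model(2, 40000)
  calls <- call_variants(sc, em)
  expect_equal(calls$filter_status, "NO_CALL")
})

test_that("vectorised site counting agrees with the per-family reference path", {
  panel <- fixture_panel(n_loci = 1L)
  v <- pick_variants(panel, 25, af = 0.10)
  samp <- sample_profile(variants = v, damage_rates = c("C>A" = 2e-3),
                         end_repair_copy_distance = 10L)
  cfgs <- sim_config(150, sequencing_error_rate = 0.002,
                     pcr_error_rate = 5e-4, seed = 27)
  rs <- tag_and_sequence(simulate_molecules(panel, samp, cfgs))
  dg <- process_reads(rs, panel = panel)
  sites <- target_sites(panel)[seq(1, 50, by = 4)]
  sc <- site_counts_table(dg, sites = sites)
  hp <- homopolymer_runs(panel$reference, cfg$homopolymer_min_run)
  ## recompute N1/n1/N2/n2 site by site through family_consensus
  for (k in seq_len(nrow(sites))) {
    s <- sites[k]
    res <- lapply(seq_len(nrow(dg$groups)), function(gi) {
      g <- dg$groups[gi]
      one <- function(fid) {
        rd <- dg$reads[family_id == fid]
        ev <- dg$events[read_id %in% rd$read_id]
        family_consensus(rd, ev, s$pos, s$ref, cfg, hp)
      }
      tf <- if (!is.na(g$top_family)) one(g$top_family) else NULL
      bf <- if (!is.na(g$bottom_family)) one(g$bottom_family) else NULL
      cover <- function(x) !is.null(x) && x$status != "NOT_COVERED"
      if (cover(tf) && cover(bf)) {
        d <- duplex_consensus(tf, bf)
        data.table(class = "duplex", status = d$status, allele = d$allele)
      } else if (cover(tf) || cover(bf)) {
        x <- if (cover(tf)) tf else bf
        data.table(class = "single", status = x$status, allele = x$allele)
      } else NULL
    })
    res <- rbindlist(res[!vapply(res, is.null, TRUE)])
    expN2 <- res[class == "duplex" & status == "CONSENSUS", .N]
    expn2 <- res[class == "duplex" & status == "CONSENSUS" &
                   allele != s$ref, .N]
    expN1 <- res[class == "single" & status == "CONSENSUS", .N]
    expn1 <- res[class == "single" & status == "CONSENSUS" &
                   allele != s$ref, .N]
    expDis <- res[class == "duplex" & status == "DISCORDANT", .N]
    row <- sc$sites[pos == s$pos]
    expect_equal(row$N2, expN2)
    expect_equal(row$n2, expn2)
    expect_equal(row$N1, expN1)
    expect_equal(row$n1, expn1)
    expect_equal(row$discordant, expDis)
  }
})

test_that("zero-error consensus recovers planted VAF and clean duplex counts", {
  panel <- fixture_panel()
  v <- pick_variants(panel, c(20, 70), af = 0.05)
  cfgs <- sim_config(800, seed = 29)
  rs <- tag_and_sequence(simulate_molecules(panel,
                                            sample_profile(variants = v),
                                            cfgs))
  dg <- process_reads(rs, panel = panel)
  sc <- site_counts_table(dg)
  s <- sc$sites
  ## no non-reference evidence off the variant sites
  off <- s[!pos %in% v$pos]
  expect_equal(sum(off$n1 + off$n2 + off$discordant), 0L)
  ## planted VAF recovered within binomial error at the variant sites
  on <- s[pos %in% v$pos]
  for (k in 1:2) {
    ci <- qbinom(c(0.0025, 0.9975), on$N1[k] + on$N2[k], 0.05)
    expect_gte(on$n1[k] + on$n2[k], ci[1])
    expect_lte(on$n1[k] + on$n2[k], ci[2])
  }
})

test_that("single-strand damage with no copying never reaches duplex counts", {
  panel <- fixture_panel(n_loci = 1L)
  samp <- sample_profile(damage_rates = c("C>A" = 5e-3),
                         end_repair_copy_distance = 0L)
  cfgs <- sim_config(1500, seed = 31)
  rs <- tag_and_sequence(simulate_molecules(panel, samp, cfgs))
  dg <- process_reads(rs, panel = panel)
  sc <- site_counts_table(dg)
  expect_equal(sum(sc$sites$n2), 0L)
  ## but the damage is visible as single-plex evidence and discordance
  expect_gt(sum(sc$sites$n1), 0L)
  expect_gt(sum(sc$sites$discordant), 0L)
})
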