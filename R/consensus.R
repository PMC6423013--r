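#' Consensus configuration
#'
#' A UMI family reaches a consensus at a site when at least 80% of all
#' covering reads and at least 80% of the high-quality covering reads agree
#' on one allele. High quality means: base quality at the site,
#' mapping quality, number of mismatches from the reference, and full
#' coverage (with one flanking base) of any homopolymer run containing the
#' site, each within the configured thresholds.
#'
#' @param min_allele_fraction Minimum agreement among all covering reads
#'   (inclusive, so exactly 80% passes).
#' @param min_hq_fraction Minimum agreement among high-quality covering
#'   reads.
#' @param min_base_quality Phred threshold for the base at the site.
#' @param min_mapping_quality Mapping-quality threshold.
#' @param max_mismatches Maximum reference mismatches per read.
#' @param homopolymer_min_run Homopolymer length from which the spanning
#'   requirement applies.
#' @return A `consensus_config` object.
#' @export
consensus_config <- function(min_allele_fraction = 0.80,
                             min_hq_fraction = 0.80,
                             min_base_quality = 25L,
                             min_mapping_quality = 30L,
                             max_mismatches = 3L,
                             homopolymer_min_run = 5L) {
  stopifnot(min_allele_fraction > 0.5, min_allele_fraction <= 1,
            min_hq_fraction > 0.5, min_hq_fraction <= 1,
            min_base_quality >= 0, min_mapping_quality >= 0,
            max_mismatches >= 0, homopolymer_min_run >= 2)
  structure(list(min_allele_fraction = min_allele_fraction,
                 min_hq_fraction = min_hq_fraction,
                 min_base_quality = as.integer(min_base_quality),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 max_mismatches = as.integer(max_mismatches),
                 homopolymer_min_run = as.integer(homopolymer_min_run)),
            class = "consensus_config")
}

# does a read/span cover a homopolymer run (plus one flank) containing pos?
hp_span_ok <- function(start, end, pos, hp_runs) {
  if (is.null(hp_runs) || nrow(hp_runs) == 0L) return(rep(TRUE, length(pos)))
  ok <- rep(TRUE, length(pos))
  for (r in seq_len(nrow(hp_runs))) {
    inrun <- pos >= hp_runs$run_start[r] & pos < hp_runs$run_end[r]
    if (!any(inrun)) next
    ok[inrun] <- ok[inrun] &
      start[inrun] <= hp_runs$run_start[r] - 1L &
      end[inrun] >= hp_runs$run_end[r] + 1L
  }
  ok
}

#' Consensus allele of one UMI family at one site
#'
#' Reference implementation of the per-family consensus rules. Singleton
#' families (one read) are excluded outright: a single read cannot be
#' error-corrected. Otherwise the majority allele among covering reads must
#' reach the all-read and high-quality agreement thresholds; a family with
#' no high-quality covering read cannot reach consensus.
#'
#' @param reads data.table of the family's reads (columns as produced by
#'   [tag_reads()]: `read_id`, `start`, `end`, `mapq`, `mismatch_count`,
#'   `median_qual`).
#' @param events data.table of reference mismatches for these reads
#'   (`read_id`, `pos`, `base`, `qual`).
#' @param site 0-based position.
#' @param ref_base Reference base at the site.
#' @param cfg A [consensus_config()].
#' @param hp_runs Homopolymer run table for the site's chromosome (from
#'   [homopolymer_runs()]), or NULL to skip the homopolymer rule.
#' @return list with `status` (`"CONSENSUS"`, `"NO_CONSENSUS"`,
#'   `"EXCLUDED_SINGLETON"` or `"NOT_COVERED"`) and `allele` (NA unless
#'   consensus).
#' @export
family_consensus <- function(reads, events, site, ref_base,
                             cfg = consensus_config(), hp_runs = NULL) {
  reads <- as.data.table(reads)
  if (nrow(reads) == 1L)
    return(list(status = "EXCLUDED_SINGLETON", allele = NA_character_))
  cov <- reads[start <= site & site < end]
  if (nrow(cov) == 0L)
    return(list(status = "NOT_COVERED", allele = NA_character_))
  ev <- as.data.table(events)[read_id %in% cov$read_id & pos == site]
  cov <- merge(cov, ev[, .(read_id, base, qual)], by = "read_id",
               all.x = TRUE)
  cov[, allele := fifelse(is.na(base), ref_base, base)]
  cov[, qual := fifelse(is.na(qual), as.integer(median_qual), qual)]
  cov[, hq := mapq >= cfg$min_mapping_quality &
        mismatch_count <= cfg$max_mismatches &
        qual >= cfg$min_base_quality &
        hp_span_ok(start, end, rep(site, .N), hp_runs)]
  tab <- cov[, .(n = .N, nhq = sum(hq)), by = allele][order(-n, allele)]
  tot <- nrow(cov)
  tothq <- sum(cov$hq)
  maj <- tab[1L]
  if (tothq == 0L ||
      maj$n / tot < cfg$min_allele_fraction ||
      maj$nhq / tothq < cfg$min_hq_fraction)
    return(list(status = "NO_CONSENSUS", allele = NA_character_))
  list(status = "CONSENSUS", allele = maj$allele)
}

#' Combine the two strand consensus results of a duplex group
#'
#' Both strand families must individually reach consensus; equal alleles
#' confirm each other, unequal alleles mark the site DISCORDANT (the
#' signature of single-strand damage), and any non-consensus or singleton
#' member leaves the duplex without a consensus.
#'
#' @param top,bottom Results from [family_consensus()] for the two strands.
#' @return list with `status` (`"CONSENSUS"`, `"DISCORDANT"`,
#'   `"NO_CONSENSUS"`) and `allele`.
#' @export
duplex_consensus <- function(top, bottom) {
  if (top$status != "CONSENSUS" || bottom$status != "CONSENSUS")
    return(list(status = "NO_CONSENSUS", allele = NA_character_))
  if (top$allele != bottom$allele)
    return(list(status = "DISCORDANT", allele = NA_character_))
  list(status = "CONSENSUS", allele = top$allele)
}

#' Per-site duplex and single-plex consensus counts
#'
#' Applies the family and duplex consensus rules over every requested site
#' and tallies, per site: `N2` concordant duplex groups and `n2` of them
#' with a non-reference consensus; `N1` single-plex families with consensus
#' and `n1` non-reference among them. Discordant duplex groups are excluded
#' from both classes (discordance is positive evidence of artifact) and
#' reported separately. A duplex group covering the site with only one of
#' its strands contributes that strand as single-plex evidence.
#'
#' The returned object also carries family-level (single-UMI) consensus
#' totals in the polymerase frame, used for background error estimation,
#' and the individual non-reference consensus calls with their distance to
#' the ligated fragment end, used for the end-repair artifact test.
#'
#' @param dg A `duplex_groups` object from [pair_duplex()] /
#'   [process_reads()].
#' @param sites data.table (`chrom`, `pos`) of 0-based sites, defaulting to
#'   all panel target sites.
#' @param cfg A [consensus_config()].
#' @return A `site_counts` object: list with `sites` (per site: `chrom`,
#'   `pos`, `ref`, `alt`, `N1`, `n1`, `N2`, `n2`, `discordant`),
#'   `fam_totals` (`chrom`, `pos`, `ref`, `strand_label`, `N`),
#'   `fam_alt` (`chrom`, `pos`, `ref`, `strand_label`, `alt`, `n`) and
#'   `alt_events` (each non-reference consensus: `chrom`, `pos`, `allele`,
#'   `evidence`, `frag_pos`, `dist5`).
#' @export
site_counts_table <- function(dg, sites = NULL, cfg = consensus_config()) {
  stopifnot(inherits(dg, "duplex_groups"))
  panel <- dg$panel
  if (is.null(sites)) sites <- target_sites(panel)
  sites <- as.data.table(sites)
  if (!"ref" %in% names(sites))
    sites[, ref := ref_base_at(panel$reference, chrom, pos)]
  hp <- homopolymer_runs(panel$reference, cfg$homopolymer_min_run)

  reads <- copy(dg$reads)
  reads[, hq := mapq >= cfg$min_mapping_quality &
          mismatch_count <= cfg$max_mismatches &
          median_qual >= cfg$min_base_quality]
  famcov <- reads[, .(cov_start = min(start), cov_end = max(end),
                      span_start = max(start), span_end = min(end),
                      n_reads = .N, n_hq = sum(hq)), by = family_id]
  fams <- merge(dg$families, famcov, by = "family_id")
  fams <- merge(fams, dg$groups[, .(group_id, classification)],
                by = "group_id")
  fams <- merge(fams, unique(panel$loci[, .(locus_id, primer_strand)]),
                by = "locus_id")

  ## (family, site) coverage pairs
  fi <- fams[, .(family_id, chrom, fam_s = cov_start, fam_e = cov_end - 1L)]
  setkey(fi, chrom, fam_s, fam_e)
  si <- sites[, .(chrom, site_s = pos, site_e = pos, pos, ref)]
  fs <- foverlaps(si, fi, by.x = c("chrom", "site_s", "site_e"),
                  type = "within", nomatch = NULL)
  fs <- fs[, .(family_id, chrom, pos, ref)]
  fs <- merge(fs, fams, by = c("family_id", "chrom"))

  ## default per-(family, site) status: consensus on the reference allele
  fs[, `:=`(status = "CONS", allele = ref)]
  fs[n_reads == 1L, `:=`(status = "SINGLETON", allele = NA_character_)]
  fs[status == "CONS" &
       (n_hq == 0L | !hp_span_ok(span_start, span_end, pos, hp)),
     `:=`(status = "NO_CONSENSUS", allele = NA_character_)]

  ## exact evaluation wherever a family has a reference mismatch at the site
  ev <- merge(dg$events, reads[, .(read_id, family_id)], by = "read_id")
  ex <- unique(ev[, .(family_id, pos)])
  ex <- merge(ex, fs[, .(family_id, pos)], by = c("family_id", "pos"))
  if (nrow(ex)) {
    cov <- merge(reads, ex, by = "family_id", allow.cartesian = TRUE)
    cov <- cov[start <= pos & pos < end]
    cov <- merge(cov, ev[, .(family_id, read_id, pos, base, qual)],
                 by = c("family_id", "read_id", "pos"), all.x = TRUE)
    cov <- merge(cov, sites[, .(chrom, pos, ref)], by = c("chrom", "pos"))
    cov[, allele := fifelse(is.na(base), ref, base)]
    cov[, qual := fifelse(is.na(qual), as.integer(median_qual), qual)]
    cov[, hq := mapq >= cfg$min_mapping_quality &
          mismatch_count <= cfg$max_mismatches &
          qual >= cfg$min_base_quality &
          hp_span_ok(start, end, pos, hp)]
    tab <- cov[, .(n = .N, nhq = sum(hq)), by = .(family_id, pos, allele)]
    tot <- tab[, .(tot = sum(n), tothq = sum(nhq)), by = .(family_id, pos)]
    setorder(tab, family_id, pos, -n, allele)
    maj <- tab[, .SD[1L], by = .(family_id, pos)]
    res <- merge(maj, tot, by = c("family_id", "pos"))
    res[, ok := tothq > 0L & n / tot >= cfg$min_allele_fraction &
          nhq / tothq >= cfg$min_hq_fraction]
    res[, `:=`(status = fifelse(ok, "CONS", "NO_CONSENSUS"),
               allele = fifelse(ok, allele, NA_character_))]
    ## singletons stay excluded no matter what the exact path says
    fs[res, on = .(family_id, pos),
       `:=`(status = fifelse(status == "SINGLETON", "SINGLETON", i.status),
            allele = fifelse(status == "SINGLETON", NA_character_,
                             i.allele))]
  }

  ## duplex / single-plex aggregation per (group, site)
  setorder(fs, group_id, chrom, pos, strand_label)
  agg <- fs[, .(m = .N, s1 = status[1L], a1 = allele[1L],
                s2 = status[.N], a2 = allele[.N],
                classification = classification[1L],
                frag_pos = frag_pos[1L],
                primer_strand = primer_strand[1L]),
            by = .(group_id, chrom, pos, ref)]
  agg[, fam_status := "EXCLUDED"]
  single <- agg$classification == "SINGLEPLEX" | agg$m == 1L
  agg[single & s1 == "CONS", fam_status := "SINGLEPLEX"]
  dup <- !single
  agg[dup & s1 == "CONS" & s2 == "CONS" & a1 == a2,
      fam_status := "DUPLEX"]
  agg[dup & s1 == "CONS" & s2 == "CONS" & a1 != a2,
      fam_status := "DISCORDANT"]

  site_tab <- agg[, .(
    N1 = sum(fam_status == "SINGLEPLEX"),
    n1 = sum(fam_status == "SINGLEPLEX" & a1 != ref),
    N2 = sum(fam_status == "DUPLEX"),
    n2 = sum(fam_status == "DUPLEX" & a1 != ref),
    discordant = sum(fam_status == "DISCORDANT")),
    by = .(chrom, pos, ref)]

  ## top alternative allele per site (ties broken lexicographically)
  altc <- agg[fam_status %in% c("SINGLEPLEX", "DUPLEX") & a1 != ref,
              .(n = .N), by = .(chrom, pos, allele = a1)]
  setorder(altc, chrom, pos, -n, allele)
  alt1 <- altc[, .SD[1L], by = .(chrom, pos)][, .(chrom, pos, alt = allele)]
  site_tab <- merge(site_tab, alt1, by = c("chrom", "pos"), all.x = TRUE)

  out <- merge(sites[, .(chrom, pos, ref)], site_tab,
               by = c("chrom", "pos", "ref"), all.x = TRUE)
  for (cc in c("N1", "n1", "N2", "n2", "discordant"))
    out[is.na(get(cc)), (cc) := 0L]

  ## family-level (single-UMI) consensus counts in the polymerase frame
  qual_fams <- fs[status == "CONS"]
  fam_totals <- qual_fams[, .(N = .N), by = .(chrom, pos, ref, strand_label)]
  fam_alt <- qual_fams[allele != ref,
                       .(n = .N), by = .(chrom, pos, ref, strand_label,
                                         alt = allele)]

  ## individual non-reference consensus calls with distance to ligated end
  alt_ev <- agg[fam_status %in% c("SINGLEPLEX", "DUPLEX") & a1 != ref,
                .(chrom, pos, allele = a1,
                  evidence = fifelse(fam_status == "DUPLEX", "duplex",
                                     "singleplex"),
                  frag_pos, primer_strand, group_id)]
  alt_ev[, dist5 := fifelse(primer_strand == "+", frag_pos - 1L - pos,
                            pos - frag_pos)]
  structure(list(sites = out[order(chrom, pos)],
                 fam_totals = fam_totals[], fam_alt = fam_alt[],
                 alt_events = alt_ev[, .(chrom, pos, allele, evidence,
                                         frag_pos, dist5, group_id)],
                 cfg = cfg),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  s <- x$sites
  cat("site counts:", nrow(s), "sites; mean qualified UMIs/site",
      round(mean(s$N1 + s$N2), 1), "; duplex share",
      round(sum(s$N2) / max(1, sum(s$N1 + s$N2)), 3), "\n")
  invisible(x)
}

#' Consensus counts for one site
#'
#' @param dg A `duplex_groups` object.
#' @param chrom,pos Site (0-based).
#' @param cfg A [consensus_config()].
#' @return One-row data.table of per-site counts (see
#'   [site_counts_table()]).
#' @export
site_counts <- function(dg, chrom, pos, cfg = consensus_config()) {
  sc <- site_counts_table(dg, sites = data.table(chrom = chrom, pos = pos),
                          cfg = cfg)
  sc$sites
}

#' Write the per-site counts table
#'
#' @param sc A `site_counts` object.
#' @param path Output TSV path (positions written 1-based).
#' @export
write_site_counts <- function(sc, path) {
  out <- copy(sc$sites)[, .(chrom, pos = pos + 1L, ref, alt, N1, n1, N2,
                            n2, discordant)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
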