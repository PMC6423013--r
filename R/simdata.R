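#' Sample profile for the library simulator
#'
#' Describes the DNA sample being emulated: spiked variants at known allele
#' fractions (a diploid mixture carries its unique SNVs at 0.1-0.4%
#' fraction), per-type strand-specific base damage (e.g. oxidative G-to-T,
#' observed as `C>A` in the polymerase frame), how far from the ligated
#' fragment end a single-strand lesion is copied onto the complementary
#' strand during end repair, and the fragment length distribution.
#'
#' @param variants data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `af` (allele fraction in (0,1)), or NULL for a wild-type sample.
#' @param damage_rates Named numeric vector over substitution types (see
#'   [substitution_types()]), the per-base per-strand lesion probability in
#'   `[0, 0.01]`. Unnamed types default to 0.
#' @param end_repair_copy_distance Lesions strictly closer than this many bp
#'   to the ligated fragment end are copied to the complementary strand
#'   during simulated end repair; 0 disables copying.
#' @param fragment_length_mean,fragment_length_sd Fragment length
#'   distribution (bp), Normal truncated at 50 bp.
#' @return A `sample_profile` object.
#' @export
sample_profile <- function(variants = NULL,
                           damage_rates = NULL,
                           end_repair_copy_distance = 15L,
                           fragment_length_mean = 170,
                           fragment_length_sd = 25) {
  types <- substitution_types()
  dr <- setNames(numeric(length(types)), types)
  if (!is.null(damage_rates)) {
    if (is.null(names(damage_rates)) ||
        !all(names(damage_rates) %in% types))
      stop("damage_rates must be named by substitution type, e.g. 'C>A'")
    dr[names(damage_rates)] <- damage_rates
  }
  if (any(dr < 0 | dr > 0.01))
    stop("damage rates must lie in [0, 0.01]")
  if (is.null(variants)) {
    variants <- data.table(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           af = numeric())
  } else {
    variants <- as.data.table(variants)
    stopifnot(all(c("chrom", "pos", "ref", "alt", "af") %in% names(variants)))
    if (nrow(variants) && (any(variants$af <= 0) || any(variants$af >= 1)))
      stop("allele fractions must lie in (0, 1)")
    variants[, pos := as.integer(pos)]
  }
  stopifnot(end_repair_copy_distance >= 0, fragment_length_mean >= 50,
            fragment_length_sd >= 0)
  structure(list(variants = variants[],
                 damage_rates = dr,
                 end_repair_copy_distance = as.integer(end_repair_copy_distance),
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd),
            class = "sample_profile")
}

#' Simulation configuration
#'
#' @param molecules_per_locus Number of original double-stranded molecules
#'   tagged per locus.
#' @param strand_capture_prob Probability `s` that each strand of a tagged
#'   molecule yields a sequenced read family. With independent capture the
#'   expected duplex share of observed UMIs is `s / (2 - s)`; the default
#'   0.387 reproduces the ~24% duplex share typical of these libraries.
#' @param reads_per_family_mean Mean reads per UMI family; family sizes are
#'   `1 + Poisson(mean - 1)` so every family has at least one read. The
#'   default 4.5 matches the observed mean read/UMI.
#' @param sequencing_error_rate Per-base substitution probability applied to
#'   every read independently (post-tagging; removed by family consensus).
#' @param pcr_error_rate Per-base substitution probability applied once to
#'   each family's founder copy (post-tagging; UMI-consistent within a
#'   family, but inconsistent between the two strands of a duplex).
#' @param read_length Read length (bp) for both reads of a pair.
#' @param primer_length Gene-specific primer length for read 2.
#' @param seed Integer RNG seed; all simulator randomness derives from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(molecules_per_locus = 1000L,
                       strand_capture_prob = 0.387,
                       reads_per_family_mean = 4.5,
                       sequencing_error_rate = 0,
                       pcr_error_rate = 0,
                       read_length = 150L,
                       primer_length = 20L,
                       seed = 1L) {
  stopifnot(molecules_per_locus >= 1,
            strand_capture_prob > 0, strand_capture_prob <= 1,
            reads_per_family_mean >= 1,
            sequencing_error_rate >= 0, sequencing_error_rate <= 0.1,
            pcr_error_rate >= 0, pcr_error_rate <= 0.1,
            read_length >= 50)
  structure(list(molecules_per_locus = as.integer(molecules_per_locus),
                 strand_capture_prob = strand_capture_prob,
                 reads_per_family_mean = reads_per_family_mean,
                 sequencing_error_rate = sequencing_error_rate,
                 pcr_error_rate = pcr_error_rate,
                 read_length = as.integer(read_length),
                 primer_length = as.integer(primer_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate tagged double-stranded molecules
#'
#' Draws `molecules_per_locus` double-stranded fragments per locus. Each
#' molecule gets a random 12-mer UMI shared by both strands, a fragment
#' length from the truncated Normal of the sample profile, and a ligated
#' (UMI-bearing) fragmentation end opposite the gene-specific primer.
#' Variants are planted on both strands with probability equal to their
#' allele fraction; damage lesions are planted on single strands at the
#' per-type rates, in the polymerase frame (a `C>A` lesion hits reference C
#' positions on the top strand and reference G positions -- observed as
#' G-to-T -- on the bottom strand); lesions strictly closer than
#' `end_repair_copy_distance` bp to the ligated end are copied to the
#' complementary strand, emulating end-repair fill-in.
#'
#' @param panel A [panel_design()].
#' @param sample A [sample_profile()].
#' @param config A [sim_config()]; `config$seed` is set before drawing.
#' @return A `molecule_set`: list with `molecules` (one row per molecule:
#'   `mol_id`, `locus_id`, `chrom`, `frag_start`, `frag_end`, `frag_pos`,
#'   `ligated` ("L"/"R"), `umi`) and `events` (one row per planted allele:
#'   `mol_id`, `strand` ("T"/"B"), `pos`, `base`, `origin` in
#'   variant/damage/damage_copy).
#' @export
simulate_molecules <- function(panel, sample, config) {
  stopifnot(inherits(panel, "panel_design"),
            inherits(sample, "sample_profile"),
            inherits(config, "sim_config"))
  set.seed(config$seed)
  loci <- panel$loci
  n <- config$molecules_per_locus
  mol <- loci[rep(seq_len(nrow(loci)), each = n),
              .(locus_id, chrom, primer_start, primer_strand)]
  nm <- nrow(mol)
  mol[, mol_id := seq_len(nm)]
  len <- pmax(50L, as.integer(round(
    rnorm(nm, sample$fragment_length_mean, sample$fragment_length_sd))))
  chrlen <- nchar(panel$reference)[mol$chrom]
  mol[, `:=`(
    frag_start = fifelse(primer_strand == "+", primer_start,
                         pmax(0L, primer_start - len)),
    frag_end = fifelse(primer_strand == "+",
                       pmin(as.integer(chrlen), primer_start + len),
                       primer_start),
    ligated = fifelse(primer_strand == "+", "R", "L")
  )]
  mol[, frag_pos := fifelse(ligated == "R", frag_end, frag_start)]
  mol[, umi := random_umis(nm)]

  events <- list()
  ## variants: carried by both strands with probability af
  v <- sample$variants
  if (nrow(v)) {
    for (i in seq_len(nrow(v))) {
      elig <- mol[chrom == v$chrom[i] & frag_start <= v$pos[i] &
                    v$pos[i] < frag_end]
      if (!nrow(elig)) next
      carrier <- elig$mol_id[rbinom(nrow(elig), 1L, v$af[i]) == 1L]
      if (!length(carrier)) next
      events[[length(events) + 1L]] <- data.table(
        mol_id = rep(carrier, 2L),
        strand = rep(c("T", "B"), each = length(carrier)),
        pos = v$pos[i], base = v$alt[i], origin = "variant")
    }
  }

  ## strand-specific damage
  base_pos <- base_position_index(panel)
  for (ty in names(sample$damage_rates)) {
    rate <- sample$damage_rates[[ty]]
    if (rate <= 0) next
    rb <- substr(ty, 1L, 1L)  # polymerase-frame template base
    ab <- substr(ty, 3L, 3L)
    for (st in c("T", "B")) {
      tmpl <- if (st == "T") rb else comp_base(rb)
      obs <- if (st == "T") ab else comp_base(ab)
      pp <- base_pos[base == tmpl]
      if (!nrow(pp)) next
      hits <- mol[pp, .(mol_id, pos = i.pos),
                  on = .(chrom, frag_start <= pos, frag_end > pos),
                  allow.cartesian = TRUE, nomatch = NULL]
      if (!nrow(hits)) next
      hits <- hits[rbinom(.N, 1L, rate) == 1L]
      if (!nrow(hits)) next
      events[[length(events) + 1L]] <- data.table(
        mol_id = hits$mol_id, strand = st, pos = hits$pos, base = obs,
        origin = "damage")
    }
  }

  events <- if (length(events)) rbindlist(events) else
    data.table(mol_id = integer(), strand = character(), pos = integer(),
               base = character(), origin = character())

  ## end-repair copying of damage near the ligated end
  cd <- sample$end_repair_copy_distance
  if (cd > 0L && nrow(events)) {
    dmg <- events[origin == "damage"]
    if (nrow(dmg)) {
      dmg <- merge(dmg, mol[, .(mol_id, frag_start, frag_end, ligated)],
                   by = "mol_id")
      dmg[, dist5 := fifelse(ligated == "R", frag_end - 1L - pos,
                             pos - frag_start)]
      cp <- dmg[dist5 < cd]
      if (nrow(cp)) {
        events <- rbind(events, cp[, .(
          mol_id, strand = fifelse(strand == "T", "B", "T"),
          pos, base, origin = "damage_copy")])
      }
    }
  }
  ## a strand never carries two alleles at one site: variant wins, then
  ## damage, then copies
  if (nrow(events)) {
    events[, origin := factor(origin,
                              levels = c("variant", "damage", "damage_copy"))]
    setorder(events, mol_id, strand, pos, origin)
    events <- unique(events, by = c("mol_id", "strand", "pos"))
    events[, origin := as.character(origin)]
  }
  structure(list(molecules = mol[, .(mol_id, locus_id, chrom, frag_start,
                                     frag_end, frag_pos, ligated, umi)],
                 events = events[], panel = panel, sample = sample,
                 config = config),
            class = "molecule_set")
}

random_umis <- function(n, length = 12L) {
  m <- matrix(sample(DNA_BASES, n * length, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m))
}

# 0-based positions of each base, restricted to a window around the panel
base_position_index <- function(panel) {
  lo <- panel$loci[, .(
    w_start = max(0L, min(primer_start, target_start) - 400L),
    w_end = min(nchar(panel$reference[[chrom]]),
                max(primer_start, target_end) + 400L)),
    by = .(locus_id, chrom)]
  out <- lo[, {
    s <- strsplit(substring(panel$reference[[chrom]], w_start + 1L, w_end),
                  "")[[1]]
    .(pos = w_start + seq_along(s) - 1L, base = s)
  }, by = .(chrom, w_start)]
  unique(out[, .(chrom, pos, base)])
}

#' Capture, amplify and sequence simulated molecules
#'
#' Each strand of each molecule is captured independently with probability
#' `strand_capture_prob`; a captured strand becomes a UMI family with
#' `1 + Poisson(reads_per_family_mean - 1)` reads. PCR errors are applied
#' once per family founder copy (shared by the whole family, absent from the
#' sister strand), sequencing errors independently per read over the full
#' read. Read 1 is `UMI + spacer + strand barcode + spacer + insert` (TT for
#' top-strand families, CC for bottom); read 2 starts with the gene-specific
#' primer. A truth table records each read's genomic placement so the
#' downstream pipeline can run without an aligner.
#'
#' @param mols A `molecule_set` from [simulate_molecules()].
#' @param config A [sim_config()]; defaults to the one stored in `mols`.
#'   The RNG is reseeded from `config$seed` so the full simulate + sequence
#'   pipeline is reproducible.
#' @param layout A [read_layout()].
#' @param sample_id Sample identifier recorded in the truth table.
#' @return A `read_set`: list with `reads` (`read_id`, `r1`, `r2`, `q1`,
#'   `q2`), `truth_align` (`read_id`, `chrom`, `r1_start`, `r1_end`,
#'   `r1_orient`, `locus_id`, `frag_pos`, `sample_id`, `mapq`),
#'   `truth_families` (one row per captured strand family) and the input
#'   `molecule_set`.
#' @export
tag_and_sequence <- function(mols, config = mols$config,
                             layout = read_layout(), sample_id = "S1") {
  stopifnot(inherits(mols, "molecule_set"))
  if (config$strand_capture_prob <= 0)
    stop("strand_capture_prob must be positive: no strand can be captured")
  set.seed((config$seed + 1L) %% .Machine$integer.max)
  panel <- mols$panel
  mol <- mols$molecules

  fams <- mol[rep(seq_len(nrow(mol)), 2L)]
  fams[, strand := rep(c("T", "B"), each = nrow(mol))]
  fams <- fams[rbinom(.N, 1L, config$strand_capture_prob) == 1L]
  if (!nrow(fams)) stop("no strand was captured; increase molecule count")
  fams[, fam_id := seq_len(.N)]
  fams[, read_count := 1L + rpois(.N, config$reads_per_family_mean - 1)]

  ins_len <- pmin(config$read_length - layout$insert_offset,
                  fams$frag_end - fams$frag_start)
  win_start <- fifelse(fams$ligated == "R", fams$frag_end - ins_len,
                       fams$frag_start)
  win_end <- win_start + ins_len

  ## founder insert in reference frame, with molecule-strand alleles applied
  ins <- substring_by_chrom(panel$reference, fams$chrom, win_start, win_end)
  ev <- mols$events[fams[, .(mol_id, strand, fam_id)],
                    on = .(mol_id, strand), nomatch = NULL]
  ev <- merge(ev, data.table(fam_id = fams$fam_id, win_start, win_end),
              by = "fam_id")
  ev <- ev[pos >= win_start & pos < win_end]
  if (nrow(ev)) {
    row <- match(ev$fam_id, fams$fam_id)
    off <- ev$pos - ev$win_start + 1L
    for (k in seq_len(nrow(ev)))
      substr(ins[row[k]], off[k], off[k]) <- ev$base[k]
  }
  ins <- apply_point_errors(ins, config$pcr_error_rate)

  ## read 2 founder: from the primer-side end
  len2 <- pmin(config$read_length, fams$frag_end - fams$frag_start)
  w2s <- fifelse(fams$ligated == "R", fams$frag_start, fams$frag_end - len2)
  w2e <- w2s + len2
  ins2 <- substring_by_chrom(panel$reference, fams$chrom, w2s, w2e)
  ev2 <- mols$events[fams[, .(mol_id, strand, fam_id)],
                     on = .(mol_id, strand), nomatch = NULL]
  ev2 <- merge(ev2, data.table(fam_id = fams$fam_id, w2s, w2e),
               by = "fam_id")
  ev2 <- ev2[pos >= w2s & pos < w2e]
  if (nrow(ev2)) {
    row <- match(ev2$fam_id, fams$fam_id)
    off <- ev2$pos - ev2$w2s + 1L
    for (k in seq_len(nrow(ev2)))
      substr(ins2[row[k]], off[k], off[k]) <- ev2$base[k]
  }
  ins2 <- apply_point_errors(ins2, config$pcr_error_rate)

  ## sequencing orientation: read 1 runs from the ligated end inward, so a
  ## right-ligated fragment is read as the reverse complement
  right <- fams$ligated == "R"
  ins_seq <- ins
  ins_seq[right] <- revcomp(ins[right])
  ins2_seq <- ins2
  ins2_seq[right == FALSE] <- revcomp(ins2[!right])

  bc <- fifelse(fams$strand == "T", layout$barcode_top, layout$barcode_bottom)
  r1_founder <- paste0(fams$umi, layout$spacer1, bc, layout$spacer2, ins_seq)

  ## expand to reads and add per-read sequencing errors
  ridx <- rep(seq_len(nrow(fams)), fams$read_count)
  nr <- length(ridx)
  r1 <- apply_point_errors(r1_founder[ridx], config$sequencing_error_rate)
  r2 <- apply_point_errors(ins2_seq[ridx], config$sequencing_error_rate)
  read_id <- sprintf("sim%08d", seq_len(nr))

  reads <- data.table(read_id = read_id, r1 = r1, r2 = r2,
                      q1 = strrep("I", nchar(r1)), q2 = strrep("I", nchar(r2)))
  truth_align <- data.table(
    read_id = read_id, chrom = fams$chrom[ridx],
    r1_start = win_start[ridx], r1_end = win_end[ridx],
    r1_orient = fifelse(right[ridx], "-", "+"),
    locus_id = fams$locus_id[ridx], frag_pos = fams$frag_pos[ridx],
    sample_id = sample_id, mapq = 60L, fam_id = fams$fam_id[ridx])
  truth_families <- fams[, .(fam_id, mol_id, strand, umi, frag_pos,
                             locus_id, chrom, read_count)]
  structure(list(reads = reads, truth_align = truth_align,
                 truth_families = truth_families, molecule_set = mols,
                 config = config, layout = layout),
            class = "read_set")
}

# vectorised substring over a named reference, grouped by chromosome
substring_by_chrom <- function(reference, chrom, start, end) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- substring(reference[[ch]], start[i] + 1L, end[i])
  }
  out
}

# sprinkle uniform substitution errors over strings at a per-base rate
apply_point_errors <- function(x, rate) {
  if (rate <= 0 || !length(x)) return(x)
  nerr <- rbinom(length(x), nchar(x), rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    p <- sample.int(nchar(x[i]), nerr[i])
    for (j in p) {
      old <- substr(x[i], j, j)
      substr(x[i], j, j) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  x
}

#' Write a read set as paired FASTQ
#'
#' @param read_set A `read_set` from [tag_and_sequence()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @param gzip Compress output with gzip.
#' @return Named character vector of written paths (`r1`, `r2`, `align`).
#' @export
write_fastq <- function(read_set, dir, prefix = "sim", gzip = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- file.path(dir, paste0(prefix, "_R1", ext))
  p2 <- file.path(dir, paste0(prefix, "_R2", ext))
  pa <- file.path(dir, paste0(prefix, "_align.tsv"))
  for (side in 1:2) {
    seqs <- if (side == 1) read_set$reads$r1 else read_set$reads$r2
    quals <- if (side == 1) read_set$reads$q1 else read_set$reads$q2
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(quals))
    names(x) <- read_set$reads$read_id
    Biostrings::writeQualityScaledXStringSet(
      x, if (side == 1) p1 else p2, compress = gzip)
  }
  fwrite(read_set$truth_align, pa, sep = "\t")
  invisible(c(r1 = p1, r2 = p2, align = pa))
}

#' Write truth files for a simulated sample
#'
#' Emits the planted variants as a VCF (1-based, allele fraction in the
#' `AF` INFO field) and the panel target intervals as BED.
#'
#' @param sample A [sample_profile()].
#' @param panel A [panel_design()].
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Named character vector of written paths (`vcf`, `bed`).
#' @export
write_truth <- function(sample, panel, dir, prefix = "truth") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vcf <- file.path(dir, paste0(prefix, ".vcf"))
  bed <- file.path(dir, paste0(prefix, ".bed"))
  v <- sample$variants
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(panel$reference),
                  ",length=", nchar(panel$reference), ">"),
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Planted allele fraction\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(v)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%g",
            v$chrom, v$pos + 1L, v$ref, v$alt, v$af)
  } else character(0)
  writeLines(c(hdr, body), vcf)
  write_target_bed(panel, bed)
  invisible(c(vcf = vcf, bed = bed))
}

#' Read a variant truth/call VCF into a table
#'
#' Minimal reader for the VCFs written by this package.
#'
#' @param path VCF path.
#' @return data.table with `chrom`, `pos` (0-based), `ref`, `alt`, `af`
#'   (NA when absent).
#' @export
read_truth_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.table(chrom = character(), pos = integer(),
                      ref = character(), alt = character(), af = numeric()))
  f <- tstrsplit(body, "\t")
  af <- suppressWarnings(as.numeric(sub("^.*AF=([0-9.eE+-]+).*$", "\\1",
                                        f[[8]])))
  data.table(chrom = f[[1]], pos = as.integer(f[[2]]) - 1L,
             ref = f[[4]], alt = f[[5]], af = af)
}

#' Simulate per-site qualified UMI counts directly
#'
#' Draws site-level duplex/single-plex consensus UMI counts without
#' simulating reads, for caller evaluation at panel scale. Each site gets a
#' total qualified UMI depth `N ~ Poisson(mean_depth)` split binomially into
#' duplex (`N2`) and single-plex (`N1`) groups. Background non-reference
#' counts follow the Beta-Binomial null: a site error rate
#' `e ~ Beta(alpha, beta)` gives `n1 ~ Binomial(N1, e)` and, because a
#' duplex non-reference consensus needs the same error on both strands,
#' `n2 ~ Binomial(N2, e^2)`. Optional strand-specific damage adds
#' single-plex-only errors with site rates drawn from a heavy-tailed Beta
#' (shape `damage_shape`, mean `damage_rate`), emulating damage hotspots
#' that never gain duplex support. Variant sites add reads at the given
#' allele fraction on both evidence classes.
#'
#' @param n_variant_sites,n_wt_sites Numbers of variant and wild-type sites.
#' @param mean_depth Mean qualified UMIs per site.
#' @param duplex_fraction Expected fraction of qualified UMIs that are
#'   duplex.
#' @param vaf Variant allele fraction at the variant sites.
#' @param alpha,beta Beta parameters of the background error distribution.
#' @param damage_rate Mean per-site single-strand damage rate (0 disables).
#' @param damage_shape Beta shape of the per-site damage-rate distribution.
#' @param seed Optional RNG seed.
#' @return data.table with `site_id`, `is_variant`, `N1`, `n1`, `N2`, `n2`.
#' @export
simulate_site_counts <- function(n_variant_sites, n_wt_sites, mean_depth,
                                 duplex_fraction, vaf,
                                 alpha = 2, beta = 40000,
                                 damage_rate = 0, damage_shape = 0.5,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- n_variant_sites + n_wt_sites
  stopifnot(ns >= 1, mean_depth > 0, duplex_fraction >= 0,
            duplex_fraction <= 1, vaf >= 0, vaf < 1)
  N <- rpois(ns, mean_depth)
  N2 <- rbinom(ns, N, duplex_fraction)
  N1 <- N - N2
  e <- rbeta(ns, alpha, beta)
  n1 <- rbinom(ns, N1, e)
  n2 <- rbinom(ns, N2, e^2)
  if (damage_rate > 0) {
    d <- rbeta(ns, damage_shape, damage_shape * (1 - damage_rate) / damage_rate)
    n1 <- n1 + rbinom(ns, N1 - n1, d)
  }
  is_variant <- c(rep(TRUE, n_variant_sites), rep(FALSE, n_wt_sites))
  if (n_variant_sites > 0 && vaf > 0) {
    iv <- which(is_variant)
    n1[iv] <- n1[iv] + rbinom(length(iv), N1[iv] - n1[iv], vaf)
    n2[iv] <- n2[iv] + rbinom(length(iv), N2[iv] - n2[iv], vaf)
  }
  data.table(site_id = seq_len(ns), is_variant = is_variant,
             N1 = N1, n1 = n1, N2 = N2, n2 = n2)
}
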