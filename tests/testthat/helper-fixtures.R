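library(data.table)

# two-locus random panel shared across tests
fixture_panel <- function(n_loci = 2L, seed = 42L, ...) {
  random_panel(n_loci = n_loci, seed = seed, ...)
}

# pick variant sites inside the well-covered target band and propose alts
pick_variants <- function(panel, idx, af) {
  vs <- target_sites(panel)[idx]
  alt <- c(A = "C", C = "A", G = "T", T = "G")[vs$ref]
  data.table(chrom = vs$chrom, pos = vs$pos, ref = vs$ref, alt = unname(alt),
             af = af)
}

# build a tagged_reads object directly from a family specification:
# fam_spec: data.table with umi, strand_label, frag_pos, n_reads and
# optionally locus_id, chrom, start, end, mapq, qual, n_alt, alt_base,
# alt_pos (reads carrying a non-reference base at alt_pos)
synth_tagged <- function(fam_spec, panel, sample_id = "S1") {
  fs <- as.data.table(fam_spec)
  l1 <- panel$loci[1]
  if (!"locus_id" %in% names(fs)) fs[, locus_id := l1$locus_id]
  if (!"chrom" %in% names(fs)) fs[, chrom := l1$chrom]
  if (!"start" %in% names(fs)) fs[, start := l1$target_start - 10L]
  if (!"end" %in% names(fs)) fs[, end := l1$target_end + 10L]
  if (!"mapq" %in% names(fs)) fs[, mapq := 60L]
  if (!"qual" %in% names(fs)) fs[, qual := 40L]
  if (!"n_alt" %in% names(fs)) fs[, n_alt := 0L]
  ridx <- rep(seq_len(nrow(fs)), fs$n_reads)
  reads <- fs[ridx, .(sample_id = sample_id, locus_id, chrom, frag_pos,
                      umi, strand_label, start, end, mapq,
                      mismatch_count = 0L, median_qual = qual)]
  reads[, read_id := sprintf("r%05d", .I)]
  events <- list()
  for (i in seq_len(nrow(fs))) {
    if (fs$n_alt[i] > 0L) {
      rid <- reads[which(ridx == i)[seq_len(fs$n_alt[i])], read_id]
      events[[length(events) + 1L]] <- data.table(
        read_id = rid, pos = fs$alt_pos[i], base = fs$alt_base[i],
        qual = fs$qual[i])
    }
  }
  events <- if (length(events)) rbindlist(events) else
    data.table(read_id = character(), pos = integer(), base = character(),
               qual = integer())
  mmc <- events[, .N, by = read_id]
  reads[mmc, mismatch_count := i.N, on = "read_id"]
  setcolorder(reads, "read_id")
  structure(list(reads = reads[], events = events,
                 rejects = table(character(0)), panel = panel),
            class = "tagged_reads")
}

# independent Beta-Binomial log pmf via the ratio recursion
# P(0) = prod_j (b+j)/(a+b+j);  P(n)/P(n-1) = (N-n+1)/n * (n-1+a)/(N-n+b)
oracle_lbetabinom <- function(n, N, a, b) {
  j <- seq_len(N) - 1
  lp <- sum(log(b + j) - log(a + b + j))
  if (n > 0) {
    k <- seq_len(n)
    lp <- lp + sum(log(N - k + 1) - log(k) + log(k - 1 + a) - log(N - k + b))
  }
  lp
}

# independent LLR evaluation mirroring the documented model definition
oracle_llr <- function(N1, n1, N2, n2, alpha, beta, floor = 1e-7,
                       mode = "duplex") {
  if (mode == "singleplex") {
    N1 <- N1 + 2 * N2; n1 <- n1 + 2 * n2; N2 <- 0; n2 <- 0
  }
  f <- (n1 + n2) / (N1 + N2)
  ed <- max((alpha / (alpha + beta))^2, floor)
  lbin <- function(k, n, p) {
    if (n == 0) return(0)
    lchoose(n, k) + ifelse(k == 0, 0, k * log(p)) +
      ifelse(n - k == 0, 0, (n - k) * log(1 - p))
  }
  l1 <- lbin(n1, N1, f) + lbin(n2, N2, f)
  l0 <- oracle_lbetabinom(n1, N1, alpha, beta) + lbin(n2, N2, ed)
  l1 - l0
}

# brute-force panel-wise error rates: explicit loop over types and rows
oracle_panel_rates <- function(fam_totals, fam_alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- data.table(type = substitution_types(), n = 0L, N = NA_integer_)
  for (k in seq_len(nrow(out))) {
    rb <- substr(out$type[k], 1, 1); ab <- substr(out$type[k], 3, 3)
    N <- 0L; n <- 0L; any_site <- FALSE
    for (i in seq_len(nrow(fam_totals))) {
      r <- fam_totals[i]
      tmpl <- if (r$strand_label == "TOP") r$ref else comp[[r$ref]]
      if (tmpl == rb) { N <- N + r$N; any_site <- TRUE }
    }
    for (i in seq_len(nrow(fam_alt))) {
      r <- fam_alt[i]
      tmpl <- if (r$strand_label == "TOP") r$ref else comp[[r$ref]]
      obs <- if (r$strand_label == "TOP") r$alt else comp[[r$alt]]
      if (tmpl == rb && obs == ab) n <- n + r$n
    }
    if (any_site) { out$N[k] <- N; out$n[k] <- n }
  }
  out[, rate := ifelse(is.na(N) | N == 0, NA_real_, n / N)]
  out[]
}
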