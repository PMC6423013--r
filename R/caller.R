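#' Caller configuration
#'
#' @param llr_threshold Natural-log likelihood-ratio threshold for calling
#'   (default 6, i.e. the mutation model must be about e^6 times more
#'   likely than the background model).
#' @param duplex_error_floor Lower bound on the duplex null error rate.
#'   The duplex null is the squared single-strand rate (an error must hit
#'   both strands independently); the floor guards against zero-probability
#'   likelihoods from end-repair-copied damage, which violates the
#'   independence assumption near fragment ends.
#' @param mode `"duplex"` uses single-plex and duplex evidence separately;
#'   `"singleplex"` treats every UMI as single-plex (each duplex contributes
#'   its two strand families), for head-to-head comparisons.
#' @param min_alt_evidence Minimum total non-reference UMIs for a call.
#' @return A `caller_config` object.
#' @export
caller_config <- function(llr_threshold = 6, duplex_error_floor = 1e-7,
                          mode = c("duplex", "singleplex"),
                          min_alt_evidence = 2L) {
  mode <- match.arg(mode)
  stopifnot(llr_threshold > 0, duplex_error_floor > 0,
            duplex_error_floor < 1, min_alt_evidence >= 0)
  structure(list(llr_threshold = llr_threshold,
                 duplex_error_floor = duplex_error_floor, mode = mode,
                 min_alt_evidence = as.integer(min_alt_evidence)),
            class = "caller_config")
}

# Beta-Binomial log pmf
lbetabinom <- function(n, N, alpha, beta) {
  lchoose(N, n) + lbeta(n + alpha, N - n + beta) - lbeta(alpha, beta)
}

#' Duplex-aware log-likelihood ratio
#'
#' Scores the evidence for a real mutation (`M1`) against background error
#' (`M0`) at sites with `N1` single-plex and `N2` duplex qualified UMIs of
#' which `n1` and `n2` carry the non-reference allele. Under `M0` the
#' single-plex count follows the Beta-Binomial background law
#' `n1 ~ BetaBin(N1, alpha, beta)` and the duplex count
#' `n2 ~ Binomial(N2, e_d)` with `e_d = max(mean^2, floor)`, since a duplex
#' non-reference consensus requires the same error independently on both
#' strands. Under `M1` all non-reference UMIs are real:
#' `n1 ~ Binomial(N1, f)` and `n2 ~ Binomial(N2, f)` with the
#' profile-likelihood plug-in `f = (n1+n2)/(N1+N2)`. The returned value is
#' `log L(M1) - log L(M0)` (natural log). In single-plex mode the counts
#' are first remapped (`N1 + 2*N2` single-plex UMIs, `n1 + 2*n2`
#' non-reference) so that every duplex contributes its two strand families
#' as independent single-plex evidence.
#'
#' All count arguments are vectorised.
#'
#' @param N1,n1,N2,n2 Qualified and non-reference UMI counts.
#' @param em An [error_model()] (requires `alpha`, `beta`).
#' @param cfg A [caller_config()].
#' @return Numeric vector of log-likelihood ratios (NA where
#'   `N1 + N2 == 0`).
#' @export
log_likelihood_ratio <- function(N1, n1, N2, n2, em,
                                 cfg = caller_config()) {
  if (is.na(em$alpha) || is.na(em$beta))
    stop("error model has no Beta parameters")
  if (cfg$mode == "singleplex") {
    N1 <- N1 + 2L * N2
    n1 <- n1 + 2L * n2
    N2 <- rep(0L, length(N1))
    n2 <- rep(0L, length(N1))
  }
  tot <- N1 + N2
  f <- ifelse(tot > 0, (n1 + n2) / tot, NA_real_)
  ed <- max((em$alpha / (em$alpha + em$beta))^2, cfg$duplex_error_floor)
  l1 <- dbinom(n1, N1, f, log = TRUE) + dbinom(n2, N2, f, log = TRUE)
  l0 <- lbetabinom(n1, N1, em$alpha, em$beta) +
    dbinom(n2, N2, ed, log = TRUE)
  out <- l1 - l0
  out[tot == 0] <- NA_real_
  out
}

#' Call variants from per-site counts
#'
#' Scores every site with the log-likelihood ratio and calls those at or
#' above the threshold with at least `min_alt_evidence` non-reference UMIs.
#'
#' @param sc A `site_counts` object, or a data.table with columns `N1`,
#'   `n1`, `N2`, `n2` (and optionally `chrom`, `pos`, `ref`, `alt`).
#' @param em An [error_model()].
#' @param cfg A [caller_config()].
#' @param vcf_path Optional path: called sites are additionally written as
#'   VCF 4.2.
#' @return data.table of all scored sites with `llr`, `vaf_hat`, `called`,
#'   `filter_status` (`PASS`, `LOW_LLR`, `MIN_ALT` or `NO_CALL`).
#' @export
call_variants <- function(sc, em, cfg = caller_config(), vcf_path = NULL) {
  x <- if (inherits(sc, "site_counts")) copy(sc$sites) else
    copy(as.data.table(sc))
  stopifnot(all(c("N1", "n1", "N2", "n2") %in% names(x)))
  x[, llr := log_likelihood_ratio(N1, n1, N2, n2, em, cfg)]
  x[, vaf_hat := fifelse(N1 + N2 > 0, (n1 + n2) / (N1 + N2), NA_real_)]
  x[, filter_status := fifelse(
    is.na(llr), "NO_CALL",
    fifelse(n1 + n2 < cfg$min_alt_evidence, "MIN_ALT",
            fifelse(llr >= cfg$llr_threshold, "PASS", "LOW_LLR")))]
  x[, called := filter_status == "PASS"]
  if (!is.null(vcf_path)) write_calls_vcf(x[called == TRUE], vcf_path)
  x[]
}

#' Write variant calls as VCF 4.2
#'
#' @param calls data.table with `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `llr`, `vaf_hat`, `N1`, `n1`, `N2`, `n2`.
#' @param path Output path.
#' @export
write_calls_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=LLR,Number=1,Type=Float,Description=\"Duplex-aware log likelihood ratio\">",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Estimated variant allele fraction\">",
           "##INFO=<ID=N1,Number=1,Type=Integer,Description=\"Qualified single-plex UMIs\">",
           "##INFO=<ID=AD1,Number=1,Type=Integer,Description=\"Non-reference single-plex UMIs\">",
           "##INFO=<ID=N2,Number=1,Type=Integer,Description=\"Qualified duplex UMIs\">",
           "##INFO=<ID=AD2,Number=1,Type=Integer,Description=\"Non-reference duplex UMIs\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls)) {
    alt <- calls$alt
    alt[is.na(alt)] <- "."
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tLLR=%.4f;VAF=%.6g;N1=%d;AD1=%d;N2=%d;AD2=%d",
            calls$chrom, calls$pos + 1L, calls$ref, alt, calls$llr,
            calls$vaf_hat, calls$N1, calls$n1, calls$N2, calls$n2)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Threshold sweep against a truth set
#'
#' Sweeps the call threshold over all observed scores and reports, for
#' each, the sensitivity (called true sites over all true sites) and the
#' number of false-positive calls. Sites failing the minimum-evidence rule
#' are never called at any threshold.
#'
#' @param scores data.table from [call_variants()] (needs `llr`,
#'   `filter_status`, and `chrom`+`pos` or `site_id`).
#' @param truth True variant sites: data.table with `chrom`+`pos` or
#'   `site_id`, or a VCF path.
#' @return data.table with `threshold`, `sensitivity`, `fp`, `n_called`,
#'   sorted by increasing threshold; `fp` is non-increasing.
#' @export
roc_sweep <- function(scores, truth) {
  x <- copy(as.data.table(scores))
  if (is.character(truth)) truth <- read_truth_vcf(truth)
  truth <- as.data.table(truth)
  if (nrow(truth) == 0L) stop("truth set is empty")
  key <- if ("site_id" %in% names(x) && "site_id" %in% names(truth))
    "site_id" else c("chrom", "pos")
  x[, is_true := FALSE]
  x[truth, is_true := TRUE, on = key]
  n_true <- sum(x$is_true)
  if (n_true == 0L) stop("no scored site matches the truth set")
  ## ineligible sites can never be called
  x[, llr := fifelse(filter_status %in% c("NO_CALL", "MIN_ALT"),
                     -Inf, llr)]
  setorder(x, -llr)
  x[, `:=`(ct = cumsum(is_true), cf = cumsum(!is_true))]
  thr <- x[is.finite(llr), .(sensitivity = max(ct) / n_true,
                             fp = max(cf), n_called = max(ct) + max(cf)),
           by = .(threshold = llr)]
  setorder(thr, threshold)
  thr[]
}

#' Operating point at a false-positive budget
#'
#' Chooses the smallest threshold whose false-positive count does not
#' exceed the budget and reports the sensitivity there.
#'
#' @param roc Output of [roc_sweep()].
#' @param max_fp Allowed false positives (0 for the zero-FP point).
#' @return list with `threshold`, `sensitivity`, `fp`.
#' @export
sensitivity_at_fp <- function(roc, max_fp = 0L) {
  ok <- roc[fp <= max_fp]
  if (nrow(ok) == 0L)
    return(list(threshold = Inf, sensitivity = 0, fp = 0L))
  best <- ok[which.min(threshold)]
  list(threshold = best$threshold, sensitivity = best$sensitivity,
       fp = best$fp)
}

#' False positives at a matched sensitivity
#'
#' Chooses the largest threshold that still reaches the requested
#' sensitivity and reports the false-positive count there, for
#' head-to-head comparisons of caller modes at matched sensitivity.
#'
#' @param roc Output of [roc_sweep()].
#' @param min_sensitivity Sensitivity that must be reached.
#' @return list with `threshold`, `sensitivity`, `fp`; `fp = Inf` when the
#'   sensitivity is unreachable.
#' @export
fp_at_sensitivity <- function(roc, min_sensitivity) {
  ok <- roc[sensitivity >= min_sensitivity]
  if (nrow(ok) == 0L)
    return(list(threshold = -Inf, sensitivity = max(roc$sensitivity),
                fp = Inf))
  best <- ok[which.max(threshold)]
  list(threshold = best$threshold, sensitivity = best$sensitivity,
       fp = best$fp)
}
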