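#' Wilson score confidence interval
#'
#' The Wilson interval for a Binomial proportion, used for the per-type
#' background error rates; bounds are clipped to `[0, 1]`.
#'
#' @param n Successes (vectorised).
#' @param N Trials.
#' @param conf Confidence level.
#' @return data.table with `lower` and `upper`.
#' @export
wilson_ci <- function(n, N, conf = 0.95) {
  if (any(N < 1)) stop("wilson_ci requires N >= 1")
  if (any(n < 0) || any(n > N)) stop("need 0 <= n <= N")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- n / N
  denom <- 1 + z^2 / N
  centre <- (p + z^2 / (2 * N)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / N + z^2 / (4 * N^2))
  data.table(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

# polymerase-frame substitution type of a family-level observation:
# top-strand families report (ref, alt) directly, bottom-strand families
# read the complementary template so the type is the complement pair
polymerase_type <- function(ref, alt, strand_label) {
  fifelse(strand_label == "BOTTOM",
          paste0(comp_base(ref), ">", comp_base(alt)),
          paste0(ref, ">", alt))
}

#' Panel-wise mean background substitution error rates
#'
#' For each substitution type X>Y, the pooled rate over all qualifying
#' sites: the summed non-reference consensus count divided by the summed
#' qualified (non-singleton, consensus) UMI total at sites whose template
#' base is X. Bottom-strand families are counted in the polymerase frame,
#' so reference-coordinate G-to-T observations on the bottom strand
#' contribute to the C>A type. Known variant sites must be excluded before
#' estimation. Types with no eligible site are reported as missing, not as
#' zero.
#'
#' @param sc A `site_counts` object from [site_counts_table()], or a list
#'   with `fam_totals` and `fam_alt` tables in the same shape.
#' @param exclude Optional data.table (`chrom`, `pos`) of sites to drop
#'   (known mutations from either mixture member).
#' @param conf Confidence level of the Wilson intervals.
#' @return data.table with one row per type: `type`, `n`, `N`, `rate`,
#'   `lower`, `upper` (rate NA when no eligible site exists).
#' @export
panel_error_rates <- function(sc, exclude = NULL, conf = 0.95) {
  tot <- as.data.table(sc$fam_totals)
  alt <- as.data.table(sc$fam_alt)
  if (nrow(tot) == 0L) stop("no qualified families: empty panel counts")
  if (!is.null(exclude) && nrow(exclude)) {
    exclude <- as.data.table(exclude)
    tot <- tot[!exclude, on = c("chrom", "pos")]
    alt <- alt[!exclude, on = c("chrom", "pos")]
  }
  types <- substitution_types()
  tot[, ptype := fifelse(strand_label == "BOTTOM", comp_base(ref), ref)]
  den <- tot[, .(N = sum(N)), by = ptype]
  if (nrow(alt)) {
    alt[, type := polymerase_type(ref, alt, strand_label)]
    num <- alt[, .(n = sum(n)), by = type]
  } else {
    num <- data.table(type = character(), n = integer())
  }
  out <- data.table(type = types)
  out[, c("tb") := substr(type, 1L, 1L)]
  out <- merge(out, den, by.x = "tb", by.y = "ptype", all.x = TRUE)
  out <- merge(out, num, by = "type", all.x = TRUE)
  out[is.na(n), n := 0L]
  out[, rate := fifelse(is.na(N) | N == 0, NA_real_, n / N)]
  ci <- out[, {
    ok <- !is.na(N) & N >= 1
    lw <- up <- rep(NA_real_, .N)
    if (any(ok)) {
      w <- wilson_ci(n[ok], N[ok], conf)
      lw[ok] <- w$lower; up[ok] <- w$upper
    }
    .(lower = lw, upper = up)
  }]
  out[, `:=`(lower = ci$lower, upper = ci$upper, tb = NULL)]
  setcolorder(out, c("type", "n", "N", "rate", "lower", "upper"))
  out[order(type)][]
}

#' Per-site counts for one substitution type
#'
#' Site-by-site (and strand-by-strand) qualified UMI totals and
#' non-reference counts for one polymerase-frame substitution type, the
#' input for [fit_beta()].
#'
#' @param sc A `site_counts` object.
#' @param type Substitution type, e.g. `"G>A"`.
#' @param exclude Optional sites to drop.
#' @return data.table with `chrom`, `pos`, `strand_label`, `N`, `n`.
#' @export
type_site_counts <- function(sc, type = "G>A", exclude = NULL) {
  rb <- substr(type, 1L, 1L)
  ab <- substr(type, 3L, 3L)
  tot <- as.data.table(sc$fam_totals)
  alt <- as.data.table(sc$fam_alt)
  if (!is.null(exclude) && nrow(exclude)) {
    exclude <- as.data.table(exclude)
    tot <- tot[!exclude, on = c("chrom", "pos")]
    alt <- alt[!exclude, on = c("chrom", "pos")]
  }
  tot <- tot[(strand_label == "TOP" & ref == rb) |
               (strand_label == "BOTTOM" & ref == comp_base(rb))]
  alt <- alt[(strand_label == "TOP" & ref == rb & alt == ab) |
               (strand_label == "BOTTOM" & ref == comp_base(rb) &
                  alt == comp_base(ab))]
  out <- merge(tot[, .(chrom, pos, strand_label, N)],
               alt[, .(chrom, pos, strand_label, n)],
               by = c("chrom", "pos", "strand_label"), all.x = TRUE)
  out[is.na(n), n := 0L]
  out[]
}

#' Maximum-likelihood Beta-Binomial fit of per-site error counts
#'
#' Models the site-to-site variation of the background error rate as
#' `e_i ~ Beta(alpha, beta)` with observed counts
#' `n_i ~ Binomial(N_i, e_i)`, i.e. a Beta-Binomial likelihood on the
#' counts. Fitting the counts rather than the empirical rates handles the
#' many sites with zero observed errors, for which a Beta likelihood on the
#' rate itself is undefined. When every site has zero errors the
#' distribution is undetermined and only the pooled mean (zero) is
#' returned, flagged accordingly.
#'
#' @param n,N Integer vectors of per-site non-reference counts and
#'   qualified UMI totals.
#' @param min_sites Below this number of sites a warning is issued.
#' @return list with `alpha`, `beta`, `mean` (`alpha/(alpha+beta)`),
#'   `pooled` (`sum(n)/sum(N)`), `loglik`, `status`
#'   (`"CONVERGED"`, `"MAXIT"` or `"UNDETERMINED"`).
#' @export
fit_beta <- function(n, N, min_sites = 20L) {
  stopifnot(length(n) == length(N), length(n) >= 1, all(n <= N),
            all(n >= 0), sum(N) > 0)
  if (length(n) < min_sites)
    warning("fewer than ", min_sites, " sites; Beta fit will be unstable")
  if (all(n == 0))
    return(list(alpha = NA_real_, beta = NA_real_, mean = 0,
                pooled = 0, loglik = 0, status = "UNDETERMINED"))
  pooled <- sum(n) / sum(N)
  ## collapse to unique (n, N) with weights for speed
  g <- data.table(n = n, N = N)[, .(w = .N), by = .(n, N)]
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    if (!is.finite(a) || !is.finite(b)) return(1e18)
    -sum(g$w * (lchoose(g$N, g$n) + lbeta(g$n + a, g$N - g$n + b) -
                  lbeta(a, b)))
  }
  init <- log(c(1, (1 - pooled) / pooled))
  opt <- optim(init, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  a <- exp(opt$par[1]); b <- exp(opt$par[2])
  list(alpha = a, beta = b, mean = a / (a + b), pooled = pooled,
       loglik = -opt$value,
       status = if (opt$convergence == 0) "CONVERGED" else "MAXIT")
}

#' One-sided test for end-repair artifact enrichment near fragment ends
#'
#' Lesions copied during end-repair fill-in sit close to the ligated
#' (UMI-bearing) 5' fragment end, whereas real variants are uniformly
#' placed within fragments. Compares the two distance samples with a Welch
#' two-sample t statistic and returns the one-sided p-value for the
#' alternative that artifact distances are smaller.
#'
#' @param artifact_distances,variant_distances Distances (bp, >= 0) from
#'   the non-reference site to the ligated fragment end.
#' @return list with `p_value`, `t`, `df`, `mean_artifact`,
#'   `mean_variant`.
#' @export
end_distance_test <- function(artifact_distances, variant_distances) {
  a <- artifact_distances; b <- variant_distances
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    p <- if (mean(a) < mean(b)) 0 else if (mean(a) == mean(b)) 0.5 else 1
    return(list(p_value = p, t = NA_real_, df = NA_real_,
                mean_artifact = mean(a), mean_variant = mean(b)))
  }
  se <- sqrt(va / length(a) + vb / length(b))
  tstat <- (mean(a) - mean(b)) / se
  df <- se^4 / ((va / length(a))^2 / (length(a) - 1) +
                  (vb / length(b))^2 / (length(b) - 1))
  list(p_value = pt(tstat, df), t = tstat, df = df,
       mean_artifact = mean(a), mean_variant = mean(b))
}

#' Background error model
#'
#' Container for the per-type background rates and the fitted Beta law of
#' the site-to-site error rate distribution. The distribution is fitted on
#' one profile type (G>A by default, the most abundant residual error
#' class) and conservatively applied to all substitution types; per-type
#' fits can be requested.
#'
#' @param alpha,beta Beta parameters.
#' @param rates Optional per-type rate table (from [panel_error_rates()]).
#' @param profile_type The substitution type the Beta law was fitted on.
#' @return An `error_model` object with `alpha`, `beta`,
#'   `mean` = alpha/(alpha+beta), `rates`, `profile_type`.
#' @export
error_model <- function(alpha, beta, rates = NULL, profile_type = "G>A") {
  stopifnot(is.numeric(alpha), is.numeric(beta))
  if (!is.na(alpha) && (alpha <= 0 || beta <= 0))
    stop("alpha and beta must be positive")
  structure(list(alpha = alpha, beta = beta,
                 mean = if (is.na(alpha)) NA_real_ else alpha / (alpha + beta),
                 rates = rates, profile_type = profile_type),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("background error model: Beta(alpha=", signif(x$alpha, 4),
      ", beta=", signif(x$beta, 4), "), mean rate ",
      signif(x$mean, 4), " (profile ", x$profile_type, ")\n", sep = "")
  invisible(x)
}

#' Estimate the background error model from consensus counts
#'
#' Computes the per-type panel rates and fits the Beta-Binomial error
#' distribution on the profile type. If the profile type shows no errors at
#' all (undetermined dispersion), the model falls back to the supplied
#' default Beta parameters, which encode the background magnitude of a few
#' errors per 100,000 UMIs typical of mildly sonicated libraries.
#'
#' @param sc A `site_counts` object.
#' @param exclude Known variant sites to exclude (`chrom`, `pos`).
#' @param profile_type Type carrying the fitted distribution.
#' @param per_type Also fit every type individually (returned in `fits`).
#' @param fallback_alpha,fallback_beta Used when the profile fit is
#'   undetermined.
#' @return An `error_model` object (with `fit` details attached).
#' @export
build_error_model <- function(sc, exclude = NULL, profile_type = "G>A",
                              per_type = FALSE,
                              fallback_alpha = 2, fallback_beta = 40000) {
  rates <- panel_error_rates(sc, exclude = exclude)
  tsc <- type_site_counts(sc, profile_type, exclude = exclude)
  fit <- if (nrow(tsc)) fit_beta(tsc$n, tsc$N, min_sites = 1L) else
    list(alpha = NA_real_, beta = NA_real_, mean = 0, pooled = 0,
         status = "UNDETERMINED")
  if (identical(fit$status, "UNDETERMINED") || is.na(fit$alpha)) {
    em <- error_model(fallback_alpha, fallback_beta, rates, profile_type)
  } else {
    em <- error_model(fit$alpha, fit$beta, rates, profile_type)
  }
  em$fit <- fit
  if (per_type) {
    em$fits <- lapply(setNames(nm = substitution_types()), function(ty) {
      x <- type_site_counts(sc, ty, exclude = exclude)
      if (nrow(x)) fit_beta(x$n, x$N, min_sites = 1L) else NULL
    })
  }
  em
}

#' Write / read an error model as JSON
#'
#' @param em An [error_model()].
#' @param path JSON path.
#' @return `read_error_model` returns an [error_model()].
#' @export
write_error_model <- function(em, path) {
  x <- list(alpha = em$alpha, beta = em$beta, mean = em$mean,
            profile_type = em$profile_type)
  if (!is.null(em$rates)) x$rates <- em$rates
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_error_model
#' @export
read_error_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rates <- if (!is.null(x$rates)) as.data.table(x$rates) else NULL
  error_model(x$alpha, x$beta, rates, x$profile_type)
}
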