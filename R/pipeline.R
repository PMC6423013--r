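#' Run the full pipeline from reads to variant calls
#'
#' Convenience wrapper chaining UMI decoding, family grouping and merging,
#' duplex pairing, per-site consensus counting, background error modelling
#' and variant calling.
#'
#' @param reads A `read_set` from [tag_and_sequence()], or a reads table
#'   (see [tag_reads()]).
#' @param align Alignment table; defaults to the read set's truth table.
#' @param panel A [panel_design()]; defaults to the read set's panel.
#' @param layout A [read_layout()].
#' @param merge_cfg A [merge_config()].
#' @param cons_cfg A [consensus_config()].
#' @param em An [error_model()], or NULL to estimate one from the data
#'   (excluding `known_variants`).
#' @param caller_cfg A [caller_config()].
#' @param known_variants data.table (`chrom`, `pos`) of sites excluded from
#'   error-rate estimation.
#' @param sample_id Sample identifier.
#' @return list with `groups`, `site_counts`, `error_model`, `calls`,
#'   `duplex_fraction`, `rejects`.
#' @export
run_pipeline <- function(reads, align = NULL, panel = NULL,
                         layout = read_layout(),
                         merge_cfg = merge_config(),
                         cons_cfg = consensus_config(),
                         em = NULL,
                         caller_cfg = caller_config(),
                         known_variants = NULL,
                         sample_id = "S1") {
  if (inherits(reads, "read_set")) {
    if (is.null(align)) align <- reads$truth_align
    if (is.null(panel)) panel <- reads$molecule_set$panel
  }
  if (is.null(panel)) stop("a panel_design is required")
  dg <- process_reads(reads, align, panel, layout, merge_cfg, sample_id)
  sc <- site_counts_table(dg, cfg = cons_cfg)
  if (is.null(em))
    em <- build_error_model(sc, exclude = known_variants)
  calls <- call_variants(sc, em, caller_cfg)
  list(groups = dg, site_counts = sc, error_model = em, calls = calls,
       duplex_fraction = duplex_fraction(dg), rejects = dg$rejects)
}

#' Distances of non-reference consensus calls to the ligated fragment end
#'
#' Splits the per-call distance records of a `site_counts` object into
#' artifact and true-variant groups for the end-repair artifact test.
#'
#' @param sc A `site_counts` object.
#' @param truth_variants data.table (`chrom`, `pos`) of true variant sites.
#' @param evidence Restrict to `"duplex"` calls (the artifact class of
#'   interest: single-strand damage only gains duplex support through
#'   end-repair copying), `"singleplex"`, or `"all"`.
#' @return list with numeric vectors `artifact` and `variant` of distances
#'   (bp) to the ligated end.
#' @export
end_distances <- function(sc, truth_variants,
                          evidence = c("duplex", "all", "singleplex")) {
  evidence <- match.arg(evidence)
  keep_class <- evidence
  ev <- copy(sc$alt_events)
  if (keep_class != "all") ev <- ev[ev$evidence == keep_class]
  truth_variants <- as.data.table(truth_variants)
  ev[, is_true := FALSE]
  if (nrow(truth_variants))
    ev[truth_variants, is_true := TRUE, on = c("chrom", "pos")]
  list(artifact = ev[is_true == FALSE, dist5],
       variant = ev[is_true == TRUE, dist5])
}
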