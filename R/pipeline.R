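# End-to-end expression-level-polymorphism pipeline: quantile normalization,
# per-probe two-way ANOVA, Venn partition, probe-set summarization with TGT
# scaling, replicate QC, CIP calling and quadrant classification.

#' Run the probe-to-CIP pipeline
#'
#' @param intensities Probe-level intensity matrix (linear scale).
#' @param design Balanced design data.frame.
#' @param map Probe map data.frame.
#' @param config A [pipeline_config()].
#' @return A list with `normalized` (intensity matrix), `anova` (per-probe
#'   records), `venn` (region counts), `signals` (probe-set signal matrix),
#'   `qc` (replicate correlations), `cips` (called CIPs) and
#'   `quadrant_counts`.
#' @export
run_elp_pipeline <- function(intensities, design, map,
                             config = pipeline_config()) {
  norm <- quantile_normalize(intensities)
  records <- anova_all_probes(norm, design)
  venn <- venn_regions(records, config$alpha)
  signals <- summarize_probesets(norm, map, tgt = config$tgt)
  qc <- replicate_correlation(signals, design)
  cips <- call_cips(records, map, alpha = config$alpha,
                    min_core_probes = config$min_core_probes,
                    signals = signals, design = design)
  list(normalized = norm, anova = records, venn = venn, signals = signals,
       qc = qc, cips = cips, quadrant_counts = quadrant_summary(cips))
}
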