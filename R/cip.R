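# Core Intersectional Probeset (CIP) calling: probes are assigned to Venn
# regions of the three ANOVA effects at a raw-p threshold; a probe set is a
# CIP when at least `min_core_probes` member probes are significant for all
# three effects; each CIP is placed in one of four expression quadrants from
# the signs of its cultivar-preference and treatment-response deltas.

.sig_matrix <- function(records, alpha, use_q = FALSE) {
  cols <- if (use_q) c("q_cultivar", "q_treatment", "q_interaction") else
    c("p_cultivar", "p_treatment", "p_interaction")
  s <- as.matrix(records[, cols]) <= alpha
  colnames(s) <- c("cultivar", "treatment", "interaction")
  s
}

#' Venn-region counts of probe-level significance
#'
#' A probe is significant for an effect iff its raw p-value is `<= alpha`;
#' each probe falls in exactly one of the 8 regions (7 non-empty effect
#' subsets plus `none`).
#'
#' @param records ANOVA record data.frame from [anova_all_probes()].
#' @param alpha Significance threshold (default 0.01).
#' @return Named integer vector over the 8 regions; sums to the probe count.
#' @export
venn_regions <- function(records, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  s <- .sig_matrix(records, alpha)
  key <- paste0(ifelse(s[, "cultivar"], "c", ""),
                ifelse(s[, "treatment"], "t", ""),
                ifelse(s[, "interaction"], "i", ""))
  lv <- c(c = "cultivar_only", t = "treatment_only", i = "interaction_only",
          ct = "cultivar_treatment", ci = "cultivar_interaction",
          ti = "treatment_interaction", cti = "triple", none = "none")
  key[key == ""] <- "none"
  counts <- table(factor(lv[key], levels = unname(lv)))
  stats::setNames(as.integer(counts), unname(lv))
}

#' Classify a probe set into an expression quadrant
#'
#' `cultivar_delta` is the mean log2 signal over genotype-A arrays minus the
#' mean over genotype-B arrays; `treatment_delta` is treated minus control.
#' The quadrant follows the sign pair; an exactly zero delta gives
#' `unclassified`.
#'
#' @param signal_row Named numeric vector of one probe set's signals (linear
#'   scale), names = array ids.
#' @param design Design data.frame.
#' @param genotype_a Label of the genotype playing the reference ("A") role;
#'   defaults to the first genotype appearing in the design.
#' @return A list with `quadrant`, `cultivar_delta`, `treatment_delta`.
#' @export
classify_quadrant <- function(signal_row, design, genotype_a = NULL) {
  if (is.null(genotype_a)) genotype_a <- design$genotype[1L]
  if (!all(design$array_id %in% names(signal_row))) {
    stop("signals missing for some arrays in the design")
  }
  lg <- log2(signal_row[design$array_id])
  dc <- mean(lg[design$genotype == genotype_a]) -
    mean(lg[design$genotype != genotype_a])
  dt <- mean(lg[design$treatment == "treated"]) -
    mean(lg[design$treatment == "control"])
  quadrant <- if (dc == 0 || dt == 0) "unclassified" else
    if (dc > 0 && dt > 0) "prefA_up" else
    if (dc > 0) "prefA_down" else
    if (dt > 0) "prefB_up" else "prefB_down"
  list(quadrant = quadrant, cultivar_delta = unname(dc),
       treatment_delta = unname(dt))
}

#' Call Core Intersectional Probesets
#'
#' A probe is a core probe iff all three raw p-values are `<= alpha`; a probe
#' set is called iff it has at least `min_core_probes` core probes. When a
#' signal matrix and design are supplied, each called set is also classified
#' into its expression quadrant.
#'
#' @param records ANOVA record data.frame.
#' @param map Probe map data.frame covering every probe in `records`.
#' @param alpha Raw-p threshold (default 0.01).
#' @param min_core_probes Minimum core probes per called set (default 3).
#' @param signals Optional signal matrix (probe sets x arrays).
#' @param design Design data.frame (required with `signals`).
#' @param genotype_a Reference genotype label (see [classify_quadrant()]).
#' @param use_q Gate on BH q-values instead of raw p (default FALSE).
#' @return A data.frame with one row per called set: `probeset_id`,
#'   `n_probes_total`, `n_core_probes`, `quadrant`, `cultivar_delta`,
#'   `treatment_delta`.
#' @export
call_cips <- function(records, map, alpha = 0.01, min_core_probes = 3L,
                      signals = NULL, design = NULL, genotype_a = NULL,
                      use_q = FALSE) {
  missing_map <- setdiff(records$probe_id, map$probe_id)
  if (length(missing_map)) stop("probe absent from map: ", missing_map[1L])
  s <- .sig_matrix(records, alpha, use_q)
  core <- rowSums(s) == 3L
  set_of <- map$probeset_id[match(records$probe_id, map$probe_id)]
  n_core <- tapply(core, set_of, sum)
  n_tot <- tapply(core, set_of, length)
  called <- names(n_core)[n_core >= min_core_probes]
  called <- called[order(called)]
  out <- data.frame(probeset_id = called,
                    n_probes_total = as.integer(n_tot[called]),
                    n_core_probes = as.integer(n_core[called]),
                    quadrant = rep("unclassified", length(called)),
                    cultivar_delta = rep(NA_real_, length(called)),
                    treatment_delta = rep(NA_real_, length(called)),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(signals) && nrow(out)) {
    if (is.null(design)) stop("design required to classify quadrants")
    for (i in seq_len(nrow(out))) {
      sid <- out$probeset_id[i]
      if (!sid %in% rownames(signals)) next
      q <- classify_quadrant(signals[sid, ], design, genotype_a)
      out$quadrant[i] <- q$quadrant
      out$cultivar_delta[i] <- q$cultivar_delta
      out$treatment_delta[i] <- q$treatment_delta
    }
  }
  out
}

#' Count CIPs per expression quadrant
#'
#' @param cips CIP data.frame from [call_cips()].
#' @return Named integer vector over the four quadrants plus `unclassified`;
#'   sums to the CIP count.
#' @export
quadrant_summary <- function(cips) {
  lv <- c("prefA_up", "prefA_down", "prefB_up", "prefB_down", "unclassified")
  tab <- table(factor(cips$quadrant, levels = lv))
  stats::setNames(as.integer(tab), lv)
}
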