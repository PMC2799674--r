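# Array-level preprocessing: quantile normalization across arrays,
# probe-set summarization by trimmed mean of log2 intensities with
# target-mean (TGT) scaling, and replicate-correlation QC.

#' Quantile-normalize an intensity matrix across arrays
#'
#' Every column's value multiset becomes the vector of row means of the
#' column-sorted data; within a column the original rank order is preserved
#' and ties receive the mean of the tied quantile values. A single-column
#' matrix is returned unchanged. The operation is idempotent.
#'
#' @param m Numeric matrix (probes x arrays), positive values.
#' @return Normalized matrix with the same dimnames.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), all(is.finite(m)), all(m > 0))
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Summarize probe sets into per-array signals with TGT scaling
#'
#' Per probe set and array the signal is `2^(trimmed mean of log2 probe
#' intensities)` (20% symmetric trim by default). Each array's signals are
#' then multiplied by a scalar so its 2%-trimmed mean of signals equals
#' `tgt`. Set `tgt = NULL` to skip scaling.
#'
#' @param m Intensity matrix (probes x arrays).
#' @param map Probe map data.frame.
#' @param tgt Target trimmed-mean signal (default 500), or `NULL`.
#' @param set_trim Trim fraction within a probe set (default 0.2).
#' @param array_trim Trim fraction for per-array scaling (default 0.02).
#' @return Signal matrix (probe sets x arrays).
#' @export
summarize_probesets <- function(m, map, tgt = 500, set_trim = 0.2,
                                array_trim = 0.02) {
  missing_map <- setdiff(rownames(m), map$probe_id)
  if (length(missing_map)) {
    stop("probe(s) absent from map: ", missing_map[1L])
  }
  lg <- log2(m)
  sets <- unique(map$probeset_id)
  sig <- matrix(NA_real_, nrow = length(sets), ncol = ncol(m),
                dimnames = list(sets, colnames(m)))
  empty <- character(0)
  for (s in sets) {
    pid <- map$probe_id[map$probeset_id == s]
    pid <- intersect(pid, rownames(m))
    if (!length(pid)) { empty <- c(empty, s); next }
    sig[s, ] <- 2^apply(lg[pid, , drop = FALSE], 2, mean, trim = set_trim)
  }
  if (length(empty)) {
    warning("probe set(s) with no probes in matrix omitted: ",
            paste(empty, collapse = ", "))
    sig <- sig[setdiff(sets, empty), , drop = FALSE]
  }
  if (!is.null(tgt)) {
    f <- tgt / apply(sig, 2, mean, trim = array_trim)
    sig <- sweep(sig, 2, f, `*`)
  }
  sig
}

#' Replicate-correlation quality control
#'
#' Computes the Pearson correlation of log2 signals for every pair of arrays
#' within the same genotype x treatment cell. Pairs below the threshold, or
#' with zero variance (undefined r), are flagged.
#'
#' @param signals Signal matrix (probe sets x arrays).
#' @param design Design data.frame.
#' @param threshold Flagging threshold on r (default 0.98).
#' @return A data.frame with columns `array_1`, `array_2`, `genotype`,
#'   `treatment`, `r`, `flagged`.
#' @export
replicate_correlation <- function(signals, design, threshold = 0.98) {
  cells <- split(design$array_id, paste(design$genotype, design$treatment))
  if (!any(lengths(cells) >= 2L)) stop("no cell has >= 2 replicates")
  rows <- list()
  for (cell in names(cells)) {
    ids <- intersect(cells[[cell]], colnames(signals))
    if (length(ids) < 2L) next
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq((i + 1L), length(ids))) {
        x <- log2(signals[, ids[i]])
        y <- log2(signals[, ids[j]])
        r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
          stats::cor(x, y)
        gt <- design[match(ids[i], design$array_id), ]
        rows[[length(rows) + 1L]] <- data.frame(
          array_1 = ids[i], array_2 = ids[j],
          genotype = gt$genotype, treatment = gt$treatment, r = r,
          flagged = is.na(r) || r < threshold,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
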