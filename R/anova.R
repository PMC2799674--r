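# Per-probe balanced two-way fixed-effects ANOVA (genotype x treatment with
# interaction) on log2 intensities, with closed-form sums of squares:
#   SS_A  = 2r * sum_a (ybar_a - ybar)^2
#   SS_B  = 2r * sum_b (ybar_b - ybar)^2
#   SS_AB = r * sum_ab (ybar_ab - ybar_a - ybar_b + ybar)^2
#   SSE   = within-cell squared deviations
# Each F has (1, 4(r-1)) degrees of freedom. With two levels per factor this
# reduces to contrasts of the four cell means, which is how the vectorized
# engine below computes it.

.anova_engine <- function(Y, geno, treat) {
  # Y: probes x arrays (log2); geno/treat: logical vectors (level-1 indicator)
  cells <- list(aa = geno & treat, ab = geno & !treat,
                ba = !geno & treat, bb = !geno & !treat)
  r <- unique(vapply(cells, sum, 1L))
  if (length(r) != 1L) stop("design must be balanced across the four cells")
  if (r < 2L) stop("need at least 2 replicates per cell")
  C <- vapply(cells, function(ix) rowMeans(Y[, ix, drop = FALSE]),
              numeric(nrow(Y)))
  if (nrow(Y) == 1L) C <- matrix(C, nrow = 1L, dimnames = list(NULL, names(cells)))
  dA <- (C[, "aa"] + C[, "ab"]) / 2 - (C[, "ba"] + C[, "bb"]) / 2
  dB <- (C[, "aa"] + C[, "ba"]) / 2 - (C[, "ab"] + C[, "bb"]) / 2
  dI <- C[, "aa"] - C[, "ab"] - C[, "ba"] + C[, "bb"]
  ss_a <- r * dA^2
  ss_b <- r * dB^2
  ss_i <- r * dI^2 / 4
  sse <- rowSums(Y^2) - r * rowSums(C^2)
  sse <- pmax(sse, 0)
  dfe <- 4 * (r - 1)
  mse <- sse / dfe
  scale2 <- rowMeans(Y^2) + 1
  degen <- mse < 1e-12 * scale2
  f_of <- function(ss) {
    f <- ifelse(degen, ifelse(ss < 1e-12 * scale2, 0, Inf), ss / mse)
    f
  }
  p_of <- function(f) {
    p <- stats::pf(f, 1, dfe, lower.tail = FALSE)
    p[is.infinite(f)] <- 0
    p
  }
  Fa <- f_of(ss_a); Fb <- f_of(ss_b); Fi <- f_of(ss_i)
  list(F_cultivar = Fa, F_treatment = Fb, F_interaction = Fi,
       p_cultivar = p_of(Fa), p_treatment = p_of(Fb), p_interaction = p_of(Fi),
       degenerate = degen, df_error = dfe)
}

#' Two-way ANOVA on one probe's cell values
#'
#' Fits the balanced 2 x 2 fixed-effects model with interaction to a single
#' probe's log2 intensities and returns the F and p triplets for the
#' cultivar (genotype), treatment and interaction effects.
#'
#' If all residual variance is zero the contract is: zero effect sum of
#' squares gives p = 1, positive effect sum of squares gives p = 0; both are
#' flagged `degenerate`.
#'
#' @param cell_values A 2 x 2 x r numeric array (genotype x treatment x
#'   replicate) of log2 intensities.
#' @return A list with `F` and `p` (named length-3 vectors: `cultivar`,
#'   `treatment`, `interaction`), `df_error` and `degenerate`.
#' @export
fit_two_way_anova <- function(cell_values) {
  d <- dim(cell_values)
  if (is.null(d) || length(d) != 3L || d[1] != 2L || d[2] != 2L) {
    stop("cell_values must be a 2 x 2 x r array")
  }
  r <- d[3]
  if (r < 2L) stop("need at least 2 replicates per cell")
  if (any(!is.finite(cell_values))) stop("cell_values must be finite (balanced design)")
  # flatten so that column block k holds (g1t1, g1t2, g2t1, g2t2) of replicate k
  geno <- rep(c(TRUE, TRUE, FALSE, FALSE), times = r)
  treat <- rep(c(TRUE, FALSE, TRUE, FALSE), times = r)
  Y <- matrix(as.numeric(vapply(seq_len(r), function(k) {
    c(cell_values[1, 1, k], cell_values[1, 2, k],
      cell_values[2, 1, k], cell_values[2, 2, k])
  }, numeric(4))), nrow = 1L)
  res <- .anova_engine(Y, geno, treat)
  list(F = c(cultivar = res$F_cultivar, treatment = res$F_treatment,
             interaction = res$F_interaction),
       p = c(cultivar = res$p_cultivar, treatment = res$p_treatment,
             interaction = res$p_interaction),
       df_error = res$df_error, degenerate = res$degenerate)
}

#' Per-probe two-way ANOVA across a whole intensity matrix
#'
#' Applies the balanced 2 x 2 ANOVA to every probe row of a
#' quantile-normalized intensity matrix, on the log2 scale, and fills BH FDR
#' q-values per effect across all probes.
#'
#' @param m Intensity matrix (probes x arrays), linear scale, normalized.
#' @param design Balanced design data.frame.
#' @param log2_transform Take log2 of `m` first (default TRUE).
#' @return A data.frame with one row per probe: `probe_id`, F/p/q for each of
#'   the cultivar, treatment and interaction effects, and `degenerate`.
#' @export
anova_all_probes <- function(m, design, log2_transform = TRUE) {
  if (!all(design$array_id %in% colnames(m))) {
    stop("intensity matrix is missing arrays present in the design")
  }
  Y <- m[, design$array_id, drop = FALSE]
  if (log2_transform) Y <- log2(Y)
  geno <- design$genotype == design$genotype[1L]
  treat <- design$treatment == "treated"
  if (length(unique(design$genotype)) != 2L) stop("need exactly two genotypes")
  res <- .anova_engine(Y, geno, treat)
  data.frame(probe_id = rownames(m),
             F_cultivar = res$F_cultivar, p_cultivar = res$p_cultivar,
             q_cultivar = bh_fdr(res$p_cultivar),
             F_treatment = res$F_treatment, p_treatment = res$p_treatment,
             q_treatment = bh_fdr(res$p_treatment),
             F_interaction = res$F_interaction,
             p_interaction = res$p_interaction,
             q_interaction = bh_fdr(res$p_interaction),
             degenerate = res$degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_(j >= i) (p_(j) * m / j)` over the sorted p-values, mapped
#' back to input order and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
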