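# Seed-and-refine de novo motif discovery over promoter sets, plus IUPAC
# pattern scanning for known cis-elements (e.g. the W-box AGTCAAAC).
#
# Discovery: every w-mer of the top-ranked sequences (both strands) seeds a
# candidate; all foreground w-mers matching the seed at >= m positions form
# its site set; candidates are scored by a relative-entropy criterion
# weighted by log2(n_sites), the top K are refined by greedy single-site
# add/remove moves within the candidate's site pool, accepted only when the
# score increases, and results are deduplicated by consensus. Fully
# deterministic.

.BASES <- c("A", "C", "G", "T")

.revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "", USE.NAMES = FALSE)
}

# n x (4w) one-hot encoding of equal-length strings
.onehot <- function(strings, w) {
  n <- length(strings)
  mat <- matrix(0L, nrow = n, ncol = 4L * w)
  chars <- matrix(unlist(strsplit(strings, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  for (j in seq_len(w)) {
    b <- match(chars[, j], .BASES)
    mat[cbind(seq_len(n), (j - 1L) * 4L + b)] <- 1L
  }
  mat
}

.score_flat <- function(counts, n, log2bg, w) {
  # counts: length 4w; log2bg: log2 background repeated per column
  f <- (counts + 0.5) / (n + 2)
  log2(n) * sum(f * (log2(f) - log2bg)) / w
}

.consensus_of <- function(counts_mat) {
  # counts_mat: 4 x w, rows A,C,G,T; ties broken alphabetically
  paste(.BASES[apply(counts_mat, 2, which.max)], collapse = "")
}

#' Score a motif model
#'
#' With pseudocounted frequencies `f_ib = (count_ib + 0.5) / (n_sites + 2)`,
#' the score is `log2(n_sites) * (1/w) * sum_i sum_b f_ib * log2(f_ib / p_b)`
#' - the mean per-column relative entropy against the background, weighted by
#' the log of the number of sites.
#'
#' @param m A motif model (list with `counts` 4 x w matrix, rows A/C/G/T, and
#'   `n_sites`), as returned by [find_motifs()].
#' @param background Background base frequencies (A, C, G, T), positive,
#'   summing to 1 (default uniform).
#' @return The numeric score.
#' @export
motif_score <- function(m, background = rep(0.25, 4)) {
  stopifnot(all(background > 0), abs(sum(background) - 1) < 1e-9)
  if (m$n_sites < 2L) stop("motif must have at least 2 sites")
  w <- ncol(m$counts)
  .score_flat(as.numeric(m$counts), m$n_sites,
              rep(log2(background), times = w), w)
}

.enumerate_windows <- function(seqs, w) {
  rows <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    L <- nchar(s)
    if (L < w) return(NULL)
    starts <- seq_len(L - w + 1L)
    fwd <- substring(s, starts, starts + w - 1L)
    data.frame(seq_id = id, offset = c(starts, starts),
               strand = rep(c("+", "-"), each = length(starts)),
               site = c(fwd, .revcomp(fwd)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' De novo motif discovery by seed-and-refine search
#'
#' @param foreground Named character vector of sequences, in rank order
#'   (most confident first).
#' @param background Optional named character vector; its 0-order base
#'   frequencies form the background model (uniform if `NULL`).
#' @param w Motif width (default 8).
#' @param top_t Number of top foreground sequences providing seeds
#'   (default 5).
#' @param match_min Minimum matching positions for a w-mer to join a seed's
#'   site set (default `w - 2`).
#' @param max_candidates Candidates kept for refinement (default 30).
#' @param max_iter Refinement iteration bound (default 100).
#' @return A list of motif models sorted by descending score (ties broken
#'   lexicographically by consensus); each has `width`, `counts`, `n_sites`,
#'   `sites` (data.frame `seq_id`, `offset`, `strand`), `consensus`, `score`.
#' @export
find_motifs <- function(foreground, background = NULL, w = 8L, top_t = 5L,
                        match_min = w - 2L, max_candidates = 30L,
                        max_iter = 100L) {
  stopifnot(!is.null(names(foreground)), w >= 2L)
  foreground <- toupper(foreground)
  if (any(nchar(foreground) < w)) stop("motif width exceeds shortest sequence")
  top_t <- min(top_t, length(foreground))
  bg <- if (is.null(background)) rep(0.25, 4) else {
    cnt <- colSums(Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(toupper(background)))[, .BASES, drop = FALSE])
    if (sum(cnt) == 0) rep(0.25, 4) else pmax(cnt / sum(cnt), 1e-6)
  }
  bg <- bg / sum(bg)
  log2bg <- rep(log2(bg), times = w)

  win <- .enumerate_windows(foreground, w)
  W <- .onehot(win$site, w)
  seed_pool <- unique(win$site[win$seq_id %in% names(foreground)[seq_len(top_t)]])
  S <- .onehot(seed_pool, w)
  # match count between every window and every seed via one-hot inner product
  M <- W %*% t(S)

  poskey <- paste(win$seq_id, win$offset)
  candidates <- list()
  for (j in seq_along(seed_pool)) {
    idx <- which(M[, j] >= match_min)
    if (length(idx) < 2L) next
    # one site per (sequence, offset): keep the better-matching strand
    o <- idx[order(-M[idx, j], win$strand[idx])]
    o <- o[!duplicated(poskey[o])]
    if (length(o) < 2L) next
    counts <- colSums(W[o, , drop = FALSE])
    candidates[[length(candidates) + 1L]] <-
      list(idx = o, pool = o, counts = counts,
           score = .score_flat(counts, length(o), log2bg, w))
  }
  if (!length(candidates)) return(list())
  ord <- order(-vapply(candidates, `[[`, 0, "score"))
  candidates <- candidates[ord[seq_len(min(max_candidates, length(ord)))]]

  LB <- matrix(log2bg, nrow = nrow(W), ncol = 4L * w, byrow = TRUE)
  refined <- lapply(candidates, function(cand) {
    idx <- cand$idx
    counts <- cand$counts
    score <- cand$score
    for (it in seq_len(max_iter)) {
      n <- length(idx)
      # best addition, drawn from the candidate's own site pool
      outside <- setdiff(cand$pool, idx)
      best_add <- -Inf; add_j <- NA_integer_
      if (length(outside)) {
        Fo <- (W[outside, , drop = FALSE] +
                 rep(counts + 0.5, each = length(outside))) / (n + 3)
        s_add <- log2(n + 1) *
          rowSums(Fo * (log2(Fo) - LB[outside, , drop = FALSE])) / w
        best_add <- max(s_add)
        add_j <- outside[which.max(s_add)]
      }
      # best removal (keep >= 2 sites)
      best_rm <- -Inf; rm_j <- NA_integer_
      if (n > 2L) {
        Fr <- (rep(counts + 0.5, each = n) -
                 W[idx, , drop = FALSE]) / (n + 1)
        s_rm <- log2(n - 1) *
          rowSums(Fr * (log2(Fr) - LB[idx, , drop = FALSE])) / w
        best_rm <- max(s_rm)
        rm_j <- idx[which.max(s_rm)]
      }
      if (max(best_add, best_rm) <= score + 1e-12) break
      if (best_add >= best_rm) {
        idx <- c(idx, add_j)
        counts <- counts + W[add_j, ]
        score <- best_add
      } else {
        counts <- counts - W[rm_j, ]
        idx <- setdiff(idx, rm_j)
        score <- best_rm
      }
    }
    cm <- matrix(counts, nrow = 4L, dimnames = list(.BASES, NULL))
    sites <- win[idx, c("seq_id", "offset", "strand")]
    rownames(sites) <- NULL
    list(width = w, counts = cm, n_sites = length(idx), sites = sites,
         consensus = .consensus_of(cm), score = score)
  })

  cons <- vapply(refined, `[[`, "", "consensus")
  scores <- vapply(refined, `[[`, 0, "score")
  keep <- !duplicated(cons[order(-scores)])
  refined <- refined[order(-scores)][keep]
  scores <- vapply(refined, `[[`, 0, "score")
  cons <- vapply(refined, `[[`, "", "consensus")
  refined[order(-scores, cons)]
}

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
            W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
            V = "ACG", N = "ACGT")

#' Scan sequences for an IUPAC pattern on both strands
#'
#' Counts overlapping occurrences of the pattern or its reverse complement;
#' an occurrence matched by both strands at the same position (a
#' strand-symmetric pattern) is counted once.
#'
#' @param sequences Named character vector of DNA sequences.
#' @param pattern IUPAC pattern string.
#' @return Named integer vector of per-sequence occurrence counts.
#' @export
scan_iupac <- function(sequences, pattern) {
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "")[[1L]], names(.IUPAC))
  if (length(bad)) stop("invalid IUPAC letter in pattern: ", bad[1L])
  pat <- Biostrings::DNAString(pattern)
  rcp <- Biostrings::reverseComplement(pat)
  counts <- vapply(toupper(sequences), function(s) {
    if (nchar(s) < nchar(pattern)) return(0L)
    subj <- Biostrings::DNAString(s)
    f <- Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = FALSE))
    r <- Biostrings::start(Biostrings::matchPattern(rcp, subj, fixed = FALSE))
    length(union(f, r))
  }, integer(1), USE.NAMES = FALSE)
  stats::setNames(counts, names(sequences))
}
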