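# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (character vectors, loops, direct formulas)
# and share no code with the package internals.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# mismatch count of `probe` at every start position of `genome` (forward)
mismatch_profile <- function(probe, genome) {
  g <- strsplit(genome, "")[[1]]
  p <- strsplit(probe, "")[[1]]
  L <- length(p)
  n <- length(g) - L + 1L
  if (n < 1L) return(integer(0))
  mis <- integer(n)
  for (j in seq_len(L)) mis <- mis + (g[j:(j + n - 1L)] != p[j])
  mis
}

# brute-force hit count of probe/revcomp against a set of sequences
oracle_hits <- function(probe, genome_set, max_mm) {
  tot <- 0L
  for (g in genome_set) {
    tot <- tot + sum(mismatch_profile(probe, g) <= max_mm) +
      sum(mismatch_profile(revcomp_chr(probe), g) <= max_mm)
  }
  tot
}

oracle_status <- function(ha, hb) {
  if (ha > 0 && hb > 0) "both" else if (ha > 0) "a_only" else
    if (hb > 0) "b_only" else "neither"
}

# exact hypergeometric upper tail by direct enumeration of the pmf
hyper_tail_oracle <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

IUPAC_SET <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                  Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                  D = c("A", "G", "T"), H = c("A", "C", "T"),
                  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
                W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
                N = "N")

iupac_revcomp <- function(pattern) {
  paste(rev(IUPAC_COMP[strsplit(pattern, "")[[1]]]), collapse = "")
}

iupac_matches_at <- function(seqchars, pos, patchars) {
  all(mapply(function(a, p) a %in% IUPAC_SET[[p]],
             seqchars[pos:(pos + length(patchars) - 1L)], patchars))
}

# union of start positions matching the pattern or its reverse complement
brute_iupac_count <- function(s, pattern) {
  sc <- strsplit(s, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  rc <- strsplit(iupac_revcomp(pattern), "")[[1]]
  n <- length(sc) - length(pc) + 1L
  if (n < 1L) return(0L)
  sum(vapply(seq_len(n), function(i) {
    iupac_matches_at(sc, i, pc) || iupac_matches_at(sc, i, rc)
  }, logical(1)))
}

# per-base membership classification of an indel against one gene
brute_indel_region <- function(gene, indel, window) {
  if (gene$chrom != indel$chrom) return(NULL)
  ipos <- indel$start:indel$end
  genic <- gene$start:gene$end
  if (any(ipos %in% genic)) return("genic")
  if (gene$strand == "+") {
    up <- (gene$start - window):(gene$start - 1L)
    down <- (gene$end + 1L):(gene$end + window)
  } else {
    up <- (gene$end + 1L):(gene$end + window)
    down <- (gene$start - window):(gene$start - 1L)
  }
  if (window > 0 && any(ipos %in% up)) return("upstream")
  if (window > 0 && any(ipos %in% down)) return("downstream")
  NULL
}

# direct evaluation of the motif score formula
score_formula <- function(counts_mat, n, bg = rep(0.25, 4)) {
  w <- ncol(counts_mat)
  f <- (counts_mat + 0.5) / (n + 2)
  log2(n) * sum(f * log2(f / bg)) / w
}

# exhaustive seed + greedy-within-pool motif search on tiny inputs, loops only
tiny_motif_search <- function(fg, w, m, bg = rep(0.25, 4)) {
  wins <- list()
  for (id in names(fg)) {
    s <- fg[[id]]
    for (off in seq_len(nchar(s) - w + 1L)) {
      fwd <- substr(s, off, off + w - 1L)
      wins[[length(wins) + 1L]] <- list(key = paste(id, off), strand = "+",
                                        site = fwd)
      wins[[length(wins) + 1L]] <- list(key = paste(id, off), strand = "-",
                                        site = revcomp_chr(fwd))
    }
  }
  sitechars <- lapply(wins, function(x) strsplit(x$site, "")[[1]])
  counts_of <- function(ix) {
    cm <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (i in ix) for (j in seq_len(w)) {
      cm[sitechars[[i]][j], j] <- cm[sitechars[[i]][j], j] + 1
    }
    cm
  }
  nmatch <- function(i, j) sum(sitechars[[i]] == sitechars[[j]])
  best <- -Inf
  seeds <- which(!duplicated(vapply(wins, `[[`, "", "site")))
  for (sd in seeds) {
    mm <- vapply(seq_along(wins), function(i) nmatch(i, sd), 1L)
    cand <- seq_along(wins)[mm >= m]
    ord <- cand[order(-mm[cand], vapply(wins[cand], `[[`, "", "strand"))]
    pool <- ord[!duplicated(vapply(wins[ord], `[[`, "", "key"))]
    if (length(pool) < 2L) next
    idx <- pool
    sc <- score_formula(counts_of(idx), length(idx), bg)
    repeat {
      moves <- list()
      for (a in setdiff(pool, idx)) moves[[length(moves) + 1L]] <- c(idx, a)
      if (length(idx) > 2L) {
        for (r in idx) moves[[length(moves) + 1L]] <- setdiff(idx, r)
      }
      if (!length(moves)) break
      scs <- vapply(moves, function(ix) score_formula(counts_of(ix), length(ix), bg), 1)
      if (max(scs) <= sc + 1e-12) break
      idx <- moves[[which.max(scs)]]
      sc <- max(scs)
    }
    if (sc > best) best <- sc
  }
  best
}
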