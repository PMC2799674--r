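# Probe-vs-genome polymorphism screen: each probe is classified as matching
# both genotype genomes, one, or neither. A hit is an ungapped occurrence of
# the probe or its reverse complement with at most `max_mismatch` mismatches
# on any sequence of the genome set; multiple hits are counted.

.count_hits <- function(probe, genome_set, max_mismatch) {
  subj <- Biostrings::DNAStringSet(genome_set)
  p <- Biostrings::DNAString(probe)
  fwd <- sum(Biostrings::vcountPattern(p, subj, max.mismatch = max_mismatch))
  rev <- sum(Biostrings::vcountPattern(Biostrings::reverseComplement(p), subj,
                                       max.mismatch = max_mismatch))
  fwd + rev
}

#' Classify one probe against two genome sequence sets
#'
#' @param probe_seq Probe sequence (ACGT only, length >= 8).
#' @param genome_a,genome_b Character vectors (or named vectors) of genome
#'   sequences for the two genotypes.
#' @param max_mismatch Allowed mismatches per hit (default 0).
#' @return A list with `status` (`both`, `a_only`, `b_only`, `neither`),
#'   `hits_a` and `hits_b`.
#' @export
classify_probe <- function(probe_seq, genome_a, genome_b, max_mismatch = 0L) {
  probe_seq <- toupper(probe_seq)
  if (nchar(probe_seq) < 8L) stop("probe length must be >= 8")
  if (grepl("[^ACGT]", probe_seq)) stop("probe contains non-ACGT characters")
  if (!length(genome_a) || !length(genome_b)) stop("genomes must be non-empty")
  ha <- .count_hits(probe_seq, toupper(genome_a), max_mismatch)
  hb <- .count_hits(probe_seq, toupper(genome_b), max_mismatch)
  status <- if (ha > 0 && hb > 0) "both" else if (ha > 0) "a_only" else
    if (hb > 0) "b_only" else "neither"
  list(probe_id = NA_character_, status = status,
       hits_a = as.integer(ha), hits_b = as.integer(hb))
}

#' Classify a set of probes against two genomes
#'
#' @param probes Named character vector of probe sequences.
#' @param genome_a,genome_b Genome sequence sets.
#' @param max_mismatch Allowed mismatches per hit.
#' @return A data.frame with columns `probe_id`, `status`, `hits_a`, `hits_b`.
#' @export
classify_probes <- function(probes, genome_a, genome_b, max_mismatch = 0L) {
  stopifnot(!is.null(names(probes)))
  rows <- lapply(seq_along(probes), function(i) {
    cls <- classify_probe(probes[[i]], genome_a, genome_b, max_mismatch)
    cls$probe_id <- names(probes)[i]
    as.data.frame(cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize probe screen fractions
#'
#' @param classes Data.frame from [classify_probes()] (needs a `status`
#'   column).
#' @return Named numeric vector of fractions (`both`, `a_only`, `b_only`,
#'   `neither`), summing to 1.
#' @export
screen_summary <- function(classes) {
  if (!nrow(classes)) stop("empty probe classification list")
  lv <- c("both", "a_only", "b_only", "neither")
  tab <- table(factor(classes$status, levels = lv))
  stats::setNames(as.numeric(tab) / nrow(classes), lv)
}
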