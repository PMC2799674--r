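# Readers and writers for every external format the pipeline touches.
# All tabular interchange is TSV; sequence interchange is FASTA; gene models
# are GFF3 (1-based inclusive, converted nowhere: the package keeps the
# R/Bioconductor convention of 1-based closed intervals throughout).

#' Read a probe-level intensity table
#'
#' Reads a TSV with a `probe_id` first column, one column per array, and a
#' strictly positive numeric body.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix (probes x arrays) with `rownames` = probe ids and
#'   `colnames` = array ids, in file order.
#' @export
read_intensity_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("intensity table needs a probe_id column plus >=1 array column")
  probe_ids <- as.character(df[[1L]])
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup)) stop("duplicate probe_id in intensity table: ", dup[1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric intensity at row ", probe_ids[bad[1L, 1L]],
         ", column ", colnames(df)[-1L][bad[1L, 2L]])
  }
  rownames(m) <- probe_ids
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive or non-finite intensity at row ", probe_ids[bad[1L, 1L]],
         ", column ", colnames(m)[bad[1L, 2L]])
  }
  m
}

#' Write a probe-level intensity table
#'
#' @param m Numeric matrix with probe rownames and array colnames.
#' @param path Output path.
#' @export
write_intensity_table <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an experiment design table
#'
#' Columns: `array_id`, `genotype`, `treatment` (one of `control`/`treated`),
#' `replicate`. Balance is checked by consumers (the ANOVA layer), not here.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with the four design columns.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("array_id", "genotype", "treatment", "replicate")
  if (nrow(df) == 0L) stop("design file is empty")
  if (!all(need %in% names(df))) {
    stop("design file must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$array_id <- as.character(df$array_id)
  df$genotype <- as.character(df$genotype)
  df$treatment <- as.character(df$treatment)
  df$replicate <- as.integer(df$replicate)
  dup <- df$array_id[duplicated(df$array_id)]
  if (length(dup)) stop("duplicate array_id in design: ", dup[1L])
  bad <- setdiff(unique(df$treatment), c("control", "treated"))
  if (length(bad)) stop("treatment must be 'control' or 'treated', got: ", bad[1L])
  df
}

#' Write an experiment design table
#' @param design Design data.frame as returned by [read_design()].
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-probe-set map
#'
#' Columns: `probe_id`, `probeset_id`, `probe_index` (position of the probe
#' within its set, unique per set).
#'
#' @param path Path to a TSV file.
#' @return A data.frame with the three map columns.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("probe_id", "probeset_id", "probe_index")
  if (!all(need %in% names(df))) {
    stop("probe map must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$probe_id <- as.character(df$probe_id)
  df$probeset_id <- as.character(df$probeset_id)
  df$probe_index <- as.integer(df$probe_index)
  validate_probe_map(df)
  df
}

validate_probe_map <- function(map) {
  dup <- map$probe_id[duplicated(map$probe_id)]
  if (length(dup)) stop("duplicate probe_id in probe map: ", dup[1L])
  if (any(map$probe_index < 0L)) stop("probe_index must be non-negative")
  key <- paste(map$probeset_id, map$probe_index)
  dup <- key[duplicated(key)]
  if (length(dup)) stop("probe_index repeated within probe set: ", dup[1L])
  invisible(map)
}

#' Write a probe map
#' @param map Probe map data.frame.
#' @param path Output path.
#' @export
write_probe_map <- function(map, path) {
  validate_probe_map(map)
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased; handling is case-insensitive throughout the
#' package.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  ss <- Biostrings::BStringSet(toupper(seqs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Only `gene` features are retained. GFF3 coordinates are 1-based inclusive
#' and are kept as such.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  bad <- which(vapply(fields, length, 1L) != 9L)
  if (length(bad)) stop("malformed GFF3 record at line ", lineno[bad[1L]])
  typ <- vapply(fields, `[[`, "", 3L)
  gene <- fields[typ == "gene"]
  glineno <- lineno[typ == "gene"]
  if (!length(gene)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  chrom <- vapply(gene, `[[`, "", 1L)
  start <- as.integer(vapply(gene, `[[`, "", 4L))
  end <- as.integer(vapply(gene, `[[`, "", 5L))
  strand <- vapply(gene, `[[`, "", 7L)
  attrs <- vapply(gene, `[[`, "", 9L)
  gene_id <- sub("^.*ID=([^;]+).*$", "\\1", attrs)
  bad <- which(is.na(start) | is.na(end) | start < 1L | start > end)
  if (length(bad)) stop("invalid gene coordinates (need 1 <= start <= end) at line ",
                        glineno[bad[1L]])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop("invalid strand at line ", glineno[bad[1L]])
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Write gene models to GFF3
#' @param genes Gene model data.frame (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tcipkit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read InDel intervals
#'
#' BED-like TSV with columns `chrom`, `start`, `end`, `kind`; this dialect is
#' 1-based inclusive. `kind` is `insertion` or `deletion`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame of InDel intervals.
#' @export
read_indels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chrom", "start", "end", "kind")
  if (!all(need %in% names(df))) {
    stop("indel file must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(df$start > df$end)
  if (length(bad)) stop("indel with start > end at data line ", bad[1L])
  bad <- setdiff(unique(df$kind), c("insertion", "deletion"))
  if (length(bad)) stop("indel kind must be insertion/deletion, got: ", bad[1L])
  df
}

#' Write InDel intervals
#' @param indels InDel data.frame.
#' @param path Output path.
#' @export
write_indels <- function(indels, path) {
  utils::write.table(indels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read category annotations
#'
#' GAF-like TSV with columns `item_id`, `category_id`, `aspect`
#' (`BP`/`MF`/`CC`). Duplicate triples are rejected.
#'
#' @param path Path to a TSV file.
#' @return A data.frame of annotations.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("item_id", "category_id", "aspect")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  bad <- setdiff(unique(df$aspect), c("BP", "MF", "CC"))
  if (length(bad)) stop("aspect must be BP/MF/CC, got: ", bad[1L])
  key <- paste(df$item_id, df$category_id, df$aspect)
  dup <- key[duplicated(key)]
  if (length(dup)) stop("duplicate annotation triple: ", dup[1L])
  df
}

#' Write a results table with header metadata
#'
#' Emits a TSV with `#`-prefixed metadata lines (key: value) followed by a
#' header line and the records, in stable column order.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @param meta Named character vector echoed as `# key: value` lines.
#' @export
write_results <- function(records, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  }
  utils::write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path Path to the TSV file.
#' @return A data.frame (metadata lines are skipped).
#' @export
read_results <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Bundles the thresholds shared across the pipeline stages.
#'
#' @param alpha Per-effect significance threshold on raw ANOVA p-values
#'   (default 0.01).
#' @param min_core_probes Minimum number of triple-significant probes for a
#'   probe set to be called a Core Intersectional Probeset (default 3).
#' @param tgt Target trimmed-mean signal for per-array scaling (default 500).
#' @param max_mismatch Mismatch tolerance of the probe-vs-genome screen
#'   (default 0).
#' @param upstream_window Extent of the upstream/downstream windows for InDel
#'   classification, in bp (default 1000).
#' @param motif_width Motif width for de novo discovery (default 8).
#' @param rng_seed Integer seed for any seeded stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.01, min_core_probes = 3L, tgt = 500,
                            max_mismatch = 0L, upstream_window = 1000L,
                            motif_width = 8L, rng_seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, min_core_probes >= 1L, tgt > 0,
            max_mismatch >= 0L, upstream_window >= 0L, motif_width >= 2L)
  structure(list(alpha = alpha, min_core_probes = as.integer(min_core_probes),
                 tgt = tgt, max_mismatch = as.integer(max_mismatch),
                 upstream_window = as.integer(upstream_window),
                 motif_width = as.integer(motif_width),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}
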