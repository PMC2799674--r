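# Strand-aware classification of InDels relative to gene models, and
# intersection of InDel-bearing genes with CIP genes. Coordinates are
# 1-based inclusive throughout. An InDel overlapping the gene span is genic
# (genic takes precedence over the flanking windows).

#' Classify one InDel relative to one gene
#'
#' Genic iff the interval overlaps `[start, end]`; upstream iff it lies
#' strictly 5' of the gene (strand-aware) within `upstream_window` bp;
#' downstream symmetric. Returns `NULL` for a different chromosome or an
#' interval outside both windows.
#'
#' @param gene One gene model (list or one-row data.frame: `gene_id`,
#'   `chrom`, `start`, `end`, `strand`).
#' @param indel One InDel interval (list or one-row data.frame: `chrom`,
#'   `start`, `end`, `kind`).
#' @param upstream_window Window extent in bp (default 1000).
#' @return A list with `gene_id`, `region` (`upstream`/`genic`/`downstream`)
#'   and `distance` (bp to the gene boundary, 0 if genic), or `NULL`.
#' @export
classify_indel <- function(gene, indel, upstream_window = 1000L) {
  stopifnot(upstream_window >= 0L)
  if (gene$chrom != indel$chrom) return(NULL)
  if (indel$start <= gene$end && indel$end >= gene$start) {
    return(list(gene_id = gene$gene_id, region = "genic", distance = 0L))
  }
  if (indel$end < gene$start) {          # low-coordinate side
    dist <- gene$start - indel$end
    side <- if (gene$strand == "+") "upstream" else "downstream"
  } else {                               # high-coordinate side
    dist <- indel$start - gene$end
    side <- if (gene$strand == "+") "downstream" else "upstream"
  }
  if (dist > upstream_window) return(NULL)
  list(gene_id = gene$gene_id, region = side, distance = as.integer(dist))
}

#' Classify all gene-InDel pairs
#'
#' One record per gene-InDel pair within range; an InDel near two genes is
#' classified independently for each.
#'
#' @param genes Gene model data.frame.
#' @param indels InDel data.frame.
#' @param upstream_window Window extent in bp.
#' @return A data.frame `gene_id`, `indel_index`, `region`, `distance`.
#' @export
gene_indel_pairs <- function(genes, indels, upstream_window = 1000L) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    same <- which(indels$chrom == g$chrom &
                    indels$start <= g$end + upstream_window &
                    indels$end >= g$start - upstream_window)
    for (j in same) {
      cls <- classify_indel(g, indels[j, ], upstream_window)
      if (is.null(cls)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = cls$gene_id, indel_index = j, region = cls$region,
        distance = cls$distance, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), indel_index = integer(),
                      region = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Per-gene InDel region flags
#'
#' @param genes Gene model data.frame.
#' @param indels InDel data.frame.
#' @param upstream_window Window extent in bp.
#' @return A data.frame with one row per gene: `gene_id`, `has_upstream`,
#'   `has_genic`, `has_downstream`.
#' @export
genes_with_indels <- function(genes, indels, upstream_window = 1000L) {
  pairs <- gene_indel_pairs(genes, indels, upstream_window)
  has <- function(g, reg) any(pairs$gene_id == g & pairs$region == reg)
  data.frame(gene_id = genes$gene_id,
             has_upstream = vapply(genes$gene_id, has, TRUE, "upstream"),
             has_genic = vapply(genes$gene_id, has, TRUE, "genic"),
             has_downstream = vapply(genes$gene_id, has, TRUE, "downstream"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect CIP genes with InDel-bearing genes
#'
#' @param cip_genes Character vector of CIP gene ids.
#' @param flags Output of [genes_with_indels()].
#' @return The flag rows of genes that are CIPs and carry at least one InDel
#'   in any region.
#' @export
intersect_cip_indel <- function(cip_genes, flags) {
  any_flag <- flags$has_upstream | flags$has_genic | flags$has_downstream
  out <- flags[flags$gene_id %in% cip_genes & any_flag, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize InDel region percentages over a gene set
#'
#' Percentages use the full gene set in `flags` as denominator (a gene can
#' contribute to several regions).
#'
#' @param flags Output of [genes_with_indels()] (possibly subset).
#' @return Named numeric vector of percentages (`upstream`, `genic`,
#'   `downstream`), rounded to 2 decimals.
#' @export
indel_region_summary <- function(flags) {
  n <- nrow(flags)
  if (!n) return(c(upstream = NA_real_, genic = NA_real_, downstream = NA_real_))
  c(upstream = round(100 * sum(flags$has_upstream) / n, 2),
    genic = round(100 * sum(flags$has_genic) / n, 2),
    downstream = round(100 * sum(flags$has_downstream) / n, 2))
}
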