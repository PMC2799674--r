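# Seeded synthetic scenarios with planted genotype/treatment/interaction
# effects, polymorphism-attenuated probes, an enriched annotation category,
# motif-bearing promoters and InDels near planted genes. Each sub-generator
# draws from its own RNG stream derived from the scenario seed, so adding a
# generator never perturbs another's draws.

.sub_seed <- function(seed, tag) {
  # deterministic per-generator stream offset; stays far below 2^31
  offs <- c(genome = 101L, probes = 211L, intensities = 307L,
            genes = 401L, annotations = 503L, promoters = 601L,
            indels = 701L, design = 809L)
  (as.integer(seed) %% 2000000000L) + offs[[tag]]
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Define a synthetic scenario
#'
#' A scenario bundles every parameter of the generative model: a balanced
#' 2 genotypes x 2 treatments x r replicates design, probe sets of
#' `probes_per_set` probes drawn as exact substrings of genome A, planted
#' log2-scale genotype/treatment/interaction effects on a fraction of probe
#' sets (the planted CIPs), polymorphism-attenuated probes, one enriched
#' annotation category among planted genes, promoters carrying a planted
#' motif, and InDels placed around planted genes.
#'
#' @param n_probesets Number of probe sets (default 200).
#' @param probes_per_set Probes per set (default 11).
#' @param probe_length Probe length in bp (default 25).
#' @param r Replicates per design cell (default 3).
#' @param baseline_mean,baseline_sd Log2 baseline per probe set (default 8, 1).
#' @param affinity_sd Per-probe log2 affinity spread (default 0.5).
#' @param noise_sd Residual log2 noise sigma (default 0.3).
#' @param delta_cultivar,delta_treatment,delta_interaction Planted log2 effect
#'   sizes for the genotype, treatment and interaction terms (defaults 1.5,
#'   1.5, 1.0).
#' @param cip_fraction Fraction of probe sets planted as true CIPs (default 0.1).
#' @param polymorphic_fraction Fraction of probes attenuated by sequence
#'   polymorphism (default 0.05; the genome-derived truth overrides this when
#'   probes are drawn from a genome pair).
#' @param attenuation Log2 attenuation of polymorphic probes in genotype B
#'   (default 2.0).
#' @param quadrant_weights Unnormalized planting weights of the four
#'   expression quadrants.
#' @param n_categories Number of annotation categories (default 30).
#' @param enriched_odds Odds multiplier of the one enriched category among
#'   planted CIP genes (default 10).
#' @param base_annotation_rate Per-item membership probability of an ordinary
#'   category (default 0.05).
#' @param motif Motif string planted in planted-gene promoters (default the
#'   W-box, `AGTCAAAC`).
#' @param promoter_length Promoter length in bp (default 1000).
#' @param genome_length Length of genome A in bp; `NULL` sizes it to fit all
#'   probe sets.
#' @param snp_rate,indel_rate Per-bp variant rates of the genome pair
#'   (defaults 0.0018 and 2e-4, chosen so that with a 25 bp probe the
#'   marginal probability of a polymorphic probe is about
#'   `polymorphic_fraction`).
#' @param upstream_window Upstream/downstream window used when placing InDels
#'   (default 1000).
#' @param rng_seed Integer master seed.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_probesets = 200L, probes_per_set = 11L,
                         probe_length = 25L, r = 3L,
                         baseline_mean = 8, baseline_sd = 1,
                         affinity_sd = 0.5, noise_sd = 0.3,
                         delta_cultivar = 1.5, delta_treatment = 1.5,
                         delta_interaction = 1.0,
                         cip_fraction = 0.1, polymorphic_fraction = 0.05,
                         attenuation = 2.0,
                         quadrant_weights = c(prefA_up = 645, prefA_down = 101,
                                              prefB_down = 223, prefB_up = 93),
                         n_categories = 30L, enriched_odds = 10,
                         base_annotation_rate = 0.05,
                         motif = "AGTCAAAC", promoter_length = 1000L,
                         genome_length = NULL, snp_rate = 0.0018,
                         indel_rate = 2e-4, upstream_window = 1000L,
                         rng_seed = 1L) {
  stopifnot(baseline_sd > 0, affinity_sd > 0, noise_sd > 0,
            cip_fraction >= 0, cip_fraction <= 1,
            polymorphic_fraction >= 0, polymorphic_fraction <= 1,
            r >= 2L, probes_per_set >= 1L, n_probesets >= 1L)
  sc <- list(n_probesets = as.integer(n_probesets),
             probes_per_set = as.integer(probes_per_set),
             probe_length = as.integer(probe_length), r = as.integer(r),
             baseline_mean = baseline_mean, baseline_sd = baseline_sd,
             affinity_sd = affinity_sd, noise_sd = noise_sd,
             delta_cultivar = delta_cultivar,
             delta_treatment = delta_treatment,
             delta_interaction = delta_interaction,
             cip_fraction = cip_fraction,
             polymorphic_fraction = polymorphic_fraction,
             attenuation = attenuation,
             quadrant_weights = quadrant_weights,
             n_categories = as.integer(n_categories),
             enriched_odds = enriched_odds,
             base_annotation_rate = base_annotation_rate,
             motif = toupper(motif),
             promoter_length = as.integer(promoter_length),
             genome_length = genome_length, snp_rate = snp_rate,
             indel_rate = indel_rate,
             upstream_window = as.integer(upstream_window),
             rng_seed = as.integer(rng_seed))
  class(sc) <- "sim_scenario"
  sc
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a genotype genome pair with recorded variants
#'
#' Genome A is uniform random DNA; genome B is derived from it by applying
#' SNPs and short (1-3 bp) insertions/deletions drawn per base at the given
#' rates. Variant footprints never overlap; positions are in genome A
#' coordinates, 1-based.
#'
#' @param length Genome length in bp (>= 1000).
#' @param snp_rate,indel_rate Per-bp event rates, each in \[0, 0.1\].
#' @param seed Integer seed.
#' @return A list with `seq_a`, `seq_b` (character scalars) and `variants`
#'   (data.frame `pos`, `type`, `length`).
#' @export
generate_genome_pair <- function(length, snp_rate, indel_rate, seed) {
  if (length < 1000L) stop("genome length must be >= 1000")
  if (snp_rate < 0 || snp_rate > 0.1 || indel_rate < 0 || indel_rate > 0.1) {
    stop("variant rates must lie in [0, 0.1]")
  }
  .with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    a <- sample(bases, length, replace = TRUE)
    u <- runif(length)
    is_snp <- u < snp_rate
    is_indel <- !is_snp & u < snp_rate + indel_rate
    pos <- sort(c(which(is_snp), which(is_indel)))
    type <- ifelse(pos %in% which(is_snp), "snp",
                   sample(c("ins", "del"), sum(is_indel), replace = TRUE))
    len <- ifelse(type == "snp", 1L, sample(1:3, length(pos), replace = TRUE))
    # drop variants whose footprint on seq_a overlaps the previous one
    foot_end <- pos + ifelse(type == "del", len - 1L, 0L)
    keep <- rep(TRUE, length(pos))
    last_end <- -1L
    for (i in seq_along(pos)) {
      if (pos[i] <= last_end) keep[i] <- FALSE else last_end <- foot_end[i]
    }
    pos <- pos[keep]; type <- type[keep]; len <- len[keep]
    keep <- !(type == "del" & pos + len - 1L > length)
    pos <- pos[keep]; type <- type[keep]; len <- as.integer(len[keep])

    b <- a
    ins_seq <- character(length(pos))
    for (i in seq_along(pos)) {
      if (type[i] == "snp") {
        b[pos[i]] <- sample(setdiff(bases, a[pos[i]]), 1L)
      } else if (type[i] == "ins") {
        ins_seq[i] <- paste(sample(bases, len[i], replace = TRUE), collapse = "")
      }
    }
    # assemble seq_b left-to-right, applying deletions and insertions
    pieces <- character(0)
    cursor <- 1L
    for (i in seq_along(pos)) {
      if (type[i] == "del") {
        if (pos[i] > cursor) pieces <- c(pieces, paste(b[cursor:(pos[i] - 1L)], collapse = ""))
        cursor <- pos[i] + len[i]
      } else if (type[i] == "ins") {
        if (pos[i] > cursor) pieces <- c(pieces, paste(b[cursor:(pos[i] - 1L)], collapse = ""))
        pieces <- c(pieces, ins_seq[i])
        cursor <- pos[i]
      }
    }
    if (cursor <= length) pieces <- c(pieces, paste(b[cursor:length], collapse = ""))
    seq_b <- paste(pieces, collapse = "")
    list(seq_a = paste(a, collapse = ""), seq_b = seq_b,
         variants = data.frame(pos = as.integer(pos), type = type,
                               length = len, stringsAsFactors = FALSE))
  })
}

#' Generate probes tiling genome A
#'
#' Probe sets are placed left-to-right in non-overlapping windows; each set's
#' probes tile its window at a fixed step. Probes are exact substrings of
#' genome A. A probe is marked polymorphic iff its footprint overlaps at
#' least one recorded variant.
#'
#' @param genome_pair Output of [generate_genome_pair()].
#' @param n_probesets,probes_per_set,probe_length Probe layout.
#' @param seed Integer seed (controls inter-set gaps).
#' @return A list with `probes` (named character vector), `map` (probe map
#'   data.frame) and `probe_truth` (data.frame `probe_id`, `is_polymorphic`).
#' @export
generate_probes <- function(genome_pair, n_probesets, probes_per_set,
                            probe_length, seed) {
  glen <- nchar(genome_pair$seq_a)
  step <- 4L
  span <- probe_length + (probes_per_set - 1L) * step
  need <- n_probesets * (span + 10L)
  if (glen < need) {
    stop("genome too short: need >= ", need, " bp for ", n_probesets,
         " probe sets, have ", glen)
  }
  .with_seed(seed, {
    gap_budget <- glen - n_probesets * span
    gaps <- 1L + as.integer(stats::rmultinom(1L, gap_budget - n_probesets,
                                             rep(1, n_probesets)))
    starts_set <- cumsum(gaps) + span * (seq_len(n_probesets) - 1L)
    offs <- (seq_len(probes_per_set) - 1L) * step
    probe_start <- as.integer(outer(offs, starts_set, `+`))
    set_idx <- rep(seq_len(n_probesets), each = probes_per_set)
    probe_idx <- rep(seq_len(probes_per_set), times = n_probesets)
    probe_end <- probe_start + probe_length - 1L
    stopifnot(max(probe_end) <= glen)
    seqs <- substring(genome_pair$seq_a, probe_start, probe_end)
    probeset_id <- sprintf("PS%04d", set_idx)
    probe_id <- sprintf("%s_p%02d", probeset_id, probe_idx)
    names(seqs) <- probe_id
    v <- genome_pair$variants
    if (nrow(v)) {
      vstart <- v$pos
      vend <- v$pos + ifelse(v$type == "del", v$length - 1L, 0L)
      poly <- vapply(seq_along(probe_start), function(i) {
        any(vstart <= probe_end[i] & vend >= probe_start[i])
      }, logical(1))
    } else poly <- rep(FALSE, length(probe_start))
    list(probes = seqs,
         map = data.frame(probe_id = probe_id, probeset_id = probeset_id,
                          probe_index = probe_idx, stringsAsFactors = FALSE),
         probe_truth = data.frame(probe_id = probe_id, is_polymorphic = poly,
                                  start = probe_start, end = probe_end,
                                  stringsAsFactors = FALSE))
  })
}

#' Build the balanced factorial design of a scenario
#'
#' @param r Replicates per genotype x treatment cell.
#' @param genotypes Two genotype labels (first plays the reference role).
#' @return A design data.frame (`array_id`, `genotype`, `treatment`,
#'   `replicate`).
#' @export
make_design <- function(r = 3L, genotypes = c("A", "B")) {
  stopifnot(length(genotypes) == 2L, r >= 1L)
  g <- rep(genotypes, each = 2L * r)
  t <- rep(rep(c("control", "treated"), each = r), times = 2L)
  rep_i <- rep(seq_len(r), times = 4L)
  data.frame(array_id = paste(g, t, rep_i, sep = "_"),
             genotype = g, treatment = t, replicate = rep_i,
             stringsAsFactors = FALSE)
}

#' Plant probe-set level truth (CIP status and quadrant)
#'
#' @param scenario A [sim_scenario()].
#' @param probeset_ids Probe set identifiers.
#' @param seed Integer seed.
#' @return A data.frame `probeset_id`, `is_cip`, `quadrant`.
#' @keywords internal
plant_set_truth <- function(scenario, probeset_ids, seed) {
  n <- length(probeset_ids)
  n_cip <- round(scenario$cip_fraction * n)
  .with_seed(seed, {
    cip_idx <- sample(n, n_cip)
    qw <- scenario$quadrant_weights / sum(scenario$quadrant_weights)
    quad <- rep("none", n)
    quad[cip_idx] <- sample(names(qw), n_cip, replace = TRUE, prob = qw)
    data.frame(probeset_id = probeset_ids,
               is_cip = seq_len(n) %in% cip_idx,
               quadrant = quad, stringsAsFactors = FALSE)
  })
}

#' Generate a probe-level intensity matrix from a scenario
#'
#' The log2 intensity of probe p on array j is
#' `baseline(set) + affinity(p) + dC*[genotype A]*[set is CIP] +
#'  dT*[treated]*[set is CIP] + dI*[A & treated]*[set is CIP] -
#'  attenuation*[p polymorphic & genotype B] + N(0, sigma)`,
#' with the signs of dC/dT following the planted quadrant and the interaction
#' sign equal to their product; the matrix is returned on the linear scale.
#'
#' @param scenario A [sim_scenario()].
#' @param map Probe map data.frame.
#' @param truth List with `sets` (from [plant_set_truth()]) and `probes`
#'   (data.frame with `probe_id`, `is_polymorphic`).
#' @param design Balanced design data.frame.
#' @return Numeric matrix (probes x arrays), linear scale.
#' @export
generate_intensities <- function(scenario, map, truth, design) {
  tab <- table(design$genotype, design$treatment)
  if (nrow(tab) != 2L || ncol(tab) != 2L || length(unique(as.vector(tab))) != 1L) {
    stop("design must be a balanced 2 x 2 factorial")
  }
  sets <- truth$sets
  probes <- truth$probes
  stopifnot(all(map$probeset_id %in% sets$probeset_id),
            all(map$probe_id %in% probes$probe_id))
  set_row <- match(map$probeset_id, sets$probeset_id)
  probe_row <- match(map$probe_id, probes$probe_id)
  is_cip <- sets$is_cip[set_row]
  quad <- sets$quadrant[set_row]
  sc <- ifelse(quad %in% c("prefA_up", "prefA_down"), 1, -1)
  st <- ifelse(quad %in% c("prefA_up", "prefB_up"), 1, -1)
  si <- sc * st
  poly <- probes$is_polymorphic[probe_row]
  geno_a <- design$genotype == design$genotype[1L]
  treated <- design$treatment == "treated"
  n_arr <- nrow(design)
  .with_seed(.sub_seed(scenario$rng_seed, "intensities"), {
    uset <- unique(map$probeset_id)
    base_set <- stats::setNames(
      rnorm(length(uset), scenario$baseline_mean, scenario$baseline_sd), uset)
    affin <- rnorm(nrow(map), 0, scenario$affinity_sd)
    mu0 <- base_set[map$probeset_id] + affin
    L <- matrix(mu0, nrow = nrow(map), ncol = n_arr)
    eff_c <- ifelse(is_cip, scenario$delta_cultivar * sc, 0)
    eff_t <- ifelse(is_cip, scenario$delta_treatment * st, 0)
    eff_i <- ifelse(is_cip, scenario$delta_interaction * si, 0)
    L <- L + outer(eff_c, as.numeric(geno_a)) +
      outer(eff_t, as.numeric(treated)) +
      outer(eff_i, as.numeric(geno_a & treated)) -
      outer(scenario$attenuation * as.numeric(poly), as.numeric(!geno_a))
    L <- L + matrix(rnorm(length(L), 0, scenario$noise_sd), nrow = nrow(L))
    m <- 2^L
    dimnames(m) <- list(map$probe_id, design$array_id)
    m
  })
}

#' Generate category annotations with one enriched category
#'
#' Every item joins each ordinary category independently at the base rate;
#' for the enriched category, planted (CIP) items join at `enriched_odds`
#' times the base odds. `enriched_odds = 1` plants no signal.
#'
#' @param set_truth Probe-set truth data.frame (`probeset_id`, `is_cip`).
#' @param n_categories Number of categories.
#' @param enriched_odds Odds multiplier for the enriched category.
#' @param seed Integer seed.
#' @param base_rate Base membership probability.
#' @param aspect Annotation aspect tag.
#' @return A list with `annotations` (data.frame `item_id`, `category_id`,
#'   `aspect`) and `enriched_category` (the planted category id).
#' @export
generate_annotations <- function(set_truth, n_categories, enriched_odds, seed,
                                 base_rate = 0.05, aspect = "BP") {
  stopifnot(n_categories >= 2L, base_rate > 0, base_rate < 1, enriched_odds > 0)
  cats <- sprintf("CAT%03d", seq_len(n_categories))
  enriched <- cats[1L]
  odds0 <- base_rate / (1 - base_rate)
  p1 <- (enriched_odds * odds0) / (1 + enriched_odds * odds0)
  items <- set_truth$probeset_id
  .with_seed(seed, {
    rows <- lapply(cats, function(cat) {
      p <- rep(base_rate, length(items))
      if (cat == enriched) p[set_truth$is_cip] <- p1
      hit <- runif(length(items)) < p
      if (!any(hit)) return(NULL)
      data.frame(item_id = items[hit], category_id = cat, aspect = aspect,
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, rows)
    list(annotations = ann[order(ann$category_id, ann$item_id), ],
         enriched_category = enriched)
  })
}

#' Generate promoter sequences with a planted motif
#'
#' One promoter per gene; genes flagged in the truth receive exactly one
#' planted occurrence of the motif at a uniform random offset.
#'
#' @param gene_ids Gene identifiers.
#' @param plant Logical vector: which genes carry the motif.
#' @param motif Motif string (ACGT).
#' @param length Promoter length in bp.
#' @param seed Integer seed.
#' @return A list with `promoters` (named character vector) and `truth`
#'   (data.frame `gene_id`, `has_motif`).
#' @export
generate_promoters <- function(gene_ids, plant, motif, length, seed) {
  w <- nchar(motif)
  if (w > length) stop("motif longer than promoter")
  .with_seed(seed, {
    seqs <- vapply(gene_ids, function(g) .random_dna(length), "")
    for (i in which(plant)) {
      at <- sample.int(length - w + 1L, 1L)
      substr(seqs[i], at, at + w - 1L) <- motif
    }
    list(promoters = stats::setNames(seqs, gene_ids),
         truth = data.frame(gene_id = gene_ids, has_motif = plant,
                            stringsAsFactors = FALSE))
  })
}

#' Generate gene models on a synthetic chromosome
#'
#' Genes of ~2 kb are laid left-to-right with >= 2.5 kb spacing on one
#' chromosome, with random strand.
#'
#' @param gene_ids Gene identifiers.
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @return Gene model data.frame.
#' @export
generate_gene_models <- function(gene_ids, seed, chrom = "chr1") {
  n <- length(gene_ids)
  .with_seed(seed, {
    glen <- sample(1500:2500, n, replace = TRUE)
    gap <- sample(2500:3500, n, replace = TRUE)
    start <- cumsum(gap) + cumsum(c(0L, head(glen, -1L)))
    data.frame(gene_id = gene_ids, chrom = chrom,
               start = as.integer(start), end = as.integer(start + glen - 1L),
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Generate InDels around selected genes
#'
#' Each flagged gene receives one InDel placed in its upstream, genic or
#' downstream region (strand-aware) with the given region probabilities;
#' unflagged genes receive an InDel at a low background rate.
#'
#' @param genes Gene model data.frame.
#' @param plant Logical: genes guaranteed to carry an InDel.
#' @param upstream_window Window extent in bp.
#' @param seed Integer seed.
#' @param region_probs Probabilities for upstream/genic/downstream placement.
#' @param background_rate InDel probability for unflagged genes.
#' @return A list with `indels` (data.frame) and `truth` (data.frame
#'   `gene_id`, `has_indel`, `region`).
#' @export
generate_indels <- function(genes, plant, upstream_window, seed,
                            region_probs = c(upstream = 0.6, genic = 0.3,
                                             downstream = 0.1),
                            background_rate = 0.05) {
  .with_seed(seed, {
    carry <- plant | (runif(nrow(genes)) < background_rate)
    region <- rep(NA_character_, nrow(genes))
    rows <- lapply(which(carry), function(i) {
      g <- genes[i, ]
      reg <- sample(names(region_probs), 1L, prob = region_probs)
      len <- sample(1:10, 1L)
      five_prime_low <- (g$strand == "+" && reg == "upstream") ||
        (g$strand == "-" && reg == "downstream")
      if (reg == "genic") {
        s <- sample(g$start:max(g$start, g$end - len), 1L)
      } else if (five_prime_low) {
        s <- g$start - sample(seq_len(max(1L, upstream_window - len)), 1L) - len
      } else {
        s <- g$end + sample(seq_len(max(1L, upstream_window - len)), 1L)
      }
      region[i] <<- reg
      data.frame(chrom = g$chrom, start = as.integer(max(1L, s)),
                 end = as.integer(max(1L, s) + len - 1L),
                 kind = sample(c("insertion", "deletion"), 1L),
                 stringsAsFactors = FALSE)
    })
    indels <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 kind = character(), stringsAsFactors = FALSE)
    list(indels = indels,
         truth = data.frame(gene_id = genes$gene_id, has_indel = carry,
                            region = region, stringsAsFactors = FALSE))
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs every sub-generator of a scenario and returns all inputs the pipeline
#' consumes together with the ground truth. Genes are in 1:1 correspondence
#' with probe sets (`gene_id == probeset_id`).
#'
#' @param scenario A [sim_scenario()].
#' @return A list with elements `genome`, `probes`, `map`, `design`,
#'   `intensities`, `truth` (list: `sets`, `probes`, `genes`), `annotations`,
#'   `enriched_category`, `promoters`, `genes`, `indels`.
#' @export
simulate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  seed <- scenario$rng_seed
  span <- scenario$probe_length + (scenario$probes_per_set - 1L) * 4L
  glen <- if (is.null(scenario$genome_length)) {
    max(1000L, scenario$n_probesets * (span + 40L))
  } else scenario$genome_length
  genome <- generate_genome_pair(glen, scenario$snp_rate, scenario$indel_rate,
                                 .sub_seed(seed, "genome"))
  pr <- generate_probes(genome, scenario$n_probesets, scenario$probes_per_set,
                        scenario$probe_length, .sub_seed(seed, "probes"))
  design <- make_design(scenario$r)
  sets <- plant_set_truth(scenario, unique(pr$map$probeset_id),
                          .sub_seed(seed, "design"))
  truth <- list(sets = sets, probes = pr$probe_truth)
  intens <- generate_intensities(scenario, pr$map, truth, design)
  ann <- generate_annotations(sets, scenario$n_categories,
                              scenario$enriched_odds,
                              .sub_seed(seed, "annotations"),
                              base_rate = scenario$base_annotation_rate)
  prom <- generate_promoters(sets$probeset_id, sets$is_cip, scenario$motif,
                             scenario$promoter_length,
                             .sub_seed(seed, "promoters"))
  genes <- generate_gene_models(sets$probeset_id, .sub_seed(seed, "genes"))
  ind <- generate_indels(genes, sets$is_cip, scenario$upstream_window,
                         .sub_seed(seed, "indels"))
  truth$genes <- merge(prom$truth, ind$truth, by = "gene_id", sort = FALSE)
  list(genome = genome, probes = pr$probes, map = pr$map, design = design,
       intensities = intens, truth = truth,
       annotations = ann$annotations, enriched_category = ann$enriched_category,
       promoters = prom$promoters, genes = genes, indels = ind$indels)
}

#' Write a simulated dataset to a directory
#'
#' Emits the plain-text files a pipeline run would consume:
#' `intensities.tsv`, `design.tsv`, `probe_map.tsv`, `genome_a.fa`,
#' `genome_b.fa`, `probes.fa`, `promoters.fa`, `genes.gff3`, `indels.tsv`,
#' `annotations.tsv`, `truth_sets.tsv`.
#'
#' @param dat Output of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_intensity_table(dat$intensities, p("intensities.tsv"))
  write_design(dat$design, p("design.tsv"))
  write_probe_map(dat$map, p("probe_map.tsv"))
  write_fasta(c(genome_a = dat$genome$seq_a), p("genome_a.fa"))
  write_fasta(c(genome_b = dat$genome$seq_b), p("genome_b.fa"))
  write_fasta(dat$probes, p("probes.fa"))
  write_fasta(dat$promoters, p("promoters.fa"))
  write_gff3(dat$genes, p("genes.gff3"))
  write_indels(dat$indels, p("indels.tsv"))
  utils::write.table(dat$annotations, p("annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dat$truth$sets, p("truth_sets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Evaluate CIP recovery against planted truth
#'
#' @param called Character vector of called probe-set ids.
#' @param set_truth Probe-set truth data.frame (`probeset_id`, `is_cip`).
#' @return A list with `sensitivity` (true calls / planted) and `fdr`
#'   (false calls / max(1, total calls)).
#' @export
evaluate_recovery <- function(called, set_truth) {
  planted <- set_truth$probeset_id[set_truth$is_cip]
  tp <- sum(called %in% planted)
  fp <- length(called) - tp
  list(sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
       fdr = fp / max(1L, length(called)))
}
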