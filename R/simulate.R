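# Synthetic transcript-structure simulator: reference annotations with
# annotated second isoforms, observed cohorts with planted AS events and
# experimental-group structure, and GMT term sets -- all with ground truth.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a salinity-challenge gill
#' transcriptome cohort: six experimental groups (2 sites x 3 treatments)
#' whose Venn sharing proportions follow the reported group partition of
#' 509 AS variants, an event-type mix with ES dominant (51.8%) and IR rare
#' (6.9%), Poisson(30) read support with a fraction of coverage-1 decoys,
#' and multi-exon gene models roomy enough to plant several independent
#' events per variant.
#'
#' @param n_genes number of genes in the reference
#' @param n_variants number of observed splice variants in the cohort
#' @param exons_per_gene integer range `c(min, max)`; min must be >= 3 so
#'   that ES/IR planting has internal targets
#' @param fraction_multi_isoform fraction of genes given a second annotated
#'   isoform (differing from the first by exactly one event)
#' @param event_mix named non-negative weights over ES/IR/AA/AD/AP
#' @param events_per_variant integer range of planted events per variant
#' @param coverage_model `list(type = "poisson", lambda = )` or
#'   `list(type = "negative_binomial", mean = , dispersion = )`
#' @param fraction_coverage_one_decoys fraction of variants forced to
#'   coverage 1 (excluded by the detector's default filter)
#' @param group_sharing named proportions over Venn regions of
#'   `{CTRL, LS, RS}` (labels joined with `+`); must sum to 1
#' @param prob_site_kil probability a variant is sampled at site KIL
#'   (otherwise GDA)
#' @param exon_length,intron_length integer ranges for simulated exon and
#'   intron sizes
#' @param seed integer seed; all simulator randomness flows from it
#' @return validated config object (class `simulation_config`)
#' @export
simulation_config <- function(n_genes = 120,
                              n_variants = 500,
                              exons_per_gene = c(9, 15),
                              fraction_multi_isoform = 0.5,
                              event_mix = c(ES = 51.8, AA = 20.3, AD = 12.0,
                                            AP = 9.0, IR = 6.9),
                              events_per_variant = c(1, 4),
                              coverage_model = list(type = "poisson",
                                                    lambda = 30),
                              fraction_coverage_one_decoys = 0.1,
                              group_sharing = c(
                                "CTRL+LS+RS" = 462, "LS+RS" = 16,
                                "CTRL+RS" = 15, "CTRL+LS" = 11,
                                "LS" = 3, "RS" = 1, "CTRL" = 1) / 509,
                              prob_site_kil = 0.5,
                              exon_length = c(80, 200),
                              intron_length = c(60, 300),
                              seed = 1L) {
  stopifnot(n_genes >= 1, n_variants >= 0,
            length(exons_per_gene) == 2, length(events_per_variant) == 2)
  if (exons_per_gene[1] < 3) {
    stop("exons_per_gene min must be >= 3 (ES/IR planting needs internal exons)")
  }
  if (fraction_multi_isoform < 0 || fraction_multi_isoform > 1) {
    stop("fraction_multi_isoform must be in [0, 1]")
  }
  if (is.null(names(event_mix)) || !all(names(event_mix) %in% EVENT_TYPES)) {
    stop("event_mix must be named with a subset of ",
         paste(EVENT_TYPES, collapse = "/"))
  }
  if (any(event_mix < 0) || all(event_mix == 0)) {
    stop("event_mix weights must be >= 0 with at least one positive")
  }
  if (!coverage_model$type %in% c("poisson", "negative_binomial")) {
    stop("coverage_model type must be poisson or negative_binomial")
  }
  if (fraction_coverage_one_decoys < 0 || fraction_coverage_one_decoys > 1) {
    stop("fraction_coverage_one_decoys must be in [0, 1]")
  }
  regions <- strsplit(names(group_sharing), "+", fixed = TRUE)
  if (!all(vapply(regions, function(r) length(r) >= 1 &&
                    all(r %in% TREATMENTS), logical(1)))) {
    stop("group_sharing names must be '+'-joined subsets of ",
         paste(TREATMENTS, collapse = "/"))
  }
  if (abs(sum(group_sharing) - 1) > 1e-8) {
    stop("group_sharing proportions must sum to 1")
  }
  if (prob_site_kil < 0 || prob_site_kil > 1) {
    stop("prob_site_kil must be in [0, 1]")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_variants = as.integer(n_variants),
    exons_per_gene = as.integer(exons_per_gene),
    fraction_multi_isoform = fraction_multi_isoform,
    event_mix = event_mix,
    events_per_variant = as.integer(events_per_variant),
    coverage_model = coverage_model,
    fraction_coverage_one_decoys = fraction_coverage_one_decoys,
    group_sharing = group_sharing,
    prob_site_kil = prob_site_kil,
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

sample_range <- function(range, n = 1L) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

sample_event_types <- function(mix, n) {
  if (n == 0L) return(character(0))
  sample(names(mix), n, replace = TRUE, prob = mix)
}

draw_coverage <- function(model, n) {
  x <- switch(model$type,
    poisson = stats::rpois(n, model$lambda),
    negative_binomial = stats::rnbinom(n, mu = model$mean,
                                       size = 1 / model$dispersion)
  )
  pmax(x, 2L)  # genuine variants carry >= 2 supporting reads; decoys are
               # forced to coverage 1 separately
}

#' Generate a synthetic reference annotation
#'
#' Each gene gets one primary isoform (`<gene>.t1`); a fraction of genes
#' additionally get a second annotated isoform (`<gene>.t2`) differing from
#' the first by exactly one randomly typed event -- these are the targets
#' of the exact-coordinate conservation rule. Deterministic under the
#' config seed. The one-event isoform differences are attached as
#' `attr(, "isoform_events")` (gene_id, event_type, start, end).
#'
#' @param config a [simulation_config()]
#' @return a [genome_annotation()]
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes_per_chrom <- 25L
  gene_rows <- list(); tx_rows <- list(); exon_rows <- list()
  iso_events <- list()
  n_multi <- ceiling(config$fraction_multi_isoform * n)
  multi <- sort(sample.int(n, n_multi))
  pos <- 0
  for (i in seq_len(n)) {
    gid <- sprintf("G%04d", i)
    chrom <- paste0("chr", (i - 1L) %/% genes_per_chrom + 1L)
    if ((i - 1L) %% genes_per_chrom == 0L) pos <- 0
    strand <- sample(c("+", "-"), 1L)
    biotype <- sample(BIOTYPES, 1L, prob = c(0.9759, 0.0177, 0.0064))
    n_ex <- sample_range(config$exons_per_gene)
    lens <- sample_range(config$exon_length, n_ex)
    gaps <- sample_range(config$intron_length, n_ex - 1L)
    starts <- pos + cumsum(c(0, lens[-n_ex] + gaps))
    chain <- cbind(start = starts, end = starts + lens)
    pos <- max(chain[, 2]) + 10000
    t1 <- paste0(gid, ".t1")
    gene_rows[[i]] <- data.frame(gene_id = gid, symbol = paste0("GENE", i),
                                 biotype = biotype, chrom = chrom,
                                 strand = strand, stringsAsFactors = FALSE)
    tx_rows[[length(tx_rows) + 1L]] <-
      data.frame(transcript_id = t1, gene_id = gid, stringsAsFactors = FALSE)
    exon_rows[[length(exon_rows) + 1L]] <-
      data.frame(transcript_id = t1, gene_id = gid, chrom = chrom,
                 start = chain[, 1], end = chain[, 2], strand = strand,
                 stringsAsFactors = FALSE)
    if (i %in% multi) {
      type <- sample_event_types(config$event_mix, 1L)
      ev <- plant_event(chain, strand, type)
      t2 <- paste0(gid, ".t2")
      tx_rows[[length(tx_rows) + 1L]] <-
        data.frame(transcript_id = t2, gene_id = gid, stringsAsFactors = FALSE)
      exon_rows[[length(exon_rows) + 1L]] <-
        data.frame(transcript_id = t2, gene_id = gid, chrom = chrom,
                   start = ev$chain[, 1], end = ev$chain[, 2], strand = strand,
                   stringsAsFactors = FALSE)
      iso_events[[length(iso_events) + 1L]] <-
        data.frame(gene_id = gid, isoform_id = t2, donor_isoform_id = t1,
                   event_type = ev$event_type, start = ev$interval[1],
                   end = ev$interval[2], stringsAsFactors = FALSE)
    }
  }
  ann <- genome_annotation(do.call(rbind, gene_rows),
                           do.call(rbind, tx_rows),
                           do.call(rbind, exon_rows))
  attr(ann, "isoform_events") <- if (length(iso_events)) {
    do.call(rbind, iso_events)
  } else {
    data.frame(gene_id = character(0), isoform_id = character(0),
               donor_isoform_id = character(0), event_type = character(0),
               start = numeric(0), end = numeric(0), stringsAsFactors = FALSE)
  }
  ann
}

#' Generate an observed-transcript cohort with planted events
#'
#' Draws variants from the reference's multi-isoform genes, plants 0..k
#' events per variant (types by `event_mix`, counts by
#' `events_per_variant`, capped by the donor's internal-exon capacity),
#' assigns each variant a treatment-sharing region, a site and a coverage,
#' and forces a fixed fraction of variants to coverage 1 (decoys). Each
#' variant is emitted once per treatment in its region; records share a
#' `variant_id`. Planted events are kept at least one base away from the
#' gene's annotated isoform difference, so every planted event is novel
#' relative to the annotation (`planted_as_conserved = FALSE`).
#' Deterministic under the config seed.
#'
#' @param annotation a [genome_annotation()] from [generate_reference()]
#' @param config the same [simulation_config()]
#' @return `list(observed = observed_set, truth = data.frame of planted
#'   events, variants = per-variant data.frame)`
#' @export
generate_cohort <- function(annotation, config) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  idx <- annotation_index(annotation)
  iso_ev <- attr(annotation, "isoform_events")
  eligible <- annotation$genes$gene_id[annotation$genes$annotated_AS]
  if (length(eligible) == 0L) eligible <- annotation$genes$gene_id
  nv <- config$n_variants
  regions <- names(config$group_sharing)
  n_dec <- round(config$fraction_coverage_one_decoys * nv)
  decoys <- if (nv > 0) sample.int(nv, n_dec) else integer(0)
  coverage <- draw_coverage(config$coverage_model, nv)
  coverage[decoys] <- 1L

  var_rows <- list(); truth_rows <- list(); tr_rows <- list(); ex_rows <- list()
  for (v in seq_len(nv)) {
    vid <- sprintf("V%04d", v)
    gid <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    gene <- idx[[gid]]
    donor_id <- names(gene$isoforms)[1]  # lexicographically first = .t1
    donor <- gene$isoforms[[donor_id]]
    k <- sample_range(config$events_per_variant)
    types <- sample_event_types(config$event_mix, k)
    forbid <- iso_ev[iso_ev$gene_id == gid, c("event_type", "start", "end")]
    block <- integer(0)
    if (nrow(forbid) > 0) {
      # exons touching the annotated isoform difference are off limits
      block <- which(donor[, 2] >= min(forbid$start) &
                       donor[, 1] <= max(forbid$end))
    }
    pl <- plant_events(donor, gene$strand, types, forbid = forbid,
                       block_exons = block)
    region <- if (length(regions) == 1L) regions else
      sample(regions, 1L, prob = config$group_sharing)
    treatments <- strsplit(region, "+", fixed = TRUE)[[1]]
    site <- if (stats::runif(1) < config$prob_site_kil) "KIL" else "GDA"
    var_rows[[v]] <- data.frame(
      variant_id = vid, gene_id = gid, donor_isoform_id = donor_id,
      region = region, site = site, coverage = coverage[v],
      n_events = nrow(pl$events), decoy = v %in% decoys,
      stringsAsFactors = FALSE)
    if (nrow(pl$events) > 0) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        variant_id = vid, gene_id = gid, donor_isoform_id = donor_id,
        event_type = pl$events$event_type, chrom = gene$chrom,
        start = pl$events$start, end = pl$events$end, strand = gene$strand,
        planted_as_conserved = FALSE, coverage = coverage[v],
        stringsAsFactors = FALSE)
    }
    for (trt in treatments) {
      tid <- paste(vid, trt, sep = "_")
      tr_rows[[length(tr_rows) + 1L]] <- data.frame(
        transcript_id = tid, variant_id = vid, gene_id = gid,
        chrom = gene$chrom, strand = gene$strand,
        coverage = coverage[v], site = site, treatment = trt,
        stringsAsFactors = FALSE)
      ex_rows[[length(ex_rows) + 1L]] <- data.frame(
        transcript_id = tid, chrom = gene$chrom,
        start = pl$chain[, 1], end = pl$chain[, 2], strand = gene$strand,
        stringsAsFactors = FALSE)
    }
  }
  empty_truth <- data.frame(
    variant_id = character(0), gene_id = character(0),
    donor_isoform_id = character(0), event_type = character(0),
    chrom = character(0), start = numeric(0), end = numeric(0),
    strand = character(0), planted_as_conserved = logical(0),
    coverage = integer(0), stringsAsFactors = FALSE)
  list(
    observed = observed_set(
      do.call(rbind, tr_rows),
      do.call(rbind, ex_rows)),
    truth = if (length(truth_rows)) do.call(rbind, truth_rows) else empty_truth,
    variants = do.call(rbind, var_rows)
  )
}

#' Generate synthetic term sets (GMT)
#'
#' Builds `n_terms` gene sets over the annotation's gene symbols: one
#' enriched term containing a specified fraction of a target gene set plus
#' a few background genes, and `n_terms - 1` decoy terms sampling symbols
#' uniformly. Deterministic under `seed`.
#'
#' @param annotation a [genome_annotation()]
#' @param n_terms total number of terms (>= 1)
#' @param enriched_term_spec `list(name =, genes = target symbols,
#'   strength = fraction of the target included in the term)`
#' @param seed integer seed
#' @param term_size integer range of decoy term sizes
#' @return named list of terms compatible with [write_gmt()]
#' @export
generate_term_sets <- function(annotation, n_terms, enriched_term_spec,
                               seed = 1L, term_size = c(10, 40)) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (n_terms < 1) stop("n_terms must be >= 1")
  universe <- annotation$genes$symbol
  target <- enriched_term_spec$genes
  if (!all(target %in% universe)) {
    stop("enriched term target genes must be annotation gene symbols")
  }
  strength <- enriched_term_spec$strength
  if (strength <= 0 || strength > 1) stop("enrichment strength must be in (0, 1]")
  set.seed(seed)
  terms <- list()
  n_in <- max(1L, round(strength * length(target)))
  members <- if (n_in == length(target)) target else sample(target, n_in)
  extras <- sample(setdiff(universe, target), max(2L, round(0.2 * n_in)))
  terms[["T0001"]] <- list(name = enriched_term_spec$name,
                           genes = c(members, extras))
  if (n_terms > 1L) {
    sizes <- sample_range(as.integer(term_size), n_terms - 1L)
    for (i in seq_len(n_terms - 1L)) {
      sz <- min(sizes[i], length(universe))
      if (sz < 1) stop("term size must be >= 1")
      terms[[sprintf("T%04d", i + 1L)]] <-
        list(name = sprintf("random term %d", i), genes = sample(universe, sz))
    }
  }
  terms
}
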