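# Orchestration: validated YAML config, simulate -> detect -> summarize ->
# enrich, with stable on-disk outputs and a run manifest.

PIPELINE_DEFAULTS <- list(
  min_coverage = 2L,
  restrict_to_annotated_AS = TRUE,
  end_convention = "paper",
  min_overlap = 4L,
  p_cutoff = 0.01,
  q_report = 0.05
)

KNOWN_KEYS <- c(
  "annotation", "observed_gtf", "gmt", "background", "species_catalogs",
  "out_dir", "min_coverage", "restrict_to_annotated_AS", "end_convention",
  "min_overlap", "p_cutoff", "q_report", "seed", "simulate"
)

#' Validate a pipeline configuration
#'
#' Reads a YAML config, applies defaults (`min_coverage` 2, `min_overlap`
#' 4, `p_cutoff` 0.01, `q_report` 0.05, `end_convention` "paper") and
#' rejects unknown keys. A config either names input files (`annotation`,
#' `observed_gtf`, optionally `gmt` + `background` and
#' `species_catalogs`) or carries a `simulate` block (fields of
#' [simulation_config()]) plus a `seed`.
#'
#' @param path YAML file, or a list already parsed
#' @return validated config list (class `pipeline_config`)
#' @export
validate_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), KNOWN_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in names(PIPELINE_DEFAULTS)) {
    if (is.null(cfg[[key]])) cfg[[key]] <- PIPELINE_DEFAULTS[[key]]
  }
  if (!is.numeric(cfg$min_coverage) || cfg$min_coverage < 1) {
    stop("min_coverage: must be a number >= 1")
  }
  if (!is.logical(cfg$restrict_to_annotated_AS)) {
    stop("restrict_to_annotated_AS: must be true/false")
  }
  if (!cfg$end_convention %in% c("paper", "conventional")) {
    stop("end_convention: must be 'paper' or 'conventional'")
  }
  if (!is.numeric(cfg$min_overlap) || cfg$min_overlap < 0) {
    stop("min_overlap: must be a number >= 0")
  }
  for (key in c("p_cutoff", "q_report")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0 || cfg[[key]] > 1) {
      stop(key, ": must be a probability in (0, 1]")
    }
  }
  if (is.null(cfg$out_dir)) stop("out_dir: required")
  simulating <- !is.null(cfg$simulate)
  if (simulating) {
    if (is.null(cfg$seed)) stop("seed: required when simulating")
  } else {
    for (key in c("annotation", "observed_gtf")) {
      if (is.null(cfg[[key]])) stop(key, ": required unless simulating")
      if (!file.exists(cfg[[key]])) stop(key, ": file not found: ", cfg[[key]])
    }
  }
  if (!is.null(cfg$gmt)) {
    if (!simulating && !file.exists(cfg$gmt)) {
      stop("gmt: file not found: ", cfg$gmt)
    }
    if (!simulating && is.null(cfg$background)) {
      stop("background: required when gmt is given")
    }
    if (!is.null(cfg$background) && !simulating &&
        !file.exists(cfg$background)) {
      stop("background: file not found: ", cfg$background)
    }
  }
  if (!is.null(cfg$species_catalogs)) {
    missing <- Filter(Negate(file.exists), unlist(cfg$species_catalogs))
    if (length(missing)) {
      stop("species_catalogs: file(s) not found: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Run the full AS analysis pipeline
#'
#' Stages: (optionally) simulate reference + cohort + term sets, detect and
#' type AS events, write the descriptive summary tables, and run term
#' over-representation. All outputs are deterministic for a fixed config
#' and seed. The manifest records per-stage counts (input transcripts,
#' coverage-excluded, skipped, variants with events, total events,
#' conserved/novel split) and echoes the config.
#'
#' @param config a `pipeline_config` from [validate_config()], a YAML
#'   path, or a plain list
#' @param quiet suppress progress messages
#' @return the manifest (list), invisibly; files are written to
#'   `config$out_dir`
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  say <- function(...) if (!quiet) message("[splicetyper] ", ...)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(config$simulate)) {
    say("stage simulate: seed ", config$seed)
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    sim_cfg <- do.call(simulation_config, sim_args)
    annotation <- generate_reference(sim_cfg)
    cohort <- generate_cohort(annotation, sim_cfg)
    observed <- cohort$observed
    truth <- cohort$truth
    write_gff3(annotation, file.path(out, "reference.gff3"))
    write_observed_gtf(observed, file.path(out, "observed.gtf"))
    tjson <- jsonlite::toJSON(truth, dataframe = "rows", auto_unbox = TRUE)
    writeLines(as.character(tjson), file.path(out, "truth.json"))
    variants_meta <- cohort$variants
  } else {
    say("stage read: ", config$annotation, " + ", config$observed_gtf)
    annotation <- read_gff3(config$annotation)
    observed <- read_observed_gtf(config$observed_gtf)
    variants_meta <- NULL
  }

  say("stage detect: ", nrow(observed$transcripts), " transcript records")
  callset <- detect_all(observed, annotation,
                        min_coverage = config$min_coverage,
                        restrict_to_annotated_AS =
                          config$restrict_to_annotated_AS,
                        end_convention = config$end_convention)
  write_tsv(callset$events, file.path(out, "events.tsv"))

  say("stage summarize: ", nrow(callset$events), " events in ",
      length(callset$variants), " variants")
  write_tsv(bin_events_per_variant(callset),
            file.path(out, "table2_bins.tsv"))
  if (nrow(callset$events) > 0) {
    write_tsv(type_frequencies(callset),
              file.path(out, "event_type_freq.tsv"))
  }
  tr <- observed$transcripts
  tr <- tr[tr$variant_id %in% callset$variants, , drop = FALSE]
  if (nrow(tr) > 0) {
    groups <- lapply(split(tr$treatment, tr$variant_id), unique)
    write_tsv(venn_partition(groups),
              file.path(out, "venn_groups.tsv"))
  }
  nov <- novelty_summary(callset)

  species <- NULL
  if (!is.null(config$species_catalogs)) {
    catalogs <- lapply(config$species_catalogs, read_symbol_list)
    sym <- stats::setNames(annotation$genes$symbol, annotation$genes$gene_id)
    focal <- unique(sym[unique(callset$events$gene_id)])
    species <- species_sharing(focal, catalogs)
    write_tsv(data.frame(species = names(species$per_species),
                         shared = as.integer(species$per_species)),
              file.path(out, "species_sharing.tsv"))
  }

  enrichment_n <- NA_integer_
  if (!is.null(config$simulate) || !is.null(config$gmt)) {
    if (!is.null(config$gmt)) {
      terms <- read_gmt(config$gmt)
      background <- read_symbol_list(config$background)
    } else {
      # simulated run: terms enriched for the genes carrying AS variants
      sym <- stats::setNames(annotation$genes$symbol, annotation$genes$gene_id)
      as_genes <- unique(sym[unique(callset$events$gene_id)])
      terms <- generate_term_sets(
        annotation, n_terms = 50,
        enriched_term_spec = list(name = "planted AS geneset",
                                  genes = utils::head(as_genes, 15),
                                  strength = 1),
        seed = config$seed + 2L)
      write_gmt(terms, file.path(out, "terms.gmt"))
      background <- annotation$genes$symbol
    }
    sym <- stats::setNames(annotation$genes$symbol, annotation$genes$gene_id)
    query <- unique(unname(sym[unique(callset$events$gene_id)]))
    say("stage enrich: ", length(terms), " terms, query ", length(query),
        " genes, background ", length(background))
    enr <- run_enrichment(query, background, terms,
                          min_overlap = config$min_overlap,
                          p_cutoff = config$p_cutoff,
                          q_report = config$q_report)
    write_tsv(enr, file.path(out, "enrichment.tsv"))
    enrichment_n <- nrow(enr)
  }

  manifest <- list(
    package = "splicetyper",
    version = as.character(utils::packageVersion("splicetyper")),
    config = unclass(config),
    counts = list(
      input_transcripts = callset$n_input,
      coverage_excluded = callset$filtered_out,
      skipped_not_annotated_AS = callset$skipped_not_annotated_AS,
      variants_with_events = length(callset$variants),
      total_events = nrow(callset$events),
      conserved_events = sum(callset$events$conserved),
      novel_events = sum(!callset$events$conserved),
      novel_variants = nov$n_novel,
      conserved_variants = nov$n_conserved,
      enriched_terms_reported = enrichment_n
    )
  )
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           pretty = TRUE, digits = NA)),
             file.path(out, "manifest.json"))
  say("done: outputs in ", out)
  invisible(list(manifest = manifest, callset = callset,
                 annotation = annotation, observed = observed,
                 truth = truth, variants = variants_meta))
}
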