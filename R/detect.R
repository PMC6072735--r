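# Core AS detection: compare observed exon chains against reference
# isoforms, emit typed events (ES/IR/AA/AD/AP), call conserved/novel.
#
# Typing rules, applied in precedence order IR > ES > boundary events so
# that an exon consumed by an intron-retention merge is never also scored
# as a boundary event:
#   IR  an observed exon spans an entire reference intron and overlaps both
#       flanking reference exons; defining interval = the retained intron
#   ES  a reference exon strictly inside the observed span overlaps no
#       observed exon; defining interval = the skipped reference exon
#   AD  matched exon pair sharing its 3' end but differing at the 5' end
#       (the field's donor/acceptor naming is sometimes inverted relative
#       to this rule; `end_convention = "conventional"` swaps the labels)
#   AA  matched pair sharing its 5' end, differing at the 3' end
#   AP  matched pair differing at both ends
# Transcript-terminal outer boundaries (alternative TSS/polyadenylation,
# assembly truncation) are not splicing and are excluded from comparison.

#' Filter observed transcripts by supporting coverage
#'
#' Records with fewer supporting reads than `min_coverage` are excluded
#' from analysis; the default of 2 drops exactly the single-read
#' alignments.
#'
#' @param observed an [observed_set()]
#' @param min_coverage minimum supporting read count (default 2)
#' @return `list(retained = observed_set, excluded = count)` with record
#'   order preserved
#' @export
filter_by_coverage <- function(observed, min_coverage = 2L) {
  stopifnot(inherits(observed, "observed_set"))
  keep <- observed$transcripts$coverage >= min_coverage
  kept_ids <- observed$transcripts$transcript_id[keep]
  retained <- structure(list(
    transcripts = observed$transcripts[keep, , drop = FALSE],
    exons = observed$exons[observed$exons$transcript_id %in% kept_ids, ,
                           drop = FALSE]
  ), class = "observed_set")
  list(retained = retained, excluded = sum(!keep))
}

#' Pair observed exons with reference exons by maximal overlap
#'
#' Each observed exon is paired with the reference exon of maximal base
#' overlap (ties go to the smaller reference genomic start). Pairing is
#' injective on reference exons: a reference exon claimed by two observed
#' exons goes to the larger overlap (tie: the upstream observed exon);
#' the losing observed exon stays unmatched. Zero-overlap exons are
#' unmatched.
#'
#' @param observed,reference exon chains (2-col matrices or data.frames)
#' @param obs_strand,ref_strand,obs_chrom,ref_chrom optional strand/chrom
#'   labels; a mismatch is an error
#' @return `list(pairs = 2-col matrix of (observed, reference) indices,
#'   unmatched_observed, unmatched_reference)`
#' @export
pair_exons <- function(observed, reference,
                       obs_strand = NULL, ref_strand = NULL,
                       obs_chrom = NULL, ref_chrom = NULL) {
  if (!is.null(obs_strand) && !is.null(ref_strand) &&
      obs_strand != ref_strand) {
    stop("strand mismatch between observed and reference chains")
  }
  if (!is.null(obs_chrom) && !is.null(ref_chrom) && obs_chrom != ref_chrom) {
    stop("chrom mismatch between observed and reference chains")
  }
  obs <- as_chain(observed)
  ref <- as_chain(reference)
  no <- nrow(obs); nr <- nrow(ref)
  best_ref <- integer(no); best_ov <- numeric(no)
  for (i in seq_len(no)) {
    ov <- overlap_len(obs[i, 1], obs[i, 2], ref[, 1], ref[, 2])
    j <- which.max(ov)  # ties -> smallest index = smallest genomic start
    best_ref[i] <- if (ov[j] > 0) j else NA_integer_
    best_ov[i] <- ov[j]
  }
  # enforce injectivity on reference exons
  claimed <- rep(NA_integer_, nr)  # winning observed index per ref exon
  for (i in seq_len(no)) {
    j <- best_ref[i]
    if (is.na(j)) next
    if (is.na(claimed[j])) {
      claimed[j] <- i
    } else if (best_ov[i] > best_ov[claimed[j]]) {
      best_ref[claimed[j]] <- NA_integer_
      claimed[j] <- i
    } else {
      best_ref[i] <- NA_integer_  # tie keeps the upstream observed exon
    }
  }
  matched <- which(!is.na(best_ref))
  list(
    pairs = cbind(observed = matched, reference = best_ref[matched]),
    unmatched_observed = which(is.na(best_ref)),
    unmatched_reference = setdiff(seq_len(nr), best_ref[matched])
  )
}

empty_events <- function() {
  data.frame(event_type = character(0), start = numeric(0), end = numeric(0),
             stringsAsFactors = FALSE)
}

# Core classifier on bare chains; returns data.frame(event_type, start, end).
classify_chains <- function(obs, ref, strand, end_convention = "paper") {
  obs <- as_chain(obs); ref <- as_chain(ref)
  check_strand(strand)
  end_convention <- match.arg(end_convention, c("paper", "conventional"))
  events <- list()
  no <- nrow(obs); nr <- nrow(ref)
  ref_introns <- introns_of(ref)

  # (1) IR: observed exon strictly spans a reference intron
  ir_consumed_ref <- logical(nr)  # ref exons flanking a retained intron
  ir_obs <- logical(no)
  if (nrow(ref_introns) > 0) {
    for (i in seq_len(no)) {
      within <- which(obs[i, 1] < ref_introns[, 1] &
                        obs[i, 2] > ref_introns[, 2])
      for (j in within) {
        events[[length(events) + 1L]] <-
          data.frame(event_type = "IR", start = ref_introns[j, 1],
                     end = ref_introns[j, 2], stringsAsFactors = FALSE)
        ir_consumed_ref[c(j, j + 1L)] <- TRUE
        ir_obs[i] <- TRUE
      }
    }
  }

  # (2) ES: reference exon strictly inside the observed span, zero overlap
  span <- c(obs[1, 1], obs[no, 2])
  for (j in seq_len(nr)) {
    if (ref[j, 1] >= span[1] && ref[j, 2] <= span[2]) {
      ov <- overlap_len(ref[j, 1], ref[j, 2], obs[, 1], obs[, 2])
      if (all(ov == 0)) {
        events[[length(events) + 1L]] <-
          data.frame(event_type = "ES", start = ref[j, 1], end = ref[j, 2],
                     stringsAsFactors = FALSE)
      }
    }
  }

  # (3) boundary events on matched pairs not consumed by IR
  pr <- pair_exons(obs, ref)
  if (nrow(pr$pairs) > 0) {
    for (p in seq_len(nrow(pr$pairs))) {
      i <- pr$pairs[p, 1]; j <- pr$pairs[p, 2]
      if (ir_obs[i] || ir_consumed_ref[j]) next
      # transcript-terminal outer ends are not splice sites: ignore the
      # genomic-start difference at a chain's first exon and the
      # genomic-end difference at its last (strand-symmetric genomically)
      ds <- obs[i, 1] != ref[j, 1] && !(i == 1L || j == 1L)
      de <- obs[i, 2] != ref[j, 2] && !(i == no || j == nr)
      if (!ds && !de) next
      type <- if (ds && de) {
        "AP"
      } else if (ds) {
        # genomic start is 5' on +, 3' on -; 5'-only difference = AD (paper)
        if (strand == "+") "AD" else "AA"
      } else {
        if (strand == "+") "AA" else "AD"
      }
      if (end_convention == "conventional" && type %in% c("AA", "AD")) {
        type <- if (type == "AD") "AA" else "AD"
      }
      events[[length(events) + 1L]] <-
        data.frame(event_type = type, start = obs[i, 1], end = obs[i, 2],
                   stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0L) return(empty_events())
  out <- do.call(rbind, events)
  out[order(out$start, out$end, out$event_type), , drop = FALSE]
}

#' Classify an observed chain against one reference isoform
#'
#' Emits every typed splicing difference between the observed exon chain
#' and the reference isoform (no differences yields an empty frame). See
#' the package vignette for the typing rules and their precedence.
#'
#' @param observed observed exon chain (matrix/data.frame, 0-based
#'   half-open)
#' @param reference reference isoform exon chain
#' @param strand shared strand (`"+"`/`"-"`)
#' @param end_convention `"paper"` (default: 5'-only difference labelled
#'   AD) or `"conventional"` (labels swapped)
#' @return data.frame: `event_type`, `start`, `end` (defining interval)
#' @export
classify_against_isoform <- function(observed, reference, strand,
                                     end_convention = "paper") {
  classify_chains(observed, reference, strand, end_convention)
}

#' Choose the best-matching reference isoform
#'
#' Parsimony rule: the isoform minimising the event count, with ties broken
#' by fewer ES events, then by lexicographically smaller transcript id.
#'
#' @param observed observed exon chain
#' @param isoforms named list of reference isoform chains (names =
#'   transcript ids)
#' @param strand shared strand
#' @param end_convention see [classify_against_isoform()]
#' @return `list(reference_isoform_id, events)` where `events` is the
#'   classification against the chosen isoform
#' @export
choose_reference_isoform <- function(observed, isoforms, strand,
                                     end_convention = "paper") {
  if (length(isoforms) == 0L) stop("gene has no isoforms")
  best <- NULL
  for (tid in sort(names(isoforms))) {
    ev <- classify_chains(observed, isoforms[[tid]], strand, end_convention)
    key <- c(nrow(ev), sum(ev$event_type == "ES"))
    if (is.null(best) || key[1] < best$key[1] ||
        (key[1] == best$key[1] && key[2] < best$key[2])) {
      best <- list(reference_isoform_id = tid, events = ev, key = key)
    }
  }
  best$key <- NULL
  best
}

#' Call an event conserved or novel
#'
#' An event is conserved iff some annotated isoform of the gene other than
#' the matched reference isoform exhibits the same event -- same type and
#' exactly equal defining-interval coordinates -- relative to that matched
#' reference isoform. A single-isoform gene therefore never yields a
#' conserved call.
#'
#' @param event list or one-row data.frame with `event_type`, `start`,
#'   `end`
#' @param isoforms named list of the gene's annotated isoform chains
#' @param reference_isoform_id the matched reference isoform
#' @param strand gene strand
#' @param end_convention see [classify_against_isoform()]
#' @return logical
#' @export
call_conservation <- function(event, isoforms, reference_isoform_id, strand,
                              end_convention = "paper") {
  others <- setdiff(names(isoforms), reference_isoform_id)
  if (length(others) == 0L) return(FALSE)
  ref <- isoforms[[reference_isoform_id]]
  for (tid in others) {
    ev <- classify_chains(isoforms[[tid]], ref, strand, end_convention)
    if (any(ev$event_type == event$event_type &
              ev$start == event$start & ev$end == event$end)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Detect and type all AS events in a cohort
#'
#' Composition of the full detection pipeline: coverage filtering,
#' per-transcript reference-isoform selection, event classification and
#' conservation calling. Identical events supported by several observed
#' transcripts of the same variant count once per variant; across variants
#' they remain distinct. By default only genes annotated as AS (>= 2
#' annotated isoforms) are considered; other transcripts are skipped with
#' a count, not an error.
#'
#' @param observed an [observed_set()]
#' @param annotation a [genome_annotation()]
#' @param min_coverage minimum supporting reads (default 2)
#' @param restrict_to_annotated_AS skip genes with a single annotated
#'   isoform (default TRUE)
#' @param end_convention see [classify_against_isoform()]
#' @return an `as_callset`: `list(events, variants, filtered_out,
#'   skipped_not_annotated_AS, per_variant_counts, n_input)` where `events`
#'   has columns `variant_id`, `gene_id`, `event_type`, `chrom`, `start`,
#'   `end`, `strand`, `reference_isoform_id`, `conserved`
#' @export
detect_all <- function(observed, annotation, min_coverage = 2L,
                       restrict_to_annotated_AS = TRUE,
                       end_convention = "paper") {
  stopifnot(inherits(observed, "observed_set"),
            inherits(annotation, "genome_annotation"))
  unknown <- setdiff(unique(observed$transcripts$gene_id),
                     annotation$genes$gene_id)
  if (length(unknown)) {
    bad <- observed$transcripts$variant_id[
      observed$transcripts$gene_id %in% unknown]
    stop("observed transcripts reference unknown gene_id(s); variants: ",
         paste(unique(bad), collapse = ", "))
  }
  flt <- filter_by_coverage(observed, min_coverage)
  retained <- flt$retained
  idx <- annotation_index(annotation)

  tr <- retained$transcripts
  skip <- if (restrict_to_annotated_AS) {
    !vapply(tr$gene_id, function(g) isTRUE(idx[[g]]$annotated_AS), logical(1))
  } else {
    rep(FALSE, nrow(tr))
  }
  n_skipped <- sum(skip)
  tr <- tr[!skip, , drop = FALSE]

  ev_rows <- list()
  # classify each unique (variant, structure) once; identical emissions of
  # a variant across treatment groups share the structure
  chains <- list()
  for (r in seq_len(nrow(tr))) {
    tid <- tr$transcript_id[r]
    chains[[tid]] <- chain_of(retained, tid)
  }
  for (r in seq_len(nrow(tr))) {
    tid <- tr$transcript_id[r]
    gid <- tr$gene_id[r]
    gene <- idx[[gid]]
    if (gene$strand != tr$strand[r] || gene$chrom != tr$chrom[r]) {
      stop("transcript ", tid, " disagrees with gene ", gid,
           " on chrom/strand")
    }
    sel <- choose_reference_isoform(chains[[tid]], gene$isoforms,
                                    gene$strand, end_convention)
    ev <- sel$events
    if (nrow(ev) == 0L) next
    conserved <- vapply(seq_len(nrow(ev)), function(k) {
      call_conservation(ev[k, ], gene$isoforms, sel$reference_isoform_id,
                        gene$strand, end_convention)
    }, logical(1))
    ev_rows[[length(ev_rows) + 1L]] <- data.frame(
      variant_id = tr$variant_id[r], gene_id = gid,
      event_type = ev$event_type, chrom = gene$chrom,
      start = ev$start, end = ev$end, strand = gene$strand,
      reference_isoform_id = sel$reference_isoform_id,
      conserved = conserved, stringsAsFactors = FALSE)
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else data.frame(
    variant_id = character(0), gene_id = character(0),
    event_type = character(0), chrom = character(0), start = numeric(0),
    end = numeric(0), strand = character(0),
    reference_isoform_id = character(0), conserved = logical(0),
    stringsAsFactors = FALSE)
  # dedupe by identity key per variant
  key <- paste(events$variant_id, events$gene_id, events$event_type,
               events$start, events$end, sep = "\r")
  events <- events[!duplicated(key), , drop = FALSE]
  events <- events[order(events$variant_id, events$start, events$end), ,
                   drop = FALSE]
  rownames(events) <- NULL
  counts <- table(events$variant_id)
  per_variant <- stats::setNames(as.integer(counts), names(counts))
  structure(list(
    events = events,
    variants = sort(unique(events$variant_id)),
    filtered_out = flt$excluded,
    skipped_not_annotated_AS = n_skipped,
    per_variant_counts = per_variant,
    n_input = nrow(observed$transcripts)
  ), class = "as_callset")
}

#' @export
print.as_callset <- function(x, ...) {
  cat("as_callset:", nrow(x$events), "events in", length(x$variants),
      "variants\n")
  cat("  coverage-excluded records:", x$filtered_out,
      "| skipped (not annotated AS):", x$skipped_not_annotated_AS, "\n")
  if (nrow(x$events)) {
    cat("  conserved:", sum(x$events$conserved),
        "| novel:", sum(!x$events$conserved), "\n")
  }
  invisible(x)
}
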