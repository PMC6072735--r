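# Descriptive surfaces: events-per-variant bins, novelty split, event-type
# frequencies, Venn partitions over experimental groups, cross-species
# sharing and group mean +/- SD summaries. All percentages use half-up
# rounding at the stated decimals.

#' Bin variants by their event count
#'
#' Buckets AS variants into the conventional 1-9 / 10-19 / >=20
#' events-per-variant bins, with counts of variants and events per bin and
#' the percentage of variants (2 decimals, half-up), plus a summary row.
#'
#' @param callset an `as_callset` from [detect_all()]
#' @return data.frame: `bin_label`, `n_variants`, `n_events`,
#'   `pct_variants`; last row is the summary
#' @export
bin_events_per_variant <- function(callset) {
  counts <- callset$per_variant_counts
  total <- length(counts)
  bins <- list("1-9" = c(1, 9), "10-19" = c(10, 19), ">=20" = c(20, Inf))
  rows <- lapply(names(bins), function(lab) {
    b <- bins[[lab]]
    sel <- counts >= b[1] & counts <= b[2]
    data.frame(bin_label = lab, n_variants = sum(sel),
               n_events = sum(counts[sel]),
               pct_variants = if (total > 0) {
                 round_half_up(100 * sum(sel) / total, 2)
               } else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(bin_label = "Summary", n_variants = total,
                        n_events = sum(counts),
                        pct_variants = if (total > 0) 100 else 0,
                        stringsAsFactors = FALSE))
}

#' Novel versus conserved variant summary
#'
#' A variant is conserved only if every one of its events is conserved;
#' any novel event makes the variant novel.
#'
#' @param callset an `as_callset`
#' @return `list(n_novel, n_conserved, pct_novel)` with `pct_novel`
#'   rounded half-up to an integer
#' @export
novelty_summary <- function(callset) {
  ev <- callset$events
  if (nrow(ev) == 0L) return(list(n_novel = 0L, n_conserved = 0L,
                                  pct_novel = 0))
  all_cons <- tapply(ev$conserved, ev$variant_id, all)
  n_cons <- sum(all_cons)
  n_nov <- sum(!all_cons)
  list(n_novel = n_nov, n_conserved = n_cons,
       pct_novel = round_half_up(100 * n_nov / (n_nov + n_cons), 0))
}

#' Event-type frequency table
#'
#' @param callset an `as_callset` with at least one event
#' @return data.frame: `event_type`, `count`, `pct` (1 decimal, half-up),
#'   in fixed ES/IR/AA/AD/AP order
#' @export
type_frequencies <- function(callset) {
  ev <- callset$events
  if (nrow(ev) == 0L) stop("cannot compute type frequencies of an empty callset")
  counts <- vapply(EVENT_TYPES, function(t) sum(ev$event_type == t),
                   integer(1))
  data.frame(event_type = EVENT_TYPES, count = as.integer(counts),
             pct = round_half_up(100 * counts / sum(counts), 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

canonical_region <- function(labels, universe) {
  known <- labels[order(match(labels, universe))]
  paste(known, collapse = "+")
}

#' Exact Venn partition of variants over group labels
#'
#' Partitions variants into disjoint exact regions: a variant carrying
#' labels `{LS, RS}` counts in the LS+RS-only region, not in LS or RS.
#' Region counts always sum to the number of labelled variants. The same
#' operation serves treatment groups, sites and species sets.
#'
#' @param variant_groups named list: variant_id -> character vector of
#'   labels (non-empty)
#' @param total denominator for percentages (default: number of variants)
#' @param universe label universe fixing region order (default: treatments
#'   CTRL/LS/RS plus any other labels seen)
#' @return data.frame: `region`, `count`, `pct` (2 decimals, half-up),
#'   `members` (comma-joined variant ids); all non-empty regions of the
#'   universe are listed, empty regions with count 0
#' @export
venn_partition <- function(variant_groups, total = length(variant_groups),
                           universe = NULL) {
  if (length(variant_groups) == 0L) {
    return(data.frame(region = character(0), count = integer(0),
                      pct = numeric(0), members = character(0),
                      stringsAsFactors = FALSE))
  }
  sizes <- lengths(variant_groups)
  if (any(sizes == 0L)) {
    stop("variant(s) with an empty label set: ",
         paste(names(variant_groups)[sizes == 0L], collapse = ", "))
  }
  seen <- unique(unlist(variant_groups))
  if (is.null(universe)) {
    universe <- c(intersect(TREATMENTS, seen), sort(setdiff(seen, TREATMENTS)))
  }
  if (!all(seen %in% universe)) {
    stop("labels outside the universe: ",
         paste(setdiff(seen, universe), collapse = ", "))
  }
  region_of <- vapply(variant_groups, canonical_region, character(1),
                      universe = universe)
  # enumerate all non-empty subsets of the universe in canonical order
  n <- length(universe)
  subsets <- unlist(lapply(seq_len(n), function(k) {
    combn(universe, k, function(s) paste(s, collapse = "+"), simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(subsets, function(lab) {
    ids <- names(region_of)[region_of == lab]
    data.frame(region = lab, count = length(ids),
               pct = round_half_up(100 * length(ids) / total, 2),
               members = paste(sort(ids), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-species sharing of AS genes
#'
#' Compares a focal AS gene-symbol set against per-species AS catalogs.
#' Symbols are trimmed and compared case-insensitively. The percentage of
#' two-or-more-species sharing uses the number of focal symbols shared with
#' any species as its denominator.
#'
#' @param focal_genes character vector of focal AS gene symbols (non-empty)
#' @param catalogs named list: species -> character vector of AS gene
#'   symbols
#' @return `list(per_species = named shared counts, n_shared_any,
#'   n_shared_two_or_more, pct_two_or_more)`; when nothing is shared the
#'   percentage is reported as 0 with a warning
#' @export
species_sharing <- function(focal_genes, catalogs) {
  if (length(focal_genes) == 0L) stop("focal gene set is empty")
  norm <- function(x) unique(toupper(trimws(x)))
  focal <- norm(focal_genes)
  cats <- lapply(catalogs, norm)
  per_species <- vapply(cats, function(s) length(intersect(focal, s)),
                        integer(1))
  n_cat <- vapply(focal, function(g) {
    sum(vapply(cats, function(s) g %in% s, logical(1)))
  }, integer(1))
  n_any <- sum(n_cat >= 1L)
  n_two <- sum(n_cat >= 2L)
  pct <- if (n_any == 0L) {
    warning("no focal symbols shared with any catalog; percentage reported as 0")
    0
  } else {
    round_half_up(100 * n_two / n_any, 2)
  }
  list(per_species = per_species, n_shared_any = n_any,
       n_shared_two_or_more = n_two, pct_two_or_more = pct)
}

#' Group summary statistics (mean and sample SD)
#'
#' @param values numeric vector of per-group values (n >= 2)
#' @return `list(values, mean, sd)`; `sd` uses the n-1 denominator
#' @export
group_summary_stats <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values for a group summary")
  list(values = values, mean = mean(values), sd = stats::sd(values))
}

#' Annotation-rate percentages
#'
#' @param n_annotated variants with any annotation
#' @param n_correct variants annotated correctly
#' @param total total AS variants (the denominator for both percentages)
#' @return `list(pct_annotated, pct_correct)`, 2 decimals half-up
#' @export
annotation_rate <- function(n_annotated, n_correct, total) {
  if (!(n_correct <= n_annotated && n_annotated <= total)) {
    stop("require n_correct <= n_annotated <= total")
  }
  list(pct_annotated = round_half_up(100 * n_annotated / total, 2),
       pct_correct = round_half_up(100 * n_correct / total, 2))
}
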