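# Event application and planting primitives.
#
# An event is canonically (event_type, defining interval):
#   ES       defining interval = the skipped reference exon
#   IR       defining interval = the retained reference intron
#   AA/AD/AP defining interval = the resulting (observed) exon
# Applying an event to a reference exon chain yields the observed chain;
# the detector inverts this mapping.

overlap_len <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
}

#' Apply one splicing event to an exon chain
#'
#' Transforms a reference exon chain into the chain that exhibits the given
#' event: ES removes the exon equal to the defining interval, IR merges the
#' two exons flanking the defining intron, and AA/AD/AP replace the exon of
#' maximal overlap with the defining interval.
#'
#' @param chain exon chain (2-column matrix or data.frame, 0-based half-open)
#' @param event_type one of `"ES"`, `"IR"`, `"AA"`, `"AD"`, `"AP"`
#' @param interval length-2 numeric `(start, end)`: the defining interval
#' @return the transformed exon chain (sorted matrix)
#' @export
apply_event <- function(chain, event_type, interval) {
  chain <- as_chain(chain)
  event_type <- match.arg(event_type, EVENT_TYPES)
  s <- interval[[1]]; e <- interval[[2]]
  if (event_type == "ES") {
    hit <- which(chain[, 1] == s & chain[, 2] == e)
    if (length(hit) != 1L) stop("ES: no exon matches defining interval (",
                                s, ", ", e, ")")
    out <- chain[-hit, , drop = FALSE]
  } else if (event_type == "IR") {
    left <- which(chain[, 2] == s)
    right <- which(chain[, 1] == e)
    if (length(left) != 1L || length(right) != 1L || right != left + 1L) {
      stop("IR: defining interval (", s, ", ", e,
           ") is not an intron of the chain")
    }
    out <- chain
    out[left, 2] <- out[right, 2]
    out <- out[-right, , drop = FALSE]
  } else {
    ov <- overlap_len(chain[, 1], chain[, 2], s, e)
    if (all(ov == 0)) stop(event_type,
                           ": defining interval overlaps no exon")
    hit <- which.max(ov)
    out <- chain
    out[hit, ] <- c(s, e)
  }
  out <- out[order(out[, 1]), , drop = FALSE]
  validate_chain(out, "event application result")
  out
}

#' Apply a set of events to a reference exon chain
#'
#' @param chain reference exon chain
#' @param events data.frame with columns `event_type`, `start`, `end`
#' @return transformed chain
#' @export
apply_events <- function(chain, events) {
  chain <- as_chain(chain)
  if (nrow(events) == 0L) return(chain)
  for (i in seq_len(nrow(events))) {
    chain <- apply_event(chain, events$event_type[i],
                         c(events$start[i], events$end[i]))
  }
  chain
}

# Shift one genomic boundary ("start" or "end") of internal exon i by a
# random magnitude in [1, min(10, slack)], direction random among feasible.
# `orig` is the unshifted exon: the result must keep >= 1 base of overlap
# with it (the detector pairs exons by overlap), which matters when both
# boundaries of one exon are shifted in turn. Returns the new
# (start, end) or NULL when no legal shift exists.
shift_boundary <- function(chain, i, side, max_shift = 10, orig = chain[i, ]) {
  ex <- chain[i, ]
  if (side == "start") {
    slack_out <- chain[i, 1] - chain[i - 1, 2] - 1  # extend into intron
    slack_in <- min(ex[2], orig[2]) - ex[1] - 1     # shrink, keep overlap
  } else {
    slack_out <- chain[i + 1, 1] - chain[i, 2] - 1
    slack_in <- ex[2] - max(ex[1], orig[1]) - 1
  }
  dirs <- c(if (slack_out >= 1) "out", if (slack_in >= 1) "in")
  if (is.null(dirs)) return(NULL)
  dir <- if (length(dirs) == 1L) dirs else sample(dirs, 1L)
  slack <- if (dir == "out") slack_out else slack_in
  m <- sample.int(min(max_shift, slack), 1L)
  delta <- if (dir == "out") -m else m   # genomic-start sense
  if (side == "start") ex[1] <- ex[1] + delta else ex[2] <- ex[2] - delta
  ex
}

#' Plant one splicing event into a donor exon chain
#'
#' Inverts the detector's typing rules: picks an internal target (exon for
#' ES/AA/AD/AP, intron for IR) and emits the transformed chain together
#' with the event's defining interval. AD shifts only the 5' boundary of an
#' internal exon (strand-aware), AA only the 3' boundary, AP both; shift
#' magnitudes are uniform on `[1, min(10, slack)]` so that exon and gap
#' invariants always hold. Terminal exon boundaries are never shifted and
#' first/last exons are never skipped.
#'
#' @param chain donor exon chain (>= 3 exons)
#' @param strand `"+"` or `"-"`
#' @param event_type one of `"ES"`, `"IR"`, `"AA"`, `"AD"`, `"AP"`
#' @param target optional target index: exon index (ES/AA/AD/AP) or intron
#'   index (IR); drawn at random when `NULL`
#' @return `list(chain = transformed chain, event_type, interval =
#'   c(start, end))` or an error when the donor is too short
#' @export
plant_event <- function(chain, strand, event_type, target = NULL) {
  chain <- as_chain(chain)
  check_strand(strand)
  event_type <- match.arg(event_type, EVENT_TYPES)
  n <- nrow(chain)
  if (n < 3L) stop("donor too short for ", event_type,
                   ": need >= 3 exons, has ", n)
  if (event_type == "IR") {
    j <- if (is.null(target)) sample(seq_len(n - 1L), 1L) else target
    if (j < 1L || j > n - 1L) stop("IR target intron out of range")
    interval <- c(chain[j, 2], chain[j + 1L, 1])
  } else {
    i <- if (is.null(target)) sample(seq.int(2L, n - 1L), 1L) else target
    if (i < 2L || i > n - 1L) stop(event_type, " target must be an internal exon")
    if (event_type == "ES") {
      interval <- chain[i, ]
    } else {
      # genomic side of the 5' boundary depends on strand
      five_side <- if (strand == "+") "start" else "end"
      three_side <- if (strand == "+") "end" else "start"
      ex <- chain[i, ]
      if (event_type %in% c("AD", "AP")) {
        shifted <- shift_boundary(chain, i, five_side)
        if (is.null(shifted)) stop("no legal 5' shift at exon ", i)
        ex <- shifted
      }
      if (event_type %in% c("AA", "AP")) {
        tmp <- chain; tmp[i, ] <- ex
        shifted <- shift_boundary(tmp, i, three_side, orig = chain[i, ])
        if (is.null(shifted)) stop("no legal 3' shift at exon ", i)
        ex <- shifted
      }
      interval <- ex
    }
  }
  list(chain = apply_event(chain, event_type, interval),
       event_type = event_type,
       interval = unname(interval))
}

# Plant several non-interacting events into one donor chain. Each event
# occupies a window of exon indices (IR occupies its intron's two flanking
# exons); windows are kept >= 1 exon apart so events never interfere with
# exon pairing. `block_exons` marks donor exon indices that may not be
# targeted at all: the cohort generator blocks the exons touching the
# gene's annotated isoform difference, so planted events stay independent
# of the annotated alternative processing and every planted event is novel.
# Events identical to `forbid` (a data.frame of event_type/start/end) are
# redrawn or dropped as a second guard. Returns list(chain, events
# data.frame); may plant fewer events than requested when the donor runs
# out of internal targets.
plant_events <- function(chain, strand, types, forbid = NULL,
                         block_exons = integer(0)) {
  chain0 <- as_chain(chain)
  n <- nrow(chain0)
  blocked <- rep(FALSE, n)
  blocked[block_exons] <- TRUE
  planted <- list()
  out_chain <- chain0
  is_forbidden <- function(type, interval) {
    !is.null(forbid) && nrow(forbid) > 0 &&
      any(forbid$event_type == type &
            forbid$start == interval[1] & forbid$end == interval[2])
  }
  for (type in types) {
    if (type == "IR") {
      cand <- which(!blocked[-n] & !blocked[-1L])  # intron j: exons j, j+1 free
      cand <- cand[!blocked[pmax(cand - 1L, 1L)] &
                     !blocked[pmin(cand + 2L, n)]]
    } else {
      cand <- seq.int(2L, n - 1L)
      cand <- cand[!blocked[cand] & !blocked[cand - 1L] & !blocked[cand + 1L]]
    }
    if (length(cand) == 0L) next
    shuffled <- if (length(cand) == 1L) cand else sample(cand)
    placed <- FALSE
    for (tgt in shuffled) {
      ok <- FALSE
      for (try in 1:10) {  # redraw random shifts away from forbidden events
        ev <- plant_event(chain0, strand, type, target = tgt)
        if (!is_forbidden(type, ev$interval)) { ok <- TRUE; break }
        if (type %in% c("ES", "IR")) break  # deterministic per target
      }
      if (!ok) next
      span <- if (type == "IR") c(tgt, tgt + 1L) else tgt
      blocked[span] <- TRUE
      planted[[length(planted) + 1L]] <-
        data.frame(event_type = type, start = ev$interval[1],
                   end = ev$interval[2], stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
  }
  events <- if (length(planted)) do.call(rbind, planted) else
    data.frame(event_type = character(0), start = numeric(0),
               end = numeric(0), stringsAsFactors = FALSE)
  list(chain = apply_events(chain0, events), events = events)
}
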