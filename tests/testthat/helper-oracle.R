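# Independent brute-force classifier, written directly from the interval-
# relation definitions with plain loops. Deliberately shares no code with
# the package internals; used to cross-check classify_against_isoform.

oracle_overlap <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))

oracle_classify <- function(obs, ref, strand) {
  obs <- obs[order(obs[, 1]), , drop = FALSE]
  ref <- ref[order(ref[, 1]), , drop = FALSE]
  no <- nrow(obs); nr <- nrow(ref)
  out <- list()
  ir_ref <- rep(FALSE, nr)
  ir_obs <- rep(FALSE, no)

  # IR: observed exon strictly spans a whole reference intron
  if (nr >= 2) {
    for (j in seq_len(nr - 1)) {
      i_start <- ref[j, 2]; i_end <- ref[j + 1, 1]
      for (i in seq_len(no)) {
        if (obs[i, 1] < i_start && obs[i, 2] > i_end) {
          out[[length(out) + 1]] <- c("IR", i_start, i_end)
          ir_ref[j] <- TRUE; ir_ref[j + 1] <- TRUE; ir_obs[i] <- TRUE
        }
      }
    }
  }

  # ES: reference exon inside the observed span overlapping nothing
  for (j in seq_len(nr)) {
    if (ref[j, 1] >= obs[1, 1] && ref[j, 2] <= obs[no, 2]) {
      any_ov <- FALSE
      for (i in seq_len(no)) {
        if (oracle_overlap(obs[i, 1], obs[i, 2], ref[j, 1], ref[j, 2]) > 0) {
          any_ov <- TRUE
        }
      }
      if (!any_ov) out[[length(out) + 1]] <- c("ES", ref[j, 1], ref[j, 2])
    }
  }

  # max-overlap pairing, injective on reference exons
  best <- rep(NA_integer_, no); bov <- rep(0, no)
  for (i in seq_len(no)) {
    for (j in seq_len(nr)) {
      o <- oracle_overlap(obs[i, 1], obs[i, 2], ref[j, 1], ref[j, 2])
      if (o > bov[i]) { bov[i] <- o; best[i] <- j }
    }
  }
  winner <- rep(NA_integer_, nr)
  for (i in seq_len(no)) {
    j <- best[i]
    if (is.na(j)) next
    if (is.na(winner[j])) {
      winner[j] <- i
    } else if (bov[i] > bov[winner[j]]) {
      best[winner[j]] <- NA_integer_
      winner[j] <- i
    } else {
      best[i] <- NA_integer_
    }
  }

  # boundary comparison on surviving pairs, terminal outer ends masked
  for (i in seq_len(no)) {
    j <- best[i]
    if (is.na(j) || ir_obs[i] || ir_ref[j]) next
    ds <- obs[i, 1] != ref[j, 1] && i != 1 && j != 1
    de <- obs[i, 2] != ref[j, 2] && i != no && j != nr
    if (ds && de) {
      out[[length(out) + 1]] <- c("AP", obs[i, 1], obs[i, 2])
    } else if (ds) {
      type <- if (strand == "+") "AD" else "AA"
      out[[length(out) + 1]] <- c(type, obs[i, 1], obs[i, 2])
    } else if (de) {
      type <- if (strand == "+") "AA" else "AD"
      out[[length(out) + 1]] <- c(type, obs[i, 1], obs[i, 2])
    }
  }

  if (length(out) == 0) {
    return(data.frame(event_type = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(event_type = vapply(out, `[`, "", 1),
                   start = as.numeric(vapply(out, `[`, "", 2)),
                   end = as.numeric(vapply(out, `[`, "", 3)),
                   stringsAsFactors = FALSE)
  df[order(df$start, df$end, df$event_type), , drop = FALSE]
}

# canonical string form of an event table for set comparison
event_key <- function(ev) {
  sort(paste(ev$event_type, ev$start, ev$end))
}
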