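#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based, half-open [start, end).
# GFF3/GTF files are 1-based inclusive; conversion happens only in I/O.

EVENT_TYPES <- c("ES", "IR", "AA", "AD", "AP")
SITES <- c("KIL", "GDA")
TREATMENTS <- c("CTRL", "LS", "RS")
BIOTYPES <- c("protein_coding", "pseudogene", "non_coding")

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; tabulated percentages here use
#' the conventional half-up rule (72.4951 -> 72.50 at two decimals).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Coerce an exon specification (2-col matrix or data.frame with start/end)
# to a sorted integer matrix. Internal.
as_chain <- function(exons) {
  if (is.data.frame(exons)) {
    exons <- as.matrix(exons[, c("start", "end")])
  }
  if (is.null(dim(exons))) exons <- matrix(exons, ncol = 2, byrow = TRUE)
  storage.mode(exons) <- "double"
  colnames(exons) <- c("start", "end")
  exons[order(exons[, 1]), , drop = FALSE]
}

# Validate exon-chain invariants: >=1 exon, start < end, pairwise
# non-overlapping with gap >= 1 between consecutive exons.
validate_chain <- function(chain, what = "exon chain") {
  if (nrow(chain) < 1L) stop(what, ": must contain at least one exon")
  if (any(chain[, 1] >= chain[, 2])) {
    stop(what, ": empty or inverted exon interval (start >= end)")
  }
  if (nrow(chain) > 1L) {
    gaps <- chain[-1L, 1] - chain[-nrow(chain), 2]
    if (any(gaps < 1)) {
      stop(what, ": exons overlap or are adjacent (gap < 1 base)")
    }
  }
  invisible(chain)
}

check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-', got: ",
         paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
  }
  invisible(strand)
}

#' Introns of a transcript
#'
#' The intervals between consecutive exons in genomic order. A single-exon
#' transcript has no introns. Exons and introns tile the transcript span
#' exactly.
#'
#' @param exons exon chain: a 2-column `start`,`end` matrix or data.frame
#'   (0-based half-open), or a list with an `exons` element
#' @return matrix with columns `start`, `end`; `nrow = n_exons - 1`
#' @examples
#' introns_of(rbind(c(100, 200), c(300, 400)))  # one intron (200, 300)
#' @export
introns_of <- function(exons) {
  if (is.list(exons) && !is.data.frame(exons) && !is.null(exons$exons)) {
    exons <- exons$exons
  }
  chain <- as_chain(exons)
  n <- nrow(chain)
  if (n < 2L) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = unname(chain[-n, 2]), end = unname(chain[-1L, 1]))
}

#' Strand-aware exon boundary
#'
#' Resolves the 5'/3' end of an exon in transcript orientation: on the plus
#' strand the 5' boundary is the genomic start, on the minus strand it is
#' the genomic end.
#'
#' @param exon length-2 numeric `(start, end)`, 0-based half-open
#' @param strand `"+"` or `"-"`
#' @param which `"five_prime"` or `"three_prime"`
#' @return base position (numeric scalar)
#' @export
exon_boundary <- function(exon, strand, which = c("five_prime", "three_prime")) {
  which <- match.arg(which)
  check_strand(strand)
  if (exon[1] >= exon[2]) stop("invalid exon: start >= end")
  if (strand == "+") {
    if (which == "five_prime") exon[[1]] else exon[[2]]
  } else {
    if (which == "five_prime") exon[[2]] else exon[[1]]
  }
}

#' Construct a genome annotation container
#'
#' Bundles the gene/transcript/exon tables the detector consumes. Normally
#' built by [read_gff3()] or [generate_reference()] rather than directly.
#'
#' @param genes data.frame: `gene_id`, `symbol`, `biotype`, `chrom`, `strand`
#' @param transcripts data.frame: `transcript_id`, `gene_id`
#' @param exons data.frame: `transcript_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (0-based half-open)
#' @return object of class `genome_annotation`; the gene table gains
#'   `n_isoforms` and `annotated_AS` (TRUE iff >= 2 annotated isoforms)
#' @export
genome_annotation <- function(genes, transcripts, exons) {
  stopifnot(is.data.frame(genes), is.data.frame(transcripts),
            is.data.frame(exons))
  check_strand(genes$strand)
  if (!all(transcripts$gene_id %in% genes$gene_id)) {
    stop("transcripts reference unknown gene_id")
  }
  if (!all(exons$transcript_id %in% transcripts$transcript_id)) {
    stop("exons reference unknown transcript_id")
  }
  # per-transcript structural invariants
  for (tid in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tid, ]
    if (length(unique(ex$strand)) != 1L || length(unique(ex$chrom)) != 1L) {
      stop("transcript ", tid, ": exons disagree on chrom/strand")
    }
    validate_chain(as_chain(ex), paste0("transcript ", tid))
  }
  n_iso <- table(transcripts$gene_id)
  genes$n_isoforms <- as.integer(n_iso[genes$gene_id])
  genes$n_isoforms[is.na(genes$n_isoforms)] <- 0L
  genes$annotated_AS <- genes$n_isoforms >= 2L
  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,", nrow(x$exons), "exons\n")
  cat("  genes with annotated AS (>= 2 isoforms):",
      sum(x$genes$annotated_AS), "\n")
  invisible(x)
}

#' Construct an observed transcript set
#'
#' Container for observed (assembled/aligned) transcript structures with
#' their supporting read coverage and experimental labels. One record per
#' `transcript_id`; records sharing a `variant_id` are emissions of the same
#' structural variant in different treatment groups.
#'
#' @param transcripts data.frame: `transcript_id`, `variant_id`, `gene_id`,
#'   `chrom`, `strand`, `coverage`, `site`, `treatment`
#' @param exons data.frame: `transcript_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open)
#' @return object of class `observed_set`
#' @export
observed_set <- function(transcripts, exons) {
  stopifnot(is.data.frame(transcripts), is.data.frame(exons))
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("duplicate transcript_id in observed set")
  }
  if (is.null(transcripts$variant_id)) {
    transcripts$variant_id <- transcripts$transcript_id
  }
  check_strand(transcripts$strand)
  if (!all(transcripts$site %in% SITES)) {
    stop("unknown site token: ",
         paste(setdiff(unique(transcripts$site), SITES), collapse = ", "))
  }
  if (!all(transcripts$treatment %in% TREATMENTS)) {
    stop("unknown treatment token: ",
         paste(setdiff(unique(transcripts$treatment), TREATMENTS),
               collapse = ", "))
  }
  cov <- transcripts$coverage
  if (any(is.na(cov)) || any(cov < 0) || any(cov != floor(cov))) {
    stop("coverage must be a non-negative integer on every record")
  }
  for (tid in transcripts$transcript_id) {
    ex <- exons[exons$transcript_id == tid, ]
    if (nrow(ex) == 0L) stop("transcript ", tid, " has no exons")
    validate_chain(as_chain(ex), paste0("observed transcript ", tid))
  }
  structure(list(transcripts = transcripts, exons = exons),
            class = "observed_set")
}

#' @export
print.observed_set <- function(x, ...) {
  cat("observed_set:", nrow(x$transcripts), "transcript records,",
      length(unique(x$transcripts$variant_id)), "variants\n")
  invisible(x)
}

# Exon chain (sorted 2-col matrix) of one transcript in a container.
chain_of <- function(obj, transcript_id) {
  ex <- obj$exons[obj$exons$transcript_id == transcript_id, ]
  if (nrow(ex) == 0L) stop("unknown transcript_id: ", transcript_id)
  as_chain(ex)
}

# Fast per-gene isoform index: list keyed by gene_id with elements
# list(chrom, strand, isoforms = named list of chain matrices).
annotation_index <- function(annotation) {
  ex_by_tx <- split(seq_len(nrow(annotation$exons)),
                    annotation$exons$transcript_id)
  chains <- lapply(ex_by_tx, function(i) {
    as_chain(annotation$exons[i, c("start", "end")])
  })
  idx <- list()
  tx <- annotation$transcripts
  genes <- annotation$genes
  rownames(genes) <- genes$gene_id
  for (g in unique(tx$gene_id)) {
    tids <- sort(tx$transcript_id[tx$gene_id == g])
    idx[[g]] <- list(
      chrom = genes[g, "chrom"],
      strand = genes[g, "strand"],
      annotated_AS = genes[g, "annotated_AS"],
      isoforms = chains[tids]
    )
  }
  idx
}
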