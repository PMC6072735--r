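# Readers/writers for the formats the pipeline touches. Parsing is done by
# rtracklayer; writing is hand-formatted so that reruns are byte-identical
# (no timestamp headers). Internal coordinates are 0-based half-open; files
# are 1-based inclusive.

# Map imported feature order back to file line numbers (rtracklayer keeps
# feature order but drops comment lines).
feature_lines <- function(path) {
  ln <- readLines(path, warn = FALSE)
  which(!grepl("^\\s*(#|$)", ln))
}

#' Read a reference gene annotation from GFF3
#'
#' Expects a gene -> mRNA/transcript -> exon hierarchy linked by
#' `ID`/`Parent` attributes. Gene symbols are taken from a `Name` or
#' `symbol` attribute (falling back to the gene ID) and biotypes from a
#' `biotype` attribute (defaulting to `protein_coding`).
#'
#' @param path GFF3 file
#' @return a [genome_annotation()]; 1-based inclusive file coordinates are
#'   converted to 0-based half-open
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  lines <- feature_lines(path)
  if (length(lines) != length(gr)) lines <- rep(NA_integer_, length(gr))
  type <- as.character(mc$type)
  strand <- as.character(GenomicRanges::strand(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1  # 0-based half-open
  end0 <- GenomicRanges::end(gr)

  bad_strand <- which(type %in% c("gene", "mRNA", "transcript", "exon") &
                        !strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop("GFF3 parse error at line ", lines[bad_strand[1]],
         ": unknown strand '", strand[bad_strand[1]], "'")
  }

  id <- if (!is.null(mc$ID)) as.character(mc$ID) else rep(NA, length(gr))
  parent <- if (!is.null(mc$Parent)) {
    vapply(mc$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"
  if (!any(is_gene) || !any(is_tx) || !any(is_exon)) {
    stop("GFF3 parse error: need gene, mRNA/transcript and exon features")
  }

  sym <- if (!is.null(mc$Name)) as.character(mc$Name) else rep(NA, length(gr))
  if (!is.null(mc$symbol)) sym <- ifelse(is.na(sym), as.character(mc$symbol), sym)
  bty <- if (!is.null(mc$biotype)) as.character(mc$biotype) else rep(NA, length(gr))

  genes <- data.frame(
    gene_id = id[is_gene],
    symbol = ifelse(is.na(sym[is_gene]), id[is_gene], sym[is_gene]),
    biotype = ifelse(is.na(bty[is_gene]), "protein_coding", bty[is_gene]),
    chrom = chrom[is_gene],
    strand = strand[is_gene],
    stringsAsFactors = FALSE
  )
  if (!all(genes$biotype %in% BIOTYPES)) {
    stop("GFF3 parse error: unknown biotype ",
         paste(setdiff(unique(genes$biotype), BIOTYPES), collapse = ", "))
  }

  tx_parent <- parent[is_tx]
  orphan <- which(!tx_parent %in% genes$gene_id)
  if (length(orphan)) {
    stop("GFF3 parse error at line ", lines[which(is_tx)[orphan[1]]],
         ": transcript Parent '", tx_parent[orphan[1]],
         "' does not match any gene ID")
  }
  transcripts <- data.frame(
    transcript_id = id[is_tx],
    gene_id = tx_parent,
    stringsAsFactors = FALSE
  )

  ex_parent <- parent[is_exon]
  orphan <- which(!ex_parent %in% transcripts$transcript_id)
  if (length(orphan)) {
    stop("GFF3 parse error at line ", lines[which(is_exon)[orphan[1]]],
         ": exon Parent '", ex_parent[orphan[1]],
         "' does not match any transcript ID")
  }
  tx2gene <- stats::setNames(transcripts$gene_id, transcripts$transcript_id)
  exons <- data.frame(
    transcript_id = ex_parent,
    gene_id = unname(tx2gene[ex_parent]),
    chrom = chrom[is_exon],
    start = start0[is_exon],
    end = end0[is_exon],
    strand = strand[is_exon],
    stringsAsFactors = FALSE
  )
  ann <- tryCatch(
    genome_annotation(genes, transcripts, exons),
    error = function(e) stop("GFF3 parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ann
}

gff3_escape <- function(x) gsub(";", "%3B", gsub("=", "%3D", x))

#' Write a reference annotation to GFF3
#'
#' Deterministic output: same annotation always yields byte-identical files.
#'
#' @param annotation a [genome_annotation()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  out <- c("##gff-version 3")
  g <- annotation$genes
  tx <- annotation$transcripts
  ex <- annotation$exons
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    gex <- ex[ex$gene_id == gid, ]
    out <- c(out, paste(
      g$chrom[i], "splicetyper", "gene",
      min(gex$start) + 1, max(gex$end), ".", g$strand[i], ".",
      paste0("ID=", gff3_escape(gid), ";Name=", gff3_escape(g$symbol[i]),
             ";biotype=", g$biotype[i]),
      sep = "\t"))
    for (tid in sort(tx$transcript_id[tx$gene_id == gid])) {
      tex <- ex[ex$transcript_id == tid, ]
      tex <- tex[order(tex$start), ]
      out <- c(out, paste(
        g$chrom[i], "splicetyper", "mRNA",
        min(tex$start) + 1, max(tex$end), ".", g$strand[i], ".",
        paste0("ID=", gff3_escape(tid), ";Parent=", gff3_escape(gid)),
        sep = "\t"))
      for (j in seq_len(nrow(tex))) {
        out <- c(out, paste(
          g$chrom[i], "splicetyper", "exon",
          tex$start[j] + 1, tex$end[j], ".", g$strand[i], ".",
          paste0("ID=", gff3_escape(tid), ".e", j,
                 ";Parent=", gff3_escape(tid)),
          sep = "\t"))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

gtf_attr <- function(mc, name, lines, idx, required = TRUE) {
  v <- mc[[name]]
  if (is.null(v)) {
    if (required) stop("GTF parse error: missing required attribute '",
                       name, "'")
    return(NULL)
  }
  v <- as.character(v)
  miss <- which(is.na(v[idx]))
  if (required && length(miss)) {
    stop("GTF parse error at line ", lines[idx[miss[1]]],
         ": missing attribute '", name, "'")
  }
  v
}

#' Read observed transcript structures from GTF
#'
#' Requires `transcript` and `exon` features carrying `transcript_id`,
#' `gene_id`, `coverage`, `site` and `treatment` attributes. `coverage` is
#' never defaulted: a record without it is an error. An optional
#' `variant_id` attribute groups emissions of the same structural variant
#' across treatment groups; it defaults to `transcript_id`.
#'
#' @param path GTF file
#' @return an [observed_set()]
#' @export
read_observed_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  lines <- feature_lines(path)
  if (length(lines) != length(gr)) lines <- rep(NA_integer_, length(gr))
  type <- as.character(mc$type)
  is_tx <- type == "transcript"
  is_exon <- type == "exon"
  if (!any(is_tx) || !any(is_exon)) {
    stop("GTF parse error: need transcript and exon features")
  }
  tid_all <- gtf_attr(mc, "transcript_id", lines, seq_along(gr))
  gid_all <- gtf_attr(mc, "gene_id", lines, seq_along(gr))
  cov_all <- gtf_attr(mc, "coverage", lines, which(is_tx))
  site_all <- gtf_attr(mc, "site", lines, which(is_tx))
  trt_all <- gtf_attr(mc, "treatment", lines, which(is_tx))
  var_all <- gtf_attr(mc, "variant_id", lines, which(is_tx), required = FALSE)

  idx <- which(is_tx)
  cov <- suppressWarnings(as.numeric(cov_all[idx]))
  bad <- which(is.na(cov) | cov < 0 | cov != floor(cov))
  if (length(bad)) {
    stop("GTF parse error at line ", lines[idx[bad[1]]],
         ": coverage '", cov_all[idx[bad[1]]],
         "' is not a non-negative integer")
  }
  site <- site_all[idx]
  bad <- which(!site %in% SITES)
  if (length(bad)) {
    stop("GTF parse error at line ", lines[idx[bad[1]]],
         ": unknown site token '", site[bad[1]], "'")
  }
  trt <- trt_all[idx]
  bad <- which(!trt %in% TREATMENTS)
  if (length(bad)) {
    stop("GTF parse error at line ", lines[idx[bad[1]]],
         ": unknown treatment token '", trt[bad[1]], "'")
  }
  transcripts <- data.frame(
    transcript_id = tid_all[idx],
    variant_id = if (is.null(var_all)) tid_all[idx] else {
      ifelse(is.na(var_all[idx]), tid_all[idx], var_all[idx])
    },
    gene_id = gid_all[idx],
    chrom = as.character(GenomicRanges::seqnames(gr))[idx],
    strand = as.character(GenomicRanges::strand(gr))[idx],
    coverage = as.integer(cov),
    site = site,
    treatment = trt,
    stringsAsFactors = FALSE
  )
  check_strand(transcripts$strand)
  eidx <- which(is_exon)
  exons <- data.frame(
    transcript_id = tid_all[eidx],
    chrom = as.character(GenomicRanges::seqnames(gr))[eidx],
    start = GenomicRanges::start(gr)[eidx] - 1,
    end = GenomicRanges::end(gr)[eidx],
    strand = as.character(GenomicRanges::strand(gr))[eidx],
    stringsAsFactors = FALSE
  )
  if (!all(exons$transcript_id %in% transcripts$transcript_id)) {
    stop("GTF parse error: exon with transcript_id lacking a transcript ",
         "feature: ",
         paste(setdiff(unique(exons$transcript_id),
                       transcripts$transcript_id), collapse = ", "))
  }
  tryCatch(
    observed_set(transcripts, exons),
    error = function(e) stop("GTF parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
}

quote_attr <- function(name, value) paste0(name, ' "', value, '";')

#' Write observed transcripts to GTF
#'
#' @param observed an [observed_set()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_observed_gtf <- function(observed, path) {
  stopifnot(inherits(observed, "observed_set"))
  tr <- observed$transcripts
  ex <- observed$exons
  out <- character(0)
  for (i in seq_len(nrow(tr))) {
    tid <- tr$transcript_id[i]
    tex <- ex[ex$transcript_id == tid, ]
    tex <- tex[order(tex$start), ]
    attrs <- paste(
      quote_attr("transcript_id", tid),
      quote_attr("gene_id", tr$gene_id[i]),
      quote_attr("variant_id", tr$variant_id[i]),
      quote_attr("coverage", tr$coverage[i]),
      quote_attr("site", tr$site[i]),
      quote_attr("treatment", tr$treatment[i])
    )
    out <- c(out,
             paste(tr$chrom[i], "splicetyper", "transcript",
                   min(tex$start) + 1, max(tex$end), ".", tr$strand[i], ".",
                   attrs, sep = "\t"),
             vapply(seq_len(nrow(tex)), function(j) {
               paste(tr$chrom[i], "splicetyper", "exon",
                     tex$start[j] + 1, tex$end[j], ".", tr$strand[i], ".",
                     attrs, sep = "\t")
             }, character(1)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One term per line: id, description, then member symbols, tab-separated.
#'
#' @param path GMT file
#' @return named list of terms; each element is
#'   `list(name = description, genes = character vector)`
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  terms <- list()
  for (i in seq_along(ln)) {
    f <- strsplit(ln[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("GMT parse error at line ", i,
           ": need id, description and >= 1 member")
    }
    terms[[f[1]]] <- list(name = f[2], genes = unique(f[-(1:2)]))
  }
  terms
}

#' Write gene sets to a GMT file
#'
#' @param terms named list as returned by [read_gmt()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gmt <- function(terms, path) {
  out <- vapply(names(terms), function(id) {
    paste(c(id, terms[[id]]$name, terms[[id]]$genes), collapse = "\t")
  }, character(1))
  writeLines(out, path)
  invisible(path)
}

#' Read a one-symbol-per-line gene list
#'
#' Used for enrichment backgrounds and per-species AS gene catalogs.
#' Symbols are trimmed; blank lines and `#` comments are skipped.
#'
#' @param path text file
#' @return character vector of symbols
#' @export
read_symbol_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- trimws(readLines(path, warn = FALSE))
  ln[nzchar(ln) & !startsWith(ln, "#")]
}
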