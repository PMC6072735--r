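# In-code fixtures shared across test files. All coordinates are 0-based
# half-open (the package's internal convention).

# canonical toy chains: exons length 10, gaps 10
toy_chain <- function(n_exons) {
  s <- seq(0, by = 20, length.out = n_exons)
  cbind(start = s, end = s + 10)
}

# a 2-isoform gene: t2 = t1 minus its second exon (annotated exon skip)
toy_annotation <- function() {
  ch <- rbind(c(100, 200), c(300, 400), c(500, 600), c(700, 800))
  genes <- data.frame(gene_id = "G1", symbol = "GENE1",
                      biotype = "protein_coding", chrom = "chr1",
                      strand = "+", stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = c("G1.t1", "G1.t2"),
                            gene_id = "G1", stringsAsFactors = FALSE)
  exons <- rbind(
    data.frame(transcript_id = "G1.t1", gene_id = "G1", chrom = "chr1",
               start = ch[, 1], end = ch[, 2], strand = "+",
               stringsAsFactors = FALSE),
    data.frame(transcript_id = "G1.t2", gene_id = "G1", chrom = "chr1",
               start = ch[-2, 1], end = ch[-2, 2], strand = "+",
               stringsAsFactors = FALSE))
  genome_annotation(genes, transcripts, exons)
}

# observed_set with a single record built from a chain
toy_observed <- function(chain, variant_id = "V1", gene_id = "G1",
                         chrom = "chr1", strand = "+", coverage = 5L,
                         site = "KIL", treatment = "CTRL",
                         transcript_id = variant_id) {
  observed_set(
    data.frame(transcript_id = transcript_id, variant_id = variant_id,
               gene_id = gene_id, chrom = chrom, strand = strand,
               coverage = coverage, site = site, treatment = treatment,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = transcript_id, chrom = chrom,
               start = chain[, 1], end = chain[, 2], strand = strand,
               stringsAsFactors = FALSE))
}

# merge several observed_sets
bind_observed <- function(...) {
  sets <- list(...)
  observed_set(do.call(rbind, lapply(sets, function(s) s$transcripts)),
               do.call(rbind, lapply(sets, function(s) s$exons)))
}

# minimal callset for the summarize operations: counts is a named integer
# vector variant -> event count; conserved_variants lists variants whose
# events are all conserved
fake_callset <- function(counts, conserved_variants = character(0)) {
  rows <- lapply(names(counts), function(v) {
    k <- counts[[v]]
    data.frame(variant_id = v, gene_id = paste0("g_", v),
               event_type = rep("ES", k),
               chrom = "chr1", start = seq_len(k) * 100,
               end = seq_len(k) * 100 + 50, strand = "+",
               reference_isoform_id = "t1",
               conserved = v %in% conserved_variants,
               stringsAsFactors = FALSE)
  })
  structure(list(
    events = do.call(rbind, rows),
    variants = sort(names(counts)),
    filtered_out = 0L, skipped_not_annotated_AS = 0L,
    per_variant_counts = stats::setNames(as.integer(counts), names(counts)),
    n_input = length(counts)
  ), class = "as_callset")
}

# small GFF3 fixture text (1-based inclusive coordinates, as in files)
toy_gff3_lines <- function() {
  c("##gff-version 3",
    "chr1\ttest\tgene\t101\t800\t.\t+\t.\tID=G1;Name=GENE1;biotype=protein_coding",
    "chr1\ttest\tmRNA\t101\t800\t.\t+\t.\tID=G1.t1;Parent=G1",
    "chr1\ttest\texon\t101\t200\t.\t+\t.\tID=e1;Parent=G1.t1",
    "chr1\ttest\texon\t301\t400\t.\t+\t.\tID=e2;Parent=G1.t1",
    "chr1\ttest\texon\t501\t800\t.\t+\t.\tID=e3;Parent=G1.t1",
    "chr1\ttest\tmRNA\t101\t800\t.\t+\t.\tID=G1.t2;Parent=G1",
    "chr1\ttest\texon\t101\t200\t.\t+\t.\tID=e4;Parent=G1.t2",
    "chr1\ttest\texon\t501\t800\t.\t+\t.\tID=e5;Parent=G1.t2")
}

toy_gtf_lines <- function(treatment = "LS", coverage = "7") {
  attrs <- paste0('transcript_id "V1"; gene_id "G1"; coverage "', coverage,
                  '"; site "KIL"; treatment "', treatment, '";')
  c(paste("chr1\ttest\ttranscript\t101\t400\t.\t+\t.", attrs, sep = "\t"),
    paste("chr1\ttest\texon\t101\t200\t.\t+\t.", attrs, sep = "\t"),
    paste("chr1\ttest\texon\t301\t400\t.\t+\t.", attrs, sep = "\t"))
}

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
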