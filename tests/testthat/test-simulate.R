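test_that("simulation config validates its fields", {
  expect_error(simulation_config(exons_per_gene = c(2, 2)), "exons_per_gene")
  expect_error(simulation_config(event_mix = c(ES = 0, IR = 0)), "event_mix")
  expect_error(simulation_config(event_mix = c(XX = 1)), "event_mix")
  expect_error(simulation_config(group_sharing = c("LS" = 0.5)), "sum to 1")
  expect_error(simulation_config(group_sharing = c("LS+XX" = 1)), "group_sharing")
  expect_error(simulation_config(fraction_coverage_one_decoys = 1.5),
               "fraction_coverage_one_decoys")
})

test_that("generate_reference produces the configured gene and isoform counts", {
  cfg <- simulation_config(n_genes = 10, fraction_multi_isoform = 0.5, seed = 1)
  ann <- generate_reference(cfg)
  expect_equal(nrow(ann$genes), 10)
  expect_equal(sum(ann$genes$annotated_AS), 5)
  expect_true(all(table(ann$exons$transcript_id) >= cfg$exons_per_gene[1] - 1))
  # the annotated isoform pairs differ by exactly the recorded event
  iso <- attr(ann, "isoform_events")
  expect_equal(nrow(iso), 5)
  for (i in seq_len(nrow(iso))) {
    donor <- ann$exons[ann$exons$transcript_id == iso$donor_isoform_id[i],
                       c("start", "end")]
    second <- ann$exons[ann$exons$transcript_id == iso$isoform_id[i],
                        c("start", "end")]
    rebuilt <- apply_event(as.matrix(donor), iso$event_type[i],
                           c(iso$start[i], iso$end[i]))
    expect_equal(unname(rebuilt),
                 unname(as.matrix(second[order(second$start), ])))
  }
})

test_that("reference generation is deterministic: same seed, byte-identical GFF3", {
  cfg <- simulation_config(n_genes = 8, seed = 21)
  p1 <- tempfile(); p2 <- tempfile()
  write_gff3(generate_reference(cfg), p1)
  write_gff3(generate_reference(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("plant_event applies the forced transformations", {
  ch <- rbind(c(0, 10), c(20, 30), c(50, 60))
  es <- plant_event(ch, "+", "ES", target = 2)
  expect_equal(unname(es$chain), rbind(c(0, 10), c(50, 60)))
  expect_equal(es$interval, c(20, 30))

  ir <- plant_event(ch, "+", "IR", target = 1)
  expect_equal(unname(ir$chain), rbind(c(0, 30), c(50, 60)))
  expect_equal(ir$interval, c(10, 20))

  # AD on + strand shifts only the genomic start of an internal exon
  set.seed(1)
  ad <- plant_event(ch, "+", "AD", target = 2)
  expect_equal(unname(ad$chain[2, 2]), 30)      # 3' end untouched
  expect_false(ad$chain[2, 1] == 20)            # 5' end moved
  # the exact spec'd instance, via apply_event
  expect_equal(unname(apply_event(ch, "AD", c(17, 30))),
               rbind(c(0, 10), c(17, 30), c(50, 60)))

  # AA on - strand shifts the genomic start (3' in transcript orientation)
  set.seed(1)
  aa <- plant_event(ch, "-", "AA", target = 2)
  expect_equal(unname(aa$chain[2, 2]), 30)
  expect_false(aa$chain[2, 1] == 20)

  expect_error(plant_event(rbind(c(0, 10), c(20, 30)), "+", "ES"),
               "too short")
})

test_that("planted chains always satisfy the transcript invariants", {
  set.seed(7)
  ch <- toy_chain(8)
  for (i in 1:200) {
    type <- sample(c("ES", "IR", "AA", "AD", "AP"), 1)
    strand <- sample(c("+", "-"), 1)
    ev <- plant_event(ch, strand, type)
    chain <- ev$chain
    expect_true(all(chain[, 1] < chain[, 2]))
    if (nrow(chain) > 1) {
      expect_true(all(chain[-1, 1] - chain[-nrow(chain), 2] >= 1))
    }
  }
})

test_that("cohort generation is self-consistent with its truth table", {
  cfg <- simulation_config(n_genes = 40, n_variants = 150, seed = 13)
  ann <- generate_reference(cfg)
  co <- generate_cohort(ann, cfg)
  # truth events applied to the donor isoform reproduce the emitted chain
  for (v in unique(co$truth$variant_id)) {
    tr <- co$truth[co$truth$variant_id == v, ]
    donor <- ann$exons[ann$exons$transcript_id == tr$donor_isoform_id[1],
                       c("start", "end")]
    rebuilt <- apply_events(as.matrix(donor),
                            tr[, c("event_type", "start", "end")])
    tid <- co$observed$transcripts$transcript_id[
      co$observed$transcripts$variant_id == v][1]
    emitted <- co$observed$exons[co$observed$exons$transcript_id == tid,
                                 c("start", "end")]
    emitted <- as.matrix(emitted[order(emitted$start), ])
    expect_equal(unname(rebuilt), unname(emitted))
  }
})

test_that("decoy count is exact and decoys carry coverage 1", {
  cfg <- simulation_config(n_genes = 20, n_variants = 50,
                           fraction_coverage_one_decoys = 0.2, seed = 2)
  ann <- generate_reference(cfg)
  co <- generate_cohort(ann, cfg)
  expect_equal(sum(co$variants$decoy), 10)
  expect_true(all(co$variants$coverage[co$variants$decoy] == 1))
  expect_true(all(co$variants$coverage[!co$variants$decoy] >= 2))
})

test_that("group sharing regions drive treatment emission", {
  cfg <- simulation_config(n_genes = 20, n_variants = 30,
                           group_sharing = c("LS+RS" = 1), seed = 4)
  ann <- generate_reference(cfg)
  co <- generate_cohort(ann, cfg)
  by_var <- split(co$observed$transcripts$treatment,
                  co$observed$transcripts$variant_id)
  for (trts in by_var) expect_setequal(trts, c("LS", "RS"))
})

test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- simulation_config(n_genes = 20, n_variants = 40, seed = 7)
  ann <- generate_reference(cfg)
  co1 <- generate_cohort(ann, cfg)
  co2 <- generate_cohort(ann, cfg)
  p1 <- tempfile(); p2 <- tempfile()
  write_observed_gtf(co1$observed, p1)
  write_observed_gtf(co2$observed, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(co1$truth, co2$truth)
})

test_that("venn-region counts follow the multinomial expectation (4 sigma at n = 1000)", {
  cfg <- simulation_config(n_genes = 60, n_variants = 1000, seed = 31,
                           events_per_variant = c(1, 2))
  ann <- generate_reference(cfg)
  co <- generate_cohort(ann, cfg)
  counts <- table(factor(co$variants$region,
                         levels = names(cfg$group_sharing)))
  n <- sum(counts)
  for (r in names(cfg$group_sharing)) {
    p <- cfg$group_sharing[[r]]
    sigma <- sqrt(n * p * (1 - p))
    expect_lt(abs(counts[[r]] - n * p), 4 * sigma + 1e-9)
  }
})

test_that("term-set generation plants the enriched term and is deterministic", {
  cfg <- simulation_config(n_genes = 40, seed = 6)
  ann <- generate_reference(cfg)
  target <- ann$genes$symbol[1:10]
  spec <- list(name = "planted", genes = target, strength = 1)
  terms <- generate_term_sets(ann, n_terms = 12, spec, seed = 8)
  expect_length(terms, 12)
  expect_gte(length(intersect(terms[[1]]$genes, target)), 10)
  terms2 <- generate_term_sets(ann, n_terms = 12, spec, seed = 8)
  expect_identical(terms, terms2)
  expect_error(generate_term_sets(ann, n_terms = 0, spec, seed = 8), "n_terms")
  expect_error(
    generate_term_sets(ann, 3, list(name = "x", genes = "NOT_A_GENE",
                                    strength = 1), seed = 1),
    "symbols")
})
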