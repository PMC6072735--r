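test_that("coverage filter drops single-read records and preserves order", {
  obs <- bind_observed(
    toy_observed(toy_chain(3), "V1", coverage = 1L),
    toy_observed(toy_chain(3), "V2", coverage = 2L),
    toy_observed(toy_chain(3), "V3", coverage = 7L))
  flt <- filter_by_coverage(obs)
  expect_equal(flt$retained$transcripts$coverage, c(2L, 7L))
  expect_equal(flt$excluded, 1L)

  none <- filter_by_coverage(toy_observed(toy_chain(3), coverage = 1L))
  expect_equal(nrow(none$retained$transcripts), 0)
  expect_equal(none$excluded, 1L)
})

test_that("exon pairing maximises overlap and stays injective on reference exons", {
  ref <- toy_chain(3)
  idd <- pair_exons(ref, ref)
  expect_equal(unname(idd$pairs), cbind(1:3, 1:3))
  expect_length(idd$unmatched_reference, 0)

  # observed missing the middle exon
  pr <- pair_exons(ref[-2, ], ref)
  expect_equal(pr$unmatched_reference, 2L)

  # IR-merged observed exon overlaps two reference exons: larger overlap
  # wins, the other reference exon stays unmatched
  obs <- rbind(c(5, 32), c(60, 70))  # covers 5 bases of exon 1, 10 of exon 2
  ref4 <- rbind(c(0, 10), c(20, 30), c(40, 50), c(60, 70))
  pr <- pair_exons(obs, ref4)
  expect_equal(unname(pr$pairs[pr$pairs[, 1] == 1, 2]), 2L)  # overlap 10 > 5
  expect_true(1L %in% pr$unmatched_reference)
  # equal overlaps tie to the smaller reference genomic start
  tie <- pair_exons(rbind(c(0, 30), c(60, 70)), ref4)
  expect_equal(unname(tie$pairs[tie$pairs[, 1] == 1, 2]), 1L)

  expect_error(pair_exons(ref, ref, obs_strand = "+", ref_strand = "-"),
               "strand mismatch")
})

test_that("classification recovers each planted single event with its interval", {
  for (strand in c("+", "-")) {
    ref <- toy_chain(5)
    expect_equal(nrow(classify_against_isoform(ref, ref, strand)), 0)
    set.seed(3)
    for (type in c("ES", "IR", "AA", "AD", "AP")) {
      ev <- plant_event(ref, strand, type)
      got <- classify_against_isoform(ev$chain, ref, strand)
      expect_equal(got$event_type, type)
      expect_equal(c(got$start, got$end), ev$interval)
    }
  }
})

test_that("a chain with planted IR and AD yields exactly those events", {
  ref <- toy_chain(6)
  set.seed(5)
  ir <- plant_event(ref, "+", "IR", target = 1)        # merge exons 1,2
  ad <- plant_event(ir$chain, "+", "AD", target = 3)   # shift internal 5'
  got <- classify_against_isoform(ad$chain, ref, "+")
  expect_setequal(got$event_type, c("IR", "AD"))
  expect_equal(event_key(got),
               event_key(data.frame(
                 event_type = c("IR", "AD"),
                 start = c(ir$interval[1], ad$interval[1]),
                 end = c(ir$interval[2], ad$interval[2]))))
  # and the independent brute-force classifier agrees
  expect_equal(event_key(got), event_key(oracle_classify(ad$chain, ref, "+")))
})

test_that("classifier agrees with the brute-force oracle on enumerated chains", {
  for (n in 3:5) {
    ref <- toy_chain(n)
    for (strand in c("+", "-")) {
      # all exon skips and intron retentions
      for (i in 2:(n - 1)) {
        obs <- ref[-i, , drop = FALSE]
        expect_equal(event_key(classify_against_isoform(obs, ref, strand)),
                     event_key(oracle_classify(obs, ref, strand)))
      }
      for (j in 1:(n - 1)) {
        obs <- ref
        obs[j, 2] <- obs[j + 1, 2]
        obs <- obs[-(j + 1), , drop = FALSE]
        expect_equal(event_key(classify_against_isoform(obs, ref, strand)),
                     event_key(oracle_classify(obs, ref, strand)))
      }
      # all boundary shifts up to 3 bases on every internal exon
      for (i in 2:(n - 1)) {
        for (ds in -3:3) for (de in -3:3) {
          if (ds == 0 && de == 0) next
          obs <- ref
          obs[i, 1] <- obs[i, 1] + ds
          obs[i, 2] <- obs[i, 2] + de
          if (obs[i, 1] >= obs[i, 2]) next
          expect_equal(event_key(classify_against_isoform(obs, ref, strand)),
                       event_key(oracle_classify(obs, ref, strand)))
        }
      }
    }
  }
})

test_that("AD/AA labelling is strand-aware and orientation-invariant", {
  set.seed(11)
  ref <- toy_chain(6)
  M <- max(ref) + 10
  mirror <- function(ch) {
    out <- cbind(M - ch[, 2], M - ch[, 1])
    out[order(out[, 1]), , drop = FALSE]
  }
  swap <- c(ES = "ES", IR = "IR", AP = "AP", AD = "AA", AA = "AD")
  for (type in c("ES", "IR", "AA", "AD", "AP")) {
    ev <- plant_event(ref, "+", type)
    fwd <- classify_against_isoform(ev$chain, ref, "+")
    # relabelling the same chains with the opposite strand swaps AD and AA
    # (the 5'/3' roles of the genomic boundaries exchange)
    flipped <- classify_against_isoform(ev$chain, ref, "-")
    expect_equal(sort(unname(swap[fwd$event_type])),
                 sort(flipped$event_type))
    # mirroring coordinates AND flipping strand is the identity in
    # transcript orientation: the same physical event keeps its label
    mir <- classify_against_isoform(mirror(ev$chain), mirror(ref), "-")
    expect_equal(sort(fwd$event_type), sort(mir$event_type))
  }
})

test_that("the end_convention switch swaps only the AD/AA labels", {
  ref <- toy_chain(4)
  set.seed(2)
  ad <- plant_event(ref, "+", "AD")
  paper <- classify_against_isoform(ad$chain, ref, "+", "paper")
  conv <- classify_against_isoform(ad$chain, ref, "+", "conventional")
  expect_equal(paper$event_type, "AD")
  expect_equal(conv$event_type, "AA")
  expect_equal(paper[, c("start", "end")], conv[, c("start", "end")])
})

test_that("reference isoform choice is parsimonious with deterministic tie-breaks", {
  ann <- toy_annotation()
  idx <- splicetyper:::annotation_index(ann)[["G1"]]
  t2 <- idx$isoforms[["G1.t2"]]
  sel <- choose_reference_isoform(t2, idx$isoforms, "+")
  expect_equal(sel$reference_isoform_id, "G1.t2")  # exact match wins
  expect_equal(nrow(sel$events), 0)

  # one AD planted on t1 stays matched to t1 (t2 would add the exon skip)
  set.seed(6)
  ad <- plant_event(idx$isoforms[["G1.t1"]], "+", "AD", target = 3)
  sel <- choose_reference_isoform(ad$chain, idx$isoforms, "+")
  expect_equal(sel$reference_isoform_id, "G1.t1")
  expect_equal(sel$events$event_type, "AD")

  # exact tie: two copies of the same isoform -> lexicographically smaller id
  iso <- list(b_copy = idx$isoforms[["G1.t1"]],
              a_copy = idx$isoforms[["G1.t1"]])
  sel <- choose_reference_isoform(ad$chain, iso, "+")
  expect_equal(sel$reference_isoform_id, "a_copy")

  expect_error(choose_reference_isoform(t2, list(), "+"), "no isoforms")
})

test_that("conservation is an exact-coordinate match against another isoform", {
  ann <- toy_annotation()
  idx <- splicetyper:::annotation_index(ann)[["G1"]]
  # t2 skips t1's exon (300,400); the same skip classified against t1 is
  # exhibited by t2, hence conserved
  ev <- list(event_type = "ES", start = 300, end = 400)
  expect_true(call_conservation(ev, idx$isoforms, "G1.t1", "+"))
  # one base off is novel
  expect_false(call_conservation(list(event_type = "ES", start = 301, end = 400),
                                 idx$isoforms, "G1.t1", "+"))
  # same coordinates, different type is novel
  expect_false(call_conservation(list(event_type = "IR", start = 300, end = 400),
                                 idx$isoforms, "G1.t1", "+"))
  # single-isoform gene can never be conserved
  expect_false(call_conservation(ev, idx$isoforms["G1.t1"], "G1.t1", "+"))
})

test_that("detect_all recovers a one-event-per-variant cohort exactly", {
  cfg <- simulation_config(n_genes = 15, n_variants = 20,
                           events_per_variant = c(1, 1),
                           fraction_coverage_one_decoys = 0, seed = 17)
  ann <- generate_reference(cfg)
  co <- generate_cohort(ann, cfg)
  cs <- detect_all(co$observed, ann)
  expect_equal(length(cs$variants), 20)
  expect_equal(nrow(cs$events), 20)
  expect_true(all(cs$per_variant_counts == 1))
  expect_equal(cs$filtered_out, 0)
  expect_equal(event_key(cs$events),
               event_key(co$truth))

  # adding coverage-1 decoys changes only the excluded count
  decoys <- lapply(1:5, function(i) {
    toy_observed(splicetyper:::chain_of(co$observed,
                                        co$observed$transcripts$transcript_id[i]),
                 variant_id = paste0("D", i), gene_id = co$observed$transcripts$gene_id[i],
                 chrom = co$observed$transcripts$chrom[i],
                 strand = co$observed$transcripts$strand[i],
                 coverage = 1L, transcript_id = paste0("D", i))
  })
  with_decoys <- do.call(bind_observed, c(list(co$observed), decoys))
  cs2 <- detect_all(with_decoys, ann)
  expect_equal(cs2$filtered_out, 5)
  expect_equal(event_key(cs2$events), event_key(cs$events))
})

test_that("unmodified transcripts yield no events and unknown genes error", {
  cfg <- simulation_config(n_genes = 10, n_variants = 10,
                           events_per_variant = c(0, 0),
                           fraction_coverage_one_decoys = 0, seed = 23)
  ann <- generate_reference(cfg)
  co <- generate_cohort(ann, cfg)
  cs <- detect_all(co$observed, ann)
  expect_equal(length(cs$variants), 0)
  expect_equal(nrow(cs$events), 0)

  stray <- toy_observed(toy_chain(3), "VX", gene_id = "NO_SUCH_GENE")
  expect_error(detect_all(stray, ann), "unknown gene_id.*VX")
})

test_that("transcripts of single-isoform genes are skipped when restricted", {
  cfg <- simulation_config(n_genes = 10, n_variants = 10,
                           fraction_multi_isoform = 0, seed = 3,
                           fraction_coverage_one_decoys = 0)
  ann <- generate_reference(cfg)
  co <- generate_cohort(ann, cfg)  # falls back to all genes when none multi
  cs <- detect_all(co$observed, ann, restrict_to_annotated_AS = TRUE)
  expect_equal(cs$skipped_not_annotated_AS, nrow(co$observed$transcripts))
  expect_equal(nrow(cs$events), 0)
  cs2 <- detect_all(co$observed, ann, restrict_to_annotated_AS = FALSE)
  expect_equal(cs2$skipped_not_annotated_AS, 0)
  expect_gt(nrow(cs2$events), 0)
})

test_that("identical events across a variant's group emissions count once", {
  cfg <- simulation_config(n_genes = 15, n_variants = 25, seed = 19,
                           group_sharing = c("CTRL+LS+RS" = 1),
                           fraction_coverage_one_decoys = 0)
  ann <- generate_reference(cfg)
  co <- generate_cohort(ann, cfg)
  expect_equal(nrow(co$observed$transcripts), 75)  # 3 emissions per variant
  cs <- detect_all(co$observed, ann)
  expect_equal(sort(unname(cs$per_variant_counts)),
               sort(co$variants$n_events[co$variants$n_events > 0]))
})

test_that("callset events applied to the matched reference reconstruct the observed chain", {
  cfg <- simulation_config(n_genes = 30, n_variants = 60, seed = 29)
  ann <- generate_reference(cfg)
  co <- generate_cohort(ann, cfg)
  cs <- detect_all(co$observed, ann)
  for (v in cs$variants) {
    ev <- cs$events[cs$events$variant_id == v, ]
    ref <- ann$exons[ann$exons$transcript_id == ev$reference_isoform_id[1],
                     c("start", "end")]
    rebuilt <- apply_events(as.matrix(ref), ev[, c("event_type", "start", "end")])
    tid <- co$observed$transcripts$transcript_id[
      co$observed$transcripts$variant_id == v][1]
    emitted <- splicetyper:::chain_of(co$observed, tid)
    expect_equal(unname(rebuilt), unname(emitted))
  }
})
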