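# Junction-evidence classification, the expression gate, empirical
# significance against controls and allele assignment.

# hand-built 3-exon model: exons [100,200) [500,600) [900,1000)
toy_model <- function() {
  gene_model("toyG", "chrT", "+",
             list(t1 = data.frame(start = c(100L, 500L, 900L),
                                  end = c(200L, 600L, 1000L))))
}

toy_records <- function() {
  alignment_records(
    read_id = sprintf("r%d", 1:8),
    contig = c(rep("chrT", 7L), "chrOther"),
    blocks = c(
      "560-600;900-940",    # wildtype donor junction of exon 2
      "160-200;500-540",    # wildtype acceptor junction of exon 2
      "160-200;900-940",    # exon 2 skipping
      "530-570;900-940",    # cryptic junction at 570
      "560-640",            # retention: 40 nt past the donor
      "520-580",            # fully exonic: exon read only
      "610-690",            # fully inside intron 2: retention
      "560-600;900-940"),   # wrong contig: ignored
    base_at_variant = c("G", NA, NA, "A", "G", "G", NA, "G"))
}

test_that("reads are classified by junction structure with conservation", {
  v <- variant("chrT", 598L, "G", "A")   # exonic, 2 nt before the donor
  jc <- classify_alignments(toy_records(), toy_model(), v)
  expect_identical(jc$wildtype_junction, 2L)
  expect_identical(jc$skip_junction, 1L)
  expect_identical(unname(jc$cryptic_junction["570-900"]), 1L)
  expect_identical(jc$intron_retention, 2L)
  expect_identical(jc$n_ignored, 1L)
  # conservation: categories + other = classified reads
  expect_identical(jc$wildtype_junction + jc$skip_junction +
                     sum(jc$cryptic_junction) + jc$intron_retention +
                     jc$other, jc$n_classified)
  # exon reads: every read overlapping [500, 600)
  expect_identical(jc$exon_reads, 5L)
})

test_that("retention requires crossing the boundary by at least k nt", {
  m <- toy_model()
  near <- alignment_records("r1", "chrT", "560-605")   # 5 nt past donor
  far <- alignment_records("r2", "chrT", "560-612")    # 12 nt past donor
  expect_identical(classify_alignments(near, m, k = 10L,
                                       affected_exon = 2L)$intron_retention,
                   0L)
  expect_identical(classify_alignments(far, m, k = 10L,
                                       affected_exon = 2L)$intron_retention,
                   1L)
  # boundary: exactly k nt past counts
  exact <- alignment_records("r3", "chrT", "560-610")
  expect_identical(classify_alignments(exact, m, k = 10L,
                                       affected_exon = 2L)$intron_retention,
                   1L)
})

test_that("the generator's multinomial draw is recovered exactly", {
  fix <- synthetic_fixture()
  don_row <- which(fix$locus$manifest$site_kind == "donor")[1L]
  pv <- plant_variant(fix$locus, fix$mats, don_row, target_delta = -4)
  for (g in c("hom_common", "het", "hom_rare")) {
    sim <- simulate_junction_reads(fix$locus, pv$variant, g, depth = 150L,
                                   seed = 900L + match(g, GENOTYPE_LEVELS))
    jc <- classify_alignments(sim$records, fix$locus$model, pv$variant,
                              affected_exon = 2L)
    expect_identical(jc$wildtype_junction, unname(sim$drawn["wildtype"]))
    expect_identical(jc$skip_junction, unname(sim$drawn["skip"]))
    expect_identical(sum(jc$cryptic_junction),
                     unname(sim$drawn["cryptic"]))
    expect_identical(jc$intron_retention, unname(sim$drawn["retention"]))
    expect_identical(jc$other, 0L)
  }
})

test_that("expression gate is inclusive at the threshold", {
  m <- toy_model()
  mk <- function(n) {
    if (n == 0L) return(alignment_records(character(0), character(0),
                                          character(0)))
    alignment_records(sprintf("r%d", seq_len(n)), "chrT",
                      rep("560-600;900-940", n))
  }
  expect_true(expression_gate(classify_alignments(mk(5L), m,
                                                  affected_exon = 2L)))
  expect_false(expression_gate(classify_alignments(mk(4L), m,
                                                   affected_exon = 2L)))
  withr::with_seed(71L, {
    for (i in 1:10) {
      n <- sample(0:12, 1L)
      expect_identical(
        expression_gate(classify_alignments(mk(n), m, affected_exon = 2L)),
        n >= 5L)
    }
  })
})

test_that("evidence significance against controls has the closed forms", {
  fix <- synthetic_fixture()
  don_row <- which(fix$locus$manifest$site_kind == "donor")[1L]
  pv <- plant_variant(fix$locus, fix$mats, don_row, target_delta = -4)
  jc_of <- function(g, depth, seed)
    classify_alignments(
      simulate_junction_reads(fix$locus, pv$variant, g, depth = depth,
                              seed = seed)$records,
      fix$locus$model, pv$variant, affected_exon = 2L)
  controls <- control_distribution(
    lapply(1:99, function(i) jc_of("hom_common", 60L, 2000L + i)))
  # carrier with heavy retention: above every control -> p = 0.01
  case_hi <- jc_of("hom_rare", 200L, 3100L)
  sig_hi <- evidence_significance(case_hi, controls, "intron_retention")
  expect_equal(sig_hi$p_value, 1 / 100)
  # a control-like case sits inside the distribution: p near 1 for a
  # case at the low end
  case_lo <- jc_of("hom_common", 200L, 3200L)
  sig_lo <- evidence_significance(case_lo, controls, "intron_retention")
  expect_gt(sig_lo$p_value, 0.1)
  # gate: too few exon reads
  gated <- jc_of("hom_common", 3L, 3300L)
  sig_gate <- evidence_significance(gated, controls, "intron_retention")
  expect_identical(sig_gate$status, "insufficient expression")
  expect_true(is.na(sig_gate$p_value))
})

test_that("evidence significance is monotone in the case count", {
  # synthesize control normals directly; increasing case count can only
  # lower (never raise) p
  ctrl <- control_distribution(lapply(1:30, function(i) {
    jc <- structure(list(locus_id = "x", wildtype_junction = 50L,
                         skip_junction = 0L, cryptic_junction = integer(0),
                         intron_retention = i %% 7L, other = 0L,
                         exon_reads = 50L, n_classified = 50L,
                         n_ignored = 0L, affected_exon = 2L,
                         allele_counts = NULL), class = "junction_counts")
  }))
  ps <- vapply(0:12, function(k) {
    case <- structure(list(locus_id = "x", wildtype_junction = 50L - k,
                           skip_junction = 0L,
                           cryptic_junction = integer(0),
                           intron_retention = k, other = 0L,
                           exon_reads = 50L, n_classified = 50L,
                           n_ignored = 0L, affected_exon = 2L,
                           allele_counts = NULL),
                      class = "junction_counts")
    evidence_significance(case, ctrl, "intron_retention")$p_value
  }, numeric(1L))
  expect_true(all(diff(ps) <= 0))
})

test_that("carriers with elevated intron retention are flagged at depth", {
  # stated world: retention proportion 0.2 in carriers vs 0.02 in
  # controls, depth 200, 50 controls; >= 90% of carriers reach p <= 0.05
  fix <- synthetic_fixture()
  don_row <- which(fix$locus$manifest$site_kind == "donor")[1L]
  pv <- plant_variant(fix$locus, fix$mats, don_row, target_delta = -4)
  ctrl_props <- c(wildtype = 0.93, skip = 0.03, cryptic = 0.02,
                  retention = 0.02)
  carrier_props <- c(wildtype = 0.70, skip = 0.06, cryptic = 0.04,
                     retention = 0.20)
  jc_of <- function(props, seed)
    classify_alignments(
      simulate_junction_reads(fix$locus, pv$variant, "het", depth = 200L,
                              props = props, seed = seed)$records,
      fix$locus$model, pv$variant, affected_exon = 2L)
  controls <- control_distribution(
    lapply(1:50, function(i) jc_of(ctrl_props, 5000L + i)))
  flagged <- vapply(1:30, function(i) {
    p <- evidence_significance(jc_of(carrier_props, 6000L + i), controls,
                               "intron_retention")$p_value
    p <= 0.05
  }, logical(1L))
  expect_gte(mean(flagged), 0.90)
})

test_that("allele assignment splits reads by observed base", {
  v <- variant("chrT", 598L, "G", "A")
  recs <- toy_records()
  got <- allele_assignment(recs, v)
  # reads covering 597 (0-based) with a readable base: r1 (G) and r5
  # (G); r4 carries base A but its blocks do not cover the variant, and
  # r8 is on the wrong contig
  expect_identical(unname(got["ref"]), 2L)
  expect_identical(unname(got["alt"]), 0L)
  expect_identical(unname(got["unresolved"]), nrow(recs) - 2L)
  # all-reference read sets have zero alt
  all_ref <- alignment_records(c("a", "b"), "chrT",
                               c("560-600;900-940", "560-640"),
                               c("G", "G"))
  expect_identical(unname(allele_assignment(all_ref, v)["alt"]), 0L)
})

test_that("per-allele splits in heterozygotes track the generating bias", {
  fix <- synthetic_fixture()
  # the variant must be exonic in the affected exon (exon 2) for reads
  # to cover it: place it 2 nt upstream of exon 2's donor junction
  ex <- fix$locus$model$transcripts$t1
  p0 <- ex$end[2L] - 2L
  ref <- substr(fix$locus$genome[[1L]], p0 + 1L, p0 + 1L)
  v <- variant(fix$locus$contig, p0 + 1L, ref,
               setdiff(c("A", "C", "G", "T"), ref)[1L])
  sim <- simulate_junction_reads(fix$locus, v, "het", depth = 400L,
                                 seed = 777L, het_alt_bias = 0.9)
  jc <- classify_alignments(sim$records, fix$locus$model, v,
                            affected_exon = 2L)
  ac <- jc$allele_counts
  wt_ref <- ac["wildtype_junction", "ref"]
  wt_alt <- ac["wildtype_junction", "alt"]
  ret_ref <- ac["intron_retention", "ref"]
  ret_alt <- ac["intron_retention", "alt"]
  # binomial error: 4 sd around the 0.9 bias
  check_frac <- function(x, n, p) {
    expect_lt(abs(x / n - p), 4 * sqrt(p * (1 - p) / n) + 1e-9)
  }
  check_frac(wt_ref, wt_ref + wt_alt, 0.9)
  check_frac(ret_alt, ret_ref + ret_alt, 0.9)
})
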