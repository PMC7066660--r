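# The generator itself: reproducibility, convergence to the truth
# frequencies, planted-site guarantees and whole-pipeline recovery.

test_that("training-site sampling is reproducible and converges to f*", {
  truth <- truth_model(seed = 3L)
  a1 <- sample_training_sites(truth, 50L, "donor", seed = 99L)
  a2 <- sample_training_sites(truth, 50L, "donor", seed = 99L)
  expect_identical(a1$sequences, a2$sequences)
  # degenerate f*: n = 1 from a point-mass model gives the consensus
  point <- truth_model(
    donor_freqs = {
      m <- matrix(0, 4L, 4L, dimnames = list(c("A", "C", "G", "T"), NULL))
      m["G", ] <- 1; m
    },
    acceptor_freqs = truth$acceptor_freqs, seed = 3L)
  expect_identical(
    sample_training_sites(point, 1L, "donor", seed = 1L)$sequences, "GGGG")
  # law of large numbers: empirical frequencies within 0.02 sup-norm
  big <- sample_training_sites(truth, 10000L, "donor", seed = 123L)
  chars <- do.call(rbind, strsplit(big$sequences, "", fixed = TRUE))
  for (l in seq_len(ncol(chars))) {
    emp <- table(factor(chars[, l], levels = c("A", "C", "G", "T"))) / 10000
    expect_lt(max(abs(as.numeric(emp) - truth$donor_freqs[, l])), 0.02)
  }
})

test_that("planted natural sites rescore above the floor and the background is clean", {
  for (seed in c(2L, 13L, 29L)) {
    truth <- truth_model(seed = seed)
    mats <- truth_matrices(truth, n = 1000L)
    expect_no_warning(locus <- build_locus(truth, mats))
    nat <- locus$manifest[locus$manifest$origin == "natural", ]
    expect_true(all(nat$ri >= truth$natural_ri_min))
    # background guarantee: no non-planted window away from planted
    # sites reaches the natural floor
    for (kind in c("donor", "acceptor")) {
      mat <- mats[[kind]]
      sc <- scan_sequence(mat, locus$genome[[1L]], "forward")
      pj <- locus$manifest$junction[locus$manifest$site_kind == kind]
      away <- vapply(sc$junction_position, function(j)
        all(abs(j - pj) >= mat$length), logical(1L))
      expect_true(all(sc$ri[away] < truth$natural_ri_min))
    }
  }
})

test_that("cryptic sites land within tolerance of their target strength", {
  truth <- truth_model(seed = 17L)
  mats <- truth_matrices(truth, n = 1000L)
  specs <- data.frame(site_kind = c("donor", "acceptor"),
                      junction_index = c(1L, 1L),
                      offset = c(-30L, 60L), target_ri = c(5, 7))
  locus <- build_locus(truth, mats, cryptic_specs = specs, tol = 0.5)
  cr <- locus$manifest[locus$manifest$origin == "cryptic", ]
  expect_identical(nrow(cr), 2L)
  expect_true(all(abs(cr$ri - cr$target_ri) <= 0.5 + 1e-9))
})

test_that("reverse-complementing the locus preserves every planted score", {
  fix <- synthetic_fixture()
  rc <- reverse_complement_locus(fix$locus)
  for (i in seq_len(nrow(rc$manifest))) {
    mat <- fix$mats[[rc$manifest$site_kind[i]]]
    w <- splicewise:::.site_window(rc$genome[[1L]],
                                   rc$manifest$junction[i], "-", mat)
    expect_equal(score_site(mat, w), fix$locus$manifest$ri[i],
                 tolerance = 1e-12)
  }
})

test_that("plant_variant picks the closest substitution and round-trips", {
  fix <- synthetic_fixture()
  don_row <- which(fix$locus$manifest$site_kind == "donor")[1L]
  mat <- fix$mats$donor
  # target 0: the minimal-|delta| substitution, against a brute-force
  # enumeration oracle
  pv0 <- plant_variant(fix$locus, fix$mats, don_row, target_delta = 0)
  w <- strsplit(.sub_window(fix$locus, don_row, mat), "")[[1L]]
  all_d <- unlist(lapply(seq_along(w), function(l)
    vapply(setdiff(c("A", "C", "G", "T"), w[l]), function(alt)
      unname(mat$weights[alt, l] - mat$weights[w[l], l]), numeric(1L))))
  all_d <- all_d[is.finite(all_d)]
  expect_equal(abs(pv0$expected_delta), min(abs(all_d)), tolerance = 1e-12)
  # round-trip: evaluate_variant reproduces the recorded delta exactly
  eff <- evaluate_variant(pv0$variant, fix$locus$model, fix$locus$genome,
                          fix$mats)
  nat <- eff[eff$origin == "natural" & eff$site_kind == "donor", ]
  expect_equal(nat$delta_ri, pv0$expected_delta, tolerance = 1e-12)
  # an unreachable target errors
  expect_error(plant_variant(fix$locus, fix$mats, don_row,
                             target_delta = -40), "within 1 bit")
})

test_that("a crushing delta on a strong site classifies as inactivating downstream", {
  fix <- synthetic_fixture()
  strong <- which.max(fix$locus$manifest$ri)
  pv <- plant_variant(fix$locus, fix$mats, strong, target_delta = -11,
                      max_miss = 2)
  eff <- evaluate_variant(pv$variant, fix$locus$model, fix$locus$genome,
                          fix$mats)
  nat <- eff[eff$origin == "natural" &
               eff$junction_position == fix$locus$manifest$junction[strong], ]
  expect_identical(nat$classification, "inactivating")
  expect_lt(nat$ri_final, 1.6)
})

test_that("cohort simulation is reproducible with ordered dose effects", {
  truth <- truth_model(seed = 8L)
  c1 <- simulate_cohort(truth, 60L, seed = 500L)
  c2 <- simulate_cohort(truth, 60L, seed = 500L)
  expect_identical(c1$intensities, c2$intensities)
  expect_identical(c1$genotypes, c2$genotypes)
  # s = 0.6, n = 60: group means ordered common > het > rare in almost
  # every seed (allow one exception in twenty)
  ordered <- vapply(1:20, function(s) {
    cs <- simulate_cohort(truth, 60L, seed = 600L + s)
    m <- tapply(cs$intensities["ps_affected", ], cs$genotypes, mean)
    all(c("hom_common", "het", "hom_rare") %in% names(m)) &&
      m[["hom_common"]] > m[["het"]] && m[["het"]] > m[["hom_rare"]]
  }, logical(1L))
  expect_gte(mean(ordered), 0.95)
})

test_that("a null cohort (s = 1) keeps the stepwise flag near its false-positive rate", {
  truth <- truth_model(si_effect = 1, seed = 9L)
  flags <- vapply(1:40, function(s) {
    cs <- simulate_cohort(truth, 60L, seed = 700L + s)
    cohort <- suppressMessages(splicing_index(cs$intensities, cs$gene_map))
    gm <- si_group_means(cohort, "ps_affected", cs$genotypes)
    if (any(is.na(gm$means))) return(NA)
    stepwise_filter(gm$means)$flag
  }, logical(1L))
  expect_lte(mean(flags, na.rm = TRUE), 0.10)
})

test_that("qPCR simulation recovers planted genotype ratios and censors zeros", {
  # the stated world for this recovery property is Ct noise sd = 0.2
  # alone; per-sample expression variation is switched off here (it is a
  # separate generator feature, cancelled only by the internal reference)
  truth <- truth_model(ct_sd = 0.2, expr_sd = 0, seed = 10L)
  geno <- stats::setNames(rep(c("hom_common", "hom_rare"), each = 3L),
                          sprintf("q%d", 1:6))
  ct <- simulate_qpcr(truth, geno, seed = 801L)
  planted <- truth$isoform_props$hom_rare[["skip"]] /
    truth$isoform_props$hom_common[["skip"]]
  got <- relative_ratio(ct, "skip", "external_ref",
                        "hom_common", "hom_rare")
  expect_lt(abs(got - planted) / planted, 0.20)
  # zero proportion: censored at the max cycle
  truth0 <- truth_model(isoform_props = list(
    hom_common = c(wildtype = 1, skip = 0, cryptic = 0, retention = 0),
    het = c(wildtype = 1, skip = 0, cryptic = 0, retention = 0),
    hom_rare = c(wildtype = 1, skip = 0, cryptic = 0, retention = 0)),
    seed = 10L)
  ct0 <- simulate_qpcr(truth0, geno[1L], seed = 802L)
  expect_true(all(ct0$ct[ct0$assay == "skip"] == truth0$max_ct))
})

test_that("junction-read simulation respects degenerate and scaled proportions", {
  fix <- synthetic_fixture()
  ex <- fix$locus$model$transcripts$t1
  p0 <- ex$end[2L] - 2L
  ref <- substr(fix$locus$genome[[1L]], p0 + 1L, p0 + 1L)
  v <- variant(fix$locus$contig, p0 + 1L, ref,
               setdiff(c("A", "C", "G", "T"), ref)[1L])
  pure <- c(wildtype = 1, skip = 0, cryptic = 0, retention = 0)
  sim <- simulate_junction_reads(fix$locus, v, "hom_common", depth = 50L,
                                 props = pure, seed = 11L)
  expect_identical(unname(sim$drawn["wildtype"]), 50L)
  expect_true(all(sim$records$true_category == "wildtype"))
  # depth scaling preserves proportions within binomial error
  props <- fix$truth$isoform_props$het
  for (depth in c(200L, 2000L)) {
    sim_d <- simulate_junction_reads(fix$locus, v, "het", depth = depth,
                                     seed = 12L)
    frac <- sim_d$drawn / depth
    for (k in names(props))
      expect_lt(abs(frac[[k]] - props[[k]]),
                4 * sqrt(props[[k]] * (1 - props[[k]]) / depth) + 1e-9)
  }
})

test_that("the full pipeline recovers every planted parameter under one master seed", {
  truth <- truth_model(seed = 42L)
  mats <- truth_matrices(truth, n = 1500L)
  locus <- build_locus(truth, mats)
  ex <- locus$model$transcripts$t1
  don2 <- which(locus$manifest$site_kind == "donor" &
                  locus$manifest$junction == ex$end[2L])
  pv <- plant_variant(locus, mats, don2, target_delta = -3)

  # stage 1: information analysis reproduces the planted delta exactly
  eff <- evaluate_variant(pv$variant, locus$model, locus$genome, mats)
  nat <- eff[eff$origin == "natural", ]
  expect_equal(nat$delta_ri, pv$expected_delta, tolerance = 1e-12)

  # stage 2: microarray screen flags the affected probeset
  cohort_sim <- simulate_cohort(truth, 90L)
  cohort <- suppressMessages(
    splicing_index(cohort_sim$intensities, cohort_sim$gene_map))
  gm <- si_group_means(cohort, "ps_affected", cohort_sim$genotypes)
  expect_true(stepwise_filter(gm$means)$flag)
  gm_null <- si_group_means(cohort, "ps_u1", cohort_sim$genotypes)
  expect_false(stepwise_filter(gm_null$means)$flag)

  # stage 3: qPCR recovers the genotype expression ratio
  geno <- stats::setNames(rep(c("hom_common", "hom_rare"), each = 3L),
                          sprintf("s%d", 1:6))
  ct <- simulate_qpcr(truth, geno)
  planted_ratio <- truth$isoform_props$hom_rare[["skip"]] /
    truth$isoform_props$hom_common[["skip"]]
  got_ratio <- relative_ratio(ct, "skip", "external_ref",
                              "hom_common", "hom_rare")
  expect_lt(abs(got_ratio - planted_ratio) / planted_ratio, 0.25)

  # stage 4: junction evidence recovers the drawn counts exactly
  sim <- simulate_junction_reads(locus, pv$variant, "hom_rare",
                                 depth = 200L)
  jc <- classify_alignments(sim$records, locus$model, pv$variant,
                            affected_exon = 2L)
  expect_identical(
    c(jc$wildtype_junction, jc$skip_junction, sum(jc$cryptic_junction),
      jc$intron_retention),
    unname(sim$drawn[c("wildtype", "skip", "cryptic", "retention")]))
})
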