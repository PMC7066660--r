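# Shared fixtures, built in code.  Heavier objects (trained matrices, a
# planted locus) are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

# small donor alignment with known composition (5 sites, window -3..+5)
tiny_donor_alignment <- function() {
  training_alignment(
    c("CAGGTAAGT",
      "AAGGTGAGT",
      "CTGGTAAGG",
      "CAGGTAAGA",
      "GAGGTAAGT"),
    "donor", -3L)
}

# a random alignment over a fixed seed, any geometry
random_alignment <- function(n = 30L, L = 7L, seed = 42L,
                             site_kind = "donor") {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1L))
  })
  training_alignment(seqs, site_kind, -3L)
}

# trained matrices + locus + planted variant under one master seed
synthetic_fixture <- function(seed = 7L) {
  key <- paste0("fix", seed)
  if (is.null(.fixture_cache[[key]])) {
    truth <- truth_model(seed = seed)
    mats <- truth_matrices(truth, n = 1000L)
    locus <- build_locus(truth, mats)
    .fixture_cache[[key]] <- list(truth = truth, mats = mats, locus = locus)
  }
  .fixture_cache[[key]]
}

# window of a manifest site (plus strand) and a planted variant's alt
# base in window sense
.sub_window <- function(locus, row, mat) {
  j <- locus$manifest$junction[row]
  s0 <- j + mat$window_start
  substr(locus$genome[[1L]], s0 + 1L, s0 + mat$length)
}
.alt_sense <- function(pv, locus) {
  if (pv$site$strand == "+") pv$variant$alt else revcomp(pv$variant$alt)
}

# brute-force R_i: per-column lookup summed by hand, independent of
# score_site's vectorized path
brute_force_ri <- function(mat, window) {
  ch <- strsplit(window, "", fixed = TRUE)[[1L]]
  tot <- 0
  for (l in seq_along(ch)) tot <- tot + mat$weights[ch[l], l]
  unname(tot)
}
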