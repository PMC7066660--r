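# Synthetic-data generator: every input the pipeline consumes, with the
# statistical structure the analysis assumes — a ground-truth base
# frequency model for splice sites, loci with planted natural and cryptic
# sites, variants of chosen delta R_i, a genotyped cohort with
# dose-dependent probeset intensities, genotype-dependent isoform Ct
# values, and multinomial junction reads.
#
# One master seed fans out to per-stage child seeds (see .child_seed) so
# each stage is independently reproducible.

# deterministic per-stage child seeds, kept below 2^31 - 1
.child_seed <- function(seed, stage) {
  stages <- c(training = 1L, locus = 2L, variant = 3L, cohort = 4L,
              qpcr = 5L, reads = 6L, scan = 7L)
  if (!stage %in% names(stages)) stop("unknown stage '", stage, "'")
  as.integer((as.numeric(seed) * 131L + stages[[stage]] * 1000003) %%
               2147483647)
}

.default_donor_freqs <- function() {
  # offsets -3..+5 around the exon|intron junction (junction = +0, the
  # first intronic base); consensus (C/A)AG | GT(A/G)AGT
  m <- cbind(
    c(.33, .37, .18, .12),   # -3
    c(.60, .13, .12, .15),   # -2
    c(.08, .03, .81, .08),   # -1
    c(.001, .001, .997, .001), # +0 G
    c(.001, .012, .001, .986), # +1 T
    c(.60, .03, .34, .03),   # +2
    c(.70, .08, .12, .10),   # +3
    c(.07, .06, .81, .06),   # +4
    c(.16, .17, .21, .46))   # +5
  rownames(m) <- BASES
  m
}

.default_acceptor_freqs <- function() {
  # offsets -25..+2 around the intron|exon junction (junction = +0, the
  # first exonic base); polypyrimidine tract then the invariant AG
  poly <- c(.09, .31, .10, .50)
  m <- matrix(rep(poly, 21L), nrow = 4L)        # -25..-5
  m <- cbind(m,
             c(.24, .30, .21, .25),             # -4
             c(.04, .65, .01, .30),             # -3
             c(.997, .001, .001, .001),         # -2 A
             c(.001, .001, .997, .001),         # -1 G
             c(.25, .14, .50, .11),             # +0
             c(.26, .18, .23, .33),             # +1
             c(.22, .26, .26, .26))             # +2
  rownames(m) <- BASES
  m
}

#' Ground-truth model for the synthetic pipeline
#'
#' Bundles every generator parameter: per-position splice-site base
#' frequencies, locus geometry, planted-site and variant specifications,
#' the allele-dose splicing-index effect, genotype frequencies (HWE),
#' isoform proportions per genotype, qPCR noise and sequencing depth.
#'
#' @param donor_freqs,acceptor_freqs 4 x L frequency matrices (rows
#'   A/C/G/T, columns summing to 1).
#' @param donor_window_start,acceptor_window_start window offsets.
#' @param exon_length_range,intron_length_range nt ranges (sampled
#'   uniformly).
#' @param n_exons exons per synthetic transcript (default 3).
#' @param natural_ri_min minimum individual information of planted natural
#'   sites, bits (default 8: a clearly functional site).
#' @param maf minor allele frequency for the simulated cohort (0 < maf <
#'   0.5; default 0.3 so all three genotype groups are populated at modest
#'   n).
#' @param si_effect multiplicative intensity effect per rare allele dose,
#'   `s` (default 0.6: a clearly stepwise decrease).
#' @param si_sigma lognormal intensity noise sd (default 0.1).
#' @param si_base baseline probeset intensity (default 100).
#' @param isoform_props per-genotype isoform proportions (each summing to
#'   1) over `wildtype`, `skip`, `cryptic`, `retention`.
#' @param ct_sd Ct replicate noise sd in cycles (default 0.2).
#' @param expr_sd per-sample lognormal expression variation applied to all
#'   within-gene assays (default 0.1).
#' @param ct_ref_base baseline Ct of reference assays (default 20 cycles).
#' @param max_ct censoring limit for undetectable products (default 40).
#' @param efficiency amplification efficiency (default 2).
#' @param depth junction-read sequencing depth (default 200).
#' @param seed master seed.
#' @return object of class `truth_model`.
#' @export
truth_model <- function(donor_freqs = .default_donor_freqs(),
                        acceptor_freqs = .default_acceptor_freqs(),
                        donor_window_start = -3L,
                        acceptor_window_start = -25L,
                        exon_length_range = c(80L, 200L),
                        intron_length_range = c(600L, 1200L),
                        n_exons = 3L,
                        natural_ri_min = 8,
                        maf = 0.3,
                        si_effect = 0.6,
                        si_sigma = 0.1,
                        si_base = 100,
                        isoform_props = list(
                          hom_common = c(wildtype = 0.94, skip = 0.02,
                                         cryptic = 0.02, retention = 0.02),
                          het        = c(wildtype = 0.70, skip = 0.10,
                                         cryptic = 0.08, retention = 0.12),
                          hom_rare   = c(wildtype = 0.40, skip = 0.20,
                                         cryptic = 0.15, retention = 0.25)),
                        ct_sd = 0.2,
                        expr_sd = 0.1,
                        ct_ref_base = 20,
                        max_ct = 40,
                        efficiency = 2,
                        depth = 200L,
                        seed = 1L) {
  for (m in list(donor_freqs, acceptor_freqs)) {
    stopifnot(nrow(m) == 4L, all(m >= 0))
    if (any(abs(colSums(m) - 1) > 1e-6))
      stop("frequency columns must sum to 1")
  }
  stopifnot(maf > 0, maf < 0.5)
  for (p in isoform_props) {
    stopifnot(abs(sum(p) - 1) < 1e-6, all(p >= 0))
  }
  structure(list(
    donor_freqs = donor_freqs, acceptor_freqs = acceptor_freqs,
    donor_window_start = as.integer(donor_window_start),
    acceptor_window_start = as.integer(acceptor_window_start),
    exon_length_range = exon_length_range,
    intron_length_range = intron_length_range,
    n_exons = as.integer(n_exons), natural_ri_min = natural_ri_min,
    maf = maf, si_effect = si_effect, si_sigma = si_sigma,
    si_base = si_base, isoform_props = isoform_props, ct_sd = ct_sd,
    expr_sd = expr_sd, ct_ref_base = ct_ref_base, max_ct = max_ct,
    efficiency = efficiency, depth = as.integer(depth),
    seed = as.integer(seed)), class = "truth_model")
}

#' Sample training splice sites from the ground-truth frequency model
#'
#' Independent per-column draws from `f*(b, l)`, reproducible under the
#' seed.
#'
#' @param truth a [truth_model()].
#' @param n number of sites.
#' @param site_kind `"donor"` or `"acceptor"`.
#' @param seed integer seed (default: child of the master seed).
#' @return a [training_alignment()].
#' @export
sample_training_sites <- function(truth, n,
                                  site_kind = c("donor", "acceptor"),
                                  seed = .child_seed(truth$seed, "training")) {
  site_kind <- match.arg(site_kind)
  stopifnot(n >= 1L)
  f <- if (site_kind == "donor") truth$donor_freqs else truth$acceptor_freqs
  ws <- if (site_kind == "donor") truth$donor_window_start
        else truth$acceptor_window_start
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  cols <- vapply(seq_len(ncol(f)), function(l)
    sample(BASES, n, replace = TRUE, prob = f[, l]), character(n))
  seqs <- if (n == 1L) paste(cols, collapse = "")
          else apply(cols, 1L, paste, collapse = "")
  training_alignment(seqs, site_kind, ws)
}

#' Donor and acceptor matrices trained on synthetic sites
#'
#' Convenience wrapper: samples `n` training sites of each kind and builds
#' both matrices with the recommended analysis pseudocount.
#'
#' @param truth a [truth_model()].
#' @param n training-set size per matrix (default 2000).
#' @param pseudocount default 0.25.
#' @param seed integer seed.
#' @return list with `donor` and `acceptor` [info_matrix][build_weight_matrix()] objects.
#' @export
truth_matrices <- function(truth, n = 2000L, pseudocount = 0.25,
                           seed = .child_seed(truth$seed, "training")) {
  list(donor = build_weight_matrix(
         sample_training_sites(truth, n, "donor", seed), pseudocount),
       acceptor = build_weight_matrix(
         sample_training_sites(truth, n, "acceptor", seed + 1L),
         pseudocount))
}

# rejection-sample one window from f* until pred(ri) holds
.sample_window <- function(f, mat, pred, max_tries = 20000L) {
  for (i in seq_len(max_tries)) {
    w <- paste(vapply(seq_len(ncol(f)), function(l)
      sample(BASES, 1L, prob = f[, l]), character(1L)), collapse = "")
    ri <- score_site(mat, w)
    if (is.finite(ri) && pred(ri)) return(list(window = w, ri = ri))
  }
  stop("could not sample a window satisfying the target after ",
       max_tries, " tries")
}

# overwrite sequence (plus strand) at a site window
.write_window <- function(seq, junction, mat, window) {
  s0 <- junction + mat$window_start
  substr(seq, s0 + 1L, s0 + mat$length) <- window
  seq
}

#' Build a synthetic locus with planted splice sites
#'
#' Generates a uniform-composition background sequence carrying a
#' multi-exon gene whose junctions are overwritten with strong sites
#' rejection-sampled from the truth frequencies (individual information at
#' least `truth$natural_ri_min`), plus optional cryptic sites at chosen
#' offsets whose scored strength lands within `tol` bits of a target.
#' After planting, background windows that rival the planted naturals
#' (score >= `background_max_ri`) are resampled, so planted sites are
#' guaranteed to be the strongest in the locus; weak sites (a few bits)
#' remain in the background, as in real sequence.
#'
#' @param truth a [truth_model()].
#' @param matrices list with `donor` and `acceptor` matrices used for
#'   scoring (see [truth_matrices()]).
#' @param cryptic_specs optional data.frame with columns `site_kind`,
#'   `junction_index` (which internal junction, in transcription order),
#'   `offset` (nt relative to that natural junction, transcription sense)
#'   and `target_ri` (bits).
#' @param tol acceptance half-width for cryptic targets (default 0.5
#'   bits).
#' @param background_max_ri resample background windows scoring at or
#'   above this (default `truth$natural_ri_min`).
#' @param contig contig name (default `"chrS"`).
#' @param flank nt of background outside the gene (default 400).
#' @param seed integer seed.
#' @return object of class `synthetic_locus`: `genome` (named character
#'   vector), `model` ([gene_model()]), `manifest` (data.frame of planted
#'   sites with achieved `ri`), `truth`, `contig`.
#' @export
build_locus <- function(truth, matrices, cryptic_specs = NULL, tol = 0.5,
                        background_max_ri = truth$natural_ri_min,
                        contig = "chrS", flank = 400L,
                        seed = .child_seed(truth$seed, "locus")) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  ex_len <- sample(truth$exon_length_range[1L]:truth$exon_length_range[2L],
                   truth$n_exons, replace = TRUE)
  in_len <- sample(truth$intron_length_range[1L]:
                     truth$intron_length_range[2L],
                   truth$n_exons - 1L, replace = TRUE)
  if (min(in_len) < 2L * max(matrices$donor$length,
                             matrices$acceptor$length))
    stop("introns shorter than the site windows")
  starts <- integer(truth$n_exons); ends <- integer(truth$n_exons)
  pos <- flank
  for (i in seq_len(truth$n_exons)) {
    starts[i] <- pos; ends[i] <- pos + ex_len[i]
    pos <- ends[i] + if (i < truth$n_exons) in_len[i] else flank
  }
  total <- pos
  seq <- paste(sample(BASES, total, replace = TRUE), collapse = "")
  model <- gene_model("synthGene", contig, "+",
                      list(t1 = data.frame(start = starts, end = ends)))
  jn <- .tx_junctions(model$transcripts$t1, "+")

  manifest <- list()
  for (i in seq_len(nrow(jn))) {
    mat <- matrices[[jn$site_kind[i]]]
    f <- if (jn$site_kind[i] == "donor") truth$donor_freqs
         else truth$acceptor_freqs
    got <- .sample_window(f, mat, function(ri) ri >= truth$natural_ri_min)
    seq <- .write_window(seq, jn$junction[i], mat, got$window)
    manifest[[length(manifest) + 1L]] <- data.frame(
      site_kind = jn$site_kind[i], junction = jn$junction[i], strand = "+",
      origin = "natural", target_ri = truth$natural_ri_min, ri = NA_real_,
      junction_index = NA_integer_, stringsAsFactors = FALSE)
  }
  # internal junction k (transcription order) -> donor of exon k is
  # junction ends[k]; acceptor of exon k+1 is starts[k+1]
  if (!is.null(cryptic_specs)) {
    for (r in seq_len(nrow(cryptic_specs))) {
      sk <- cryptic_specs$site_kind[r]
      ji <- cryptic_specs$junction_index[r]
      target <- cryptic_specs$target_ri[r]
      anchor <- if (sk == "donor") ends[ji] else starts[ji + 1L]
      cj <- anchor + cryptic_specs$offset[r]
      mat <- matrices[[sk]]
      f <- if (sk == "donor") truth$donor_freqs else truth$acceptor_freqs
      got <- .sample_window(f, mat,
                            function(ri) abs(ri - target) <= tol)
      seq <- .write_window(seq, cj, mat, got$window)
      manifest[[length(manifest) + 1L]] <- data.frame(
        site_kind = sk, junction = cj, strand = "+", origin = "cryptic",
        target_ri = target, ri = NA_real_, junction_index = ji,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)

  # background cleanup: resample windows rivaling the planted naturals
  planted_pos <- unlist(lapply(seq_len(nrow(manifest)), function(i) {
    mat <- matrices[[manifest$site_kind[i]]]
    .site_window_positions(manifest$junction[i], "+", mat)
  }))
  converged <- FALSE
  for (round in 1:50) {
    offender <- NULL
    for (kind in c("donor", "acceptor")) {
      mat <- matrices[[kind]]
      sc <- scan_sequence(mat, seq, "forward", contig)
      # windows sharing positions with a planted site are not background:
      # shifted copies of a strong planted site (e.g. tandem acceptor AGs)
      # are realistic and are left alone
      pj <- manifest$junction[manifest$site_kind == kind]
      overlaps_planted <- vapply(sc$junction_position, function(j)
        any(abs(j - pj) < mat$length), logical(1L))
      bad <- sc[!overlaps_planted & sc$ri >= background_max_ri, ,
                drop = FALSE]
      if (nrow(bad)) { offender <- list(mat = mat, jp = bad$junction_position[1L]); break }
    }
    if (is.null(offender)) { converged <- TRUE; break }
    # rewrite the offending window with fresh background, keeping any
    # positions that belong to planted sites untouched
    posn <- .site_window_positions(offender$jp, "+", offender$mat)
    for (p in setdiff(posn, planted_pos))
      substr(seq, p + 1L, p + 1L) <- sample(BASES, 1L)
  }
  if (!converged)
    warning("background cleanup did not converge; a non-planted site may ",
            "score above ", background_max_ri, " bits")

  # rescore planted sites as they stand (overlaps may perturb them)
  for (i in seq_len(nrow(manifest))) {
    mat <- matrices[[manifest$site_kind[i]]]
    manifest$ri[i] <- score_site(
      mat, .site_window(seq, manifest$junction[i], "+", mat))
  }
  genome <- stats::setNames(seq, contig)
  structure(list(genome = genome, model = model, manifest = manifest,
                 truth = truth, contig = contig),
            class = "synthetic_locus")
}

#' Reverse-complement an entire synthetic locus
#'
#' Mirrors the locus onto the minus strand: the sequence is
#' reverse-complemented and all junction coordinates and the gene model
#' are mapped accordingly.  Site scores are invariant under this
#' operation.
#'
#' @param locus a [build_locus()] result.
#' @return a new `synthetic_locus` on the minus strand.
#' @export
reverse_complement_locus <- function(locus) {
  n <- nchar(locus$genome[[1L]])
  seq_rc <- revcomp(locus$genome[[1L]])
  ex <- locus$model$transcripts[[1L]]
  ex_rc <- data.frame(start = n - rev(ex$end), end = n - rev(ex$start))
  model <- gene_model(locus$model$gene_id, locus$contig, "-",
                      stats::setNames(list(ex_rc),
                                      names(locus$model$transcripts)[1L]))
  manifest <- locus$manifest
  manifest$junction <- n - 1L - manifest$junction
  manifest$strand <- "-"
  structure(list(genome = stats::setNames(seq_rc, locus$contig),
                 model = model, manifest = manifest, truth = locus$truth,
                 contig = locus$contig),
            class = "synthetic_locus")
}

#' Plant a variant with a chosen information effect
#'
#' Enumerates every single-base substitution inside the chosen site's
#' window, computes each one's exact delta R_i from the weight matrix
#' (one-column difference) and picks the substitution closest to
#' `target_delta`.
#'
#' @param locus a [build_locus()] result.
#' @param matrices the matrices the locus was built with.
#' @param site row index into `locus$manifest`.
#' @param target_delta desired delta R_i in bits.
#' @param max_miss error if the best substitution misses the target by
#'   more than this (default 1 bit).
#' @return list with `variant` (a [variant()]), `expected_delta` (exact,
#'   from the matrix), `site` (the manifest row), `column` (window
#'   position substituted).
#' @export
plant_variant <- function(locus, matrices, site, target_delta,
                          max_miss = 1) {
  stopifnot(inherits(locus, "synthetic_locus"),
            site >= 1L, site <= nrow(locus$manifest))
  row <- locus$manifest[site, ]
  mat <- matrices[[row$site_kind]]
  seq <- locus$genome[[1L]]
  posn <- .site_window_positions(row$junction, row$strand, mat)
  window <- .site_window(seq, row$junction, row$strand, mat)
  wchars <- strsplit(window, "", fixed = TRUE)[[1L]]
  best <- NULL
  for (l in seq_len(mat$length)) {
    cur <- wchars[l]
    for (alt in setdiff(BASES, cur)) {
      d <- unname(mat$weights[alt, l] - mat$weights[cur, l])
      if (!is.finite(d)) next
      if (is.null(best) || abs(d - target_delta) < abs(best$d - target_delta))
        best <- list(l = l, alt = alt, d = d)
    }
  }
  if (is.null(best) || abs(best$d - target_delta) > max_miss)
    stop("no substitution within ", max_miss, " bit of target ",
         target_delta)
  gpos <- posn[best$l]                       # 0-based genomic
  ref_g <- .sub0(seq, gpos, gpos + 1L)       # genomic-strand bases
  alt_g <- if (row$strand == "+") best$alt else revcomp(best$alt)
  list(variant = variant(locus$contig, gpos + 1L, ref_g, alt_g,
                         rsid = paste0("rsSYN", site), het = 0.42),
       expected_delta = best$d, site = row, column = best$l)
}

#' Simulate a genotyped expression cohort
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium at the stated
#' minor allele frequency (dose ~ Binomial(2, maf)).  The affected
#' probeset's intensity is `si_base * si_effect^dose * exp(N(0, si_sigma))`;
#' unaffected probesets are dose-independent.  Gene-level intensity is the
#' mean over the gene's probesets.
#'
#' @param truth a [truth_model()].
#' @param n_samples cohort size (>= 3).
#' @param n_unaffected unaffected probesets per gene (default 3).
#' @param seed integer seed.
#' @return list with `genotypes` (named character), `doses`,
#'   `intensities` (probeset x sample matrix), `probesets`
#'   (a [probeset_table()]), `gene_map`, `affected_probeset`.
#' @export
simulate_cohort <- function(truth, n_samples,
                            n_unaffected = 3L,
                            seed = .child_seed(truth$seed, "cohort")) {
  stopifnot(n_samples >= 3L)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n_samples))
  doses <- stats::rbinom(n_samples, 2L, truth$maf)
  genotypes <- stats::setNames(
    c("hom_common", "het", "hom_rare")[doses + 1L], samples)
  ids <- c("ps_affected", sprintf("ps_u%d", seq_len(n_unaffected)))
  inten <- matrix(NA_real_, nrow = length(ids), ncol = n_samples,
                  dimnames = list(ids, samples))
  inten["ps_affected", ] <- truth$si_base * truth$si_effect^doses *
    exp(stats::rnorm(n_samples, 0, truth$si_sigma))
  for (i in seq_len(n_unaffected))
    inten[i + 1L, ] <- truth$si_base *
      exp(stats::rnorm(n_samples, 0, truth$si_sigma))
  width <- 80L
  probesets <- probeset_table(data.frame(
    probeset_id = ids, gene_id = "synthGene", contig = "chrS",
    start = 1000L + (seq_along(ids) - 1L) * 200L,
    end = 1000L + (seq_along(ids) - 1L) * 200L + width,
    strand = "+", stringsAsFactors = FALSE))
  list(genotypes = genotypes, doses = doses, intensities = inten,
       probesets = probesets,
       gene_map = stats::setNames(rep("synthGene", length(ids)), ids),
       affected_probeset = "ps_affected")
}

#' Simulate genotype-dependent qPCR Ct tables
#'
#' For each sample, each isoform assay's Ct is
#' `ct_ref_base - log_E(proportion * expression) + N(0, ct_sd)` in
#' triplicate, where the isoform proportion depends on the sample's
#' genotype and `expression` is a per-sample lognormal factor shared by
#' all within-gene assays.  Reference assays are dose-independent; the
#' external reference is also free of the per-sample expression factor.
#' A zero proportion censors the Ct at `max_ct`.
#'
#' @param truth a [truth_model()].
#' @param genotypes named character vector: sample -> genotype group.
#' @param replicates default 3 (run in triplicate).
#' @param seed integer seed.
#' @return a [ct_table()] with isoform assays (named after the isoform
#'   categories), `internal_ref` and `external_ref`.
#' @export
simulate_qpcr <- function(truth, genotypes, replicates = 3L,
                          seed = .child_seed(truth$seed, "qpcr")) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  E <- truth$efficiency
  rows <- list()
  for (s in names(genotypes)) {
    g <- genotypes[[s]]
    props <- truth$isoform_props[[g]]
    expr <- exp(stats::rnorm(1L, 0, truth$expr_sd))
    for (iso in names(props)) {
      # undetectable product: censored exactly at the max cycle
      cts <- if (props[[iso]] <= 0) rep(truth$max_ct, replicates)
             else pmin(truth$ct_ref_base -
                         log(props[[iso]] * expr, base = E) +
                         stats::rnorm(replicates, 0, truth$ct_sd),
                       truth$max_ct)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, group = g, assay = iso,
        replicate = seq_len(replicates), ct = cts,
        stringsAsFactors = FALSE)
    }
    for (ref in c("internal_ref", "external_ref")) {
      base <- if (ref == "internal_ref")
        truth$ct_ref_base - log(expr, base = E) else truth$ct_ref_base
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, group = g, assay = ref,
        replicate = seq_len(replicates),
        ct = base + stats::rnorm(replicates, 0, truth$ct_sd),
        stringsAsFactors = FALSE)
    }
  }
  ct_table(do.call(rbind, rows))
}

#' Simulate junction reads for one sample
#'
#' Draws `depth` reads from a multinomial over the genotype's isoform
#' proportions and gives each read the block structure of its category:
#' wildtype reads span the affected exon's donor junction, skip reads join
#' the flanking exons, cryptic reads splice from the planted cryptic site
#' (or a default exonic position) and retention reads run across the
#' donor boundary into the intron.  Reads covering the variant carry an
#' allele base consistent with their isoform: in heterozygotes, aberrant
#' isoforms derive from the alt allele (and wildtype reads from ref) with
#' probability `het_alt_bias`.
#'
#' @param locus a [build_locus()] result (plus strand).
#' @param v a [variant()] inside the affected exon (near its donor).
#' @param genotype `"hom_common"`, `"het"` or `"hom_rare"`.
#' @param depth number of reads (default `truth$depth`).
#' @param affected_exon default 2 (the middle exon).
#' @param read_flank nt of read anchored each side of a junction
#'   (default 40).
#' @param het_alt_bias probability an aberrant read in a heterozygote
#'   carries the alt allele (default 0.9).
#' @param props category proportions; default the genotype's entry in
#'   `truth$isoform_props`.
#' @param seed integer seed.
#' @return list with `records` (an [alignment_records()] table with a
#'   `true_category` column), `drawn` (the generating multinomial counts)
#'   and `cryptic_junction` (position used for cryptic reads).
#' @export
simulate_junction_reads <- function(locus, v, genotype,
                                    depth = locus$truth$depth,
                                    affected_exon = 2L, read_flank = 40L,
                                    het_alt_bias = 0.9, props = NULL,
                                    seed = .child_seed(locus$truth$seed,
                                                       "reads")) {
  stopifnot(inherits(locus, "synthetic_locus"), depth >= 1L)
  if (is.null(props)) props <- locus$truth$isoform_props[[genotype]]
  stopifnot(abs(sum(props) - 1) < 1e-6,
            all(c("wildtype", "skip", "cryptic", "retention") %in%
                  names(props)))
  ex <- locus$model$transcripts[[1L]]
  e <- affected_exon
  stopifnot(e > 1L, e < nrow(ex))
  f <- read_flank
  don <- ex$end[e]; acc_next <- ex$start[e + 1L]
  don_prev <- ex$end[e - 1L]
  cj <- locus$manifest$junction[locus$manifest$origin == "cryptic" &
                                  locus$manifest$site_kind == "donor"]
  cj <- if (length(cj)) cj[1L] else don - 24L   # default exonic cryptic
  blocks_for <- list(
    wildtype  = sprintf("%d-%d;%d-%d", don - f, don, acc_next,
                        acc_next + f),
    skip      = sprintf("%d-%d;%d-%d", don_prev - f, don_prev, acc_next,
                        acc_next + f),
    cryptic   = sprintf("%d-%d;%d-%d", cj - f, cj, acc_next, acc_next + f),
    retention = sprintf("%d-%d", don - f, don + f))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  drawn <- as.integer(stats::rmultinom(
    1L, depth, props[c("wildtype", "skip", "cryptic", "retention")]))
  names(drawn) <- c("wildtype", "skip", "cryptic", "retention")
  cat_vec <- rep(names(drawn), drawn)
  cat_vec <- sample(cat_vec)
  p0 <- v$pos - 1L
  base_for <- function(cat) {
    allele <- switch(genotype,
      hom_common = "ref",
      hom_rare = "alt",
      het = if (cat == "wildtype") {
        if (stats::runif(1L) < het_alt_bias) "ref" else "alt"
      } else {
        if (stats::runif(1L) < het_alt_bias) "alt" else "ref"
      })
    if (allele == "ref") v$ref else v$alt
  }
  blocks <- vapply(cat_vec, function(cat) blocks_for[[cat]], character(1L))
  covers <- vapply(blocks, function(b) {
    m <- .parse_blocks(b)
    any(p0 >= m[, "start"] & p0 < m[, "end"])
  }, logical(1L))
  bases <- rep(NA_character_, depth)
  for (i in which(covers)) bases[i] <- base_for(cat_vec[i])
  recs <- alignment_records(
    read_id = sprintf("r%05d", seq_len(depth)),
    contig = locus$contig, blocks = blocks, base_at_variant = bases)
  recs$true_category <- cat_vec
  list(records = recs, drawn = drawn, cryptic_junction = cj)
}
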