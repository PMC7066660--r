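# Relative expression from replicate quantification-cycle (Ct) tables.
#
# Expression is proportional to E^(-Ct) for amplification efficiency E
# (2.0 = perfect doubling).  Ratios between genotype groups are computed
# REST-style: the target assay's group Ct difference is normalized by the
# reference assay's, and significance comes from fixed-reallocation
# randomization of whole-sample group labels.

#' Validate a tidy Ct table
#'
#' @param df data.frame with columns `sample`, `group`, `assay`,
#'   `replicate`, `ct` (cycles, > 0).
#' @return validated data.frame (class `ct_table`).
#' @export
ct_table <- function(df) {
  need <- c("sample", "group", "assay", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$ct)) || any(df$ct <= 0))
    stop("all Ct values must be finite and > 0")
  structure(as.data.frame(df), class = c("ct_table", "data.frame"))
}

# replicate-mean Ct per (sample, assay); carries group along
.sample_means <- function(ct, assay) {
  sub <- ct[ct$assay == assay, , drop = FALSE]
  if (!nrow(sub)) stop("assay '", assay, "' absent from Ct table")
  agg <- stats::aggregate(ct ~ sample + group, data = sub, FUN = mean)
  agg
}

.group_mean_ct <- function(sm, group) {
  v <- sm$ct[sm$group == group]
  if (!length(v)) stop("group '", group, "' absent for this assay")
  mean(v)
}

#' Reference-normalized expression ratio between two groups
#'
#' `ratio = E_target^(dCt_target) / E_ref^(dCt_ref)` with
#' `dCt = mean Ct(group_a) - mean Ct(group_b)` per assay (replicates are
#' averaged within samples first).  Because expression falls as Ct rises,
#' a ratio > 1 means the reference-normalized target is *higher in
#' group_b*.  With both efficiencies 2 this is the classic `2^-ddCt`
#' quantity (with `ddCt = dCt_ref - dCt_target` oriented the same way).
#'
#' @param ct a [ct_table()].
#' @param target_assay,ref_assay assay ids.
#' @param group_a,group_b group labels to compare.
#' @param efficiency named or unnamed numeric of length 1 or 2: per-assay
#'   amplification efficiencies (target, ref); default 2.
#' @return numeric ratio (> 0).
#' @export
relative_ratio <- function(ct, target_assay, ref_assay, group_a, group_b,
                           efficiency = 2) {
  eff <- rep_len(efficiency, 2L)
  if (any(eff <= 0)) stop("efficiencies must be positive")
  sm_t <- .sample_means(ct, target_assay)
  sm_r <- .sample_means(ct, ref_assay)
  dct_t <- .group_mean_ct(sm_t, group_a) - .group_mean_ct(sm_t, group_b)
  dct_r <- .group_mean_ct(sm_r, group_a) - .group_mean_ct(sm_r, group_b)
  eff[1L]^dct_t / eff[2L]^dct_r
}

#' Randomization test for a relative expression ratio
#'
#' Fixed-reallocation significance: group labels are permuted over whole
#' samples (a sample's target and reference Cts travel together), the
#' ratio is recomputed each iteration, and the two-sided empirical p is
#' `(1 + #{|log ratio_perm| >= |log ratio_obs|}) / (iterations + 1)`.
#'
#' @inheritParams relative_ratio
#' @param groups length-2 character vector of group labels.
#' @param iterations number of label permutations (default 2000).
#' @param seed integer seed; the test is fully reproducible.
#' @return object of class `expression_ratio`: `ratio`, `p_value`,
#'   `iterations`, `seed`, `groups`.
#' @export
randomization_test <- function(ct, target_assay, ref_assay, groups,
                               iterations = 2000L, seed = 1L,
                               efficiency = 2) {
  stopifnot(length(groups) == 2L)
  obs <- relative_ratio(ct, target_assay, ref_assay, groups[1L], groups[2L],
                        efficiency)
  sub <- ct[ct$group %in% groups, , drop = FALSE]
  samples <- unique(sub[, c("sample", "group")])
  if (nrow(samples) < 2L) stop("need at least 2 samples across both groups")
  if (min(table(factor(samples$group, levels = groups))) < 1L)
    stop("both groups must be present")
  if (all(table(factor(samples$group, levels = groups)) == 1L)) {
    warning("single-sample groups: randomization degenerate, p = 1")
    return(structure(list(ratio = obs, p_value = 1, iterations = 0L,
                          seed = seed, groups = groups),
                     class = "expression_ratio"))
  }
  labels <- samples$group
  perm_ratio <- function(lab) {
    map <- stats::setNames(lab, samples$sample)
    p <- sub
    p$group <- map[p$sample]
    relative_ratio(ct_table(p), target_assay, ref_assay,
                   groups[1L], groups[2L], efficiency)
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  hits <- 0L
  obs_l <- abs(log(obs))
  for (i in seq_len(iterations)) {
    rp <- perm_ratio(sample(labels))
    if (abs(log(rp)) >= obs_l - 1e-12) hits <- hits + 1L
  }
  structure(list(ratio = obs,
                 p_value = (1 + hits) / (iterations + 1),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed), groups = groups),
            class = "expression_ratio")
}

#' @export
print.expression_ratio <- function(x, ...) {
  cat(sprintf("expression ratio %s vs %s: %.3f (p = %.4g, %d iterations)\n",
              x$groups[1L], x$groups[2L], x$ratio, x$p_value, x$iterations))
  invisible(x)
}

#' Isoform abundance relative to an internal gene reference
#'
#' `percent = 100 * E^-(mean Ct_isoform - mean Ct_internal_ref)` within
#' one group.  Per-sample percents (replicate-mean Cts) provide the
#' spread; a single-sample group falls back to replicate-paired percents.
#' Raw values >= 100 are formatted as `"~100"` (the isoform is at least as
#' abundant as the reference), with the raw value retained.
#'
#' @param ct a [ct_table()].
#' @param isoform_assay,internal_ref_assay assay ids.
#' @param group group label.
#' @param efficiency amplification efficiency (default 2).
#' @return list with `percent` (group-level raw value), `per_sample`,
#'   `mean`, `sd`, `formatted` (Table-style `"x ± y"` string).
#' @export
isoform_relative_abundance <- function(ct, isoform_assay,
                                       internal_ref_assay, group,
                                       efficiency = 2) {
  sub <- ct[ct$group == group, , drop = FALSE]
  if (!nrow(sub)) stop("group '", group, "' absent")
  sm_i <- .sample_means(ct_table(sub), isoform_assay)
  sm_r <- .sample_means(ct_table(sub), internal_ref_assay)
  common <- intersect(sm_i$sample, sm_r$sample)
  if (!length(common)) stop("no sample measured for both assays")
  per_sample <- vapply(common, function(s)
    100 * efficiency^-(sm_i$ct[sm_i$sample == s] -
                         sm_r$ct[sm_r$sample == s]), numeric(1L))
  if (length(common) > 1L) {
    m <- mean(per_sample); s <- stats::sd(per_sample)
  } else {
    # single sample: pair replicates by index for a within-sample spread
    iso <- sub$ct[sub$assay == isoform_assay][order(
      sub$replicate[sub$assay == isoform_assay])]
    ref <- sub$ct[sub$assay == internal_ref_assay][order(
      sub$replicate[sub$assay == internal_ref_assay])]
    k <- min(length(iso), length(ref))
    reps <- 100 * efficiency^-(iso[seq_len(k)] - ref[seq_len(k)])
    m <- per_sample[[1L]]
    s <- if (k > 1L) stats::sd(reps) else 0
  }
  grp_ct_i <- mean(sm_i$ct); grp_ct_r <- mean(sm_r$ct)
  percent <- 100 * efficiency^-(grp_ct_i - grp_ct_r)
  formatted <- if (percent >= 100) "~100"
               else sprintf("%.1f ± %.1f", m, s)
  list(percent = percent, per_sample = per_sample, mean = m, sd = s,
       formatted = formatted)
}

# preserve the caller's RNG state around seeded internals
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
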