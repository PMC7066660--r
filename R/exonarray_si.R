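# Exon-microarray splicing indices and the genotype-stepwise screen.
#
# The splicing index SI of a probeset in a sample is its normalized
# intensity divided by the overall intensity of its gene, i.e. exon-level
# expression corrected for gene-level expression.  The screen looks for a
# dose-dependent ("stepwise") change of mean SI across the three genotype
# groups of a nearby SNP.

GENOTYPE_LEVELS <- c("hom_common", "het", "hom_rare", "missing")

#' Validate a probeset coordinate table
#'
#' @param df data.frame with columns `probeset_id`, `gene_id`, `contig`,
#'   `start`, `end` (0-based half-open) and `strand`.
#' @return the validated data.frame (class `probeset_table`).
#' @export
probeset_table <- function(df) {
  need <- c("probeset_id", "gene_id", "contig", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("probeset table needs columns: ", paste(need, collapse = ", "))
  if (any(df$start >= df$end)) stop("probeset with start >= end")
  if (anyDuplicated(df$probeset_id)) stop("duplicate probeset ids")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -")
  structure(df, class = c("probeset_table", "data.frame"))
}

#' Drop probesets whose probes overlap a SNP
#'
#' A probeset is removed when any SNP position falls inside its half-open
#' interval `[start, end)` — so a SNP exactly at `start` drops the
#' probeset and one at the `end` coordinate does not.
#'
#' @param probesets a [probeset_table()].
#' @param snp_positions data.frame with columns `contig` and `pos`
#'   (0-based positions).
#' @return filtered probeset table; the number removed is reported with a
#'   message and stored in attribute `n_removed`.
#' @export
remove_probes_overlapping_snps <- function(probesets, snp_positions) {
  stopifnot(all(c("contig", "pos") %in% names(snp_positions)))
  hit <- rep(FALSE, nrow(probesets))
  for (ctg in unique(probesets$contig)) {
    pk <- which(probesets$contig == ctg)
    sp <- snp_positions$pos[snp_positions$contig == ctg]
    if (!length(sp)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = sp + 1L, width = 1L),
      IRanges::IRanges(start = probesets$start[pk] + 1L,
                       end = probesets$end[pk]))
    hit[pk[unique(S4Vectors::subjectHits(ov))]] <- TRUE
  }
  message(sum(hit), " probeset(s) removed for SNP overlap")
  out <- probesets[!hit, , drop = FALSE]
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Link a SNP to its nearest like-stranded probeset
#'
#' Distance is the gap in nt between the SNP position and the probeset
#' interval (0 when the SNP lies inside it).  Only probesets on the SNP's
#' strand and contig are considered; ties are broken by the smaller start
#' coordinate.
#'
#' @param snp list or one-row data.frame with `contig`, `pos` (0-based)
#'   and `strand`.
#' @param probesets a [probeset_table()].
#' @param max_dist maximum gap in nt (default 500).
#' @return list with `probeset_id` (or `NA` if none within reach) and
#'   `distance`.
#' @export
link_snp_to_probeset <- function(snp, probesets, max_dist = 500L) {
  cand <- probesets[probesets$contig == snp$contig &
                      probesets$strand == snp$strand, , drop = FALSE]
  if (!nrow(cand)) return(list(probeset_id = NA_character_,
                               distance = NA_integer_))
  p <- snp$pos
  dist <- ifelse(p >= cand$start & p < cand$end, 0L,
                 ifelse(p < cand$start, cand$start - p,
                        p - cand$end + 1L))
  ok <- which(dist <= max_dist)
  if (!length(ok)) return(list(probeset_id = NA_character_,
                               distance = NA_integer_))
  ok <- ok[order(dist[ok], cand$start[ok])]
  list(probeset_id = cand$probeset_id[ok[1L]],
       distance = as.integer(dist[ok[1L]]))
}

#' Splicing index of every probeset in every sample
#'
#' `SI(p, s) = I(p, s) / I(gene(p), s)`.  When no gene-level summary is
#' supplied, gene intensity falls back to the mean of the gene's probesets
#' (reported loudly; proper gene-level summaries are the preferred input).
#' Samples with zero gene intensity are excluded for that gene, with a
#' warning.
#'
#' @param intensities probeset x sample matrix of non-negative normalized
#'   intensities (rownames are probeset ids).
#' @param gene_map named character vector: probeset id -> gene id.
#' @param gene_intensities optional gene x sample matrix (rownames gene
#'   ids, same sample columns).
#' @return object of class `si_cohort`: list with `si` (probeset x sample
#'   matrix), `gene_map`, `gene_intensity_source`.
#' @export
splicing_index <- function(intensities, gene_map, gene_intensities = NULL) {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)))
  if (any(intensities < 0)) stop("negative intensity")
  if (!all(rownames(intensities) %in% names(gene_map)))
    stop("every probeset needs a gene in gene_map")
  genes <- gene_map[rownames(intensities)]
  if (is.null(gene_intensities)) {
    message("no gene-level intensities supplied; ",
            "using the mean of each gene's probesets as gene intensity")
    gene_intensities <- do.call(rbind, lapply(
      split(seq_len(nrow(intensities)), genes),
      function(ix) colMeans(intensities[ix, , drop = FALSE])))
    src <- "probeset_mean"
  } else {
    stopifnot(is.matrix(gene_intensities))
    if (!all(unique(genes) %in% rownames(gene_intensities)))
      stop("gene_intensities lacks some genes")
    gene_intensities <-
      gene_intensities[, colnames(intensities), drop = FALSE]
    src <- "supplied"
  }
  denom <- gene_intensities[genes, , drop = FALSE]
  if (any(denom == 0)) {
    warning(sum(denom == 0),
            " probeset x sample cell(s) with zero gene intensity set to NA")
    denom[denom == 0] <- NA_real_
  }
  si <- intensities / denom
  dimnames(si) <- dimnames(intensities)
  structure(list(si = si, gene_map = gene_map,
                 gene_intensity_source = src),
            class = "si_cohort")
}

#' Per-genotype SI group means for one probeset and one SNP
#'
#' @param cohort an [si_cohort][splicing_index()].
#' @param probeset_id probeset to summarize.
#' @param genotypes named character vector: sample -> genotype, coded
#'   `hom_common` / `het` / `hom_rare` / `missing`.
#' @return list with `means` (named numeric, NA for empty groups) and
#'   `sizes` (named integer), over non-missing samples only.
#' @export
si_group_means <- function(cohort, probeset_id, genotypes) {
  stopifnot(inherits(cohort, "si_cohort"),
            probeset_id %in% rownames(cohort$si))
  if (!all(genotypes %in% GENOTYPE_LEVELS))
    stop("genotypes must be coded ", paste(GENOTYPE_LEVELS, collapse = "/"))
  samples <- intersect(colnames(cohort$si), names(genotypes))
  g <- genotypes[samples]
  si <- cohort$si[probeset_id, samples]
  grp <- c("hom_common", "het", "hom_rare")
  means <- vapply(grp, function(k) {
    v <- si[g == k & !is.na(si)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1L))
  sizes <- vapply(grp, function(k) sum(g == k & !is.na(si)), integer(1L))
  list(means = means, sizes = sizes)
}

#' Genotype-stepwise splicing-index filter
#'
#' Flags a probeset/SNP pair when mean SI changes stepwise with the
#' genotype dose: the heterozygote mean must lie strictly between the two
#' homozygote means, and both the heterozygote and rare-homozygote means
#' must be `< ratio_threshold` (default 90%) of the common-homozygote
#' mean.  The comparison is strict at the threshold.  When no rare
#' homozygotes exist, the reduced two-group test (het < 90% of common) is
#' applied and the result is labelled `partial`.  `direction = "increase"`
#' mirrors the criterion for probesets that gain signal (e.g. detection of
#' an intronic cryptic site).
#'
#' @param means named numeric with `hom_common`, `het`, `hom_rare` (NA for
#'   an absent group).
#' @param sizes optional named integer group sizes (same names).
#' @param ratio_threshold default 0.90.
#' @param min_group_n minimum samples per non-empty group (default 1; the
#'   screen is criterion-based, not a significance test).
#' @param direction `"decrease"` (the screen's form) or `"increase"`.
#' @return list with `flag`, `partial`, `reason`.
#' @export
stepwise_filter <- function(means, sizes = NULL, ratio_threshold = 0.90,
                            min_group_n = 1L,
                            direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  mc <- means[["hom_common"]]; mh <- means[["het"]]; mr <- means[["hom_rare"]]
  present <- !is.na(c(mc, mh, mr))
  if (sum(present) < 2L) stop("need at least two non-empty genotype groups")
  if (!is.null(sizes)) {
    small <- !is.na(c(mc, mh, mr)) & c(sizes[["hom_common"]], sizes[["het"]],
                                       sizes[["hom_rare"]]) < min_group_n
    if (any(small))
      return(list(flag = FALSE, partial = FALSE, reason = "group too small"))
  }
  if (direction == "increase") {
    # mirror: rescore on reciprocals so "decrease" logic applies
    mc <- 1 / mc; mh <- 1 / mh; mr <- if (is.na(mr)) NA else 1 / mr
  }
  if (is.na(mh) || is.na(mc))
    return(list(flag = FALSE, partial = FALSE,
                reason = "het or common group absent"))
  if (is.na(mr)) {
    flag <- mh < ratio_threshold * mc
    return(list(flag = flag, partial = TRUE,
                reason = "no rare homozygotes; two-group reduction"))
  }
  between <- mr < mh && mh < mc   # strict interior ordering
  step <- mh < ratio_threshold * mc && mr < ratio_threshold * mc
  list(flag = between && step, partial = FALSE,
       reason = if (between && step) "stepwise decrease"
                else if (!between) "het mean not between homozygote means"
                else "means above threshold ratio")
}

#' Tidy per-genotype SI vectors for boxplotting
#'
#' @param cohort an [si_cohort][splicing_index()].
#' @param probeset_id probeset linked to the SNP.
#' @param genotypes named character vector: sample -> genotype.
#' @return data.frame `genotype`, `sample`, `si`, missing genotypes
#'   excluded, ordered by genotype (common, het, rare) then sample.
#' @export
export_boxplot_data <- function(cohort, probeset_id, genotypes) {
  stopifnot(inherits(cohort, "si_cohort"))
  if (!probeset_id %in% rownames(cohort$si))
    stop("probeset ", probeset_id, " not in cohort (unlinked SNP?)")
  samples <- intersect(colnames(cohort$si), names(genotypes))
  g <- genotypes[samples]
  keep <- g %in% c("hom_common", "het", "hom_rare")
  out <- data.frame(genotype = factor(g[keep],
                                      levels = c("hom_common", "het",
                                                 "hom_rare")),
                    sample = samples[keep],
                    si = unname(cohort$si[probeset_id, samples[keep]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$genotype, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}
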