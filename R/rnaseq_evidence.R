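# Classification of spliced-read evidence around a variant-affected exon
# into wildtype junction use, exon skipping, cryptic junction use and
# intron retention, plus an empirical control-cohort significance test.
#
# Input is a simplified spliced-alignment table (one row per read: contig,
# aligned blocks, optionally the base observed at the variant).  An
# adapter from real alignment files only needs to emit the same columns.

EVIDENCE_CATEGORIES <- c("wildtype_junction", "skip_junction",
                         "cryptic_junction", "intron_retention")

#' Build a spliced-alignment record table
#'
#' @param read_id character read names.
#' @param contig contig per read.
#' @param blocks character, aligned blocks as `"start-end;start-end"`
#'   (0-based half-open, sorted); a single block means an unspliced read.
#' @param base_at_variant optional base observed at the variant position
#'   (NA when unknown).
#' @return data.frame of class `alignment_records`.
#' @export
alignment_records <- function(read_id, contig, blocks,
                              base_at_variant = NA_character_) {
  n <- length(read_id)
  df <- data.frame(read_id = read_id,
                   contig = rep_len(contig, n),
                   blocks = rep_len(blocks, n),
                   base_at_variant = rep_len(base_at_variant, n),
                   stringsAsFactors = FALSE)
  structure(df, class = c("alignment_records", "data.frame"))
}

.parse_blocks <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

.read_introns <- function(blocks) {
  if (nrow(blocks) < 2L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = blocks[-nrow(blocks), "end"], end = blocks[-1L, "start"])
}

#' Classify spliced reads around a variant-affected exon
#'
#' Each read is assigned to exactly one evidence category by its junction
#' structure at the affected exon: a junction joining the flanking exons
#' is `skip_junction`; any unannotated junction in the region is
#' `cryptic_junction` (keyed by its exact `start-end` coordinates); a
#' junction matching an annotated intron adjacent to the exon is
#' `wildtype_junction`; reads without junctions that run at least `k` nt
#' past an exon boundary into the flanking intron, or lie fully within a
#' flanking intron, are `intron_retention`.  Reads overlapping the exon
#' but fitting none of these (e.g. fully exonic) count only towards
#' `exon_reads`.
#'
#' @param records an [alignment_records()] table.
#' @param model a [gene_model()]; the first transcript is used unless
#'   `transcript` names another.
#' @param v optional [variant()]; used to pick the affected exon and to
#'   tally per-allele counts.
#' @param k intron-retention threshold: nt a read must extend past the
#'   junction (default 10).
#' @param affected_exon exon index; default: the exon nearest the variant
#'   (or the middle exon when no variant is given).
#' @param transcript transcript name.
#' @return object of class `junction_counts`: counts per category
#'   (`cryptic_junction` is a named vector keyed by junction), `exon_reads`,
#'   `other`, `n_classified`, `n_ignored`, `allele_counts` (category x
#'   allele matrix when a variant is supplied).
#' @export
classify_alignments <- function(records, model, v = NULL, k = 10L,
                                affected_exon = NULL, transcript = NULL) {
  stopifnot(is.data.frame(records), inherits(model, "gene_model"))
  tx <- if (is.null(transcript)) names(model$transcripts)[1L] else transcript
  ex <- model$transcripts[[tx]]
  n_ex <- nrow(ex)
  if (is.null(affected_exon)) {
    affected_exon <- if (!is.null(v)) {
      p0 <- v$pos - 1L
      d <- pmax(ex$start - p0, p0 - ex$end + 1L, 0L)
      which.min(d)
    } else (n_ex + 1L) %/% 2L
  }
  e <- affected_exon
  stopifnot(e >= 1L, e <= n_ex)
  annotated <- if (n_ex > 1L)
    paste(ex$end[-n_ex], ex$start[-1L], sep = "-") else character(0)
  wt_introns <- c(
    if (e > 1L) paste(ex$end[e - 1L], ex$start[e], sep = "-"),
    if (e < n_ex) paste(ex$end[e], ex$start[e + 1L], sep = "-"))
  skip_intron <- if (e > 1L && e < n_ex)
    paste(ex$end[e - 1L], ex$start[e + 1L], sep = "-") else NA_character_
  region_lo <- if (e > 1L) ex$start[e - 1L] else ex$start[e]
  region_hi <- if (e < n_ex) ex$end[e + 1L] else ex$end[e]
  flank_introns <- rbind(
    if (e > 1L) c(ex$end[e - 1L], ex$start[e]),
    if (e < n_ex) c(ex$end[e], ex$start[e + 1L]))

  on_contig <- records$contig == model$contig
  n_ignored <- sum(!on_contig)
  recs <- records[on_contig, , drop = FALSE]

  counts <- c(wildtype_junction = 0L, skip_junction = 0L,
              intron_retention = 0L)
  cryptic <- integer(0)
  other <- 0L
  exon_reads <- 0L
  category <- character(nrow(recs))
  p0 <- if (!is.null(v)) v$pos - 1L else NA_integer_

  for (i in seq_len(nrow(recs))) {
    b <- .parse_blocks(recs$blocks[i])
    if (any(b[, "start"] < b[, "end"]) &&
        any(b[, "end"] > ex$start[e] & b[, "start"] < ex$end[e]))
      exon_reads <- exon_reads + 1L
    introns <- .read_introns(b)
    rel <- introns[introns[, "end"] > region_lo &
                     introns[, "start"] < region_hi, , drop = FALSE]
    keys <- if (nrow(rel)) paste(rel[, "start"], rel[, "end"], sep = "-")
            else character(0)
    cat_i <- if (!is.na(skip_intron) && skip_intron %in% keys) {
      "skip_junction"
    } else if (length(keys) && any(!keys %in% annotated)) {
      key <- keys[!keys %in% annotated][1L]
      cryptic[key] <- if (key %in% names(cryptic)) cryptic[[key]] + 1L else 1L
      "cryptic_junction"
    } else if (any(keys %in% wt_introns)) {
      "wildtype_junction"
    } else if (!nrow(rel) && .is_retention(b, ex, e, n_ex, flank_introns, k)) {
      "intron_retention"
    } else {
      "other"
    }
    if (cat_i %in% names(counts)) counts[[cat_i]] <- counts[[cat_i]] + 1L
    if (cat_i == "other") other <- other + 1L
    category[i] <- cat_i
  }

  allele_counts <- NULL
  if (!is.null(v) && nrow(recs)) {
    allele <- vapply(seq_len(nrow(recs)), function(i) {
      b <- .parse_blocks(recs$blocks[i])
      covered <- any(p0 >= b[, "start"] & p0 < b[, "end"])
      base <- recs$base_at_variant[i]
      if (!covered || is.na(base) || !base %in% BASES) "unresolved"
      else if (base == v$ref) "ref"
      else if (base == v$alt) "alt"
      else "other_base"
    }, character(1L))
    allele_counts <- table(
      category = factor(category, levels = c(EVIDENCE_CATEGORIES, "other")),
      allele = factor(allele, levels = c("ref", "alt", "other_base",
                                         "unresolved")))
  }

  structure(list(
    locus_id = model$gene_id,
    wildtype_junction = counts[["wildtype_junction"]],
    skip_junction = counts[["skip_junction"]],
    cryptic_junction = cryptic,
    intron_retention = counts[["intron_retention"]],
    other = other,
    exon_reads = exon_reads,
    n_classified = nrow(recs),
    n_ignored = n_ignored,
    affected_exon = e,
    allele_counts = allele_counts),
    class = "junction_counts")
}

# no junction: retention when a block crosses an exon/intron boundary by
# >= k nt, or the read is fully inside a flanking intron
.is_retention <- function(b, ex, e, n_ex, flank_introns, k) {
  lo <- ex$start[e]; hi <- ex$end[e]
  crosses <- any(b[, "start"] < hi & b[, "end"] >= hi + k) ||
    any(b[, "end"] > lo & b[, "start"] <= lo - k)
  if (crosses) return(TRUE)
  if (is.null(flank_introns)) return(FALSE)
  for (r in seq_len(nrow(flank_introns))) {
    if (all(b[, "start"] >= flank_introns[r, 1L] &
              b[, "end"] <= flank_introns[r, 2L]))
      return(TRUE)
  }
  FALSE
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf(
    "junction counts at %s (exon %d): wildtype %d, skip %d, cryptic %d, retention %d; exon reads %d\n",
    x$locus_id, x$affected_exon, x$wildtype_junction, x$skip_junction,
    sum(x$cryptic_junction), x$intron_retention, x$exon_reads))
  invisible(x)
}

#' Expression gate for RNA-seq evidence
#'
#' The affected exon must carry at least `min_reads` reads (inclusive)
#' before junction evidence is interpreted.
#'
#' @param counts a [junction_counts][classify_alignments()] object.
#' @param min_reads default 5.
#' @return logical.
#' @export
expression_gate <- function(counts, min_reads = 5L) {
  stopifnot(inherits(counts, "junction_counts"))
  counts$exon_reads >= min_reads
}

# total count for one category from a junction_counts object
.category_count <- function(counts, category) {
  stopifnot(category %in% EVIDENCE_CATEGORIES)
  v <- counts[[category]]
  if (category == "cryptic_junction") sum(v) else v
}

#' Control distribution of normalized evidence counts
#'
#' @param controls list of [junction_counts][classify_alignments()]
#'   objects from control samples.
#' @return object of class `control_distribution`: matrix of per-category
#'   counts normalized by each control's `exon_reads` (controls with zero
#'   exon reads contribute 0).
#' @export
control_distribution <- function(controls) {
  stopifnot(length(controls) >= 1L)
  m <- t(vapply(controls, function(jc) {
    denom <- max(jc$exon_reads, 1L)
    vapply(EVIDENCE_CATEGORIES, function(cat)
      .category_count(jc, cat) / denom, numeric(1L))
  }, numeric(length(EVIDENCE_CATEGORIES))))
  colnames(m) <- EVIDENCE_CATEGORIES
  structure(list(normalized = m, n = length(controls)),
            class = "control_distribution")
}

#' Empirical significance of case evidence against controls
#'
#' One-sided empirical p-value on counts normalized by `exon_reads`:
#' `p = (1 + #{controls >= case}) / (N_controls + 1)`.  Cases failing the
#' expression gate get no p-value, with status
#' `"insufficient expression"`.
#'
#' @param case a [junction_counts][classify_alignments()] object.
#' @param controls a [control_distribution()].
#' @param category one of `wildtype_junction`, `skip_junction`,
#'   `cryptic_junction`, `intron_retention`.
#' @param min_reads expression gate threshold (default 5).
#' @return list with `p_value` (NA when gated), `status`,
#'   `case_normalized`, `n_controls`.
#' @export
evidence_significance <- function(case, controls, category,
                                  min_reads = 5L) {
  stopifnot(inherits(controls, "control_distribution"))
  if (!expression_gate(case, min_reads))
    return(list(p_value = NA_real_, status = "insufficient expression",
                case_normalized = NA_real_, n_controls = controls$n))
  case_norm <- .category_count(case, category) / case$exon_reads
  hits <- sum(controls$normalized[, category] >= case_norm)
  list(p_value = (1 + hits) / (controls$n + 1), status = "ok",
       case_normalized = case_norm, n_controls = controls$n)
}

#' Per-allele evidence counts at a variant
#'
#' Splits reads by the base observed at the variant position; reads not
#' covering the variant (or with an unreadable base) are `unresolved`.
#'
#' @param records an [alignment_records()] table.
#' @param v a [variant()].
#' @return named integer vector: `ref`, `alt`, `other_base`, `unresolved`.
#' @export
allele_assignment <- function(records, v) {
  p0 <- v$pos - 1L
  allele <- vapply(seq_len(nrow(records)), function(i) {
    b <- .parse_blocks(records$blocks[i])
    covered <- records$contig[i] == v$contig &&
      any(p0 >= b[, "start"] & p0 < b[, "end"])
    base <- records$base_at_variant[i]
    if (!covered || is.na(base) || !base %in% BASES) "unresolved"
    else if (base == v$ref) "ref"
    else if (base == v$alt) "alt"
    else "other_base"
  }, character(1L))
  tab <- table(factor(allele, levels = c("ref", "alt", "other_base",
                                         "unresolved")))
  stats::setNames(as.integer(tab), names(tab))
}
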