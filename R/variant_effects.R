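# Variant evaluation against gene models: delta R_i at natural sites,
# cryptic-site enumeration, effect classification and candidate filtering.
#
# Coordinates are 0-based half-open internally; VCF's 1-based positions are
# converted at the reader boundary only.  A junction coordinate is the
# first intronic base for donors and the first exonic base for acceptors,
# on the transcribed strand.

#' Gene model: transcripts as ordered exon lists
#'
#' @param gene_id gene identifier.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts named list; each element a data.frame with integer
#'   columns `start`, `end` (0-based half-open, genomic coordinates).
#'   Exons must be sorted by `start` and non-overlapping.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, transcripts) {
  stopifnot(strand %in% c("+", "-"), is.list(transcripts),
            length(transcripts) >= 1L)
  if (is.null(names(transcripts)))
    names(transcripts) <- paste0(gene_id, ".t", seq_along(transcripts))
  for (tx in names(transcripts)) {
    ex <- transcripts[[tx]]
    if (!all(c("start", "end") %in% names(ex)))
      stop("transcript ", tx, " lacks start/end columns")
    if (any(ex$start >= ex$end))
      stop("transcript ", tx, ": empty or inverted exon")
    if (is.unsorted(ex$start, strictly = TRUE) ||
        any(utils::head(ex$end, -1L) > utils::tail(ex$start, -1L)))
      stop("transcript ", tx, ": exons must be sorted and non-overlapping")
    transcripts[[tx]] <- ex[, c("start", "end")]
  }
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s, %s strand): %d transcript(s)\n",
              x$gene_id, x$contig, x$strand, length(x$transcripts)))
  invisible(x)
}

#' Thresholds controlling effect classification and candidate filtering
#'
#' @param ri_min minimum functional splice-site strength in bits; sites
#'   whose weakened strength stays at or above it are predicted to splice
#'   leakily (both normal and aberrant product).  Default 1.6.
#' @param delta_min smallest information change treated as an effect
#'   (bits).  Default 0.1.
#' @param sp_flag variant-screen flag threshold: natural-site
#'   `delta R_i < sp_flag` bits.  Default -1.0.
#' @param het_min minimum average heterozygosity for the common-variant
#'   screen.  Default 0.10.
#' @param cryptic_window nt searched each side of a natural junction for
#'   cryptic sites.  Default 300 (600 covers the most distant activation
#'   reported in validation work).
#' @param comparable_margin a cryptic site within this many bits of the
#'   neighbouring natural site is "comparable" (1 bit = twofold affinity).
#' @param pseudoexon_dist nt into the intron beyond which a cryptic site
#'   crossing `ri_min` is called a pseudo-exon candidate rather than an
#'   exon-extension event.  Default 200.
#' @return object of class `criteria_config`.
#' @export
criteria_config <- function(ri_min = 1.6, delta_min = 0.1, sp_flag = -1.0,
                            het_min = 0.10, cryptic_window = 300L,
                            comparable_margin = 1.0,
                            pseudoexon_dist = 200L) {
  vals <- list(ri_min = ri_min, delta_min = delta_min, sp_flag = sp_flag,
               het_min = het_min, cryptic_window = as.integer(cryptic_window),
               comparable_margin = comparable_margin,
               pseudoexon_dist = as.integer(pseudoexon_dist))
  if (!all(vapply(vals, function(v) is.finite(v) && length(v) == 1L,
                  logical(1L))))
    stop("all criteria must be finite scalars")
  structure(vals, class = "criteria_config")
}

#' Create a single-nucleotide variant record
#'
#' @param contig contig name.
#' @param pos 1-based position (VCF convention).
#' @param ref,alt single reference/alternate bases.
#' @param rsid optional identifier.
#' @param het optional average heterozygosity in `[0, 1]`.
#' @return one-row data.frame of class `variant`.
#' @export
variant <- function(contig, pos, ref, alt, rsid = NA_character_,
                    het = NA_real_) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("only single-nucleotide variants are supported")
  if (ref == alt) stop("ref and alt must differ")
  if (!is.na(het) && (het < 0 || het > 1))
    stop("het must be in [0, 1]")
  structure(data.frame(contig = contig, pos = as.integer(pos), ref = ref,
                       alt = alt, rsid = rsid, het = het,
                       stringsAsFactors = FALSE),
            class = c("variant", "data.frame"))
}

# genome access: genome is a named character vector (contig -> sequence)
.get_contig <- function(genome, contig) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.null(names(genome)) || !contig %in% names(genome))
    stop("contig '", contig, "' not present in genome")
  toupper(genome[[contig]])
}

# substring by 0-based half-open coordinates
.sub0 <- function(seq, start0, end0) substr(seq, start0 + 1L, end0)

# window of matrix `mat` anchored at `junction` (0-based) on `strand`;
# returns NA if out of bounds
.site_window <- function(seq, junction, strand, mat) {
  L <- mat$length; ws <- mat$window_start
  if (strand == "+") {
    s0 <- junction + ws
    if (s0 < 0L || s0 + L > nchar(seq)) return(NA_character_)
    .sub0(seq, s0, s0 + L)
  } else {
    # relative offset o maps to genomic position junction - o
    s0 <- junction - ws - L + 1L
    if (s0 < 0L || s0 + L > nchar(seq)) return(NA_character_)
    revcomp(.sub0(seq, s0, s0 + L))
  }
}

# genomic 0-based positions covered by a site window, in window order
.site_window_positions <- function(junction, strand, mat) {
  off <- mat$window_start + seq_len(mat$length) - 1L
  if (strand == "+") junction + off else junction - off
}

# natural junctions of one transcript: data.frame(site_kind, junction)
.tx_junctions <- function(ex, strand) {
  k <- nrow(ex)
  if (k < 2L) return(data.frame(site_kind = character(0),
                                junction = integer(0)))
  i <- seq_len(k - 1L)
  if (strand == "+") {
    data.frame(site_kind = rep(c("donor", "acceptor"), each = k - 1L),
               junction = c(ex$end[i], ex$start[i + 1L]))
  } else {
    data.frame(site_kind = rep(c("donor", "acceptor"), each = k - 1L),
               junction = c(ex$start[i + 1L] - 1L, ex$end[i] - 1L))
  }
}

#' Score the natural splice sites of a gene model
#'
#' One acceptor and one donor per internal exon junction, scored with the
#' configured matrices; window extraction is strand-aware.
#'
#' @param model a [gene_model()].
#' @param genome named character vector (or `DNAStringSet`) of contig
#'   sequences.
#' @param matrices list with elements `donor` and `acceptor`, each an
#'   [info_matrix][build_weight_matrix()].
#' @return data.frame with columns `contig`, `junction_position`, `strand`,
#'   `site_kind`, `ri`, `origin` (= `"natural"`), `transcript`, `window`.
#' @export
natural_sites_for <- function(model, genome, matrices) {
  stopifnot(inherits(model, "gene_model"),
            all(c("donor", "acceptor") %in% names(matrices)))
  seq <- .get_contig(genome, model$contig)
  out <- list()
  for (tx in names(model$transcripts)) {
    jn <- .tx_junctions(model$transcripts[[tx]], model$strand)
    if (!nrow(jn)) next
    win <- character(nrow(jn)); ri <- numeric(nrow(jn))
    for (i in seq_len(nrow(jn))) {
      mat <- matrices[[jn$site_kind[i]]]
      w <- .site_window(seq, jn$junction[i], model$strand, mat)
      if (is.na(w)) stop("exon junction at ", jn$junction[i],
                         " runs outside contig ", model$contig)
      win[i] <- w
      ri[i] <- score_site(mat, w)
    }
    out[[tx]] <- data.frame(
      contig = model$contig, junction_position = jn$junction,
      strand = model$strand, site_kind = jn$site_kind, ri = ri,
      origin = "natural", transcript = tx, window = win,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# apply a variant to a contig sequence; checks the reference base
.apply_variant <- function(seq, v) {
  p0 <- v$pos - 1L
  have <- .sub0(seq, p0, p0 + 1L)
  if (have != v$ref)
    stop("reference mismatch at ", v$contig, ":", v$pos, ": genome has ",
         have, ", variant says ", v$ref)
  substr(seq, v$pos, v$pos) <- v$alt
  seq
}

#' Evaluate a variant against every splice site it can touch
#'
#' For each natural site whose window covers the variant the site is
#' rescored under both alleles.  Additionally, `cryptic_window` nt on each
#' side of every nearby natural junction are scanned under both alleles;
#' cryptic sites are reported when the variant changes their strength, or
#' when their (post-variant) strength reaches that of a weakened natural
#' site or comes within `comparable_margin` bits of the natural site —
#' provided they clear `ri_min`.
#'
#' @param v a [variant()].
#' @param model a [gene_model()].
#' @param genome named character vector of contig sequences.
#' @param matrices list with `donor` and `acceptor` matrices.
#' @param criteria a [criteria_config()].
#' @return data.frame of effects (class `variant_effects`), one row per
#'   variant x site, with `ri_initial`, `ri_final`, `delta_ri`, `fold`,
#'   `distance_to_natural`, `classification` and bookkeeping columns.
#'   Empty (with a message) if the variant touches no window.
#' @export
evaluate_variant <- function(v, model, genome, matrices,
                             criteria = criteria_config()) {
  stopifnot(inherits(v, "variant") || is.data.frame(v))
  if (v$contig != model$contig) {
    message("variant ", v$contig, ":", v$pos,
            " is on a different contig than gene ", model$gene_id)
    return(.empty_effects())
  }
  ref_seq <- .get_contig(genome, v$contig)
  alt_seq <- .apply_variant(ref_seq, v)
  p0 <- v$pos - 1L
  nat <- natural_sites_for(model, genome, matrices)
  # deduplicate natural sites shared between transcripts
  nat <- nat[!duplicated(nat[, c("junction_position", "site_kind")]), ]

  rows <- list()
  for (i in seq_len(nrow(nat))) {
    mat <- matrices[[nat$site_kind[i]]]
    jpos <- nat$junction_position[i]
    covered <- p0 %in% .site_window_positions(jpos, nat$strand[i], mat)
    if (!covered) next
    w_ref <- .site_window(ref_seq, jpos, nat$strand[i], mat)
    w_alt <- .site_window(alt_seq, jpos, nat$strand[i], mat)
    rows[[length(rows) + 1L]] <- .effect_row(
      v, nat$contig[i], jpos, nat$strand[i], nat$site_kind[i], "natural",
      score_site(mat, w_ref), score_site(mat, w_alt), 0L,
      natural_ri_ref = NA_real_, natural_ri_final = NA_real_,
      intronic = FALSE)
  }
  natural_hits <- do.call(rbind, rows)

  # cryptic scan around every natural junction within reach of the variant
  cw <- criteria$cryptic_window
  crows <- list()
  for (i in seq_len(nrow(nat))) {
    jpos <- nat$junction_position[i]
    if (abs(p0 - jpos) > cw + matrices[[nat$site_kind[i]]]$length) next
    mat <- matrices[[nat$site_kind[i]]]
    lo <- max(0L, jpos - cw - mat$length)
    hi <- min(nchar(ref_seq), jpos + cw + mat$length)
    sub_ref <- .sub0(ref_seq, lo, hi)
    sub_alt <- .sub0(alt_seq, lo, hi)
    # scan the transcribed strand only: forward scan of the extracted
    # (possibly reverse-complemented) strand
    strand <- nat$strand[i]
    if (strand == "-") { sub_ref <- revcomp(sub_ref); sub_alt <- revcomp(sub_alt) }
    sc_ref <- scan_sequence(mat, sub_ref, "forward")
    sc_alt <- scan_sequence(mat, sub_alt, "forward")
    # map scan junction offsets back to genomic coordinates
    to_genomic <- function(jp) if (strand == "+") lo + jp else hi - 1L - jp
    merged <- merge(sc_ref[, c("junction_position", "ri")],
                    sc_alt[, c("junction_position", "ri")],
                    by = "junction_position", suffixes = c("_ref", "_alt"))
    merged$genomic <- to_genomic(merged$junction_position)
    # exclude every natural junction of this kind, not just the anchor
    nat_pos <- nat$junction_position[nat$site_kind == nat$site_kind[i]]
    merged <- merged[!merged$genomic %in% nat_pos, ]
    if (!nrow(merged)) next

    # natural context: final strength of this natural site under alt
    w_nat_alt <- .site_window(alt_seq, jpos, strand, mat)
    nat_ri_final <- score_site(mat, w_nat_alt)
    nat_weakened <- nat_ri_final < nat$ri[i]

    changed <- merged$ri_alt != merged$ri_ref
    strong <- merged$ri_alt >= criteria$ri_min &
      (( nat_weakened & merged$ri_alt >= nat_ri_final) |
         abs(merged$ri_alt - nat$ri[i]) <= criteria$comparable_margin)
    keep <- merged[changed | strong, ]
    for (j in seq_len(nrow(keep))) {
      gpos <- keep$genomic[j]
      dist <- if (strand == "+") gpos - jpos else jpos - gpos
      intronic <- .is_intronic(model, gpos)
      crows[[length(crows) + 1L]] <- .effect_row(
        v, model$contig, gpos, strand, nat$site_kind[i], "cryptic",
        keep$ri_ref[j], keep$ri_alt[j], dist,
        natural_ri_ref = nat$ri[i], natural_ri_final = nat_ri_final,
        intronic = intronic)
    }
  }
  cryptic_hits <- do.call(rbind, crows)
  eff <- rbind(natural_hits, cryptic_hits)
  if (is.null(eff) || !nrow(eff)) {
    message("variant ", v$contig, ":", v$pos,
            " does not overlap any site window of ", model$gene_id)
    return(.empty_effects())
  }
  # deduplicate on (site coordinate, kind, origin)
  eff <- eff[!duplicated(eff[, c("junction_position", "site_kind",
                                 "origin")]), ]
  eff$classification <- vapply(seq_len(nrow(eff)), function(i)
    classify_effect(eff[i, ], criteria), character(1L))
  rownames(eff) <- NULL
  class(eff) <- c("variant_effects", "data.frame")
  eff
}

.effect_row <- function(v, contig, jpos, strand, kind, origin,
                        ri_initial, ri_final, dist,
                        natural_ri_ref, natural_ri_final, intronic) {
  delta <- ri_final - ri_initial
  data.frame(
    contig = contig, pos = v$pos, ref = v$ref, alt = v$alt, rsid = v$rsid,
    het = v$het, junction_position = jpos, strand = strand,
    site_kind = kind, origin = origin,
    ri_initial = ri_initial, ri_final = ri_final, delta_ri = delta,
    fold = if (is.finite(delta)) 2^abs(delta) else Inf,
    distance_to_natural = dist,
    natural_ri_ref = natural_ri_ref, natural_ri_final = natural_ri_final,
    intronic = intronic, stringsAsFactors = FALSE)
}

.empty_effects <- function() {
  e <- data.frame(
    contig = character(0), pos = integer(0), ref = character(0),
    alt = character(0), rsid = character(0), het = numeric(0),
    junction_position = integer(0), strand = character(0),
    site_kind = character(0), origin = character(0),
    ri_initial = numeric(0), ri_final = numeric(0), delta_ri = numeric(0),
    fold = numeric(0), distance_to_natural = integer(0),
    natural_ri_ref = numeric(0), natural_ri_final = numeric(0),
    intronic = logical(0), classification = character(0),
    stringsAsFactors = FALSE)
  class(e) <- c("variant_effects", "data.frame")
  e
}

.is_intronic <- function(model, pos0) {
  for (ex in model$transcripts)
    if (any(pos0 >= ex$start & pos0 < ex$end)) return(FALSE)
  TRUE
}

#' Classify one scored variant effect
#'
#' Natural sites: `inactivating` when the site is weakened below `ri_min`;
#' `leaky_weakened` when weakened by at least `delta_min` but still
#' functional (`ri_final >= ri_min`); `strengthened` when gaining at least
#' `delta_min`.  Cryptic sites: `pseudoexon_candidate` when a deep-intronic
#' site crosses `ri_min` from below; otherwise `cryptic_activated` when a
#' functional cryptic site is strengthened, or reaches the (weakened)
#' natural site's final strength; `strengthened` for sub-threshold gains.
#' Everything else is `none`.
#'
#' @param effect one effect row (list or single-row data.frame) with
#'   `origin`, `delta_ri`, `ri_initial`, `ri_final`, and for cryptic sites
#'   `natural_ri_final`, `natural_ri_ref`, `intronic`,
#'   `distance_to_natural`.
#' @param criteria a [criteria_config()].
#' @return classification string.
#' @export
classify_effect <- function(effect, criteria = criteria_config()) {
  d <- effect$delta_ri
  rf <- effect$ri_final
  if (effect$origin == "natural") {
    if (d < 0 && rf < criteria$ri_min) return("inactivating")
    if (d <= -criteria$delta_min && rf >= criteria$ri_min)
      return("leaky_weakened")
    if (d >= criteria$delta_min) return("strengthened")
    return("none")
  }
  # cryptic site
  crossed <- effect$ri_initial < criteria$ri_min && rf >= criteria$ri_min
  deep <- isTRUE(effect$intronic) &&
    abs(effect$distance_to_natural) > criteria$pseudoexon_dist
  if (crossed && deep) return("pseudoexon_candidate")
  nat_weakened <- !is.na(effect$natural_ri_final) &&
    !is.na(effect$natural_ri_ref) &&
    effect$natural_ri_final < effect$natural_ri_ref
  if (rf >= criteria$ri_min &&
      (d >= criteria$delta_min ||
       (nat_weakened && rf >= effect$natural_ri_final)))
    return("cryptic_activated")
  if (d >= criteria$delta_min) return("strengthened")
  "none"
}

#' Flag candidate variants for the two screens
#'
#' The variant screen (SP-style) flags natural-site effects with
#' `delta_ri < sp_flag` whose variant is common (`het > het_min`; the
#' heterozygosity test is skipped when `het` is missing).  The
#' microarray-style flag marks effects with `|delta_ri| >= delta_min` or a
#' comparable/activated cryptic site.
#'
#' @param effects a `variant_effects` data.frame from [evaluate_variant()]
#'   (or any frame with the same columns).
#' @param criteria a [criteria_config()].
#' @return `effects` with logical columns `sp_flagged` and
#'   `array_flagged` appended.
#' @export
candidate_filter <- function(effects, criteria = criteria_config()) {
  stopifnot(is.data.frame(effects))
  het_ok <- is.na(effects$het) | effects$het > criteria$het_min
  effects$sp_flagged <- effects$origin == "natural" &
    effects$delta_ri < criteria$sp_flag & het_ok
  comparable <- effects$origin == "cryptic" &
    (!is.na(effects$natural_ri_ref) &
       abs(effects$ri_final - effects$natural_ri_ref) <=
       criteria$comparable_margin |
       effects$classification %in% c("cryptic_activated",
                                     "pseudoexon_candidate"))
  effects$array_flagged <- abs(effects$delta_ri) >= criteria$delta_min |
    comparable
  effects
}

#' Exon definition: total information of an exon
#'
#' `R_i,total = R_i(acceptor) + R_i(donor) - length_term`.  Under the null
#' length model the length term is 0 and total information is additive.
#' With an exon-length histogram, the term is the self-information of the
#' exon's length bin relative to the modal bin,
#' `-log2 p(length) + log2 p(mode)`, so a modal-length exon is not
#' penalized.
#'
#' @param ri_acceptor,ri_donor site strengths in bits.
#' @param exon_length exon length in nt (>= 1).
#' @param length_model optional histogram: data.frame with columns
#'   `lower`, `upper` (half-open nt bins) and `count`.  A length outside
#'   the support is given the largest observed penalty, with a warning.
#' @return object of class `exon_definition`: `ri_acceptor`, `ri_donor`,
#'   `length_term`, `ri_total`.
#' @export
exon_definition_total <- function(ri_acceptor, ri_donor, exon_length,
                                  length_model = NULL) {
  stopifnot(is.finite(ri_acceptor), is.finite(ri_donor), exon_length >= 1)
  length_term <- 0
  if (!is.null(length_model)) {
    stopifnot(all(c("lower", "upper", "count") %in% names(length_model)),
              all(length_model$count >= 0), sum(length_model$count) > 0)
    p <- length_model$count / sum(length_model$count)
    bin <- which(exon_length >= length_model$lower &
                   exon_length < length_model$upper)
    p_mode <- max(p)
    if (!length(bin)) {
      warning("exon length ", exon_length,
              " outside histogram support; applying largest-bin penalty")
      p_len <- min(p[p > 0])
    } else {
      p_len <- p[bin[1L]]
      if (p_len == 0) {
        warning("exon length ", exon_length,
                " falls in an empty bin; applying largest-bin penalty")
        p_len <- min(p[p > 0])
      }
    }
    length_term <- -log2(p_len) + log2(p_mode)
  }
  structure(list(ri_acceptor = ri_acceptor, ri_donor = ri_donor,
                 length_term = length_term,
                 ri_total = ri_acceptor + ri_donor - length_term),
            class = "exon_definition")
}

#' @export
print.exon_definition <- function(x, ...) {
  cat(sprintf(
    "exon definition: acceptor %.1f + donor %.1f - length %.2f = %.1f bits\n",
    x$ri_acceptor, x$ri_donor, x$length_term, x$ri_total))
  invisible(x)
}
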