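BASES <- c("A", "C", "G", "T")

#' Training alignment of splice-site windows
#'
#' Bundles equal-length sequence windows centred on a splice junction, the
#' raw material for an information weight matrix.  Each sequence is one
#' verified functional site, written 5'->3' on the mRNA sense strand.
#'
#' @param sequences character vector of equal-length strings over A/C/G/T.
#' @param site_kind `"donor"` or `"acceptor"`.
#' @param window_start integer offset of the first alignment column relative
#'   to the splice junction.  The junction coordinate is the first intronic
#'   base for donors and the first exonic base for acceptors, so the default
#'   donor window `-3..+5` has `window_start = -3` and the default acceptor
#'   window `-25..+2` has `window_start = -25`.
#' @return object of class `training_alignment`.
#' @examples
#' training_alignment(c("CAGGTAAGT", "AAGGTGAGT"), "donor", -3L)
#' @export
training_alignment <- function(sequences,
                               site_kind = c("donor", "acceptor"),
                               window_start = NA_integer_) {
  site_kind <- match.arg(site_kind)
  if (length(sequences) < 1L)
    stop("training alignment needs at least one sequence")
  sequences <- toupper(as.character(sequences))
  L <- nchar(sequences[1L])
  if (L < 1L) stop("sequences must have length >= 1")
  bad_len <- which(nchar(sequences) != L)
  if (length(bad_len))
    stop("ragged alignment: sequence ", bad_len[1L], " has length ",
         nchar(sequences[bad_len[1L]]), ", expected ", L)
  bad_chr <- which(grepl("[^ACGT]", sequences))
  if (length(bad_chr))
    stop("invalid character in sequence ", bad_chr[1L], ": '",
         sequences[bad_chr[1L]], "' (alphabet is ACGT; N is rejected)")
  if (is.na(window_start))
    window_start <- if (site_kind == "donor") -3L else 2L - L
  structure(
    list(site_kind = site_kind,
         window_start = as.integer(window_start),
         sequences = sequences),
    class = "training_alignment")
}

#' @export
print.training_alignment <- function(x, ...) {
  cat(sprintf("training_alignment: %d %s sites, window %+d..%+d\n",
              length(x$sequences), x$site_kind, x$window_start,
              x$window_start + nchar(x$sequences[1L]) - 1L))
  invisible(x)
}

#' Build an information weight matrix from a training alignment
#'
#' Per-position base frequencies are converted to weights in bits:
#' `Riw(b, l) = 2 + log2 f(b, l) - e_n(l)`, where
#' `f(b, l) = (count(b, l) + pseudocount) / (n + 4 * pseudocount)` and
#' `e_n` is an optional small-sample correction.  Summing `Riw` over a
#' window gives the individual information `R_i` of a candidate site; one
#' bit corresponds to a twofold change in predicted binding affinity.
#'
#' With `pseudocount = 0`, a base never observed at a position gets weight
#' `-Inf`: any window containing it scores `-Inf` rather than a silently
#' finite number.  `pseudocount = 0.25` (one prior observation spread over
#' the four bases) is the recommended analysis setting.
#'
#' The analytic small-sample correction is `e(n) = 3 / (2 * ln(2) * n)`
#' bits per column; default off so closed-form identities hold exactly.
#'
#' @param alignment a [training_alignment()].
#' @param pseudocount non-negative prior count added to every cell.
#' @param correction `"none"` or `"analytic"`.
#' @return object of class `info_matrix` with elements `weights`
#'   (4 x L, rows A/C/G/T), `freqs`, `n`, `e_n`, `site_kind`,
#'   `window_start`, `length`, `pseudocount`, `correction`.
#' @examples
#' aln <- training_alignment(rep("GTAAGT", 4), "donor", 0L)
#' m <- build_weight_matrix(aln)
#' m$weights["G", 1]  # 2 bits: invariant position
#' @export
build_weight_matrix <- function(alignment, pseudocount = 0,
                                correction = c("none", "analytic")) {
  correction <- match.arg(correction)
  stopifnot(inherits(alignment, "training_alignment"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      is.na(pseudocount) || pseudocount < 0)
    stop("pseudocount must be a single non-negative number")
  L <- nchar(alignment$sequences[1L])
  n <- length(alignment$sequences)
  chars <- matrix(unlist(strsplit(alignment$sequences, "", fixed = TRUE)),
                  nrow = n, byrow = TRUE)
  counts <- vapply(seq_len(L), function(l)
    tabulate(match(chars[, l], BASES), nbins = 4L), integer(4L))
  dimnames(counts) <- list(BASES, NULL)
  freqs <- (counts + pseudocount) / (n + 4 * pseudocount)
  e_n <- if (correction == "analytic")
    rep(3 / (2 * log(2) * n), L) else rep(0, L)
  weights <- 2 + log2(freqs) - rep(e_n, each = 4L)  # -Inf where f = 0
  structure(
    list(site_kind = alignment$site_kind,
         window_start = alignment$window_start,
         length = L,
         weights = weights,
         freqs = freqs,
         n = rep(n, L),
         e_n = e_n,
         pseudocount = pseudocount,
         correction = correction),
    class = "info_matrix")
}

#' @export
print.info_matrix <- function(x, ...) {
  cat(sprintf(
    "info_matrix: %s, window %+d..%+d (L=%d), n=%d, pseudocount=%g, correction=%s\n",
    x$site_kind, x$window_start, x$window_start + x$length - 1L,
    x$length, x$n[1L], x$pseudocount, x$correction))
  cat(sprintf("R_sequence-style mean information: %.2f bits\n",
              sum(ifelse(x$freqs > 0, x$freqs * x$weights, 0))))
  invisible(x)
}

#' Mean information content of the model over its training set
#'
#' Returns `sum_l sum_b f(b, l) * Riw(b, l)` in bits (the R_sequence
#' diagnostic).  With pseudocount 0 and no correction this equals the mean
#' of [score_site()] over the training sequences exactly.
#'
#' @param matrix an [info_matrix][build_weight_matrix()].
#' @param alignment the training alignment the matrix was built from.
#' @return bits (numeric scalar).
#' @export
rsequence <- function(matrix, alignment) {
  stopifnot(inherits(matrix, "info_matrix"),
            inherits(alignment, "training_alignment"))
  if (nchar(alignment$sequences[1L]) != matrix$length)
    stop("dimension mismatch: alignment length ",
         nchar(alignment$sequences[1L]), " vs matrix length ", matrix$length)
  # 0 * -Inf cells (never-seen bases) contribute nothing
  sum(ifelse(matrix$freqs > 0, matrix$freqs * matrix$weights, 0))
}

#' Individual information of one sequence window
#'
#' `R_i = sum_l Riw(window[l], l)` in bits.  A window containing a base
#' never observed in training (pseudocount 0) scores `-Inf`.
#'
#' @param matrix an [info_matrix][build_weight_matrix()].
#' @param window string of length `matrix$length` over A/C/G/T.
#' @return bits (numeric scalar, possibly `-Inf`).
#' @export
score_site <- function(matrix, window) {
  stopifnot(inherits(matrix, "info_matrix"))
  window <- toupper(window)
  if (nchar(window) != matrix$length)
    stop("window length ", nchar(window), " != matrix length ", matrix$length)
  idx <- match(strsplit(window, "", fixed = TRUE)[[1L]], BASES)
  if (anyNA(idx))
    stop("invalid character in window '", window, "' (alphabet is ACGT)")
  sum(matrix$weights[cbind(idx, seq_len(matrix$length))])
}

#' Scan a sequence for candidate splice sites
#'
#' Slides the matrix along the sequence and reports the individual
#' information of every complete window.  Windows containing `N` are
#' skipped and counted in the `n_skipped` attribute.  In `"both"` mode the
#' reverse strand is scored on the reverse complement, with junction
#' coordinates mapped back to the forward strand.
#'
#' @param matrix an [info_matrix][build_weight_matrix()].
#' @param sequence string over A/C/G/T/N.
#' @param strand_mode `"forward"` or `"both"`.
#' @param contig contig name stored in the result.
#' @param origin site origin label (`"natural"` or `"cryptic"`).
#' @return data.frame of site scores with columns `contig`,
#'   `junction_position` (0-based, first intronic base for donors / first
#'   exonic base for acceptors), `strand`, `site_kind`, `ri`, `origin`;
#'   attribute `n_skipped` counts N-containing windows.  A sequence shorter
#'   than the window yields an empty frame.
#' @export
scan_sequence <- function(matrix, sequence,
                          strand_mode = c("forward", "both"),
                          contig = "seq", origin = "cryptic") {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(matrix, "info_matrix"))
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence may only contain A/C/G/T/N")
  fwd <- .scan_one_strand(matrix, sequence)
  res <- data.frame(
    contig = rep(contig, length(fwd$pos)),
    junction_position = fwd$pos - matrix$window_start,
    strand = rep("+", length(fwd$pos)),
    site_kind = rep(matrix$site_kind, length(fwd$pos)),
    ri = fwd$ri,
    origin = rep(origin, length(fwd$pos)),
    stringsAsFactors = FALSE)
  n_skipped <- fwd$n_skipped
  if (strand_mode == "both") {
    n <- nchar(sequence)
    rc <- revcomp(sequence)
    rev <- .scan_one_strand(matrix, rc)
    res_rev <- data.frame(
      contig = rep(contig, length(rev$pos)),
      junction_position = n - 1L - (rev$pos - matrix$window_start),
      strand = rep("-", length(rev$pos)),
      site_kind = rep(matrix$site_kind, length(rev$pos)),
      ri = rev$ri,
      origin = rep(origin, length(rev$pos)),
      stringsAsFactors = FALSE)
    res <- rbind(res, res_rev)
    n_skipped <- n_skipped + rev$n_skipped
  }
  attr(res, "n_skipped") <- n_skipped
  res
}

# vectorised per-offset window scores for one strand; pos is the 0-based
# offset of the window's first column
.scan_one_strand <- function(matrix, sequence) {
  L <- matrix$length
  n <- nchar(sequence)
  if (n < L)
    return(list(pos = integer(0), ri = numeric(0), n_skipped = 0L))
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], BASES)  # NA for N
  n_off <- n - L + 1L
  ri <- numeric(n_off)
  ok <- rep(TRUE, n_off)
  for (l in seq_len(L)) {
    col <- idx[l:(l + n_off - 1L)]
    ok <- ok & !is.na(col)
    w <- matrix$weights[cbind(col, rep(l, n_off))]
    ri <- ri + ifelse(is.na(w), 0, w)
  }
  list(pos = which(ok) - 1L, ri = ri[ok], n_skipped = sum(!ok))
}

#' Reverse complement of a DNA string
#'
#' @param x string over A/C/G/T/N.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Information change caused by substituting a window
#'
#' `delta R_i = score_site(alt) - score_site(ref)`.  For a single-base
#' substitution this reduces to the one-column weight difference
#' `Riw(alt, l*) - Riw(ref, l*)`.
#'
#' @param matrix an [info_matrix][build_weight_matrix()].
#' @param ref_window,alt_window strings of the matrix length.
#' @return bits (numeric scalar).
#' @export
delta_ri <- function(matrix, ref_window, alt_window) {
  score_site(matrix, alt_window) - score_site(matrix, ref_window)
}

#' Fold change in predicted binding affinity
#'
#' One bit of individual information corresponds to a twofold change in
#' affinity, so the minimum fold change implied by an information change is
#' `2^|delta R_i|`.  A 3.0-bit change is an eightfold change.
#'
#' @param ri_initial,ri_final site strength in bits before/after the change.
#' @return object of class `fold_change`: `ri_initial`, `ri_final`,
#'   `delta_ri`, `fold` (unrounded), `fold_reported` (rounded to one
#'   decimal, the convention used in report tables), `direction`
#'   (`"weakened"`, `"strengthened"` or `"unchanged"`).
#' @examples
#' fold_change(9.1, 4.6)$fold_reported  # 22.6
#' @export
fold_change <- function(ri_initial, ri_final) {
  if (!is.finite(ri_initial) || !is.finite(ri_final))
    stop("fold_change requires finite information values")
  delta <- ri_final - ri_initial
  structure(
    list(ri_initial = ri_initial,
         ri_final = ri_final,
         delta_ri = delta,
         fold = 2^abs(delta),
         fold_reported = round(2^abs(delta), 1),
         direction = if (delta == 0) "unchanged"
                     else if (delta < 0) "weakened" else "strengthened"),
    class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("%.1f -> %.1f bits (delta %.1f): %.1f-fold, %s\n",
              x$ri_initial, x$ri_final, x$delta_ri, x$fold_reported,
              x$direction))
  invisible(x)
}

#' Write an information weight matrix to a self-describing TSV
#'
#' Header lines (`# key value`) carry `site_kind`, `window_start`,
#' `length`, `n`, `pseudocount` and `correction`; the body has one row per
#' position with offset, the four base weights, `n` and `e_n`.  Weights are
#' written with 17 significant digits so [read_info_matrix()] round-trips
#' bit-exactly; `-Inf` sentinels survive the trip.
#'
#' @param matrix an [info_matrix][build_weight_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_info_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "info_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# site_kind", matrix$site_kind),
    paste("# window_start", matrix$window_start),
    paste("# length", matrix$length),
    paste("# n", matrix$n[1L]),
    paste("# pseudocount", sprintf("%.17g", matrix$pseudocount)),
    paste("# correction", matrix$correction),
    paste("offset", "A", "C", "G", "T", "n", "e_n", sep = "\t")), con)
  num <- function(v) ifelse(is.finite(v), sprintf("%.17g", v), as.character(v))
  for (l in seq_len(matrix$length)) {
    writeLines(paste(matrix$window_start + l - 1L,
                     num(matrix$weights["A", l]), num(matrix$weights["C", l]),
                     num(matrix$weights["G", l]), num(matrix$weights["T", l]),
                     matrix$n[l], num(matrix$e_n[l]), sep = "\t"), con)
  }
  invisible(path)
}

#' Read an information weight matrix written by [write_info_matrix()]
#'
#' @param path file path.
#' @return an `info_matrix`.  The `freqs` element is reconstructed from the
#'   weights (`f = 2^(Riw - 2 + e_n)`).
#' @export
read_info_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), " ", fixed = TRUE))
  meta <- stats::setNames(kv[, 2L], kv[, 1L])
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            header = TRUE, sep = "\t",
                            colClasses = "character")
  L <- as.integer(meta[["length"]])
  if (nrow(body) != L) stop("matrix body has ", nrow(body),
                            " rows, header says ", L)
  w <- t(vapply(BASES, function(b) as.numeric(body[[b]]), numeric(L)))
  dimnames(w) <- list(BASES, NULL)
  e_n <- as.numeric(body$e_n)
  structure(
    list(site_kind = meta[["site_kind"]],
         window_start = as.integer(meta[["window_start"]]),
         length = L,
         weights = w,
         freqs = 2^(w - 2 + rep(e_n, each = 4L)),
         n = as.integer(body$n),
         e_n = e_n,
         pseudocount = as.numeric(meta[["pseudocount"]]),
         correction = meta[["correction"]]),
    class = "info_matrix")
}

#' Read a training alignment from FASTA or one-window-per-line text
#'
#' @param path file path.  Files whose first non-blank line starts with
#'   `>` are parsed as FASTA (via Biostrings); anything else is read as one
#'   fixed-width window per line.
#' @param site_kind,window_start passed to [training_alignment()].
#' @return a `training_alignment`.
#' @export
read_training_alignment <- function(path, site_kind = c("donor", "acceptor"),
                                    window_start = NA_integer_) {
  first <- readLines(path, n = 50L)
  first <- first[nzchar(trimws(first))]
  seqs <- if (length(first) && startsWith(first[1L], ">")) {
    as.character(Biostrings::readDNAStringSet(path))
  } else {
    trimws(readLines(path))
  }
  seqs <- seqs[nzchar(seqs)]
  training_alignment(unname(seqs), site_kind, window_start)
}
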