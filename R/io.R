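# Readers and writers for the standard interchange formats.  Coordinates
# are converted between external conventions (1-based GFF3/VCF) and the
# internal 0-based half-open convention here, and only here.

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, one element per contig, uppercase.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  v <- toupper(as.character(ss))
  names(v) <- sub("\\s.*$", "", names(v))
  v
}

#' Write a named character vector of contigs as FASTA
#'
#' @param genome named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a gene model as GFF3
#'
#' @param model a [gene_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(model, path) {
  lines <- "##gff-version 3"
  gstart <- min(vapply(model$transcripts, function(ex) min(ex$start),
                       integer(1L)))
  gend <- max(vapply(model$transcripts, function(ex) max(ex$end),
                     integer(1L)))
  row <- function(type, s0, e0, id, parent = NULL) {
    attr <- paste0("ID=", id,
                   if (!is.null(parent)) paste0(";Parent=", parent))
    paste(model$contig, "splicewise", type, s0 + 1L, e0, ".",
          model$strand, ".", attr, sep = "\t")
  }
  lines <- c(lines, row("gene", gstart, gend, model$gene_id))
  for (tx in names(model$transcripts)) {
    ex <- model$transcripts[[tx]]
    lines <- c(lines, row("mRNA", min(ex$start), max(ex$end), tx,
                          model$gene_id))
    for (i in seq_len(nrow(ex)))
      lines <- c(lines, row("exon", ex$start[i], ex$end[i],
                            paste0(tx, ".e", i), tx))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3 (exon features)
#'
#' Uses rtracklayer when available; groups exons by their `Parent`
#' attribute into transcripts and by transcript parent into genes.
#'
#' @param path GFF3 file.
#' @return list of [gene_model()] objects, one per gene.
#' @export
read_gene_models_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  ex <- df[df$type == "exon", , drop = FALSE]
  mr <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_parent <- stats::setNames(
    vapply(mr$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1L)), mr$ID)
  out <- list()
  ex_parent <- vapply(ex$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1L))
  for (gene in unique(stats::na.omit(tx_parent))) {
    txs <- names(tx_parent)[tx_parent == gene]
    exons <- lapply(txs, function(tx) {
      sub <- ex[ex_parent == tx, , drop = FALSE]
      sub <- sub[order(sub$start), ]
      data.frame(start = sub$start - 1L, end = sub$end)  # to 0-based
    })
    names(exons) <- txs
    first <- ex[ex_parent == txs[1L], ][1L, ]
    out[[gene]] <- gene_model(gene, as.character(first$seqnames),
                              as.character(first$strand), exons)
  }
  out
}

#' Write variants as a minimal VCF
#'
#' @param variants data.frame with `contig`, `pos` (1-based), `ref`,
#'   `alt`, optional `rsid` and `het` (written as an `AVGHET` INFO tag).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AVGHET,Number=1,Type=Float,Description=\"Average heterozygosity\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    id <- if (!is.null(v$rsid) && !is.na(v$rsid)) v$rsid else "."
    info <- if (!is.null(v$het) && !is.na(v$het))
      sprintf("AVGHET=%g", v$het) else "."
    paste(v$contig, v$pos, id, v$ref, v$alt, ".", "PASS", info, sep = "\t")
  }, character(1L))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read single-nucleotide variants from a VCF
#'
#' Uses VariantAnnotation when available; multi-nucleotide records are
#' dropped with a message.  The `AVGHET` INFO tag, when present, fills the
#' `het` column.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @return data.frame with `contig`, `pos` (1-based), `ref`, `alt`,
#'   `rsid`, `het`.
#' @export
read_variants_vcf <- function(path) {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    rr <- as.data.frame(SummarizedExperiment::rowRanges(vcf))
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- vapply(as.list(VariantAnnotation::alt(vcf)), function(a)
      as.character(a)[1L], character(1L))
    info <- VariantAnnotation::info(vcf)
    het <- if ("AVGHET" %in% names(info)) as.numeric(info$AVGHET)
           else rep(NA_real_, nrow(rr))
    out <- data.frame(contig = as.character(rr$seqnames), pos = rr$start,
                      ref = ref, alt = alt, rsid = rownames(rr), het = het,
                      stringsAsFactors = FALSE)
  } else {
    # fallback: fixed-column read of the standard VCF body
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#")]
    f <- utils::read.table(text = body, sep = "\t",
                           colClasses = "character")
    het <- ifelse(grepl("AVGHET=", f$V8),
                  as.numeric(sub(".*AVGHET=([0-9.eE+-]+).*", "\\1", f$V8)),
                  NA_real_)
    out <- data.frame(contig = f$V1, pos = as.integer(f$V2), ref = f$V4,
                      alt = f$V5, rsid = ifelse(f$V3 == ".", NA, f$V3),
                      het = het, stringsAsFactors = FALSE)
  }
  snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L
  if (any(!snv))
    message(sum(!snv), " non-SNV record(s) dropped")
  out[snv, , drop = FALSE]
}

#' Write a variant-effect table as TSV
#'
#' Full-precision numeric columns plus one-decimal report columns
#' (`ri_initial_r`, `ri_final_r`, `delta_ri_r`, `fold_r`), the rounding
#' convention used in report tables.
#'
#' @param effects a `variant_effects` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_effects_tsv <- function(effects, path) {
  out <- as.data.frame(effects)
  out$ri_initial_r <- round(out$ri_initial, 1)
  out$ri_final_r <- round(out$ri_final, 1)
  out$delta_ri_r <- round(out$delta_ri, 1)
  out$fold_r <- round(out$fold, 1)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
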