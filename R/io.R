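# Readers and writers for the file formats at the pipeline's boundaries.
# Only the feature subset the pipeline itself produces and consumes is
# supported: single-end all-match SAM records, haploid single-sample VCF
# with per-strand allelic depths, GFF3 CDS gene models, and plain TSV.

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

readTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

ALIGNMENT_COLS <- c("read_id", "contig", "pos", "strand", "cigar",
                    "seq", "qual")

# query bases consumed by a CIGAR string (M, I, S, =, X consume query)
cigarQueryLength <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    if (ops[1] == -1L) return(NA_integer_)
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    if (nchar(paste(toks, collapse = "")) != nchar(cg)) return(NA_integer_)
    n <- as.integer(sub("[A-Z=]", "", toks))
    op <- sub("\\d+", "", toks)
    sum(n[op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Write and read alignment records as SAM
#'
#' `writeSam()` emits a minimal SAM 1.6 file (header with `@SQ` lines; flags
#' 0/16; MAPQ 60). `readSam()` parses it back: records with the unmapped
#' flag are dropped, strand is derived from flag bit 16, and records whose
#' CIGAR does not consume exactly the sequence length are skipped with a
#' warning naming their line numbers.
#'
#' @param alignments `data.frame` of alignment records (columns `read_id`,
#'   `contig`, `pos`, `strand`, `cigar`, `seq`, `qual`).
#' @param contigLengths named integer vector for the `@SQ` header lines.
#' @param path file path.
#' @return `readSam()` returns an alignment `data.frame` as above.
#' @export
writeSam <- function(alignments, contigLengths, path) {
  stopifnot(all(ALIGNMENT_COLS %in% names(alignments)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contigLengths),
                     as.integer(contigLengths)), con)
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                       alignments$read_id, flag, alignments$contig,
                       as.integer(alignments$pos), alignments$cigar,
                       alignments$seq, alignments$qual), con)
  }
  invisible(path)
}

#' @rdname writeSam
#' @export
readSam <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  if (!any(grepl("^@SQ\t", lines[hdr])))
    stop("SAM format error: no @SQ header lines in ", path)
  body <- lines[!hdr]
  lineNo <- which(!hdr)
  if (length(body) == 0L) return(emptyAlignments())
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- nf < 11L
  fields <- function(i) vapply(parts[!bad], `[[`, character(1), i)
  flag <- suppressWarnings(as.integer(fields(2L)))
  rec <- data.frame(read_id = fields(1L), contig = fields(3L),
                    pos = suppressWarnings(as.integer(fields(4L))),
                    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    cigar = fields(6L), seq = fields(10L),
                    qual = fields(11L), stringsAsFactors = FALSE)
  recLine <- lineNo[!bad]
  unmapped <- bitwAnd(flag, 4L) > 0L
  qlen <- cigarQueryLength(rec$cigar)
  malformed <- is.na(rec$pos) | rec$pos < 1L | is.na(qlen) |
    qlen != nchar(rec$seq) | nchar(rec$seq) != nchar(rec$qual)
  if (any(bad) || any(malformed))
    warning("skipped ", sum(bad) + sum(malformed),
            " malformed SAM record(s) at line(s) ",
            paste(sort(c(lineNo[bad], recLine[malformed])), collapse = ", "))
  out <- rec[!unmapped & !malformed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

VARIANT_COLS <- c("contig", "pos", "ref", "alt", "qual", "depth",
                  "genotype", "adf_ref", "adf_alt", "adr_ref", "adr_alt")

emptyVariants <- function() {
  data.frame(contig = character(0), pos = integer(0), ref = character(0),
             alt = character(0), qual = numeric(0), depth = integer(0),
             genotype = integer(0), adf_ref = integer(0),
             adf_alt = integer(0), adr_ref = integer(0),
             adr_alt = integer(0), stringsAsFactors = FALSE)
}

#' Write and read substitution variants as VCF 4.2
#'
#' The emitted subset is haploid single-sample: `INFO/DP`, `FORMAT`
#' `GT:ADF:ADR` where `ADF`/`ADR` hold the (ref, alt) allelic depths on the
#' forward/reverse strand. Round trips are lossless. On read, indel lines
#' (REF or ALT longer than one base) are skipped with a warning and
#' multi-allelic lines are rejected.
#'
#' @param variants variant `data.frame` (columns `contig`, `pos`, `ref`,
#'   `alt`, `qual`, `depth`, `genotype`, `adf_ref`, `adf_alt`, `adr_ref`,
#'   `adr_alt`), sorted by (contig, pos).
#' @param path file path.
#' @return `readVariants()` returns a variant `data.frame` as above.
#' @export
writeVariants <- function(variants, path) {
  stopifnot(all(VARIANT_COLS %in% names(variants)))
  if (!identical(order(variants$contig, variants$pos),
                 seq_len(nrow(variants))))
    stop("variants must be sorted by (contig, pos)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=",
           "\"Allelic depths (ref,alt) on the forward strand\">"),
    paste0("##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=",
           "\"Allelic depths (ref,alt) on the reverse strand\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"), con)
  if (nrow(variants)) {
    writeLines(sprintf(
      "%s\t%d\t.\t%s\t%s\t%s\tPASS\tDP=%d\tGT:ADF:ADR\t%d:%d,%d:%d,%d",
      variants$contig, as.integer(variants$pos), variants$ref, variants$alt,
      vapply(variants$qual, function(q) format(q, digits = 15),
             character(1)),
      as.integer(variants$depth), as.integer(variants$genotype),
      as.integer(variants$adf_ref), as.integer(variants$adf_alt),
      as.integer(variants$adr_ref), as.integer(variants$adr_alt)), con)
  }
  invisible(path)
}

#' @rdname writeVariants
#' @export
readVariants <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0L) return(emptyVariants())
  parts <- strsplit(body, "\t", fixed = TRUE)
  getf <- function(i) vapply(parts, `[[`, character(1), i)
  alt <- getf(5L)
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic VCF records are not supported: ", path)
  ref <- getf(4L)
  indel <- nchar(ref) != 1L | nchar(alt) != 1L
  if (any(indel))
    warning("skipped ", sum(indel), " indel record(s) in ", path)
  keep <- !indel
  fmt <- strsplit(getf(10L)[keep], ":", fixed = TRUE)
  adf <- strsplit(vapply(fmt, `[[`, character(1), 2L), ",", fixed = TRUE)
  adr <- strsplit(vapply(fmt, `[[`, character(1), 3L), ",", fixed = TRUE)
  info <- getf(8L)[keep]
  data.frame(
    contig = getf(1L)[keep], pos = as.integer(getf(2L)[keep]),
    ref = ref[keep], alt = alt[keep],
    qual = as.numeric(getf(6L)[keep]),
    depth = as.integer(sub("^.*DP=(\\d+).*$", "\\1", info)),
    genotype = as.integer(vapply(fmt, `[[`, character(1), 1L)),
    adf_ref = as.integer(vapply(adf, `[[`, character(1), 1L)),
    adf_alt = as.integer(vapply(adf, `[[`, character(1), 2L)),
    adr_ref = as.integer(vapply(adr, `[[`, character(1), 1L)),
    adr_alt = as.integer(vapply(adr, `[[`, character(1), 2L)),
    stringsAsFactors = FALSE)
}

#' Read the assembly annotation bundle
#'
#' Loads contigs (FASTA), gene models (GFF3 `CDS` features, 1-based
#' inclusive) and the contig-to-genus taxonomy table. Every gene model must
#' lie within its contig's bounds; contigs absent from the taxonomy table
#' are assigned genus `"unclassified"`.
#'
#' @param fastaPath,gffPath,taxonomyPath file paths; `taxonomyPath` may be
#'   `NULL` (all contigs unclassified). The taxonomy TSV has columns
#'   `contig_id`, `genus`.
#' @return `list(contigs = DNAStringSet, genes = GRanges,
#'   taxonomy = data.frame)`.
#' @export
readAnnotations <- function(fastaPath, gffPath, taxonomyPath = NULL) {
  contigs <- Biostrings::readDNAStringSet(fastaPath)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  genes <- rtracklayer::import(gffPath, format = "gff3")
  genes <- genes[genes$type == "CDS"]
  gid <- genes$ID %||% genes$gene_id
  if (is.null(gid)) gid <- paste0("gene", seq_along(genes))
  genes$gene_id <- gid
  cl <- setNames(Biostrings::width(contigs), names(contigs))
  ctg <- as.character(GenomicRanges::seqnames(genes))
  if (!all(ctg %in% names(cl)))
    stop("gene model(s) on unknown contig(s): ",
         paste(unique(gid[!ctg %in% names(cl)]), collapse = ", "))
  bad <- GenomicRanges::start(genes) < 1L |
    GenomicRanges::end(genes) > cl[ctg]
  if (any(bad))
    stop("gene model(s) exceed contig bounds: ",
         paste(gid[bad], collapse = ", "))
  if (is.null(genes$phase)) genes$phase <- 0L
  genes$phase[is.na(genes$phase)] <- 0L
  taxonomy <- if (is.null(taxonomyPath)) {
    data.frame(contig_id = character(0), genus = character(0))
  } else readTsv(taxonomyPath)
  missing <- setdiff(names(contigs), taxonomy$contig_id)
  if (length(missing))
    taxonomy <- rbind(taxonomy[, c("contig_id", "genus")],
                      data.frame(contig_id = missing,
                                 genus = "unclassified"))
  list(contigs = contigs, genes = genes, taxonomy = taxonomy)
}
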