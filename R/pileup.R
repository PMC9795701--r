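# Strand-resolved pileup and substitution-variant calling on gut contigs.
#
# This stands in, at desk scale, for an external mpileup-based caller: the
# same thresholds apply (site quality >= 20, depth >= 10, depth capped at
# 1000), indels never arise because only all-match alignments are counted,
# and the site quality is an explicit binomial-tail Phred score so the
# filter thresholds stay meaningful and independently checkable.

#' @import data.table
NULL

#' Default variant-calling parameters
#'
#' @param minQual minimum site quality (Phred) for a call.
#' @param minDepth minimum used read depth for a call.
#' @param maxDepth per-position depth cap applied during pileup.
#' @param gtAltFraction alternative-allele fraction at or above which the
#'   haploid genotype is 1 (consensus semantics; an exact tie gives 1).
#' @param errorRate per-base error rate assumed by the quality model.
#' @return a named list of parameters.
#' @export
callParams <- function(minQual = 20, minDepth = 10L, maxDepth = 1000L,
                       gtAltFraction = 0.5, errorRate = 0.001) {
  stopifnot(minDepth >= 1L, maxDepth >= minDepth,
            errorRate > 0, errorRate < 1,
            gtAltFraction >= 0, gtAltFraction <= 1)
  list(minQual = minQual, minDepth = as.integer(minDepth),
       maxDepth = as.integer(maxDepth), gtAltFraction = gtAltFraction,
       errorRate = errorRate)
}

PILEUP_COUNT_COLS <- as.vector(outer(BASES, c("fwd", "rev"), paste, sep = "_"))

emptyPileup <- function(contigSet = character(0)) {
  out <- data.table(contig = character(0), pos = integer(0))
  for (cn in PILEUP_COUNT_COLS) out[[cn]] <- integer(0)
  out$depth_used <- integer(0)
  attr(out, "skipped") <- 0L
  attr(out, "contigs") <- contigSet
  out[]
}

#' Strand-resolved allele counts per position
#'
#' Counts, for every covered position, how many overlapping reads
#' contribute each base on each strand. Records whose CIGAR is not a single
#' all-match run (or whose length disagrees with the sequence) are skipped
#' and tallied in the `"skipped"` attribute. When coverage at a position
#' exceeds `maxDepth`, reads are truncated deterministically in ascending
#' (position, read id) order before counting, and `depth_used` reports the
#' retained depth.
#'
#' @param alignments alignment `data.frame` (see [readSam()]).
#' @param contig optional single contig name to restrict to.
#' @param maxDepth per-position depth cap (default 1000).
#' @param contigSet optional character vector declaring the full contig
#'   universe the alignments were mapped to; recorded as an attribute so
#'   downstream steps can distinguish "uncovered" from "unknown" contigs.
#' @return `data.table` with columns `contig`, `pos`, `A_fwd` ... `T_rev`,
#'   `depth_used`; attributes `skipped` and `contigs`.
#' @export
pileupCounts <- function(alignments, contig = NULL, maxDepth = 1000L,
                         contigSet = NULL) {
  al <- alignments
  if (!is.null(contig)) al <- al[al$contig == contig, , drop = FALSE]
  universe <- contigSet %||% unique(alignments$contig)
  if (nrow(al) == 0L) return(emptyPileup(universe))
  len <- suppressWarnings(as.integer(sub("M$", "", al$cigar)))
  ok <- grepl("^\\d+M$", al$cigar) & !is.na(len) & len == nchar(al$seq)
  skipped <- sum(!ok)
  al <- al[ok, , drop = FALSE]
  len <- len[ok]
  if (nrow(al) == 0L) {
    out <- emptyPileup(universe)
    attr(out, "skipped") <- skipped
    return(out)
  }
  # deterministic read order for max-depth truncation
  ord <- order(al$pos, al$read_id)
  rnk <- integer(length(ord)); rnk[ord] <- seq_along(ord)
  dt <- data.table(
    contig = rep(al$contig, len),
    pos = rep(al$pos, len) + sequence(len) - 1L,
    base = unlist(strsplit(al$seq, ""), use.names = FALSE),
    fwd = rep(al$strand == "+", len),
    rdrank = rep(rnk, len))
  dt <- dt[dt$base %in% BASES]
  if (is.finite(maxDepth) &&
      max(dt[, .N, by = c("contig", "pos")]$N) > maxDepth) {
    dt[, keep := frank(rdrank, ties.method = "first") <= maxDepth,
       by = c("contig", "pos")]
    dt <- dt[dt$keep == TRUE][, keep := NULL]
  }
  dt[, col := factor(paste0(base, ifelse(fwd, "_fwd", "_rev")),
                     PILEUP_COUNT_COLS)]
  counts <- dt[, .N, by = c("contig", "pos", "col")]
  wide <- dcast(counts, contig + pos ~ col,
                value.var = "N", fill = 0L, drop = c(TRUE, FALSE))
  for (cn in setdiff(PILEUP_COUNT_COLS, names(wide))) wide[[cn]] <- 0L
  setcolorder(wide, c("contig", "pos", PILEUP_COUNT_COLS))
  wide[, depth_used := rowSums(.SD), .SDcols = PILEUP_COUNT_COLS]
  wide[, depth_used := as.integer(depth_used)]
  setorder(wide, contig, pos)
  attr(wide, "skipped") <- skipped
  attr(wide, "contigs") <- universe
  wide[]
}

#' Binomial-tail site quality
#'
#' Phred-scaled probability of observing at least `nAlt` alternative bases
#' among `nRef + nAlt` reads under a per-base error model:
#' `-10 log10 P(X >= nAlt)` with `X ~ Binomial(nRef + nAlt, errorRate)`,
#' capped at 255. `nAlt = 0` (tail probability 1) and empty sites give 0.
#' Monotone non-decreasing in `nAlt` for a fixed total.
#'
#' @param nRef,nAlt non-negative reference / alternative allele counts
#'   (vectorised).
#' @param errorRate assumed per-base error probability, in (0, 1).
#' @return numeric vector of Phred-scaled qualities.
#' @export
siteQuality <- function(nRef, nAlt, errorRate) {
  stopifnot(errorRate > 0, errorRate < 1, all(nRef >= 0), all(nAlt >= 0))
  n <- nRef + nAlt
  q <- numeric(length(n))
  live <- nAlt > 0 & n > 0
  if (any(live)) {
    logp <- pbinom(nAlt[live] - 1, n[live], errorRate,
                   lower.tail = FALSE, log.p = TRUE)
    q[live] <- -10 * logp / log(10)
  }
  pmin(q, 255)
}

#' Call substitution variants from a strand-resolved pileup
#'
#' At each position the candidate alternative allele is the non-reference
#' base with the highest total (both-strand) count, ties broken
#' alphabetically. A variant is emitted iff that count is positive, the
#' binomial-tail [siteQuality()] over (ref, alt) counts reaches
#' `params$minQual`, and `depth_used >= params$minDepth`. The haploid
#' genotype is 1 iff `alt / (ref + alt) >= params$gtAltFraction`, else 0.
#' Per-strand allelic depths fill `ADF`/`ADR`.
#'
#' @param pileup output of [pileupCounts()].
#' @param contigSeqs reference sequences (`DNAStringSet` or named character)
#'   covering every pileup contig.
#' @param params a [callParams()] list.
#' @return variant `data.frame` (see [writeVariants()] for columns), sorted
#'   by (contig, pos).
#' @export
callVariants <- function(pileup, contigSeqs, params = callParams()) {
  if (is(contigSeqs, "DNAStringSet")) contigSeqs <-
      setNames(as.character(contigSeqs), names(contigSeqs))
  if (nrow(pileup) == 0L) return(emptyVariants())
  if (!all(unique(pileup$contig) %in% names(contigSeqs)))
    stop("contigSeqs does not cover all pileup contigs")
  fwd <- as.matrix(pileup[, paste0(BASES, "_fwd"), with = FALSE])
  rev <- as.matrix(pileup[, paste0(BASES, "_rev"), with = FALSE])
  tot <- fwd + rev
  refBase <- substr(contigSeqs[pileup$contig], pileup$pos, pileup$pos)
  refIdx <- match(refBase, BASES)
  valid <- !is.na(refIdx)
  n <- nrow(pileup)
  ij <- cbind(seq_len(n), refIdx)
  refCount <- ifelse(valid, tot[ij], NA_integer_)
  masked <- tot
  masked[ij[valid, , drop = FALSE]] <- -1L
  altIdx <- max.col(masked, ties.method = "first")
  aij <- cbind(seq_len(n), altIdx)
  altCount <- tot[aij]
  qual <- siteQuality(ifelse(valid, refCount, 0L), altCount,
                      params$errorRate)
  emit <- valid & altCount > 0L & qual >= params$minQual &
    pileup$depth_used >= params$minDepth
  gt <- as.integer(altCount / (refCount + altCount) >= params$gtAltFraction)
  out <- data.frame(
    contig = pileup$contig, pos = pileup$pos, ref = refBase,
    alt = BASES[altIdx], qual = qual, depth = pileup$depth_used,
    genotype = gt,
    adf_ref = fwd[ij], adf_alt = fwd[aij],
    adr_ref = rev[ij], adr_alt = rev[aij],
    stringsAsFactors = FALSE)[emit, , drop = FALSE]
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
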