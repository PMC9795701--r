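# Cross-site, cross-omic support criteria for variants called on gut
# contigs, read extraction, per-taxon transfer summaries, and the
# condition-level comparison of transfer abundance distributions.

# Evidence (strand-resolved allele depths and haploid genotype) for a set
# of variant sites from one pileup. Uncovered positions give zero depths
# and NA genotype.
pileupEvidence <- function(pileup, variants, gtAltFraction = 0.5) {
  n <- nrow(variants)
  ev <- data.frame(adf_ref = integer(n), adf_alt = integer(n),
                   adr_ref = integer(n), adr_alt = integer(n),
                   gt = rep(NA_integer_, n))
  if (n == 0L) return(ev)
  universe <- attr(pileup, "contigs")
  if (!is.null(universe) && !all(variants$contig %in% universe))
    stop("pileup is missing contig(s): ",
         paste(setdiff(unique(variants$contig), universe), collapse = ", "))
  key <- paste(variants$contig, variants$pos)
  m <- match(key, paste(pileup$contig, pileup$pos))
  hit <- !is.na(m)
  if (!any(hit)) return(ev)
  fwd <- as.matrix(pileup[m[hit], paste0(BASES, "_fwd"), with = FALSE])
  rv <- as.matrix(pileup[m[hit], paste0(BASES, "_rev"), with = FALSE])
  ii <- seq_len(sum(hit))
  refIdx <- cbind(ii, match(variants$ref[hit], BASES))
  altIdx <- cbind(ii, match(variants$alt[hit], BASES))
  ev$adf_ref[hit] <- fwd[refIdx]; ev$adf_alt[hit] <- fwd[altIdx]
  ev$adr_ref[hit] <- rv[refIdx];  ev$adr_alt[hit] <- rv[altIdx]
  refTot <- ev$adf_ref[hit] + ev$adr_ref[hit]
  altTot <- ev$adf_alt[hit] + ev$adr_alt[hit]
  covered <- refTot + altTot > 0L
  gt <- ifelse(covered,
               as.integer(altTot / (refTot + altTot) >= gtAltFraction),
               NA_integer_)
  ev$gt[hit] <- gt
  ev
}

#' Apply the cross-site, cross-omic support criteria
#'
#' A gut-called variant is retained iff (i) its alternative allele has
#' positive depth on BOTH the forward and reverse strands in BOTH the gut
#' DNA and the oral DNA pileups, and (ii) its haploid genotype is 1 in the
#' oral DNA. Retained variants are classified `MG_MT` when the gut-RNA
#' genotype is also 1, and `MG_only` when the gut-RNA clause fails (no RNA
#' coverage, or genotype 0). All other variants are dropped. The two
#' classes are disjoint and exhaustive over retained variants.
#'
#' @param gutVariants variant `data.frame` from [callVariants()] on the
#'   gut DNA pileup.
#' @param oralDnaPileup,gutDnaPileup,gutRnaPileup [pileupCounts()] outputs
#'   on the same gut contigs (oral DNA pooled across visits).
#' @param gtAltFraction haploid genotype threshold, as in [callParams()].
#' @param genes,contigSeqs optional gene models and contig sequences; when
#'   given, effects are annotated with [annotateVariantEffect()].
#' @param taxonomy optional contig-to-genus table; contigs without an
#'   entry get genus `"unclassified"`.
#' @return `data.frame` of tracked variants: the variant site columns plus
#'   `support_class` (`"MG_MT"`/`"MG_only"`), per-source evidence columns
#'   (`oral_`, `gutdna_`, `gutrna_` prefixes for `adf_ref`, `adf_alt`,
#'   `adr_ref`, `adr_alt`, `gt`), `mp_supported` (initialised `FALSE`;
#'   see [matchVariantPeptides()]), and, when annotation inputs are given,
#'   `effect`, `gene_id`, `residue_index`, `ref_aa`, `alt_aa`, `genus`,
#'   `variant_id`.
#' @export
evaluateCrossSiteCriteria <- function(gutVariants, oralDnaPileup,
                                      gutDnaPileup, gutRnaPileup,
                                      gtAltFraction = 0.5,
                                      genes = NULL, contigSeqs = NULL,
                                      taxonomy = NULL) {
  v <- gutVariants
  oral <- pileupEvidence(oralDnaPileup, v, gtAltFraction)
  gdna <- pileupEvidence(gutDnaPileup, v, gtAltFraction)
  grna <- pileupEvidence(gutRnaPileup, v, gtAltFraction)
  crit1 <- gdna$adf_alt > 0L & gdna$adr_alt > 0L &
    oral$adf_alt > 0L & oral$adr_alt > 0L
  oralGt1 <- !is.na(oral$gt) & oral$gt == 1L
  rnaGt1 <- !is.na(grna$gt) & grna$gt == 1L
  keep <- crit1 & oralGt1
  cls <- ifelse(rnaGt1, "MG_MT", "MG_only")
  names(oral) <- paste0("oral_", names(oral))
  names(gdna) <- paste0("gutdna_", names(gdna))
  names(grna) <- paste0("gutrna_", names(grna))
  out <- cbind(v, support_class = cls, oral, gdna, grna,
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out$mp_supported <- rep(FALSE, nrow(out))
  out$variant_id <- if (nrow(out)) paste0(out$contig, ":", out$pos,
                                          out$ref, ">", out$alt)
                    else character(0)
  if (!is.null(genes) && !is.null(contigSeqs)) {
    ann <- annotateVariantEffect(out, genes, contigSeqs)
    out <- cbind(out, ann[, c("effect", "gene_id", "residue_index",
                              "ref_aa", "alt_aa")])
  }
  if (!is.null(taxonomy)) {
    out$genus <- taxonomy$genus[match(out$contig, taxonomy$contig_id)]
    out$genus[is.na(out$genus)] <- "unclassified"
  }
  rownames(out) <- NULL
  out
}

#' Extract reads carrying tracked variant alleles
#'
#' A read is assigned to a variant iff its alignment covers the variant
#' position and its base there equals the alternative allele; a read
#' covering k variant positions yields k assignments.
#'
#' @param alignments alignment `data.frame` (all-match CIGARs; other
#'   records are ignored).
#' @param tracked `data.frame` with columns `contig`, `pos`, `alt` (and
#'   optionally `variant_id`).
#' @param source label recorded with each assignment (e.g. the sample id).
#' @return `data.frame` with columns `read_id`, `source`, `variant_id`,
#'   `contig`, `pos`.
#' @export
extractVariantReads <- function(alignments, tracked, source = NA_character_) {
  empty <- data.frame(read_id = character(0), source = character(0),
                      variant_id = character(0), contig = character(0),
                      pos = integer(0), stringsAsFactors = FALSE)
  if (nrow(alignments) == 0L || nrow(tracked) == 0L) return(empty)
  len <- suppressWarnings(as.integer(sub("M$", "", alignments$cigar)))
  ok <- grepl("^\\d+M$", alignments$cigar) & !is.na(len) &
    len == nchar(alignments$seq)
  al <- alignments[ok, , drop = FALSE]
  len <- len[ok]
  if (nrow(al) == 0L) return(empty)
  tv <- tracked
  if (!"variant_id" %in% names(tv))
    tv$variant_id <- paste0(tv$contig, ":", tv$pos, tv$ref, ">", tv$alt)
  adt <- data.table(read_id = al$read_id, contig = al$contig,
                    rstart = al$pos, rend = al$pos + len - 1L,
                    seq = al$seq)
  vdt <- data.table(contig = tv$contig, vpos = as.integer(tv$pos),
                    alt = tv$alt, variant_id = tv$variant_id)
  j <- adt[vdt, on = .(contig, rstart <= vpos, rend >= vpos),
           nomatch = NULL,
           .(read_id, contig, vpos = i.vpos, alt = i.alt,
             variant_id = i.variant_id, seq = x.seq, rs = x.rstart)]
  if (nrow(j) == 0L) return(empty)
  j <- j[substr(j$seq, j$vpos - j$rs + 1L, j$vpos - j$rs + 1L) == j$alt]
  if (nrow(j) == 0L) return(empty)
  data.frame(read_id = j$read_id, source = source,
             variant_id = j$variant_id, contig = j$contig, pos = j$vpos,
             stringsAsFactors = FALSE)
}

#' Per-taxon transfer summary across omic layers
#'
#' Sums variant-read assignments per (genus, sample, layer) and variant
#' peptide spectra into the `MP` layer, then derives per (genus, layer)
#' the number of distinct variants, the number of samples with at least
#' one variant observation, and the median number of variants per such
#' sample. Layers follow the support classes: gut DNA reads over `MG_MT`
#' variants form `MG`, gut RNA reads over `MG_MT` variants form `MT`, gut
#' DNA reads over `MG_only` variants form `MG_only`, and variant-peptide
#' spectra form `MP`.
#'
#' @param assignments read assignments with columns `sample_id`, `ome`
#'   (`"MG"`/`"MT"`), `variant_id`, `contig`, `support_class`.
#' @param mpHits variant peptide hits with columns `sample_id`,
#'   `variant_id`, `spectral_count` plus a `contig` column (may be
#'   derived from the variant id).
#' @param taxonomy contig-to-genus table (`contig_id`, `genus`).
#' @return `list(perSample, perGenus)` of `data.frame`s:
#'   `perSample` has `genus`, `sample_id`, `layer`, `n_variants`,
#'   `n_reads_or_spectra`; `perGenus` has `genus`, `layer`, `n_variants`,
#'   `n_samples_with_variants`, `median_variants_per_sample`.
#' @export
taxonVariantAbundance <- function(assignments, mpHits = NULL,
                                  taxonomy = NULL) {
  genusOf <- function(ctg) {
    if (is.null(taxonomy)) return(rep("unclassified", length(ctg)))
    g <- taxonomy$genus[match(ctg, taxonomy$contig_id)]
    g[is.na(g)] <- "unclassified"
    g
  }
  rows <- list()
  if (!is.null(assignments) && nrow(assignments)) {
    a <- as.data.table(assignments)
    a <- a[(a$support_class == "MG_MT" & a$ome %in% c("MG", "MT")) |
             (a$support_class == "MG_only" & a$ome == "MG")]
    a[, layer := ifelse(support_class == "MG_only", "MG_only", ome)]
    a[, genus := genusOf(contig)]
    rows[["reads"]] <- a[, .(n_variants = length(unique(variant_id)),
                             n_reads_or_spectra = .N),
                         by = c("genus", "sample_id", "layer")]
  }
  if (!is.null(mpHits) && nrow(mpHits)) {
    h <- as.data.table(mpHits)
    if (!"contig" %in% names(h))
      h[, contig := sub(":.*$", "", variant_id)]
    h[, genus := genusOf(contig)]
    rows[["mp"]] <- h[, .(n_variants = length(unique(variant_id)),
                          n_reads_or_spectra = sum(spectral_count)),
                      by = c("genus", "sample_id")][, layer := "MP"]
  }
  perSample <- if (length(rows)) {
    ps <- rbindlist(rows, use.names = TRUE)
    setcolorder(ps, c("genus", "sample_id", "layer", "n_variants",
                      "n_reads_or_spectra"))
    setorder(ps, genus, layer, sample_id)
    as.data.frame(ps)
  } else {
    data.frame(genus = character(0), sample_id = character(0),
               layer = character(0), n_variants = integer(0),
               n_reads_or_spectra = integer(0), stringsAsFactors = FALSE)
  }
  pg <- as.data.table(perSample)[
    , .(n_variants = sum(n_variants),
        n_samples_with_variants = .N,
        median_variants_per_sample = median(n_variants)),
    by = c("genus", "layer")]
  list(perSample = perSample, perGenus = as.data.frame(pg))
}

#' Compare transfer abundance between conditions
#'
#' For each (genus, layer), per-sample variant-read (or spectra) totals
#' are compared between T1DM and control with a two-sided Mann-Whitney U
#' test ([groupCompare()]). Samples of the layer's ome with no variant
#' observations count as zeros.
#'
#' @param summary output of [taxonVariantAbundance()].
#' @param metadata sample table with `sample_id`, `condition`, `site`,
#'   `ome` columns.
#' @return `data.frame` with columns `genus`, `layer`, `U`, `p`,
#'   `testable`.
#' @export
compareTransferByCondition <- function(summary, metadata) {
  ps <- summary$perSample
  layerOme <- c(MG = "MG", MG_only = "MG", MT = "MT", MP = "MP")
  combos <- unique(ps[, c("genus", "layer")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    gl <- combos[i, ]
    universe <- metadata[metadata$site == "gut" &
                           metadata$ome == layerOme[[gl$layer]], ]
    vals <- setNames(rep(0, nrow(universe)), universe$sample_id)
    obs <- ps[ps$genus == gl$genus & ps$layer == gl$layer, ]
    vals[obs$sample_id[obs$sample_id %in% names(vals)]] <-
      obs$n_reads_or_spectra[obs$sample_id %in% names(vals)]
    gc <- groupCompare(vals[universe$condition == "T1DM"],
                       vals[universe$condition == "control"])
    data.frame(genus = gl$genus, layer = gl$layer, U = gc$U, p = gc$p,
               testable = gc$testable, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(genus = character(0), layer = character(0),
                      U = numeric(0), p = numeric(0),
                      testable = logical(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
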