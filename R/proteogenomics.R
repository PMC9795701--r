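# Variant effect annotation against CDS gene models, variant-augmented
# protein search databases, and in-silico tryptic variant-peptide matching.

GENCODE <- Biostrings::GENETIC_CODE

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Annotate the coding effect of substitution variants
#'
#' Locates the codon containing each variant with respect to the
#' overlapping CDS gene model (respecting strand and frame; reverse-strand
#' genes are read on the reverse complement) and classifies the change
#' under the standard genetic code: `synonymous` when ref and alt codons
#' translate identically, `missense` for a changed non-stop residue,
#' `nonsense` when the alt codon is a stop, and `intergenic` when no gene
#' model covers the position. Variants falling in an incomplete terminal
#' codon are returned as `intergenic` with a warning.
#'
#' @param variants `data.frame` with columns `contig`, `pos`, `ref`, `alt`.
#' @param genes `GRanges` of CDS models with `gene_id` and `phase`
#'   metadata columns.
#' @param contigSeqs `DNAStringSet` or named character vector of contig
#'   sequences.
#' @return `data.frame` with one row per variant: `effect`, `gene_id`,
#'   `residue_index` (1-based within the protein), `ref_aa`, `alt_aa`,
#'   `ref_codon`, `alt_codon` (`NA` outside genes).
#' @export
annotateVariantEffect <- function(variants, genes, contigSeqs) {
  if (is(contigSeqs, "DNAStringSet")) contigSeqs <-
      setNames(as.character(contigSeqs), names(contigSeqs))
  n <- nrow(variants)
  out <- data.frame(effect = rep("intergenic", n),
                    gene_id = rep(NA_character_, n),
                    residue_index = rep(NA_integer_, n),
                    ref_aa = rep(NA_character_, n),
                    alt_aa = rep(NA_character_, n),
                    ref_codon = rep(NA_character_, n),
                    alt_codon = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  vr <- GenomicRanges::GRanges(variants$contig,
                               IRanges::IRanges(variants$pos,
                                                variants$pos))
  hits <- GenomicRanges::findOverlaps(vr, genes, ignore.strand = TRUE)
  # non-overlapping ORFs assumed: keep the first gene per variant
  hits <- hits[!duplicated(S4Vectors::queryHits(hits))]
  qi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  nWarn <- 0L
  for (k in seq_along(qi)) {
    i <- qi[k]
    g <- genes[gi[k]]
    ph <- g$phase %||% 0L
    if (is.na(ph)) ph <- 0L
    gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
    minus <- as.character(GenomicRanges::strand(g)) == "-"
    cds0 <- if (minus) (ge - ph) - variants$pos[i]
            else variants$pos[i] - (gs + ph)
    if (cds0 < 0L) { nWarn <- nWarn + 1L; next }
    codonIdx <- cds0 %/% 3L
    within <- cds0 %% 3L
    if (minus) {
      cEnd <- ge - ph - 3L * codonIdx
      cStart <- cEnd - 2L
      if (cStart < gs) { nWarn <- nWarn + 1L; next }
      refCodon <- revcompChar(substr(contigSeqs[[variants$contig[i]]],
                                     cStart, cEnd))
      altB <- COMPLEMENT[[variants$alt[i]]]
    } else {
      cStart <- gs + ph + 3L * codonIdx
      cEnd <- cStart + 2L
      if (cEnd > ge) { nWarn <- nWarn + 1L; next }
      refCodon <- substr(contigSeqs[[variants$contig[i]]], cStart, cEnd)
      altB <- variants$alt[i]
    }
    altCodon <- refCodon
    substr(altCodon, within + 1L, within + 1L) <- altB
    refAa <- unname(GENCODE[refCodon])
    altAa <- unname(GENCODE[altCodon])
    eff <- if (identical(refAa, altAa)) "synonymous"
           else if (identical(altAa, "*")) "nonsense"
           else "missense"
    out$effect[i] <- eff
    out$gene_id[i] <- g$gene_id
    out$residue_index[i] <- codonIdx + 1L
    out$ref_aa[i] <- refAa
    out$alt_aa[i] <- altAa
    out$ref_codon[i] <- refCodon
    out$alt_codon[i] <- altCodon
  }
  if (nWarn > 0L)
    warning(nWarn, " variant(s) fell in an incomplete terminal codon; ",
            "classified intergenic")
  out
}

#' Variant proteins for missense variants
#'
#' One protein per (gene, missense variant): the gene's reference protein
#' with the single substituted residue.
#'
#' @param variants `data.frame` with columns `contig`, `pos`, `ref`, `alt`
#'   and (from [annotateVariantEffect()]) `effect`, `gene_id`,
#'   `residue_index`, `alt_aa`, `ref_aa`; rows whose effect is not
#'   `missense` are ignored.
#' @param genes,contigSeqs as in [annotateVariantEffect()].
#' @return `data.frame` with columns `protein_id`, `sequence`,
#'   `variant_residue_index`, `ref_aa`, `alt_aa`, `variant_id`, `gene_id`.
#' @export
variantProteins <- function(variants, genes, contigSeqs) {
  if (is(contigSeqs, "DNAStringSet")) contigSeqs <-
      setNames(as.character(contigSeqs), names(contigSeqs))
  mis <- variants[variants$effect %in% "missense", , drop = FALSE]
  out <- data.frame(protein_id = character(0), sequence = character(0),
                    variant_residue_index = integer(0),
                    ref_aa = character(0), alt_aa = character(0),
                    variant_id = character(0), gene_id = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(mis) == 0L) return(out)
  if (!"variant_id" %in% names(mis))
    mis$variant_id <- paste0(mis$contig, ":", mis$pos, mis$ref, ">",
                             mis$alt)
  rows <- vector("list", nrow(mis))
  for (i in seq_len(nrow(mis))) {
    g <- genes[genes$gene_id == mis$gene_id[i]]
    if (length(g) == 0L) next
    prot <- geneProtein(g[1], contigSeqs)
    idx <- mis$residue_index[i]
    if (is.na(idx) || idx > nchar(prot)) next
    substr(prot, idx, idx) <- mis$alt_aa[i]
    rows[[i]] <- data.frame(
      protein_id = paste0(mis$gene_id[i], "|", mis$variant_id[i]),
      sequence = prot, variant_residue_index = idx,
      ref_aa = mis$ref_aa[i], alt_aa = mis$alt_aa[i],
      variant_id = mis$variant_id[i], gene_id = mis$gene_id[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(variantProteins(mis[0, ], genes, contigSeqs))
  rownames(out) <- NULL
  out
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal of K or R except when the next residue is P, retains
#' peptides with up to `missedCleavages` internal sites, and applies the
#' length filter. Spans are 1-based inclusive residue coordinates in the
#' parent protein.
#'
#' @param protein amino-acid sequence (single string).
#' @param missedCleavages maximum internal missed cleavage sites.
#' @param minLen,maxLen peptide length bounds.
#' @return `data.frame` with columns `peptide`, `start`, `end`,
#'   `missed`.
#' @export
trypticDigest <- function(protein, missedCleavages = 0L, minLen = 7L,
                          maxLen = 50L) {
  stopifnot(nchar(protein) > 0L)
  chars <- strsplit(protein, "")[[1]]
  np <- length(chars)
  cut <- which(chars %in% c("K", "R"))
  cut <- cut[cut < np & chars[pmin(cut + 1L, np)] != "P"]
  bounds <- c(0L, cut, np)
  nb <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nb)) {
    for (m in 0:missedCleavages) {
      j <- i + m
      if (j > nb) break
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      rows[[length(rows) + 1L]] <- c(s, e, m)
    }
  }
  sp <- do.call(rbind, rows)
  pep <- substring(protein, sp[, 1], sp[, 2])
  out <- data.frame(peptide = pep, start = sp[, 1], end = sp[, 2],
                    missed = sp[, 3], stringsAsFactors = FALSE)
  out[nchar(out$peptide) >= minLen & nchar(out$peptide) <= maxLen, ,
      drop = FALSE]
}

#' Select the protein database for a sample with individual/family fallback
#'
#' Uses the sample's own database when available; otherwise concatenates
#' all databases of the sample's individual; otherwise all databases of
#' the individual's family; otherwise raises an error naming the family.
#'
#' @param sampleId sample to search.
#' @param available named list mapping sample ids to named character
#'   vectors of protein sequences.
#' @param metadata sample table resolving `sample_id` to `individual` and
#'   `family`.
#' @return `list(proteins = named character, provenance = "sample" |
#'   "individual" | "family")`.
#' @export
selectDatabase <- function(sampleId, available, metadata) {
  row <- metadata[metadata$sample_id == sampleId, ]
  if (nrow(row) != 1L) stop("unknown sample_id: ", sampleId)
  if (sampleId %in% names(available))
    return(list(proteins = available[[sampleId]], provenance = "sample"))
  sibs <- metadata$sample_id[metadata$individual == row$individual]
  pool <- available[intersect(sibs, names(available))]
  if (length(pool))
    return(list(proteins = do.call(c, unname(pool)),
                provenance = "individual"))
  fam <- metadata$sample_id[metadata$family == row$family]
  pool <- available[intersect(fam, names(available))]
  if (length(pool))
    return(list(proteins = do.call(c, unname(pool)),
                provenance = "family"))
  stop("no protein database available at any level for family ",
       row$family)
}

#' Build a size-filtered, deduplicated target-decoy search database
#'
#' Pools microbial, variant, host and contaminant proteins; removes
#' sequences outside `[minLen, maxLen]` residues; collapses exact sequence
#' duplicates keeping the lexicographically smallest id; appends reversed
#' decoys with a `DECOY_` prefix.
#'
#' @param microbial,variant,host,contaminants named character vectors of
#'   uppercase amino-acid sequences (any may be empty).
#' @param minLen,maxLen residue-length bounds (defaults 60 and 40000).
#' @param provenance free-form provenance tag stored on the result.
#' @return `list(entries = named character (targets then decoys),
#'   nTargets, provenance, decoysIncluded = TRUE)`, class
#'   `"SearchDatabase"`.
#' @export
buildSearchDatabase <- function(microbial, variant = character(0),
                                host = character(0),
                                contaminants = character(0),
                                minLen = 60L, maxLen = 40000L,
                                provenance = "sample") {
  pool <- c(microbial, variant, host, contaminants)
  if (is.null(names(pool)) || any(!nzchar(names(pool))))
    stop("all proteins must be named")
  len <- nchar(pool)
  pool <- pool[len >= minLen & len <= maxLen]
  if (length(pool) == 0L)
    stop("empty database after size filtering")
  ord <- order(names(pool))
  pool <- pool[ord]
  pool <- pool[!duplicated(unname(pool))]
  pool <- pool[order(names(pool))]
  decoys <- setNames(
    vapply(pool, function(s)
      paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1)),
    paste0("DECOY_", names(pool)))
  structure(list(entries = c(pool, decoys), nTargets = length(pool),
                 provenance = provenance, decoysIncluded = TRUE),
            class = "SearchDatabase")
}

#' @export
print.SearchDatabase <- function(x, ...) {
  cat("SearchDatabase:", x$nTargets, "targets +",
      length(x$entries) - x$nTargets, "decoys (provenance:",
      paste0(x$provenance, ")\n"))
  invisible(x)
}

databaseTargets <- function(db) {
  db$entries[seq_len(db$nTargets)]
}

#' Match observed peptides to variant-spanning tryptic peptides
#'
#' A hit requires an observed peptide to equal, by exact string match, a
#' tryptic peptide of a variant protein that spans the variant residue and
#' that does not occur among the tryptic peptides of the reference
#' (non-variant) proteome. Spectral counts are carried through. Only
#' missense variants can produce hits, since only they yield variant
#' proteins.
#'
#' @param observed `data.frame` with columns `sample_id`, `peptide`,
#'   `spectral_count`.
#' @param variantProteins output of [variantProteins()].
#' @param referenceProteins named character vector of reference protein
#'   sequences.
#' @param missedCleavages,minLen,maxLen digestion settings (defaults: up
#'   to 2 missed cleavages, peptide length 7-50).
#' @return `data.frame` with columns `sample_id`, `peptide`,
#'   `spectral_count`, `variant_id`, `protein_id`.
#' @export
matchVariantPeptides <- function(observed, variantProteins,
                                 referenceProteins,
                                 missedCleavages = 2L, minLen = 7L,
                                 maxLen = 50L) {
  empty <- data.frame(sample_id = character(0), peptide = character(0),
                      spectral_count = integer(0),
                      variant_id = character(0), protein_id = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(observed) == 0L || nrow(variantProteins) == 0L) return(empty)
  refPeps <- unique(unlist(lapply(referenceProteins, function(p)
    trypticDigest(p, missedCleavages, minLen, maxLen)$peptide),
    use.names = FALSE))
  vp <- lapply(seq_len(nrow(variantProteins)), function(i) {
    dig <- trypticDigest(variantProteins$sequence[i], missedCleavages,
                         minLen, maxLen)
    idx <- variantProteins$variant_residue_index[i]
    dig <- dig[dig$start <= idx & dig$end >= idx, , drop = FALSE]
    dig <- dig[!dig$peptide %in% refPeps, , drop = FALSE]
    if (nrow(dig) == 0L) return(NULL)
    data.frame(peptide = unique(dig$peptide),
               variant_id = variantProteins$variant_id[i],
               protein_id = variantProteins$protein_id[i],
               stringsAsFactors = FALSE)
  })
  vp <- do.call(rbind, vp[!vapply(vp, is.null, logical(1))])
  if (is.null(vp)) return(empty)
  hits <- merge(observed[, c("sample_id", "peptide", "spectral_count")],
                vp, by = "peptide")
  hits <- hits[, c("sample_id", "peptide", "spectral_count", "variant_id",
                   "protein_id")]
  hits <- hits[order(hits$sample_id, hits$variant_id, hits$peptide), ]
  rownames(hits) <- NULL
  hits
}
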