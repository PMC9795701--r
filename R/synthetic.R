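# Synthetic multi-omic cohort generator.
#
# The generator plants strain variants on a simulated gut co-assembly and
# draws, per individual, whether each oral variant also reached the gut
# (Bernoulli with a per-(genus, condition) transmission probability). DNA,
# RNA and peptide observations are then simulated from that ground truth so
# the whole tracking pipeline can be exercised and scored against the ledger.

SENSE_CODONS <- local({
  cods <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  cods[!cods %in% c("TAA", "TAG", "TGA")]
})

# ORFs are kept >= readLength away from contig ends, and planted variants
# >= readLength - 1 away from ORF boundaries, so that uniform read placement
# yields full fold-coverage at every variant position (no edge attenuation).
orfLayout <- function(contigLength, orfLength, readLength, gap = 30L) {
  lo <- readLength + 1L
  hi <- contigLength - readLength
  starts <- seq.int(lo, by = orfLength + gap, length.out = 64L)
  starts[starts + orfLength - 1L <= hi]
}

#' Generate a synthetic cohort with planted, partially transmitted variants
#'
#' Builds a family-structured cohort (conditions assigned deterministically
#' at alternating positions within each family so both conditions occur in
#' every family), a random gut co-assembly with in-frame non-overlapping
#' ORFs, a per-contig taxonomy, and a set of planted substitution variants
#' per genus. Every planted variant is carried by each individual's oral
#' strain; its presence in that individual's gut is drawn
#' `Bernoulli(transmissionProb[genus, condition])`. Output is deterministic
#' for a fixed seed.
#'
#' @param config a [CohortConfig-class], see [cohortConfig()].
#' @return a [Cohort-class] holding the assembly, sample sheet and the full
#'   ground-truth ledger.
#' @examples
#' cfg <- cohortConfig(nFamilies = 1L, individualsPerFamily = 2L, seed = 1L)
#' coh <- generateCohort(cfg)
#' coh
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  withSeed(config@seed, .generateCohort(config))
}

.generateCohort <- function(config) {
  taxa <- config@taxa
  rl <- config@readLength
  orfLen <- config@orfLength

  ## sample sheet ------------------------------------------------------------
  fams <- sprintf("F%02d", seq_len(config@nFamilies))
  k <- config@individualsPerFamily
  nT <- max(1L, min(k - 1L, round(config@t1dmFraction * k)))
  ord <- c(seq.int(1L, k, 2L), if (k > 1L) seq.int(2L, k, 2L))
  condPattern <- rep("control", k)
  condPattern[ord[seq_len(nT)]] <- "T1DM"
  indiv <- as.vector(vapply(fams, function(f)
    paste0(f, ".", seq_len(k)), character(k)))
  indTab <- data.frame(
    individual = indiv,
    family = rep(fams, each = k),
    condition = rep(condPattern, config@nFamilies),
    stringsAsFactors = FALSE)
  omes <- data.frame(
    site = c("oral", "gut", "gut", "gut"),
    ome = c("MG", "MG", "MT", "MP"),
    stringsAsFactors = FALSE)
  st <- merge(
    merge(indTab, data.frame(visit = seq_len(config@visitsPerIndividual))),
    omes)
  st <- st[order(st$individual, st$visit, st$site, st$ome), ]
  st$sample_id <- paste(st$individual, paste0("V", st$visit),
                        st$site, st$ome, sep = "_")
  rownames(st) <- NULL
  st <- st[, c("sample_id", "individual", "family", "visit",
               "condition", "site", "ome")]

  ## contigs, ORFs, taxonomy -------------------------------------------------
  contigSeqs <- character(0)
  geneRows <- list()
  taxRows <- list()
  for (ti in seq_len(nrow(taxa))) {
    genus <- taxa$genus[ti]
    L <- taxa$contig_length[ti]
    starts <- orfLayout(L, orfLen, rl)
    if (length(starts) == 0L)
      stop("taxon '", genus, "': contig_length ", L,
           " too short to host an ORF of ", orfLen,
           " bp with read-length margins")
    for (ci in seq_len(taxa$n_contigs[ti])) {
      cname <- paste0(genus, "_c", ci)
      seqChars <- sample(BASES, L, replace = TRUE)
      for (gi in seq_along(starts)) {
        body <- sample(SENSE_CODONS, orfLen / 3L - 2L, replace = TRUE)
        orf <- paste0("ATG", paste(body, collapse = ""), "TAA")
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") orf <- revcompChar(orf)
        idx <- starts[gi]:(starts[gi] + orfLen - 1L)
        seqChars[idx] <- strsplit(orf, "")[[1]]
        geneRows[[length(geneRows) + 1L]] <- data.frame(
          gene_id = paste0(cname, "_g", gi), contig = cname,
          start = starts[gi], end = starts[gi] + orfLen - 1L,
          strand = strand, stringsAsFactors = FALSE)
      }
      contigSeqs[cname] <- paste(seqChars, collapse = "")
      taxRows[[length(taxRows) + 1L]] <- data.frame(
        contig_id = cname, genus = genus, stringsAsFactors = FALSE)
    }
  }
  genesDf <- do.call(rbind, geneRows)
  genesDf$expressed <- runif(nrow(genesDf)) < config@expressedFraction
  genesDf$expr_weight <- ifelse(genesDf$expressed,
                                runif(nrow(genesDf), 0.75, 1.5), 0)
  taxonomy <- do.call(rbind, taxRows)

  contigSet <- Biostrings::DNAStringSet(contigSeqs)
  genes <- GenomicRanges::GRanges(
    seqnames = genesDf$contig,
    ranges = IRanges::IRanges(genesDf$start, genesDf$end),
    strand = genesDf$strand,
    gene_id = genesDf$gene_id,
    phase = 0L,
    expressed = genesDf$expressed,
    expr_weight = genesDf$expr_weight,
    seqlengths = setNames(nchar(contigSeqs), names(contigSeqs)))

  ## planted variants --------------------------------------------------------
  varRows <- list()
  for (ti in seq_len(nrow(taxa))) {
    genus <- taxa$genus[ti]
    ctgs <- taxonomy$contig_id[taxonomy$genus == genus]
    cand <- list()
    for (cname in ctgs) {
      L <- nchar(contigSeqs[[cname]])
      ok <- rep(FALSE, L)
      ok[rl:(L - rl + 1L)] <- TRUE
      g <- genesDf[genesDf$contig == cname, ]
      for (gi in seq_len(nrow(g))) {
        span <- g$start[gi]:g$end[gi]
        ok[span] <- FALSE
        interior <- span[span >= g$start[gi] + rl - 1L &
                           span <= g$end[gi] - rl + 1L]
        ok[interior] <- TRUE
      }
      pos <- which(ok)
      unit <- character(length(pos))
      for (gi in seq_len(nrow(g))) {
        inG <- pos >= g$start[gi] & pos <= g$end[gi]
        unit[inG] <- g$gene_id[gi]
      }
      cand[[cname]] <- data.frame(contig = cname, pos = pos, unit = unit,
                                  stringsAsFactors = FALSE)
    }
    cand <- do.call(rbind, cand)
    # at most one variant per gene: variant proteins model exactly one
    # substituted residue, so co-occurring in-gene variants are not planted
    sh <- cand[sample.int(nrow(cand)), ]
    sh <- sh[!nzchar(sh$unit) | !duplicated(sh$unit), , drop = FALSE]
    if (nrow(sh) < config@variantsPerTaxon)
      stop("taxon '", genus, "': contigs too short to host ",
           config@variantsPerTaxon, " variants away from ORF/contig edges")
    pick <- sh[seq_len(config@variantsPerTaxon), c("contig", "pos")]
    pick <- pick[order(pick$contig, pick$pos), ]
    pick$ref <- substr(contigSeqs[pick$contig], pick$pos, pick$pos)
    pick$alt <- vapply(pick$ref,
                       function(r) sample(setdiff(BASES, r), 1L),
                       character(1), USE.NAMES = FALSE)
    pick$genus <- genus
    varRows[[genus]] <- pick
  }
  variants <- do.call(rbind, varRows)
  rownames(variants) <- NULL
  variants$variant_id <- paste0(variants$contig, ":", variants$pos,
                                variants$ref, ">", variants$alt)
  ann <- annotateVariantEffect(variants, genes, contigSet)
  variants$gene_id <- ann$gene_id
  variants$effect <- ann$effect
  variants$residue_index <- ann$residue_index
  variants$ref_aa <- ann$ref_aa
  variants$alt_aa <- ann$alt_aa
  variants <- variants[, c("variant_id", "contig", "pos", "ref", "alt",
                           "genus", "gene_id", "effect", "residue_index",
                           "ref_aa", "alt_aa")]

  ## per-individual transmission --------------------------------------------
  tp <- config@transmissionProb
  trans <- merge(indTab, variants[, c("variant_id", "genus")])
  trans <- trans[order(trans$individual, trans$variant_id), ]
  pr <- tp$prob[match(paste(trans$genus, trans$condition),
                      paste(tp$genus, tp$condition))]
  if (any(is.na(pr)))
    stop("transmissionProb is missing (genus, condition) combinations")
  trans$present_in_oral <- TRUE
  trans$present_in_gut <- runif(nrow(trans)) < pr
  trans <- trans[, c("individual", "variant_id",
                     "present_in_oral", "present_in_gut")]
  rownames(trans) <- NULL

  variants$present_in_oral <- TRUE
  agg <- tapply(trans$present_in_gut, trans$variant_id, any)
  variants$present_in_gut <- as.logical(agg[variants$variant_id])

  coh <- new("Cohort", config = config, sampleTable = st,
             contigs = contigSet, genes = genes, taxonomy = taxonomy,
             variants = variants, transmission = trans)
  validObject(coh)
  coh
}

# Alleles carried by one individual's strain at a given body site.
individualAlleles <- function(cohort, individual, site) {
  tr <- cohort@transmission
  tr <- tr[tr$individual == individual, ]
  keep <- if (site == "oral") tr$present_in_oral else tr$present_in_gut
  v <- cohort@variants
  v[v$variant_id %in% tr$variant_id[keep], , drop = FALSE]
}

applyAlleles <- function(contigSeqs, alleles) {
  if (nrow(alleles) == 0L) return(contigSeqs)
  for (i in seq_len(nrow(alleles)))
    substr(contigSeqs[alleles$contig[i]],
           alleles$pos[i], alleles$pos[i]) <- alleles$alt[i]
  contigSeqs
}

emptyAlignments <- function() {
  data.frame(read_id = character(0), contig = character(0),
             pos = integer(0), strand = character(0), cigar = character(0),
             seq = character(0), qual = character(0),
             stringsAsFactors = FALSE)
}

# Draw reads with uniform starts over [lo, hi] windows; one row per window.
drawReads <- function(windows, seqs, n, rl, errorRate, qualChar, prefix) {
  out <- list()
  for (i in seq_len(nrow(windows))) {
    ni <- n[i]
    if (ni == 0L) next
    starts <- windows$lo[i] + sample.int(windows$hi[i] - windows$lo[i] + 1L,
                                         ni, replace = TRUE) - 1L
    sq <- substring(seqs[[windows$contig[i]]], starts, starts + rl - 1L)
    strand <- ifelse(runif(ni) < 0.5, "+", "-")
    out[[length(out) + 1L]] <- data.frame(
      contig = windows$contig[i], pos = starts, strand = strand, seq = sq,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(emptyAlignments())
  reads <- do.call(rbind, out)
  nr <- nrow(reads)
  if (errorRate > 0) {
    chars <- matrix(unlist(strsplit(reads$seq, ""), use.names = FALSE),
                    nrow = rl)
    hit <- which(runif(length(chars)) < errorRate)
    if (length(hit)) {
      # substitute uniformly among the three other bases
      shift <- sample.int(3L, length(hit), replace = TRUE)
      cur <- match(chars[hit], BASES)
      chars[hit] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
      reads$seq <- apply(chars, 2L, paste, collapse = "")
    }
  }
  data.frame(read_id = sprintf("%s_r%06d", prefix, seq_len(nr)),
             contig = reads$contig, pos = reads$pos, strand = reads$strand,
             cigar = paste0(rl, "M"), seq = reads$seq,
             qual = strrep(qualChar, rl), stringsAsFactors = FALSE)
}

#' Simulate aligned reads for one cohort sample
#'
#' DNA reads (`MG`) are placed uniformly along every contig with per-strand
#' fold-coverage `coverageDna` scaled by the taxon's abundance weight at the
#' sample's body site; RNA reads (`MT`) are placed within expressed ORFs
#' with fold-coverage `coverageRna` scaled by the gene's expression weight.
#' Reads drawn from a contig carrying one of the individual's variants (as
#' recorded in the transmission ledger for that body site) carry the
#' alternative base; sequencing errors then flip bases uniformly at
#' `baseErrorRate`. Roughly half of the reads fall on each strand. Base
#' qualities are constant at the Phred equivalent of the error rate (capped
#' at 40), so a binomial caller's error model is exact on these data.
#'
#' @param cohort a [Cohort-class].
#' @param sampleId a `sample_id` from `sampleTable(cohort)` with ome MG or
#'   MT.
#' @return alignment records as a `data.frame` with columns `read_id`,
#'   `contig`, `pos` (1-based), `strand` (`+`/`-`), `cigar` (all-match),
#'   `seq`, `qual`.
#' @export
simulateAlignments <- function(cohort, sampleId) {
  st <- cohort@sampleTable
  row <- st[st$sample_id == sampleId, ]
  if (nrow(row) != 1L)
    stop("unknown sample_id: ", sampleId)
  if (!row$ome %in% c("MG", "MT"))
    stop("alignments are simulated for MG/MT samples only")
  cfg <- cohort@config
  rl <- cfg@readLength
  seed <- deriveSeed(cfg@seed, match(sampleId, st$sample_id))
  withSeed(seed, {
    alleles <- individualAlleles(cohort, row$individual, row$site)
    seqs <- applyAlleles(as.character(cohort@contigs), alleles)
    qc <- phredToChar(phredFromError(cfg@baseErrorRate))
    if (row$ome == "MG") {
      wcol <- if (row$site == "oral") "oral_weight" else "gut_weight"
      w <- setNames(cfg@taxa[[wcol]], cfg@taxa$genus)
      tax <- cohort@taxonomy
      L <- nchar(seqs)
      windows <- data.frame(contig = names(seqs), lo = 1L,
                            hi = pmax(1L, L - rl + 1L),
                            stringsAsFactors = FALSE)
      cov <- 2 * cfg@coverageDna * w[tax$genus[match(windows$contig,
                                                     tax$contig_id)]]
      n <- rpois(nrow(windows), cov * (windows$hi - windows$lo + 1L) / rl)
      drawReads(windows, seqs, n, rl, cfg@baseErrorRate, qc, sampleId)
    } else {
      g <- cohort@genes
      g <- g[g$expressed]
      if (length(g) == 0L) return(emptyAlignments())
      windows <- data.frame(
        contig = as.character(GenomicRanges::seqnames(g)),
        lo = GenomicRanges::start(g),
        hi = GenomicRanges::end(g) - rl + 1L,
        stringsAsFactors = FALSE)
      keep <- windows$hi >= windows$lo
      windows <- windows[keep, ]
      nStarts <- windows$hi - windows$lo + 1L
      n <- rpois(nrow(windows),
                 cfg@coverageRna * g$expr_weight[keep] * nStarts / rl)
      drawReads(windows, seqs, n, rl, cfg@baseErrorRate, qc, sampleId)
    }
  })
}

#' Simulate peptide observations for one metaproteomic sample
#'
#' The individual's gut proteome is taken to be the proteins of all
#' expressed genes, with the individual's transmitted variants applied at
#' the DNA level before translation (nonsense variants truncate). Proteins
#' are digested in silico with trypsin (no missed cleavages, peptide length
#' 7-50) and `Poisson(peptideDepth)` spectra are allocated to peptides
#' multinomially with weights proportional to the parent gene's expression.
#' A peptide is flagged `is_variant_spanning` when its span covers an
#' applied variant's codon and its sequence does not occur in the reference
#' (non-variant) digest.
#'
#' @param cohort a [Cohort-class].
#' @param sampleId a gut `MP` `sample_id` from `sampleTable(cohort)`.
#' @return `data.frame` with columns `sample_id`, `peptide`,
#'   `spectral_count`, `is_variant_spanning`, `gene_id`.
#' @export
simulatePeptideObservations <- function(cohort, sampleId) {
  st <- cohort@sampleTable
  row <- st[st$sample_id == sampleId, ]
  if (nrow(row) != 1L) stop("unknown sample_id: ", sampleId)
  if (!(row$ome == "MP" && row$site == "gut"))
    stop("peptides are simulated for gut MP samples only")
  cfg <- cohort@config
  empty <- data.frame(sample_id = character(0), peptide = character(0),
                      spectral_count = integer(0),
                      is_variant_spanning = logical(0),
                      gene_id = character(0), pep_start = integer(0),
                      pep_end = integer(0), variant_ids = character(0),
                      stringsAsFactors = FALSE)
  seed <- deriveSeed(cfg@seed, match(sampleId, st$sample_id) + 10000L)
  withSeed(seed, {
    alleles <- individualAlleles(cohort, row$individual, "gut")
    refSeqs <- as.character(cohort@contigs)
    mutSeqs <- applyAlleles(refSeqs, alleles)
    g <- cohort@genes
    g <- g[g$expressed]
    if (length(g) == 0L || cfg@peptideDepth <= 0) return(empty)
    refPeps <- character(0)
    cand <- list()
    for (i in seq_along(g)) {
      gi <- g[i]
      refProt <- geneProtein(gi, refSeqs)
      mutProt <- geneProtein(gi, mutSeqs)
      refDig <- trypticDigest(refProt, missedCleavages = 0L)
      refPeps <- c(refPeps, refDig$peptide)
      dig <- trypticDigest(mutProt, missedCleavages = 0L)
      if (nrow(dig) == 0L) next
      dig$gene_id <- gi$gene_id
      dig$weight <- gi$expr_weight
      gv <- alleles[!is.na(alleles$gene_id) &
                      alleles$gene_id == gi$gene_id &
                      alleles$effect == "missense", , drop = FALSE]
      dig$variant_ids <- vapply(seq_len(nrow(dig)), function(j)
        paste(gv$variant_id[gv$residue_index >= dig$start[j] &
                              gv$residue_index <= dig$end[j]],
              collapse = ","), character(1))
      cand[[length(cand) + 1L]] <- dig
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand) || nrow(cand) == 0L) return(empty)
    cand$is_variant_spanning <- !(cand$peptide %in% refPeps) &
      nzchar(cand$variant_ids)
    nSpectra <- rpois(1L, cfg@peptideDepth)
    if (nSpectra == 0L) return(empty)
    counts <- as.vector(rmultinom(1L, nSpectra,
                                  cand$weight / sum(cand$weight)))
    keep <- counts > 0L
    out <- data.frame(sample_id = sampleId, peptide = cand$peptide[keep],
                      spectral_count = counts[keep],
                      is_variant_spanning = cand$is_variant_spanning[keep],
                      gene_id = cand$gene_id[keep],
                      pep_start = cand$start[keep],
                      pep_end = cand$end[keep],
                      variant_ids = ifelse(cand$is_variant_spanning[keep],
                                           cand$variant_ids[keep], ""),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

# Protein sequence of a gene model from named contig character sequences,
# truncated at the first stop codon.
geneProtein <- function(gene, contigSeqs) {
  cds <- substr(contigSeqs[[as.character(GenomicRanges::seqnames(gene))]],
                GenomicRanges::start(gene), GenomicRanges::end(gene))
  if (as.character(GenomicRanges::strand(gene)) == "-")
    cds <- revcompChar(cds)
  ph <- gene$phase %||% 0L
  if (ph > 0L) cds <- substr(cds, ph + 1L, nchar(cds))
  aa <- translateCds(cds)
  sub("\\*.*$", "", aa)
}

#' Write a cohort's files to a directory
#'
#' Emits the gut co-assembly FASTA, the gene models as GFF3 (`CDS`
#' features, 1-based inclusive, with strand and frame), the contig
#' taxonomy, the sample metadata, and the truth ledger (planted variants
#' and the per-individual transmission table) as TSV.
#'
#' @param cohort a [Cohort-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "contigs.fasta"),
    gff = file.path(dir, "genes.gff3"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    variants = file.path(dir, "truth_variants.tsv"),
    transmission = file.path(dir, "truth_transmission.tsv"))
  Biostrings::writeXStringSet(cohort@contigs, paths["fasta"])
  g <- cohort@genes
  gff <- g
  S4Vectors::mcols(gff) <- S4Vectors::DataFrame(
    type = "CDS", ID = g$gene_id, phase = g$phase,
    expressed = tolower(as.character(g$expressed)))
  rtracklayer::export(gff, paths["gff"], format = "gff3")
  writeTsv(cohort@taxonomy, paths["taxonomy"])
  writeTsv(cohort@sampleTable, paths["metadata"])
  writeTsv(cohort@variants, paths["variants"])
  writeTsv(cohort@transmission, paths["transmission"])
  invisible(paths)
}
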