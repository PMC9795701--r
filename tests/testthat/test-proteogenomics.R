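# Variant effect annotation, tryptic digestion, database assembly with
# the size/dedup/decoy rules, the database fallback chain, and variant
# peptide matching.

test_that("canonical codon changes classify correctly on both strands", {
  # gene ATG | GAA | TAC | TAA; third codon position changes
  fx <- oneGeneFixture("ATGGAATACTAA")
  # GAA -> GAG (Glu -> Glu): synonymous
  v <- data.frame(contig = "ctg", pos = fx$start + 5L, ref = "A",
                  alt = "G", stringsAsFactors = FALSE)
  ann <- annotateVariantEffect(v, fx$genes, fx$contigs)
  expect_identical(ann$effect, "synonymous")
  expect_identical(ann$residue_index, 2L)
  # GAA -> GAT (Glu -> Asp): missense with alt residue D
  v$alt <- "T"
  ann <- annotateVariantEffect(v, fx$genes, fx$contigs)
  expect_identical(ann$effect, "missense")
  expect_identical(ann$alt_aa, "D")
  # TAC -> TAA: nonsense
  v2 <- data.frame(contig = "ctg", pos = fx$start + 8L, ref = "C",
                   alt = "A", stringsAsFactors = FALSE)
  expect_identical(annotateVariantEffect(v2, fx$genes,
                                         fx$contigs)$effect, "nonsense")
  # outside any gene: intergenic
  v3 <- data.frame(contig = "ctg", pos = 2L, ref = "C", alt = "A",
                   stringsAsFactors = FALSE)
  expect_identical(annotateVariantEffect(v3, fx$genes,
                                         fx$contigs)$effect, "intergenic")

  # minus-strand gene: same codon change read on the reverse complement
  fxm <- oneGeneFixture("ATGGAATACTAA", strand = "-")
  # genomic position of the 3rd base of codon 2 (GAA) on the minus strand
  gpos <- fxm$end - 5L
  refBase <- substr(fxm$seq, gpos, gpos)  # complement of A = T
  vm <- data.frame(contig = "ctg", pos = gpos, ref = refBase, alt = "C",
                   stringsAsFactors = FALSE)  # G on cds = GAG
  annm <- annotateVariantEffect(vm, fxm$genes, fxm$contigs)
  expect_identical(annm$effect, "synonymous")
  expect_identical(annm$residue_index, 2L)
})

test_that("effect annotation matches full-protein translation for all
          single-base codon changes", {
  # oracle: mutate the full CDS, translate the whole protein with
  # Biostrings, and compare proteins residue by residue
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  translateFull <- function(cds) {
    as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                       no.init.codon = TRUE))
  }
  for (strand in c("+", "-")) {
    for (codon in codons) {
      cds <- paste0("ATG", codon, "TGGTAA")
      fx <- oneGeneFixture(cds, strand = strand)
      for (cpos in 1:3) {
        refB <- substr(codon, cpos, cpos)
        for (altB in setdiff(bases, refB)) {
          gpos <- if (strand == "+") fx$start + 2L + cpos
                  else fx$end - 2L - cpos
          refG <- substr(fx$seq, gpos, gpos)
          altG <- if (strand == "+") altB else
            chartr("ACGT", "TGCA", altB)
          v <- data.frame(contig = "ctg", pos = gpos, ref = refG,
                          alt = altG, stringsAsFactors = FALSE)
          ann <- annotateVariantEffect(v, fx$genes, fx$contigs)
          mutCds <- cds
          substr(mutCds, 3L + cpos, 3L + cpos) <- altB
          refProt <- strsplit(translateFull(cds), "")[[1]]
          altProt <- strsplit(translateFull(mutCds), "")[[1]]
          diffIdx <- which(refProt != altProt)
          expected <- if (length(diffIdx) == 0L) "synonymous"
                      else if (altProt[diffIdx] == "*") "nonsense"
                      else "missense"
          expect_identical(ann$effect, expected,
                           label = paste(strand, codon, cpos, altB))
          if (length(diffIdx) == 1L) {
            expect_identical(ann$residue_index, diffIdx + 0L)
            expect_identical(ann$ref_aa, refProt[diffIdx])
            expect_identical(ann$alt_aa, altProt[diffIdx])
          }
        }
      }
    }
  }
})

test_that("variants in incomplete terminal codons are flagged", {
  fx <- oneGeneFixture("ATGGAATACTAA")
  genes2 <- fx$genes
  GenomicRanges::end(genes2) <- fx$end - 1L  # truncate: last codon broken
  v <- data.frame(contig = "ctg", pos = fx$end - 1L, ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  expect_warning(ann <- annotateVariantEffect(v, genes2, fx$contigs),
                 "incomplete terminal codon")
  expect_identical(ann$effect, "intergenic")
})

test_that("tryptic digestion follows the K/R rule with the KP exception", {
  d <- trypticDigest("MAAAAAAKGGGGGGR", 0L)
  expect_identical(d$peptide, c("MAAAAAAK", "GGGGGGR"))
  expect_identical(d$start, c(1L, 9L))
  expect_identical(d$end, c(8L, 15L))

  d2 <- trypticDigest("MAAAAKPGGGGGGR", 0L)
  expect_identical(d2$peptide, "MAAAAKPGGGGGGR")

  # missed cleavages include composite peptides
  d3 <- trypticDigest("MAAAAAAKGGGGGGR", 1L)
  expect_true("MAAAAAAKGGGGGGR" %in% d3$peptide)

  # partition property: 0-missed peptides reconstruct the protein
  set.seed(1)
  for (i in 1:10) {
    prot <- paste(sample(c(LETTERS[1:20], "K", "R", "P"), 80,
                         replace = TRUE), collapse = "")
    d <- trypticDigest(prot, 0L, minLen = 1L, maxLen = 1000L)
    expect_identical(paste(d$peptide, collapse = ""), prot)
    expect_identical(d$start[1], 1L)
    expect_identical(d$end[nrow(d)], nchar(prot))
  }
})

test_that("database assembly filters by size, dedups by sequence, and
          doubles with decoys", {
  p59 <- strrep("A", 59); p60 <- strrep("A", 60)
  db <- buildSearchDatabase(c(a = p60, b = strrep("C", 70)))
  expect_identical(db$nTargets, 2L)
  expect_identical(length(db$entries), 4L)
  expect_true(all(grepl("^DECOY_", names(db$entries)[3:4])))
  expect_identical(unname(db$entries[["DECOY_b"]]), strrep("C", 70))

  expect_error(buildSearchDatabase(c(tiny = p59)), "empty database")
  db2 <- buildSearchDatabase(c(short = p59, ok = p60))
  expect_identical(db2$nTargets, 1L)
  expect_identical(names(db2$entries)[1], "ok")

  # duplicates collapse to the lexicographically smallest id
  db3 <- buildSearchDatabase(c(zeta = p60, alpha = p60))
  expect_identical(db3$nTargets, 1L)
  expect_identical(names(db3$entries)[1], "alpha")

  # idempotence on targets
  t1 <- mouth2gut:::databaseTargets(db3)
  db4 <- buildSearchDatabase(t1)
  expect_identical(mouth2gut:::databaseTargets(db4), t1)

  # reversed decoy sequence
  seqAB <- paste0(strrep("A", 30), strrep("W", 30))
  db5 <- buildSearchDatabase(c(x = seqAB))
  expect_identical(unname(db5$entries[["DECOY_x"]]),
                   paste0(strrep("W", 30), strrep("A", 30)))
})

test_that("database selection falls back sample -> individual -> family", {
  meta <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    individual = c("I1", "I1", "I2", "I3"),
    family = c("F1", "F1", "F1", "F2"), stringsAsFactors = FALSE)
  av <- list(s1 = c(p1 = "SEQ1"), s2 = c(p2 = "SEQ2"), s3 = c(p3 = "SEQ3"))

  r <- selectDatabase("s1", av, meta)
  expect_identical(r$provenance, "sample")
  expect_identical(r$proteins, c(p1 = "SEQ1"))

  # s2 removed: individual-level concatenation for I1's other sample
  r2 <- selectDatabase("s2", av[c("s1", "s3")], meta)
  expect_identical(r2$provenance, "individual")
  expect_identical(r2$proteins, c(p1 = "SEQ1"))

  # individual has none: family concatenation
  r3 <- selectDatabase("s3", av[c("s1", "s2")], meta)
  expect_identical(r3$provenance, "family")
  expect_identical(sort(names(r3$proteins)), c("p1", "p2"))

  # nothing anywhere: error names the family
  expect_error(selectDatabase("s4", av[0], meta), "F2")
})

test_that("variant peptide matching requires span and specificity", {
  refProt <- c(g1 = "MAAAAAAKGGGGGGRDDDDDDDK")
  # variant at residue 4: A -> W
  varSeq <- refProt[["g1"]]
  substr(varSeq, 4, 4) <- "W"
  vp <- data.frame(protein_id = "g1|v1", sequence = varSeq,
                   variant_residue_index = 4L, ref_aa = "A", alt_aa = "W",
                   variant_id = "v1", gene_id = "g1",
                   stringsAsFactors = FALSE)
  obs <- data.frame(sample_id = "m1",
                    peptide = c("MAAWAAAK",     # variant-spanning
                                "GGGGGGR",      # shared with reference
                                "ZZZZZZZ"),     # not in any digest
                    spectral_count = c(3L, 5L, 1L),
                    stringsAsFactors = FALSE)
  hits <- matchVariantPeptides(obs, vp, refProt)
  expect_identical(hits$peptide, "MAAWAAAK")
  expect_identical(hits$spectral_count, 3L)
  expect_identical(hits$variant_id, "v1")

  # a variant peptide identical to a reference peptide is not a hit:
  # plant the "variant" so the resulting peptide also exists in reference
  vp2 <- vp; vp2$sequence <- refProt[["g1"]]
  hits2 <- matchVariantPeptides(
    data.frame(sample_id = "m1", peptide = "MAAAAAAK",
               spectral_count = 2L, stringsAsFactors = FALSE),
    vp2, refProt)
  expect_identical(nrow(hits2), 0L)

  # peptides not covering the variant residue never match
  hits3 <- matchVariantPeptides(
    data.frame(sample_id = "m1", peptide = "DDDDDDDK",
               spectral_count = 2L, stringsAsFactors = FALSE),
    vp, refProt)
  expect_identical(nrow(hits3), 0L)
})
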