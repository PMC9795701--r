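# The cohort generator: determinism, degenerate probabilities, coverage
# and strand-balance contracts, and truth-ledger consistency.

test_that("generation is byte-identical under a fixed seed", {
  cfg <- quickCfg(seed = 7L)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- writeCohort(c1, d1)
  p2 <- writeCohort(c2, d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     label = paste("file", k))
  s <- sampleTable(c1)$sample_id[sampleTable(c1)$ome == "MG"][1]
  expect_identical(simulateAlignments(c1, s), simulateAlignments(c2, s))
  mp <- sampleTable(c1)$sample_id[sampleTable(c1)$ome == "MP"][1]
  expect_identical(simulatePeptideObservations(c1, mp),
                   simulatePeptideObservations(c2, mp))
})

test_that("degenerate transmission probabilities give all-or-none transfer", {
  c0 <- generateCohort(quickCfg(transmissionProb = 0, seed = 5L))
  expect_false(any(plantedVariants(c0)$present_in_oral &
                     plantedVariants(c0)$present_in_gut))
  expect_false(any(transmissionLedger(c0)$present_in_gut))

  taxa3 <- data.frame(genus = c("Prevotella", "Streptococcus",
                                "Bacteroides"),
                      n_contigs = 1L, contig_length = 800L,
                      oral_weight = 1, gut_weight = 1)
  c1 <- generateCohort(quickCfg(taxa = taxa3, variantsPerTaxon = 5L,
                                transmissionProb = 1, seed = 5L))
  v <- plantedVariants(c1)
  expect_identical(sum(v$present_in_oral & v$present_in_gut), 15L)
  expect_true(all(transmissionLedger(c1)$present_in_gut))
})

test_that("conditions alternate within families so both occur in each", {
  coh <- generateCohort(quickCfg(nFamilies = 2L,
                                 individualsPerFamily = 4L))
  st <- unique(sampleTable(coh)[, c("individual", "family", "condition")])
  byFam <- split(st$condition, st$family)
  for (f in byFam) expect_setequal(unique(f), c("T1DM", "control"))
})

test_that("zero coverage yields no reads and reads honour the error model", {
  coh0 <- generateCohort(quickCfg(coverageDna = 0, coverageRna = 0,
                                  seed = 3L))
  st <- sampleTable(coh0)
  for (s in st$sample_id[st$ome %in% c("MG", "MT")][1:4])
    expect_identical(nrow(simulateAlignments(coh0, s)), 0L)

  # error-free channel: every read overlapping a gut-present variant
  # carries the alt base, and no other read carries a non-reference base
  coh <- generateCohort(quickCfg(seed = 13L))
  st <- sampleTable(coh)
  ind <- st$individual[1]
  gut <- st$sample_id[st$individual == ind & st$site == "gut" &
                        st$ome == "MG"][1]
  al <- simulateAlignments(coh, gut)
  tr <- transmissionLedger(coh)
  v <- plantedVariants(coh)
  present <- v[v$variant_id %in%
                 tr$variant_id[tr$individual == ind & tr$present_in_gut], ]
  refSeqs <- as.character(contigs(coh))
  for (i in seq_len(nrow(al))) {
    len <- nchar(al$seq[i])
    ref <- substr(refSeqs[[al$contig[i]]], al$pos[i], al$pos[i] + len - 1L)
    mism <- which(strsplit(al$seq[i], "")[[1]] != strsplit(ref, "")[[1]])
    for (k in mism) {
      p <- al$pos[i] + k - 1L
      hit <- present$contig == al$contig[i] & present$pos == p
      expect_true(any(hit), label = paste("mismatch at", al$contig[i], p))
      expect_identical(substr(al$seq[i], k, k), present$alt[hit])
    }
  }
  # and every variant-overlapping read carries alt
  for (j in seq_len(nrow(present))) {
    over <- al[al$contig == present$contig[j] &
                 al$pos <= present$pos[j] &
                 al$pos + nchar(al$seq) - 1L >= present$pos[j], ]
    if (nrow(over) == 0L) next
    bases <- substr(over$seq, present$pos[j] - over$pos + 1L,
                    present$pos[j] - over$pos + 1L)
    expect_true(all(bases == present$alt[j]))
  }
})

test_that("per-strand depth and strand balance match the coverage model", {
  cfg <- quickCfg(nFamilies = 1L, individualsPerFamily = 1L,
                  coverageDna = 30, seed = 21L,
                  taxa = data.frame(genus = "Prevotella", n_contigs = 4L,
                                    contig_length = 5000L,
                                    oral_weight = 1, gut_weight = 1))
  coh <- generateCohort(cfg)
  st <- sampleTable(coh)
  al <- simulateAlignments(coh, st$sample_id[st$site == "gut" &
                                               st$ome == "MG"][1])
  expect_gt(nrow(al), 10000)  # ~ 2*30*20000/100 = 12000 reads
  fracFwd <- mean(al$strand == "+")
  expect_gte(fracFwd, 0.45); expect_lte(fracFwd, 0.55)
  # brute-force per-position depth at interior positions, per strand
  rl <- 100L
  for (ctg in unique(al$contig)) {
    a <- al[al$contig == ctg, ]
    for (p in c(1500L, 3000L)) {
      for (s in c("+", "-")) {
        d <- sum(a$strand == s & a$pos <= p & a$pos + rl - 1L >= p)
        # Poisson(30) sampling bounds (~6 sd)
        expect_gt(d, 5); expect_lt(d, 70)
      }
    }
  }
})

test_that("peptide emission respects depth, expression and variant truth", {
  coh0 <- generateCohort(quickCfg(peptideDepth = 0, seed = 31L))
  st <- sampleTable(coh0)
  mp <- st$sample_id[st$ome == "MP"]
  expect_identical(nrow(simulatePeptideObservations(coh0, mp[1])), 0L)

  # large depth: every transmitted missense variant in an expressed gene
  # yields at least one variant-spanning peptide
  coh <- generateCohort(quickCfg(
    peptideDepth = 20000, transmissionProb = 1, expressedFraction = 1,
    variantsPerTaxon = 6L, seed = 33L,
    taxa = data.frame(genus = c("Prevotella", "Streptococcus"),
                      n_contigs = 1L, contig_length = 1200L,
                      oral_weight = 1, gut_weight = 1)))
  st <- sampleTable(coh)
  v <- plantedVariants(coh)
  g <- geneModels(coh)
  expressed <- setNames(g$expressed, g$gene_id)
  target <- v[v$effect == "missense" & expressed[v$gene_id], ]
  expect_gt(nrow(target), 0)
  mp1 <- st$sample_id[st$ome == "MP"][1]
  obs <- simulatePeptideObservations(coh, mp1)
  expect_true(all(obs$spectral_count >= 1L))
  spanned <- unlist(strsplit(obs$variant_ids[obs$is_variant_spanning], ","))
  # oracle: enumerate the tryptic peptides of the variant protein that
  # cover the variant residue and differ from the reference digest; a
  # variant is emittable iff at least one exists
  vp <- variantProteins(target, g, contigs(coh))
  refPeps <- unlist(lapply(unique(target$gene_id), function(gid) {
    gg <- g[g$gene_id == gid]
    trypticDigest(mouth2gut:::geneProtein(
      gg, as.character(contigs(coh))), 0L)$peptide
  }))
  for (i in seq_len(nrow(vp))) {
    dig <- trypticDigest(vp$sequence[i], 0L)
    idx <- vp$variant_residue_index[i]
    cov <- dig[dig$start <= idx & dig$end >= idx, ]
    emittable <- nrow(cov) > 0 && any(!cov$peptide %in% refPeps)
    expect_identical(vp$variant_id[i] %in% spanned, emittable,
                     label = vp$variant_id[i])
  }

  # no transmission => no variant-spanning peptides
  cohN <- generateCohort(quickCfg(transmissionProb = 0, seed = 33L))
  stN <- sampleTable(cohN)
  obsN <- simulatePeptideObservations(cohN,
                                      stN$sample_id[stN$ome == "MP"][1])
  expect_false(any(obsN$is_variant_spanning))
})

test_that("impossible layouts raise configuration errors naming the taxon", {
  bad <- data.frame(genus = "Tinybug", n_contigs = 1L, contig_length = 350L,
                    oral_weight = 1, gut_weight = 1)
  expect_error(generateCohort(quickCfg(taxa = bad)), "Tinybug")
})

test_that("truth ledger is internally consistent", {
  coh <- generateCohort(quickCfg(seed = 41L))
  v <- plantedVariants(coh)
  seqs <- as.character(contigs(coh))
  expect_true(all(substr(seqs[v$contig], v$pos, v$pos) == v$ref))
  expect_true(all(v$ref != v$alt))
  expect_true(all(v$pos >= 1 & v$pos <= nchar(seqs[v$contig])))
})
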