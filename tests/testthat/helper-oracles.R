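# Shared fixtures and independent brute-force oracles used across the
# suite. Oracles deliberately use naive loops / closed forms so they stay
# independent of the implementation paths they check.

mkRead <- function(read_id, contig, pos, strand, seq) {
  data.frame(read_id = read_id, contig = contig, pos = as.integer(pos),
             strand = strand, cigar = paste0(nchar(seq), "M"), seq = seq,
             qual = strrep("I", nchar(seq)), stringsAsFactors = FALSE)
}

mkReads <- function(...) do.call(rbind, list(...))

# O(reads x positions) recount of strand-resolved allele depths with
# per-position truncation in ascending (pos, read_id) order.
naivePileup <- function(alignments, maxDepth = 1000L) {
  al <- alignments[grepl("^\\d+M$", alignments$cigar), , drop = FALSE]
  al <- al[order(al$pos, al$read_id), , drop = FALSE]
  res <- list()
  for (i in seq_len(nrow(al))) {
    len <- nchar(al$seq[i])
    for (k in seq_len(len)) {
      p <- al$pos[i] + k - 1L
      b <- substr(al$seq[i], k, k)
      if (!b %in% c("A", "C", "G", "T")) next
      key <- paste(al$contig[i], p)
      cell <- res[[key]]
      if (is.null(cell))
        cell <- list(n = 0L,
                     cnt = matrix(0L, 2, 4,
                                  dimnames = list(c("fwd", "rev"),
                                                  c("A", "C", "G", "T"))))
      if (cell$n >= maxDepth) next
      s <- if (al$strand[i] == "+") "fwd" else "rev"
      cell$cnt[s, b] <- cell$cnt[s, b] + 1L
      cell$n <- cell$n + 1L
      res[[key]] <- cell
    }
  }
  res
}

# compare a pileupCounts() table against the naive recount with a single
# expectation per instance (both rendered as sorted count tables)
expectPileupMatchesNaive <- function(pileup, naive) {
  keys <- paste(pileup$contig, pileup$pos)
  expect_setequal(keys, names(naive))
  cols <- as.vector(outer(c("A", "C", "G", "T"), c("fwd", "rev"),
                          paste, sep = "_"))
  got <- as.matrix(as.data.frame(pileup)[, c(cols, "depth_used")])
  rownames(got) <- keys
  want <- t(vapply(keys, function(k) {
    cell <- naive[[k]]
    c(cell$cnt["fwd", ], cell$cnt["rev", ], depth_used = cell$n)
  }, integer(9)))
  colnames(want) <- c(cols[1:4], cols[5:8], "depth_used")
  expect_identical(got[order(keys), , drop = FALSE],
                   want[order(keys), , drop = FALSE])
}

# brute-force binomial tail as an explicit sum of density terms
bruteTailQual <- function(nRef, nAlt, e) {
  n <- nRef + nAlt
  if (nAlt == 0 || n == 0) return(0)
  tail <- sum(vapply(nAlt:n, function(k) choose(n, k) * e^k * (1 - e)^(n - k),
                     numeric(1)))
  min(-10 * log10(tail), 255)
}

bruteSimpson <- function(x) {
  p <- x / sum(x)
  1 - sum(p^2)
}

bruteBray <- function(u, v) {
  1 - 2 * sum(pmin(u, v)) / (sum(u) + sum(v))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
bruteMWW <- function(a, b) {
  vals <- c(a, b)
  n1 <- length(a)
  U <- sum(rank(vals)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(vals), n1)
  us <- apply(combs, 2, function(idx)
    sum(rank(vals)[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
  list(U = U, p = p)
}

bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# small, fast cohort configuration for tests
quickCfg <- function(...) {
  args <- list(...)
  defaults <- list(nFamilies = 1L, individualsPerFamily = 2L,
                   visitsPerIndividual = 1L,
                   taxa = data.frame(genus = c("Prevotella",
                                               "Streptococcus"),
                                     n_contigs = 1L, contig_length = 800L,
                                     oral_weight = 1, gut_weight = 1),
                   variantsPerTaxon = 5L, transmissionProb = 0.5,
                   coverageDna = 20, coverageRna = 15,
                   baseErrorRate = 0, peptideDepth = 200,
                   readLength = 100L, seed = 101L)
  defaults[names(args)] <- args
  do.call(cohortConfig, defaults)
}

# a one-gene fixture: contig with a single plus- or minus-strand ORF
oneGeneFixture <- function(orf, strand = "+", pad5 = 12L, pad3 = 12L) {
  insert <- if (strand == "-")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
  else orf
  seq <- paste0(strrep("C", pad5), insert, strrep("C", pad3))
  contigs <- Biostrings::DNAStringSet(c(ctg = seq))
  genes <- GenomicRanges::GRanges(
    "ctg", IRanges::IRanges(pad5 + 1L, pad5 + nchar(orf)), strand,
    gene_id = "g1", phase = 0L, expressed = TRUE, expr_weight = 1)
  list(contigs = contigs, genes = genes, seq = seq,
       start = pad5 + 1L, end = pad5 + nchar(orf))
}
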