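#' @import methods
#' @importFrom stats median p.adjust pbinom pt rmultinom rpois
#'   runif setNames wilcox.test cor
#' @importFrom utils read.delim write.table head
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
withSeed <- function(seed, expr) {
  if (!is.null(globalenv()$.Random.seed)) {
    old <- globalenv()$.Random.seed
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

# Deterministic per-stream seed derived from a master seed; keeps results
# independent across streams (samples, replicates) but reproducible.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %%
               (.Machine$integer.max - 1L)) + 1L
}

BASES <- c("A", "C", "G", "T")

# Random DNA of length n as a plain character string.
randomDna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

revcompChar <- function(x) {
  vapply(x, function(s)
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", s)))),
    character(1), USE.NAMES = FALSE)
}

translateCds <- function(cds) {
  # drop incomplete trailing codon if any, translate (standard code),
  # drop terminal stop
  n <- nchar(cds) - nchar(cds) %% 3
  if (n < 3L) return("")
  codons <- substring(cds, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  sub("\\*$", "", paste(aa, collapse = ""))
}

# phred-scaled integer quality for a per-base error rate, capped at 40
phredFromError <- function(e) {
  if (e <= 0) return(40L)
  as.integer(min(40, round(-10 * log10(e))))
}

phredToChar <- function(q) {
  vapply(q, function(x) rawToChar(as.raw(x + 33L)), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
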