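---
title: "Tracking oral-to-gut strain-variant transmission with mouth2gut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking oral-to-gut strain-variant transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mouth2gut)
```

## The problem

Saliva continuously seeds the gastrointestinal tract with oral microbes,
but only some of them survive the gastric barrier and colonise the gut.
Species-level profiles are too coarse to show that a gut population
actually descends from the mouth of the same person: many species are
resident at both sites as distinct, locally adapted strains. Strain
variants — substitution alleles that distinguish co-occurring
conspecific strains — make the link observable. If the same alternative
allele is seen in the oral DNA and in the gut DNA of an individual, and
additionally in the gut RNA or as a variant peptide, the variant is not
only transferred but carried by an active population.

`mouth2gut` implements this cross-omic tracking logic as a testable
pipeline: strand-resolved pileups and substitution-variant calling on
gut contigs; cross-site support criteria; variant effect annotation
against CDS gene models; variant-augmented protein search databases with
in-silico tryptic variant-peptide matching; per-taxon transfer
summaries; and the accompanying count-matrix statistics (visit medians,
prevalence filters, richness and Simpson diversity, Bray-Curtis,
Mann-Whitney, Spearman/BH screening). A synthetic family-structured
cohort generator with planted, partially transmitted variants makes the
whole chain scoreable against ground truth.

## Variant calling model

`pileupCounts()` counts, per position and strand, how many all-match
reads contribute each base. Coverage above `maxDepth` (default 1000) is
truncated deterministically in ascending (position, read id) order —
unlike a sampling caller, re-running the pipeline gives identical
output.

The site quality is an explicit binomial tail: with `nRef` reference and
`nAlt` alternative reads and an assumed per-base error rate $e$,

$$Q = -10\,\log_{10} P\!\left(X \ge n_{alt}\right),
  \qquad X \sim \mathrm{Binom}(n_{ref}+n_{alt},\, e),$$

capped at 255. This keeps the conventional filter thresholds — site
quality at least 20, used depth at least 10 — meaningful, and the score
is independently checkable by summing binomial densities. The
alternative allele at a site is the non-reference base with the highest
total count (ties broken alphabetically); only substitutions are
considered, indel-containing records are skipped and tallied. The
genotype model is haploid consensus: GT = 1 iff the alternative fraction
among (ref + alt) reads is at least `gtAltFraction` (default 0.5; an
exact tie gives 1), matching microbial contigs where a swept strain
dominates.

The caller's assumed error rate defaults to the cohort's base error rate
floored at $10^{-3}$, so the quality model stays defined for error-free
simulations.

## Cross-site, cross-omic support criteria

A variant called on the gut DNA of an individual is retained iff

1. its alternative allele has positive depth on **both** strands in
   **both** the gut DNA and the (visit-pooled) oral DNA, and
2. its genotype is 1 in the oral DNA.

Retained variants are `MG_MT` when the gut RNA genotype is also 1, and
`MG_only` when the RNA clause fails — either no RNA coverage at the
position or a reference-dominated genotype. The two classes are
disjoint and exhaustive over retained variants. "Positive allelic
depth" is interpreted as the *alternative* allele's depth, since the
criterion exists to reinforce confidence in the alternative call.
Gut-DNA genotype is deliberately not constrained: a minority transferred
strain can still be tracked as long as both strands carry the allele.

Oral reads from all visits are pooled before the criteria are
evaluated; the package also pools gut DNA and RNA across visits within
an individual, because visits share the same strain variants and
downstream statistics aggregate visits by medians anyway.

## Proteogenomic support

Missense variants (located by codon against the CDS model, respecting
strand and frame, standard genetic code) each yield one variant protein
with exactly one substituted residue. Search databases follow the
conventional assembly rules: pool microbial, variant, host and
contaminant sequences; drop proteins outside 60–40,000 residues;
collapse exact duplicate sequences keeping the lexicographically
smallest identifier; append reversed `DECOY_` entries. When a sample
has no database of its own, the fallback chain concatenates the
individual's databases, then the family's.

A variant peptide hit requires an observed peptide to exactly match a
tryptic peptide of a variant protein that spans the substituted residue
*and* is absent from the digest of the reference proteome (trypsin
C-terminal of K/R except before P, up to 2 missed cleavages, length
7–50). Spectral search, PSM scoring and FDR control are out of scope:
observed peptides enter as a table, as from a search engine export
filtered upstream.

## The synthetic cohort

`generateCohort()` emulates a multiplex-family cohort: `nFamilies`
families of `individualsPerFamily`, conditions (T1DM / control)
assigned deterministically at alternating positions within each family
so both conditions occur in every family; `visitsPerIndividual`
repeated visits that share the individual's variants and differ only by
sampling noise. The gut co-assembly is random DNA with non-overlapping
in-frame ORFs (ATG start, internal sense codons, TAA stop); contigs are
assigned to genera; a fraction of genes (default 0.7) is expressed with
lognormal-ish weights in [0.75, 1.5].

Planted variants are substitutions only. Every planted variant is
carried by each individual's oral strain; its presence in that
individual's gut is Bernoulli with the per-(genus, condition)
transmission probability. Transmitted variants are modeled as swept
(all gut reads carry the alternative base before sequencing error),
which makes the haploid genotype rule exact.

Three placement rules keep the truth ledger and the detection contracts
consistent:

* variants sit at least a read length from contig ends, so uniform DNA
  read placement yields full fold-coverage at every variant site;
* variants inside genes sit at least a read length from the ORF
  boundaries, and RNA reads are placed strictly within ORFs, so an
  expressed gene guarantees full RNA coverage at its variants and
  intergenic variants get none;
* at most one variant is planted per gene, because variant proteins
  carry exactly one substituted residue — two variants inside one
  tryptic peptide would produce peptides that no single-variant protein
  can match (multi-variant haplotypes are out of scope).

Reads have fixed length, uniform starts, Poisson-distributed counts per
contig (DNA; per-strand mean coverage `coverageDna` scaled by the
taxon's site weight) or per expressed gene (RNA; total mean
`coverageRna` scaled by expression weight), a Bernoulli(1/2) strand,
and bases flipped uniformly at `baseErrorRate`. Base qualities are
constant at the Phred equivalent of the error rate (capped at 40), so
the caller's binomial error model is exact on these data. Peptide
observations allocate Poisson(`peptideDepth`) spectra multinomially
over the tryptic peptides (no missed cleavages) of expressed,
variant-applied proteins, weighted by gene expression.

What the generator does **not** emulate — and hence what green tests do
not show about real data: strain mixtures below the consensus
threshold, paired-end and indel-containing reads, coverage biases and
chimeras, within-species co-assembly collapse, per-read taxonomic
misclassification (taxonomy is a fixed contig-to-genus table), and the
mass-spectrometry acquisition process.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `coverageDna` | 30 | mean DNA fold-coverage per strand |
| `coverageRna` | 20 | mean total RNA fold-coverage of expressed genes |
| `baseErrorRate` | 0.001 | per-base substitution error |
| `minQual` / `minDepth` / `maxDepth` | 20 / 10 / 1000 | calling filters |
| `gtAltFraction` | 0.5 | haploid genotype threshold (tie gives 1) |
| `variantsPerTaxon` | 10 | planted variants per genus |
| `transmissionProb` | 0.5 | flat per-(genus, condition) default |
| `peptideDepth` | 300 | expected spectra per MP sample |
| prevalence filter | 20 reads / 10 spectra in 25% of individuals | feature retention |
| network thresholds | rho 0.7, adjusted p 0.001 | transcript-taxon screening |

The per-sample coverages are package choices — the source cohort does
not pin per-contig coverage — selected so that a 30x/20x desk-scale
simulation leaves negligible probability of a strand dropping out at a
variant site.

## Worked example

```{r example, eval = FALSE}
cfg <- cohortConfig(nFamilies = 2L, individualsPerFamily = 4L,
                    visitsPerIndividual = 3L, baseErrorRate = 0,
                    seed = 11L)
coh <- generateCohort(cfg)
res <- trackTransmission(coh)
scoreRecovery(res, coh)
head(res$tracked[, c("individual", "variant_id", "support_class",
                     "effect", "genus", "mp_supported")])
res$summary$perGenus
```

On this error-free cohort every transmitted variant is recovered
(sensitivity 1, no false detections), support classes equal the truth
ledger's expression flags, and every transmitted missense variant whose
variant peptide was actually emitted gains `mp_supported`.

## Numerical and design choices

* **Deterministic truncation** above `maxDepth` instead of read
  sampling: reproducibility over fidelity to the external caller.
* **Alphabetical tie-break** for the alternative allele; multi-allelic
  sites keep only the majority alternative, since the support criteria
  are defined for a single alternative allele.
* **Exact Mann-Whitney** for groups of at most 8 without ties, normal
  approximation with tie and continuity correction otherwise; two
  identical constant groups give p = 1; groups under 2 observations are
  flagged not testable rather than erroring.
* **Spearman p-values** from the t approximation with average ranks for
  ties (the common `rcorr`-style route); BH adjustment is applied
  within each analysis family (one network, one correlation battery),
  not globally.
* **Median over visits** with the even-count mean convention;
  permutation-invariant by construction.
* Degenerate inputs are flagged, not fatal: all-zero samples in
  diversity/dissimilarity give `NA` with a warning; constant features
  are excluded from correlation screens with a flag.

Problem sizes used by the tests and the acceptance script (2 families x
4 individuals x 3 visits at 30x/20x for recovery; 15 families x 2 for
the differential-transmission power analysis at 15x; 20–50 replicates
for power and correlation-structure rates) are package choices that keep
a full run on a single CPU within minutes while leaving the detection
contracts sharp.

## Limitations

The taxonomy of variant reads comes from the contig-to-genus table, not
per-read classification — a deliberate, deterministic stand-in. The
pipeline tracks variants within individuals only; cross-individual
strain sharing, haplotype phasing and SNV-distance transmission scores
are out of scope, as are differential-abundance model fitting
(matrices are prepared for it) and ordination methods.
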