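#' Configuration for a synthetic oral-gut cohort
#'
#' An S4 container holding every parameter of the synthetic-cohort generator:
#' the family structure, the taxa and their contigs, the number of planted
#' strain variants, per-(genus, condition) transmission probabilities, read
#' coverage and error model, and peptide sampling depth.
#'
#' @slot nFamilies number of families in the cohort.
#' @slot individualsPerFamily individuals recruited per family.
#' @slot t1dmFraction fraction of individuals labelled T1DM; conditions are
#'   assigned deterministically within each family (alternating positions) so
#'   every family contains both conditions.
#' @slot visitsPerIndividual repeated sampling visits per individual.
#' @slot taxa `data.frame` with columns `genus`, `n_contigs`,
#'   `contig_length`, `oral_weight`, `gut_weight`.
#' @slot variantsPerTaxon strain variants planted per genus.
#' @slot transmissionProb `data.frame` with columns `genus`, `condition`,
#'   `prob`: per-individual probability that a planted oral variant is also
#'   present in that individual's gut.
#' @slot coverageDna mean DNA fold-coverage per strand.
#' @slot coverageRna mean total RNA fold-coverage over expressed genes.
#' @slot baseErrorRate per-base sequencing error probability.
#' @slot peptideDepth expected number of spectra per metaproteomic sample.
#' @slot readLength simulated read length in bp.
#' @slot orfLength length in bp of each simulated ORF (multiple of 3).
#' @slot expressedFraction fraction of genes given nonzero expression.
#' @slot seed master seed; all randomness derives from it.
#'
#' @seealso [cohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig", representation(
  nFamilies = "integer",
  individualsPerFamily = "integer",
  t1dmFraction = "numeric",
  visitsPerIndividual = "integer",
  taxa = "data.frame",
  variantsPerTaxon = "integer",
  transmissionProb = "data.frame",
  coverageDna = "numeric",
  coverageRna = "numeric",
  baseErrorRate = "numeric",
  peptideDepth = "numeric",
  readLength = "integer",
  orfLength = "integer",
  expressedFraction = "numeric",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  chkProb <- function(p, what) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
      msg <<- c(msg, paste0(what, " must lie in [0, 1]"))
  }
  chkPos <- function(x, what) {
    if (any(is.na(x)) || any(x <= 0))
      msg <<- c(msg, paste0(what, " must be > 0"))
  }
  chkProb(object@t1dmFraction, "t1dmFraction")
  chkProb(object@baseErrorRate, "baseErrorRate")
  chkProb(object@expressedFraction, "expressedFraction")
  chkPos(object@nFamilies, "nFamilies")
  chkPos(object@individualsPerFamily, "individualsPerFamily")
  chkPos(object@visitsPerIndividual, "visitsPerIndividual")
  chkPos(object@variantsPerTaxon, "variantsPerTaxon")
  chkPos(object@readLength, "readLength")
  chkPos(object@orfLength, "orfLength")
  if (object@coverageDna < 0) msg <- c(msg, "coverageDna must be >= 0")
  if (object@coverageRna < 0) msg <- c(msg, "coverageRna must be >= 0")
  if (object@peptideDepth < 0) msg <- c(msg, "peptideDepth must be >= 0")
  need <- c("genus", "n_contigs", "contig_length", "oral_weight", "gut_weight")
  if (!all(need %in% names(object@taxa))) {
    msg <- c(msg, paste0("taxa must have columns ",
                         paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(object@taxa$genus))
      msg <- c(msg, "genus names must be unique")
    chkPos(object@taxa$n_contigs, "taxa$n_contigs")
    chkPos(object@taxa$contig_length, "taxa$contig_length")
    if (any(object@taxa$oral_weight < 0) || any(object@taxa$gut_weight < 0))
      msg <- c(msg, "abundance weights must be >= 0")
  }
  if (!all(c("genus", "condition", "prob") %in%
             names(object@transmissionProb))) {
    msg <- c(msg, "transmissionProb must have columns genus, condition, prob")
  } else {
    chkProb(object@transmissionProb$prob, "transmissionProb$prob")
  }
  if (object@orfLength %% 3L != 0L)
    msg <- c(msg, "orfLength must be a multiple of 3")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort with its complete ground truth
#'
#' Returned by [generateCohort()]. Besides the simulated gut co-assembly
#' (contigs, gene models, contig-level taxonomy) and the sample sheet, the
#' object keeps the generator's truth ledger: the planted strain variants,
#' the per-individual transmission status of each variant, and per-gene
#' expression weights. Downstream recovery tests compare pipeline output
#' against these slots.
#'
#' @slot config the [CohortConfig-class] used.
#' @slot sampleTable `data.frame` with one row per (individual, visit, site,
#'   ome) sample: `sample_id`, `individual`, `family`, `visit`, `condition`,
#'   `site`, `ome`.
#' @slot contigs `DNAStringSet` of gut co-assembly contigs.
#' @slot genes `GRanges` of CDS gene models (`gene_id`, `phase`,
#'   `expressed`, `expr_weight` metadata columns).
#' @slot taxonomy `data.frame` mapping `contig_id` to `genus`.
#' @slot variants `data.frame` of planted variants: `variant_id`, `contig`,
#'   `pos`, `ref`, `alt`, `genus`, `gene_id` (`NA` when intergenic),
#'   `effect`, `present_in_oral`, `present_in_gut` (cohort-level: present in
#'   at least one individual).
#' @slot transmission `data.frame` with one row per (individual, variant):
#'   `individual`, `variant_id`, `present_in_oral`, `present_in_gut`.
#'
#' @seealso [generateCohort()], [simulateAlignments()],
#'   [simulatePeptideObservations()]
#' @export
setClass("Cohort", representation(
  config = "CohortConfig",
  sampleTable = "data.frame",
  contigs = "DNAStringSet",
  genes = "GRanges",
  taxonomy = "data.frame",
  variants = "data.frame",
  transmission = "data.frame"
))

setValidity("Cohort", function(object) {
  msg <- character(0)
  v <- object@variants
  if (nrow(v)) {
    if (!all(v$contig %in% names(object@contigs))) {
      msg <- c(msg, "every planted variant must lie on a known contig")
    } else {
      cl <- setNames(Biostrings::width(object@contigs),
                     names(object@contigs))[v$contig]
      if (any(v$pos < 1 | v$pos > cl))
        msg <- c(msg, "variant positions must lie within their contig")
      refs <- substr(as.character(object@contigs[v$contig]), v$pos, v$pos)
      if (any(refs != v$ref))
        msg <- c(msg, "variant ref base must equal the contig base")
    }
    if (any(v$ref == v$alt))
      msg <- c(msg, "variant ref and alt must differ")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CohortConfig-class Construct a cohort configuration. Defaults
#'   describe a family-structured T1DM cohort: 8 families of 4 with roughly
#'   half the individuals T1DM, three visits each, three genera commonly
#'   observed in oral-gut transfer, ten planted variants per genus, a flat
#'   transmission probability of 0.5, 30x DNA coverage per strand, 20x RNA
#'   coverage, and a 0.1% base error rate.
#'
#' @param nFamilies,individualsPerFamily,t1dmFraction,visitsPerIndividual
#'   cohort structure; see slots.
#' @param taxa,variantsPerTaxon,transmissionProb planted-variant model; see
#'   slots. `transmissionProb` may be a single number (applied to every
#'   (genus, condition) pair) or a full `data.frame`.
#' @param coverageDna,coverageRna,baseErrorRate,peptideDepth,readLength,
#'   orfLength,expressedFraction,seed sequencing / sampling model; see slots.
#' @export
cohortConfig <- function(nFamilies = 8L,
                         individualsPerFamily = 4L,
                         t1dmFraction = 0.5,
                         visitsPerIndividual = 3L,
                         taxa = defaultTaxa(),
                         variantsPerTaxon = 10L,
                         transmissionProb = 0.5,
                         coverageDna = 30,
                         coverageRna = 20,
                         baseErrorRate = 0.001,
                         peptideDepth = 300,
                         readLength = 100L,
                         orfLength = 300L,
                         expressedFraction = 0.7,
                         seed = 42L) {
  taxa <- as.data.frame(taxa)
  if (is.numeric(transmissionProb) && length(transmissionProb) == 1L)
    transmissionProb <- transmissionTable(taxa, prob = transmissionProb)
  cfg <- new("CohortConfig",
    nFamilies = as.integer(nFamilies),
    individualsPerFamily = as.integer(individualsPerFamily),
    t1dmFraction = as.numeric(t1dmFraction),
    visitsPerIndividual = as.integer(visitsPerIndividual),
    taxa = taxa,
    variantsPerTaxon = as.integer(variantsPerTaxon),
    transmissionProb = transmissionProb,
    coverageDna = as.numeric(coverageDna),
    coverageRna = as.numeric(coverageRna),
    baseErrorRate = as.numeric(baseErrorRate),
    peptideDepth = as.numeric(peptideDepth),
    readLength = as.integer(readLength),
    orfLength = as.integer(orfLength),
    expressedFraction = as.numeric(expressedFraction),
    seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Default taxa table for the synthetic cohort
#'
#' Three genera repeatedly reported as orally seeded and detectable in gut
#' co-assemblies. Abundance weights scale fold-coverage at each body site.
#'
#' @return `data.frame` with columns `genus`, `n_contigs`, `contig_length`,
#'   `oral_weight`, `gut_weight`.
#' @export
defaultTaxa <- function() {
  data.frame(
    genus = c("Prevotella", "Streptococcus", "Bacteroides"),
    n_contigs = 2L,
    contig_length = 1200L,
    oral_weight = 1,
    gut_weight = 1,
    stringsAsFactors = FALSE)
}

#' Flat transmission-probability table
#'
#' @param taxa taxa table as in [cohortConfig()].
#' @param prob single probability, or a named list/vector keyed by genus, or
#'   per-(genus, condition) values via the `t1dm`/`control` arguments.
#' @param t1dm,control optional per-condition probabilities (recycled over
#'   genera) overriding `prob`.
#' @return `data.frame` with columns `genus`, `condition`, `prob`.
#' @export
transmissionTable <- function(taxa = defaultTaxa(), prob = 0.5,
                              t1dm = NULL, control = NULL) {
  tb <- expand.grid(genus = taxa$genus, condition = c("T1DM", "control"),
                    stringsAsFactors = FALSE)
  tb$prob <- prob
  if (!is.null(t1dm)) tb$prob[tb$condition == "T1DM"] <- t1dm
  if (!is.null(control)) tb$prob[tb$condition == "control"] <- control
  tb
}

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:",
      object@nFamilies, "families x", object@individualsPerFamily,
      "individuals,", object@visitsPerIndividual, "visits\n")
  cat("  taxa:", paste(object@taxa$genus, collapse = ", "), "\n")
  cat("  variants/taxon:", object@variantsPerTaxon,
      " coverage DNA/strand:", object@coverageDna,
      " RNA:", object@coverageRna,
      " base error:", object@baseErrorRate, "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "Cohort", function(object) {
  cat("Cohort:", length(unique(object@sampleTable$individual)),
      "individuals,", nrow(object@sampleTable), "samples\n")
  cat("  contigs:", length(object@contigs),
      " genes:", length(object@genes),
      " planted variants:", nrow(object@variants), "\n")
  tr <- object@transmission
  if (nrow(tr))
    cat("  transmitted (individual x variant):", sum(tr$present_in_gut),
        "of", nrow(tr), "\n")
})

#' Accessors for Cohort objects
#'
#' @param x a [Cohort-class].
#' @return the corresponding slot: the configuration, sample sheet, contig
#'   sequences, gene models, taxonomy table, planted-variant table, or
#'   per-individual transmission ledger.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
cohortConfigOf <- function(x) x@config
#' @rdname cohort-accessors
#' @export
sampleTable <- function(x) x@sampleTable
#' @rdname cohort-accessors
#' @export
contigs <- function(x) x@contigs
#' @rdname cohort-accessors
#' @export
geneModels <- function(x) x@genes
#' @rdname cohort-accessors
#' @export
taxonomyTable <- function(x) x@taxonomy
#' @rdname cohort-accessors
#' @export
plantedVariants <- function(x) x@variants
#' @rdname cohort-accessors
#' @export
transmissionLedger <- function(x) x@transmission
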