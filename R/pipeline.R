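# End-to-end orchestration on a synthetic cohort: simulate reads, pool per
# individual, pileup, call, apply cross-omic criteria, annotate, extract
# variant reads per sample, confer metaproteomic support, and summarise
# transfer per taxon.

poolAlignments <- function(cohort, sampleIds) {
  if (length(sampleIds) == 0L) return(emptyAlignments())
  do.call(rbind, lapply(sampleIds, function(s)
    simulateAlignments(cohort, s)))
}

#' Run the strain-variant tracking pipeline on a synthetic cohort
#'
#' For every individual: oral DNA, gut DNA and gut RNA reads are simulated
#' for all visits and pooled per source (oral reads from all visits are
#' mapped against the gut contigs); strand-resolved pileups are computed;
#' substitution variants are called on the gut DNA pileup; the cross-site,
#' cross-omic criteria classify retained variants as `MG_MT` or `MG_only`;
#' effects and genera are annotated; variant-carrying reads are extracted
#' per visit-level sample; and missense variant proteins are matched
#' against the individual's observed peptides to confer `mp_supported`.
#'
#' @param cohort a [Cohort-class] from [generateCohort()].
#' @param params [callParams()]; by default the caller's error rate is the
#'   cohort's base error rate (floored at 1e-3 so the quality model stays
#'   defined for error-free simulations).
#' @param withPeptides simulate and match metaproteomic evidence.
#' @return `list(tracked, assignments, mpHits, summary, comparisons)`:
#'   `tracked` has one row per (individual, retained variant) with an
#'   `individual` column prepended; `assignments` are per-sample variant
#'   read assignments; `summary` is the [taxonVariantAbundance()] output;
#'   `comparisons` the [compareTransferByCondition()] output.
#' @export
trackTransmission <- function(cohort, params = NULL, withPeptides = TRUE) {
  cfg <- cohort@config
  if (is.null(params))
    params <- callParams(errorRate = max(cfg@baseErrorRate, 1e-3))
  st <- cohort@sampleTable
  ctgSeqs <- setNames(as.character(cohort@contigs),
                      names(cohort@contigs))
  universe <- names(ctgSeqs)
  refProteins <- setNames(
    vapply(seq_along(cohort@genes),
           function(i) geneProtein(cohort@genes[i], ctgSeqs), character(1)),
    cohort@genes$gene_id)
  trackedAll <- list(); assignAll <- list(); hitsAll <- list()
  for (ind in unique(st$individual)) {
    si <- st[st$individual == ind, ]
    oralIds <- si$sample_id[si$site == "oral" & si$ome == "MG"]
    gutDnaIds <- si$sample_id[si$site == "gut" & si$ome == "MG"]
    gutRnaIds <- si$sample_id[si$site == "gut" & si$ome == "MT"]
    mpIds <- si$sample_id[si$site == "gut" & si$ome == "MP"]
    oralAl <- poolAlignments(cohort, oralIds)
    gutDnaBySample <- lapply(setNames(gutDnaIds, gutDnaIds),
                             function(s) simulateAlignments(cohort, s))
    gutRnaBySample <- lapply(setNames(gutRnaIds, gutRnaIds),
                             function(s) simulateAlignments(cohort, s))
    gutDnaAl <- do.call(rbind, unname(gutDnaBySample)) %||%
      emptyAlignments()
    gutRnaAl <- do.call(rbind, unname(gutRnaBySample)) %||%
      emptyAlignments()
    oralPu <- pileupCounts(oralAl, maxDepth = params$maxDepth,
                           contigSet = universe)
    gutDnaPu <- pileupCounts(gutDnaAl, maxDepth = params$maxDepth,
                             contigSet = universe)
    gutRnaPu <- pileupCounts(gutRnaAl, maxDepth = params$maxDepth,
                             contigSet = universe)
    called <- callVariants(gutDnaPu, ctgSeqs, params)
    tracked <- evaluateCrossSiteCriteria(
      called, oralPu, gutDnaPu, gutRnaPu,
      gtAltFraction = params$gtAltFraction,
      genes = cohort@genes, contigSeqs = ctgSeqs,
      taxonomy = cohort@taxonomy)
    if (withPeptides && nrow(tracked)) {
      vp <- variantProteins(tracked, cohort@genes, ctgSeqs)
      obs <- do.call(rbind, lapply(mpIds, function(s)
        simulatePeptideObservations(cohort, s)))
      hits <- matchVariantPeptides(obs, vp, refProteins)
      tracked$mp_supported <- tracked$variant_id %in% hits$variant_id
      if (nrow(hits)) {
        hits$individual <- ind
        hitsAll[[ind]] <- hits
      }
    }
    if (nrow(tracked)) {
      perSampleAl <- c(lapply(gutDnaBySample, function(a)
                         list(al = a, ome = "MG")),
                       lapply(gutRnaBySample, function(a)
                         list(al = a, ome = "MT")))
      asg <- lapply(names(perSampleAl), function(s) {
        a <- extractVariantReads(perSampleAl[[s]]$al, tracked, source = s)
        if (nrow(a) == 0L) return(NULL)
        a$sample_id <- s
        a$ome <- perSampleAl[[s]]$ome
        a$support_class <- tracked$support_class[
          match(a$variant_id, tracked$variant_id)]
        a
      })
      asg <- do.call(rbind, asg[!vapply(asg, is.null, logical(1))])
      if (!is.null(asg)) assignAll[[ind]] <- asg
      tracked <- cbind(individual = ind, tracked,
                       stringsAsFactors = FALSE)
      trackedAll[[ind]] <- tracked
    }
  }
  tracked <- if (length(trackedAll)) do.call(rbind, trackedAll) else NULL
  if (!is.null(tracked)) rownames(tracked) <- NULL
  assignments <- if (length(assignAll)) do.call(rbind, assignAll) else NULL
  if (!is.null(assignments)) rownames(assignments) <- NULL
  mpHits <- if (length(hitsAll)) do.call(rbind, hitsAll) else NULL
  if (!is.null(mpHits)) rownames(mpHits) <- NULL
  summary <- taxonVariantAbundance(assignments, mpHits, cohort@taxonomy)
  comparisons <- compareTransferByCondition(summary, cohort@sampleTable)
  list(tracked = tracked, assignments = assignments, mpHits = mpHits,
       summary = summary, comparisons = comparisons)
}

#' Score pipeline output against the generator's truth ledger
#'
#' Per individual, the expected detections are the planted variants
#' transmitted to that individual's gut; the expected support class is
#' `MG_MT` when the variant lies in an expressed gene and `MG_only`
#' otherwise. Metaproteomic support is expected for transmitted missense
#' variants for which at least one variant-spanning peptide was actually
#' emitted in the individual's MP samples.
#'
#' @param result output of [trackTransmission()].
#' @param cohort the [Cohort-class] the result was computed from.
#' @return `list(sensitivity, fdr, labelAccuracy, mpAccuracy, detail)`:
#'   `sensitivity` is the fraction of transmitted (individual, variant)
#'   pairs detected; `fdr` the fraction of detections not matching a
#'   transmitted pair; `labelAccuracy` the fraction of detected true
#'   pairs with the expected class; `mpAccuracy` the fraction of
#'   peptide-emitting transmitted missense pairs with `mp_supported`.
#' @export
scoreRecovery <- function(result, cohort) {
  tr <- cohort@transmission
  truth <- tr[tr$present_in_gut, c("individual", "variant_id")]
  v <- cohort@variants
  g <- cohort@genes
  expressed <- setNames(g$expressed, g$gene_id)
  vExpr <- !is.na(v$gene_id) & expressed[v$gene_id]
  truth$expected_class <- ifelse(vExpr[match(truth$variant_id,
                                             v$variant_id)],
                                 "MG_MT", "MG_only")
  truthKey <- paste(truth$individual, truth$variant_id)
  det <- result$tracked
  detKey <- if (is.null(det)) character(0)
            else paste(det$individual, det$variant_id)
  tp <- intersect(detKey, truthKey)
  sens <- if (nrow(truth)) length(tp) / nrow(truth) else NA_real_
  fdr <- if (length(detKey)) 1 - length(tp) / length(detKey) else 0
  lab <- NA_real_
  if (length(tp)) {
    dcls <- det$support_class[match(tp, detKey)]
    ecls <- truth$expected_class[match(tp, truthKey)]
    lab <- mean(dcls == ecls)
  }
  # transmitted missense pairs with at least one emitted variant peptide
  mpTruth <- emittedVariantPeptides(cohort)
  mpKey <- paste(mpTruth$individual, mpTruth$variant_id)
  mpAcc <- NA_real_
  if (length(mpKey)) {
    sup <- if (is.null(det)) logical(0)
           else det$mp_supported[match(mpKey, detKey)]
    sup[is.na(sup)] <- FALSE
    mpAcc <- mean(sup)
  }
  list(sensitivity = sens, fdr = fdr, labelAccuracy = lab,
       mpAccuracy = mpAcc,
       detail = list(truth = truth, detectedKeys = detKey,
                     mpTruthKeys = mpKey))
}

# (individual, variant) pairs for which the simulator actually emitted a
# variant-spanning peptide in that individual's gut MP samples
emittedVariantPeptides <- function(cohort) {
  st <- cohort@sampleTable
  mp <- st[st$site == "gut" & st$ome == "MP", ]
  rows <- list()
  for (i in seq_len(nrow(mp))) {
    obs <- simulatePeptideObservations(cohort, mp$sample_id[i])
    obs <- obs[obs$is_variant_spanning & nzchar(obs$variant_ids), ,
               drop = FALSE]
    if (nrow(obs) == 0L) next
    vids <- unique(unlist(strsplit(obs$variant_ids, ",")))
    rows[[length(rows) + 1L]] <- data.frame(
      individual = mp$individual[i], variant_id = vids,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(individual = character(0), variant_id = character(0),
                      stringsAsFactors = FALSE)
  unique(out)
}
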