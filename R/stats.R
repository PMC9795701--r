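# Count-matrix preparation, diversity measures and correlation analyses
# for microbiome read/spectra matrices.

asCountMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x)
  else as.matrix(x)
}

#' Collapse visit-level counts to per-individual medians and filter by
#' prevalence
#'
#' Because repeated visits of one individual are not independent, each
#' feature is first summarised as the median over the individual's
#' available visits. Features are then removed unless their per-individual
#' value reaches `minCount` in at least a `minFraction` share of all
#' individuals (defaults: 20 reads, or 10 spectra, in 25% of
#' individuals).
#'
#' @param counts features x samples matrix, or a `SummarizedExperiment`
#'   whose `colData` has an `individual` column.
#' @param metadata `data.frame` with `sample_id` and `individual` columns
#'   (ignored when `counts` is a `SummarizedExperiment` carrying them).
#' @param minCount,minFraction prevalence filter parameters.
#' @return features x individuals matrix (or `SummarizedExperiment` with
#'   individual-level `colData` if one was supplied), with filtered
#'   features dropped.
#' @export
prepareFeatureMatrix <- function(counts, metadata = NULL, minCount = 20,
                                 minFraction = 0.25) {
  stopifnot(minCount > 0, minFraction > 0, minFraction <= 1)
  isSE <- is(counts, "SummarizedExperiment")
  mat <- asCountMatrix(counts)
  if (isSE && is.null(metadata))
    metadata <- as.data.frame(SummarizedExperiment::colData(counts))
  if (is.null(metadata$sample_id)) metadata$sample_id <- colnames(mat)
  indiv <- metadata$individual[match(colnames(mat), metadata$sample_id)]
  if (any(is.na(indiv)))
    stop("sample(s) without an individual in the metadata: ",
         paste(colnames(mat)[is.na(indiv)], collapse = ", "))
  ids <- unique(indiv)
  med <- vapply(ids, function(id)
    apply(mat[, indiv == id, drop = FALSE], 1L, median), numeric(nrow(mat)))
  med <- matrix(med, nrow = nrow(mat),
                dimnames = list(rownames(mat), ids))
  prev <- rowSums(med >= minCount)
  keep <- prev >= minFraction * length(ids)
  out <- med[keep, , drop = FALSE]
  if (!isSE) return(out)
  cd <- metadata[match(ids, metadata$individual), , drop = FALSE]
  cd <- cd[, setdiff(names(cd), c("sample_id", "visit")), drop = FALSE]
  rownames(cd) <- ids
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = out), colData = cd)
}

#' Richness and Simpson's index of diversity per sample
#'
#' Counts are converted to relative abundances per sample (dividing by the
#' sample's total); richness is the number of features with nonzero
#' abundance and Simpson's index of diversity is `D = 1 - sum(p_i^2)`
#' (computed through `vegan::diversity`). All-zero samples are flagged and
#' get `NA` diversity.
#'
#' @param counts features x samples matrix or `SummarizedExperiment`.
#' @return `data.frame` with columns `sample_id`, `richness`, `simpson`,
#'   `flagged`.
#' @export
alphaDiversity <- function(counts) {
  mat <- asCountMatrix(counts)
  tot <- colSums(mat)
  flagged <- tot <= 0
  simpson <- rep(NA_real_, ncol(mat))
  if (any(!flagged))
    simpson[!flagged] <- vegan::diversity(t(mat[, !flagged, drop = FALSE]),
                                          index = "simpson")
  data.frame(sample_id = colnames(mat) %||%
               paste0("S", seq_len(ncol(mat))),
             richness = as.integer(colSums(mat > 0)), simpson = simpson,
             flagged = flagged, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(u, v) = 1 - 2 sum(min(u_i, v_i)) / (sum u_i + sum v_i)` over the
#' columns of the count matrix (computed through `vegan::vegdist`).
#' Distances involving an all-zero sample are undefined and returned as
#' `NA` with a warning.
#'
#' @param counts features x samples matrix or `SummarizedExperiment` of
#'   non-negative counts.
#' @return symmetric samples x samples matrix with zero diagonal.
#' @export
brayCurtis <- function(counts) {
  mat <- asCountMatrix(counts)
  if (any(mat < 0)) stop("counts must be non-negative")
  zero <- colSums(mat) <= 0
  d <- as.matrix(suppressWarnings(vegan::vegdist(t(mat), method = "bray")))
  if (any(zero)) {
    warning("all-zero sample(s): ",
            paste(colnames(mat)[zero], collapse = ", "),
            "; their distances are undefined (NA)")
    d[zero, ] <- NA_real_
    d[, zero] <- NA_real_
  }
  diag(d) <- 0
  dimnames(d) <- list(colnames(mat), colnames(mat))
  d
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p-value when both groups have at most 8 observations and no ties
#' are present; normal approximation with tie correction (and continuity
#' correction) otherwise. Two identical constant groups give p = 1.
#' Groups with fewer than two observations are flagged not testable.
#'
#' @param a,b numeric vectors.
#' @return `list(U, p, testable)`; `U` is the Mann-Whitney statistic for
#'   the first group.
#' @export
groupCompare <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    return(list(U = NA_real_, p = NA_real_, testable = FALSE))
  ties <- anyDuplicated(c(a, b)) > 0L
  if (!ties && max(length(a), length(b)) <= 8L) {
    wt <- wilcox.test(a, b, exact = TRUE)
  } else if (length(unique(c(a, b))) == 1L) {
    return(list(U = length(a) * length(b) / 2, p = 1, testable = TRUE))
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                       correct = TRUE))
  }
  list(U = unname(wt$statistic), p = wt$p.value, testable = TRUE)
}

#' Spearman correlations with Benjamini-Hochberg correction
#'
#' Computes Spearman's rho (average ranks for ties) between every feature
#' of `x` and every feature of `y` (or all within-`x` pairs when `y` is
#' `NULL`), with two-sided p-values from the t approximation, adjusts all
#' tested pairs with the Benjamini-Hochberg step-up procedure, and returns
#' the edges passing both the correlation magnitude and adjusted
#' significance thresholds. Constant features cannot be ranked and their
#' pairs are excluded with a flag.
#'
#' @param x,y features x samples matrices sharing column names (at least
#'   4 shared samples); `y = NULL` correlates `x` against itself.
#' @param rhoMin minimum `|rho|` for an edge (e.g. 0.7 for the
#'   transcript-taxon network, 0 elsewhere).
#' @param alpha adjusted-significance threshold (e.g. 0.001 for the
#'   network, 0.05 elsewhere).
#' @return `list(edges, tested, excluded)`: `edges` and `tested` are
#'   `data.frame`s with columns `feature_a`, `feature_b`, `rho`, `p_raw`,
#'   `p_adjusted`; `excluded` names the constant features.
#' @export
spearmanBH <- function(x, y = NULL, rhoMin = 0, alpha = 0.05) {
  x <- asCountMatrix(x)
  self <- is.null(y)
  y <- if (self) x else asCountMatrix(y)
  shared <- intersect(colnames(x), colnames(y))
  if (length(shared) < 4L)
    stop("need at least 4 shared samples, got ", length(shared))
  x <- x[, shared, drop = FALSE]
  y <- y[, shared, drop = FALSE]
  constX <- apply(x, 1L, function(v) length(unique(v)) == 1L)
  constY <- apply(y, 1L, function(v) length(unique(v)) == 1L)
  excluded <- unique(c(rownames(x)[constX], rownames(y)[constY]))
  rx <- t(apply(x[!constX, , drop = FALSE], 1L, rank))
  ry <- t(apply(y[!constY, , drop = FALSE], 1L, rank))
  n <- length(shared)
  rho <- cor(t(rx), t(ry))
  pairs <- which(if (self) upper.tri(rho) else
                   matrix(TRUE, nrow(rho), ncol(rho)), arr.ind = TRUE)
  r <- rho[pairs]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  tested <- data.frame(
    feature_a = rownames(rho)[pairs[, 1]],
    feature_b = colnames(rho)[pairs[, 2]],
    rho = r, p_raw = p, p_adjusted = p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE)
  edges <- tested[abs(tested$rho) >= rhoMin &
                    tested$p_adjusted < alpha, , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, tested = tested, excluded = excluded)
}
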