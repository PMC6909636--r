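# Expression-inferred band copy number (iCNV).
#
# For one sample and one band, genes on the band form set B and all genes
# assigned to any other band form set A; the iCNV is the Welch two-sample
# t-statistic on relative expression,
#
#   t = (xbar_B - xbar_A) / sqrt(s2_B/n_B + s2_A/n_A),
#
# with sample variances. Positive t = relative gain. Bands with fewer than
# `min_genes` genes are excluded as unreliable.

#' Normalize a gene expression matrix to relative expression
#'
#' Optionally log2(x + 1)-transforms, then centers each gene across samples
#' by its mean (default) or median, yielding the relative expression values
#' the iCNV is computed on. Genes that are missing in every sample are
#' dropped; partial missingness is an error (no imputation). Zero-variance
#' genes are kept (their centered row is all zeros) with a warning.
#'
#' @param expr Genes x samples numeric matrix with gene row names and
#'   sample column names.
#' @param log_transform If `TRUE`, apply log2(x + 1) first (values must be
#'   non-negative).
#' @param center Per-gene centering statistic: `"mean"` (default) or
#'   `"median"`.
#' @return The centered matrix with attribute `scale = "relative"`.
#' @export
normalize_expression <- function(expr, log_transform = FALSE,
                                 center = c("mean", "median")) {
  center <- match.arg(center)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene row names and sample column names",
         call. = FALSE)
  }
  all_na <- rowSums(!is.na(expr)) == 0L
  if (any(all_na)) expr <- expr[!all_na, , drop = FALSE]
  if (anyNA(expr)) {
    g <- rownames(expr)[which(rowSums(is.na(expr)) > 0L)[1L]]
    stop("gene '", g, "' has partially missing values; ",
         "imputation is not supported", call. = FALSE)
  }
  if (log_transform) {
    if (any(expr < 0)) stop("negative values: cannot log2(x + 1) transform",
                            call. = FALSE)
    expr <- log2(expr + 1)
  }
  ctr <- switch(center,
                mean = rowMeans(expr),
                median = apply(expr, 1L, stats::median))
  out <- expr - ctr
  nzero <- sum(apply(expr, 1L, function(r) all(r == r[1L])))
  if (nzero > 0L) {
    warning(nzero, " zero-variance gene(s) centered to all-zero rows",
            call. = FALSE)
  }
  attr(out, "scale") <- "relative"
  out
}

#' Infer per-sample band copy numbers from expression (iCNV)
#'
#' For every sample and every reliable band, computes the Welch t-statistic
#' comparing relative expression of the band's genes (set B) against all
#' genes assigned to any other band (set A). Genes mapping to no band are
#' excluded from both sets. Bands with fewer than the gene-set object's
#' `min_genes` genes present in the expression matrix are excluded and
#' reported with a reason.
#'
#' @param expr Relative expression matrix from [normalize_expression()]
#'   (attribute `scale = "relative"`).
#' @param sets A `positional_gene_sets` object.
#' @return An `icnv_matrix` object: `icnv` (bands x samples t-statistics),
#'   `df` (matching Welch-Satterthwaite degrees of freedom), `excluded`
#'   (data frame band/reason/n_genes), `min_genes`.
#' @export
compute_icnv <- function(expr, sets) {
  stopifnot(inherits(sets, "positional_gene_sets"))
  if (!identical(attr(expr, "scale"), "relative")) {
    stop("expression must be relative-scale; run normalize_expression() first",
         call. = FALSE)
  }
  map <- .gene_band_map(sets)
  genes <- intersect(rownames(expr), names(map))
  if (length(genes) < 2L) {
    stop("fewer than 2 expression genes are assigned to catalog bands",
         call. = FALSE)
  }
  E <- expr[genes, , drop = FALSE]
  band <- map[genes]
  counts <- table(band)
  present <- names(counts)
  reliable <- present[counts >= sets$min_genes]
  excluded <- present[counts < sets$min_genes]
  if (!length(reliable)) stop("no band has enough genes for inference",
                              call. = FALSE)
  N <- nrow(E)
  S <- colSums(E)
  Q <- colSums(E^2)
  tmat <- dfmat <- matrix(NA_real_, length(reliable), ncol(E),
                          dimnames = list(reliable, colnames(E)))
  for (b in reliable) {
    idx <- which(band == b)
    nB <- length(idx); nA <- N - nB
    SB <- colSums(E[idx, , drop = FALSE])
    QB <- colSums(E[idx, , drop = FALSE]^2)
    xB <- SB / nB
    xA <- (S - SB) / nA
    s2B <- pmax((QB - nB * xB^2) / (nB - 1), 0)
    s2A <- pmax((Q - QB - nA * xA^2) / (nA - 1), 0)
    se2 <- s2B / nB + s2A / nA
    if (any(se2 == 0)) {
      s <- colnames(E)[which(se2 == 0)[1L]]
      stop("zero variance in both gene sets for band ", b,
           ", sample ", s, ": t-statistic undefined", call. = FALSE)
    }
    tmat[b, ] <- (xB - xA) / sqrt(se2)
    dfmat[b, ] <- se2^2 / ((s2B / nB)^2 / (nB - 1) + (s2A / nA)^2 / (nA - 1))
  }
  excl <- data.frame(
    band = excluded,
    reason = rep(sprintf("fewer than %d genes in expression data",
                         sets$min_genes), length(excluded)),
    n_genes = as.integer(counts[excluded]),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(icnv = tmat, df = dfmat, excluded = excl,
                 min_genes = sets$min_genes),
            class = "icnv_matrix")
}

# accept an icnv_matrix or a plain bands x samples matrix
.band_matrix <- function(x) {
  if (inherits(x, "icnv_matrix")) x$icnv else as.matrix(x)
}

#' @export
as.matrix.icnv_matrix <- function(x, ...) x$icnv

#' @export
print.icnv_matrix <- function(x, ...) {
  cat("iCNV matrix: ", nrow(x$icnv), " bands x ", ncol(x$icnv),
      " samples (", nrow(x$excluded), " band(s) excluded: < ",
      x$min_genes, " genes)\n", sep = "")
  invisible(x)
}

#' Validate inferred against measured band copy numbers
#'
#' Correlates each band's iCNV profile with its measured copy-number
#' profile across shared samples (Pearson), and computes the full
#' cross-band correlation matrix to assess specificity (the own-band
#' correlation should dominate every cross-band one). Bands constant in
#' either matrix get `NA` correlations.
#'
#' @param icnv An `icnv_matrix` (or bands x samples matrix).
#' @param measured A bands x samples matrix of measured/mapped copy numbers.
#' @param threshold Correlation regarded as "high" for the summary fraction
#'   (default 0.8).
#' @return An `icnv_validation` object: `per_band` named vector of own-band
#'   correlations, `cross` (iCNV bands x measured bands matrix),
#'   `fraction_above`, `threshold`, `n_samples`.
#' @export
validate_icnv <- function(icnv, measured, threshold = 0.8) {
  mi <- .band_matrix(icnv)
  mm <- as.matrix(measured)
  bands <- intersect(rownames(mi), rownames(mm))
  samples <- intersect(colnames(mi), colnames(mm))
  if (length(samples) < 3L) {
    stop("need at least 3 shared samples (found ", length(samples), ")",
         call. = FALSE)
  }
  if (!length(bands)) stop("no shared bands", call. = FALSE)
  xi <- t(mi[bands, samples, drop = FALSE])
  xm <- t(mm[bands, samples, drop = FALSE])
  cross <- suppressWarnings(stats::cor(xi, xm))
  per_band <- stats::setNames(diag(cross), bands)
  structure(
    list(per_band = per_band, cross = cross,
         fraction_above = mean(per_band > threshold, na.rm = TRUE),
         threshold = threshold, n_samples = length(samples)),
    class = "icnv_validation")
}

#' @export
print.icnv_validation <- function(x, ...) {
  ok <- x$per_band[is.finite(x$per_band)]
  cat("iCNV validation over ", x$n_samples, " samples: median own-band r = ",
      round(stats::median(ok), 3), "; ",
      round(100 * x$fraction_above, 1), "% of bands with r > ",
      x$threshold, "\n", sep = "")
  invisible(x)
}
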