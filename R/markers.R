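#' Validate a marker dosage matrix
#'
#' A marker panel is an ordinary numeric matrix of allele dosages with lines
#' in rows and biallelic markers in columns. Entries are 0, 1 or 2 copies of
#' the counted allele; missing genotypes are `NA`. Row names identify lines,
#' column names identify markers; both must be unique.
#'
#' @param markers numeric matrix, lines x markers, entries in {0, 1, 2, NA}.
#' @return the input, invisibly, after validation.
#' @keywords internal
check_markers <- function(markers) {
  if (!is.matrix(markers) || !is.numeric(markers))
    stop("`markers` must be a numeric matrix (lines x markers)")
  if (nrow(markers) < 2L)
    stop("marker panel needs at least 2 lines")
  if (ncol(markers) < 1L)
    stop("marker panel needs at least 1 marker")
  if (is.null(rownames(markers)) || anyDuplicated(rownames(markers)))
    stop("`markers` must have unique row names (line identifiers)")
  if (is.null(colnames(markers)) || anyDuplicated(colnames(markers)))
    stop("`markers` must have unique column names (marker identifiers)")
  vals <- markers[!is.na(markers)]
  if (length(bad <- vals[!vals %in% c(0, 1, 2)]))
    stop("invalid dosage value(s): ", paste(utils::head(unique(bad), 5L),
                                            collapse = ", "),
         " (allowed: 0, 1, 2, NA)")
  invisible(markers)
}

#' Marker quality control
#'
#' Removes markers with too many missing genotypes or a low minor allele
#' frequency. The MAF of a marker is `min(p, 1 - p)` where `p` is the mean
#' non-missing dosage divided by 2; it is always computed on the raw
#' (unimputed) genotypes so that imputation cannot alter QC outcomes.
#' Marker order is preserved.
#'
#' @param markers numeric dosage matrix, lines x markers (see
#'   [check_markers()]).
#' @param maf_min minimum minor allele frequency to retain a marker
#'   (default 0.05).
#' @param missing_max maximum tolerated fraction of missing genotypes per
#'   marker (default 0.15).
#' @return the filtered dosage matrix.
#' @examples
#' m <- rbind(a = c(0, 0), b = c(1, 0), c = c(2, 0))
#' colnames(m) <- c("snp1", "snp2")
#' filter_markers(m)  # snp2 is monomorphic (MAF 0) and dropped
#' @export
filter_markers <- function(markers, maf_min = 0.05, missing_max = 0.15) {
  check_markers(markers)
  if (maf_min < 0 || maf_min >= 0.5) stop("`maf_min` must be in [0, 0.5)")
  if (missing_max < 0 || missing_max > 1)
    stop("`missing_max` must be in [0, 1]")
  miss <- colMeans(is.na(markers))
  p <- colMeans(markers, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing column: removed by the missing rule too
  keep <- miss <= missing_max & maf >= maf_min
  if (!any(keep))
    stop("empty panel: no marker passed QC (maf_min = ", maf_min,
         ", missing_max = ", missing_max, ")")
  markers[, keep, drop = FALSE]
}

#' Mean imputation of missing genotypes
#'
#' Replaces each missing dosage by the mean of the marker's non-missing
#' dosages. Deterministic stand-in for model-based genotype imputation;
#' adequate at low missingness rates.
#'
#' @inheritParams filter_markers
#' @return dosage matrix without missing entries.
#' @export
impute_mean <- function(markers) {
  check_markers(markers)
  nmiss <- colSums(!is.na(markers))
  if (any(nmiss == 0L))
    stop("marker(s) with all genotypes missing: ",
         paste(colnames(markers)[nmiss == 0L], collapse = ", "))
  if (!anyNA(markers)) return(markers)
  mu <- colMeans(markers, na.rm = TRUE)
  idx <- which(is.na(markers), arr.ind = TRUE)
  markers[idx] <- mu[idx[, 2L]]
  markers
}

#' VanRaden genomic relationship matrix
#'
#' Computes `G = W W' / (2 * sum(p_k (1 - p_k)))` where `W` is the dosage
#' matrix with each column centered by twice its allele frequency `p_k`
#' (VanRaden method 1). Markers fixed for one allele (`p_k` of 0 or 1)
#' carry no information and are excluded from both the numerator and the
#' denominator. A small ridge,
#' `1e-8 * mean(diag(G))`, is added to the diagonal so that finite-precision
#' Gram matrices stay positive semi-definite under factorization.
#'
#' @param markers numeric dosage matrix without missing entries (impute
#'   first, see [impute_mean()]).
#' @return J x J symmetric genomic relationship matrix with line names on
#'   both dimensions.
#' @examples
#' m <- rbind(l1 = c(0, 1, 2), l2 = c(2, 1, 0), l3 = c(1, 1, 1))
#' colnames(m) <- paste0("s", 1:3)
#' vanraden_grm(m)
#' @export
vanraden_grm <- function(markers) {
  check_markers(markers)
  if (anyNA(markers))
    stop("missing genotypes present; run impute_mean() first")
  p <- colMeans(markers) / 2
  poly <- p > 0 & p < 1
  if (!any(poly))
    stop("all markers are monomorphic: GRM denominator is zero")
  W <- sweep(markers[, poly, drop = FALSE], 2L, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  diag(G) <- diag(G) + 1e-8 * mean(diag(G))
  G
}

#' Environmental relationship matrix from environment incidence
#'
#' Builds `H = X_L X_L' / scale` where `X_L` is the n x I one-hot environment
#' incidence matrix over observations: entry (a, b) is `1/scale` when
#' observations a and b share an environment and 0 otherwise. Any positive
#' `scale` is absorbed by the associated variance component during fitting,
#' so predictions do not depend on it.
#'
#' @param env_labels vector of environment identifiers, one per observation.
#' @param scale positive divisor applied to the incidence cross-product
#'   (default 1).
#' @return n x n block-structured environmental relationship matrix.
#' @export
env_kernel <- function(env_labels, scale = 1) {
  if (length(env_labels) == 0L) stop("`env_labels` is empty")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("`scale` must be a positive number")
  f <- factor(env_labels, levels = unique(env_labels))
  X <- outer(f, levels(f), `==`) * 1
  tcrossprod(X) / scale
}

#' Genotype-by-environment interaction kernel
#'
#' Elementwise (Hadamard) product of the environmental kernel `H` and the
#' observation-level genomic kernel `Z_g G Z_g'`, where `Z_g` maps
#' observations to lines: entry (a, b) is `H[a, b] * G[line(a), line(b)]`.
#'
#' @param H n x n environmental relationship matrix (see [env_kernel()]).
#' @param line_labels vector of line identifiers, one per observation; every
#'   label must index a row of `G`.
#' @param G genomic relationship matrix with line names.
#' @return n x n interaction kernel.
#' @export
interaction_kernel <- function(H, line_labels, G) {
  n <- length(line_labels)
  if (!is.matrix(H) || nrow(H) != n || ncol(H) != n)
    stop("`H` must be an n x n matrix matching `line_labels`")
  unknown <- setdiff(unique(as.character(line_labels)), rownames(G))
  if (length(unknown))
    stop("line label(s) not present in G: ", paste(unknown, collapse = ", "))
  idx <- match(as.character(line_labels), rownames(G))
  H * G[idx, idx, drop = FALSE]
}

#' Observation-level genomic kernel
#'
#' Expands a line-level genomic relationship matrix to the observation level
#' (`Z_g G Z_g'`) by indexing rows and columns with each observation's line.
#'
#' @inheritParams interaction_kernel
#' @return n x n genomic covariance over observations.
#' @export
line_kernel <- function(line_labels, G) {
  unknown <- setdiff(unique(as.character(line_labels)), rownames(G))
  if (length(unknown))
    stop("line label(s) not present in G: ", paste(unknown, collapse = ", "))
  idx <- match(as.character(line_labels), rownames(G))
  G[idx, idx, drop = FALSE]
}
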