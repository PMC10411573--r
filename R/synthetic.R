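#' Simulate a biallelic marker panel
#'
#' Draws one allele frequency per marker uniformly from `maf_range` and then
#' independent dosages `Binomial(2, freq)` per line — a linkage-free,
#' unstructured panel of the shape found in multi-environment trial data
#' sets (hundreds of lines by thousands of SNPs). Deterministic given
#' `seed`.
#'
#' @param J number of lines (>= 2).
#' @param p number of markers (>= 10).
#' @param maf_range allele-frequency interval within (0, 0.5] to draw from.
#' @param seed integer seed.
#' @return J x p dosage matrix with line names `L0001...` and marker names
#'   `M000001...`.
#' @export
simulate_markers <- function(J, p, maf_range = c(0.05, 0.5), seed = 1) {
  if (J < 2L) stop("need J >= 2 lines")
  if (p < 10L) stop("need p >= 10 markers")
  if (length(maf_range) != 2L || maf_range[1L] > maf_range[2L] ||
      maf_range[1L] <= 0 || maf_range[2L] > 0.5)
    stop("`maf_range` must be an interval within (0, 0.5]")
  set.seed(seed)
  freq <- stats::runif(p, maf_range[1L], maf_range[2L])
  M <- vapply(freq, function(f) stats::rbinom(J, 2L, f), numeric(J))
  dimnames(M) <- list(sprintf("L%04d", seq_len(J)),
                      sprintf("M%06d", seq_len(p)))
  M
}

#' Simulate a balanced multi-environment trial
#'
#' Generates phenotypes under the additive multi-environment model
#' `y_ij = mu + L_i + g_j + gL_ij + e_ij`:
#' * line values `g = W w` with marker effects
#'   `w ~ N(0, var_g / (2 * sum(p_k q_k)))` on the centered dosages, so
#'   `var(g)` is approximately `var_g`;
#' * environment effects `L_i ~ N(0, var_env)`, plus a deterministic mean
#'   offset `shift` added to one designated environment — the controlled
#'   train/test distribution mismatch produced by non-stationary
#'   environments;
#' * interaction `gL_ij` built from independent environment-specific
#'   marker-effect deviations with variance `var_ge`, giving a separable
#'   covariance (`G` within an environment, independent across) that
#'   matches the Hadamard interaction kernel in expectation;
#' * residual `e_ij ~ N(0, var_e)`.
#'
#' @param markers dosage matrix (see [simulate_markers()]); no missing
#'   entries.
#' @param I number of environments (>= 3), labelled `E1..EI`.
#' @param mu grand mean, trait units.
#' @param var_g,var_env,var_ge,var_e variance components (trait units
#'   squared, all >= 0).
#' @param shift deterministic mean offset (trait units) added to
#'   `shift_env`.
#' @param shift_env designated environment for the offset (default `"E1"`).
#' @param trait trait label for the output table.
#' @param seed integer seed.
#' @return list with `phenos` (balanced long-format table) and `truth`
#'   (list with `g`, `L` including the shift, `gL` matrix J x I, and the
#'   J x I matrix of genetic values `mu + L + g + gL` used by oracle
#'   accuracy computations).
#' @export
simulate_trial <- function(markers, I = 4, mu = 10, var_g = 1,
                           var_env = 1, var_ge = 0.25, var_e = 0.5,
                           shift = 0, shift_env = "E1", trait = "trait",
                           seed = 1) {
  check_markers(markers)
  if (anyNA(markers)) stop("`markers` must have no missing entries")
  if (I < 3L) stop("need I >= 3 environments")
  if (any(c(var_g, var_env, var_ge, var_e) < 0))
    stop("variances must be >= 0")
  set.seed(seed)
  J <- nrow(markers)
  envs <- sprintf("E%d", seq_len(I))
  if (shift != 0 && !shift_env %in% envs)
    stop("`shift_env` must be one of ", paste(envs, collapse = ", "))

  pfreq <- colMeans(markers) / 2
  sum2pq <- 2 * sum(pfreq * (1 - pfreq))
  W <- sweep(markers, 2L, 2 * pfreq)
  draw_genetic <- function(v) {
    if (v == 0 || sum2pq == 0) return(numeric(J))
    drop(W %*% stats::rnorm(ncol(W), 0, sqrt(v / sum2pq)))
  }

  g <- draw_genetic(var_g)
  L <- stats::rnorm(I, 0, sqrt(var_env))
  names(L) <- envs
  if (shift != 0) L[shift_env] <- L[shift_env] + shift
  gL <- vapply(seq_len(I), function(i) draw_genetic(var_ge), numeric(J))
  colnames(gL) <- envs
  genetic <- mu + outer(g, L, `+`) + gL  # J x I, before residual noise
  eps <- matrix(stats::rnorm(J * I, 0, sqrt(var_e)), J, I)
  Y <- genetic + eps

  phenos <- data.frame(
    line = rep(rownames(markers), times = I),
    env = rep(envs, each = J),
    trait = trait,
    value = as.vector(Y),
    stringsAsFactors = FALSE)
  list(phenos = phenos,
       truth = list(g = stats::setNames(g, rownames(markers)), L = L,
                    gL = gL, genetic = genetic, mu = mu, shift = shift,
                    shift_env = if (shift != 0) shift_env else NULL))
}
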