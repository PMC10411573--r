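#' Conventional multi-environment GBLUP (M1)
#'
#' Fits the conventional GBLUP predictor
#' \deqn{y_{ij} = \mu + L_i + g_j + gL_{ij} + \varepsilon_{ij}}
#' over all (line, environment) observations of one trait, with random
#' environment effects (covariance `sigma^2_L H`, `H` the incidence-based
#' environmental kernel), random line effects (`sigma^2_g Z_g G Z_g'`) and —
#' when `include_ge = TRUE` — a genotype-by-environment interaction with the
#' Hadamard kernel `sigma^2_gL H * Z_g G Z_g'`. All responses of
#' `target_env` are masked before fitting, so the target environment
#' contributes nothing to estimation and its predictions come from the
#' conditional mean given the training environments. `include_ge = TRUE` is
#' the M1_GE predictor, `include_ge = FALSE` is M1_NO_GE.
#'
#' Because `H` is built from environment incidence alone, a held-out
#' environment shares no covariance with the training data: its environment
#' and interaction BLUPs are 0 and its predictions reduce to
#' `mu + g_j`, the same line ranking for any target environment.
#'
#' @param phenos long-format phenotype table (see [check_phenotypes()]).
#' @param G genomic relationship matrix covering every line in `phenos`.
#' @param target_env environment to hold out and predict.
#' @param trait trait label; defaults to the single trait present.
#' @param include_ge include the interaction kernel (M1_GE) or not
#'   (M1_NO_GE).
#' @param env_scale divisor of the environmental incidence kernel.
#' @param ... further arguments passed to [fit_gblup()] (e.g. `fix`,
#'   `method`, `tol`).
#' @return a `data.frame` of class `"gp_predictions"` with one row per line:
#'   columns `line`, `env`, `trait`, `observed`, `predicted`, `model`. The
#'   full mixed-model fit is attached as attribute `"fit"`.
#' @export
fit_m1 <- function(phenos, G, target_env, trait = NULL, include_ge = TRUE,
                   env_scale = 1, ...) {
  info <- check_phenotypes(phenos)
  if (is.null(trait)) {
    if (length(info$traits) > 1L)
      stop("multiple traits present; specify `trait`")
    trait <- info$traits
  }
  if (!target_env %in% info$envs)
    stop("target environment not in phenotypes: ", target_env)
  if (length(info$envs) < 2L)
    stop("M1 needs at least 2 environments")
  missing_lines <- setdiff(info$lines, rownames(G))
  if (length(missing_lines))
    stop("line(s) without genotype in G: ",
         paste(utils::head(missing_lines, 5L), collapse = ", "))

  Y <- pheno_matrix(phenos, trait)
  J <- nrow(Y)
  envs <- colnames(Y)
  # Observation index: environment-major, lines in panel order within each.
  env_lab <- rep(envs, each = J)
  line_lab <- rep(rownames(Y), times = length(envs))
  y <- as.vector(Y)
  y_obs <- y
  y[env_lab == target_env] <- NA

  H <- env_kernel(env_lab, scale = env_scale)
  Kg <- line_kernel(line_lab, G)
  kernels <- list(env = H, line = Kg)
  if (include_ge) kernels$gxe <- H * Kg

  fit <- fit_gblup(y, kernels, ...)
  sel <- env_lab == target_env
  out <- data.frame(line = line_lab[sel], env = target_env, trait = trait,
                    observed = y_obs[sel], predicted = fit$fitted[sel],
                    model = if (include_ge) "M1_GE" else "M1_NO_GE",
                    stringsAsFactors = FALSE)
  class(out) <- c("gp_predictions", "data.frame")
  attr(out, "fit") <- fit
  out
}
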