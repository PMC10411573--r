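#' Enumerate unordered environment pairs
#'
#' All `choose(I, 2)` pairs of distinct environments, ordered
#' lexicographically by position in the input ordering, with each pair's
#' first element the earlier one: `(E1,E2), (E1,E3), ..., (E_{I-1},E_I)`.
#'
#' @param envs ordered vector of distinct environment identifiers.
#' @return data.frame with columns `env_i`, `env_iprime`, one row per pair.
#' @examples
#' enumerate_env_pairs(c("E1", "E2", "E3"))
#' @export
enumerate_env_pairs <- function(envs) {
  envs <- as.character(envs)
  if (anyDuplicated(envs))
    stop("duplicate environment identifiers: ",
         paste(unique(envs[duplicated(envs)]), collapse = ", "))
  if (length(envs) < 2L) stop("need at least 2 environments")
  idx <- utils::combn(length(envs), 2L)
  data.frame(env_i = envs[idx[1L, ]], env_iprime = envs[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Build the stacked difference frame
#'
#' The difference-response method replaces the phenotype as training target
#' with pairwise between-environment differences. For every environment pair
#' `(E_i, E_i')` (see [enumerate_env_pairs()]) and every line `j` it computes
#' `d_{i,i',j} = y_{ij} - y_{i'j}` and stacks the pair blocks — lines in
#' panel order within each block — into one frame of `J * choose(I, 2)`
#' rows with columns `obs`, `line`, `env_i`, `env_iprime`, `y_i`,
#' `y_iprime`, `d`.
#'
#' @inheritParams fit_m1
#' @return a `data.frame` of class `"diff_frame"`; the pair ordering is
#'   attached as attribute `"pair_order"`.
#' @export
difference_frame <- function(phenos, trait = NULL) {
  info <- check_phenotypes(phenos, trait)
  if (is.null(trait)) {
    if (length(info$traits) > 1L)
      stop("multiple traits present; specify `trait`")
    trait <- info$traits
  }
  if (length(info$envs) < 3L)
    stop("the difference-response method requires at least 3 environments (I >= 3)")
  Y <- pheno_matrix(phenos, trait)
  if (anyNA(Y)) stop("missing phenotype value(s) in the balanced table")
  pairs <- enumerate_env_pairs(colnames(Y))
  J <- nrow(Y)
  blocks <- lapply(seq_len(nrow(pairs)), function(b) {
    yi <- Y[, pairs$env_i[b]]
    yip <- Y[, pairs$env_iprime[b]]
    data.frame(line = rownames(Y), env_i = pairs$env_i[b],
               env_iprime = pairs$env_iprime[b], y_i = yi, y_iprime = yip,
               d = yi - yip, stringsAsFactors = FALSE, row.names = NULL)
  })
  frame <- do.call(rbind, blocks)
  frame <- cbind(obs = seq_len(nrow(frame)), frame)
  attr(frame, "pair_order") <- pairs
  attr(frame, "trait") <- trait
  class(frame) <- c("diff_frame", "data.frame")
  frame
}

#' Mask the difference response for a target environment
#'
#' Every row whose pair involves `target_env` gets `d = NA`: those rows form
#' the testing set of the difference model, the remaining rows the training
#' set. For a frame with I environments exactly `J * (I - 1)` rows are
#' masked.
#'
#' @param frame a [difference_frame()].
#' @param target_env the environment to be predicted.
#' @return the frame with `d` set to `NA` on the testing rows.
#' @export
mask_target_env <- function(frame, target_env) {
  if (!inherits(frame, "diff_frame")) stop("`frame` must be a diff_frame")
  sel <- frame$env_i == target_env | frame$env_iprime == target_env
  if (!any(sel))
    stop("target environment not present in the difference frame: ",
         target_env)
  frame$d[sel] <- NA_real_
  attr(frame, "target_env") <- target_env
  frame
}

#' Fit the difference GBLUP and predict masked differences
#'
#' Fits `d_{i,i',j} = mu + g_j + eps` on the unmasked rows of a masked
#' difference frame — an intercept plus a line effect with covariance
#' `sigma^2_g G` and an i.i.d. residual — and returns predictions `d-hat`
#' for the masked rows, in frame order.
#'
#' @param frame a masked [difference_frame()] (see [mask_target_env()]).
#' @param G genomic relationship matrix covering every line in the frame.
#' @param ... passed to [fit_gblup()].
#' @return numeric vector of predicted differences for the masked rows,
#'   named by their `obs` index; the mixed-model fit is attached as
#'   attribute `"fit"`.
#' @export
fit_difference_model <- function(frame, G, ...) {
  if (!inherits(frame, "diff_frame")) stop("`frame` must be a diff_frame")
  if (!anyNA(frame$d)) stop("frame has no masked rows; mask_target_env() first")
  if (all(is.na(frame$d))) stop("no training rows: every difference is masked")
  Kg <- line_kernel(frame$line, G)
  fit <- fit_gblup(frame$d, kernels = list(line = Kg), ...)
  d_hat <- predict(fit)
  names(d_hat) <- frame$obs[is.na(frame$d)]
  attr(d_hat, "fit") <- fit
  d_hat
}

#' Ensemble reconstruction of target-environment phenotypes
#'
#' Converts predicted differences back to the phenotype scale. For target
#' environment `t` and line `j`, each of the `I - 1` masked pairs containing
#' `t` pairs it with a training environment `i'`; the ensemble averages the
#' `I - 1` terms
#' \deqn{\hat y_{t,j} = \frac{1}{I-1}\sum_{i'} (y_{i',j} + s\,\hat d),}
#' where `s = +1` when `t` is the pair's first element (`d` estimates
#' `y_t - y_{i'}`) and `s = -1` when it is the second (`d` estimates
#' `y_{i'} - y_t`). Only training-environment phenotypes enter, which is why
#' a mean shift confined to the target environment cannot propagate into the
#' predictions.
#'
#' @param frame a masked [difference_frame()].
#' @param d_hat predicted differences for the masked rows, in frame order
#'   (see [fit_difference_model()]).
#' @param target_env the masked environment.
#' @return a `data.frame` of class `"gp_predictions"` with one row per line
#'   (`line`, `env`, `trait`, `observed`, `predicted`, `model = "M2"`).
#' @export
ensemble_from_differences <- function(frame, d_hat, target_env) {
  if (!inherits(frame, "diff_frame")) stop("`frame` must be a diff_frame")
  masked <- which(is.na(frame$d))
  sel <- frame$env_i == target_env | frame$env_iprime == target_env
  if (!setequal(masked, which(sel)))
    stop("masked rows do not correspond to target environment ", target_env)
  if (length(d_hat) != length(masked))
    stop("`d_hat` has length ", length(d_hat), ", expected ",
         length(masked), " (J * (I - 1) masked rows)")
  sub <- frame[masked, , drop = FALSE]
  first <- sub$env_i == target_env
  # Training-environment phenotype of each masked row, and the signed d-hat.
  y_train <- ifelse(first, sub$y_iprime, sub$y_i)
  term <- y_train + ifelse(first, 1, -1) * d_hat
  lines <- unique(sub$line)
  pred <- vapply(lines, function(l) mean(term[sub$line == l]), numeric(1))
  obs_y <- vapply(lines, function(l) {
    v <- c(sub$y_i[first & sub$line == l], sub$y_iprime[!first & sub$line == l])
    if (length(v)) v[1L] else NA_real_
  }, numeric(1))
  out <- data.frame(line = lines, env = target_env,
                    trait = attr(frame, "trait") %||% NA_character_,
                    observed = obs_y, predicted = unname(pred),
                    model = "M2", stringsAsFactors = FALSE)
  class(out) <- c("gp_predictions", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Difference-response prediction of a held-out environment (M2)
#'
#' Runs the full difference-response pipeline for one trait and one target
#' environment: build the stacked difference frame, mask every pair
#' involving the target environment, fit the difference GBLUP on the
#' remaining pairs, and reconstruct target-environment predictions as the
#' ensemble over the `I - 1` predicted differences per line. Requires at
#' least three environments, so that at least one pair remains for
#' training.
#'
#' @inheritParams fit_m1
#' @param ... passed to [fit_gblup()].
#' @return a `"gp_predictions"` data.frame as in [fit_m1()], with
#'   `model = "M2"` and the difference-model fit attached as attribute
#'   `"fit"`.
#' @export
fit_m2 <- function(phenos, G, target_env, trait = NULL, ...) {
  frame <- difference_frame(phenos, trait)
  frame <- mask_target_env(frame, target_env)
  d_hat <- fit_difference_model(frame, G, ...)
  out <- ensemble_from_differences(frame, d_hat, target_env)
  attr(out, "fit") <- attr(d_hat, "fit")
  out
}
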