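#' Leave-one-environment-out folds
#'
#' One fold per environment, in first-appearance order: each environment
#' serves once as the complete testing set while the remaining environments
#' form the training set.
#'
#' @inheritParams fit_m1
#' @return list of folds, each `list(target_env, training_envs)`.
#' @export
loeo_folds <- function(phenos) {
  info <- check_phenotypes(phenos)
  if (length(info$envs) < 2L) stop("LOEO needs at least 2 environments")
  lapply(info$envs, function(e)
    list(target_env = e, training_envs = setdiff(info$envs, e)))
}

#' Pearson correlation between observed and predicted values
#'
#' Computed within each (trait, env) group of a prediction table; the
#' average Pearson correlation (APC) is the mean over groups. Groups with a
#' constant observed or predicted vector have no defined correlation; they
#' are reported as `NA` with a warning and excluded from averages.
#'
#' @param results a `"gp_predictions"` data.frame (columns `trait`, `env`,
#'   `model`, `observed`, `predicted`).
#' @return data.frame with one row per (trait, env, model) and column
#'   `value`.
#' @export
pearson_apc <- function(results) {
  metric_by_group(results, function(o, p) {
    if (length(o) < 3L || stats::sd(o) == 0 || stats::sd(p) == 0) {
      warning("constant vector in a correlation group; reported as NA")
      return(NA_real_)
    }
    stats::cor(o, p)
  }, metric = "APC")
}

#' Top-line capture (Best10 / Best20)
#'
#' Percentage of the truly best `fraction` of lines (by observed value,
#' within an environment) that also rank in the best `fraction` by
#' prediction. `k = max(1, round(fraction * J))` lines are selected on each
#' side; ties are broken by line order in the table (stable and
#' deterministic). "Best" means largest when `higher_is_better` (yield-type
#' traits) and smallest otherwise (e.g. a 1-5 disease-severity scale).
#'
#' @inheritParams pearson_apc
#' @param fraction selected fraction of lines, in (0, 1); 0.10 gives Best10,
#'   0.20 gives Best20.
#' @param higher_is_better direction of favorability (default `TRUE`).
#' @return data.frame with one row per (trait, env, model), values in
#'   percent.
#' @export
top_capture <- function(results, fraction, higher_is_better = TRUE) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("`fraction` must be a single number in (0, 1)")
  metric_by_group(results, function(o, p) {
    k <- max(1L, round(fraction * length(o)))
    s <- if (higher_is_better) -1 else 1
    top_o <- order(s * o)[seq_len(k)]
    top_p <- order(s * p)[seq_len(k)]
    100 * length(intersect(top_o, top_p)) / k
  }, metric = sprintf("Best%d", round(100 * fraction)))
}

#' Normalized root mean squared error
#'
#' RMSE between observed and predicted values divided by a per-group
#' normalizer: the absolute mean of the observed values (default) or their
#' range. Lower is better; the ratio is invariant to rescaling both vectors.
#'
#' @inheritParams pearson_apc
#' @param normalize `"mean"` (RMSE / |mean(observed)|) or `"range"`
#'   (RMSE / (max - min)).
#' @return data.frame with one row per (trait, env, model).
#' @export
nrmse <- function(results, normalize = c("mean", "range")) {
  normalize <- match.arg(normalize)
  metric_by_group(results, function(o, p) {
    rmse <- sqrt(mean((o - p)^2))
    denom <- if (normalize == "mean") abs(mean(o)) else diff(range(o))
    if (denom == 0)
      stop("zero ", if (normalize == "mean") "group mean" else "range",
           " in NRMSE; try normalize = \"",
           setdiff(c("mean", "range"), normalize), "\"")
    rmse / denom
  }, metric = "NRMSE")
}

# Apply a two-vector metric within every (trait, env, model) group.
metric_by_group <- function(results, f, metric) {
  need <- c("trait", "env", "model", "observed", "predicted")
  if (!all(need %in% names(results)))
    stop("`results` must have columns ", paste(need, collapse = ", "))
  groups <- unique(results[, c("trait", "env", "model")])
  groups$metric <- metric
  groups$value <- vapply(seq_len(nrow(groups)), function(i) {
    sel <- results$trait == groups$trait[i] & results$env == groups$env[i] &
      results$model == groups$model[i]
    f(results$observed[sel], results$predicted[sel])
  }, numeric(1))
  rownames(groups) <- NULL
  groups
}

#' Relative gain of one model over another
#'
#' Percent improvement of a challenger metric over a reference. For metrics
#' where larger is better (APC, Best10, Best20) the gain is
#' `100 * (challenger - reference) / |reference|`; for lower-is-better
#' metrics (NRMSE) it is `100 * (reference - challenger) / |challenger|`,
#' which allows gains above 100% when the challenger error is less than half
#' the reference error.
#'
#' @param challenger,reference metric values.
#' @param higher_is_better direction of the metric.
#' @return gain in percent; `NA` with a warning when the denominator is 0.
#' @export
relative_gain <- function(challenger, reference, higher_is_better = TRUE) {
  denom <- if (higher_is_better) abs(reference) else abs(challenger)
  out <- ifelse(denom == 0, NA_real_,
                if (higher_is_better) 100 * (challenger - reference) / denom
                else 100 * (reference - challenger) / denom)
  if (anyNA(out) && any(denom == 0))
    warning("zero denominator in relative gain; reported as NA")
  out
}

#' Leave-one-environment-out evaluation of the competing predictors
#'
#' Drives the full study: for every trait and every LOEO fold, fits the
#' requested models (M1_NO_GE, M1_GE, and/or the difference-response M2),
#' predicts the held-out environment, and scores the predictions with APC,
#' Best10, Best20 and NRMSE. Per-environment metrics are averaged within
#' trait, then across traits; pairwise relative gains are computed on the
#' across-trait averages.
#'
#' @inheritParams fit_m1
#' @param models subset of `c("M1_NO_GE", "M1_GE", "M2")`.
#' @param traits traits to evaluate (default: all present).
#' @param higher_is_better named logical (per trait) or single flag:
#'   direction of favorability for ranking metrics.
#' @param nrmse_normalize passed to [nrmse()].
#' @param ... passed to [fit_gblup()] via the model fitters.
#' @return object of class `"loeo_eval"`: list with `predictions` (all
#'   held-out predictions), `metrics` (tidy per trait/env/model/metric),
#'   `by_trait` (per-trait averages over environments), `summary`
#'   (across-trait averages per model/metric) and `gains` (pairwise relative
#'   gains on the summary).
#' @export
loeo_evaluate <- function(phenos, G, models = c("M1_NO_GE", "M1_GE", "M2"),
                          traits = NULL, higher_is_better = TRUE,
                          nrmse_normalize = "mean", ...) {
  models <- match.arg(models, c("M1_NO_GE", "M1_GE", "M2"),
                      several.ok = TRUE)
  info <- check_phenotypes(phenos)
  if (is.null(traits)) traits <- info$traits
  folds <- loeo_folds(phenos)

  preds <- list()
  for (tr in traits) {
    for (fold in folds) {
      te <- fold$target_env
      if ("M1_NO_GE" %in% models)
        preds[[length(preds) + 1L]] <-
          fit_m1(phenos, G, te, tr, include_ge = FALSE, ...)
      if ("M1_GE" %in% models)
        preds[[length(preds) + 1L]] <-
          fit_m1(phenos, G, te, tr, include_ge = TRUE, ...)
      if ("M2" %in% models)
        preds[[length(preds) + 1L]] <- fit_m2(phenos, G, te, tr, ...)
    }
  }
  predictions <- do.call(rbind, lapply(preds, function(p) {
    attr(p, "fit") <- NULL
    as.data.frame(p)
  }))

  dir_for <- function(tr) {
    if (length(higher_is_better) == 1L && is.null(names(higher_is_better)))
      higher_is_better
    else if (tr %in% names(higher_is_better)) higher_is_better[[tr]]
    else TRUE
  }
  metrics <- do.call(rbind, lapply(traits, function(tr) {
    sub <- predictions[predictions$trait == tr, ]
    rbind(pearson_apc(sub),
          top_capture(sub, 0.10, dir_for(tr)),
          top_capture(sub, 0.20, dir_for(tr)),
          nrmse(sub, nrmse_normalize))
  }))

  by_trait <- stats::aggregate(value ~ trait + model + metric, metrics,
                               mean, na.rm = TRUE)
  summary_tab <- stats::aggregate(value ~ model + metric, by_trait,
                                  mean, na.rm = TRUE)

  gains <- NULL
  if (length(models) > 1L) {
    combos <- utils::combn(models, 2L)
    gains <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
      a <- combos[1L, i]; b <- combos[2L, i]
      do.call(rbind, lapply(unique(summary_tab$metric), function(mt) {
        va <- summary_tab$value[summary_tab$model == a &
                                  summary_tab$metric == mt]
        vb <- summary_tab$value[summary_tab$model == b &
                                  summary_tab$metric == mt]
        hib <- mt != "NRMSE"
        data.frame(challenger = b, reference = a, metric = mt,
                   gain = suppressWarnings(relative_gain(vb, va, hib)),
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(gains) <- NULL
  }

  out <- list(predictions = predictions, metrics = metrics,
              by_trait = by_trait, summary = summary_tab, gains = gains,
              models = models, traits = traits)
  class(out) <- "loeo_eval"
  out
}

#' @export
print.loeo_eval <- function(x, digits = 4, ...) {
  cat("Leave-one-environment-out evaluation\n")
  cat("  traits:", paste(x$traits, collapse = ", "), "\n")
  cat("  models:", paste(x$models, collapse = ", "), "\n\n")
  cat("Across-trait averages:\n")
  wide <- stats::reshape(x$summary, idvar = "metric", timevar = "model",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(format(wide, digits = digits), row.names = FALSE)
  if (!is.null(x$gains)) {
    cat("\nRelative gains (%):\n")
    print(format(x$gains, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.loeo_eval <- function(object, ...) object$summary

#' Bar chart of per-model accuracy metrics
#'
#' One panel per metric, bars grouped by model, across-trait averages.
#'
#' @param x a [loeo_evaluate()] result.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.loeo_eval <- function(x, ...) {
  mets <- unique(x$summary$metric)
  op <- graphics::par(mfrow = c(2, ceiling(length(mets) / 2)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (mt in mets) {
    sub <- x$summary[x$summary$metric == mt, ]
    graphics::barplot(sub$value, names.arg = sub$model, main = mt,
                      ylab = mt, ...)
  }
  invisible(x)
}
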