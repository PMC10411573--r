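#' Validate a long-format phenotype table
#'
#' Phenotypes are stored long: one row per (line, environment, trait) with
#' columns `line`, `env`, `trait`, `value`. For each trait the table must be
#' balanced — every line observed exactly once in every environment (the
#' design both the conventional and the difference-response predictors
#' assume). Line and environment orderings are taken from first appearance.
#'
#' @param phenos data.frame with columns `line`, `env`, `trait`, `value`.
#' @param trait optional trait label to restrict the check to.
#' @return invisibly, a list with `lines`, `envs`, `traits` (character
#'   vectors in first-appearance order).
#' @export
check_phenotypes <- function(phenos, trait = NULL) {
  need <- c("line", "env", "trait", "value")
  if (!is.data.frame(phenos) || !all(need %in% names(phenos)))
    stop("`phenos` must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (!is.null(trait)) {
    phenos <- phenos[phenos$trait == trait, , drop = FALSE]
    if (!nrow(phenos)) stop("trait not found: ", trait)
  }
  if (!is.numeric(phenos$value)) stop("`value` must be numeric")
  key <- paste(phenos$line, phenos$env, phenos$trait, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- phenos[duplicated(key), c("line", "env", "trait")]
    stop("duplicate (line, env, trait) records: ",
         paste(utils::head(paste0("(", dup$line, ", ", dup$env, ", ",
                                  dup$trait, ")"), 3L), collapse = " "))
  }
  lines <- unique(as.character(phenos$line))
  envs <- unique(as.character(phenos$env))
  traits <- unique(as.character(phenos$trait))
  for (tr in traits) {
    sub <- phenos[phenos$trait == tr, ]
    have <- paste(sub$line, sub$env, sep = "\r")
    want <- as.vector(outer(lines, envs, paste, sep = "\r"))
    miss <- setdiff(want, have)
    if (length(miss)) {
      cell <- strsplit(miss[1L], "\r", fixed = TRUE)[[1L]]
      stop("unbalanced phenotype table for trait \"", tr, "\": missing (line ",
           cell[1L], ", env ", cell[2L], ")",
           if (length(miss) > 1L) paste0(" and ", length(miss) - 1L, " more"))
    }
  }
  invisible(list(lines = lines, envs = envs, traits = traits))
}

# Wide J x I matrix of one trait's values, lines in rows (first-appearance
# order), environments in columns.
pheno_matrix <- function(phenos, trait) {
  info <- check_phenotypes(phenos, trait)
  sub <- phenos[phenos$trait == trait, ]
  Y <- matrix(NA_real_, length(info$lines), length(info$envs),
              dimnames = list(info$lines, info$envs))
  Y[cbind(match(as.character(sub$line), info$lines),
          match(as.character(sub$env), info$envs))] <- sub$value
  Y
}
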