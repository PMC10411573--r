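#' Read a long-format phenotype CSV
#'
#' Expects a header `line,env,trait,value`; `value` may be empty or `NA`
#' for a missing record. Balance (every line once in every environment, per
#' trait) and duplicate records are validated on load.
#'
#' @param path CSV file path.
#' @return validated phenotype data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(line = "character",
                                       env = "character",
                                       trait = "character"))
  need <- c("line", "env", "trait", "value")
  if (!all(need %in% names(df)))
    stop("phenotype file must have columns ", paste(need, collapse = ", "),
         "; found: ", paste(names(df), collapse = ", "))
  if (!is.numeric(df$value)) {
    val <- suppressWarnings(as.numeric(df$value))
    bad <- which(!is.na(df$value) & df$value != "" & df$value != "NA" &
                   is.na(val))
    if (length(bad))
      stop("non-numeric phenotype value at data row ", bad[1L], ": \"",
           df$value[bad[1L]], "\"")
    df$value <- val
  }
  check_phenotypes(df)
  df
}

#' @rdname read_phenotypes
#' @param phenos phenotype data.frame.
#' @export
write_phenotypes <- function(phenos, path) {
  check_phenotypes(phenos)
  utils::write.csv(phenos[, c("line", "env", "trait", "value")], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a genotype matrix
#'
#' CSV format: first column `line`, one column per marker, entries 0/1/2 or
#' empty/`NA` for missing. VCF format (requires the `vcfR` package):
#' biallelic SNPs are converted to alternate-allele dosage; multi-allelic
#' records are skipped with a warning reporting the count.
#'
#' @param path file path.
#' @param format `"csv"` or `"vcf"`.
#' @return numeric dosage matrix, lines x markers (see [check_markers()]).
#' @export
read_genotypes <- function(path, format = c("csv", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(read_genotypes_vcf(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "line")
    stop("genotype CSV must have `line` as its first column")
  M <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(M) <- "numeric"
  rownames(M) <- as.character(df$line)
  check_markers(M)
  M
}

#' @rdname read_genotypes
#' @param markers dosage matrix.
#' @export
write_genotypes <- function(markers, path) {
  check_markers(markers)
  df <- data.frame(line = rownames(markers), markers,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the `vcfR` package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    vcf <- vcf[!multi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dosage <- function(x) {
    x <- sub(":.*", "", x)
    ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(x, "[/|]"), function(a)
             sum(as.numeric(a) > 0), numeric(1)))
  }
  M <- t(apply(gt, 1L, dosage))
  dimnames(M) <- list(rownames(gt), colnames(gt))
  M <- t(M)  # lines x markers
  if (is.null(colnames(M)) || anyDuplicated(colnames(M)))
    colnames(M) <- make.unique(vcfR::getID(vcf)[!multi])
  check_markers(M)
  M
}

#' Export a (masked) difference frame as CSV
#'
#' Columns `obs, line, env_i, env_iprime, y_i, y_iprime, d`, with masked
#' differences written as empty fields.
#'
#' @param frame a [difference_frame()], masked or not.
#' @param path output CSV path.
#' @export
write_difference_frame <- function(frame, path) {
  if (!inherits(frame, "diff_frame")) stop("`frame` must be a diff_frame")
  utils::write.csv(as.data.frame(frame), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Serialize an evaluation report
#'
#' Writes the tidy metric table as CSV (`trait, env, model, metric, value`)
#' and, when `json_path` is given, a JSON summary with across-trait averages
#' and pairwise gains.
#'
#' @param eval a [loeo_evaluate()] result.
#' @param csv_path metrics CSV path.
#' @param json_path optional JSON summary path.
#' @export
write_metric_report <- function(eval, csv_path, json_path = NULL) {
  if (!inherits(eval, "loeo_eval")) stop("`eval` must be a loeo_eval")
  utils::write.csv(eval$metrics[, c("trait", "env", "model", "metric",
                                    "value")],
                   csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(summary = eval$summary, by_trait = eval$by_trait,
           gains = eval$gains),
      json_path, dataframe = "rows", digits = NA, auto_unbox = TRUE,
      pretty = TRUE)
  }
  invisible(csv_path)
}
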