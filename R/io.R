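# Tab-delimited readers/writers for the pipeline's on-disk interchange
# formats. All tables carry a header row; genomic positions are 1-based.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write a simulated cohort to a directory
#'
#' Emits the pipeline's interchange files: snp_panel.tsv, cn_logratio.tsv,
#' expression.tsv, annotation.tsv, samples.tsv, patients.tsv, screen.tsv and
#' truth.json (the planted ground truth). All tables are tab-delimited with
#' a header row.
#'
#' @param cohort list as returned by [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv(cohort$panel, p("snp_panel.tsv"))
  write_matrix_tsv(cohort$cn, p("cn_logratio.tsv"), "probe_id")
  write_matrix_tsv(cohort$expr, p("expression.tsv"), "transcript_id")
  write_tsv(cohort$annotation, p("annotation.tsv"))
  write_tsv(cohort$samples, p("samples.tsv"))
  if (!is.null(cohort$patients)) write_tsv(cohort$patients, p("patients.tsv"))
  if (!is.null(cohort$screen)) write_tsv(cohort$screen, p("screen.tsv"))
  jsonlite::write_json(cohort$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing the interchange files.
#' @return list with panel, cn, expr, annotation, samples, and (if present)
#'   patients, screen, truth.
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  out <- list(panel = read_tsv(p("snp_panel.tsv")),
              cn = read_matrix_tsv(p("cn_logratio.tsv")),
              expr = read_matrix_tsv(p("expression.tsv")),
              annotation = read_tsv(p("annotation.tsv")),
              samples = read_tsv(p("samples.tsv")))
  if (file.exists(p("patients.tsv"))) out$patients <- read_tsv(p("patients.tsv"))
  if (file.exists(p("screen.tsv"))) out$screen <- read_tsv(p("screen.tsv"))
  if (file.exists(p("truth.json"))) out$truth <- jsonlite::read_json(p("truth.json"),
                                                                     simplifyVector = TRUE)
  out
}
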