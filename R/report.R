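#' Bundled example dataset: high-altitude sojourn volumetry and CVR
#'
#' Per-subject values from a longitudinal study of six healthy adults imaged
#' before and one week after a three-week sojourn at 5050 m: gray- and
#' white-matter volumes with percent changes and white-matter hyperintensity
#' counts (`volumetry`; lesion reads are missing for one subject's baseline),
#' gray- and white-matter CVR with percent changes (`cvr`), and resting
#' respiratory summaries as mean (SE) pairs (`rest`). Shipped as plain CSV
#' under `extdata` and used by the package's worked examples and acceptance
#' checks of the group-statistics machinery.
#'
#' @return Named list of tibbles: `volumetry`, `cvr`, `rest`.
#' @examples
#' tabs <- altitude_study_tables()
#' mean(tabs$cvr$gm_pre)  # 0.31
#' @export
altitude_study_tables <- function() {
  rd <- function(f) {
    tibble::as_tibble(utils::read.csv(
      system.file("extdata", f, package = "cvrmap", mustWork = TRUE)
    ))
  }
  list(
    volumetry = rd("altitude_volumetry.csv"),
    cvr = rd("altitude_cvr.csv"),
    rest = rd("altitude_rest.csv")
  )
}

#' Append mean and standard-error rows to a per-subject table
#'
#' Reproduces the usual publication layout: one row per subject and a final
#' mean (SE) pair computed from the subject rows, for every numeric column.
#'
#' @param data Tibble with a subject identifier column and numeric columns.
#' @param subject_col Name of the identifier column.
#' @return The table with two extra rows, `mean` and `se` in `subject_col`;
#'   NA values are dropped column-wise.
#' @export
summary_table <- function(data, subject_col = "subject") {
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  num <- setdiff(num, subject_col)
  mrow <- srow <- data[1, ]
  mrow[] <- NA
  srow[] <- NA
  mrow[[subject_col]] <- "mean"
  srow[[subject_col]] <- "se"
  for (cn in num) {
    v <- data[[cn]][!is.na(data[[cn]])]
    mrow[[cn]] <- mean(v)
    srow[[cn]] <- stats::sd(v) / sqrt(length(v))
  }
  out <- data
  out[[subject_col]] <- as.character(out[[subject_col]])
  dplyr::bind_rows(out, mrow, srow)
}

#' Assemble and write the analysis report
#'
#' Collects whatever stage outputs are available — per-subject volumetric and
#' CVR tables (given mean (SE) rows via [summary_table()]), regional and
#' compartment summaries, fractional distributions — writes each as CSV, and
#' writes a JSON manifest recording parameters, seeds, the package version
#' and which stages were present. Missing stages are listed in the manifest;
#' the partial report is still written.
#'
#' @param dir Output directory.
#' @param volumetry,cvr Per-subject tibbles (one row per subject).
#' @param regional,compartments,distributions Optional tidy tibbles.
#' @param params Named list of parameters to record.
#' @param seed Seed(s) to record.
#' @return Invisibly, a list of the tables written plus the manifest.
#' @export
build_report <- function(dir, volumetry = NULL, cvr = NULL, regional = NULL,
                         compartments = NULL, distributions = NULL,
                         params = list(), seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list(volumetry = volumetry, cvr = cvr, regional = regional,
                 compartments = compartments, distributions = distributions)
  written <- list()
  for (nm in names(stages)) {
    x <- stages[[nm]]
    if (is.null(x)) next
    if (nm %in% c("volumetry", "cvr") && "subject" %in% names(x)) {
      x <- summary_table(x)
    }
    utils::write.csv(x, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    written[[nm]] <- x
  }
  manifest <- list(
    stages_present = names(written),
    stages_missing = setdiff(names(stages), names(written)),
    params = params,
    seed = seed,
    package_version = as.character(utils::packageVersion("cvrmap")),
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(written, list(manifest = manifest)))
}
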