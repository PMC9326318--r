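# MD5 sums of the packaged cohort tables; load_fixture() refuses to parse
# a tampered file.
FIXTURE_MD5 <- c(
  table1 = "64711be42902a75b15ec02db5adeb1f3",
  table2 = "e975478413e9b1244f4293479e926004",
  table3 = "358562bc7a452f25b60d0cfcc98262e1",
  table4 = "7580cd80ace0fd351f295b553c48895d")

#' Load a packaged cohort fixture table
#'
#' The package bundles the published cohort tables of the 17-patient
#' high-grade glioma study as plain CSV: clinical/molecular records
#' (`table1`), per-patient habitat volume fractions (`table2`),
#' per-habitat map medians (`table3`, MD in 10^-3 mm^2/s), and the
#' per-biopsy histology/habitat rows (`table4`). Files are
#' checksum-verified before parsing.
#'
#' @param name `"table1"`, `"table2"`, `"table3"` or `"table4"`.
#' @param path optional override of the bundled file (checksum still
#'   enforced).
#' @return a typed data.frame:
#'   * `table1`: one row per patient (`subject_id`, `age`, `sex`,
#'     `ce_volume`, `flair_volume` in cm^3, `n_lesions`, `procedure`,
#'     `histology_grade`, `mgmt`, `idh1`, `os_weeks`, ...).
#'   * `table2`: one row per patient with `frac_1`..`frac_8` (percent);
#'     the printed per-habitat row averages are kept in attribute
#'     `printed_row_average` and the habitat H/L definition in attribute
#'     `definition`.
#'   * `table3`: long rows `map`, `habitat` (`"1"`..`"8"`, `"whole"`),
#'     `case_1`..`case_17`, `row_average`.
#'   * `table4`: one row per biopsy sample with `cellularity`,
#'     `necrosis_class`, `vessels` and the prevalence-ordered `habitats`
#'     string.
#' @export
load_fixture <- function(name = c("table1", "table2", "table3", "table4"),
                         path = NULL) {
  name <- match.arg(name)
  if (is.null(path))
    path <- system.file("extdata", paste0(name, ".csv"),
                        package = "gliohabitats", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(FIXTURE_MD5[name])))
    stop(sprintf("fixture '%s' checksum mismatch (%s): file corrupted or modified",
                 name, sum))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = if (name == "table1") c(subject_id = "character")
                                     else if (name == "table4") c(subject_id = "character", sample_label = "character")
                                     else NA)
  switch(name,
    table1 = df,
    table2 = {
      cases <- grep("^case_", names(df), value = TRUE)
      frac <- t(as.matrix(df[, cases]))
      colnames(frac) <- paste0("frac_", df$habitat)
      out <- cbind(data.frame(subject_id = sub("^case_", "", cases),
                              stringsAsFactors = FALSE),
                   as.data.frame(frac))
      rownames(out) <- NULL
      attr(out, "printed_row_average") <- stats::setNames(df$row_average,
                                                          paste0("habitat_", df$habitat))
      attr(out, "definition") <- df[, c("habitat", "perfusion", "hypoxia", "diffusivity")]
      out
    },
    table3 = {
      df$habitat <- as.character(df$habitat)
      df
    },
    table4 = df)
}
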