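.fixture_md5 <- c(
  pipc_final = "333bfdfb373c69f5759dc890710922cd",
  taz_final = "6e301c34ccd555d0e656ccbb2c9fc5ed",
  table1_cohort = "8299fb57eebab1f8b7f24fc867029c87",
  table4_breakpoints = "ead758a860438ead380073ccdc15bc00",
  table5_recommendations = "a2c056dfa5ef6c9099a4e0964367f4ba",
  taz_attainment_reference = "f95f504e4258c191ce1dce5244e8a9e2"
)

#' Load a packaged reference table
#'
#' The package ships the reference study's summary tables as plain-CSV
#' fixtures: final population-model estimates per analyte
#' (`"pipc_final"`, `"taz_final"`), cohort demographics
#' (`"table1_cohort"`), the piperacillin PK/PD breakpoint grid
#' (`"table4_breakpoints"`), the joint dosing recommendation grid
#' (`"table5_recommendations"`) and the tazobactam attainment grid
#' (`"taz_attainment_reference"`).  Files are checksum-verified on load.
#'
#' @param name Fixture name (see above).
#' @return A data frame.
#' @examples
#' load_fixture("pipc_final")
#' @export
load_fixture <- function(name) {
  name <- match.arg(name, names(.fixture_md5))
  path <- system.file("extdata", paste0(name, ".csv"), package = "piptazpk",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[[name]])))
    stop("fixture '", name, "' failed its checksum; file corrupted?")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_fixture(name, tab)
  tab
}

validate_fixture <- function(name, tab) {
  ok <- switch(name,
    pipc_final = ,
    taz_final = all(c("parameter", "estimate") %in% names(tab)) &&
      nrow(tab) == 11 && all(tab$estimate >= 0),
    table1_cohort = all(c("variable", "mean", "sd", "min", "max") %in%
                          names(tab)) && all(tab$min <= tab$mean) &&
      all(tab$mean <= tab$max),
    table4_breakpoints = nrow(tab) == 36 && all(tab$breakpoint > 0),
    table5_recommendations = nrow(tab) == 36 &&
      all(tab$regimen != "" | is.na(tab$regimen)),
    table5_diff = TRUE,
    taz_attainment_reference = nrow(tab) == 36 && is.logical(tab$attain),
    TRUE)
  if (!isTRUE(ok)) stop("fixture '", name, "' failed validation")
  invisible(TRUE)
}
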