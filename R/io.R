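POPULATION_SCHEMA_VERSION <- "1.0"

population_schema <- function() {
  list(
    schema_version = POPULATION_SCHEMA_VERSION,
    persons = list(
      person_id = "integer id, unique within table",
      household_id = "integer id",
      age = "years at interview",
      age_band = "adult band 18-24 ... 65+ (NA for children)",
      sex = "female/male (NA for children)",
      ethnicity = "aggregate category",
      region = "UK nation",
      marital_status = "category",
      employment_status = "category",
      education = "highest qualification",
      earned_income = "GBP/month, gross",
      unearned_income = "GBP/month, gross",
      weight = "persons represented per sample person"
    ),
    households = list(
      household_id = "integer id",
      region = "UK nation",
      tenure = "housing tenure",
      n_adults = "members aged 14+ (OECD adults)",
      n_children = "members aged 0-13",
      weight = "sum of member person weights"
    ),
    panel = list(
      person_id = "integer id", wave = "1..n_waves",
      net_equiv_income = "GBP/month, net equivalised, before housing costs",
      mcs = "SF-12 mental component summary, 0-100",
      pcs = "SF-12 physical component summary, 0-100",
      prior_case_mcs = "case (MCS <= threshold) at previous wave",
      prior_case_pcs = "case (PCS <= threshold) at previous wave",
      attrition = "person was exposed to attrition"
    )
  )
}

#' Write synthetic tables with a versioned schema
#'
#' Writes person/household/panel tables as CSV (and Parquet when the arrow
#' package is installed and `parquet = TRUE`), a versioned JSON schema file,
#' and -- for panels -- the ground-truth generator parameters as a JSON
#' sidecar.
#'
#' @param tables Named list of data frames (e.g. the result of
#'   [gen_cross_section()], optionally plus `panel`).
#' @param dir Output directory.
#' @param parquet Also write Parquet copies.
#' @return Files written, invisibly.
#' @export
write_population <- function(tables, dir, parquet = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tab, path, row.names = FALSE)
    files <- c(files, path)
    if (parquet && requireNamespace("arrow", quietly = TRUE)) {
      pq <- file.path(dir, paste0(nm, ".parquet"))
      arrow::write_parquet(as.data.frame(tab), pq)
      files <- c(files, pq)
    }
    truth <- attr(tab, "truth")
    if (!is.null(truth)) {
      tp <- file.path(dir, paste0(nm, "_truth.json"))
      jsonlite::write_json(unclass(truth), tp, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      files <- c(files, tp)
    }
  }
  sp <- file.path(dir, "schema.json")
  jsonlite::write_json(population_schema(), sp, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(files, sp))
}
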