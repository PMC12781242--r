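# GTEx subject phenotypes and the sample-to-donor identifier rule.

AGE_BRACKETS <- c("20", "30", "40", "50", "60", "70+")

decode_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("1", "m", "male")] <- "male"
  out[key %in% c("2", "f", "female")] <- "female"
  out
}

decode_age_bracket <- function(x) {
  key <- trimws(as.character(x))
  out <- rep(NA_character_, length(key))
  dec <- sub("^([2-7]0)-[0-9]{2}$", "\\1", key)
  hit <- dec %in% c("20", "30", "40", "50", "60", "70")
  out[hit] <- dec[hit]
  out[out %in% "70"] <- "70+"
  out[key == "70+"] <- "70+"
  out
}

#' Read a GTEx subject phenotypes table
#'
#' Tab-separated table with one row per donor, as in
#' `GTEx_Analysis_v10_Annotations_SubjectPhenotypesDS`. Sex is decoded from
#' the GTEx numeric convention (1 = male, 2 = female) or from literal
#' `"male"`/`"female"` (case-insensitive); ages of the form `"20-29"` ...
#' `"70-79"` map to decade brackets (`"70-79"` to `"70+"`). Unknown codes are
#' recorded as missing; such donors' samples are dropped downstream.
#'
#' @param path path to the tab-separated table; must contain `SUBJID`, `SEX`
#'   and `AGE` columns (case-insensitive).
#' @return `data.frame` with columns `donor_id`, `sex` (`"male"`/`"female"`
#'   or `NA`) and `age_bracket` (one of `"20" "30" "40" "50" "60" "70+"` or
#'   `NA`).
#' @export
read_subject_phenotypes <- function(path) {
  if (!file.exists(path)) {
    gd_abort(sprintf("phenotype file not found: %s", path), "gd_io_error")
  }
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, check.names = FALSE)
  want <- c("SUBJID", "SEX", "AGE")
  idx <- match(want, toupper(names(tab)))
  if (anyNA(idx)) {
    gd_abort(sprintf("phenotype table %s lacks required column(s): %s",
                     path, paste(want[is.na(idx)], collapse = ", ")),
             "gd_format_error")
  }
  data.frame(
    donor_id = as.character(tab[[idx[1]]]),
    sex = decode_sex(tab[[idx[2]]]),
    age_bracket = decode_age_bracket(tab[[idx[3]]]),
    stringsAsFactors = FALSE
  )
}

#' Map GTEx sample identifiers to donor identifiers
#'
#' Donor (subject) IDs are the first two hyphen-delimited tokens of the
#' sample ID: `"GTEX-X4EP-0011-R10a-SM-XXXXX"` belongs to donor
#' `"GTEX-X4EP"`.
#'
#' @param sample_id character vector of sample identifiers, each with at
#'   least two hyphen-delimited tokens.
#' @return Character vector of donor identifiers.
#' @export
map_sample_to_donor <- function(sample_id) {
  parts <- strsplit(as.character(sample_id), "-", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    gd_abort(sprintf(
      "sample identifier(s) without a hyphen-delimited donor prefix: %s",
      paste(utils::head(sample_id[bad], 5L), collapse = ", ")),
      "gd_identifier_error")
  }
  vapply(parts, function(p) paste(p[1:2], collapse = "-"), character(1))
}
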