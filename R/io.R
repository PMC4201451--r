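#' Read a long-format EDSS visit table
#'
#' Reads delimited text with one row per EDSS measurement and assembles an
#' [edss_cohort()]. Expected columns are `patient_id`, `edss` and either
#' `time` (years since onset) or `date` (calendar date, converted to years
#' since onset using the metadata's assessed onset year and a 365.25-day
#' year; year-only onsets are resolved to mid-year, 1 July). Rows flagged
#' `source = "expected_midpoint"` are dropped with a message: expected
#' measures are always regenerated, never read.
#'
#' @param path Path to a CSV (or TSV, by extension or `sep`) visit table.
#' @param metadata Optional per-patient metadata: a data frame or path to a
#'   delimited file with columns `patient_id` and any of `onset_year`,
#'   `onset_time` and `groups` (`";"`-separated labels). A patient with an
#'   `onset_year` or `onset_time` entry has a known onset.
#' @param add_anchor If `TRUE` (default), patients with a known onset gain a
#'   synthetic onset-anchor record (time 0, EDSS 0) unless one is present.
#' @param sep Field separator; default `"\t"` for `.tsv` files, `","`
#'   otherwise.
#' @return An [edss_cohort()].
#' @export
read_visits <- function(path, metadata = NULL, add_anchor = TRUE, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)

  meta <- NULL
  if (!is.null(metadata)) {
    meta <- if (is.character(metadata)) {
      msep <- if (grepl("\\.tsv$", metadata)) "\t" else ","
      utils::read.csv(metadata, sep = msep, stringsAsFactors = FALSE)
    } else {
      as.data.frame(metadata)
    }
    meta$patient_id <- as.character(meta$patient_id)
  }

  if (!"time" %in% names(raw)) {
    if (!"date" %in% names(raw)) {
      stop("visit table needs a 'time' or 'date' column", call. = FALSE)
    }
    if (is.null(meta) || !"onset_year" %in% names(meta)) {
      stop("a 'date' column requires metadata with 'onset_year' to anchor time",
           call. = FALSE)
    }
    onset_year <- meta$onset_year[match(as.character(raw$patient_id),
                                        meta$patient_id)]
    if (anyNA(onset_year)) {
      stop("onset_year missing for patient(s) with dated visits: ",
           paste(unique(raw$patient_id[is.na(onset_year)])[1:3], collapse = ", "),
           call. = FALSE)
    }
    onset_date <- as.Date(sprintf("%d-07-01", as.integer(onset_year)))
    raw$time <- as.numeric(as.Date(raw$date) - onset_date) / 365.25
  }

  if (!"source" %in% names(raw)) raw$source <- rep("clinical", nrow(raw))
  n_exp <- sum(raw$source == "expected_midpoint")
  if (n_exp > 0) {
    message("read_visits: dropping ", n_exp,
            " expected_midpoint row(s); expected measures are regenerated, not read")
    raw <- raw[raw$source != "expected_midpoint", , drop = FALSE]
  }

  patients <- NULL
  if (!is.null(meta)) {
    patients <- data.frame(patient_id = meta$patient_id,
                           stringsAsFactors = FALSE)
    known <- rep(FALSE, nrow(meta))
    if ("onset_year" %in% names(meta)) known <- known | !is.na(meta$onset_year)
    if ("onset_time" %in% names(meta)) known <- known | !is.na(meta$onset_time)
    patients$onset_known <- known
    if ("onset_year" %in% names(meta)) patients$onset_year <- meta$onset_year
    if ("groups" %in% names(meta)) patients$groups <- as.character(meta$groups)
  }

  if (add_anchor && !is.null(patients)) {
    known <- patients$patient_id[patients$onset_known]
    have <- unique(raw$patient_id[raw$source == "onset_anchor"])
    need <- setdiff(intersect(known, unique(as.character(raw$patient_id))), have)
    if (length(need)) {
      anchors <- data.frame(patient_id = need, time = 0, edss = 0,
                            source = "onset_anchor", stringsAsFactors = FALSE)
      common <- intersect(names(raw), names(anchors))
      raw <- merge_rows(raw[, c(common, setdiff(names(raw), names(anchors)))],
                        anchors, common)
    }
  }

  coh <- edss_cohort(raw[, intersect(names(raw),
                                     c("patient_id", "time", "edss", "source"))],
                     patients)
  message("read_visits: ", n_records(coh), " records for ", n_patients(coh),
          " patients from ", path)
  coh
}

# rbind two frames on their shared columns, filling the rest with NA.
merge_rows <- function(a, b, common) {
  for (col in setdiff(names(a), names(b))) b[[col]] <- NA
  rbind(a[, union(common, names(a))], b[, union(common, names(a))])
}

#' Write a (possibly augmented) cohort to delimited text
#'
#' Writes one row per record with columns `patient_id`, `time`, `edss`,
#' `source`, `label` (observation label, see [observation_labels()]) and the
#' generating bracket (`bracket_low`, `bracket_high`) for expected-midpoint
#' rows. Numeric fields are written with full double precision, so
#' `read_visits(write_augmented(x))` reproduces the clinical records
#' bit-exactly.
#'
#' @param cohort An [edss_cohort()].
#' @param path Output path; `.tsv` extension selects tab separation.
#' @param metadata_path Optional path to also write the patient metadata
#'   table.
#' @return `path`, invisibly.
#' @export
write_augmented <- function(cohort, path, metadata_path = NULL) {
  stopifnot(inherits(cohort, "edss_cohort"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- as.data.frame(cohort$visits)
  out$label <- cohort_labels(cohort)
  for (col in c("time", "edss", "bracket_low", "bracket_high")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 17, format = "g"))
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata_path)) {
    utils::write.table(as.data.frame(cohort$patients), metadata_path, sep = sep,
                       row.names = FALSE, quote = FALSE)
  }
  message("write_augmented: wrote ", nrow(out), " records to ", path)
  invisible(path)
}
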