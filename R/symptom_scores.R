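# The six rhinoconjunctivitis symptom columns, in canonical order:
# four nasal (sneezing, rhinorrhea, pruritus, nasal congestion) and two
# ocular (ocular pruritus, lacrimation), each graded 0-3 by the patient.
SYMPTOM_COLS <- c("sneezing", "rhinorrhea", "pruritus", "nasal_congestion",
                  "ocular_pruritus", "lacrimation")

#' Symptom column names of a daily record
#'
#' Returns the canonical names of the six symptom-intensity columns expected
#' in a daily record table: four nasal and two ocular symptoms, each on a
#' 0-3 severity scale.
#'
#' @return Character vector of length six.
#' @export
symptom_columns <- function() SYMPTOM_COLS

check_symptom_range <- function(x, what = "symptom") {
  bad <- !is.na(x) & (x < 0 | x > 3)
  if (any(bad))
    stop(sprintf("%s values must lie in [0, 3]; offending value: %s",
                 what, x[bad][1]), call. = FALSE)
  invisible(x)
}

#' Average Rhinoconjunctivitis Total Symptom Score (ARTSS)
#'
#' The ARTSS for one day is the arithmetic mean of the six symptom
#' intensities (each graded 0-3), so it ranges in \[0, 3\]. A day with any
#' of the six symptoms unrecorded has no defined ARTSS and yields `NA`;
#' such days are treated as missing downstream and later imputed, never
#' part-filled here.
#'
#' @param symptoms Numeric vector of length six (one day), or a matrix/
#'   data frame with six columns (one row per day), in the canonical
#'   symptom order (see [symptom_columns()]).
#' @return Numeric score(s) in \[0, 3\]; `NA` where any symptom is missing.
#' @export
#' @examples
#' artss(c(1, 2, 0, 3, 1, 2))   # 1.5
artss <- function(symptoms) {
  if (is.data.frame(symptoms)) symptoms <- as.matrix(symptoms)
  if (is.null(dim(symptoms))) {
    if (length(symptoms) != 6L)
      stop("artss() needs exactly six symptom intensities", call. = FALSE)
    symptoms <- matrix(symptoms, nrow = 1L)
  }
  if (ncol(symptoms) != 6L)
    stop("symptom table must have six columns", call. = FALSE)
  check_symptom_range(symptoms)
  out <- rowMeans(symptoms)            # NA whenever any of the six is NA
  unname(out)
}

#' Rescue Medication Score (RMS)
#'
#' The RMS for one day is the category of the strongest anti-symptomatic
#' drug taken: 0 = none, 1 = antihistamine, 2 = nasal corticosteroid,
#' 3 = oral corticosteroid. When several drugs are taken the highest
#' category is recorded upstream, so the input carries one category per
#' day. A day whose symptoms were entered but whose medication field was
#' left blank counts as "no medication", RMS = 0; a day with neither
#' symptoms nor medication stays `NA` (a missing day).
#'
#' @param medication Integer category in `{0,1,2,3}` or `NA`, vectorised.
#' @param symptoms_present Logical, same length (or length 1): whether the
#'   day's six symptoms were all recorded.
#' @return Integer score(s) in `{0,1,2,3}`, `NA` for fully missing days.
#' @export
rms <- function(medication, symptoms_present = !is.na(medication)) {
  bad <- !is.na(medication) & !(medication %in% 0:3)
  if (any(bad))
    stop("medication category must be in {0,1,2,3}", call. = FALSE)
  out <- ifelse(is.na(medication) & symptoms_present, 0, medication)
  as.numeric(out)
}

#' Combined Symptom and Medication Score (CSMS)
#'
#' CSMS = ARTSS + RMS, the equally weighted combination of symptom burden
#' and medication need, ranging in \[0, 6\]. `NA` propagates from either
#' component (a day with incomplete symptoms has no CSMS).
#'
#' @param artss ARTSS value(s) in \[0, 3\] (or `NA`).
#' @param rms RMS value(s) in `{0,1,2,3}` (or `NA`).
#' @return Numeric score(s) in \[0, 6\].
#' @export
csms <- function(artss, rms) {
  check_symptom_range(artss, "ARTSS")
  if (any(!is.na(rms) & !(rms %in% 0:3)))
    stop("RMS must be in {0,1,2,3}", call. = FALSE)
  artss + rms
}

#' Score a table of daily records into per-patient CSMS series
#'
#' Takes a long-format table of raw daily entries (one row per patient-day)
#' and returns a patient-by-day CSMS matrix on the common observation
#' window. Days with incomplete symptom entry are `NA`. Missing medication
#' on a day with full symptoms is scored RMS = 0.
#'
#' @param records Data frame with columns `patient_id`, `day`, the six
#'   symptom columns (see [symptom_columns()]) and `medication`. Blank/`NA`
#'   cells denote missing entries. Days absent from the table are missing.
#' @param days Integer vector of the common observation window; default
#'   `1:max(records$day)`.
#' @return Numeric matrix (patients x days) of raw CSMS values in \[0, 6\]
#'   with `NA` for missing days; rownames are patient ids, colnames the day
#'   indices. Attribute `normalized` is `FALSE`.
#' @export
score_records <- function(records, days = NULL) {
  req <- c("patient_id", "day", SYMPTOM_COLS, "medication")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(days)) days <- seq_len(max(records$day))
  a <- artss(records[SYMPTOM_COLS])
  r <- rms(records$medication, symptoms_present = !is.na(a))
  cs <- csms(a, r)
  ids <- unique(as.character(records$patient_id))
  m <- matrix(NA_real_, length(ids), length(days),
              dimnames = list(ids, as.character(days)))
  ri <- match(as.character(records$patient_id), ids)
  ci <- match(records$day, days)
  keep <- !is.na(ci)
  m[cbind(ri[keep], ci[keep])] <- cs[keep]
  attr(m, "normalized") <- FALSE
  m
}

#' Normalize CSMS series to the unit interval
#'
#' Divides every CSMS value by 6, its theoretical maximum, so that symptom
#' and pollen curves share the \[0, 1\] scale. Refuses to renormalize a
#' matrix already flagged as normalized.
#'
#' @param scores CSMS matrix or vector with raw values in \[0, 6\].
#' @return Same shape, values in \[0, 1\], `normalized` attribute `TRUE`.
#' @export
normalize_csms <- function(scores) {
  if (isTRUE(attr(scores, "normalized")))
    stop("scores are already normalized", call. = FALSE)
  if (any(!is.na(scores) & (scores < 0 | scores > 6)))
    stop("raw CSMS values must lie in [0, 6]", call. = FALSE)
  out <- scores / 6
  attr(out, "normalized") <- TRUE
  out
}

#' Normalize a pollen-count series to its seasonal maximum
#'
#' Divides each daily count (grains/m^3) by the maximum observed over the
#' reference window, mapping the seasonal peak to 1. The scaling makes
#' pollen curves comparable to normalized CSMS curves. Applying the
#' function twice equals applying it once (max becomes 1).
#'
#' @param counts Numeric vector (or matrix with taxa in rows) of
#'   non-negative pollen counts; `NA`s are ignored for the maximum.
#' @return Same shape, values in \[0, 1\].
#' @export
normalize_pollen <- function(counts) {
  scale1 <- function(x) {
    mx <- max(x, na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0)
      stop("pollen series needs at least one positive count", call. = FALSE)
    x / mx
  }
  if (!is.null(dim(counts))) t(apply(counts, 1L, scale1)) else scale1(counts)
}

#' Read daily symptom records from a delimited text file
#'
#' Expects a header with columns `patient_id`, `day`, the six symptom
#' columns and `medication`; empty cells are read as missing.
#'
#' @param path File path; any delimiter `read.table` can infer via `sep`.
#' @param sep Field separator (default tab).
#' @return Data frame of daily records.
#' @export
read_symptom_records <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep,
                    na.strings = c("NA", ""), stringsAsFactors = FALSE)
}

#' Write a CSMS score matrix as a tidy delimited table
#'
#' One row per patient-day with columns `patient_id`, `day`, `csms`,
#' `missing`.
#'
#' @param scores Patient-by-day score matrix (as from [score_records()]).
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return Invisibly, the tidy data frame written.
#' @export
write_score_series <- function(scores, path, sep = "\t") {
  df <- data.frame(
    patient_id = rep(rownames(scores), times = ncol(scores)),
    day = rep(as.integer(colnames(scores)), each = nrow(scores)),
    csms = as.vector(scores),
    missing = as.vector(is.na(scores))
  )
  df <- df[order(df$patient_id, df$day), ]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(df)
}
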