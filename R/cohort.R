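# Canonical fields of the two cohort tables. Optional fields may be absent
# from the input and are then carried as NA, never as sentinel numbers.

.baseline_fields <- c(
  "patient_id", "cohort_label", "onset_site", "sex", "age_at_onset",
  "disease_duration_at_baseline", "alsfrs_r_at_baseline", "bmi",
  "nfl_at_baseline", "deceased", "months_survived_since_onset"
)
.baseline_required <- c(
  "patient_id", "onset_site", "disease_duration_at_baseline",
  "alsfrs_r_at_baseline", "nfl_at_baseline"
)
.visit_fields <- c(
  "patient_id", "months_since_baseline", "months_since_onset",
  "alsfrs_r", "nfl_pg_ml"
)
.visit_required <- c("patient_id", "months_since_baseline", "alsfrs_r")

#' Assemble a longitudinal ALS cohort
#'
#' A cohort bundles one row of baseline covariates per patient with the
#' longitudinal ALSFRS-R (and optionally NfL) visit records. Baseline NfL is
#' in pg/ml, times are in months, and the ALSFRS-R sum score runs 0--48.
#'
#' @param baselines Data frame of per-patient baseline covariates. Required
#'   columns: `patient_id`, `onset_site` (`"spinal"` or `"bulbar"`),
#'   `disease_duration_at_baseline` (months since symptom onset, > 0),
#'   `alsfrs_r_at_baseline` (0--48), `nfl_at_baseline` (pg/ml, > 0).
#'   Optional: `cohort_label`, `sex` (`"male"`/`"female"`), `age_at_onset`,
#'   `bmi`, `deceased`, `months_survived_since_onset`.
#' @param visits Data frame of visit records. Required columns:
#'   `patient_id`, `months_since_baseline` (>= 0), `alsfrs_r` (0--48).
#'   Optional: `months_since_onset`, `nfl_pg_ml` (pg/ml, > 0 or `NA`).
#' @param check If `TRUE` (default), enforce structural integrity: unique
#'   patient ids, every visit attached to a known patient, and no duplicated
#'   (patient, time) pair. Set `FALSE` to assemble a possibly broken cohort
#'   for inspection with [validate_cohort()].
#'
#' @return An object of class `nfl_cohort`: a list with tibbles `baselines`
#'   and `visits` (visits sorted by patient and time).
#' @seealso [read_cohort()], [validate_cohort()], [generate_cohort()]
#' @export
#' @examples
#' b <- data.frame(patient_id = "P1", onset_site = "spinal",
#'                 disease_duration_at_baseline = 10,
#'                 alsfrs_r_at_baseline = 42, nfl_at_baseline = 100)
#' v <- data.frame(patient_id = "P1", months_since_baseline = c(0, 3),
#'                 alsfrs_r = c(42, 40))
#' cohort(b, v)
cohort <- function(baselines, visits, check = TRUE) {
  baselines <- tibble::as_tibble(baselines)
  visits <- tibble::as_tibble(visits)
  miss_b <- setdiff(.baseline_required, names(baselines))
  miss_v <- setdiff(.visit_required, names(visits))
  if (length(miss_b) || length(miss_v)) {
    stop("missing required column(s): ",
         paste(c(miss_b, miss_v), collapse = ", "), call. = FALSE)
  }
  for (f in setdiff(.baseline_fields, names(baselines))) baselines[[f]] <- NA
  for (f in setdiff(.visit_fields, names(visits))) visits[[f]] <- NA
  baselines <- .coerce_baselines(baselines[.baseline_fields])
  visits <- .coerce_visits(visits[.visit_fields])
  visits <- visits[order(visits$patient_id, visits$months_since_baseline), ]
  x <- structure(list(baselines = baselines, visits = visits),
                 class = "nfl_cohort")
  if (check) .check_cohort_structure(x)
  x
}

.coerce_baselines <- function(b) {
  tibble::tibble(
    patient_id = as.character(b$patient_id),
    cohort_label = as.character(b$cohort_label),
    onset_site = tolower(as.character(b$onset_site)),
    sex = tolower(as.character(b$sex)),
    age_at_onset = as.numeric(b$age_at_onset),
    disease_duration_at_baseline = as.numeric(b$disease_duration_at_baseline),
    alsfrs_r_at_baseline = as.numeric(b$alsfrs_r_at_baseline),
    bmi = as.numeric(b$bmi),
    nfl_at_baseline = as.numeric(b$nfl_at_baseline),
    deceased = as.logical(b$deceased),
    months_survived_since_onset = as.numeric(b$months_survived_since_onset)
  )
}

.coerce_visits <- function(v) {
  tibble::tibble(
    patient_id = as.character(v$patient_id),
    months_since_baseline = as.numeric(v$months_since_baseline),
    months_since_onset = as.numeric(v$months_since_onset),
    alsfrs_r = as.numeric(v$alsfrs_r),
    nfl_pg_ml = as.numeric(v$nfl_pg_ml)
  )
}

.check_cohort_structure <- function(x) {
  dup_id <- x$baselines$patient_id[duplicated(x$baselines$patient_id)]
  if (length(dup_id)) {
    stop("duplicated patient id(s) in baseline table: ",
         paste(unique(dup_id), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(x$visits$patient_id, x$baselines$patient_id)
  if (length(unknown)) {
    stop("visit(s) reference unknown patient(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  key <- paste(x$visits$patient_id, x$visits$months_since_baseline)
  dup <- x$visits$patient_id[duplicated(key)]
  if (length(dup)) {
    stop("duplicated (patient, time) visit(s) for patient(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Read a cohort from baseline and visit CSV files
#'
#' Both tables are comma-separated UTF-8 text with a header row. A
#' `column_map` (or a YAML/JSON config file containing one) maps the
#' canonical field names used by this package to whatever headers the files
#' carry, so published supplementary tables can be ingested without editing.
#'
#' Rows whose required fields do not parse or violate a field invariant
#' (non-positive NfL, non-positive disease duration, ALSFRS-R outside
#' 0--48, unknown onset site, negative visit time) are rejected, and a
#' per-row report is attached as `attr(x, "rejected")`. Referential
#' integrity (visits pointing at unknown patients) and duplicated
#' (patient, time) pairs are hard errors.
#'
#' @param baseline_file,visits_file Paths to the two CSV files.
#' @param column_map Named character vector or list mapping canonical field
#'   names (see [cohort()]) to the column names in the files, e.g.
#'   `c(patient_id = "ID", nfl_at_baseline = "NfL")`. Unmapped canonical
#'   names are looked up verbatim.
#' @param config Optional path to a YAML (or JSON) file with a top-level
#'   `column_map` mapping; entries in `column_map` override it.
#'
#' @return An `nfl_cohort` with attribute `"rejected"`: a tibble with
#'   columns `table`, `row`, `patient_id`, `reason` (empty when every row
#'   was accepted).
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(baseline_file, visits_file, column_map = NULL,
                        config = NULL) {
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    from_cfg <- cfg$column_map %||% cfg
    column_map <- modifyList(as.list(from_cfg), as.list(column_map %||% list()))
  }
  chr_only <- readr::cols(.default = readr::col_character())
  braw <- readr::read_csv(baseline_file, col_types = chr_only, progress = FALSE)
  vraw <- readr::read_csv(visits_file, col_types = chr_only, progress = FALSE)
  braw <- .apply_column_map(braw, column_map, .baseline_required, "baseline")
  vraw <- .apply_column_map(vraw, column_map, .visit_required, "visits")
  pb <- .parse_baseline_rows(braw)
  pv <- .parse_visit_rows(vraw)
  rejected <- dplyr::bind_rows(pb$rejected, pv$rejected)
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " row(s) rejected during import; ",
            "see attr(x, \"rejected\") for the per-row report")
  }
  out <- cohort(pb$rows, pv$rows, check = TRUE)
  attr(out, "rejected") <- rejected
  out
}

.apply_column_map <- function(df, column_map, required, table) {
  map <- as.list(column_map %||% list())
  for (canon in names(map)) {
    src <- map[[canon]]
    if (src %in% names(df)) {
      names(df)[names(df) == src] <- canon
    } else if (canon %in% required) {
      stop("configuration error: mapped column '", src,
           "' for required field '", canon, "' not found in ", table,
           " table", call. = FALSE)
    }
  }
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("configuration error: required column(s) missing from ", table,
         " table: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

# Per-row parser shared machinery: the first failing check wins as the
# row's rejection reason.
.row_screen <- function(n) {
  reason <- rep(NA_character_, n)
  list(
    flag = function(cond, why) {
      cond[is.na(cond)] <- FALSE
      reason[is.na(reason) & cond] <<- why
    },
    reasons = function() reason
  )
}

.num <- function(x) suppressWarnings(as.numeric(x))

.parse_baseline_rows <- function(b) {
  n <- nrow(b)
  scr <- .row_screen(n)
  pid <- as.character(b$patient_id)
  scr$flag(is.na(pid) | pid == "", "missing patient_id")
  site <- tolower(as.character(b$onset_site))
  scr$flag(is.na(site) | !site %in% c("spinal", "bulbar"),
           "onset_site not spinal/bulbar")
  dur <- .num(b$disease_duration_at_baseline)
  scr$flag(is.na(dur), "unparseable disease_duration_at_baseline")
  scr$flag(dur <= 0, "non-positive disease duration")
  score <- .num(b$alsfrs_r_at_baseline)
  scr$flag(is.na(score), "unparseable alsfrs_r_at_baseline")
  scr$flag(score < 0 | score > 48, "ALSFRS-R score out of range")
  nfl <- .num(b$nfl_at_baseline)
  scr$flag(is.na(nfl), "unparseable nfl_at_baseline")
  scr$flag(nfl <= 0, "non-positive NfL")
  reason <- scr$reasons()
  keep <- is.na(reason)

  opt_chr <- function(f) if (f %in% names(b)) as.character(b[[f]]) else NA
  opt_num <- function(f) if (f %in% names(b)) .num(b[[f]]) else NA_real_
  sex <- tolower(opt_chr("sex"))
  sex[!sex %in% c("male", "female")] <- NA
  dec_raw <- tolower(opt_chr("deceased"))
  deceased <- dplyr::case_when(
    dec_raw %in% c("true", "t", "1", "yes") ~ TRUE,
    dec_raw %in% c("false", "f", "0", "no") ~ FALSE,
    .default = NA
  )
  rows <- tibble::tibble(
    patient_id = pid, cohort_label = opt_chr("cohort_label"),
    onset_site = site, sex = sex,
    age_at_onset = opt_num("age_at_onset"),
    disease_duration_at_baseline = dur,
    alsfrs_r_at_baseline = score, bmi = opt_num("bmi"),
    nfl_at_baseline = nfl, deceased = deceased,
    months_survived_since_onset = opt_num("months_survived_since_onset")
  )[keep, ]
  rejected <- tibble::tibble(table = "baseline", row = which(!keep),
                             patient_id = pid[!keep],
                             reason = reason[!keep])
  list(rows = rows, rejected = rejected)
}

.parse_visit_rows <- function(v) {
  n <- nrow(v)
  scr <- .row_screen(n)
  pid <- as.character(v$patient_id)
  scr$flag(is.na(pid) | pid == "", "missing patient_id")
  t_bl <- .num(v$months_since_baseline)
  scr$flag(is.na(t_bl), "unparseable months_since_baseline")
  scr$flag(t_bl < 0, "negative visit time")
  score <- .num(v$alsfrs_r)
  scr$flag(is.na(score), "unparseable alsfrs_r")
  scr$flag(score < 0 | score > 48, "ALSFRS-R score out of range")
  nfl_raw <- if ("nfl_pg_ml" %in% names(v)) as.character(v$nfl_pg_ml) else NA
  nfl <- .num(nfl_raw)
  has_nfl <- !is.na(nfl_raw) & nfl_raw != ""
  scr$flag(has_nfl & is.na(nfl), "unparseable nfl_pg_ml")
  scr$flag(has_nfl & nfl <= 0, "non-positive NfL")
  t_on <- if ("months_since_onset" %in% names(v)) .num(v$months_since_onset) else NA_real_
  reason <- scr$reasons()
  keep <- is.na(reason)
  rows <- tibble::tibble(
    patient_id = pid, months_since_baseline = t_bl,
    months_since_onset = t_on, alsfrs_r = score, nfl_pg_ml = nfl
  )[keep, ]
  rejected <- tibble::tibble(table = "visits", row = which(!keep),
                             patient_id = pid[!keep],
                             reason = reason[!keep])
  list(rows = rows, rejected = rejected)
}

#' Write a cohort back to the two CSV tables
#'
#' The inverse of [read_cohort()] under the canonical headers: writing and
#' re-reading yields a field-for-field identical cohort.
#'
#' @param x An `nfl_cohort`.
#' @param baseline_file,visits_file Output paths.
#' @return `x`, invisibly.
#' @export
write_cohort <- function(x, baseline_file, visits_file) {
  stopifnot(inherits(x, "nfl_cohort"))
  readr::write_csv(x$baselines, baseline_file, progress = FALSE)
  readr::write_csv(x$visits, visits_file, progress = FALSE)
  invisible(x)
}

#' Report every cohort-invariant violation
#'
#' A pure reporting operation: it never raises on malformed (but parseable)
#' data. An empty report certifies that all invariants hold.
#'
#' @param x An `nfl_cohort` (possibly assembled with `check = FALSE`).
#' @param time_tolerance Rounding tolerance, in months, for the consistency
#'   check `months_since_onset == months_since_baseline + disease duration`.
#' @return A tibble with columns `patient_id`, `field`, `issue`; zero rows
#'   when the cohort is valid.
#' @export
validate_cohort <- function(x, time_tolerance = 0.5) {
  stopifnot(inherits(x, "nfl_cohort"))
  b <- x$baselines
  v <- x$visits
  issue <- function(patient_id, field, what) {
    tibble::tibble(patient_id = as.character(patient_id), field = field,
                   issue = what)
  }
  out <- list()
  out$dup_id <- issue(unique(b$patient_id[duplicated(b$patient_id)]),
                      "patient_id", "duplicated patient id")
  bad <- !b$onset_site %in% c("spinal", "bulbar")
  out$site <- issue(b$patient_id[bad], "onset_site",
                    "onset site not spinal/bulbar")
  bad <- is.na(b$alsfrs_r_at_baseline) | b$alsfrs_r_at_baseline < 0 |
    b$alsfrs_r_at_baseline > 48
  out$score <- issue(b$patient_id[bad], "alsfrs_r_at_baseline",
                     "score out of range [0, 48]")
  bad <- is.na(b$nfl_at_baseline) | b$nfl_at_baseline <= 0
  out$nfl <- issue(b$patient_id[bad], "nfl_at_baseline", "non-positive NfL")
  bad <- is.na(b$disease_duration_at_baseline) |
    b$disease_duration_at_baseline <= 0
  out$dur <- issue(b$patient_id[bad], "disease_duration_at_baseline",
                   "non-positive disease duration")

  unknown <- unique(setdiff(v$patient_id, b$patient_id))
  out$unknown <- issue(unknown, "patient_id", "visit for unknown patient")
  key <- paste(v$patient_id, v$months_since_baseline)
  out$dup_t <- issue(unique(v$patient_id[duplicated(key)]),
                     "months_since_baseline", "duplicated time point")
  bad <- is.na(v$alsfrs_r) | v$alsfrs_r < 0 | v$alsfrs_r > 48
  out$vscore <- issue(v$patient_id[bad], "alsfrs_r",
                      "score out of range [0, 48]")
  bad <- is.na(v$months_since_baseline) | v$months_since_baseline < 0
  out$vt <- issue(v$patient_id[bad], "months_since_baseline",
                  "missing or negative visit time")
  bad <- !is.na(v$nfl_pg_ml) & v$nfl_pg_ml <= 0
  out$vnfl <- issue(v$patient_id[bad], "nfl_pg_ml", "non-positive NfL")

  novisit <- setdiff(b$patient_id, v$patient_id)
  out$novisit <- issue(novisit, "patient_id", "no visits")

  dur <- setNames(b$disease_duration_at_baseline, b$patient_id)
  have <- !is.na(v$months_since_onset) & !is.na(v$months_since_baseline) &
    v$patient_id %in% names(dur)
  expect_on <- v$months_since_baseline + unname(dur[v$patient_id])
  bad <- have & !is.na(expect_on) &
    abs(v$months_since_onset - expect_on) > time_tolerance
  out$tcons <- issue(v$patient_id[bad], "months_since_onset",
                     "inconsistent with months_since_baseline + disease duration")

  dplyr::distinct(dplyr::bind_rows(out))
}

#' @export
print.nfl_cohort <- function(x, ...) {
  labs <- unique(x$baselines$cohort_label)
  labs <- labs[!is.na(labs)]
  cat("<nfl_cohort>",
      if (length(labs)) paste0(" [", paste(labs, collapse = ", "), "]"),
      "\n", sep = "")
  cat("  patients: ", nrow(x$baselines),
      "   visits: ", nrow(x$visits), "\n", sep = "")
  n_nfl <- sum(!is.na(x$visits$nfl_pg_ml))
  cat("  longitudinal NfL measurements: ", n_nfl, "\n", sep = "")
  invisible(x)
}
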