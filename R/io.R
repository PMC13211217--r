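# data_io: per-subject CSV dialect, demographics table, validation -----------
#
# CSV dialect: comma-separated, '.' decimal, UTF-8, mandatory header.
# Columns (exact order):
#   subject_id,time_s,acc_x,acc_y,acc_z,gyro_x,gyro_y,gyro_z,hs_gt,hs_pred,vo2
# vo2 is sparse: empty everywhere except at the sample nearest each breath.
# hs_pred may be entirely empty until stage 1 fills it.

subject_csv_columns <- c("subject_id", "time_s", "acc_x", "acc_y", "acc_z",
                         "gyro_x", "gyro_y", "gyro_z", "hs_gt", "hs_pred", "vo2")

fmt_num <- function(x, digits) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[is.na(x)] <- ""
  out
}

#' Write one subject record to CSV
#'
#' Fixed decimal formatting (time 4 d.p., signals 6 d.p., VO2 4 d.p.) so that
#' identical records serialize to identical bytes. VO2 breath samples are
#' placed on the nearest IMU sample row; all other vo2 cells are empty, as are
#' hs_pred cells when stage 1 has not run.
#'
#' @param record a `subject_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_subject_csv <- function(record, path) {
  stopifnot(inherits(record, "subject_record"))
  n <- length(record$time_s)
  vo2_col <- rep(NA_real_, n)
  if (nrow(record$vo2) > 0) {
    idx <- pmin(n, pmax(1L, round(record$vo2$time_s * record$sampling_rate_hz) + 1L))
    vo2_col[idx] <- record$vo2$vo2
  }
  hp <- record$hs_pred
  hp_chr <- ifelse(is.na(hp), "", as.character(hp))
  lines <- paste(record$subject_id,
                 fmt_num(record$time_s, 4),
                 fmt_num(record$acc[, 1], 6), fmt_num(record$acc[, 2], 6),
                 fmt_num(record$acc[, 3], 6),
                 fmt_num(record$gyro[, 1], 6), fmt_num(record$gyro[, 2], 6),
                 fmt_num(record$gyro[, 3], 6),
                 record$hs_gt, hp_chr, fmt_num(vo2_col, 4), sep = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(subject_csv_columns, collapse = ","), lines), con)
  invisible(path)
}

#' Read one subject record from CSV
#'
#' @param path CSV file written by [write_subject_csv()] (or hand-authored in
#'   the same dialect).
#' @param demographics optional [demographics()] to attach.
#' @param sampling_rate_hz sampling rate; inferred from the time column when
#'   `NULL`.
#' @return A `subject_record`.
#' @export
read_subject_csv <- function(path, demographics = NULL, sampling_rate_hz = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  missing <- setdiff(subject_csv_columns, names(df))
  if (length(missing) > 0)
    abort("schema error: missing column(s) %s", paste(missing, collapse = ", "))
  if (nrow(df) < 2) abort("subject CSV must contain at least 2 samples")
  if (any(diff(df$time_s) <= 0)) abort("validation error: time_s is not strictly increasing")
  if (is.null(sampling_rate_hz))
    sampling_rate_hz <- 1 / median(diff(df$time_s))
  hs_gt <- as.integer(df$hs_gt)
  if (any(!hs_gt %in% c(0L, 1L))) abort("validation error: hs_gt must be binary")
  hp <- suppressWarnings(as.integer(df$hs_pred))
  breath <- !is.na(df$vo2)
  structure(list(subject_id = df$subject_id[1],
                 sampling_rate_hz = sampling_rate_hz,
                 time_s = df$time_s,
                 acc = cbind(acc_x = df$acc_x, acc_y = df$acc_y, acc_z = df$acc_z),
                 gyro = cbind(gyro_x = df$gyro_x, gyro_y = df$gyro_y, gyro_z = df$gyro_z),
                 hs_gt = hs_gt, hs_pred = hp,
                 vo2 = data.frame(time_s = df$time_s[breath], vo2 = df$vo2[breath]),
                 demographics = demographics),
            class = "subject_record")
}

#' Write / read the cohort demographics table
#'
#' Schema: `subject_id,age,height_cm,weight_kg,gender`.
#'
#' @param cohort a `cohort`.
#' @param path CSV path.
#' @return `path` invisibly (write); a data.frame (read).
#' @export
write_demographics_csv <- function(cohort, path) {
  rows <- lapply(cohort$subjects, function(s) {
    d <- s$demographics
    data.frame(subject_id = s$subject_id, age = d$age, height_cm = d$height_cm,
               weight_kg = d$weight_kg, gender = d$gender)
  })
  df <- do.call(rbind, rows)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = ","),
               do.call(paste, c(df, sep = ","))), con)
  invisible(path)
}

#' @rdname write_demographics_csv
#' @export
read_demographics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  need <- c("subject_id", "age", "height_cm", "weight_kg", "gender")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    abort("schema error: missing column(s) %s", paste(missing, collapse = ", "))
  df$bmi <- df$weight_kg / (df$height_cm / 100)^2
  df
}

#' Read a cohort from a directory of subject CSVs
#'
#' @param dir directory containing `S*.csv` subject files and
#'   `demographics.csv`.
#' @return A `cohort`.
#' @export
read_cohort_dir <- function(dir) {
  demo_path <- file.path(dir, "demographics.csv")
  demo <- if (file.exists(demo_path)) read_demographics_csv(demo_path) else NULL
  files <- sort(list.files(dir, pattern = "^S.*\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "demographics.csv"]
  if (length(files) == 0) abort("no subject CSVs found in %s", dir)
  subjects <- lapply(files, function(f) {
    rec <- read_subject_csv(f)
    if (!is.null(demo)) {
      row <- demo[demo$subject_id == rec$subject_id, ]
      if (nrow(row) == 1)
        rec$demographics <- demographics(row$age, row$height_cm, row$weight_kg, row$gender)
    }
    rec
  })
  structure(list(subjects = subjects,
                 sampling_rate_hz = subjects[[1]]$sampling_rate_hz),
            class = "cohort")
}

#' Write a cohort to a directory
#'
#' One CSV per subject plus `demographics.csv`.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects)
    write_subject_csv(s, file.path(dir, paste0(s$subject_id, ".csv")))
  write_demographics_csv(cohort, file.path(dir, "demographics.csv"))
  invisible(dir)
}

#' Validate a cohort against the record invariants
#'
#' Checks, per subject: equal channel lengths, binary `hs_gt`, strictly
#' increasing VO2 timestamps inside the recording span, positive BMI identity,
#' shared sampling rate, and cohort-wide unique subject ids. Reports rather
#' than throws.
#'
#' @param cohort a `cohort`.
#' @return Character vector of violations; empty when all invariants hold.
#' @export
validate_cohort <- function(cohort) {
  v <- character(0)
  ids <- subject_ids(cohort)
  if (anyDuplicated(ids))
    v <- c(v, sprintf("duplicate subject_id: %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (s in cohort$subjects) {
    n <- length(s$time_s)
    if (nrow(s$acc) != n || nrow(s$gyro) != n)
      v <- c(v, sprintf("%s: IMU channel lengths differ from time base", s$subject_id))
    if (any(!s$hs_gt %in% c(0L, 1L)))
      v <- c(v, sprintf("%s: hs_gt not binary", s$subject_id))
    if (nrow(s$vo2) > 1 && any(diff(s$vo2$time_s) <= 0))
      v <- c(v, sprintf("%s: vo2 timestamps not strictly increasing", s$subject_id))
    span <- range(s$time_s)
    if (nrow(s$vo2) > 0 &&
        (min(s$vo2$time_s) < span[1] - 1e-9 || max(s$vo2$time_s) > span[2] + 1 / s$sampling_rate_hz))
      v <- c(v, sprintf("%s: vo2 timestamps outside recording span", s$subject_id))
    if (s$sampling_rate_hz != cohort$sampling_rate_hz)
      v <- c(v, sprintf("%s: sampling rate differs from cohort", s$subject_id))
    d <- s$demographics
    if (!is.null(d) && abs(d$bmi - d$weight_kg / (d$height_cm / 100)^2) > 1e-9)
      v <- c(v, sprintf("%s: bmi does not match weight/height", s$subject_id))
  }
  v
}
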