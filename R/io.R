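# File formats: casualty table CSV, responder roster CSV, ID list text,
# JSON reports.  All plain text, UTF-8, comma-separated with a header.

.read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", strip.white = TRUE),
    error = function(e) stop("cannot read ", what, " file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(what, " file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop(what, " file ", path, " has no data rows", call. = FALSE)
  df
}

.parse_int <- function(x, row, col, lo, hi, allow_na = FALSE) {
  if (is.na(x) || x == "") {
    if (allow_na) return(NA_integer_)
    stop(sprintf("row %d, column '%s': value required", row, col),
         call. = FALSE)
  }
  if (!grepl("^[0-9]+$", x))
    stop(sprintf("row %d, column '%s': expected an integer, got '%s'",
                 row, col, x), call. = FALSE)
  v <- as.integer(x)
  if (v < lo || v > hi)
    stop(sprintf("row %d, column '%s': %d outside %d..%d", row, col, v,
                 lo, hi), call. = FALSE)
  v
}

#' Read a casualty table
#'
#' Reads a CSV with header
#' `casualty_id,day,triage_number,age,age_decade,gender,name_initial,triage_class`.
#' Empty cells mean unknown.  Decade notation in the `age` column (`"70s"`,
#' `"30s"`, ...) is parsed into the decade digit; an exact age and a decade
#' may not both be given for the same casualty.
#'
#' @param path Path to the CSV file.
#' @return A data frame with typed columns as documented in
#'   [table1_casualties()].
#' @examples
#' read_casualties(system.file("extdata", "virtual_casualties.csv",
#'                             package = "mciid"))
#' @export
read_casualties <- function(path) {
  req <- c("casualty_id", "day", "triage_number", "age", "age_decade",
           "gender", "name_initial", "triage_class")
  df <- .read_csv_checked(path, req, "casualty")
  n <- nrow(df)
  out <- data.frame(casualty_id = df$casualty_id,
                    day = integer(n), triage_number = integer(n),
                    age = NA_integer_, age_decade = NA_integer_,
                    gender = character(n), name_initial = NA_character_,
                    triage_class = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    out$day[i] <- .parse_int(df$day[i], i, "day", 1L, 31L)
    out$triage_number[i] <- .parse_int(df$triage_number[i], i,
                                       "triage_number", 1L, 9999L)
    age_raw <- df$age[i]
    dec_raw <- df$age_decade[i]
    if (!is.na(age_raw) && grepl("^[0-9]0s$", age_raw)) {
      # decade-only notation like "70s" carried in the age column
      dec_raw <- substr(age_raw, 1L, 1L)
      age_raw <- ""
    }
    age <- .parse_int(age_raw, i, "age", 0L, 150L, allow_na = TRUE)
    dec <- .parse_int(dec_raw, i, "age_decade", 0L, 9L, allow_na = TRUE)
    if (!is.na(age) && !is.na(dec))
      stop(sprintf("row %d: both exact age and age_decade given", i),
           call. = FALSE)
    out$age[i] <- age
    out$age_decade[i] <- dec
    g <- df$gender[i]
    if (is.na(g) || g == "" || g == "u" || tolower(g) == "unknown") {
      out$gender[i] <- "unknown"
    } else if (g %in% c("M", "F")) {
      out$gender[i] <- g
    } else {
      stop(sprintf("row %d, column 'gender': expected M, F or empty, got '%s'",
                   i, g), call. = FALSE)
    }
    ni <- df$name_initial[i]
    if (!is.na(ni) && ni != "") {
      if (!grepl("^[A-Z]$", ni))
        stop(sprintf(
          "row %d, column 'name_initial': expected A-Z or empty, got '%s'",
          i, ni), call. = FALSE)
      out$name_initial[i] <- ni
    }
    tc <- df$triage_class[i]
    if (!is.na(tc) && tc != "") {
      if (!tc %in% c("O", "I", "II", "III"))
        stop(sprintf(
          "row %d, column 'triage_class': expected O, I, II or III, got '%s'",
          i, tc), call. = FALSE)
      out$triage_class[i] <- tc
    }
  }
  out
}

#' Read a responder roster
#'
#' Reads a CSV with header `responder_id,job,initial_family,initial_given,age`
#' and an optional `start_serial` column (serial counters start at 1 when it
#' is absent).
#'
#' @param path Path to the CSV file.
#' @return A list of [responder_profile()] objects, named by `responder_id`.
#' @export
read_roster <- function(path) {
  req <- c("responder_id", "job", "initial_family", "initial_given", "age")
  df <- .read_csv_checked(path, req, "roster")
  has_serial <- "start_serial" %in% names(df)
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    serial <- if (has_serial)
      .parse_int(df$start_serial[i], i, "start_serial", 1L, 999999L)
    else 1L
    out[[i]] <- tryCatch(
      responder_profile(df$job[i], df$initial_family[i],
                        df$initial_given[i],
                        .parse_int(df$age[i], i, "age", 0L, 150L),
                        next_triage_number = serial),
      error = function(e) stop(sprintf("roster row %d: %s", i,
                                       conditionMessage(e)), call. = FALSE))
  }
  names(out) <- df$responder_id
  out
}

#' Read and write ID list files
#'
#' An ID list file is plain UTF-8 text with one code per line, in canonical
#' or display form; blank lines and lines starting with `#` are ignored.
#' `read_ids()` validates every code and reports the offending line on
#' failure; `write_ids()` writes one code per line.
#'
#' @param path File path.
#' @return `read_ids()`: a character vector of canonical 16-character codes.
#' @export
read_ids <- function(path) {
  if (!file.exists(path)) stop("ID file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  codes <- trimws(lines[keep])
  for (k in seq_along(codes)) {
    v <- validate_id(codes[k])
    if (nrow(v) > 0L)
      stop(sprintf("%s line %d: invalid ID '%s' (%s: expected %s)",
                   path, keep[k], codes[k], v$field[1L], v$expected[1L]),
           call. = FALSE)
  }
  vapply(codes, .strip_hyphen, "", USE.NAMES = FALSE)
}

#' @rdname read_ids
#' @param ids Character vector of codes, or a list of `id_code` objects.
#' @param form `"canonical"` (16 characters) or `"display"` (hyphenated).
#' @export
write_ids <- function(path, ids, form = c("canonical", "display")) {
  form <- match.arg(form)
  if (is.list(ids))
    ids <- vapply(ids, function(x)
      if (inherits(x, "id_code")) x$canonical else as.character(x), "")
  canon <- vapply(ids, .strip_hyphen, "", USE.NAMES = FALSE)
  out <- if (form == "display")
    paste0(substr(canon, 1L, 7L), "-", substr(canon, 8L, 16L))
  else canon
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Write a duplication report as JSON
#'
#' Serializes every field of a [pattern_duplication_stats()] or
#' [id_duplication_stats()] report (or any named list of scalars) to a JSON
#' object with bare numeric values.
#'
#' @param path Output file path.
#' @param report A `duplication_report` or named list.
#' @export
write_report <- function(path, report) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
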