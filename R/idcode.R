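# Positional grammar of the 16-character code.  Positions are 1-based into the
# canonical (hyphen-free) form; the display form inserts a hyphen after
# position 7.  Kept as a single table so that validation, decoding and field
# diffing all share one definition.
.id_fields <- data.frame(
  field = c("job", "initial_1", "initial_2", "responder_age", "serial",
            "day", "hour", "minute", "age_decade", "gender",
            "casualty_initial"),
  start = c(1L, 2L, 3L, 4L, 6L, 8L, 10L, 12L, 14L, 15L, 16L),
  end   = c(1L, 2L, 3L, 5L, 7L, 9L, 11L, 13L, 14L, 15L, 16L),
  stringsAsFactors = FALSE
)

.JOB_LETTERS <- c("D", "N", "P", "V")
.UNKNOWN <- "u"

.is_upper <- function(x) grepl("^[A-Z]$", x)

#' Create a responder profile
#'
#' A responder is the person performing triage: a doctor (`"D"`), nurse
#' (`"N"`), paramedic (`"P"`) or volunteer (`"V"`), identified in the code by
#' job letter, two uppercase name initials (family initial first), two-digit
#' age and a two-digit serial triage number that wraps at 100 (the 100th
#' casualty a responder triages is serial `"00"`, the 101st `"01"` again).
#' Responder fields are always known; the unknown marker applies only to
#' casualty information.
#'
#' @param job One of `"D"`, `"N"`, `"P"`, `"V"`.
#' @param initial_1,initial_2 Uppercase Roman letters: family-name initial,
#'   then given-name initial.
#' @param age Integer age in years, `>= 0`. Ages of 100 or more are encoded
#'   modulo 100, mirroring the serial-wrap convention.
#' @param next_triage_number Serial number of the responder's next triage,
#'   starting at 1.
#' @return An object of class `responder_profile`.
#' @examples
#' responder_profile("D", "K", "S", 35)
#' @export
responder_profile <- function(job, initial_1, initial_2, age,
                              next_triage_number = 1L) {
  if (length(job) != 1L || !job %in% .JOB_LETTERS)
    stop("`job` must be one of ", paste(.JOB_LETTERS, collapse = ", "),
         " (got ", deparse(job), ")", call. = FALSE)
  if (!.is_upper(initial_1))
    stop("`initial_1` must be a single uppercase letter A-Z", call. = FALSE)
  if (!.is_upper(initial_2))
    stop("`initial_2` must be a single uppercase letter A-Z", call. = FALSE)
  age <- as.integer(age)
  if (is.na(age) || age < 0L)
    stop("`age` must be a non-negative integer", call. = FALSE)
  next_triage_number <- as.integer(next_triage_number)
  if (is.na(next_triage_number) || next_triage_number < 1L)
    stop("`next_triage_number` must be an integer >= 1", call. = FALSE)
  structure(
    list(job = job, initial_1 = initial_1, initial_2 = initial_2,
         age = age, next_triage_number = next_triage_number),
    class = "responder_profile"
  )
}

#' @export
print.responder_profile <- function(x, ...) {
  cat(sprintf("<responder %s%s%s, age %d, next serial %d>\n",
              x$job, x$initial_1, x$initial_2, x$age, x$next_triage_number))
  invisible(x)
}

#' Create a casualty record
#'
#' A casualty's attributes as known (or estimated) at first contact.  Any of
#' age, gender and name initial may be unknown; unknowns are encoded as the
#' lowercase letter `u`, which is unambiguous because real initials are always
#' uppercase.  Age may be given exactly (`age`), or only to a decade
#' (`age_decade`, e.g. 7 for a casualty in their seventies); at most one of
#' the two may be supplied.
#'
#' @param day Day of month of triage, 1-31.
#' @param hour,minute Time of triage, 24-hour clock.
#' @param age Exact age in years, or `NA` if not known exactly.
#' @param age_decade Estimated age decade digit 0-9, or `NA`.
#' @param gender `"M"`, `"F"` or `"unknown"` (the code letter `"u"` is also
#'   accepted on input).
#' @param name_initial Uppercase family-name initial (falling back to the
#'   given name when only that is known), or `NA` if no name is available.
#' @param triage_class Optional START triage class label carried with the
#'   record: `"O"` (black), `"I"` (red), `"II"` (yellow) or `"III"` (green).
#'   It is a data label only and never enters the code.
#' @return An object of class `casualty_record`.
#' @examples
#' casualty_record(day = 1, hour = 1, minute = 1, age = 5, gender = "M",
#'                 name_initial = "K")
#' # age known only as "30s", gender and name unknown:
#' casualty_record(day = 31, hour = 14, minute = 30, age_decade = 3)
#' @export
casualty_record <- function(day, hour, minute, age = NA, age_decade = NA,
                            gender = "unknown", name_initial = NA,
                            triage_class = NA) {
  day <- as.integer(day); hour <- as.integer(hour); minute <- as.integer(minute)
  if (is.na(day) || day < 1L || day > 31L)
    stop("`day` must be in 1..31", call. = FALSE)
  if (is.na(hour) || hour < 0L || hour > 23L)
    stop("`hour` must be in 0..23", call. = FALSE)
  if (is.na(minute) || minute < 0L || minute > 59L)
    stop("`minute` must be in 0..59", call. = FALSE)
  if (!is.na(age) && !is.na(age_decade))
    stop("supply at most one of `age` and `age_decade`", call. = FALSE)
  if (!is.na(age)) {
    age <- as.integer(age)
    if (age < 0L) stop("`age` must be >= 0", call. = FALSE)
  }
  if (!is.na(age_decade)) {
    age_decade <- as.integer(age_decade)
    if (age_decade < 0L || age_decade > 9L)
      stop("`age_decade` must be a digit 0..9", call. = FALSE)
  }
  if (identical(gender, .UNKNOWN)) gender <- "unknown"
  if (length(gender) != 1L || !gender %in% c("M", "F", "unknown"))
    stop("`gender` must be \"M\", \"F\" or \"unknown\"", call. = FALSE)
  if (!is.na(name_initial) && !.is_upper(name_initial))
    stop("`name_initial` must be an uppercase letter A-Z or NA", call. = FALSE)
  if (!is.na(triage_class) && !triage_class %in% c("O", "I", "II", "III"))
    stop("`triage_class` must be one of O, I, II, III", call. = FALSE)
  structure(
    list(day = day, hour = hour, minute = minute,
         age = if (is.na(age)) NA_integer_ else age,
         age_decade = if (is.na(age_decade)) NA_integer_ else age_decade,
         gender = gender,
         name_initial = if (is.na(name_initial)) NA_character_ else name_initial,
         triage_class = if (is.na(triage_class)) NA_character_ else triage_class),
    class = "casualty_record"
  )
}

#' @export
print.casualty_record <- function(x, ...) {
  age <- if (!is.na(x$age)) sprintf("age %d", x$age)
         else if (!is.na(x$age_decade)) sprintf("age %d0s", x$age_decade)
         else "age unknown"
  cat(sprintf("<casualty day %02d %02d:%02d, %s, gender %s, initial %s%s>\n",
              x$day, x$hour, x$minute, age, x$gender,
              ifelse(is.na(x$name_initial), "unknown", x$name_initial),
              ifelse(is.na(x$triage_class), "",
                     paste0(", triage ", x$triage_class))))
  invisible(x)
}

#' Encode the 7-character responder block
#'
#' Layout: job letter, two initials, two-digit age (modulo 100), two-digit
#' serial triage number.  The serial wraps: the first case is `01`, the 100th
#' `00`, and the 101st `01` again, i.e. the field is `serial %% 100` rendered
#' with `%02d`.
#'
#' @param r A [responder_profile()].
#' @param serial Serial triage number to encode; defaults to the profile's
#'   `next_triage_number`.
#' @return A 7-character string.
#' @examples
#' encode_responder_block(responder_profile("D", "K", "S", 35))  # "DKS3501"
#' @export
encode_responder_block <- function(r, serial = r$next_triage_number) {
  stopifnot(inherits(r, "responder_profile"))
  serial <- as.integer(serial)
  if (is.na(serial) || serial < 1L)
    stop("`serial` must be an integer >= 1", call. = FALSE)
  sprintf("%s%s%s%02d%02d", r$job, r$initial_1, r$initial_2,
          r$age %% 100L, serial %% 100L)
}

# Age-decade digit: exact age floor(age/10) capped at 9 (90+ encodes as 9),
# else the estimated decade, else unknown.
.age_decade_char <- function(c) {
  if (!is.na(c$age)) as.character(min(c$age %/% 10L, 9L))
  else if (!is.na(c$age_decade)) as.character(c$age_decade)
  else .UNKNOWN
}

#' Encode the 9-character casualty block
#'
#' Layout: day, hour and minute of triage (two zero-padded digits each), age
#' decade digit, gender letter and name initial.  A casualty under 10 years
#' encodes decade `0`; 65 years encodes `6`; 90 years or above encodes `9`.
#' Unknown age, gender or name each render as lowercase `u`.
#'
#' @param c A [casualty_record()].
#' @return A 9-character string.
#' @examples
#' encode_casualty_block(casualty_record(1, 1, 1, age = 5, gender = "M",
#'                                       name_initial = "K"))  # "0101010MK"
#' @export
encode_casualty_block <- function(c) {
  stopifnot(inherits(c, "casualty_record"))
  gender_char <- switch(c$gender, M = "M", F = "F", unknown = .UNKNOWN)
  initial_char <- if (is.na(c$name_initial)) .UNKNOWN else c$name_initial
  sprintf("%02d%02d%02d%s%s%s", c$day, c$hour, c$minute,
          .age_decade_char(c), gender_char, initial_char)
}

#' Encode a full 16-character casualty identification code
#'
#' Concatenates the responder block and the casualty block.  The canonical
#' form is 16 characters with no separator; the display form inserts a hyphen
#' between the two blocks (17 glyphs).
#'
#' @inheritParams encode_responder_block
#' @param c A [casualty_record()].
#' @return An object of class `id_code`: a list with elements `canonical`
#'   (16-character string), `display` (17 glyphs with hyphen), and `fields`
#'   (the decoded field list, see [decode_id()]).
#' @examples
#' r <- responder_profile("D", "K", "S", 35)
#' c <- casualty_record(1, 1, 1, age = 5, gender = "M", name_initial = "K")
#' encode_id(r, c)  # DKS3501-0101010MK
#' @export
encode_id <- function(r, c, serial = r$next_triage_number) {
  canonical <- paste0(encode_responder_block(r, serial),
                      encode_casualty_block(c))
  new_id_code(canonical)
}

new_id_code <- function(canonical) {
  structure(
    list(canonical = canonical,
         display = paste0(substr(canonical, 1L, 7L), "-",
                          substr(canonical, 8L, 16L)),
         responder_block = substr(canonical, 1L, 7L),
         casualty_block = substr(canonical, 8L, 16L),
         fields = .split_fields(canonical)),
    class = "id_code"
  )
}

#' @export
print.id_code <- function(x, ...) {
  cat(x$display, "\n")
  invisible(x)
}

#' @export
format.id_code <- function(x, ...) x$display

#' @export
as.character.id_code <- function(x, ...) x$canonical

# Raw positional split; no interpretation of unknown markers.
.split_fields <- function(canonical) {
  out <- substring(canonical, .id_fields$start, .id_fields$end)
  names(out) <- .id_fields$field
  as.list(out)
}

.strip_hyphen <- function(s) {
  if (nchar(s) == 17L && substr(s, 8L, 8L) == "-")
    paste0(substr(s, 1L, 7L), substr(s, 9L, 17L))
  else s
}

# One row per positional rule; `ok` is a predicate over the extracted field
# string.  Used by validate_id() so every rule yields a named violation.
.grammar_rules <- list(
  job = list(ok = function(x) x %in% .JOB_LETTERS,
             expected = "job letter D, N, P or V"),
  initial_1 = list(ok = function(x) grepl("^[A-Z]$", x),
                   expected = "uppercase letter A-Z"),
  initial_2 = list(ok = function(x) grepl("^[A-Z]$", x),
                   expected = "uppercase letter A-Z"),
  responder_age = list(ok = function(x) grepl("^[0-9]{2}$", x),
                       expected = "two digits 00-99"),
  serial = list(ok = function(x) grepl("^[0-9]{2}$", x),
                expected = "two digits 00-99"),
  day = list(ok = function(x) grepl("^[0-9]{2}$", x) &&
               as.integer(x) >= 1L && as.integer(x) <= 31L,
             expected = "day of month 01-31"),
  hour = list(ok = function(x) grepl("^[0-9]{2}$", x) && as.integer(x) <= 23L,
              expected = "hour 00-23"),
  minute = list(ok = function(x) grepl("^[0-9]{2}$", x) && as.integer(x) <= 59L,
                expected = "minute 00-59"),
  age_decade = list(ok = function(x) grepl("^[0-9u]$", x),
                    expected = "decade digit 0-9 or 'u'"),
  gender = list(ok = function(x) x %in% c("M", "F", .UNKNOWN),
                expected = "'M', 'F' or 'u'"),
  casualty_initial = list(ok = function(x) grepl("^[A-Zu]$", x),
                          expected = "uppercase letter A-Z or 'u'")
)

#' Validate a candidate identification code
#'
#' A total function: accepts any string and returns a data frame of grammar
#' violations, one row per failed positional rule, with zero rows exactly when
#' [decode_id()] would succeed.  Both the 16-character canonical form and the
#' 17-glyph hyphenated display form are accepted.
#'
#' @param s A character string.
#' @return A data frame with columns `field`, `position` (e.g. `"12-13"`),
#'   `expected` and `found`.  Zero rows means the code is valid.
#' @examples
#' validate_id("DKS35010101010MK")   # valid: zero rows
#' validate_id("XKS35010101010MK")   # job-category violation
#' @export
validate_id <- function(s) {
  empty <- data.frame(field = character(), position = character(),
                      expected = character(), found = character(),
                      stringsAsFactors = FALSE)
  if (length(s) != 1L || !is.character(s) || is.na(s))
    return(rbind(empty, data.frame(field = "input", position = "-",
                                   expected = "a single character string",
                                   found = class(s)[1L])))
  if (nchar(s) == 17L && substr(s, 8L, 8L) != "-")
    return(rbind(empty, data.frame(
      field = "separator", position = "8",
      expected = "hyphen between responder and casualty blocks",
      found = substr(s, 8L, 8L))))
  canonical <- .strip_hyphen(s)
  if (nchar(canonical) != 16L)
    return(rbind(empty, data.frame(
      field = "length", position = "-",
      expected = "16 characters (or 17 with hyphen after position 7)",
      found = as.character(nchar(s)))))
  fields <- .split_fields(canonical)
  rows <- lapply(seq_len(nrow(.id_fields)), function(i) {
    f <- .id_fields$field[i]
    rule <- .grammar_rules[[f]]
    if (rule$ok(fields[[f]])) return(NULL)
    pos <- if (.id_fields$start[i] == .id_fields$end[i])
      as.character(.id_fields$start[i])
    else paste0(.id_fields$start[i], "-", .id_fields$end[i])
    data.frame(field = f, position = pos, expected = rule$expected,
               found = fields[[f]], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(list(empty), rows))
}

#' Decode an identification code into named fields
#'
#' Inverts the encoder: splits a canonical or display-form code into its
#' named fields, mapping the `u` unknown markers back to explicit unknown
#' states (`NA` for age decade and casualty initial, `"unknown"` for gender).
#'
#' @param s A 16-character canonical code or 17-glyph display form.
#' @return A list of class `id_fields` with elements `job`, `initial_1`,
#'   `initial_2`, `responder_age`, `serial`, `day`, `hour`, `minute`,
#'   `age_decade`, `gender`, `casualty_initial`, plus `canonical`.
#'   `responder_age` and `serial` are the two-digit field values (0-99);
#'   the serial for a responder's 100th case decodes as 0.
#' @examples
#' decode_id("DKS3501-0101010MK")
#' @export
decode_id <- function(s) {
  v <- validate_id(s)
  if (nrow(v) > 0L) {
    first <- v[1L, ]
    stop(sprintf("invalid ID code at position %s (%s): expected %s, found %s",
                 first$position, first$field, first$expected,
                 dQuote(first$found)), call. = FALSE)
  }
  canonical <- .strip_hyphen(s)
  f <- .split_fields(canonical)
  structure(
    list(job = f$job, initial_1 = f$initial_1, initial_2 = f$initial_2,
         responder_age = as.integer(f$responder_age),
         serial = as.integer(f$serial),
         day = as.integer(f$day), hour = as.integer(f$hour),
         minute = as.integer(f$minute),
         age_decade = if (f$age_decade == .UNKNOWN) NA_integer_
                      else as.integer(f$age_decade),
         gender = if (f$gender == .UNKNOWN) "unknown" else f$gender,
         casualty_initial = if (f$casualty_initial == .UNKNOWN) NA_character_
                            else f$casualty_initial,
         canonical = canonical),
    class = "id_fields"
  )
}

#' @export
print.id_fields <- function(x, ...) {
  cat(sprintf(
    "ID %s\n  responder: job %s, initials %s%s, age %02d, serial %02d\n  casualty:  day %02d %02d:%02d, decade %s, gender %s, initial %s\n",
    x$canonical, x$job, x$initial_1, x$initial_2, x$responder_age, x$serial,
    x$day, x$hour, x$minute,
    ifelse(is.na(x$age_decade), "unknown", x$age_decade), x$gender,
    ifelse(is.na(x$casualty_initial), "unknown", x$casualty_initial)))
  invisible(x)
}
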