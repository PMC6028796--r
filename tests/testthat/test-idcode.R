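test_that("worked example encodes to the published code and decodes back", {
  r <- responder_profile("D", "K", "S", 35, next_triage_number = 1)
  cas <- casualty_record(day = 1, hour = 1, minute = 1, age = 5,
                         gender = "M", name_initial = "K")
  id <- encode_id(r, cas)
  expect_equal(id$canonical, "DKS35010101010MK")
  expect_equal(id$display, "DKS3501-0101010MK")
  expect_equal(id$responder_block, "DKS3501")
  expect_equal(id$casualty_block, "0101010MK")

  f <- decode_id(id$display)
  expect_equal(f$job, "D")
  expect_equal(f$initial_1, "K")
  expect_equal(f$initial_2, "S")
  expect_equal(f$responder_age, 35L)
  expect_equal(f$serial, 1L)
  expect_equal(f$day, 1L)
  expect_equal(f$hour, 1L)
  expect_equal(f$minute, 1L)
  expect_equal(f$age_decade, 0L)
  expect_equal(f$gender, "M")
  expect_equal(f$casualty_initial, "K")
})

test_that("serial triage number wraps at 100", {
  r <- function(n) responder_profile("D", "K", "S", 35, n)
  expect_equal(encode_responder_block(r(1)), "DKS3501")
  expect_equal(encode_responder_block(r(100)), "DKS3500")
  expect_equal(encode_responder_block(r(101)), "DKS3501")
  # wrap-around coincidence: n and n + 100 produce identical blocks
  for (n in c(1, 7, 42, 99)) {
    expect_equal(encode_responder_block(r(n)), encode_responder_block(r(n + 100)))
  }
  expect_equal(encode_responder_block(responder_profile("V", "A", "A", 0, 101)),
               "VAA0001")
})

test_that("age decade digit follows the under-10 / 65 / 90-plus rules", {
  block_for_age <- function(a)
    encode_casualty_block(casualty_record(1, 9, 5, age = a, gender = "F",
                                          name_initial = "S"))
  decade <- function(a) substr(block_for_age(a), 7, 7)
  expect_equal(decade(5), "0")
  expect_equal(decade(9), "0")
  expect_equal(decade(65), "6")
  expect_equal(decade(90), "9")
  expect_equal(decade(93), "9")
  expect_equal(decade(104), "9")
  expect_equal(block_for_age(93), "0109059FS")
})

test_that("estimated decades and unknown markers render correctly", {
  # decade-only age, unknown gender and name (Table-style casualty in their 30s)
  c5 <- casualty_record(day = 31, hour = 14, minute = 30, age_decade = 3)
  expect_equal(encode_casualty_block(c5), "3114303uu")
  # everything unknown about the casualty except the time
  cu <- casualty_record(day = 2, hour = 0, minute = 0)
  expect_equal(substr(encode_casualty_block(cu), 7, 9), "uuu")
  f <- decode_id(paste0("PKS3501", "0101010uu"))
  expect_equal(f$gender, "unknown")
  expect_true(is.na(f$casualty_initial))
  expect_equal(f$age_decade, 0L)
  fu <- decode_id("PKS3501010101uuu")
  expect_true(is.na(fu$age_decade))
})

test_that("constructors reject invalid field values by name", {
  expect_error(responder_profile("X", "K", "S", 35), "job")
  expect_error(responder_profile("D", "k", "S", 35), "initial_1")
  expect_error(responder_profile("D", "K", "S", -1), "age")
  expect_error(responder_profile("D", "K", "S", 35, 0), "next_triage_number")
  expect_error(casualty_record(0, 1, 1), "day")
  expect_error(casualty_record(1, 24, 1), "hour")
  expect_error(casualty_record(1, 1, 60), "minute")
  expect_error(casualty_record(1, 1, 1, age = 20, age_decade = 2),
               "at most one")
  expect_error(casualty_record(1, 1, 1, gender = "X"), "gender")
  expect_error(casualty_record(1, 1, 1, name_initial = "k"), "name_initial")
})

test_that("validate_id pinpoints the violated positional rule", {
  expect_equal(nrow(validate_id("DKS35010101010MK")), 0L)
  expect_equal(nrow(validate_id("DKS3501-0101010MK")), 0L)

  v <- validate_id("")
  expect_equal(v$field, "length")
  v <- validate_id("XKS35010101010MK")
  expect_equal(v$field, "job")
  expect_equal(v$position, "1")
  v <- validate_id("DKS350101019X0MK")  # letter in the minute field
  expect_true("minute" %in% v$field)
  expect_equal(v$position[v$field == "minute"], "12-13")
  v <- validate_id("DKS35010101990MK")  # minute 99 out of range
  expect_true("minute" %in% v$field)
  v <- validate_id("DKS3501010101XMK")  # letter where the decade digit goes
  expect_equal(v$field, "age_decade")
  expect_equal(v$position, "14")
  v <- validate_id("DKS35013201010MK")  # day 32
  expect_true("day" %in% v$field)
  v <- validate_id("DKS35010125010MK")  # hour 25
  expect_true("hour" %in% v$field)
  v <- validate_id("DKS35010101010mK")  # lowercase gender letter
  expect_true("gender" %in% v$field)
  # hyphen misplaced
  v <- validate_id("DKS350101-01010MK")
  expect_equal(v$field, "separator")
  # unknown marker is lowercase only: 'U' as decade is a real letter, invalid
  v <- validate_id("DKS3501010101UMK")
  expect_true("age_decade" %in% v$field)
})

test_that("decode_id errors report position and expected class", {
  expect_error(decode_id("DKS350101019X0MK"), "position 12-13")
  expect_error(decode_id("DKS3501010101XMK"), "position 14")
  expect_error(decode_id("DKS3501"), "16 characters")
  expect_error(decode_id("dks35010101010mk"), "position 1")
})

test_that("encode/decode round trip over random valid inputs", {
  set.seed(20260922)
  for (i in 1:300) {
    r <- random_responder()
    cas <- random_casualty()
    id <- encode_id(r, cas)
    expect_equal(nchar(id$canonical), 16L)
    expect_equal(nchar(id$display), 17L)
    expect_equal(substr(id$display, 8, 8), "-")
    f <- decode_id(id$canonical)
    expect_equal(f$job, r$job)
    expect_equal(f$initial_1, r$initial_1)
    expect_equal(f$initial_2, r$initial_2)
    expect_equal(f$responder_age, r$age %% 100L)
    expect_equal(f$serial, r$next_triage_number %% 100L)
    expect_equal(f$day, cas$day)
    expect_equal(f$hour, cas$hour)
    expect_equal(f$minute, cas$minute)
    expected_decade <- if (!is.na(cas$age)) min(cas$age %/% 10L, 9L)
                       else if (!is.na(cas$age_decade)) cas$age_decade
                       else NA_integer_
    expect_equal(f$age_decade, expected_decade)
    expect_equal(f$gender, cas$gender)
    expect_equal(f$casualty_initial, cas$name_initial)
  }
})

test_that("validate_id accepts exactly the strings decode_id accepts", {
  set.seed(4871)
  alphabet <- c(LETTERS, letters, 0:9, "-", " ")
  for (i in 1:300) {
    s <- encode_id(random_responder(), random_casualty())$canonical
    # random single-character mutation (may or may not stay valid)
    pos <- sample(1:16, 1)
    substr(s, pos, pos) <- sample(alphabet, 1)
    decodes <- !inherits(tryCatch(decode_id(s), error = identity), "error")
    expect_equal(nrow(validate_id(s)) == 0L, decodes, label = s)
  }
})
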