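# Duplication statistics and the analytic collision model.
#
# "Pattern duplication" is counted at the item level: an item (participant,
# ID, ...) is duplicated if its key occurs at least twice in the multiset.

#' Round half-up to a number of decimal places
#'
#' Commercial rounding: halves always round away from zero (for the
#' non-negative percentages used here, upward).  This is the rule that
#' reproduces every printed fraction/percentage pair of the verification
#' study: 43/89 -> 48.3, 17/89 -> 19.1, 2/89 -> 2.2, 2/890 -> 0.2,
#' 888/890 -> 99.8.  `base::round()` rounds half to even and would not.
#'
#' @param x Numeric vector, assumed non-negative.
#' @param digits Number of decimal places.
#' @return `x` rounded half-up.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

new_duplication_report <- function(keys) {
  tab <- table(keys)
  n_items <- length(keys)
  n_patterns <- length(tab)
  dup <- tab[tab >= 2L]
  n_duplicated_patterns <- length(dup)
  n_items_in_duplicated <- sum(dup)
  rep <- structure(
    list(n_items = n_items,
         n_patterns = n_patterns,
         n_duplicated_patterns = n_duplicated_patterns,
         n_items_in_duplicated = as.integer(n_items_in_duplicated),
         percent_items_in_duplicated =
           round_half_up(100 * n_items_in_duplicated / n_items, 1L)),
    class = "duplication_report"
  )
  # accounting identities, asserted on every report
  n_singletons <- n_items - rep$n_items_in_duplicated
  stopifnot(n_singletons + rep$n_duplicated_patterns == rep$n_patterns,
            rep$percent_items_in_duplicated >= 0,
            rep$percent_items_in_duplicated <= 100)
  rep
}

#' Duplication statistics over a multiset of keys
#'
#' Counts how many distinct patterns occur, how many occur at least twice,
#' and how many items fall in those duplicated patterns.  Keys are opaque:
#' pass initials (`"KS"`), initials+age (`"KS35"`), full responder prefixes,
#' or complete 16-character codes, depending on the question.
#'
#' @param keys Non-empty character (or coercible) vector of keys.
#' @return An object of class `duplication_report`: a list with `n_items`,
#'   `n_patterns` (distinct keys), `n_duplicated_patterns` (keys occurring
#'   at least twice), `n_items_in_duplicated` (items whose key occurs at
#'   least twice) and `percent_items_in_duplicated` (one decimal, half-up).
#' @examples
#' pattern_duplication_stats(c("KS", "KS", "TT", "AB"))
#' @export
pattern_duplication_stats <- function(keys) {
  if (length(keys) == 0L) stop("`keys` must be non-empty", call. = FALSE)
  new_duplication_report(as.character(keys))
}

#' @export
print.duplication_report <- function(x, ...) {
  cat(sprintf("Duplication report: %d items, %d patterns\n",
              x$n_items, x$n_patterns))
  cat(sprintf("  duplicated: %d/%d items in %d patterns (%.1f%%)\n",
              x$n_items_in_duplicated, x$n_items, x$n_duplicated_patterns,
              x$percent_items_in_duplicated))
  invisible(x)
}

#' Duplication statistics over complete identification codes
#'
#' Validates every code, then counts complete duplications: codes whose
#' exact 16-character canonical string occurs at least twice.  In the
#' 890-ID verification study exactly one such pair occurred, so 2 IDs
#' (0.2%) were complete duplicates and 888 (99.8%) were unique.
#'
#' @param ids Character vector of codes (canonical or display form), or a
#'   list of `id_code` objects.
#' @return A `duplication_report` (keyed on the full canonical string) with
#'   extra elements `n_complete_duplicates`, `n_unique`,
#'   `percent_complete_duplicates` and `percent_unique`.
#' @examples
#' id_duplication_stats(c("DKS35010101010MK", "DKS35010101010MK",
#'                        "NAB44050102011FT"))
#' @export
id_duplication_stats <- function(ids) {
  if (is.list(ids))
    ids <- vapply(ids, function(x)
      if (inherits(x, "id_code")) x$canonical else as.character(x), "")
  if (length(ids) == 0L) stop("`ids` must be non-empty", call. = FALSE)
  canon <- vapply(ids, .strip_hyphen, "", USE.NAMES = FALSE)
  for (i in seq_along(canon)) {
    v <- validate_id(canon[i])
    if (nrow(v) > 0L)
      stop(sprintf("invalid ID on line %d (%s): %s violation, expected %s",
                   i, canon[i], v$field[1L], v$expected[1L]), call. = FALSE)
  }
  rep <- new_duplication_report(canon)
  rep$n_complete_duplicates <- rep$n_items_in_duplicated
  rep$n_unique <- rep$n_items - rep$n_complete_duplicates
  rep$percent_complete_duplicates <-
    round_half_up(100 * rep$n_complete_duplicates / rep$n_items, 1L)
  rep$percent_unique <- round_half_up(100 * rep$n_unique / rep$n_items, 1L)
  rep
}

#' Explain why two codes do not collide
#'
#' Lists the fields on which two codes differ, in positional order; an empty
#' result means the two are complete duplicates.  In the verification study
#' the one prefix-sharing responder pair was kept apart on 18 of their 20
#' codes by casualty information alone: the minute of triage (14 codes) and
#' the casualty's initial (4 codes).
#'
#' @param a,b Codes: strings (canonical or display) or `id_code` objects.
#' @return Character vector of differing field names, ordered by position
#'   in the code; `character(0)` iff the codes are identical.
#' @examples
#' explain_nonduplication("DKS35010101010MK", "DKS35010102010MK")  # "minute"
#' @export
explain_nonduplication <- function(a, b) {
  canon <- function(x) {
    if (inherits(x, "id_code")) return(x$canonical)
    v <- validate_id(x)
    if (nrow(v) > 0L)
      stop("invalid ID code: ", v$field[1L], " violation", call. = FALSE)
    .strip_hyphen(x)
  }
  fa <- .split_fields(canon(a))
  fb <- .split_fields(canon(b))
  .id_fields$field[mapply(Negate(identical), fa, fb)]
}

#' Define an analytic collision model
#'
#' A structured birthday problem: each code field is drawn independently
#' from its own categorical distribution, and two independently drawn items
#' collide on a field set when they match on every field in it.  Field
#' independence is an explicit model assumption; use the Monte Carlo
#' simulator for dependent structures.
#'
#' @param ... Named numeric probability vectors, one per field (e.g.
#'   `initial_1 = c(K = 0.3, S = 0.3, T = 0.4)`).  Each must sum to 1
#'   (tolerance `1e-9`) with non-negative entries.
#' @return An object of class `collision_model`.
#' @examples
#' collision_model(gender = c(M = 0.5, F = 0.5),
#'                 job = c(D = 0.25, N = 0.25, P = 0.25, V = 0.25))
#' @export
collision_model <- function(...) {
  fields <- list(...)
  if (length(fields) == 0L || is.null(names(fields)) ||
      any(!nzchar(names(fields))))
    stop("all field distributions must be named", call. = FALSE)
  for (nm in names(fields)) {
    p <- fields[[nm]]
    if (!is.numeric(p) || any(p < 0))
      stop("field ", nm, ": probabilities must be non-negative numerics",
           call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9)
      stop("field ", nm, ": probabilities must sum to 1 (got ",
           format(sum(p)), ")", call. = FALSE)
  }
  structure(fields, class = "collision_model")
}

#' @export
print.collision_model <- function(x, ...) {
  cat(sprintf("Collision model over %d independent fields:\n", length(x)))
  for (nm in names(x))
    cat(sprintf("  %-16s %d categories, match prob %.4g\n",
                nm, length(x[[nm]]), sum(x[[nm]]^2)))
  invisible(x)
}

#' Probability that two independent draws match on a field subset
#'
#' For each field with category probabilities \eqn{p_i}, the chance that two
#' independent draws agree is \eqn{\sum_i p_i^2}; under the model's
#' independence assumption the joint match probability over a field set is
#' the product of the per-field sums.
#'
#' @param model A [collision_model()].
#' @param fields Character vector of field names; defaults to all fields.
#' @return A probability in `[0, 1]`.
#' @examples
#' m <- collision_model(gender = c(M = 0.5, F = 0.5))
#' pair_match_probability(m)  # 0.5
#' @export
pair_match_probability <- function(model, fields = names(model)) {
  stopifnot(inherits(model, "collision_model"))
  missing <- setdiff(fields, names(model))
  if (length(missing) > 0L)
    stop("unknown field(s): ", paste(missing, collapse = ", "), call. = FALSE)
  prod(vapply(model[fields], function(p) sum(p^2), numeric(1)))
}

#' Expected number of colliding pairs in a roster
#'
#' Among `n` items drawn independently from the model there are
#' \eqn{\binom{n}{2}} pairs, each matching on the chosen field set with the
#' pairwise match probability, so the expected number of matching pairs is
#' \eqn{\binom{n}{2} \prod_f \sum_i p_{fi}^2}.
#'
#' @inheritParams pair_match_probability
#' @param n Roster size, at least 2.
#' @return Expected count of matching pairs.
#' @examples
#' m <- collision_model(initials = c(TS = 0.5, KS = 0.5))
#' expected_duplicate_pairs(m, n = 89)
#' @export
expected_duplicate_pairs <- function(model, n, fields = names(model)) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  choose(n, 2) * pair_match_probability(model, fields)
}
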