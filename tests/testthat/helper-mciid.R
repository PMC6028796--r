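# Shared generators and independent brute-force oracles.

random_responder <- function() {
  responder_profile(sample(c("D", "N", "P", "V"), 1),
                    sample(LETTERS, 1), sample(LETTERS, 1),
                    sample(0:119, 1),
                    next_triage_number = sample(1:250, 1))
}

random_casualty <- function() {
  age_kind <- sample(c("exact", "decade", "unknown"), 1)
  casualty_record(
    day = sample(1:31, 1), hour = sample(0:23, 1), minute = sample(0:59, 1),
    age = if (age_kind == "exact") sample(0:110, 1) else NA,
    age_decade = if (age_kind == "decade") sample(0:9, 1) else NA,
    gender = sample(c("M", "F", "unknown"), 1),
    name_initial = if (stats::runif(1) < 0.8) sample(LETTERS, 1) else NA)
}

# Brute-force duplication counting: pairwise comparisons only, no table().
brute_dup_counts <- function(keys) {
  n <- length(keys)
  mult <- vapply(seq_len(n), function(i) sum(keys == keys[i]), 0L)
  dup_items <- sum(mult >= 2L)
  pats <- unique(keys)
  dup_pats <- sum(vapply(pats, function(p) sum(keys == p) >= 2L, TRUE))
  list(n_items = n, n_patterns = length(pats),
       n_duplicated_patterns = dup_pats, n_items_in_duplicated = dup_items)
}

# Exhaustive enumeration of P(two independent draws match on all fields):
# walks the full joint support of the pair.
brute_pair_match <- function(model, fields = names(model)) {
  p <- 1
  for (f in fields) {
    d <- model[[f]]
    m <- 0
    for (i in seq_along(d)) for (j in seq_along(d))
      if (i == j) m <- m + d[i] * d[j]
    p <- p * m
  }
  unname(p)
}

# A deterministic 89-responder roster with exact job counts D29/N15/P19/V26
# and exactly one pair sharing the full 7-character prefix (two paramedics
# "PKS35..").  All other responders have pairwise-distinct initials.
fixture_study_roster <- function() {
  pairs <- expand.grid(f = LETTERS, g = LETTERS, stringsAsFactors = FALSE)
  pairs <- pairs[!(pairs$f == "K" & pairs$g == "S"), ]
  jobs <- rep(c("D", "N", "P", "V"), times = c(29, 15, 17, 26))
  roster <- lapply(seq_along(jobs), function(i)
    responder_profile(jobs[i], pairs$f[i], pairs$g[i], 20 + (i %% 40)))
  c(roster,
    list(responder_profile("P", "K", "S", 35),
         responder_profile("P", "K", "S", 35)))
}

# Minute-offset matrix for fixture_study_roster(): the prefix-sharing pair
# (rows 88 and 89) coincide on casualty 1 only; all their other stamps
# differ.  Remaining rows are arbitrary non-decreasing sequences.
fixture_study_offsets <- function(n_casualties = 10) {
  m <- t(vapply(1:87, function(i) cumsum(rep(i %% 3, n_casualties)),
                numeric(n_casualties)))
  m <- pmin(m, 20)
  row88 <- pmin(cumsum(c(0, rep(2, n_casualties - 1))), 20)
  row89 <- pmin(cumsum(c(0, rep(1, n_casualties - 1))), 20)
  rbind(m, row88, row89)
}
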