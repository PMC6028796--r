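# Desk-based triage simulation: synthetic rosters, the fixed virtual-casualty
# list, and Monte Carlo replication of the 89-responder x 10-casualty study.

# Sub-stream seed derivation: one root seed, sub-seeds obtained by a
# Lehmer-style mix of the stream index.  Keeps every draw reproducible from
# the root seed while decoupling roster, time-stamp and replicate streams.
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 104729 * as.numeric(k)) %% 2147483647)
}

# Default initial-letter frequencies: a documented skewed categorical standing
# in for common-surname (and common given-name) concentration, where a few
# letters (S, T, K, M, ...) carry most of the mass.  Fully overridable.
.default_family_freqs <- function() {
  w <- rep(0.4, 26)
  names(w) <- LETTERS
  w[c("S", "T", "K", "M", "N", "I", "Y", "W", "H", "O", "A", "F")] <-
    c(17, 13, 12, 8, 7, 6, 6, 5, 5, 4, 3, 2)
  w / sum(w)
}

.default_given_freqs <- function() {
  w <- rep(0.5, 26)
  names(w) <- LETTERS
  w[c("T", "K", "S", "M", "Y", "A", "H", "R", "N", "J")] <-
    c(15, 12, 10, 9, 8, 7, 6, 5, 5, 4)
  w / sum(w)
}

.check_dist <- function(p, what) {
  if (!is.numeric(p) || is.null(names(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-9)
    stop(what, " must be a named non-negative vector summing to 1",
         call. = FALSE)
  p
}

#' The ten fixed virtual casualties of the desk-based verification study
#'
#' The predetermined casualty list used to stress the coding method: it
#' deliberately contains casualties with identical name initials, age and
#' gender (rows 8 and 10), decade-only ages ("70s", "80s", "30s"), missing
#' names and an unknown gender, and printed triage numbers spanning the
#' serial wrap (1 through 123, including 99, 100 and 101).  Casualties 1-5
#' are dated the 31st of the month, 6-10 the 1st.
#'
#' @return A data frame with columns `casualty_id`, `day`, `triage_number`,
#'   `age` (exact years, `NA` if only a decade is known), `age_decade`
#'   (decade digit, `NA` if the exact age is known), `gender` (`"M"`, `"F"`
#'   or `"unknown"`), `name_initial` (`NA` when no name is available) and
#'   `triage_class`.
#' @examples
#' table1_casualties()
#' @export
table1_casualties <- function() {
  read_casualties(system.file("extdata", "virtual_casualties.csv",
                              package = "mciid", mustWork = TRUE))
}

#' Configure a desk-study simulation scenario
#'
#' Bundles everything one simulated exercise needs: the roster-generating
#' distributions, the casualty list, the timing model and the RNG seed.  The
#' defaults reproduce the verification study's conditions: 89 responders
#' with exact job counts D 29 / N 15 / P 19 / V 26, a cohort-like age
#' distribution concentrated on 22-24 years (median 23), skewed name-initial
#' frequencies, the ten fixed virtual casualties, and a 20-minute exercise
#' window within which each responder's ten time stamps are drawn as
#' non-decreasing cumulative increments.
#'
#' @param n_responders Number of responders in the roster.
#' @param job_mix Either exact job counts summing to `n_responders`
#'   (`job_mode = "exact"`, the default, mirroring the study's assigned
#'   counts) or a probability distribution over `D`, `N`, `P`, `V`
#'   (`job_mode = "iid"`).
#' @param job_mode `"exact"` for deterministic allocation of `job_mix`
#'   counts (shuffled across the roster), `"iid"` for independent sampling.
#' @param family_freqs,given_freqs Named probability vectors over `LETTERS`
#'   for the family- and given-name initials.
#' @param age_distribution Named probability vector; names are integer ages.
#' @param casualties Casualty table as returned by [table1_casualties()] or
#'   [read_casualties()].
#' @param start_hour,start_minute Wall-clock start of the exercise.
#' @param time_window_minutes Maximum span of one responder's time stamps;
#'   stamps are clamped to the window.
#' @param pacing Named probability vector over non-negative integer
#'   minute increments between consecutive casualties.
#' @param serial_mode `"printed"`: the serial field of every code is the
#'   casualty's printed triage number, identical across responders (the
#'   study design that made duplication more likely); `"per_responder"`:
#'   each responder's own free-running counter.
#' @param error_rate Per-ID transcription-error probability passed to
#'   [inject_transcription_errors()]; default 0.
#' @param seed Root RNG seed.
#' @return An object of class `scenario_config`.
#' @examples
#' cfg <- scenario_config(seed = 1)
#' cfg$n_responders
#' @export
scenario_config <- function(n_responders = 89L,
                            job_mix = c(D = 29L, N = 15L, P = 19L, V = 26L),
                            job_mode = c("exact", "iid"),
                            family_freqs = .default_family_freqs(),
                            given_freqs = .default_given_freqs(),
                            age_distribution = c("22" = 0.25, "23" = 0.5,
                                                 "24" = 0.25),
                            casualties = table1_casualties(),
                            start_hour = 10L, start_minute = 0L,
                            time_window_minutes = 20L,
                            pacing = c("0" = 0.2, "1" = 0.3, "2" = 0.3,
                                       "3" = 0.2),
                            serial_mode = c("printed", "per_responder"),
                            error_rate = 0,
                            seed = 1L) {
  job_mode <- match.arg(job_mode)
  serial_mode <- match.arg(serial_mode)
  n_responders <- as.integer(n_responders)
  if (is.na(n_responders) || n_responders < 1L)
    stop("`n_responders` must be >= 1", call. = FALSE)
  if (is.null(names(job_mix)) || !setequal(names(job_mix), .JOB_LETTERS))
    stop("`job_mix` must be named with exactly D, N, P, V", call. = FALSE)
  if (job_mode == "exact") {
    if (any(job_mix < 0) || sum(job_mix) != n_responders)
      stop("exact `job_mix` counts must sum to `n_responders`",
           call. = FALSE)
  } else {
    .check_dist(job_mix, "`job_mix`")
  }
  .check_dist(family_freqs, "`family_freqs`")
  .check_dist(given_freqs, "`given_freqs`")
  .check_dist(age_distribution, "`age_distribution`")
  .check_dist(pacing, "`pacing`")
  if (any(as.integer(names(pacing)) < 0L))
    stop("`pacing` increments must be non-negative minutes", call. = FALSE)
  if (!is.data.frame(casualties) || nrow(casualties) == 0L)
    stop("`casualties` must be a non-empty casualty table", call. = FALSE)
  if (error_rate < 0 || error_rate > 1)
    stop("`error_rate` must be in [0, 1]", call. = FALSE)
  structure(
    list(n_responders = n_responders, job_mix = job_mix, job_mode = job_mode,
         family_freqs = family_freqs, given_freqs = given_freqs,
         age_distribution = age_distribution, casualties = casualties,
         start_hour = as.integer(start_hour),
         start_minute = as.integer(start_minute),
         time_window_minutes = as.integer(time_window_minutes),
         pacing = pacing, serial_mode = serial_mode,
         error_rate = error_rate, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario: %d responders (%s job mix), %d casualties, %d-min window, seed %d\n",
    x$n_responders, x$job_mode, nrow(x$casualties), x$time_window_minutes,
    x$seed))
  invisible(x)
}

#' Generate a synthetic responder roster
#'
#' Draws `n_responders` profiles from the scenario's job, initial and age
#' distributions.  In `"exact"` job mode the configured counts are allocated
#' deterministically and shuffled across roster positions; in `"iid"` mode
#' jobs are sampled independently.  Deterministic given the scenario seed.
#'
#' @param cfg A [scenario_config()].
#' @param seed Seed for this draw; defaults to a sub-stream derived from
#'   `cfg$seed`.
#' @return A list of [responder_profile()] objects.
#' @examples
#' roster <- generate_roster(scenario_config(n_responders = 5, seed = 7,
#'   job_mix = c(D = 2, N = 1, P = 1, V = 1)))
#' @export
generate_roster <- function(cfg, seed = .derive_seed(cfg$seed, 1L)) {
  stopifnot(inherits(cfg, "scenario_config"))
  n <- cfg$n_responders
  set.seed(seed)
  jobs <- if (cfg$job_mode == "exact") {
    sample(rep(names(cfg$job_mix), times = cfg$job_mix))
  } else {
    sample(names(cfg$job_mix), n, replace = TRUE, prob = cfg$job_mix)
  }
  fam <- sample(names(cfg$family_freqs), n, replace = TRUE,
                prob = cfg$family_freqs)
  giv <- sample(names(cfg$given_freqs), n, replace = TRUE,
                prob = cfg$given_freqs)
  ages <- as.integer(sample(names(cfg$age_distribution), n, replace = TRUE,
                            prob = cfg$age_distribution))
  lapply(seq_len(n), function(i)
    responder_profile(jobs[i], fam[i], giv[i], ages[i]))
}

# Draw one responder's minute offsets (from exercise start) for all
# casualties: cumulative pacing increments, clamped to the window.
.draw_minute_offsets <- function(cfg, n_casualties) {
  inc <- as.integer(sample(names(cfg$pacing), n_casualties, replace = TRUE,
                           prob = cfg$pacing))
  pmin(cumsum(inc), cfg$time_window_minutes)
}

.casualty_from_row <- function(row, hour, minute) {
  casualty_record(day = row$day, hour = hour, minute = minute,
                  age = row$age, age_decade = row$age_decade,
                  gender = row$gender, name_initial = row$name_initial,
                  triage_class = row$triage_class)
}

#' Run one desk-study replicate
#'
#' Every responder encodes every casualty in listed order.  In the default
#' `"printed"` serial mode the serial field is the casualty's printed triage
#' number, identical across responders as in the study design; each
#' responder's time stamps are drawn as non-decreasing minute offsets within
#' the exercise window (or supplied explicitly via `minute_offsets`).
#' If `cfg$error_rate > 0`, the finished IDs are perturbed by
#' [inject_transcription_errors()].
#'
#' @param roster List of [responder_profile()], e.g. from
#'   [generate_roster()].
#' @param cfg A [scenario_config()].
#' @param seed Seed for the time-stamp draw; defaults to a sub-stream of
#'   `cfg$seed`.
#' @param minute_offsets Optional integer matrix (`length(roster)` rows,
#'   one column per casualty) of minute offsets from the exercise start,
#'   overriding the random draw — used to construct collision scenarios.
#' @return An object of class `simulation_result`: `ids` (canonical codes,
#'   responder-major order), `reports` (duplication reports for the key
#'   cascade `initials`, `initials_age`, `initials_age_job`,
#'   `responder_block`, and `full_id` for the complete codes), `roster`,
#'   and the echoed `cfg`.
#' @examples
#' cfg <- scenario_config(n_responders = 3, seed = 42,
#'                        job_mix = c(D = 1, N = 1, P = 1, V = 0))
#' res <- run_desk_study(generate_roster(cfg), cfg)
#' length(res$ids)  # 30
#' @export
run_desk_study <- function(roster, cfg, seed = .derive_seed(cfg$seed, 2L),
                           minute_offsets = NULL) {
  stopifnot(inherits(cfg, "scenario_config"), length(roster) > 0L)
  cas <- cfg$casualties
  n_r <- length(roster)
  n_c <- nrow(cas)
  if (is.null(minute_offsets)) {
    set.seed(seed)
    minute_offsets <- t(vapply(seq_len(n_r), function(i)
      .draw_minute_offsets(cfg, n_c), integer(n_c)))
  }
  stopifnot(nrow(minute_offsets) == n_r, ncol(minute_offsets) == n_c)
  start <- cfg$start_hour * 60L + cfg$start_minute
  ids <- character(n_r * n_c)
  k <- 0L
  for (i in seq_len(n_r)) {
    for (j in seq_len(n_c)) {
      stamp <- start + minute_offsets[i, j]
      rec <- .casualty_from_row(cas[j, ],
                                hour = (stamp %/% 60L) %% 24L,
                                minute = stamp %% 60L)
      serial <- if (cfg$serial_mode == "printed") {
        cas$triage_number[j]  # identical across responders; encoder wraps
      } else {
        roster[[i]]$next_triage_number + j - 1L  # free-running counter
      }
      k <- k + 1L
      ids[k] <- encode_id(roster[[i]], rec, serial = serial)$canonical
    }
  }
  if (cfg$error_rate > 0)
    ids <- inject_transcription_errors(ids, cfg$error_rate,
                                       seed = .derive_seed(seed, 3L))
  prefix <- vapply(roster, function(r)
    c(initials = paste0(r$initial_1, r$initial_2),
      initials_age = sprintf("%s%s%02d", r$initial_1, r$initial_2,
                             r$age %% 100L),
      initials_age_job = sprintf("%s%s%s%02d", r$job, r$initial_1,
                                 r$initial_2, r$age %% 100L)),
    c(initials = "", initials_age = "", initials_age_job = ""))
  structure(
    list(ids = ids,
         reports = list(
           initials = pattern_duplication_stats(prefix["initials", ]),
           initials_age = pattern_duplication_stats(prefix["initials_age", ]),
           initials_age_job =
             pattern_duplication_stats(prefix["initials_age_job", ]),
           responder_block =
             pattern_duplication_stats(substr(ids, 1L, 7L)),
           full_id = id_duplication_stats(ids)),
         roster = roster, cfg = cfg),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Desk-study replicate: %d responders x %d casualties = %d IDs\n",
              length(x$roster), nrow(x$cfg$casualties), length(x$ids)))
  f <- x$reports$full_id
  cat(sprintf("  complete ID duplicates: %d (%.1f%%); unique: %d (%.1f%%)\n",
              f$n_complete_duplicates, f$percent_complete_duplicates,
              f$n_unique, f$percent_unique))
  for (nm in c("initials", "initials_age", "initials_age_job"))
    cat(sprintf("  %-18s %d/%d duplicated (%.1f%%)\n", nm,
                x$reports[[nm]]$n_items_in_duplicated,
                x$reports[[nm]]$n_items,
                x$reports[[nm]]$percent_items_in_duplicated))
  invisible(x)
}

#' Monte Carlo replication of the desk study
#'
#' Repeats roster generation and the desk-study run under per-replicate
#' sub-seeds derived from the root seed, and aggregates the duplication
#' percentages to mean, standard deviation, minimum and maximum.
#'
#' @param cfg A [scenario_config()].
#' @param n_replicates Number of independent replicates, at least 1.
#' @return An object of class `mc_summary`: `replicates` (a data frame with
#'   one row per replicate and the duplication percentages for each key
#'   subset plus complete-ID duplicates) and `summary` (mean/sd/min/max per
#'   column).
#' @examples
#' mc <- monte_carlo(scenario_config(n_responders = 10, seed = 3,
#'   job_mix = c(D = 0.25, N = 0.25, P = 0.25, V = 0.25),
#'   job_mode = "iid"), n_replicates = 3)
#' mc$summary
#' @export
monte_carlo <- function(cfg, n_replicates) {
  stopifnot(inherits(cfg, "scenario_config"))
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop("`n_replicates` must be >= 1", call. = FALSE)
  rows <- lapply(seq_len(n_replicates), function(r) {
    rs <- .derive_seed(cfg$seed, 100L + r)
    roster <- generate_roster(cfg, seed = rs)
    res <- run_desk_study(roster, cfg, seed = .derive_seed(rs, 2L))
    data.frame(
      replicate = r,
      pct_initials = res$reports$initials$percent_items_in_duplicated,
      pct_initials_age =
        res$reports$initials_age$percent_items_in_duplicated,
      pct_initials_age_job =
        res$reports$initials_age_job$percent_items_in_duplicated,
      pct_responder_block =
        res$reports$responder_block$percent_items_in_duplicated,
      n_complete_duplicates = res$reports$full_id$n_complete_duplicates,
      pct_complete_duplicates =
        res$reports$full_id$percent_complete_duplicates)
  })
  reps <- do.call(rbind, rows)
  metrics <- setdiff(names(reps), "replicate")
  summ <- do.call(rbind, lapply(metrics, function(m) data.frame(
    metric = m, mean = mean(reps[[m]]), sd = stats::sd(reps[[m]]),
    min = min(reps[[m]]), max = max(reps[[m]]))))
  structure(list(replicates = reps, summary = summ, cfg = cfg,
                 n_replicates = n_replicates),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte Carlo summary over %d replicates (seed %d):\n",
              x$n_replicates, x$cfg$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Inject transcription errors into finished codes
#'
#' Models the simple recording mistakes seen in hand-written codes (wrong
#' gender, wrong date): each ID is independently perturbed with probability
#' `rate` by one single-field mistake, drawn uniformly from a gender flip
#' (M to F or F to M; an unknown gender becomes a random letter) or a day
#' error (a different valid day of month).  Perturbed codes always remain
#' grammar-valid.
#'
#' @param ids Character vector of canonical or display codes.
#' @param rate Per-ID perturbation probability in `[0, 1]`.
#' @param seed Optional seed for reproducibility.
#' @return Character vector of canonical codes, same length and order.
#' @examples
#' inject_transcription_errors(c("DKS35010101010MK"), rate = 1, seed = 1)
#' @export
inject_transcription_errors <- function(ids, rate, seed = NULL) {
  if (rate < 0 || rate > 1) stop("`rate` must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  canon <- vapply(ids, .strip_hyphen, "", USE.NAMES = FALSE)
  hit <- stats::runif(length(canon)) < rate
  for (i in which(hit)) {
    s <- canon[i]
    kind <- sample(c("gender", "day"), 1L)
    if (kind == "gender") {
      g <- substr(s, 15L, 15L)
      new_g <- switch(g, M = "F", F = "M", sample(c("M", "F"), 1L))
      substr(s, 15L, 15L) <- new_g
    } else {
      day <- as.integer(substr(s, 8L, 9L))
      new_day <- sample(setdiff(1:31, day), 1L)
      s <- paste0(substr(s, 1L, 7L), sprintf("%02d", new_day),
                  substr(s, 10L, 16L))
    }
    canon[i] <- s
  }
  canon
}
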