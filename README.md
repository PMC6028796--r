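# mciid

Low-tech identification codes for mass-casualty triage: a fixed-width codec,
duplication-risk analytics, and a seeded desk-study simulator.

## The problem

During a mass casualty incident, first responders must label every casualty
at first contact — by hand, on a paper triage tag, often without knowing the
casualty's name, age or gender. `mciid` implements a 16-character
alphanumeric coding scheme designed for exactly that setting, and the
statistics needed to ask the question that matters about any such scheme:
*how often do two independently created codes collide?*

The code is the concatenation of a responder block and a casualty block,
displayed with a hyphen between them:

```
DKS3501-0101010MK
│││││││ │││││││││
│││││││ ││││││└┴┴─ casualty: age decade, gender (M/F/u), name initial (A-Z/u)
│││││││ └┴┴┴┴┴──── time of triage: day, hour, minute (two digits each)
││││└┴┴─────────── serial triage number, wrapping: 01, ..., 99, 00, 01, ...
│││└┴───────────── responder age (two digits, mod 100)
│└┴─────────────── responder initials (family, given)
└───────────────── job: D doctor, N nurse, P paramedic, V volunteer
```

Anything unknowable about the casualty is written as lowercase `u`, so a
valid code can always be completed in seconds. Collision risk is analysed
two ways: analytically, as a structured birthday problem — for $n$ items
drawn independently with per-field category probabilities $p_{fi}$, the
expected number of pairs matching on field set $F$ is
$\binom{n}{2}\prod_{f\in F}\sum_i p_{fi}^2$ — and by Monte Carlo simulation
of a full desk exercise (a synthetic responder roster triaging a fixed list
of ten virtual casualties, everyone in the same order within a 20-minute
window).

Intended users: disaster-medicine and health-information researchers
evaluating identifier schemes, and developers of triage-tag tooling.

## Worked example

```r
library(mciid)

r   <- responder_profile("D", "K", "S", 35)          # doctor K.S., age 35
cas <- casualty_record(day = 1, hour = 1, minute = 1,
                       age = 5, gender = "M", name_initial = "K")
encode_id(r, cas)
#> DKS3501-0101010MK

decode_id("DKS3501-0101010MK")
#> ID DKS35010101010MK
#>   responder: job D, initials KS, age 35, serial 01
#>   casualty:  day 01 01:01, decade 0, gender M, initial K
```

The serial field wraps at 100 (`encode_responder_block(responder_profile("D",
"K", "S", 35, 100))` gives `"DKS3500"`), and the casualty age decade follows
the published rules: a 5-year-old encodes `0`, a 65-year-old `6`, a
93-year-old `9`.

A full simulated desk study under the default scenario — 89 responders with
job counts D 29 / N 15 / P 19 / V 26, ages 22–24, skewed name-initial
frequencies, the packaged ten-casualty list:

```r
cfg <- scenario_config(seed = 42)
res <- run_desk_study(generate_roster(cfg), cfg)
res
#> Desk-study replicate: 89 responders x 10 casualties = 890 IDs
#>   complete ID duplicates: 8 (0.9%); unique: 882 (99.1%)
#>   initials           48/89 duplicated (53.9%)
#>   initials_age       21/89 duplicated (23.6%)
#>   initials_age_job   8/89 duplicated (9.0%)
```

Reading the numbers: over half the roster shares two-letter initials with
someone else, adding the responder's age cuts that to a quarter, adding the
job category cuts it again, and of 890 complete codes fewer than one percent
collide — the casualty block (minute of triage, casualty details) resolves
almost everything the responder block leaves ambiguous.
`monte_carlo(cfg, n_replicates)` aggregates these percentages over
replicates; `explain_nonduplication(a, b)` names the fields that kept two
codes apart.

A command-line interface is installed at `exec/mciid` inside the package
library, with subcommands `encode`, `decode`, `validate`, `stats` and
`simulate`:

```sh
Rscript "$(Rscript -e 'cat(find.package("mciid"))')/exec/mciid" \
  decode DKS3501-0101010MK
```

## Package layout

- `R/idcode.R` — types, encoder, decoder, validator (the positional grammar)
- `R/dup_stats.R` — duplication reports, half-up rounding, collision model
- `R/sim.R` — scenario configuration, roster generator, desk-study runner,
  Monte Carlo, error injection
- `R/io.R`, `R/cli.R`, `exec/mciid` — file formats and the CLI
- `inst/extdata/virtual_casualties.csv` — the fixed ten-casualty list
- `vignettes/casualty-id-coding.Rmd` — the methods vignette
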