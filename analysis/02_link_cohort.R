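#!/usr/bin/env Rscript
# Stage 2: link claims into episodes of care, select the obstetric cohort
# (women 10-49, discharged alive or dead), and confirm deaths against the
# registry. Writes the cohort episode table (diagnoses semicolon-joined)
# and the stage counts.

suppressMessages(library(morbrules))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- match(flag, args); if (!is.na(i)) args[i + 1L] else default
}
dir <- arg("--dir", "results/analysis")

claims <- read_claims(file.path(dir, "claims.csv"))
linked <- link_episodes(claims)
eps <- episodes(linked)
cohort <- select_cohort(eps)
registry <- read_death_registry(file.path(dir, "death_registry.csv"))
cohort <- confirm_deaths(cohort, registry)

flat <- cohort
flat$diagnoses <- vapply(flat$diagnoses, paste, character(1), collapse = ";")
flat$procedures <- vapply(flat$procedures, paste, character(1), collapse = ";")
readr::write_csv(flat, file.path(dir, "cohort_episodes.csv"))

counts <- c(attr(linked, "linkage_log"),
            attr(cohort, "confirm_log"),
            list(cohort_episodes = nrow(cohort),
                 cohort_deaths = sum(cohort$outcome == "in_hospital_death")))
jsonlite::write_json(counts, file.path(dir, "stage_counts.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("%d claims -> %d episodes (%.1f%% single-claim)\n",
            nrow(claims), nrow(eps), 100 * mean(eps$n_claims == 1)))
cat(sprintf("cohort: %d episodes, %d confirmed deaths (%d removed unconfirmed)\n",
            nrow(cohort), counts$cohort_deaths, counts$removed_unconfirmed))
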