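#!/usr/bin/env Rscript
# Stage 5: produce the death-profile and combination tables from the
# filtered rules, at the conventional reporting precision.

suppressMessages(library(morbrules))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- match(flag, args); if (!is.na(i)) args[i + 1L] else default
}
dir <- arg("--dir", "results/analysis")

tx <- readr::read_csv(file.path(dir, "transactions.csv"),
                      show_col_types = FALSE)
tx$items <- strsplit(tx$items, ";", fixed = TRUE)
db <- transaction_db(tx)

rules <- readr::read_csv(file.path(dir, "rules.csv"), show_col_types = FALSE)
rules$antecedent <- strsplit(rules$antecedent, ";", fixed = TRUE)

profile <- death_profile_table(rules, db)
combos <- combination_table(rules)
profile_fmt <- profile
if (nrow(profile_fmt)) {
  profile_fmt$support <- sprintf("%.2E", as.numeric(profile_fmt$support))
  profile_fmt$confidence <- round(profile_fmt$confidence, 3)
  profile_fmt$lift <- round(profile_fmt$lift, 3)
}
readr::write_csv(profile_fmt, file.path(dir, "death_profile.csv"), na = "")
readr::write_csv(combos, file.path(dir, "combinations.csv"), na = "")

s <- attr(profile, "summary")
cat(sprintf("episodes: %d; deaths: %d (%.2f%%)\n",
            s$n_episodes, s$n_deaths, s$death_pct))
cat(sprintf("single-antecedent death rules: %d; combinations: %d\n",
            nrow(profile), nrow(combos)))
if (nrow(profile)) print(as.data.frame(profile_fmt), row.names = FALSE)
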