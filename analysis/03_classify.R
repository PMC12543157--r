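#!/usr/bin/env Rscript
# Stage 3: classify every diagnosis of every cohort episode into the
# WHO-adapted morbidity groups and build the transaction table (one
# deduplicated item set per episode plus its outcome item).

suppressMessages(library(morbrules))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- match(flag, args); if (!is.na(i)) args[i + 1L] else default
}
dir <- arg("--dir", "results/analysis")

flat <- readr::read_csv(file.path(dir, "cohort_episodes.csv"),
                        show_col_types = FALSE)
flat$diagnoses <- strsplit(flat$diagnoses, ";", fixed = TRUE)
tx <- episodes_to_transactions(flat)

out <- tibble::tibble(
  episode_id = tx$episode_id,
  items = vapply(tx$items, paste, character(1), collapse = ";"),
  outcome_item = tx$outcome_item)
readr::write_csv(out, file.path(dir, "transactions.csv"))

freq <- sort(table(unlist(tx$items)), decreasing = TRUE)
readr::write_csv(tibble::tibble(item = names(freq), episodes = as.integer(freq)),
                 file.path(dir, "item_frequencies.csv"))

cat(sprintf("%d transactions over %d distinct items\n",
            nrow(tx), length(freq)))
print(head(freq))
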