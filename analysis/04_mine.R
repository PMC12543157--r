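#!/usr/bin/env Rscript
# Stage 4: mine association rules linking morbidity-group profiles to the
# discharge outcome, then apply the selection filters (lift >= 1.1,
# redundancy, count >= 4, childbirth excluded from antecedents).

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

cfg <- mining_config()
fi <- frequent_itemsets(db, cfg$min_support)
rules_all <- generate_rules(fi, db, cfg)
rules <- filter_rules(rules_all, cfg)

write_rules(rules_all, file.path(dir, "rules_all.csv"), formatted = FALSE)
write_rules(rules, file.path(dir, "rules.csv"))
jsonlite::write_json(c(list(frequent_itemsets = nrow(fi),
                            rules_generated = nrow(rules_all)),
                       attr(rules, "filter_log"),
                       list(rules_kept = nrow(rules))),
                     file.path(dir, "mining_log.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("%d frequent itemsets -> %d rules -> %d kept after filters\n",
            nrow(fi), nrow(rules_all), nrow(rules)))
print(unlist(attr(rules, "filter_log")))
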