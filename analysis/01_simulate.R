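#!/usr/bin/env Rscript
# Stage 1: generate a synthetic obstetric claims stream emulating the
# surveillance setting (one episode per patient, ~98.9% single-claim
# episodes) with planted death relative risks shaped like the group-level
# risk profile observed in hospital-claims surveillance: direct obstetric
# complications at moderate risk, non-obstetric complications and unknown/
# external causes at high risk. The run is a scaled-down emulation: 200,000
# episodes with the per-episode death probability raised tenfold (3e-3) so
# that planted associations are measurable with a few hundred deaths
# instead of the millions of episodes of a full national extract. A death
# registry at 95% coverage accompanies the claims.

suppressMessages(library(morbrules))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- match(flag, args); if (!is.na(i)) args[i + 1L] else default
}
n <- as.integer(arg("--n", "200000"))
seed <- as.integer(arg("--seed", "20140101"))
out_dir <- arg("--out", "results/analysis")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

planted_risks <- c(
  "1b" = 3.0, "2a" = 4.4, "2b" = 4.2, "3" = 4.2, "4a" = 7.5, "4b" = 6.3,
  "5" = 5.8, "7b" = 1.3, "8a" = 73, "8b" = 51, "8c" = 47, "8d" = 9.2,
  "8e" = 10, "9" = 200, "12" = 20, "13" = 2.6)

cfg <- simulation_config(n_patients = n, baseline_death_prob = 3e-3,
                         death_relative_risks = planted_risks, seed = seed)
claims <- generate_claims(cfg)
registry <- generate_death_registry(claims, coverage = 0.95, seed = seed + 1L)

write_claims(claims, file.path(out_dir, "claims.csv"))
write_death_registry(registry, file.path(out_dir, "death_registry.csv"))

cat(sprintf("simulated %d patients -> %d claims (%d death discharges)\n",
            n, nrow(claims),
            sum(claims$discharge_reason == "in_hospital_death")))
cat(sprintf("death registry: %d entries (coverage 0.95)\n", nrow(registry)))
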