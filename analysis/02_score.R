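#!/usr/bin/env Rscript
# Stage 2 — quality control and anchor-based scoring.
#
# Reads the term records written by stage 1, sanitizes them (dedup within
# person, junk-token removal), scores every retained term against each
# facet's anchor set by mean cosine similarity, aggregates to person-by-facet
# composites, and standardizes each facet across persons. Writes the
# composites in wide and long form plus the QC report.

suppressPackageStartupMessages(library(semanchor))

seed <- 20260923L
cfg <- sim_config(n_persons = 176, seed = seed)
cohort <- simulate_cohort(cfg)          # re-derives the embedding space
records <- read_term_records("results/inputs/term_records.jsonl")
lexicon <- read_anchor_lexicon("results/inputs/anchor_lexicon.json")

san <- sanitize_terms(records)
cm <- build_composites(san$records, lexicon, cohort$embedding)
coherence <- semantic_coherence(san$records, cohort$embedding)

dir.create("results", showWarnings = FALSE)
write_scores_wide(cm$Z, "results/dm_composites_wide.csv")
write_composites_long(cm, "results/dm_composites_long.csv")
jsonlite::write_json(unclass(san$qc), "results/qc_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("scored %d persons x %d facets (excluded: %d)\n",
            length(cm$pids), length(cm$facets), length(cm$excluded)))
cat(sprintf("retention rate: %.1f%%\n", 100 * san$qc$retention_rate))
cat(sprintf("raw composite range: [%.3f, %.3f]\n", min(cm$X), max(cm$X)))
cat(sprintf("mean within-person semantic coherence: %.3f\n",
            mean(coherence, na.rm = TRUE)))
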