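#!/usr/bin/env Rscript

# Stage 5: pathway enrichment.  Pools the target genes of the discovery
# trauma-modifier hits (synthetic miRDB-style table, binding score >= 80)
# and tests every pathway for over-representation with an upper-tail
# hypergeometric test, BH-adjusted across pathways (significant at
# adjusted p < 0.1).

suppressMessages(library(mirmod))

truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)
counts2 <- read_expression("results/data/counts_wave2.tsv")

# synthetic target/pathway resources: targets of the true modifiers
# concentrate in the gene block that forms pathway_01
td <- gen_target_data(rownames(counts2),
                      signal_mirnas = truth$modifier_ids, seed = 1L)
write.table(td$targets, "results/data/targets_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(td$gmt_lines, "results/data/pathways_synthetic.gmt")

targets <- read_target_table("results/data/targets_synthetic.tsv",
                             score_cutoff = 80)
sets <- read_gmt("results/data/pathways_synthetic.gmt")

disc <- read_screen_records("results/screen_discovery_trauma_lifetime.tsv")
hits <- significant_hits(disc)$mirna_id
usable <- intersect(hits, unique(targets$mirna))
message(sprintf("%d of %d hit miRNAs have binding-score-filtered targets",
                length(usable), length(hits)))

tab <- enrich_all(usable, targets, sets, fdr_threshold = 0.1)
write.table(tab, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("%d of %d pathways significant at adjusted p < 0.1",
                sum(tab$significant), nrow(tab)))
print(head(tab[, c("pathway_id", "overlap", "K", "n", "N", "p", "q",
                   "significant")], 5), row.names = FALSE)
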