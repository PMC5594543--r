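#!/usr/bin/env Rscript

# Stage 5 — miRNA-target / disease-gene network integration.
#
# Runs on the packaged synthetic fixture tables (inst/extdata), which
# mirror the structure of miRWalk-style prediction exports, DisGeNET-style
# curated disease-gene tables, and a KEGG-style pathway gene list: bona
# fide target calling (>= 2 of 6 algorithms), per-disease one-sided Fisher
# enrichment with BH FDR, hub genes (>= 4 diseases), and the coagulation
# pathway overlay for the mediator miRNAs.
#
# Writes results/network/{enrichment,hubs,overlay}.csv and edges.tsv.

suppressPackageStartupMessages(library(evmir))

out_dir <- "results/network"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ext <- function(f) system.file("extdata", f, package = "evmir")
preds <- utils::read.delim(ext("synthetic_target_predictions.tsv"),
                           stringsAsFactors = FALSE)
dtab <- utils::read.delim(ext("synthetic_disease_genes.tsv"),
                          stringsAsFactors = FALSE)
pathway <- readLines(ext("synthetic_coagulation_genes.txt"))

targets <- bona_fide_targets(preds, min_algorithms = 2)
sets <- disease_gene_sets(dtab, min_genes = 20)
cat(sprintf("bona fide edges: %d miRNAs, %d target genes; %d curated diseases\n",
            length(targets), length(unique(unlist(targets))), length(sets)))

enr <- disease_enrichment(targets, sets)
utils::write.csv(enr, file.path(out_dir, "enrichment.csv"), row.names = FALSE)
cat(sprintf("enrichment: %d of %d (miRNA, disease) tests at FDR < 0.1\n",
            sum(enr$enriched), nrow(enr)))

hubs <- hub_genes(targets, sets, min_diseases = 4)
utils::write.csv(hubs, file.path(out_dir, "hubs.csv"), row.names = FALSE)
cat("top hub genes:\n")
print(utils::head(hubs, 5), row.names = FALSE)

mediators <- intersect(c("miR-01", "miR-02", "miR-03", "miR-04", "miR-05"),
                       names(targets))
ov <- pathway_overlay(targets[mediators], pathway)
utils::write.csv(ov$per_gene, file.path(out_dir, "overlay.csv"),
                 row.names = FALSE)
cat(sprintf("coagulation overlay: %d of %d pathway genes targeted by the mediator miRNAs\n",
            ov$n_covered, ov$n_pathway))

edges <- do.call(rbind, lapply(names(targets), function(mi)
  data.frame(mirna = mi, gene = targets[[mi]], stringsAsFactors = FALSE)))
utils::write.table(edges, file.path(out_dir, "edges.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("wrote", out_dir, "\n")
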