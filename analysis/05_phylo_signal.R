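#!/usr/bin/env Rscript
# Phylogenetic signal (Pagel's lambda, Blomberg's K) in the curated log
# accumulation rate and every comparative trait.

library(accumrate)

sp <- read.csv("results/tables/curated_species_rates.csv")
traits <- load_trait_table("results/data/synthetic_species_traits.csv")
tree <- ape::read.tree("results/data/synthetic_tree.nwk")

df <- merge(sp[, c("species", "log_rate")],
            traits[, c("species", "genome_size", "gc", "pin_pis", "lab_dt")],
            by = "species")
df$log_pin_pis <- log10(df$pin_pis)
df$log_lab_dt <- log10(df$lab_dt)
sig <- signal_table(tree,
                    df[, c("species", "log_rate", "genome_size", "gc",
                           "log_pin_pis", "log_lab_dt")],
                    n_perm = 999L, seed = 20240105L)
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.csv(sig, "results/tables/phylogenetic_signal.csv", row.names = FALSE)
print(sig, digits = 3)
cat("Traits were simulated with full Brownian signal (lambda = 1);\n",
    "estimates near 1 with small p-values confirm the pipeline detects it.\n")
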