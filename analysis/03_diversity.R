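#!/usr/bin/env Rscript
# piN/piS from the simulated codon alignment: the Nei-Gojobori estimate of
# the effectiveness of purifying selection, checked against the omega the
# generator injected (0.3).

library(accumrate)

aln <- load_codon_alignment("results/data/codon_alignment.fasta")
res <- pi_n_pi_s(aln)
print(res)
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.csv(data.frame(pi_n = res$pi_n, pi_s = res$pi_s, ratio = res$ratio,
                     n_pairs = res$n_pairs),
          "results/tables/diversity.csv", row.names = FALSE)
cat(sprintf("Estimated piN/piS = %.3f against an injected omega of 0.3\n",
            res$ratio))
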