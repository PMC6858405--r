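#!/usr/bin/env Rscript
# The population-genetic model: how much purifying selection under a gamma
# DFE depresses the accumulation rate as a function of sampling time.
# Produces the two standard curve families: shape varied at mean Ns = 100,
# and mean Ns varied at shape = 0.5; each over 0-4N generations with
# N = 100 chromosomes, and over the first 0.1N generations with N = 1000
# for fine resolution at short times.

library(accumrate)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
seed <- 20240104L

grid_coarse <- expand.grid(shape = c(0.25, 0.50, 0.75), mean_Ns = 100)
grid_coarse <- rbind(grid_coarse,
                     expand.grid(shape = 0.5, mean_Ns = c(10, 1000)))

times_for <- function(N, span) unique(pmax(1, round(exp(
  seq(log(1), log(span * N), length.out = 15)))))

run_grid <- function(N, span, grid) {
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cv <- suppressWarnings(
      dfe_relative_rate(N, grid$shape[i], grid$mean_Ns[i],
                        times_for(N, span), n_samples = 100, seed = seed))
    cbind(N = N, shape = grid$shape[i], mean_Ns = grid$mean_Ns[i],
          as.data.frame(cv))
  }))
}

coarse <- run_grid(100, 4, grid_coarse)
write.csv(coarse, "results/tables/wf_curves_4N.csv", row.names = FALSE)
cat("Wrote 0-4N curves (N = 100).\n")

fine <- run_grid(1000, 0.1, grid_coarse)
write.csv(fine, "results/tables/wf_curves_0.1N.csv", row.names = FALSE)
cat("Wrote 0-0.1N curves (N = 1000).\n")

at <- function(df, sh, m) {
  sub <- df[df$shape == sh & df$mean_Ns == m, ]
  sub$A[which.max(sub$t)]
}
cat(sprintf("At 4N generations, A = %.3f / %.3f / %.3f for shape 0.25/0.50/0.75 (mean Ns = 100)\n",
            at(coarse, 0.25, 100), at(coarse, 0.5, 100), at(coarse, 0.75, 100)))
cat(sprintf("and A = %.3f / %.3f / %.3f for mean Ns 10/100/1000 (shape = 0.5).\n",
            at(coarse, 0.5, 10), at(coarse, 0.5, 100), at(coarse, 0.5, 1000)))
cat("Within the first 0.1N generations the curves barely separate,\n",
    "which is why a sampling-time effect is hard to detect empirically.\n")
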