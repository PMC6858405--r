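# Shared fixtures and independent oracles used across test files.

# A small random ultrametric tree with unit depth.
random_unit_tree <- function(n_tips, seed) {
  tr <- simulate_tree(n_tips, birth_rate = 1, seed = seed)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

# Independent GLS oracle: slope of y on x with intercept under Brownian tip
# covariance C, by direct generalized least squares (matrix algebra only,
# no contrasts).
gls_slope <- function(tree, x, y) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]; y <- y[rownames(C)]
  W <- solve(C)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  unname(beta[2, 1])
}

# Brownian tip values named by tip label (ape's simulator as the
# independent trait generator).
bm_trait <- function(tree, sigma = 1) {
  stats::setNames(ape::rTraitCont(tree, model = "BM", sigma = sigma),
                  tree$tip.label)
}

# Tiny valid rate-estimate table exercising all three curation rules.
toy_rate_table <- function() {
  data.frame(
    species = c("A", "A", "B", "C", "D"),
    rate = c(1e-6, 3e-6, 2e-6, 5e-7, 8e-6),
    sampling_time = c(10, 100, 2000, 50, 30),
    site_class = c("all", "all", "all", "synonymous", "all"),
    hypermutator = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    study = paste0("s", 1:5)
  )
}
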