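test_that("Yule trees are ultrametric, seeded and of the right size", {
  tr <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(tr), 2)
  tr1 <- simulate_tree(20, seed = 5)
  tr2 <- simulate_tree(20, seed = 5)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  expect_true(ape::is.ultrametric(tr1, tol = 1e-8))
  # expected depth grows roughly as log(n)/birth
  depths <- vapply(1:200, function(s)
    max(ape::node.depth.edgelength(simulate_tree(40, birth_rate = 2, seed = s))),
    numeric(1))
  # E[depth] = (1/b) * sum_{k=2..n} 1/k
  expect_equal(mean(depths), sum(1 / (2:40)) / 2, tolerance = 0.1)
})

test_that("simulated traits hit their target correlations and signal", {
  tr <- random_unit_tree(200, seed = 2)
  R <- diag(2); R[1, 2] <- R[2, 1] <- 0.7
  dimnames(R) <- list(c("u", "v"), c("u", "v"))
  td <- simulate_traits(tr, lambda = 1, correlation_matrix = R, seed = 3)
  expect_lt(abs(cor(td$u, td$v) - 0.7), 0.15)
  # lambda = 1, identity matrix: independent BM traits with strong signal
  td2 <- simulate_traits(tr, lambda = 1, correlation_matrix = diag(2), seed = 4)
  expect_gt(pagel_lambda(tr, stats::setNames(td2[[1]], rownames(td2)))$lambda, 0.8)
  # lambda = 0: tip values carry no phylogenetic signal
  td0 <- simulate_traits(tr, lambda = 0, correlation_matrix = diag(2), seed = 5)
  expect_lt(pagel_lambda(tr, stats::setNames(td0[[1]], rownames(td0)))$lambda, 0.3)
  expect_error(simulate_traits(tr, 1, 1, matrix(c(1, 2, 2, 1), 2)), "definite")
})

test_that("rate-estimate simulation injects and omits sampling-time effects", {
  sp <- data.frame(species = sprintf("s%02d", 1:20),
                   log_rate = rnorm(20, -6, 0.5))
  # zero noise, zero slope: every estimate equals the species rate
  est0 <- simulate_rate_estimates(sp, rate_noise_sd = 0, seed = 1)
  expect_equal(log10(est0$rate),
               sp$log_rate[match(est0$species, sp$species)])
  # k = 1 everywhere: averaging is the identity
  est1 <- simulate_rate_estimates(sp, estimates_per_species = c(1L, 1L),
                                  rate_noise_sd = 0, seed = 2)
  expect_equal(nrow(est1), 20)
  expect_equal(average_by_species(est1)$mean_rate, est1$rate)
  # injected slope is recovered by the ANCOVA
  est2 <- simulate_rate_estimates(sp, estimates_per_species = c(3L, 5L),
                                  rate_noise_sd = 0.1,
                                  time_effect_slope = -0.5, seed = 3)
  est2$log_rate <- log10(est2$rate)
  est2$log_time <- log10(est2$sampling_time)
  fit <- ancova_common_slope(est2, "log_rate", "log_time", "species")
  expect_equal(fit$common_slope, -0.5, tolerance = 0.1)
  # flagged rows violate exactly the curation rules
  est3 <- simulate_rate_estimates(sp, n_flagged = 10, seed = 4)
  flt <- filter_estimates(est3)
  expect_equal(nrow(flt$audit), 10)
})

test_that("codon alignment simulation controls the piN/piS ground truth", {
  # omega = 0: no nonsynonymous variation at all
  a0 <- simulate_codon_alignment(6, 200, 0.05, 0, seed = 1)
  expect_equal(pi_n_pi_s(a0)$pi_n, 0)
  # theta = 0: identical sequences
  a1 <- simulate_codon_alignment(4, 50, 0, 1, seed = 2)
  expect_equal(length(unique(a1)), 1L)
  # omega = 1: ratio near 1 on a long alignment
  a2 <- simulate_codon_alignment(8, 5000, 0.02, 1, seed = 3)
  expect_equal(pi_n_pi_s(a2)$ratio, 1, tolerance = 0.2)
})

test_that("the full synthetic bundle is reproducible and writable", {
  ds1 <- synthetic_dataset(n_species = 12, seed = 7)
  ds2 <- synthetic_dataset(n_species = 12, seed = 7)
  expect_identical(ds1$traits, ds2$traits)
  expect_identical(ds1$estimates, ds2$estimates)
  d <- withr::local_tempdir()
  paths <- write_synthetic_dataset(ds1, d)
  expect_true(all(file.exists(unlist(paths))))
  back <- load_rate_table(paths$rates)
  expect_equal(nrow(back), nrow(ds1$estimates))
})

test_that("the pipeline recovers a known trait-rate correlation end to end", {
  tr <- random_unit_tree(100, seed = 21)
  R <- diag(2); R[1, 2] <- R[2, 1] <- -0.6
  dimnames(R) <- list(c("log_rate", "gc"), c("log_rate", "gc"))
  std <- simulate_traits(tr, lambda = 1, correlation_matrix = R, seed = 22)
  traits <- data.frame(species = rownames(std),
                       log_rate = -6 + 0.8 * std$log_rate,
                       gc = 45 + 10 * std$gc)
  est <- simulate_rate_estimates(traits, rate_noise_sd = 0.15, seed = 23)
  avg <- average_by_species(filter_estimates(est)$estimates)
  avg$log_rate <- log_transform(avg$mean_rate)
  m <- merge(avg, traits[, c("species", "gc")], by = "species")
  expect_equal(pearson(m$gc, m$log_rate)$r, -0.6, tolerance = 0.15)
})
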