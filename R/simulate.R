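# Default target correlation structure among the comparative variables
# (log10 accumulation rate, genome size, GC%, log10 piN/piS, log10 lab
# doubling time, log10 mutation rate per generation). Magnitudes follow the
# correlations the comparative analysis is designed to detect.
.default_trait_correlations <- function() {
  vars <- c("log_rate", "genome_size", "gc", "log_pin_pis", "log_lab_dt", "log_mu")
  R <- diag(6)
  dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set_r("log_rate", "genome_size", -0.45)
  set_r("log_rate", "gc", -0.50)
  set_r("log_rate", "log_pin_pis", -0.35)
  set_r("log_rate", "log_lab_dt", -0.30)
  set_r("log_rate", "log_mu", 0.10)
  set_r("genome_size", "gc", 0.50)
  set_r("genome_size", "log_pin_pis", 0.10)
  set_r("genome_size", "log_lab_dt", -0.20)
  set_r("genome_size", "log_mu", -0.68)
  set_r("gc", "log_pin_pis", 0.47)
  set_r("gc", "log_lab_dt", -0.10)
  set_r("gc", "log_mu", -0.50)
  set_r("log_pin_pis", "log_lab_dt", 0.10)
  R
}

#' Simulate a Yule (pure-birth) phylogeny
#'
#' Wraps `ape::rphylo` with `death = 0`, giving an ultrametric tree of
#' extant tips, reproducible by seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per unit time.
#' @param seed RNG seed.
#' @return A `phylo` object with tip labels `sp01, sp02, ...`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tr
}

#' Simulate correlated traits with controlled phylogenetic signal
#'
#' Draws a matrix of tip values whose among-tip covariance is the
#' lambda-transformed Brownian covariance of the tree (`sigma2` scales the
#' Brownian rate) and whose among-trait correlation is `correlation_matrix`.
#' With `lambda = 1` this is plain correlated Brownian motion; with
#' `lambda = 0` tip values are independent of the phylogeny.
#'
#' @param tree A `phylo` tree.
#' @param lambda Phylogenetic signal in `[0, 1]`.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param correlation_matrix Symmetric PSD matrix with unit diagonal; its
#'   column names name the traits (default: the package's comparative set).
#' @param seed RNG seed.
#' @return Data.frame of standardized trait values, rownames = tip labels.
#' @export
simulate_traits <- function(tree, lambda = 1, sigma2 = 1,
                            correlation_matrix = .default_trait_correlations(),
                            seed = 1L) {
  stopifnot(lambda >= 0, lambda <= 1, sigma2 > 0)
  R <- as.matrix(correlation_matrix)
  if (!isSymmetric(unname(R))) stop("correlation matrix must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  C <- sigma2 * .lambda_vcv(ape::vcv(tree), lambda)
  n <- nrow(C); p <- ncol(R)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * p), n, p)
  # ridge for exactly-singular R (e.g. duplicated target traits)
  Rc <- chol(R + diag(1e-10, p))
  X <- t(chol(C)) %*% Z %*% Rc
  out <- as.data.frame(X)
  names(out) <- if (is.null(colnames(R))) paste0("trait", seq_len(p))
                else colnames(R)
  rownames(out) <- rownames(C)
  out
}

#' Build a species trait table on realistic scales
#'
#' Takes standardized simulated traits and maps them onto the scales of the
#' real comparative variables: accumulation rates around 1e-6 per site per
#' year, genome sizes of a few Mb, GC between ~25 and ~70%, piN/piS around
#' 0.1, lab doubling times of around an hour, mutation rates around 1e-10
#' per site per generation. Adds lifestyle labels (obligate/opportunistic,
#' no injected rate effect), rrn operon copies and tRNA counts.
#'
#' @param std Data.frame from [simulate_traits()] using the default
#'   correlation set.
#' @param seed RNG seed for the categorical/count columns.
#' @return Data.frame with columns `species`, `log_rate`, `genome_size`,
#'   `gc`, `pin_pis`, `lab_dt`, `mutation_rate`, `rrn_copies`,
#'   `trna_count`, `lifestyle`.
#' @export
scale_species_traits <- function(std, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(std)
  data.frame(
    species = rownames(std),
    log_rate = -6 + 0.8 * std$log_rate,
    genome_size = pmax(0.5, 3.5 + 1.2 * std$genome_size),
    gc = pmin(75, pmax(20, 45 + 10 * std$gc)),
    pin_pis = 10^(-1 + 0.3 * std$log_pin_pis),
    lab_dt = 10^(0.2 + 0.4 * std$log_lab_dt),
    mutation_rate = 10^(-10 + 0.5 * std$log_mu),
    rrn_copies = 1L + stats::rpois(n, 3),
    trna_count = pmax(30L, as.integer(round(stats::rnorm(n, 55, 10)))),
    lifestyle = sample(c("obligate", "opportunistic"), n, replace = TRUE),
    row.names = NULL
  )
}

#' Simulate a literature-style rate-estimate table
#'
#' For each species draws a number of replicate estimates spread over
#' sampling times, with log10 rate = species log10 rate +
#' `time_effect_slope * log10(sampling time)` + noise. A sampling-time
#' effect can thus be injected (negative slope) or omitted (0, the
#' default). Optional flagged rows (too-long timeframe, synonymous-only,
#' hypermutator) exercise the curation rules.
#'
#' @param species_traits Data.frame with `species` and `log_rate` columns.
#' @param estimates_per_species Integer range `c(min, max)` of estimates
#'   drawn per species (default 1-4).
#' @param sampling_time_range Years, `c(min, max)`; times are drawn
#'   log-uniformly (default 1-1500).
#' @param rate_noise_sd Estimate noise in log10 units (default 0.3).
#' @param time_effect_slope Injected within-species slope of log10 rate on
#'   log10 sampling time (default 0).
#' @param n_flagged Number of extra rows that violate one curation rule
#'   each (default 0).
#' @param seed RNG seed.
#' @return Data.frame in the rate-table layout of [load_rate_table()].
#' @export
simulate_rate_estimates <- function(species_traits,
                                    estimates_per_species = c(1L, 4L),
                                    sampling_time_range = c(1, 1500),
                                    rate_noise_sd = 0.3,
                                    time_effect_slope = 0,
                                    n_flagged = 0L,
                                    seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lo <- log10(sampling_time_range[1]); hi <- log10(sampling_time_range[2])
  rows <- lapply(seq_len(nrow(species_traits)), function(ii) {
    sp <- species_traits$species[ii]
    k <- sample(estimates_per_species[1]:estimates_per_species[2], 1L)
    st <- 10^stats::runif(k, lo, hi)
    lr <- species_traits$log_rate[ii] + time_effect_slope * log10(st) +
      stats::rnorm(k, 0, rate_noise_sd)
    data.frame(species = sp, rate = 10^lr, sampling_time = st,
               site_class = "all", hypermutator = FALSE,
               study = paste0(sp, "_study", seq_len(k)))
  })
  out <- do.call(rbind, rows)
  if (n_flagged > 0) {
    idx <- sample(nrow(out), n_flagged, replace = TRUE)
    flagged <- out[idx, ]
    why <- sample(c("time", "syn", "hyper"), n_flagged, replace = TRUE)
    flagged$sampling_time[why == "time"] <- 10^stats::runif(sum(why == "time"),
                                                            log10(1600), 4)
    flagged$site_class[why == "syn"] <- "synonymous"
    flagged$hypermutator[why == "hyper"] <- TRUE
    flagged$study <- paste0(flagged$study, "_flagged")
    out <- rbind(out, flagged)
  }
  rownames(out) <- NULL
  out
}

#' Simulate a toy codon alignment with controlled diversity
#'
#' Builds a random ancestral coding sequence and sprinkles biallelic
#' variant columns onto the sequences: synonymous variants arise at rate
#' `theta_syn` per synonymous site and nonsynonymous variants at
#' `omega * theta_syn` per nonsynonymous site, each variant carried by a
#' sequence with probability 1/2. The expected piN/piS of the alignment is
#' therefore `omega` (and piS itself about `theta_syn / 2`).
#'
#' @param n_seqs Number of sequences (>= 2).
#' @param n_codons Codons per sequence (>= 10).
#' @param theta_syn Synonymous variant rate per synonymous site.
#' @param omega Ratio of nonsynonymous to synonymous variant rates.
#' @param seed RNG seed.
#' @return Named character vector of aligned sequences.
#' @export
simulate_codon_alignment <- function(n_seqs, n_codons, theta_syn, omega,
                                     seed = 1L) {
  stopifnot(n_seqs >= 2, n_codons >= 10, theta_syn >= 0, omega >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tab <- .codon_table()
  sense <- names(tab)[tab != "*"]
  anc <- sample(sense, n_codons, replace = TRUE)

  single_mutants <- function(codon) {
    ch <- strsplit(codon, "")[[1]]
    muts <- character(0)
    for (pos in 1:3) for (b in setdiff(c("T", "C", "A", "G"), ch[pos])) {
      m <- ch; m[pos] <- b
      muts <- c(muts, paste(m, collapse = ""))
    }
    muts
  }

  seqs <- matrix(rep(anc, n_seqs), nrow = n_codons)
  for (cc in seq_len(n_codons)) {
    st <- count_sites(anc[cc])
    p_s <- theta_syn * st["syn"]
    p_n <- omega * theta_syn * st["nonsyn"]
    tot <- p_s + p_n
    if (tot > 0.9) { p_s <- 0.9 * p_s / tot; p_n <- 0.9 * p_n / tot }
    u <- stats::runif(1)
    klass <- if (u < p_s) "syn" else if (u < p_s + p_n) "nonsyn" else next
    muts <- single_mutants(anc[cc])
    muts <- muts[tab[muts] != "*"]
    muts <- if (klass == "syn") muts[tab[muts] == tab[anc[cc]]]
            else muts[tab[muts] != tab[anc[cc]]]
    if (length(muts) == 0) next
    variant <- sample(muts, 1L)
    carriers <- stats::runif(n_seqs) < 0.5
    seqs[cc, carriers] <- variant
  }
  out <- apply(seqs, 2, paste, collapse = "")
  names(out) <- sprintf("seq%02d", seq_len(n_seqs))
  out
}

#' Generate a complete synthetic comparative dataset
#'
#' One call producing everything the pipeline consumes: a Yule tree, a
#' species trait table with the default correlation structure, and a
#' rate-estimate table — the synthetic stand-in for a literature-curated
#' comparative dataset.
#'
#' @param n_species Number of species (default 34, the size of a typical
#'   curated bacterial rate compilation).
#' @param trait_lambda Phylogenetic signal of the traits.
#' @param time_effect_slope Injected sampling-time effect (default 0).
#' @param rate_noise_sd Within-species estimate noise, log10 units.
#' @param estimates_per_species Range of estimates per species.
#' @param n_flagged Rows violating curation rules (default 3).
#' @param seed RNG seed; sub-seeds are derived deterministically.
#' @return List with `tree`, `traits`, `estimates`, and `spec` (the
#'   parameters used).
#' @export
synthetic_dataset <- function(n_species = 34L, trait_lambda = 1,
                              time_effect_slope = 0, rate_noise_sd = 0.3,
                              estimates_per_species = c(1L, 4L),
                              n_flagged = 3L, seed = 1L) {
  tree <- simulate_tree(n_species, birth_rate = 1, seed = seed)
  # rescale depth to 1 so trait variances are comparable across runs
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  std <- simulate_traits(tree, lambda = trait_lambda, seed = seed + 1L)
  traits <- scale_species_traits(std, seed = seed + 2L)
  est <- simulate_rate_estimates(traits,
                                 estimates_per_species = estimates_per_species,
                                 rate_noise_sd = rate_noise_sd,
                                 time_effect_slope = time_effect_slope,
                                 n_flagged = n_flagged,
                                 seed = seed + 3L)
  list(tree = tree, traits = traits, estimates = est,
       spec = list(n_species = n_species, trait_lambda = trait_lambda,
                   time_effect_slope = time_effect_slope,
                   rate_noise_sd = rate_noise_sd, seed = seed))
}

#' Write a synthetic dataset to disk in the pipeline's file dialects
#'
#' @param ds A list from [synthetic_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`rates`, `traits`, `tree`).
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(rates = file.path(dir, "synthetic_rate_estimates.csv"),
                traits = file.path(dir, "synthetic_species_traits.csv"),
                tree = file.path(dir, "synthetic_tree.nwk"))
  utils::write.csv(ds$estimates, paths$rates, row.names = FALSE)
  utils::write.csv(ds$traits, paths$traits, row.names = FALSE)
  ape::write.tree(ds$tree, paths$tree)
  invisible(paths)
}
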