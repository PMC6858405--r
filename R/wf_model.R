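#' Allele frequency after one round of viability selection
#'
#' Deterministic change in the frequency of a deleterious mutant under
#' haploid viability selection: the wild type has fitness 1 and the mutant
#' fitness `1 - s`, so a mutant at frequency `f` moves to
#' `f' = (1 - s) f / (1 - s f)` before drift acts.
#'
#' @param f Mutant frequency, in `[0, 1]`. Vectorised.
#' @param s Selection coefficient, in `[0, 1)`; `s = 0` is neutral.
#' @return The post-selection frequency, same length as `f`.
#' @examples
#' selection_map(0.5, 0)    # neutral: unchanged
#' selection_map(0.5, 0.5)  # 1/3
#' @export
selection_map <- function(f, s) {
  if (length(s) != 1L || !is.finite(s) || s < 0 || s >= 1)
    stop("'s' must be a single value in [0, 1)")
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("'f' must lie in [0, 1]")
  (1 - s) * f / (1 - s * f)
}

#' Wright-Fisher transition probability with selection
#'
#' Probability of finding the mutation in `x` copies next generation given
#' `i` copies now, in a haploid population of `N` chromosomes: binomial
#' sampling around the post-selection frequency
#' `f' = selection_map(i / N, s)`.
#'
#' @param N Population size (chromosomes).
#' @param x Copy count next generation, `0..N`. Vectorised.
#' @param i Copy count this generation, `0..N`.
#' @param s Selection coefficient in `[0, 1)`.
#' @return Probability (vector over `x`); sums to 1 over `x = 0..N`.
#' @export
binomial_kernel <- function(N, x, i, s) {
  stopifnot(length(N) == 1L, length(i) == 1L, N >= 1)
  if (any(x < 0) || any(x > N) || i < 0 || i > N)
    stop("copy counts must lie in 0..N")
  stats::dbinom(x, size = N, prob = selection_map(i / N, s))
}

#' Build the (N+1) x (N+1) selection-drift transition matrix
#'
#' Column `i + 1` holds the distribution of next-generation copy counts
#' given `i` copies now. Loss (0 copies) and fixation (N copies) are
#' absorbing: their columns are unit vectors, so probability mass that has
#' been absorbed stays put and total probability is conserved.
#'
#' @param N Population size (chromosomes).
#' @param s Selection coefficient in `[0, 1)`.
#' @return A dense `(N+1) x (N+1)` column-stochastic matrix.
#' @export
wf_transition_matrix <- function(N, s) {
  fp <- selection_map((0:N) / N, s)
  M <- vapply(fp, function(p) stats::dbinom(0:N, N, p), numeric(N + 1L))
  # enforce absorption exactly (dbinom already gives unit vectors, but be
  # explicit about the boundary columns)
  M[, 1L] <- c(1, rep(0, N))
  M[, N + 1L] <- c(rep(0, N), 1)
  M
}

#' Construct a frequency spectrum
#'
#' A probability vector over copy counts `0..N`; index 1 is loss, index
#' `N + 1` fixation. A new mutation is a point mass at one copy.
#'
#' @param N Population size (chromosomes).
#' @param probs Optional probability vector of length `N + 1`; defaults to
#'   the new-mutation spectrum (mass 1 at one copy).
#' @return An object of class `frequency_spectrum`.
#' @export
frequency_spectrum <- function(N, probs = NULL) {
  stopifnot(N >= 1)
  if (is.null(probs)) {
    probs <- rep(0, N + 1L)
    probs[2L] <- 1
  }
  if (length(probs) != N + 1L) stop("'probs' must have length N + 1")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12)
    stop("'probs' must be non-negative and sum to 1 within 1e-12")
  structure(list(N = N, probs = probs), class = "frequency_spectrum")
}

#' @export
print.frequency_spectrum <- function(x, ...) {
  cat("Frequency spectrum, N =", x$N, "chromosomes\n")
  cat("  P(lost)  =", format(x$probs[1L]), "\n")
  cat("  P(fixed) =", format(x$probs[x$N + 1L]), "\n")
  cat("  P(segregating) =", format(1 - x$probs[1L] - x$probs[x$N + 1L]), "\n")
  invisible(x)
}

#' Propagate a frequency spectrum through selection and drift
#'
#' Applies the selection-then-binomial-drift transition `generations` times.
#' Total probability is conserved to 1e-12 per step and mass at the loss and
#' fixation boundaries is retained (both classes are absorbing).
#'
#' @param spectrum A [frequency_spectrum()].
#' @param s Selection coefficient in `[0, 1)`.
#' @param generations Non-negative integer number of generations.
#' @param transition Optional precomputed matrix from
#'   [wf_transition_matrix()] (saves rebuilding it in loops).
#' @return The propagated `frequency_spectrum`.
#' @export
propagate <- function(spectrum, s, generations, transition = NULL) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  if (length(generations) != 1L || generations < 0 || generations != round(generations))
    stop("'generations' must be a non-negative integer")
  if (generations == 0) return(spectrum)
  M <- if (is.null(transition)) wf_transition_matrix(spectrum$N, s) else transition
  p <- spectrum$probs
  for (g in seq_len(generations)) {
    p <- as.vector(M %*% p)
    if (abs(sum(p) - 1) > 1e-12)
      stop("probability not conserved at generation ", g)
  }
  frequency_spectrum(spectrum$N, p)
}

#' Expected divergence of a lineage after t generations of mutation input
#'
#' The chance that a sequence sampled `t` generations after a mutation
#' entered the population differs from the ancestor, summed over the
#' generations at which the mutation could have entered:
#' `D(N, s, t) = sum_{v=1..t} sum_{x=1..N} P(N, x, s, v) x / N`.
#' Fixed mutations contribute `x/N = 1` permanently, which is why the
#' fixation class must be retained as an absorbing state.
#'
#' @param N Population size (chromosomes).
#' @param s Selection coefficient in `[0, 1)`.
#' @param t Generations, `t >= 1`. If a vector, the cumulative values at
#'   each time are returned (computed in one pass).
#' @return Divergence per unit mutation input, same length as `t`.
#' @export
expected_divergence <- function(N, s, t) {
  if (any(t < 1) || any(t != round(t))) stop("'t' must be positive integers")
  tmax <- max(t)
  M <- wf_transition_matrix(N, s)
  freq <- (0:N) / N
  # generation v = 1 is the introduction generation: point mass at one copy,
  # contributing 1/N before selection or drift have acted
  p <- c(0, 1, rep(0, N - 1L))
  cum <- numeric(tmax)
  run <- 0
  for (v in seq_len(tmax)) {
    run <- run + sum(p * freq)
    cum[v] <- run
    p <- as.vector(M %*% p)
  }
  cum[t]
}

#' Accumulation rate relative to neutral
#'
#' The expected divergence under selection divided by the neutral
#' expectation over the same window: `A(N, s, t) = D(N, s, t) / D(N, 0, t)`.
#' Under neutrality the mean frequency of a new mutation is a martingale at
#' `1/N`, so `D(N, 0, t) = t / N` exactly and no neutral matrix needs to be
#' propagated. `A` is 1 for neutral mutations and declines towards the
#' fixation probability ratio as `t` grows.
#'
#' @inheritParams expected_divergence
#' @return Relative accumulation rate(s) in `(0, 1]`, same length as `t`.
#' @export
relative_rate <- function(N, s, t) {
  expected_divergence(N, s, t) / (t / N)
}

#' Sample a gamma distribution of fitness effects
#'
#' Selection coefficients are drawn from a gamma distribution with the given
#' shape and mean `mean_Ns / N` (scale = `mean_Ns / (shape * N)`). Draws at
#' or above `s = 1` (impossible fitness) are capped at `1 - 1e-6`,
#' effectively lethal; a warning is issued if more than half the draws are
#' capped.
#'
#' @param shape Gamma shape parameter (> 0).
#' @param mean_Ns Mean selection strength scaled by population size (>= 0).
#' @param N Population size (chromosomes).
#' @param n_samples Number of mutations to draw.
#' @param seed RNG seed (integer).
#' @return Numeric vector of selection coefficients in `[0, 1)`.
#' @export
sample_dfe <- function(shape, mean_Ns, N, n_samples = 100L, seed = 1L) {
  stopifnot(shape > 0, mean_Ns >= 0, n_samples >= 1)
  if (mean_Ns == 0) return(rep(0, n_samples))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  s <- stats::rgamma(n_samples, shape = shape, scale = mean_Ns / (shape * N))
  capped <- s >= 1
  if (mean(capped) > 0.5)
    warning(sprintf("%.0f%% of sampled selection coefficients were capped at s = 1 - 1e-6",
                    100 * mean(capped)))
  s[capped] <- 1 - 1e-6
  s
}

#' Relative accumulation rate under a gamma DFE
#'
#' Draws `n_samples` selection coefficients from the gamma distribution of
#' fitness effects, computes the expected divergence for each, averages
#' across mutations, and divides by the neutral expectation. This is the
#' quantity plotted against sampling time in the model's accumulation-rate
#' curves.
#'
#' @param N Population size (chromosomes).
#' @param shape Gamma shape parameter of the DFE.
#' @param mean_Ns Mean of `N s` for new mutations.
#' @param times Integer generations at which to evaluate the curve.
#' @param n_samples Mutations drawn from the DFE (default 100).
#' @param seed RNG seed for the DFE draws.
#' @return A data.frame of class `accumulation_curve` with columns `t`
#'   (generations), `t_over_N`, and `A` (relative accumulation rate).
#' @export
dfe_relative_rate <- function(N, shape, mean_Ns, times, n_samples = 100L, seed = 1L) {
  if (any(times < 1) || any(times != round(times)))
    stop("'times' must be positive integers")
  times <- sort(unique(as.integer(times)))
  s_draws <- sample_dfe(shape, mean_Ns, N, n_samples, seed)
  D <- matrix(0, length(times), n_samples)
  for (k in seq_len(n_samples)) D[, k] <- expected_divergence(N, s_draws[k], times)
  A <- rowMeans(D) / (times / N)
  structure(
    data.frame(t = times, t_over_N = times / N, A = A),
    class = c("accumulation_curve", "data.frame"),
    N = N, shape = shape, mean_Ns = mean_Ns, n_samples = n_samples, seed = seed
  )
}

#' Monte-Carlo estimate of the expected divergence
#'
#' Forward-simulates single-mutation copy-count trajectories under the same
#' selection-then-binomial scheme as the transition matrix and averages the
#' per-replicate sum of `x/N` over the window. This is an unbiased,
#' implementation-independent estimator of [expected_divergence()], used as
#' a stochastic oracle.
#'
#' @param N Population size (chromosomes).
#' @param s Selection coefficient in `[0, 1)`.
#' @param t Generations.
#' @param replicates Number of simulated trajectories.
#' @param seed RNG seed.
#' @return List with `D` (estimate), `se` (standard error; `NA` when
#'   `replicates == 1`) and `replicates`.
#' @export
monte_carlo_divergence <- function(N, s, t, replicates = 20000L, seed = 1L) {
  stopifnot(replicates >= 1, t >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  x <- rep(1L, replicates)
  acc <- numeric(replicates)
  for (v in seq_len(t)) {
    acc <- acc + x / N  # generation v = 1 is the introduction generation
    seg <- x > 0L & x < N
    if (any(seg)) x[seg] <- stats::rbinom(sum(seg), N, selection_map(x[seg] / N, s))
  }
  list(D = mean(acc),
       se = if (replicates > 1) stats::sd(acc) / sqrt(replicates) else NA_real_,
       replicates = replicates)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
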