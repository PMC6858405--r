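# Match a named trait vector to a tree's tips, resolving polytomies with
# zero-length branches (flagged with a message) and checking completeness.
.align_trait <- function(tree, trait) {
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label))
      stop("unnamed trait vector must have one value per tip")
    names(trait) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing))
    stop("no trait value for tip(s): ", paste(missing, collapse = ", "))
  if (!ape::is.binary(tree)) {
    message("resolving polytomies with zero-length branches")
    tree <- ape::multi2di(tree)
  }
  list(tree = tree, trait = trait[tree$tip.label])
}

#' Phylogenetic independent contrasts
#'
#' Felsenstein's contrasts: at each internal node of a rooted binary tree
#' the standardized difference between the daughter values, each contrast
#' divided by its expected standard deviation (the square root of the
#' summed, recursion-adjusted branch lengths). Under Brownian motion the
#' contrasts are independent draws from one normal distribution, so
#' ordinary statistics (through the origin) can be applied to comparative
#' data. Computation is delegated to `ape::pic`.
#'
#' @param tree A rooted `phylo` tree with branch lengths. Polytomies are
#'   resolved arbitrarily with zero-length branches.
#' @param trait Numeric vector of tip values, named by tip label.
#' @return A data.frame of class `contrast_set` with columns `node`,
#'   `contrast` (standardized) and `expected_sd`.
#' @export
pic_contrasts <- function(tree, trait) {
  al <- .align_trait(tree, trait)
  pp <- ape::pic(al$trait, al$tree, scaled = TRUE, var.contrasts = TRUE)
  structure(
    data.frame(node = as.integer(rownames(pp)),
               contrast = pp[, "contrasts"],
               expected_sd = sqrt(pp[, "variance"]),
               row.names = NULL),
    class = c("contrast_set", "data.frame"))
}

#' Drop low-variance contrasts
#'
#' Contrasts between very close relatives have small expected standard
#' deviations, and estimation error in the traits then dominates the
#' contrast. Contrasts with expected SD below the threshold are removed.
#'
#' @param contrasts A `contrast_set` from [pic_contrasts()].
#' @param threshold Expected-SD cutoff (default 0.21).
#' @return The filtered `contrast_set`; the number removed is attached as
#'   attribute `n_removed`.
#' @export
filter_low_variance_contrasts <- function(contrasts, threshold = 0.21) {
  keep <- contrasts$expected_sd >= threshold
  out <- contrasts[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

# lambda-transformed Brownian covariance: off-diagonal entries scaled,
# diagonal (tip heights) untouched.
.lambda_vcv <- function(C, lambda) {
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

# Profile log-likelihood of a trait under the lambda model: the ancestral
# mean and the Brownian rate are maximized analytically, leaving a
# one-dimensional function of lambda.
.lambda_loglik <- function(lambda, C, x) {
  V <- .lambda_vcv(C, lambda)
  n <- length(x)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  Vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  Vix <- backsolve(ch, forwardsolve(t(ch), x))
  mu <- sum(Vi1 * x) / sum(Vi1)
  r <- x - mu
  Vir <- Vix - mu * Vi1
  s2 <- sum(r * Vir) / n
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' lambda scales the off-diagonal entries of the Brownian tip covariance
#' matrix: 1 means the trait covaries exactly as Brownian motion on the
#' tree predicts, 0 means no phylogenetic covariance. The estimate
#' maximizes the multivariate-normal likelihood over `[0, 1]` (Brent search,
#' 1e-6 tolerance); significance is a likelihood-ratio test against
#' `lambda = 0` on one degree of freedom.
#'
#' @param tree A rooted `phylo` tree with branch lengths (>= 4 tips).
#' @param trait Named numeric tip values.
#' @return List with `lambda`, `logL`, `logL0` (at lambda = 0) and `p`
#'   (LRT p-value vs lambda = 0).
#' @export
pagel_lambda <- function(tree, trait) {
  al <- .align_trait(tree, trait)
  if (length(al$trait) < 4L) stop("need at least 4 tips")
  C <- ape::vcv(al$tree)
  x <- al$trait[rownames(C)]
  opt <- stats::optimize(.lambda_loglik, c(0, 1), C = C, x = x,
                         maximum = TRUE, tol = 1e-6)
  # optimize never evaluates the exact endpoints; take them if better
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, .lambda_loglik(0, C, x), .lambda_loglik(1, C, x))
  best <- which.max(ll)
  logL0 <- ll[2]
  lrt <- 2 * (ll[best] - logL0)
  list(lambda = cand[best], logL = ll[best], logL0 = logL0,
       p = stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE))
}

#' Blomberg's K with a permutation test
#'
#' K compares the observed ratio of the mean squared error of tip values
#' about the phylogenetic mean to the GLS mean squared error, against the
#' same ratio expected under Brownian motion; K = 1 matches Brownian
#' expectation, K < 1 less signal, K > 1 more. Significance is assessed by
#' permuting trait values across tips and asking how often the variance of
#' the independent contrasts is as small as (or smaller than) observed.
#'
#' @param tree A rooted `phylo` tree with branch lengths (>= 4 tips).
#' @param trait Named numeric tip values.
#' @param n_perm Number of permutations (default 999); 0 skips the test and
#'   returns `p = NA`.
#' @param seed RNG seed for the permutations.
#' @return List with `K` and `p`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999L, seed = 1L) {
  al <- .align_trait(tree, trait)
  tree <- al$tree; x <- al$trait
  n <- length(x)
  if (n < 4L) stop("need at least 4 tips")
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  Ci <- solve(C)
  one <- rep(1, n)
  a_hat <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
  r <- x - a_hat
  mse0 <- sum(r^2) / (n - 1)
  mse <- as.numeric(r %*% Ci %*% r) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  K <- (mse0 / mse) / expected

  p <- NA_real_
  if (n_perm > 0) {
    obs <- stats::var(ape::pic(x, tree))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(i) {
      xp <- stats::setNames(sample(x), names(x))
      stats::var(ape::pic(xp, tree))
    }, numeric(1))
    # low contrast variance = strong signal; include the observation itself
    p <- (sum(perm <= obs) + 1) / (n_perm + 1)
  }
  list(K = K, p = p)
}

#' Phylogenetic signal summary for a set of traits
#'
#' Runs [pagel_lambda()] and [blomberg_k()] on each column of a trait table,
#' producing the usual lambda / K signal table.
#'
#' @param tree A rooted `phylo` tree.
#' @param traits Data.frame of numeric traits, rownames = tip labels (or a
#'   `species` column).
#' @param n_perm Permutations for the K test.
#' @param seed RNG seed.
#' @return Data.frame with one row per trait: `trait`, `lambda`,
#'   `lambda_p`, `K`, `K_p`, `n`.
#' @export
signal_table <- function(tree, traits, n_perm = 999L, seed = 1L) {
  if ("species" %in% names(traits)) {
    rownames(traits) <- traits$species
    traits$species <- NULL
  }
  out <- lapply(names(traits), function(tr) {
    x <- traits[[tr]]
    names(x) <- rownames(traits)
    x <- x[!is.na(x)]
    sub <- ape::keep.tip(tree, intersect(tree$tip.label, names(x)))
    x <- x[sub$tip.label]
    lam <- pagel_lambda(sub, x)
    kk <- blomberg_k(sub, x, n_perm = n_perm, seed = seed)
    data.frame(trait = tr, lambda = lam$lambda, lambda_p = lam$p,
               K = kk$K, K_p = kk$p, n = length(x))
  })
  do.call(rbind, out)
}

#' Sister pairs of tips contrasting two groups
#'
#' Finds the cherries of the tree (internal nodes whose two daughters are
#' both tips) whose members carry different group labels. Because cherries
#' are disjoint by construction, the pairs can be used directly in a paired
#' t-test that controls for phylogeny.
#'
#' @param tree A rooted `phylo` tree.
#' @param group_labels Character vector of group labels named by tip label.
#' @return Data.frame with columns `tip1`, `tip2`, `group1`, `group2`; zero
#'   rows (with a warning) when no mixed-label cherry exists.
#' @export
sister_pairs <- function(tree, group_labels) {
  missing <- setdiff(tree$tip.label, names(group_labels))
  if (length(missing))
    stop("no group label for tip(s): ", paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  pairs <- list()
  for (node in unique(edge[, 1])) {
    kids <- edge[edge[, 1] == node, 2]
    if (length(kids) == 2L && all(kids <= ntip)) {
      t1 <- tree$tip.label[kids[1]]; t2 <- tree$tip.label[kids[2]]
      g1 <- group_labels[[t1]]; g2 <- group_labels[[t2]]
      if (!identical(g1, g2))
        pairs[[length(pairs) + 1L]] <- data.frame(
          tip1 = t1, tip2 = t2, group1 = g1, group2 = g2)
    }
  }
  if (length(pairs) == 0L) {
    warning("no mixed-label sister pairs found")
    return(data.frame(tip1 = character(), tip2 = character(),
                      group1 = character(), group2 = character()))
  }
  do.call(rbind, pairs)
}
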