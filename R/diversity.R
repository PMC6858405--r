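# Standard-code codon table, built once from seqinr's translation machinery.
.codon_env <- new.env(parent = emptyenv())

.codon_table <- function() {
  if (is.null(.codon_env$aa)) {
    bases <- c("T", "C", "A", "G")
    codons <- as.vector(outer(outer(bases, bases, paste0), bases,
                              function(a, b) paste0(a, b)))
    aa <- vapply(codons, function(cd)
      seqinr::translate(strsplit(cd, "")[[1]]), character(1))
    names(aa) <- codons
    .codon_env$aa <- aa
  }
  .codon_env$aa
}

.is_stop <- function(codon) unname(.codon_table()[codon] == "*")

.valid_codon <- function(codon) {
  nchar(codon) == 3L && !is.na(.codon_table()[codon])
}

#' Nonsynonymous and synonymous site counts of a codon
#'
#' Nei-Gojobori (1986) counting: each codon position contributes a
#' synonymous-site fraction equal to the proportion of its three possible
#' single-base changes that leave the amino acid unchanged. Changes that
#' create a stop codon are counted as nonsynonymous. The two counts always
#' sum to 3.
#'
#' @param codon A 3-letter upper-case DNA codon (standard genetic code).
#' @return Named numeric vector `c(nonsyn = , syn = )`.
#' @examples
#' count_sites("TTT")  # Phe: 8/3 nonsynonymous, 1/3 synonymous
#' count_sites("TGG")  # Trp: every change is nonsynonymous (or stop)
#' @export
count_sites <- function(codon) {
  codon <- toupper(codon)
  tab <- .codon_table()
  if (!.valid_codon(codon)) stop("not a valid unambiguous codon: ", codon)
  if (.is_stop(codon)) stop("stop codon has no site counts: ", codon)
  aa0 <- tab[codon]
  bases <- c("T", "C", "A", "G")
  syn <- 0
  chars <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (b in setdiff(bases, chars[pos])) {
      mut <- chars
      mut[pos] <- b
      mutc <- paste(mut, collapse = "")
      if (!.is_stop(mutc) && tab[mutc] == aa0) syn <- syn + 1 / 3
    }
  }
  c(nonsyn = 3 - syn, syn = syn)
}

# Synonymous/nonsynonymous difference counts between two sense codons,
# averaging over mutational pathways (all orderings of the differing
# positions). Pathways through stop codons are excluded; if every pathway
# is blocked, all are used with stop steps counted as nonsynonymous.
.perms <- list(`1` = list(1L),
               `2` = list(c(1L, 2L), c(2L, 1L)),
               `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                          c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

.codon_diffs <- function(c1, c2) {
  tab <- .codon_table()
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diff_pos <- which(a != b)
  d <- length(diff_pos)
  if (d == 0L) return(c(nonsyn = 0, syn = 0))
  orders <- lapply(.perms[[as.character(d)]], function(p) diff_pos[p])
  walk <- function(pos_order, allow_stop) {
    cur <- a
    syn <- 0; nonsyn <- 0
    for (pos in pos_order) {
      nxt <- cur
      nxt[pos] <- b[pos]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (tab[to] == "*" || tab[from] == "*") {
        if (!allow_stop) return(NULL)
        nonsyn <- nonsyn + 1
      } else if (tab[from] == tab[to]) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(nonsyn = nonsyn, syn = syn)
  }
  ok <- lapply(orders, walk, allow_stop = FALSE)
  ok <- ok[!vapply(ok, is.null, logical(1))]
  if (length(ok) == 0L) ok <- lapply(orders, walk, allow_stop = TRUE)
  Reduce(`+`, ok) / length(ok)
}

#' Read a codon alignment from FASTA
#'
#' @param path FASTA file of aligned, equal-length nucleotide sequences.
#' @return Named character vector of upper-case sequences.
#' @export
load_codon_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(dna), paste, character(1), collapse = ""))
  validate_codon_alignment(seqs)
  seqs
}

#' Validate a codon alignment
#'
#' Checks that there are at least two sequences, all of equal length
#' divisible by 3, with no internal stop codons (gap-containing codons are
#' ignored; they are handled pairwise downstream).
#'
#' @param seqs Named character vector of aligned sequences.
#' @return `seqs`, invisibly, after validation.
#' @export
validate_codon_alignment <- function(seqs) {
  if (length(seqs) < 2L) stop("alignment needs at least 2 sequences")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences are not all the same length")
  if (L %% 3L != 0L) stop("alignment length is not a multiple of 3")
  tab <- .codon_table()
  for (k in seq_along(seqs)) {
    cods <- substring(seqs[k], seq(1, L, 3), seq(3, L, 3))
    cods <- cods[cods %in% names(tab)]
    internal <- cods[-length(cods)]
    if (length(internal) && any(tab[internal] == "*"))
      stop("internal stop codon in sequence ", names(seqs)[k] %||% k)
  }
  invisible(seqs)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a) || a == "") b else a

#' Pairwise piN/piS nucleotide diversity from a codon alignment
#'
#' For every unordered pair of sequences, counts synonymous and
#' nonsynonymous differences and sites by the Nei-Gojobori (1986)
#' proportion method (no multiple-hit correction; within-species diversity
#' is small) and averages the per-pair ratios of differences to sites.
#' Codons containing gaps, ambiguity codes or stops in either member of a
#' pair are skipped for that pair only.
#'
#' @param seqs Named character vector of aligned sequences (or a path is
#'   accepted via [load_codon_alignment()] first).
#' @return A list of class `diversity_result`: `pi_n`, `pi_s`, `ratio`
#'   (`NA` when `pi_s == 0`), and `n_pairs`.
#' @export
pi_n_pi_s <- function(seqs) {
  validate_codon_alignment(seqs)
  L <- nchar(seqs[1])
  starts <- seq(1, L, 3)
  codmat <- vapply(seqs, function(s) substring(s, starts, starts + 2L),
                   character(length(starts)))
  tab <- .codon_table()
  sense <- function(cd) cd %in% names(tab) & tab[cd] != "*"

  nseq <- length(seqs)
  pin <- numeric(0); pis <- numeric(0)
  site_cache <- new.env(parent = emptyenv())
  sites_of <- function(cd) {
    v <- site_cache[[cd]]
    if (is.null(v)) {
      v <- count_sites(cd)
      site_cache[[cd]] <- v
    }
    v
  }
  for (i in seq_len(nseq - 1L)) for (j in (i + 1L):nseq) {
    ci <- codmat[, i]; cj <- codmat[, j]
    use <- sense(ci) & sense(cj)
    if (!any(use)) next
    Ns <- 0; Ss <- 0; Nd <- 0; Sd <- 0
    for (k in which(use)) {
      si <- sites_of(ci[k]); sj <- sites_of(cj[k])
      Ns <- Ns + (si["nonsyn"] + sj["nonsyn"]) / 2
      Ss <- Ss + (si["syn"] + sj["syn"]) / 2
      if (ci[k] != cj[k]) {
        dd <- .codon_diffs(ci[k], cj[k])
        Nd <- Nd + dd["nonsyn"]; Sd <- Sd + dd["syn"]
      }
    }
    pin <- c(pin, if (Ns > 0) Nd / Ns else 0)
    pis <- c(pis, if (Ss > 0) Sd / Ss else 0)
  }
  pi_n <- mean(pin); pi_s <- mean(pis)
  structure(list(pi_n = pi_n, pi_s = pi_s,
                 ratio = if (pi_s > 0) pi_n / pi_s else NA_real_,
                 n_pairs = length(pin)),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("piN =", format(x$pi_n, digits = 4),
      " piS =", format(x$pi_s, digits = 4),
      " piN/piS =", if (is.na(x$ratio)) "undefined (piS = 0)"
      else format(x$ratio, digits = 4),
      " (", x$n_pairs, "pairs )\n")
  invisible(x)
}
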