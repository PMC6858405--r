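#' Read a per-estimate accumulation-rate table
#'
#' Reads a CSV of literature-style accumulation-rate estimates, one row per
#' estimate. Mandatory columns: `species`, `rate` (substitutions per site
#' per year), `sampling_time` (years), `site_class` (`"all"` or
#' `"synonymous"`), `hypermutator` (logical), `study`. Extra columns are
#' preserved untouched.
#'
#' @param path Path to a CSV file with a header row.
#' @return A data.frame of rate estimates.
#' @export
load_rate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "rate", "sampling_time", "site_class", "hypermutator", "study")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("rate table is missing mandatory column(s): ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(df$rate) | df$rate <= 0)
  if (length(bad))
    stop("non-positive or non-numeric rate in row(s): ", paste(bad, collapse = ", "))
  bad <- which(!is.finite(df$sampling_time) | df$sampling_time <= 0)
  if (length(bad))
    stop("non-positive sampling_time in row(s): ", paste(bad, collapse = ", "))
  df$hypermutator <- as.logical(df$hypermutator)
  df
}

#' Read a per-species trait table
#'
#' Reads a CSV of per-species genomic and life-history covariates.
#' Mandatory column: `species`. Recognised covariates (any may be absent):
#' `genome_size` (Mb), `gc` (percent), `pin_pis`, `lab_dt` (hours),
#' `rrn_copies`, `trna_count`, `lifestyle`
#' (`obligate`/`opportunistic`/`other`), `mutation_rate` (per site per
#' generation).
#'
#' @param path Path to a CSV file with a header row.
#' @return A data.frame of species traits.
#' @export
load_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) stop("trait table is missing mandatory column: species")
  if ("gc" %in% names(df) && any(df$gc <= 0 | df$gc >= 100, na.rm = TRUE))
    stop("gc must be a percentage in (0, 100)")
  if ("genome_size" %in% names(df) && any(df$genome_size <= 0, na.rm = TRUE))
    stop("genome_size must be positive")
  df
}

#' Apply the curation rules to a rate-estimate table
#'
#' Keeps estimates that were (1) sampled over a historical timeframe of at
#' most 1500 years (inclusive), (2) computed over all sites rather than
#' synonymous sites only, and (3) not from a hypermutator strain. Row order
#' is preserved. The exclusions, with reasons, are attached as an audit log.
#'
#' @param estimates A rate-estimate data.frame (see [load_rate_table()]).
#' @param max_sampling_time Timeframe cutoff in years (default 1500).
#' @return A list with `estimates` (the retained rows) and `audit` (a
#'   data.frame of excluded rows with a `reason` column; an estimate failing
#'   several rules is reported once with all reasons).
#' @export
filter_estimates <- function(estimates, max_sampling_time = 1500) {
  reasons <- character(nrow(estimates))
  add <- function(cur, r) ifelse(cur == "", r, paste(cur, r, sep = "; "))
  bad_time <- estimates$sampling_time > max_sampling_time
  reasons[bad_time] <- add(reasons[bad_time],
                           sprintf("sampling time > %g years", max_sampling_time))
  bad_site <- estimates$site_class != "all"
  reasons[bad_site] <- add(reasons[bad_site], "synonymous-only rate")
  bad_hyper <- as.logical(estimates$hypermutator)
  reasons[bad_hyper] <- add(reasons[bad_hyper], "hypermutator strain")
  keep <- reasons == ""
  audit <- estimates[!keep, , drop = FALSE]
  audit$reason <- reasons[!keep]
  list(estimates = estimates[keep, , drop = FALSE], audit = audit)
}

#' Average rate estimates by species
#'
#' Where a species has several estimates, the per-species rate is their
#' arithmetic mean on the raw (per site per year) scale; a geometric mean is
#' available as an option. The number of contributing estimates is recorded.
#'
#' @param estimates Filtered rate-estimate data.frame.
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @return A data.frame with columns `species`, `mean_rate`, `n_estimates`,
#'   one row per species, in first-appearance order.
#' @export
average_by_species <- function(estimates, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  sp <- unique(estimates$species)
  avg <- vapply(sp, function(z) {
    r <- estimates$rate[estimates$species == z]
    if (method == "arithmetic") mean(r) else exp(mean(log(r)))
  }, numeric(1))
  n <- vapply(sp, function(z) sum(estimates$species == z), integer(1))
  data.frame(species = sp, mean_rate = unname(avg), n_estimates = unname(n),
             row.names = NULL)
}

#' Base-10 logarithm of rates
#'
#' Rates span orders of magnitude, so all comparative analyses are run on
#' log10-transformed rates.
#'
#' @param rates Positive numeric vector.
#' @return `log10(rates)`.
#' @export
log_transform <- function(rates) {
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("rates must be positive to log-transform")
  log10(rates)
}

#' Fold range of a set of rates
#'
#' Ratio of the largest to the smallest rate — the headline spread of
#' accumulation rates across species.
#'
#' @param rates Positive numeric vector.
#' @return `max(rates) / min(rates)`.
#' @export
fold_range <- function(rates) {
  if (length(rates) == 0) stop("no rates supplied")
  if (any(rates <= 0)) stop("rates must be positive")
  max(rates) / min(rates)
}
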