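#' Pipeline configuration
#'
#' Collects the inputs, exclusions, thresholds and seeds of a full
#' comparative run into one declarative object. Outlier exclusion is
#' configuration rather than code because the analysis is reported both
#' with and without named outliers.
#'
#' @param rate_csv,trait_csv,tree_file Input paths (see
#'   [load_rate_table()], [load_trait_table()]; newick tree).
#' @param out_dir Output directory; tables are written here.
#' @param exclude_species Species excluded from the sensitivity variant of
#'   every correlation (e.g. a conspicuous outlier).
#' @param max_sampling_time Curation cutoff in years (default 1500).
#' @param pic_sd_threshold Low-variance contrast cutoff (default 0.21).
#' @param n_perm Permutations for the K test (default 999).
#' @param seed Master seed, recorded in the output.
#' @param wf List of Wright-Fisher model settings: `N`, `shape`, `mean_Ns`
#'   (vectors crossed into a grid), `n_samples`, `n_times`.
#' @return A `run_config` list.
#' @export
run_config <- function(rate_csv, trait_csv, tree_file, out_dir,
                       exclude_species = character(),
                       max_sampling_time = 1500,
                       pic_sd_threshold = 0.21,
                       n_perm = 999L, seed = 1L,
                       wf = list(N = 100L, shape = 0.5, mean_Ns = 100,
                                 n_samples = 100L, n_times = 12L)) {
  for (f in c(rate_csv, trait_csv, tree_file))
    if (!file.exists(f)) stop("input file does not exist: ", f)
  structure(list(rate_csv = rate_csv, trait_csv = trait_csv,
                 tree_file = tree_file, out_dir = out_dir,
                 exclude_species = exclude_species,
                 max_sampling_time = max_sampling_time,
                 pic_sd_threshold = pic_sd_threshold,
                 n_perm = n_perm, seed = seed, wf = wf),
            class = "run_config")
}

# One correlation row: raw Pearson and PIC variant, with provenance.
.correlation_row <- function(label, df, tree, xvar, pic_sd_threshold,
                             excluded = character()) {
  df <- df[!df$species %in% excluded, , drop = FALSE]
  df <- df[is.finite(df[[xvar]]) & is.finite(df$log_rate), , drop = FALSE]
  raw <- pearson(df[[xvar]], df$log_rate)
  sub <- ape::keep.tip(tree, intersect(tree$tip.label, df$species))
  xs <- stats::setNames(df[[xvar]], df$species)[sub$tip.label]
  ys <- stats::setNames(df$log_rate, df$species)[sub$tip.label]
  cx <- pic_contrasts(sub, xs); cy <- pic_contrasts(sub, ys)
  keep <- cx$expected_sd >= pic_sd_threshold
  pic_r <- if (sum(keep) >= 3)
    pearson(cx$contrast[keep], cy$contrast[keep], through_origin = TRUE)
  else list(r = NA_real_, p = NA_real_, n = sum(keep))
  data.frame(analysis = label, variable = xvar,
             excluded = paste(excluded, collapse = ";"),
             r = raw$r, p = raw$p, n = raw$n,
             pic_r = pic_r$r, pic_p = pic_r$p, pic_n = pic_r$n,
             pic_removed = sum(!keep))
}

#' Run the full comparative pipeline
#'
#' Curates the rate table (timeframe, site-class and hypermutator rules),
#' averages estimates per species, log-transforms, merges with the trait
#' table and the phylogeny, and then produces: the correlation table (raw
#' and independent-contrast variants, with and without the configured
#' outliers), the sampling-time analyses (across-study correlation and
#' within-species common-slope ANCOVA), phylogenetic-signal estimates
#' (lambda, K) for every trait, the lifestyle t-tests (Welch and
#' sister-pair paired), a standardized multiple regression, the correlation
#' power analysis, and relative accumulation-rate curves from the
#' Wright-Fisher model. All tables are written as CSV under `out_dir` and
#' returned. Deterministic given the config's seed.
#'
#' @param config A [run_config()].
#' @return Invisible list of result tables (also written to disk).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "setup"
  res <- tryCatch({
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

    stage <- "curate"
    est <- load_rate_table(config$rate_csv)
    filt <- filter_estimates(est, config$max_sampling_time)
    sp_rates <- average_by_species(filt$estimates)
    sp_rates$log_rate <- log_transform(sp_rates$mean_rate)

    stage <- "merge"
    traits <- load_trait_table(config$trait_csv)
    # the curated log rate is the analysis response; a trait-table column of
    # the same name (e.g. a generator's ground truth) must not shadow it
    traits <- traits[, setdiff(names(traits),
                               c("log_rate", "mean_rate", "n_estimates")),
                     drop = FALSE]
    tree <- ape::read.tree(config$tree_file)
    df <- merge(sp_rates, traits, by = "species")
    df$log_pin_pis <- ifelse(df$pin_pis > 0, log10(df$pin_pis), NA)
    df$log_lab_dt <- ifelse(df$lab_dt > 0, log10(df$lab_dt), NA)

    stage <- "correlations"
    covars <- intersect(c("genome_size", "gc", "log_pin_pis", "log_lab_dt",
                          "rrn_copies", "trna_count"), names(df))
    cors <- do.call(rbind, c(
      lapply(covars, function(v)
        .correlation_row("all_species", df, tree, v, config$pic_sd_threshold)),
      if (length(config$exclude_species))
        lapply(covars, function(v)
          .correlation_row("outliers_excluded", df, tree, v,
                           config$pic_sd_threshold, config$exclude_species))
    ))

    stage <- "sampling_time"
    fe <- filt$estimates
    fe$log_rate <- log_transform(fe$rate)
    fe$log_time <- log10(fe$sampling_time)
    st_cor <- pearson(fe$log_time, fe$log_rate)
    multi <- names(which(table(fe$species) >= 2))
    anc <- if (length(multi) >= 2)
      ancova_common_slope(fe[fe$species %in% multi, ],
                          y = "log_rate", x = "log_time", group = "species")
    else NULL
    sampling <- data.frame(
      statistic = c("pearson_r", "pearson_p", "pearson_n",
                    "ancova_slope", "ancova_p", "ancova_n_species"),
      value = c(st_cor$r, st_cor$p, st_cor$n,
                if (is.null(anc)) rep(NA, 3)
                else c(anc$common_slope, anc$p, anc$n_groups)))

    stage <- "signal"
    sig_traits <- df[, intersect(c("log_rate", "genome_size", "gc",
                                   "log_pin_pis", "log_lab_dt"), names(df))]
    rownames(sig_traits) <- df$species
    sig <- signal_table(tree, sig_traits, n_perm = config$n_perm,
                        seed = config$seed)

    stage <- "lifestyle"
    lifestyle <- NULL
    if ("lifestyle" %in% names(df) && length(unique(df$lifestyle)) == 2) {
      tt <- group_ttest(df$log_rate, df$lifestyle)
      labs <- stats::setNames(df$lifestyle, df$species)
      prs <- suppressWarnings(
        sister_pairs(ape::keep.tip(tree, intersect(tree$tip.label, df$species)),
                     labs))
      ptt <- if (nrow(prs) >= 2) {
        lr <- stats::setNames(df$log_rate, df$species)
        group_ttest(c(lr[prs$tip1], lr[prs$tip2]),
                    rep(c("g1", "g2"), each = nrow(prs)), paired = TRUE)
      } else NULL
      lifestyle <- data.frame(
        test = c("welch_t", "welch_p", "paired_t", "paired_p", "n_pairs"),
        value = c(tt$t, tt$p,
                  if (is.null(ptt)) c(NA, NA) else c(ptt$t, ptt$p),
                  nrow(prs)))
    }

    stage <- "multiple_regression"
    mr_vars <- intersect(c("genome_size", "gc", "log_pin_pis", "log_lab_dt"),
                         names(df))
    cc <- stats::complete.cases(df[, mr_vars])
    mreg <- if (sum(cc) > length(mr_vars) + 2)
      multiple_regression_standardized(df[cc, mr_vars], df$log_rate[cc])
    else NULL
    mreg_df <- if (is.null(mreg)) NULL else
      data.frame(predictor = names(mreg$coefficients),
                 std_coef = unname(mreg$coefficients),
                 p = unname(mreg$p_values), n = mreg$n)

    stage <- "power"
    power_df <- data.frame(
      n = nrow(df), alpha = 0.05, power = 0.95,
      detectable_r = detectable_correlation(nrow(df), 0.05, 0.95))

    stage <- "wf_model"
    wf <- config$wf
    grid <- expand.grid(shape = wf$shape, mean_Ns = wf$mean_Ns)
    times <- unique(pmax(1, round(exp(seq(log(1), log(4 * wf$N),
                                          length.out = wf$n_times)))))
    curves <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      cv <- dfe_relative_rate(wf$N, grid$shape[i], grid$mean_Ns[i], times,
                              n_samples = wf$n_samples, seed = config$seed)
      cbind(shape = grid$shape[i], mean_Ns = grid$mean_Ns[i],
            as.data.frame(cv))
    }))

    stage <- "write"
    tables <- list(curated_species = sp_rates, exclusions = filt$audit,
                   correlations = cors, sampling_time = sampling,
                   signal = sig, lifestyle = lifestyle,
                   multiple_regression = mreg_df, power = power_df,
                   wf_curves = curves)
    for (nm in names(tables)) if (!is.null(tables[[nm]]))
      utils::write.csv(tables[[nm]], file.path(config$out_dir,
                                               paste0(nm, ".csv")),
                       row.names = FALSE)
    writeLines(c(sprintf("seed: %d", config$seed),
                 sprintf("excluded: %s",
                         paste(config$exclude_species, collapse = ", "))),
               file.path(config$out_dir, "run_info.txt"))
    tables
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
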