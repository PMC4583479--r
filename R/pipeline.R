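#' Configuration for a fine-mapping simulation grid
#'
#' Defines the full factorial experiment: risk-allele frequencies x odds
#' ratios x study-design scenarios, with optional trans-ethnic cohort mixes,
#' functional priors and a second causal variant. Every replicate draws a
#' fresh region panel (mirroring a design with many distinct genomic
#' regions), simulates `n_studies` case-control cohorts, applies the
#' scenario transforms, meta-analyzes, fine-maps and scores the outcome.
#' All thresholds of the analysis appear here as keys with their
#' conventional defaults.
#'
#' @param replicates Replicate regions per setting.
#' @param raf_levels,or_levels The RAF / OR grid (defaults: RAF 5-50%,
#'   OR 1.0-1.5; OR 1.0 is the null model).
#' @param scenarios Character vector among `"gold"`, `"gwas"`,
#'   `"gwas_failure"`; scenarios share the same simulated cohorts within a
#'   replicate.
#' @param n_afr Number of the `n_studies` cohorts simulated from the
#'   diverged (AFR-like) panel.
#' @param prior_coding Vector of prior weights applied to coding variants;
#'   each value produces its own fine-mapping pass on identical data
#'   (1 = uniform prior).
#' @param n_causal 1 or 2 causal variants.
#' @param causal_coding Restrict the causal variant to coding variants.
#' @param levels Credible levels (0.95 and 0.99).
#' @param n_studies,n_cases,n_controls Cohort structure (ten studies of
#'   1,000 cases and 1,000 controls by default).
#' @param prevalence Disease prevalence K.
#' @param array_density_per_mb Array content density for the gwas scenarios.
#' @param failure_fraction Per-cohort fraction of array variants failed
#'   (gwas_failure).
#' @param W ABF prior variance.
#' @param qc [qc_thresholds()] applied after imputation.
#' @param k_neighbors,ridge Imputation-model controls.
#' @param region_length Region length in bp.
#' @param panel Named list of [panel_params()] overrides (e.g.
#'   `list(target_density = 600)`); the seed is always set internally.
#' @param r2_thresholds Optional r-squared thresholds for comparator sets
#'   (e.g. `c(0.5, 0.8, 0.9)`).
#' @param alpha Significance level used for the analytic power column.
#' @param switch_scale Mosaic re-switching scale (bp) of the cohort
#'   simulator.
#' @param min_fraction Effective-sample-size exclusion rule for ABF
#'   rescaling.
#' @param retry_cap Maximum panel re-draws when a replicate cannot place
#'   its causal variant(s).
#' @param seed Master seed; every replicate's seed is derived from
#'   (seed, setting, replicate).
#' @param out_dir Optional output directory for resumable per-replicate
#'   records.
#' @return A validated `grid_config` list.
#' @export
grid_config <- function(replicates = 1000L,
                        raf_levels = c(0.05, 0.10, 0.20, 0.50),
                        or_levels = c(1.0, 1.1, 1.2, 1.5),
                        scenarios = "gold",
                        n_afr = 0L,
                        prior_coding = 1,
                        n_causal = 1L,
                        causal_coding = FALSE,
                        levels = c(0.95, 0.99),
                        n_studies = 10L, n_cases = 1000L, n_controls = 1000L,
                        prevalence = 0.0055,
                        array_density_per_mb = 800,
                        failure_fraction = 0.05,
                        W = 0.04,
                        qc = qc_thresholds(),
                        k_neighbors = 30L, ridge = 1e-4,
                        region_length = 1e6,
                        panel = list(),
                        r2_thresholds = NULL,
                        alpha = 5e-8,
                        switch_scale = 4e5,
                        min_fraction = 0.7,
                        retry_cap = 50L,
                        seed = 1L,
                        out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$replicates >= 1,
            all(cfg$raf_levels > 0 & cfg$raf_levels < 1),
            all(cfg$or_levels > 0),
            all(cfg$scenarios %in% c("gold", "gwas", "gwas_failure")),
            cfg$n_afr >= 0, cfg$n_afr <= cfg$n_studies,
            all(cfg$prior_coding > 0),
            cfg$n_causal %in% c(1L, 2L),
            all(cfg$levels > 0 & cfg$levels < 1),
            cfg$n_studies >= 1, cfg$n_cases >= 1, cfg$n_controls >= 1,
            inherits(cfg$qc, "qc_thresholds"),
            is.list(cfg$panel))
  class(cfg) <- "grid_config"
  cfg
}

panel_for_config <- function(cfg, pseed) {
  args <- cfg$panel
  args$seed <- pseed
  params <- do.call(panel_params, args)
  synthesize_panel(params, cfg$region_length)
}

# choose orientation so the risk-allele frequency is nearest target
orient_to_raf <- function(panel, id, raf) {
  p <- panel_freq(panel)[match(id, panel$variants$id)]
  if (abs(p - raf) <= abs((1 - p) - raf)) "alt" else "ref"
}

#' Run one replicate of the simulation pipeline
#'
#' Synthesizes a region panel (re-drawing it, up to `retry_cap` times, when
#' the requested causal configuration cannot be placed), simulates the
#' cohorts, applies each scenario, meta-analyzes, fine-maps under each
#' prior, and scores the outcome.
#'
#' @param cfg A [grid_config()].
#' @param raf,or Setting values.
#' @param replicate Replicate index (seeds are derived from it).
#' @return A data frame with one row per scenario x prior weight.
#' @export
run_replicate <- function(cfg, raf, or, replicate = 1L) {
  seed_base <- derive_seed(cfg$seed, round(raf * 10000), round(or * 1000),
                           replicate)
  panel <- NULL
  model <- NULL
  for (attempt in seq_len(cfg$retry_cap)) {
    cand <- try(suppressWarnings({
      pp <- panel_for_config(cfg, derive_seed(seed_base, 11L, attempt))
      if (cfg$n_causal == 2L) {
        ids <- select_multi_causal_pair(pp, maf_target = raf,
                                        seed = derive_seed(seed_base, 15L,
                                                           attempt))
        spec <- data.frame(id = ids, or = or,
                           risk_allele = vapply(ids, orient_to_raf, "",
                                                panel = pp, raf = raf))
      } else {
        spec <- data.frame(raf = raf, or = or, coding = cfg$causal_coding)
      }
      list(panel = pp,
           model = with_seed(derive_seed(seed_base, 16L, attempt),
                             build_disease_model(pp, spec, cfg$prevalence)))
    }), silent = TRUE)
    if (!inherits(cand, "try-error")) {
      panel <- cand$panel
      model <- cand$model
      break
    }
  }
  if (is.null(panel))
    stop("could not place causal variant(s) after ", cfg$retry_cap,
         " panel draws")
  causal_ids <- model$causal$id

  afr_panel <- NULL
  afr_model <- NULL
  if (cfg$n_afr > 0) {
    afr_panel <- derive_diverged_panel(panel, seed = derive_seed(seed_base,
                                                                 12L))
    afr_model <- build_disease_model(
      afr_panel,
      data.frame(id = model$causal$id, or = model$causal$or,
                 risk_allele = model$causal$risk_allele),
      cfg$prevalence)
  }

  needs_array <- any(cfg$scenarios != "gold")
  mask <- if (needs_array)
    select_array_mask(panel, cfg$array_density_per_mb,
                      seed = derive_seed(seed_base, 13L))
  imp_base <- list()
  if (needs_array) {
    imp_base$eur <- fit_imputation_model(panel, mask, cfg$k_neighbors,
                                         cfg$ridge, cfg$switch_scale)
    if (cfg$n_afr > 0)
      imp_base$afr <- fit_imputation_model(afr_panel, mask, cfg$k_neighbors,
                                           cfg$ridge, cfg$switch_scale)
  }

  assoc <- setNames(vector("list", length(cfg$scenarios)), cfg$scenarios)
  for (scen in cfg$scenarios) assoc[[scen]] <- vector("list", cfg$n_studies)
  for (s in seq_len(cfg$n_studies)) {
    is_afr <- s <= cfg$n_afr
    pnl <- if (is_afr) afr_panel else panel
    mdl <- if (is_afr) afr_model else model
    study <- simulate_case_control(pnl, mdl, cfg$n_cases, cfg$n_controls,
                                   seed = derive_seed(seed_base, 20L + s),
                                   study_id = sprintf("study%02d", s),
                                   switch_scale = cfg$switch_scale)
    for (scen in cfg$scenarios) {
      if (scen == "gold") {
        assoc[[scen]][[s]] <- association_scan(study)
      } else {
        sc <- scenario_spec(scen, array_mask = mask,
                            failure_fraction = if (scen == "gwas_failure")
                              cfg$failure_fraction else 0,
                            seed = derive_seed(seed_base, 40L + s))
        st <- apply_scenario(study, sc)
        imp <- if (any(st$failed)) {
          fit_imputation_model(pnl, setdiff(mask,
                                            st$variants$id[st$failed]),
                               cfg$k_neighbors, cfg$ridge,
                               cfg$switch_scale)
        } else if (is_afr) imp_base$afr else imp_base$eur
        st <- impute_study(st, imp)
        res <- association_scan(st)
        # per-study INFO filter: a study contributes a variant only when
        # its INFO in that study exceeds the threshold
        low <- !is.na(res$info) & res$info <= cfg$qc$info_min &
          res$status == "ok"
        res$status[low] <- "low_info"
        assoc[[scen]][[s]] <- res
      }
    }
  }

  major_panel <- if (cfg$n_afr > cfg$n_studies / 2) afr_panel else panel
  rows <- list()
  for (scen in cfg$scenarios) {
    meta <- meta_analyze(assoc[[scen]])
    keep <- qc_filter(meta, thresholds = cfg$qc) & meta$n_studies > 0
    meta_f <- meta[keep, , drop = FALSE]
    class(meta_f) <- class(meta)
    censored <- !any(causal_ids %in% meta_f$id)
    rk <- suppressWarnings(min(vapply(causal_ids, function(cid)
      causal_rank(meta_f, cid) %||% NA_integer_, NA_integer_), na.rm = TRUE))
    if (!is.finite(rk)) rk <- NA_integer_
    r2_cols <- NULL
    if (!is.null(cfg$r2_thresholds) && nrow(meta_f) > 0) {
      r2_cols <- list()
      for (thr in cfg$r2_thresholds) {
        set <- try(r2_proxy_set(meta_f, major_panel, thr), silent = TRUE)
        tag <- sprintf("%g", 100 * thr)
        if (inherits(set, "try-error")) {
          r2_cols[[paste0("r2size", tag)]] <- NA_integer_
          r2_cols[[paste0("r2cov", tag)]] <- NA
        } else {
          r2_cols[[paste0("r2size", tag)]] <- length(set)
          r2_cols[[paste0("r2cov", tag)]] <- any(causal_ids %in% set)
        }
      }
    }
    coding <- panel$variants$is_coding[match(meta_f$id, panel$variants$id)]
    for (pw in cfg$prior_coding) {
      if (nrow(meta_f) == 0) {
        row <- data.frame(raf = raf, or = or, scenario = scen,
                          n_afr = cfg$n_afr, prior_w = pw,
                          n_causal = cfg$n_causal, replicate = replicate,
                          n_qc = 0L, censored = TRUE, rank = NA_integer_,
                          size95 = NA_integer_, size99 = NA_integer_,
                          cov95 = FALSE, cov99 = FALSE,
                          stringsAsFactors = FALSE)
      } else {
        weights <- ifelse(coding, pw, 1)
        fm <- finemap_abf(meta_f, W = cfg$W, prior_weights = weights,
                          levels = cfg$levels, rescale = TRUE,
                          min_fraction = cfg$min_fraction)
        s95 <- fm$credible_sets[["0.95"]]
        s99 <- fm$credible_sets[["0.99"]]
        row <- data.frame(raf = raf, or = or, scenario = scen,
                          n_afr = cfg$n_afr, prior_w = pw,
                          n_causal = cfg$n_causal, replicate = replicate,
                          n_qc = nrow(meta_f), censored = censored,
                          rank = rk,
                          size95 = s95$size, size99 = s99$size,
                          cov95 = !censored && any(causal_ids %in% s95$variants),
                          cov99 = !censored && any(causal_ids %in% s99$variants),
                          stringsAsFactors = FALSE)
      }
      row$cat95 <- as.character(classify_fine_mapping(
        row$size95 %||% NA, isTRUE(row$cov95)))
      row$cat99 <- as.character(classify_fine_mapping(
        row$size99 %||% NA, isTRUE(row$cov99)))
      if (!is.null(r2_cols)) row <- cbind(row, as.data.frame(r2_cols))
      row$causal <- paste(causal_ids, collapse = ";")
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

# canonical column types for replicate records read back from disk
normalize_records <- function(df) {
  num <- c("raf", "or", "prior_w")
  int <- c("n_afr", "n_causal", "replicate", "n_qc", "rank", "size95",
           "size99")
  lgl <- c("censored", "cov95", "cov99")
  chr <- c("scenario", "cat95", "cat99", "causal")
  for (cl in intersect(num, names(df))) df[[cl]] <- as.numeric(df[[cl]])
  for (cl in intersect(int, names(df))) df[[cl]] <- as.integer(df[[cl]])
  for (cl in intersect(lgl, names(df))) df[[cl]] <- as.logical(df[[cl]])
  for (cl in intersect(chr, names(df))) df[[cl]] <- as.character(df[[cl]])
  for (cl in grep("^r2size", names(df), value = TRUE))
    df[[cl]] <- as.integer(df[[cl]])
  for (cl in grep("^r2cov", names(df), value = TRUE))
    df[[cl]] <- as.logical(df[[cl]])
  df
}

#' Run the full simulation grid
#'
#' Iterates the RAF x OR grid of `cfg`, running `cfg$replicates` replicates
#' per setting (each with a fresh region panel and a seed derived from the
#' master seed, the setting and the replicate index), and summarizes the
#' outcomes. When `cfg$out_dir` is set, per-replicate records are written
#' as one tab-delimited file per setting and existing records are reused,
#' so interrupted runs resume without recomputation and a completed run is
#' reproduced byte-identically.
#'
#' @param cfg A [grid_config()].
#' @param progress Print one line per completed setting.
#' @return A `grid_result`: `outcomes` (replicate records), `summary`
#'   (from [summarize_replicates()]) and the config.
#' @export
run_grid <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "grid_config"))
  settings <- expand.grid(raf = cfg$raf_levels, or = cfg$or_levels,
                          KEEP.OUT.ATTRS = FALSE)
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  all_rows <- list()
  for (k in seq_len(nrow(settings))) {
    raf <- settings$raf[k]
    or <- settings$or[k]
    rec_path <- if (!is.null(cfg$out_dir))
      file.path(cfg$out_dir, sprintf("records_raf%s_or%s.tsv", raf, or))
    done <- NULL
    if (!is.null(rec_path) && file.exists(rec_path)) {
      done <- normalize_records(
        as.data.frame(data.table::fread(rec_path, sep = "\t")))
    }
    todo <- seq_len(cfg$replicates)
    if (!is.null(done) && nrow(done))
      todo <- setdiff(todo, unique(done$replicate))
    new_rows <- lapply(todo, function(r) run_replicate(cfg, raf, or, r))
    rows <- c(if (!is.null(done) && nrow(done)) list(done), new_rows)
    rows <- do.call(rbind, rows)
    rows <- rows[order(rows$replicate, rows$scenario, rows$prior_w), ,
                 drop = FALSE]
    rownames(rows) <- NULL
    if (!is.null(rec_path) && length(new_rows))
      data.table::fwrite(rows, rec_path, sep = "\t", quote = FALSE)
    if (progress)
      message(sprintf("setting RAF %.2f OR %.2f: %d replicates", raf, or,
                      cfg$replicates))
    all_rows[[k]] <- rows
  }
  outcomes <- do.call(rbind, all_rows)
  summary <- summarize_replicates(
    outcomes,
    n_cases_total = cfg$n_studies * cfg$n_cases,
    n_controls_total = cfg$n_studies * cfg$n_controls,
    prevalence = cfg$prevalence, alpha = cfg$alpha)
  structure(list(outcomes = outcomes, summary = summary, config = cfg),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("grid_result: %d settings x %d replicates (%d outcome rows)\n",
              nrow(unique(x$outcomes[, c("raf", "or")])),
              x$config$replicates, nrow(x$outcomes)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Fine-map a summary-statistics file
#'
#' The entry point for external (e.g. published) GWAS summary statistics:
#' reads a tab-delimited summary file (see [read_sumstats()] for the
#' format), applies effective-sample-size rescaling, computes ABFs,
#' posteriors and credible sets, and optionally an LD comparator set when a
#' phased panel VCF is given.
#'
#' @param summary_path Path to the summary-statistics file.
#' @param panel_path Optional phased panel VCF for r-squared sets.
#' @param W ABF prior variance.
#' @param levels Credible levels.
#' @param prior_weights Optional per-variant prior weights (aligned with
#'   the file rows).
#' @param rescale,min_fraction Sample-size rescaling controls.
#' @param r2_threshold Optional r-squared threshold for the comparator set.
#' @return A list: `table` (per-variant posterior table with `log10_abf`,
#'   `posterior`, `cumulative`, `in_95`, `in_99`), `credible_sets`, and
#'   `r2_set` (or `NULL`).
#' @export
finemap_summary_file <- function(summary_path, panel_path = NULL, W = 0.04,
                                 levels = c(0.95, 0.99),
                                 prior_weights = NULL, rescale = TRUE,
                                 min_fraction = 0.7, r2_threshold = NULL) {
  meta <- read_sumstats(summary_path)
  usable <- is.finite(meta$beta) & is.finite(meta$se) & meta$se > 0
  meta <- meta[usable, , drop = FALSE]
  if (!nrow(meta)) stop("no usable variants in summary file")
  if (!is.null(prior_weights)) prior_weights <- prior_weights[usable]
  rescale <- rescale && all(is.finite(meta$n_eff))
  fm <- finemap_abf(meta, W = W, prior_weights = prior_weights,
                    levels = levels, rescale = rescale,
                    min_fraction = min_fraction)
  tab <- fm$table
  ord <- order(-ifelse(is.na(tab$posterior), -1, tab$posterior),
               -abs(tab$z), tab$position)
  tab <- tab[ord, , drop = FALSE]
  tab$cumulative <- cumsum(ifelse(is.na(tab$posterior), 0, tab$posterior))
  tab$log10_abf <- tab$log_abf / log(10)
  for (lv in levels) {
    cs <- fm$credible_sets[[sprintf("%g", lv)]]
    tab[[sprintf("in_%g", 100 * lv)]] <- tab$id %in% cs$variants
  }
  rownames(tab) <- NULL
  r2_set <- NULL
  if (!is.null(panel_path) && !is.null(r2_threshold)) {
    panel <- read_panel_vcf(panel_path)
    r2_set <- r2_proxy_set(meta, panel, r2_threshold)
  }
  list(table = tab, credible_sets = fm$credible_sets, r2_set = r2_set)
}
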