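#' Rank of the causal variant by association strength
#'
#' 1-based rank of the causal variant when variants are sorted by
#' descending `|z|` (ties broken by ascending position). A causal variant
#' removed by QC has no rank and is reported as censored (`NA`).
#'
#' @param meta A `meta_result` (post-QC).
#' @param causal_id Causal variant id.
#' @return Integer rank, or `NA` if the causal variant is absent.
#' @export
causal_rank <- function(meta, causal_id) {
  i <- match(causal_id, meta$id)
  if (is.na(i)) return(NA_integer_)
  ord <- order(-abs(meta$z), meta$position)
  match(i, ord)
}

#' Proportion of replicates whose credible set covers a causal variant
#'
#' @param outcomes A data frame of replicate outcomes (as produced by
#'   [run_grid()]), with logical columns `cov95`/`cov99`.
#' @param level Credible level (0.95 or 0.99).
#' @return Proportion in `[0, 1]`. Censored replicates (causal variant
#'   filtered out) count as not covered.
#' @export
coverage_rate <- function(outcomes, level = 0.95) {
  col <- sprintf("cov%g", 100 * level)
  stopifnot(nrow(outcomes) >= 1, col %in% names(outcomes))
  mean(outcomes[[col]] %in% TRUE)
}

#' Classify a fine-mapping outcome
#'
#' The four-way classification used to summarize fine-mapping success:
#' `causal_singleton` (set of exactly one variant containing the causal),
#' `causal_lt10` (set of 2-9 variants containing the causal),
#' `lt10_no_causal` (fewer than `success_threshold` variants but causal
#' absent) and `ge10` (at or above the threshold; "fewer than ten" is
#' strict, so a 10-variant set is `ge10`).
#'
#' @param size Credible-set size(s).
#' @param contains_causal Logical: does the set contain a causal variant.
#' @param success_threshold Success cut-off (default 10).
#' @return Factor with the four categories.
#' @export
classify_fine_mapping <- function(size, contains_causal,
                                  success_threshold = 10L) {
  stopifnot(length(size) == length(contains_causal))
  out <- ifelse(size >= success_threshold, "ge10",
         ifelse(contains_causal & size == 1L, "causal_singleton",
         ifelse(contains_causal, "causal_lt10", "lt10_no_causal")))
  factor(out, levels = c("causal_singleton", "causal_lt10",
                         "lt10_no_causal", "ge10"))
}

#' Analytic power of a case-control association test
#'
#' Computes the power to detect an additive allelic association at
#' significance `alpha` with a two-sample allele-frequency z-test
#' (comparable to Quanto's gene-only case-control calculation). Genotype
#' frequencies follow Hardy-Weinberg at the risk-allele frequency,
#' penetrances solve the prevalence constraint as in
#' [build_disease_model()], and the expected case allele frequency is
#' compared with the control frequency using `2n` alleles per group, with
#' the standard error evaluated under the alternative:
#' `power = Phi(-z_{alpha/2} + |p_case - p_ctrl| / SE) +
#'  Phi(-z_{alpha/2} - |p_case - p_ctrl| / SE)`.
#' At `OR = 1` the power equals `alpha` exactly.
#'
#' @param n_cases,n_controls Number of cases and controls.
#' @param raf Risk-allele frequency in the population.
#' @param or Allelic odds ratio.
#' @param prevalence Disease prevalence K.
#' @param alpha Two-sided significance level (default genome-wide 5e-8).
#' @param controls Control sampling: `"population"` (frequency equals the
#'   population frequency) or `"unaffected"` (frequency among unaffected
#'   individuals; at sub-percent prevalence the two are nearly identical).
#' @return Power in `[0, 1]`.
#' @export
power_case_control <- function(n_cases, n_controls, raf, or,
                               prevalence = 0.0055, alpha = 5e-8,
                               controls = c("population", "unaffected")) {
  controls <- match.arg(controls)
  stopifnot(n_cases > 0, n_controls > 0, alpha > 0, alpha < 1,
            or > 0, prevalence > 0, prevalence < 1)
  if (raf <= 0 || raf >= 1) stop("degenerate risk-allele frequency")
  p <- raf
  P_g <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  orv <- or^(0:2)
  f0 <- prevalence / sum(P_g * orv)
  f_g <- f0 * orv
  case_d <- P_g * f_g / prevalence
  p_case <- sum((0:2) * case_d) / 2
  p_ctrl <- if (controls == "population") p else {
    ctrl_d <- P_g * (1 - f_g) / (1 - prevalence)
    sum((0:2) * ctrl_d) / 2
  }
  a1 <- 2 * n_cases
  a0 <- 2 * n_controls
  se_alt <- sqrt(p_case * (1 - p_case) / a1 + p_ctrl * (1 - p_ctrl) / a0)
  za <- qnorm(1 - alpha / 2)
  d <- abs(p_case - p_ctrl) / se_alt
  pnorm(-za + d) + pnorm(-za - d)
}

#' Summarize fine-mapping replicate outcomes
#'
#' Aggregates per-replicate outcomes into per-setting performance:
#' coverage at each credible level, median and 90th-centile set sizes
#' (nearest-rank convention), success rates (set smaller than 10 variants),
#' the rate at which the causal variant is the lead (rank 1, censored
#' replicates excluded from the denominator but tallied), and analytic
#' power for the setting. The regression of log set size on power across
#' all replicates is attached as attribute `"size_power_fit"` (slope and
#' R-squared per level).
#'
#' @param outcomes Replicate outcome data frame from [run_grid()].
#' @param n_cases_total,n_controls_total Total meta-analysis sample sizes
#'   used for the power column.
#' @param prevalence,alpha Power-calculation parameters.
#' @return A data frame, one row per setting x scenario x prior.
#' @export
summarize_replicates <- function(outcomes, n_cases_total = 10000,
                                 n_controls_total = 10000,
                                 prevalence = 0.0055, alpha = 5e-8) {
  stopifnot(nrow(outcomes) >= 1)
  dt <- data.table::as.data.table(outcomes)
  keys <- intersect(c("raf", "or", "scenario", "n_afr", "prior_w",
                      "n_causal"), names(dt))
  summ <- dt[, list(
    n_replicates = .N,
    coverage95 = mean(cov95 %in% TRUE),
    coverage99 = mean(cov99 %in% TRUE),
    median_size95 = as.numeric(stats::median(size95)),
    median_size99 = as.numeric(stats::median(size99)),
    p90_size95 = as.numeric(nearest_rank_quantile(size95, 0.9)),
    p90_size99 = as.numeric(nearest_rank_quantile(size99, 0.9)),
    success95 = mean(size95 < 10),
    success99 = mean(size99 < 10),
    rank1_rate = {
      r <- rank[!censored]
      if (length(r)) mean(r == 1L) else NA_real_
    },
    n_censored = sum(censored)
  ), by = keys]
  out <- as.data.frame(summ)
  out$power <- vapply(seq_len(nrow(out)), function(i)
    power_case_control(n_cases_total, n_controls_total,
                       out$raf[i], out$or[i], prevalence, alpha),
    numeric(1))
  fits <- lapply(c(95, 99), function(lv) {
    sz <- outcomes[[sprintf("size%d", lv)]]
    pw <- out$power[match(
      interaction(outcomes$raf, outcomes$or),
      interaction(out$raf, out$or))]
    if (length(unique(pw)) < 2) return(c(slope = NA, r_squared = NA))
    fit <- stats::lm(log(sz) ~ pw)
    c(slope = unname(stats::coef(fit)[2]),
      r_squared = summary(fit)$r.squared)
  })
  names(fits) <- c("level95", "level99")
  attr(out, "size_power_fit") <- fits
  out
}
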