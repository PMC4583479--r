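#' Study-design scenario specification
#'
#' Three designs are supported: `"gold"` (full sequence data, no transform),
#' `"gwas"` (genotypes restricted to an array content mask; everything else
#' becomes untyped and must be imputed) and `"gwas_failure"` (additionally, a
#' random fraction of the array variants fails completely in the cohort).
#'
#' @param name One of `"gold"`, `"gwas"`, `"gwas_failure"`.
#' @param array_mask Character vector of variant ids on the array (required
#'   for the gwas scenarios).
#' @param failure_fraction Fraction of array variants whose genotypes are
#'   removed per cohort (gwas_failure only; default 0.05).
#' @param seed Integer seed for the per-cohort failure draw.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(name = c("gold", "gwas", "gwas_failure"),
                          array_mask = NULL, failure_fraction = 0,
                          seed = 1L) {
  name <- match.arg(name)
  if (name == "gold") {
    if (!is.null(array_mask) || failure_fraction > 0)
      stop("gold scenario takes no array mask and no failure")
  } else {
    if (is.null(array_mask) || !length(array_mask))
      stop("array mask empty under a gwas scenario")
    if (name == "gwas_failure" && failure_fraction <= 0)
      stop("gwas_failure requires failure_fraction > 0")
  }
  structure(list(name = name, array_mask = array_mask,
                 failure_fraction = failure_fraction,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Apply a study-design scenario transform to a simulated cohort
#'
#' `gold` returns the cohort unchanged. `gwas` flags all variants outside
#' the array mask as untyped and removes their genotypes (to be refilled by
#' [impute_study()]). `gwas_failure` additionally removes all genotypes of a
#' random `failure_fraction` of the array variants in this cohort.
#'
#' @param study A `study_genotypes` object.
#' @param scenario A [scenario_spec()].
#' @return A transformed `study_genotypes`.
#' @export
apply_scenario <- function(study, scenario) {
  stopifnot(inherits(study, "study_genotypes"),
            inherits(scenario, "scenario_spec"))
  if (scenario$name == "gold") return(study)
  ids <- study$variants$id
  if (!all(scenario$array_mask %in% ids))
    stop("array mask contains variants absent from the study")
  typed <- ids %in% scenario$array_mask
  study$typed <- typed
  study$dosages <- if (is.integer(study$dosages))
    mask_untyped_cpp(study$dosages, which(!typed))
  else {
    d <- study$dosages * 1.0
    d[, !typed] <- NA_real_
    d
  }
  study$info[!typed] <- NA_real_
  if (scenario$name == "gwas_failure") {
    with_seed(scenario$seed, {
      arr <- which(typed)
      n_fail <- round(scenario$failure_fraction * length(arr))
      if (n_fail > 0) {
        fail <- sample(arr, n_fail)
        study$failed[fail] <- TRUE
        study$dosages[, fail] <- NA_real_
        study$info[fail] <- NA_real_
      }
    })
  }
  study
}

#' Select a genotyping-array content mask from a panel
#'
#' Emulates a commercial array manifest: variants are drawn at the target
#' density with inclusion probability proportional to minor-allele frequency
#' (arrays favour common variants).
#'
#' @param panel A `haplotype_panel`.
#' @param density_per_mb Target array density (variants per megabase).
#' @param seed Integer seed.
#' @return Character vector of selected variant ids.
#' @export
select_array_mask <- function(panel, density_per_mb = 800, seed = 1L) {
  maf <- panel_maf(panel)
  n_target <- round(density_per_mb * panel$region_length / 1e6)
  if (n_target > length(maf))
    stop("array density exceeds panel density")
  if (n_target == length(maf)) return(panel$variants$id)
  with_seed(seed, {
    idx <- sample.int(length(maf), n_target, prob = maf)
    panel$variants$id[sort(idx)]
  })
}

#' Select a pair of weakly linked causal variants for multi-signal designs
#'
#' Finds two variants, both with MAF near `maf_target`, pairwise LD below
#' `max_r2`, and both inside the central `central_fraction` of the region
#' (the central 750 kb of a 1 Mb region by default).
#'
#' @param panel A `haplotype_panel`.
#' @param maf_target Target minor-allele frequency (default 0.10).
#' @param max_r2 Maximum pairwise r-squared (default 0.05).
#' @param central_fraction Central fraction of the region that must contain
#'   both variants.
#' @param maf_tol MAF matching tolerance (default 2 percentage points).
#' @param seed Integer seed (candidate order is randomized).
#' @return Character vector of two variant ids.
#' @export
select_multi_causal_pair <- function(panel, maf_target = 0.10, max_r2 = 0.05,
                                     central_fraction = 0.75, maf_tol = 0.02,
                                     seed = 1L) {
  maf <- panel_maf(panel)
  pos <- panel$variants$position
  margin <- (1 - central_fraction) / 2 * panel$region_length
  cand <- which(abs(maf - maf_target) <= maf_tol &
                  pos >= margin & pos <= panel$region_length - margin)
  pair <- NULL
  if (length(cand) >= 2) {
    pair <- with_seed(seed, {
      cand <- sample(cand)
      n_try <- min(length(cand), 40L)
      found <- NULL
      for (i in seq_len(n_try - 1L)) {
        if (!is.null(found)) break
        for (j in (i + 1L):n_try) {
          if (compute_r2(panel, cand[i], cand[j]) < max_r2) {
            found <- sort(c(cand[i], cand[j]))
            break
          }
        }
      }
      found
    })
  }
  if (is.null(pair))
    stop("no qualifying weakly-linked variant pair in panel")
  panel$variants$id[pair]
}
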