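#' QC thresholds for imputed variants
#'
#' @param info_min Minimum INFO score; the filter is strict (`INFO > 0.4`
#'   removes a variant at exactly 0.4).
#' @param maf_min Minimum minor-allele frequency; non-strict (`MAF >= 1%`
#'   retains a variant at exactly 0.01).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(info_min = 0.4, maf_min = 0.01) {
  stopifnot(info_min > 0, info_min < 1, maf_min > 0, maf_min < 1)
  structure(list(info_min = info_min, maf_min = maf_min),
            class = "qc_thresholds")
}

#' Fit a panel-LD linear imputation model
#'
#' For each untyped variant, fits a ridge-regularized linear regression of
#' its panel haplotype alleles on the `k_neighbors` nearest typed variants'
#' alleles, over the reference haplotypes. The fitted coefficients define an
#' expected-dosage predictor for study genotypes, and the ratio of predicted
#' to panel variance gives a theoretical INFO score. This is a deliberate
#' simplification of per-individual hidden-Markov haplotype imputation: one
#' regression per region instead of one HMM per individual, with
#' near-identical expected dosages for common variants.
#'
#' @param panel A `haplotype_panel` (the imputation reference).
#' @param array_mask Character vector of typed variant ids (variants failed
#'   in a cohort should be excluded before calling, so they are imputed like
#'   untyped variants).
#' @param k_neighbors Number of nearest typed predictor variants.
#' @param ridge Ridge penalty on the (haplotype-scale) covariance.
#' @param decay_scale Length scale (bp) of the exponential LD decay of the
#'   target samples relative to the panel. Study haplotypes produced by
#'   mosaic resampling lose correlation between sites distance `d` apart by
#'   a factor `exp(-d/decay_scale)`; the regression is fitted on the
#'   so-decayed covariances, i.e. on the LD the study individuals actually
#'   have, rather than on raw panel LD. Matches the cohort simulator's
#'   `switch_scale` (default 400 kb); `Inf` disables the adjustment.
#' @return An `imputation_model` with per-untyped-variant coefficients and
#'   theoretical INFO; untyped variants monomorphic in the panel are flagged
#'   unimputable (INFO 0, dosage imputed at twice the panel frequency).
#' @export
fit_imputation_model <- function(panel, array_mask, k_neighbors = 30L,
                                 ridge = 1e-4, decay_scale = 4e5) {
  stopifnot(inherits(panel, "haplotype_panel"), length(array_mask) >= 1)
  ids <- panel$variants$id
  typed <- which(ids %in% array_mask)
  if (!length(typed)) stop("array mask matches no panel variant")
  untyped <- setdiff(seq_along(ids), typed)
  k <- min(as.integer(k_neighbors), length(typed))
  pos <- panel$variants$position
  # the mosaic process of simulated cohorts switches sources only at block
  # boundaries, so LD decay acts on block-midpoint distance: two sites in
  # the same block never decorrelate. Panels without a block model fall
  # back to base-pair distance.
  dpos <- if (!is.null(panel$model)) {
    mids <- (panel$model$block_starts + panel$model$block_ends) / 2
    mids[panel$model$var_block]
  } else pos
  Hm <- panel$haplotypes
  Hn <- nrow(Hm)
  U <- length(untyped)
  nbr <- matrix(0L, k, U)
  coef <- matrix(0, k, U)
  icept <- numeric(U)
  info_theo <- numeric(U)
  unimputable <- logical(U)
  tpos <- pos[typed]
  for (j in seq_len(U)) {
    u <- untyped[j]
    o <- order(abs(tpos - pos[u]))[seq_len(k)]
    nbr[, j] <- typed[o]
    y <- Hm[, u]
    py <- mean(y)
    if (py <= 0 || py >= 1) {
      unimputable[j] <- TRUE
      icept[j] <- py
      next
    }
    X <- Hm[, nbr[, j], drop = FALSE]
    xm <- colMeans(X)
    Xc <- sweep(X, 2, xm)
    yc <- y - py
    Cxx <- crossprod(Xc) / Hn
    cxy <- crossprod(Xc, yc) / Hn
    if (is.finite(decay_scale)) {
      np <- dpos[nbr[, j]]
      Cxx <- Cxx * exp(-abs(outer(np, np, "-")) / decay_scale)
      cxy <- cxy * exp(-abs(np - dpos[u]) / decay_scale)
    }
    b <- solve(Cxx + diag(ridge, k), cxy)
    pred_var <- drop(crossprod(b, Cxx %*% b))
    # calibrate the linear score to a conditional-mean scale
    # (cov(pred, y) = var(pred)), as an HMM posterior dosage would be;
    # without this the dosage-variance INFO understates accuracy
    expl <- drop(crossprod(b, cxy))
    kappa <- if (pred_var > 0) expl / pred_var else 0
    b <- kappa * b
    vy <- mean(yc^2)
    info_theo[j] <- min(1, max(0, kappa^2 * pred_var / vy))
    coef[, j] <- b
    icept[j] <- py - sum(xm * b)
  }
  structure(list(untyped = untyped, typed = typed, nbr = nbr, coef = coef,
                 icept = icept, info_theo = info_theo,
                 unimputable = unimputable, k = k, ridge = ridge,
                 ids = ids, panel_freq = panel_freq(panel)),
            class = "imputation_model")
}

#' @export
print.imputation_model <- function(x, ...) {
  cat(sprintf("imputation_model: %d typed -> %d untyped variants (k = %d); median theoretical INFO %.3f\n",
              length(x$typed), length(x$untyped), x$k,
              stats::median(x$info_theo[!x$unimputable])))
  invisible(x)
}

#' Impute untyped variants in a study with expected dosages
#'
#' Fills the missing (untyped or failed) variant columns of a cohort with
#' expected dosages from the panel-LD linear predictor, clipped to
#' `[0, 2]`. The per-variant empirical INFO score is the MaCH-style dosage
#' variance ratio `Var(dosage) / (2 p (1 - p))` with `p` the mean imputed
#' allele frequency, capped at 1. Typed, non-failed variants keep their hard
#' calls and INFO 1.
#'
#' @param study A `study_genotypes` after [apply_scenario()].
#' @param model An [fit_imputation_model()] result whose typed set matches
#'   the study's observed variants.
#' @return The study with all dosages filled and `info`/`imputed` updated.
#' @export
impute_study <- function(study, model) {
  stopifnot(inherits(study, "study_genotypes"),
            inherits(model, "imputation_model"))
  observed <- which(study$typed & !study$failed)
  if (!setequal(observed, model$typed))
    stop("study's observed variants do not match the imputation model's typed set")
  U <- length(model$untyped)
  if (U == 0) return(study)
  D <- if (is.double(study$dosages)) study$dosages else study$dosages * 1.0
  filled <- impute_fill_cpp(D, as.integer(model$untyped), model$nbr,
                            model$coef, model$icept, model$unimputable,
                            2 * model$panel_freq[model$untyped])
  study$dosages <- filled$dosages
  study$info[model$untyped] <- filled$info
  study$imputed[model$untyped] <- TRUE
  study
}

#' Variant QC filter on INFO score and minor-allele frequency
#'
#' Retains variants with `INFO > info_min` (strict) and `MAF >= maf_min`
#' (non-strict). Typed variants carry INFO 1 and pass the INFO condition
#' automatically.
#'
#' @param meta A `meta_result`.
#' @param info Per-variant INFO (default: the minimum across contributing
#'   studies stored in `meta$info`; `NA` is treated as failing).
#' @param thresholds A [qc_thresholds()] object.
#' @return Logical vector over the rows of `meta`: `TRUE` = retained.
#' @export
qc_filter <- function(meta, info = meta$info, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  maf <- pmin(meta$eaf, 1 - meta$eaf)
  !is.na(info) & info > thresholds$info_min &
    !is.na(maf) & maf >= thresholds$maf_min
}
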