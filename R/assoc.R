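#' Per-variant logistic association scan
#'
#' Fits, for every variant, the maximum-likelihood additive logistic
#' regression of case status on dosage (Newton-Raphson, convergence
#' tolerance 1e-8, at most 25 iterations) and reports Wald effect estimates.
#' Individuals with a missing genotype at a variant are excluded at that
#' variant. Monomorphic variants and fits that do not converge (e.g. under
#' separation) are flagged, not returned as numbers. Imputed variants are
#' analyzed on their expected dosages.
#'
#' @param study A `study_genotypes` object.
#' @param tol,maxit Newton-Raphson controls.
#' @return An `assoc_result` data frame with per-variant columns `id`,
#'   `position`, `ea`/`nea` (effect = alternate allele), `eaf`, `beta`,
#'   `se`, `z`, `n_eff` (effective sample size `4/(1/n_case + 1/n_ctrl)`
#'   among non-missing individuals), `info` and `status`
#'   (`ok`/`monomorphic`/`unstable`).
#' @export
association_scan <- function(study, tol = 1e-8, maxit = 25L) {
  stopifnot(inherits(study, "study_genotypes"))
  if (length(unique(study$phenotype)) < 2)
    stop("both phenotype classes must be present")
  fit <- if (is.integer(study$dosages))
    logit_scan_int_cpp(study$dosages, study$phenotype,
                       tol = tol, maxit = as.integer(maxit))
  else
    logit_scan_cpp(study$dosages, study$phenotype,
                   tol = tol, maxit = as.integer(maxit))
  status <- c("ok", "monomorphic", "unstable")[fit$status + 1L]
  n_eff <- ifelse(fit$n_case > 0 & fit$n_ctrl > 0,
                  4 / (1 / fit$n_case + 1 / fit$n_ctrl), 0)
  res <- data.frame(
    id = study$variants$id, position = study$variants$position,
    ea = study$variants$alt, nea = study$variants$ref,
    eaf = fit$eaf, beta = fit$beta, se = fit$se,
    z = fit$beta / fit$se, n_eff = n_eff, info = study$info,
    status = status, stringsAsFactors = FALSE)
  if (all(res$status != "ok"))
    warning("no variant could be tested in study ", study$study_id)
  attr(res, "study_id") <- study$study_id
  attr(res, "population") <- study$population
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Fixed-effects inverse-variance meta-analysis across cohorts
#'
#' Combines per-study association results by inverse-variance weighting:
#' `beta_meta = sum(w_i b_i) / sum(w_i)` and `se_meta = 1/sqrt(sum w_i)`
#' with `w_i = 1/se_i^2`. A variant flagged (monomorphic/unstable) or absent
#' in a study simply omits that study; the total effective sample size is
#' the sum over contributing studies. Studies must agree on effect/other
#' alleles; a mismatch is an error naming the variant.
#'
#' @param results List of `assoc_result` objects over the same variant list.
#' @return A `meta_result` data frame with columns `id`, `position`, `ea`,
#'   `nea`, `eaf` (n_eff-weighted), `beta`, `se`, `z`, `n_eff`,
#'   `n_studies` and `info` (minimum INFO across contributing studies);
#'   the per-study presence mask is attached as attribute `"presence"`.
#' @export
meta_analyze <- function(results) {
  stopifnot(is.list(results), length(results) >= 1)
  ref <- results[[1]]
  for (s in seq_along(results)) {
    r <- results[[s]]
    if (!identical(r$id, ref$id))
      stop("studies report different variant lists")
    mism <- which(r$ea != ref$ea | r$nea != ref$nea)
    if (length(mism))
      stop("allele mismatch between studies at variant ", ref$id[mism[1]])
  }
  M <- nrow(ref)
  S <- length(results)
  ok <- vapply(results, function(r) r$status == "ok" & is.finite(r$se) &
                 r$se > 0, logical(M))
  ok <- matrix(ok, M, S)
  w <- vapply(results, function(r) 1 / r$se^2, numeric(M))
  b <- vapply(results, function(r) r$beta, numeric(M))
  ne <- vapply(results, function(r) r$n_eff, numeric(M))
  af <- vapply(results, function(r) r$eaf, numeric(M))
  inf <- vapply(results, function(r) r$info, numeric(M))
  w <- matrix(w, M, S); b <- matrix(b, M, S)
  ne <- matrix(ne, M, S); af <- matrix(af, M, S); inf <- matrix(inf, M, S)
  w[!ok] <- 0
  sw <- rowSums(w)
  beta <- rowSums(w * ifelse(ok, b, 0)) / sw
  se <- 1 / sqrt(sw)
  n_eff <- rowSums(ne * ok)
  n_studies <- rowSums(ok)
  eaf <- rowSums(af * ne * ok) / pmax(rowSums(ne * ok), 1e-300)
  info_min <- suppressWarnings(apply(ifelse(ok, inf, NA), 1, min, na.rm = TRUE))
  info_min[!is.finite(info_min)] <- NA_real_
  beta[n_studies == 0] <- NA_real_
  se[n_studies == 0] <- NA_real_
  out <- data.frame(
    id = ref$id, position = ref$position, ea = ref$ea, nea = ref$nea,
    eaf = eaf, beta = beta, se = se, z = beta / se, n_eff = n_eff,
    n_studies = n_studies, info = info_min, stringsAsFactors = FALSE)
  attr(out, "presence") <- ok
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Read and write GWAS summary statistics
#'
#' Tab-delimited format with header `SNPID CHR POS EA NEA EAF BETA SE Z
#' N_EFF N_STUDIES [INFO]` — the interface through which externally
#' published summary statistics enter the fine-mapping functions. `POS` is
#' 1-based in the file.
#'
#' @param meta A `meta_result` (or compatible data frame).
#' @param path File path.
#' @param chr Chromosome label to write.
#' @return `read_sumstats` returns a `meta_result`; `write_sumstats`
#'   returns `path` invisibly.
#' @export
write_sumstats <- function(meta, path, chr = "1") {
  out <- data.table::data.table(
    SNPID = meta$id, CHR = chr, POS = meta$position + 1L, EA = meta$ea,
    NEA = meta$nea, EAF = meta$eaf, BETA = meta$beta, SE = meta$se,
    Z = meta$z, N_EFF = meta$n_eff, N_STUDIES = meta$n_studies,
    INFO = if (!is.null(meta$info)) meta$info else 1)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  required <- c("SNPID", "POS", "EA", "NEA", "BETA", "SE")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop("summary-statistics file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(
    id = as.character(dt$SNPID), position = as.integer(dt$POS) - 1L,
    ea = dt$EA, nea = dt$NEA,
    eaf = if ("EAF" %in% names(dt)) dt$EAF else NA_real_,
    beta = dt$BETA, se = dt$SE,
    z = if ("Z" %in% names(dt)) dt$Z else dt$BETA / dt$SE,
    n_eff = if ("N_EFF" %in% names(dt)) dt$N_EFF else NA_real_,
    n_studies = if ("N_STUDIES" %in% names(dt)) dt$N_STUDIES else 1L,
    info = if ("INFO" %in% names(dt)) dt$INFO else 1,
    stringsAsFactors = FALSE)
  class(out) <- c("meta_result", "data.frame")
  out
}
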