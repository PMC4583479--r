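#' Wakefield log approximate Bayes factor for association
#'
#' With `V = se^2`, shrinkage factor `r = W/(V + W)` and `z = beta/se`, the
#' log Bayes factor in favour of association is
#' `log BF = 0.5 * log(1 - r) + z^2 * r / 2`,
#' which equals the normal-normal marginal likelihood ratio
#' `log[N(beta; 0, V + W) / N(beta; 0, V)]`. Larger values mean more
#' evidence for association (the reciprocal orientation of the null-favoring
#' form, matching the use of ABFs as evidence for association).
#'
#' @param beta Effect estimate (log odds ratio); vectorized.
#' @param se Standard error (> 0).
#' @param W Prior variance of the log odds ratio under association. The
#'   default 0.04 (prior SD 0.2) encodes a 95% belief that the relative
#'   risk under association is below 1.5, since `(log(1.5)/1.96)^2 ~ 0.04`.
#' @return Log Bayes factor(s).
#' @export
log_abf <- function(beta, se, W = 0.04) {
  if (any(se <= 0, na.rm = TRUE)) stop("se must be positive")
  stopifnot(W > 0)
  V <- se^2
  r <- W / (V + W)
  0.5 * log1p(-r) + (beta / se)^2 * r / 2
}

#' Rescale per-variant variances to the maximum effective sample size
#'
#' Variants analyzed on fewer samples (e.g. after per-cohort genotype
#' failure) have inflated variance; before computing ABFs their variance is
#' rescaled as if observed at the maximum effective sample size,
#' `V' = V * n_eff / n_max` (variance is inversely proportional to sample
#' size). Variants whose `n_eff` falls below `min_fraction` of the maximum
#' (default 70%, i.e. more than 30% below) are instead flagged
#' `excluded_low_n` and left out of the posterior normalization.
#'
#' @param meta A `meta_result`.
#' @param n_max Maximum observed effective sample size (default: maximum of
#'   `meta$n_eff`).
#' @param min_fraction Minimum `n_eff/n_max` for a variant to be rescaled
#'   rather than excluded.
#' @return `meta` with adjusted `se`, plus logical columns `rescaled` and
#'   `excluded_low_n`.
#' @export
rescale_to_max_n <- function(meta, n_max = max(meta$n_eff, na.rm = TRUE),
                             min_fraction = 0.7) {
  if (!is.finite(n_max) || n_max <= 0) stop("n_max must be positive")
  frac <- meta$n_eff / n_max
  if (any(frac > 1 + 1e-9, na.rm = TRUE))
    stop("n_eff exceeds n_max")
  excl <- !is.na(frac) & frac < min_fraction
  scale_ok <- !excl & !is.na(frac) & frac < 1
  meta$se[scale_ok] <- meta$se[scale_ok] * sqrt(frac[scale_ok])
  meta$rescaled <- scale_ok
  meta$excluded_low_n <- excl
  meta
}

#' Posterior probabilities of causality from log Bayes factors
#'
#' Under the single-causal-variant assumption, the posterior for variant j
#' is `w_j BF_j / sum_k w_k BF_k`, computed stably in log space.
#'
#' @param log_bfs Per-variant log Bayes factors.
#' @param prior_weights Positive per-variant prior weights (default
#'   uniform); only relative magnitudes matter.
#' @return Posterior probabilities summing to 1.
#' @export
posterior_probabilities <- function(log_bfs, prior_weights = NULL) {
  n <- length(log_bfs)
  if (n == 0) stop("no included variants")
  if (is.null(prior_weights)) prior_weights <- rep(1, n)
  stopifnot(length(prior_weights) == n, all(prior_weights > 0))
  lw <- log_bfs + log(prior_weights)
  exp(lw - logsumexp(lw))
}

#' Assemble a credible set from posterior probabilities
#'
#' Variants are sorted by descending posterior (ties broken by descending
#' `|z|`, then ascending position) and the smallest prefix with cumulative
#' posterior at or above `level` is taken.
#'
#' @param posteriors Normalized posterior probabilities.
#' @param level Credible level in (0, 1), e.g. 0.95 or 0.99.
#' @param ids Variant identifiers (default: indices).
#' @param z,position Tie-breaking statistics (optional).
#' @return A `credible_set`: ordered variant ids, the cumulative posterior
#'   at the boundary, and the set size.
#' @export
credible_set <- function(posteriors, level, ids = seq_along(posteriors),
                         z = NULL, position = NULL) {
  stopifnot(level > 0, level < 1)
  n <- length(posteriors)
  z2 <- if (is.null(z)) rep(0, n) else abs(z)
  pos <- if (is.null(position)) seq_len(n) else position
  ord <- order(-posteriors, -z2, pos)
  cum <- cumsum(posteriors[ord])
  size <- which(cum >= level - 1e-12)[1]
  if (is.na(size)) size <- n
  structure(list(level = level, variants = ids[ord[seq_len(size)]],
                 cumulative = cum[size], size = size),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("%g%% credible set: %d variant(s), cumulative posterior %.4f\n",
              100 * x$level, x$size, x$cumulative))
  invisible(x)
}

#' Fine-map a locus from meta-analysis summary statistics
#'
#' Runs the full approximate-Bayes-factor fine-mapping step: optional
#' effective-sample-size rescaling, per-variant log ABFs, prior-weighted
#' posteriors and credible sets at the requested levels.
#'
#' @param meta A `meta_result` restricted to the variants to fine-map
#'   (after QC).
#' @param W Prior variance of the log odds ratio (see [log_abf()]).
#' @param prior_weights Per-variant positive prior weights (default
#'   uniform); e.g. 10 on coding variants for a functional prior.
#' @param levels Credible levels.
#' @param rescale Apply [rescale_to_max_n()] first.
#' @param min_fraction Exclusion threshold for the rescaling rule.
#' @return A `finemap_result`: the per-variant table (`id`, `position`,
#'   `z`, `V`, `r`, `log_abf`, `prior`, `posterior`, flags) and a list of
#'   `credible_set`s named by level.
#' @export
finemap_abf <- function(meta, W = 0.04, prior_weights = NULL,
                        levels = c(0.95, 0.99), rescale = TRUE,
                        min_fraction = 0.7) {
  stopifnot(nrow(meta) >= 1)
  if (rescale && all(is.finite(meta$n_eff)))
    meta <- rescale_to_max_n(meta, min_fraction = min_fraction)
  else {
    meta$rescaled <- FALSE
    meta$excluded_low_n <- FALSE
  }
  n <- nrow(meta)
  if (is.null(prior_weights)) prior_weights <- rep(1, n)
  stopifnot(length(prior_weights) == n)
  inc <- !meta$excluded_low_n
  if (!any(inc)) stop("all variants excluded from posterior normalization")
  labf <- log_abf(meta$beta, meta$se, W)
  posterior <- rep(NA_real_, n)
  posterior[inc] <- posterior_probabilities(labf[inc], prior_weights[inc])
  tab <- data.frame(
    id = meta$id, position = meta$position, z = meta$beta / meta$se,
    V = meta$se^2, r = W / (meta$se^2 + W), log_abf = labf,
    prior = prior_weights / sum(prior_weights[inc]),
    posterior = posterior, rescaled = meta$rescaled,
    excluded_low_n = meta$excluded_low_n, stringsAsFactors = FALSE)
  sets <- lapply(levels, function(lv)
    credible_set(posterior[inc], lv, ids = meta$id[inc], z = tab$z[inc],
                 position = meta$position[inc]))
  names(sets) <- sprintf("%g", levels)
  structure(list(table = tab, credible_sets = sets, W = W),
            class = "finemap_result")
}

#' @export
print.finemap_result <- function(x, ...) {
  cat(sprintf("finemap_result: %d variants, W = %g\n", nrow(x$table), x$W))
  for (s in x$credible_sets) print(s)
  invisible(x)
}

#' r-squared proxy comparator set around the lead variant
#'
#' The heuristic fine-mapping comparator: take the lead variant (maximum
#' `|z|`) and all variants whose panel LD with it exceeds the threshold.
#' The lead itself is always in the set.
#'
#' @param meta A `meta_result` (post-QC).
#' @param panel The `haplotype_panel` on which to compute LD (the majority
#'   ancestry's panel in mixed designs).
#' @param threshold r-squared threshold, conventionally 0.5, 0.8 or 0.9.
#' @return Character vector of variant ids; the lead id is attached as
#'   attribute `"lead"`.
#' @export
r2_proxy_set <- function(meta, panel, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  lead_i <- which.max(abs(meta$z))
  lead <- meta$id[lead_i]
  r2 <- r2_to_lead(panel, lead)
  ids_in_panel <- panel$variants$id
  r2m <- r2[match(meta$id, ids_in_panel)]
  set <- meta$id[!is.na(r2m) & r2m > threshold]
  set <- union(lead, set)
  attr(set, "lead") <- lead
  set
}
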