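#' Build an additive case-control disease model on a panel
#'
#' Assigns one or two causal variants with allelic odds ratios and solves the
#' genotype penetrances `f_g = f0 * OR^g` (multiplicative across causal loci
#' on the odds-ratio scale) so that the population prevalence constraint
#' `sum_g P(g) f_g = K` holds exactly under the panel's genotype
#' distribution. For a single causal variant the genotype distribution is
#' Hardy-Weinberg at the realized risk-allele frequency; for a pair it is the
#' random union of the panel's two-locus haplotypes.
#'
#' @param panel A `haplotype_panel`.
#' @param causal_spec A data frame with one row per causal variant and
#'   columns `or` (allelic odds ratio, 1.0 = null model) plus either `id`
#'   (explicit variant) or `raf` (target risk-allele frequency; one variant
#'   is chosen uniformly at random among those with either allele frequency
#'   within `raf_tol` of the target, using the current RNG state — seed the
#'   call for reproducibility). Optional columns: `coding` (restrict the
#'   RAF search to coding variants) and `risk_allele` (`"ref"`/`"alt"`,
#'   to force the orientation when selecting by id).
#' @param prevalence Disease prevalence K (default 0.55%, an ankylosing
#'   spondylitis-like disease).
#' @param raf_tol RAF matching tolerance (absolute, default 0.5 percentage
#'   points).
#' @return A `disease_model` object.
#' @export
build_disease_model <- function(panel, causal_spec, prevalence = 0.0055,
                                raf_tol = 0.005) {
  stopifnot(inherits(panel, "haplotype_panel"),
            prevalence > 0, prevalence < 1)
  cs <- as.data.frame(causal_spec)
  stopifnot(nrow(cs) %in% c(1L, 2L), "or" %in% names(cs), all(cs$or > 0))
  freq <- panel_freq(panel)
  pick <- lapply(seq_len(nrow(cs)), function(j) {
    row <- cs[j, ]
    if (!is.null(row$id) && !is.na(row$id)) {
      idx <- match(row$id, panel$variants$id)
      if (is.na(idx)) stop("causal variant not in panel: ", row$id)
      ra <- if (!is.null(row$risk_allele) && !is.na(row$risk_allele))
        row$risk_allele else "alt"
      return(list(index = idx, risk_allele = ra,
                  raf = if (ra == "alt") freq[idx] else 1 - freq[idx]))
    }
    cand <- seq_along(freq)
    if (isTRUE(row$coding)) cand <- cand[panel$variants$is_coding[cand]]
    if (!length(cand)) stop("no candidate causal variant (coding mask empty)")
    d_alt <- abs(freq[cand] - row$raf)
    d_ref <- abs((1 - freq[cand]) - row$raf)
    use_alt <- d_alt <= d_ref
    d <- pmin(d_alt, d_ref)
    ok <- which(d <= raf_tol)
    if (!length(ok))
      stop(sprintf("no variant within %.3f of RAF %.3f", raf_tol, row$raf))
    # uniform choice among qualifying variants ("a causal variant of
    # specified RAF"), not nearest-match: nearest-match over-samples
    # variants with unusual haplotype patterns, because perfect proxies
    # share a single frequency value
    best <- ok[sample.int(length(ok), 1L)]
    idx <- cand[best]
    ra <- if (use_alt[best]) "alt" else "ref"
    list(index = idx, risk_allele = ra,
         raf = if (ra == "alt") freq[idx] else 1 - freq[idx])
  })
  causal <- data.frame(
    id = panel$variants$id[vapply(pick, `[[`, 1L, "index")],
    index = vapply(pick, `[[`, 1L, "index"),
    risk_allele = vapply(pick, `[[`, "", "risk_allele"),
    or = cs$or,
    raf = vapply(pick, `[[`, 0, "raf"),
    stringsAsFactors = FALSE)

  if (nrow(causal) == 1L) {
    p <- causal$raf[1]
    P_g <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    or_mult <- causal$or[1]^(0:2)
  } else {
    q2 <- joint_hap_freq(panel, causal)        # 2 x 2 haplotype classes
    P_g <- genotype_joint_from_hap(q2)         # 3 x 3 genotype joint
    or_mult <- outer(causal$or[1]^(0:2), causal$or[2]^(0:2))
  }
  f0 <- prevalence / sum(P_g * or_mult)
  f_g <- f0 * or_mult
  if (any(f_g >= 1))
    stop("penetrance >= 1: effect too strong for this prevalence")
  if (abs(sum(P_g * f_g) - prevalence) > 1e-10)
    stop("internal error: prevalence constraint not satisfied")
  structure(list(causal = causal, prevalence = prevalence, f0 = f0,
                 P_g = P_g, f_g = f_g,
                 case_dist = P_g * f_g / prevalence,
                 control_dist = P_g * (1 - f_g) / (1 - prevalence)),
            class = "disease_model")
}

# risk-allele-coded haplotype alleles at one causal variant
risk_hap_allele <- function(panel, causal, j) {
  h <- panel$haplotypes[, causal$index[j]]
  if (causal$risk_allele[j] == "ref") 1L - h else h
}

joint_hap_freq <- function(panel, causal) {
  a1 <- risk_hap_allele(panel, causal, 1)
  a2 <- risk_hap_allele(panel, causal, 2)
  q <- matrix(0, 2, 2)
  for (x in 0:1) for (y in 0:1) q[x + 1, y + 1] <- mean(a1 == x & a2 == y)
  q
}

genotype_joint_from_hap <- function(q) {
  P <- matrix(0, 3, 3)
  for (x1 in 0:1) for (y1 in 0:1) for (x2 in 0:1) for (y2 in 0:1)
    P[x1 + x2 + 1, y1 + y2 + 1] <- P[x1 + x2 + 1, y1 + y2 + 1] +
      q[x1 + 1, y1 + 1] * q[x2 + 1, y2 + 1]
  P
}

#' Expected risk-allele frequency in cases or controls under a disease model
#'
#' @param model A `disease_model`.
#' @param group `"case"` or `"control"`.
#' @param which Causal variant index (1 or 2).
#' @return Expected risk-allele frequency.
#' @export
expected_raf <- function(model, group = c("case", "control"), which = 1L) {
  group <- match.arg(group)
  d <- if (group == "case") model$case_dist else model$control_dist
  if (nrow(model$causal) == 1L) sum((0:2) * d) / 2
  else if (which == 1L) sum((0:2) * rowSums(d)) / 2
  else sum((0:2) * colSums(d)) / 2
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf("disease_model: K = %.4g, f0 = %.4g\n", x$prevalence, x$f0))
  print(x$causal, row.names = FALSE)
  invisible(x)
}

#' Simulate a case-control cohort by conditional haplotype resampling
#'
#' Retrospective, genotype-first sampling: each case draws its causal
#' genotype from `P(g | case)` and each control from `P(g | control)`
#' (controls are unaffected individuals, not population samples), then the
#' individual's two haplotypes are assembled as block mosaics of panel
#' haplotypes anchored at the causal variant, so that local LD is preserved
#' while individuals are not verbatim panel copies. The mosaic switches
#' source haplotype at block boundaries at a rate of one expected switch per
#' `switch_scale` base pairs.
#'
#' @param panel A synthesized `haplotype_panel` (block model required).
#' @param model A `disease_model` built on the same panel.
#' @param n_cases,n_controls Cohort arm sizes.
#' @param seed Integer seed.
#' @param study_id Label carried into downstream summary statistics.
#' @param switch_scale Mosaic re-switching length scale in bp. The default,
#'   one expected switch per 400 kb, is the Li-Stephens rate of copying a
#'   200-haplotype panel (4 Ne r / H with Ne = 1e4, r = 1.2e-8 per bp).
#' @return A `study_genotypes` object: integer dosage matrix
#'   (individuals x variants), phenotype vector (1 = case), per-variant
#'   typed/failed flags and INFO scores (1 before any scenario transform).
#' @export
simulate_case_control <- function(panel, model, n_cases = 1000L,
                                  n_controls = 1000L, seed = 1L,
                                  study_id = "study1",
                                  switch_scale = 4e5) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(model, "disease_model"))
  if (is.null(panel$model))
    stop("cohort simulation requires a synthesized panel (block model)")
  m <- panel$model
  H_n <- nrow(panel$haplotypes)
  B <- length(m$block_starts)
  mids <- (m$block_starts + m$block_ends) / 2
  sw <- 1 - exp(-diff(mids) / switch_scale)
  N <- n_cases + n_controls
  y <- c(rep(1L, n_cases), rep(0L, n_controls))
  with_seed(seed, {
    if (nrow(model$causal) == 1L) {
      g <- c(sample(0:2, n_cases, TRUE, model$case_dist),
             sample(0:2, n_controls, TRUE, model$control_dist))
      # split genotype onto two haplotypes
      a1 <- integer(N); a2 <- integer(N)
      a1[g == 2] <- 1L; a2[g == 2] <- 1L
      het <- which(g == 1L)
      side <- runif(length(het)) < 0.5
      a1[het[side]] <- 1L; a2[het[!side]] <- 1L
      req <- c(a1, a2)                       # 2N required causal alleles
      rall <- risk_hap_allele(panel, model$causal, 1)
      carriers <- list(which(rall == 0L), which(rall == 1L))
      for (a in 0:1)
        if (any(req == a) && !length(carriers[[a + 1]]))
          stop("required causal-allele haplotype class empty in panel")
      init <- integer(2 * N)
      for (a in 0:1) {
        k <- which(req == a)
        if (length(k))
          init[k] <- carriers[[a + 1]][sample.int(length(carriers[[a + 1]]),
                                                  length(k), replace = TRUE)]
      }
      anchor <- m$var_block[model$causal$index[1]]
      S <- mosaic_states(H_n, B, anchor, init, sw)
    } else {
      S <- simulate_pair_states(panel, model, n_cases, n_controls, sw)
    }
    s1 <- S[seq_len(N), , drop = FALSE]
    s2 <- S[N + seq_len(N), , drop = FALSE]
    dos <- assemble_dosage(panel$haplotypes, s1, s2, m$var_block)
    new_study_genotypes(dos, y, panel, study_id)
  })
}

new_study_genotypes <- function(dosages, phenotype, panel, study_id) {
  M <- ncol(dosages)
  structure(list(dosages = dosages, phenotype = phenotype,
                 variants = panel$variants[, c("id", "position", "ref", "alt",
                                               "is_coding")],
                 study_id = study_id, population = panel$population,
                 typed = rep(TRUE, M), failed = rep(FALSE, M),
                 imputed = rep(FALSE, M), info = rep(1, M),
                 n_cases = sum(phenotype == 1L),
                 n_controls = sum(phenotype == 0L)),
            class = "study_genotypes")
}

#' @export
print.study_genotypes <- function(x, ...) {
  cat(sprintf("study_genotypes %s (%s): %d cases / %d controls x %d variants; %d typed, %d failed, %d imputed\n",
              x$study_id, x$population, x$n_cases, x$n_controls,
              ncol(x$dosages), sum(x$typed & !x$failed), sum(x$failed),
              sum(x$imputed)))
  invisible(x)
}

# Block-mosaic source chain: anchored at `anchor_b` with given initial
# sources, switching to a uniformly random panel haplotype at each boundary
# with the per-boundary probabilities `sw`.
mosaic_states <- function(H_n, B, anchor_b, init, sw) {
  mosaic_states_cpp(H_n, B, anchor_b, as.integer(init), sw)
}

# Mosaic states for the two-causal-variant model: haplotypes are anchored at
# the first causal variant's block with a source carrying both required
# alleles; if switches occur before the second causal block, the chain is
# re-anchored there onto a carrier of the required second allele.
simulate_pair_states <- function(panel, model, n_cases, n_controls, sw) {
  m <- panel$model
  H_n <- nrow(panel$haplotypes)
  B <- length(m$block_starts)
  N <- n_cases + n_controls
  ord <- order(m$var_block[model$causal$index])
  causal <- model$causal[ord, ]
  b1 <- m$var_block[causal$index[1]]
  b2 <- m$var_block[causal$index[2]]
  # joint genotype draw (distributions are on the original causal order)
  dist_case <- model$case_dist; dist_ctrl <- model$control_dist
  if (!identical(ord, 1:2)) { dist_case <- t(dist_case); dist_ctrl <- t(dist_ctrl) }
  draw_joint <- function(n, d) {
    k <- sample.int(9L, n, TRUE, as.vector(d))
    cbind((k - 1L) %% 3L, (k - 1L) %/% 3L)
  }
  G <- rbind(draw_joint(n_cases, dist_case), draw_joint(n_controls, dist_ctrl))
  r1 <- risk_hap_allele(panel, causal, 1)
  r2 <- risk_hap_allele(panel, causal, 2)
  qcls <- matrix(0, 2, 2)
  cls <- vector("list", 4)
  for (x in 0:1) for (yv in 0:1) {
    idx <- which(r1 == x & r2 == yv)
    cls[[x + 2 * yv + 1]] <- idx
    qcls[x + 1, yv + 1] <- length(idx) / H_n
  }
  # split each individual's joint genotype onto two haplotype classes
  hap_req <- matrix(0L, 2 * N, 2)
  for (i in seq_len(N)) {
    g1 <- G[i, 1]; g2 <- G[i, 2]
    opts <- list(); wts <- numeric(0)
    for (x1 in max(0, g1 - 1):min(1, g1)) for (x2 in max(0, g2 - 1):min(1, g2)) {
      w <- qcls[x1 + 1, x2 + 1] * qcls[g1 - x1 + 1, g2 - x2 + 1]
      opts <- c(opts, list(c(x1, x2))); wts <- c(wts, w)
    }
    if (sum(wts) <= 0)
      stop("required causal-allele haplotype class empty in panel")
    pickk <- opts[[sample.int(length(opts), 1, prob = wts)]]
    hap_req[i, ] <- pickk
    hap_req[N + i, ] <- c(G[i, 1] - pickk[1], G[i, 2] - pickk[2])
  }
  init <- integer(2 * N)
  for (x in 0:1) for (yv in 0:1) {
    k <- which(hap_req[, 1] == x & hap_req[, 2] == yv)
    pool <- cls[[x + 2 * yv + 1]]
    if (length(k)) {
      if (!length(pool))
        stop("required causal-allele haplotype class empty in panel")
      init[k] <- pool[sample.int(length(pool), length(k), replace = TRUE)]
    }
  }
  S <- mosaic_states(H_n, B, b1, init, sw)
  if (b2 != b1) {
    # re-anchor at the second causal block where switching broke the allele
    need <- hap_req[, 2]
    bad <- which(r2[S[, b2]] != need)
    if (length(bad)) {
      old_src <- S[bad, b2]
      pools <- list(which(r2 == 0L), which(r2 == 1L))
      for (a in 0:1) {
        k <- bad[need[bad] == a]
        if (length(k)) {
          if (!length(pools[[a + 1]]))
            stop("required causal-allele haplotype class empty in panel")
          S[k, b2] <- pools[[a + 1]][sample.int(length(pools[[a + 1]]),
                                                length(k), replace = TRUE)]
        }
      }
      # propagate the corrected source forward until the next mosaic switch
      if (b2 < B) for (b in (b2 + 1):B) {
        stayed <- S[bad, b] == old_src
        bad <- bad[stayed]
        old_src <- old_src[stayed]
        if (!length(bad)) break
        S[bad, b] <- S[bad, b - 1]
      }
    }
  }
  S
}
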