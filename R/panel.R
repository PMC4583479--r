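#' Parameters of the blockwise haplotype-panel model
#'
#' The panel generator uses a blockwise mosaic model rather than a coalescent
#' simulator: the region is partitioned into LD blocks with exponentially
#' distributed lengths, each block carries a small number of distinct
#' "block-haplotypes" with Dirichlet-distributed frequencies, and each panel
#' haplotype is a Markov chain of block-haplotype choices that is carried
#' across block boundaries with probability `inter_block_correlation`.
#' Variants are placed uniformly and assigned alleles on subsets of
#' block-haplotypes so that folded minor-allele frequencies follow a density
#' proportional to 1/p on `[maf_min, 0.5]`.
#'
#' @param n_haplotypes Even number of phased haplotypes in the panel
#'   (default 200, the order of the 85-88 individuals of a 1000 Genomes
#'   population panel).
#' @param target_density Number of MAF >= `maf_min` variants per megabase
#'   (default 3000, the order of 1000 Genomes common-variant density).
#' @param block_length_mean Mean LD-block length in base pairs.
#' @param haplotypes_per_block Number of distinct block-haplotypes per block.
#' @param inter_block_correlation Probability that a haplotype keeps its
#'   aligned block-haplotype choice across a block boundary; governs
#'   cross-block LD decay.
#' @param fst Balding-Nichols drift parameter used when deriving a second
#'   population; in `[0, 1)`.
#' @param recomb_scale Block-subdivision factor for the diverged population
#'   (>1 shortens LD, emulating e.g. African-ancestry panels).
#' @param dirichlet_alpha Symmetric Dirichlet concentration for
#'   block-haplotype frequencies.
#' @param block_freq_drift Concentration of the Dirichlet random walk that
#'   evolves block-haplotype frequencies along the region: block b+1's
#'   frequency vector is drawn from `Dirichlet(block_freq_drift * f_b)`.
#'   Larger is smoother; `Inf` makes blocks independent draws. A slowly
#'   drifting composition gives low-frequency alleles the long-haplotype
#'   signature (and hence array-imputability) that real variants have.
#' @param maf_min Lower truncation of the folded frequency spectrum; variants
#'   rarer than this are not generated (downstream QC discards them anyway).
#' @param exons_per_mb,exon_length Number and length (bp) of synthetic "exon"
#'   intervals per megabase used to flag `is_coding` variants for
#'   functional-prior scenarios.
#' @param seed Integer seed; panel generation is fully deterministic given
#'   the parameters and the seed.
#' @return An object of class `panel_params` (a validated list).
#' @export
panel_params <- function(n_haplotypes = 200L,
                         target_density = 3000,
                         block_length_mean = 40000,
                         haplotypes_per_block = 12L,
                         inter_block_correlation = 0.85,
                         fst = 0.15,
                         recomb_scale = 2,
                         dirichlet_alpha = 0.65,
                         block_freq_drift = 45,
                         maf_min = 0.01,
                         exons_per_mb = 10L,
                         exon_length = 300L,
                         seed = 1L) {
  p <- list(n_haplotypes = as.integer(n_haplotypes),
            target_density = target_density,
            block_length_mean = block_length_mean,
            haplotypes_per_block = as.integer(haplotypes_per_block),
            inter_block_correlation = inter_block_correlation,
            fst = fst, recomb_scale = recomb_scale,
            dirichlet_alpha = dirichlet_alpha,
            block_freq_drift = block_freq_drift, maf_min = maf_min,
            exons_per_mb = exons_per_mb, exon_length = exon_length,
            seed = as.integer(seed))
  stopifnot(p$n_haplotypes >= 4, p$n_haplotypes %% 2 == 0,
            p$target_density > 0, p$block_length_mean > 0,
            p$haplotypes_per_block >= 2,
            p$inter_block_correlation >= 0, p$inter_block_correlation <= 1,
            p$fst >= 0, p$fst < 1, p$recomb_scale > 0,
            p$dirichlet_alpha > 0, p$block_freq_drift > 0,
            p$maf_min > 0, p$maf_min < 0.5)
  class(p) <- "panel_params"
  p
}

# Markov chain of block-haplotype states, H haplotypes x B blocks.
# Alignment between blocks uses a shared latent uniform (quantile coupling):
# the state in block b is the quantile of that block's frequency vector at a
# latent u that is retained across the boundary with probability `corr`.
# This keeps the marginal state distribution of block b exactly freqs[[b]].
chain_states <- function(H, freqs, corr) {
  B <- length(freqs)
  S <- matrix(0L, H, B)
  # stratified uniforms: realized state counts track the model frequencies
  # with sub-binomial noise (a permuted systematic sample)
  strat_u <- function(n) (sample.int(n) - runif(n)) / n
  u <- strat_u(H)
  for (b in seq_len(B)) {
    if (b > 1L) {
      redraw <- which(runif(H) >= corr)
      if (length(redraw)) u[redraw] <- strat_u(length(redraw))
    }
    cs <- cumsum(freqs[[b]])
    cs[length(cs)] <- 1
    S[, b] <- 1L + findInterval(u, cs[-length(cs)])
  }
  S
}

# Random binary genealogy over the K block-haplotype labels. A variant's
# carrier set is a clade of this tree (K leaves plus K-2 internal nodes; the
# root, which would be monomorphic, is excluded) — the carrier structure a
# mutation on a haplotype genealogy produces. Restricting carriers to clades
# gives the perfect-proxy cliques and linear predictability that real
# common-variant LD has.
make_clades <- function(K) {
  groups <- as.list(seq_len(K))
  clades <- as.list(seq_len(K))
  while (length(groups) > 2) {
    i <- sample.int(length(groups), 2)
    merged <- sort(c(groups[[i[1]]], groups[[i[2]]]))
    groups <- c(groups[-i], list(merged))
    clades <- c(clades, list(merged))
  }
  clades
}

# Pick a clade whose folded frequency is near the target minor-allele
# frequency; near-ties are randomized so proxy cliques are plausibly sized.
choose_clade <- function(clade_freq, target) {
  folded <- pmin(clade_freq, 1 - clade_freq)
  w <- 1 / (abs(folded - target) + 0.02)
  sample.int(length(clade_freq), 1L, prob = w)
}

# Build the H x M 0/1 allele matrix from chain states and per-variant label
# subsets (grouped by block for speed).
build_hap_matrix <- function(states, var_block, subsets, flip, K) {
  H <- nrow(states)
  M <- length(var_block)
  out <- matrix(0L, H, M)
  for (b in unique(var_block)) {
    idx <- which(var_block == b)
    A <- matrix(0L, K, length(idx))
    for (j in seq_along(idx)) A[subsets[[idx[j]]], j] <- 1L
    sub <- A[states[, b], , drop = FALSE]
    fl <- flip[idx]
    if (any(fl)) sub[, fl] <- 1L - sub[, fl]
    out[, idx] <- sub
  }
  out
}

new_haplotype_panel <- function(population, variants, haplotypes,
                                region_length, model = NULL, params = NULL) {
  stopifnot(nrow(variants) == ncol(haplotypes),
            all(haplotypes %in% c(0L, 1L)),
            nrow(haplotypes) %% 2 == 0,
            all(diff(variants$position) > 0),
            region_length >= max(variants$position) + 1)
  structure(list(population = population, variants = variants,
                 haplotypes = haplotypes, region_length = region_length,
                 model = model, params = params),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %s, %d haplotypes x %d variants, %.0f kb\n",
              x$population, nrow(x$haplotypes), ncol(x$haplotypes),
              x$region_length / 1000))
  cat(sprintf("  MAF range %.3f-%.3f; %d coding variants\n",
              min(panel_maf(x)), max(panel_maf(x)), sum(x$variants$is_coding)))
  invisible(x)
}

#' Alternate-allele frequencies and minor-allele frequencies of a panel
#'
#' @param panel A `haplotype_panel`.
#' @return Numeric vector over variants.
#' @export
panel_freq <- function(panel) colMeans(panel$haplotypes)

#' @rdname panel_freq
#' @export
panel_maf <- function(panel) {
  p <- panel_freq(panel)
  pmin(p, 1 - p)
}

#' Synthesize a phased haplotype panel with block LD structure
#'
#' Generates a panel standing in for a 1000 Genomes-style population panel
#' over a 1 Mb (by default) region. See [panel_params()] for the generative
#' model. The realized number of MAF >= 1% variants is within 20% of
#' `target_density` scaled by region length.
#'
#' @param params A [panel_params()] object.
#' @param region_length Region length in base pairs.
#' @param population Population label.
#' @return A `haplotype_panel`: variant table (`id`, `position` 0-based,
#'   `ref`, `alt`, `ancestral_freq`, `freq`, `is_coding`), binary haplotype
#'   matrix (haplotypes x variants), and the block model used to generate it.
#' @export
synthesize_panel <- function(params = panel_params(), region_length = 1e6,
                             population = "EUR") {
  stopifnot(inherits(params, "panel_params"))
  if (region_length < 2 * params$block_length_mean / 10 ||
      region_length < 1000)
    stop("region too short for one LD block")
  with_seed(params$seed, {
    H <- params$n_haplotypes
    K <- params$haplotypes_per_block
    # block partition
    lens <- numeric(0)
    while (sum(lens) < region_length)
      lens <- c(lens, rexp(64, 1 / params$block_length_mean))
    ends <- pmin(cumsum(lens), region_length)
    B <- which(ends >= region_length)[1]
    ends <- ends[seq_len(B)]
    starts <- c(0, ends[-B])
    # block-haplotype frequencies follow a Dirichlet random walk along the
    # region (the haplotype composition of a chromosome changes gradually)
    freqs <- vector("list", B)
    freqs[[1]] <- rdirichlet1(rep(params$dirichlet_alpha, K))
    drift <- params$block_freq_drift
    for (b in seq_len(B)[-1]) {
      freqs[[b]] <- if (is.finite(drift))
        rdirichlet1(drift * pmax(freqs[[b - 1]], 1e-8))
      else rdirichlet1(rep(params$dirichlet_alpha, K))
    }
    states <- chain_states(H, freqs, params$inter_block_correlation)
    counts <- apply(states, 2, tabulate, nbins = K) / H  # K x B realized
    # one clade topology per region (the genealogy drifts slowly along a
    # chromosome); block-specific frequencies still differentiate blocks.
    # Within a block, clades whose realized carrier sets coincide (because
    # some block-haplotypes have ~zero frequency there) are collapsed to
    # one representative, so allele-pattern multiplicity reflects genuine
    # repeated mutation targets rather than bookkeeping duplicates.
    clades <- make_clades(K)
    clade_use <- lapply(seq_len(B), function(b) {
      sig <- vapply(clades, function(cl)
        paste(sort(which(states[, b] %in% cl)), collapse = ","), "")
      which(!duplicated(sig))
    })
    clade_freq <- lapply(seq_len(B), function(b)
      vapply(clades[clade_use[[b]]], function(cl) sum(counts[cl, b]), 0))

    m_target <- max(1L, as.integer(round(params$target_density *
                                           region_length / 1e6)))
    pos <- integer(0); subsets <- list(); flip <- logical(0)
    anc <- numeric(0); frq <- numeric(0); vb <- integer(0)
    attempts <- 0L
    while (length(pos) < m_target && attempts < 40L) {
      attempts <- attempts + 1L
      n_draw <- max(32L, ceiling(1.4 * (m_target - length(pos))))
      cand_pos <- sample.int(region_length, min(n_draw, region_length)) - 1L
      cand_maf <- params$maf_min * (0.5 / params$maf_min)^runif(length(cand_pos))
      cand_b <- findInterval(cand_pos, starts)
      for (j in seq_along(cand_pos)) {
        b <- cand_b[j]
        ci <- choose_clade(clade_freq[[b]], cand_maf[j])
        s <- clades[[clade_use[[b]][ci]]]
        p_real <- sum(counts[s, b])
        if (min(p_real, 1 - p_real) < params$maf_min) next
        fl <- runif(1) < 0.5  # alt allele is the clade or its complement
        pos <- c(pos, cand_pos[j]); subsets <- c(subsets, list(s))
        flip <- c(flip, fl); vb <- c(vb, b)
        a_model <- sum(freqs[[b]][s]); f_real <- p_real
        if (fl) { a_model <- 1 - a_model; f_real <- 1 - f_real }
        anc <- c(anc, a_model); frq <- c(frq, f_real)
        if (length(pos) >= m_target) break
      }
    }
    if (length(pos) < 0.8 * m_target)
      stop("variant density infeasible for this block configuration")
    keep <- !duplicated(pos)
    ord <- order(pos[keep])
    idx <- which(keep)[ord]
    pos <- pos[idx]; subsets <- subsets[idx]; flip <- flip[idx]
    anc <- anc[idx]; frq <- frq[idx]; vb <- vb[idx]

    haps <- build_hap_matrix(states, vb, subsets, flip, K)

    # synthetic exon mask for the functional-prior design
    n_ex <- max(0L, as.integer(round(params$exons_per_mb *
                                       region_length / 1e6)))
    is_coding <- rep(FALSE, length(pos))
    if (n_ex > 0) {
      ex_start <- sort(sample.int(max(1L, region_length - params$exon_length),
                                  n_ex))
      for (e in ex_start)
        is_coding <- is_coding | (pos >= e & pos < e + params$exon_length)
    }
    anc <- pmin(pmax(anc, 1e-9), 1 - 1e-9)
    variants <- data.frame(
      id = sprintf("v%07d", pos + 1L), position = pos,
      ref = "A", alt = "G", ancestral_freq = anc, freq = colMeans(haps),
      is_coding = is_coding, stringsAsFactors = FALSE)
    stopifnot(max(abs(variants$freq - frq)) < 1e-12)
    model <- list(block_starts = starts, block_ends = ends, freqs = freqs,
                  subsets = subsets, flip = flip, var_block = vb, K = K,
                  corr = params$inter_block_correlation)
    new_haplotype_panel(population, variants, haps, region_length,
                        model = model, params = params)
  })
}

#' Derive a diverged-population panel by Balding-Nichols drift
#'
#' Starting from a synthesized panel, re-draws each block's block-haplotype
#' frequency vector from a Dirichlet with concentration `(1 - F)/F` times the
#' source frequencies (the Balding-Nichols model, so
#' `Var(p' - p) = F p (1 - p)` per variant), subdivides blocks by
#' `recomb_scale` to shorten LD, and regenerates haplotypes. All source
#' variants remain present, possibly at very different (even near-zero)
#' frequencies.
#'
#' @param panel A panel produced by [synthesize_panel()] (the block model
#'   must be available).
#' @param fst Drift parameter F in `[0, 1)`; `fst = 0` returns a
#'   statistically exchangeable re-draw of the source panel.
#' @param recomb_scale Factor by which blocks are subdivided (>= 1 shortens
#'   LD; non-integer values are rounded up).
#' @param seed Integer seed.
#' @param population Label for the derived panel.
#' @return A `haplotype_panel` over the same variant list.
#' @export
derive_diverged_panel <- function(panel, fst = panel$params$fst,
                                  recomb_scale = panel$params$recomb_scale,
                                  seed = 1L, population = "AFR") {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (is.null(panel$model))
    stop("panel has no block model (was it read from VCF?); ",
         "derive_diverged_panel requires a synthesized panel")
  if (fst >= 1 || fst < 0) stop("fst must be in [0, 1)")
  stopifnot(recomb_scale > 0)
  m <- panel$model
  K <- m$K
  H <- nrow(panel$haplotypes)
  with_seed(seed, {
    B <- length(m$freqs)
    conc <- if (fst == 0) Inf else (1 - fst) / fst
    freqs2 <- lapply(m$freqs, function(f) {
      if (!is.finite(conc)) return(f)
      rdirichlet1(conc * pmax(f, 1e-12))
    })
    # subdivide each block into ceiling(recomb_scale) sub-blocks
    nsub <- max(1L, as.integer(ceiling(recomb_scale)))
    sub_starts <- sub_ends <- numeric(0)
    sub_freqs <- list()
    parent <- integer(0)
    for (b in seq_len(B)) {
      cuts <- seq(m$block_starts[b], m$block_ends[b], length.out = nsub + 1)
      sub_starts <- c(sub_starts, cuts[-(nsub + 1)])
      sub_ends <- c(sub_ends, cuts[-1])
      sub_freqs <- c(sub_freqs, rep(list(freqs2[[b]]), nsub))
      parent <- c(parent, rep(b, nsub))
    }
    states <- chain_states(H, sub_freqs, m$corr)
    var_sub <- findInterval(panel$variants$position, sub_starts)
    haps <- build_hap_matrix(states, var_sub, m$subsets, m$flip, K)
    variants <- panel$variants
    variants$freq <- colMeans(haps)
    model <- list(block_starts = sub_starts, block_ends = sub_ends,
                  freqs = sub_freqs, subsets = m$subsets, flip = m$flip,
                  var_block = var_sub, K = K, corr = m$corr)
    new_haplotype_panel(population, variants, haps, panel$region_length,
                        model = model, params = panel$params)
  })
}

#' Squared haplotype correlation (LD r-squared) between two variants
#'
#' `r^2 = D^2 / (pA (1-pA) pB (1-pB))` with `D = pAB - pA pB`, computed on
#' the phased haplotypes of the panel.
#'
#' @param panel A `haplotype_panel`.
#' @param a,b Variant indices (1-based) or variant ids.
#' @return r-squared in `[0, 1]`. Monomorphic variants are an error (the
#'   quantity is undefined, not zero).
#' @export
compute_r2 <- function(panel, a, b) {
  ia <- resolve_variant(panel, a)
  ib <- resolve_variant(panel, b)
  x <- panel$haplotypes[, ia]
  y <- panel$haplotypes[, ib]
  pa <- mean(x); pb <- mean(y)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1)
    stop("r-squared undefined: variant monomorphic in panel")
  d <- mean(x * y) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# r2 of every variant against a lead variant; NA where monomorphic
r2_to_lead <- function(panel, lead) {
  il <- resolve_variant(panel, lead)
  y <- panel$haplotypes[, il]
  pb <- mean(y)
  if (pb <= 0 || pb >= 1) stop("lead variant monomorphic in panel")
  p <- panel_freq(panel)
  d <- colMeans(panel$haplotypes * y) - p * pb
  r2 <- d^2 / (p * (1 - p) * pb * (1 - pb))
  r2[p <= 0 | p >= 1] <- NA_real_
  r2
}

resolve_variant <- function(panel, v) {
  if (is.character(v)) {
    i <- match(v, panel$variants$id)
    if (is.na(i)) stop("unknown variant id: ", v)
    return(i)
  }
  stopifnot(v >= 1, v <= ncol(panel$haplotypes))
  as.integer(v)
}
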