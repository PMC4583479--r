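test_that("synthesized panels honour density, spectrum and invariants", {
  panel <- small_panel(seed = 3, density = 500)
  expect_s3_class(panel, "haplotype_panel")
  m <- ncol(panel$haplotypes)
  expect_true(abs(m - 500) / 500 <= 0.2)
  expect_true(all(panel$haplotypes %in% c(0L, 1L)))
  expect_true(nrow(panel$haplotypes) %% 2 == 0)
  expect_true(all(diff(panel$variants$position) > 0))
  expect_gte(panel$region_length, max(panel$variants$position) + 1)
  # stored frequency matches the matrix exactly
  expect_lt(max(abs(panel$variants$freq - colMeans(panel$haplotypes))), 1e-12)
  expect_true(all(panel$variants$ancestral_freq > 0 &
                    panel$variants$ancestral_freq < 1))
  # folded 1/p spectrum: low-frequency bin dominates the common bin
  maf <- panel_maf(panel)
  expect_true(all(maf >= 0.01))
  expect_gt(mean(maf <= 0.05), mean(maf >= 0.4))
})

test_that("panel generation is deterministic under seed and errors sanely", {
  p1 <- small_panel(seed = 9, density = 200)
  p2 <- small_panel(seed = 9, density = 200)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$variants, p2$variants)
  p3 <- small_panel(seed = 10, density = 200)
  expect_false(identical(p1$haplotypes, p3$haplotypes))
  expect_error(synthesize_panel(panel_params(seed = 1), region_length = 50),
               "too short")
})

test_that("within-block LD exceeds cross-block LD and decays with distance", {
  pp <- panel_params(n_haplotypes = 200, target_density = 3000,
                     block_length_mean = 20000, haplotypes_per_block = 6,
                     inter_block_correlation = 0.7, seed = 1)
  panel <- synthesize_panel(pp, 1e6)
  vb <- panel$model$var_block
  maf <- panel_maf(panel)
  ok <- maf >= 0.05
  set.seed(4)
  idx <- sample(which(ok), 400)
  r2 <- function(i, j) compute_r2(panel, i, j)
  within <- c(); cross <- c(); dist <- c(); vals <- c()
  for (k in seq(1, length(idx) - 1, by = 2)) {
    i <- idx[k]; j <- idx[k + 1]
    v <- r2(i, j)
    d <- abs(panel$variants$position[i] - panel$variants$position[j])
    if (vb[i] == vb[j]) within <- c(within, v) else cross <- c(cross, v)
    dist <- c(dist, d); vals <- c(vals, v)
  }
  # also collect guaranteed within-block pairs
  for (b in unique(vb)[1:20]) {
    vs <- which(vb == b & ok)
    if (length(vs) >= 2) within <- c(within, r2(vs[1], vs[2]))
  }
  expect_gt(median(within), median(cross))
  # LD decay: mean r2 over distance bins is non-increasing up to noise
  bins <- cut(dist, breaks = quantile(dist, seq(0, 1, length.out = 21)),
              include.lowest = TRUE)
  mu <- tapply(vals, bins, mean)
  fit <- isoreg(seq_along(mu), -as.numeric(mu))
  expect_lt(mean((fit$yf + as.numeric(mu))^2), 0.01)
})

test_that("inter-block correlation limits behave as designed", {
  # corr = 0: different blocks are independent by construction
  pp0 <- panel_params(target_density = 400, inter_block_correlation = 0,
                      seed = 2)
  p0 <- synthesize_panel(pp0, 1e6)
  vb <- p0$model$var_block
  maf <- panel_maf(p0)
  set.seed(1)
  cand <- which(maf > 0.1)
  pairs <- matrix(sample(cand, 300, replace = TRUE), ncol = 2)
  pairs <- pairs[vb[pairs[, 1]] != vb[pairs[, 2]], , drop = FALSE]
  r2s <- apply(pairs, 1, function(ij) compute_r2(p0, ij[1], ij[2]))
  expect_lt(mean(r2s), 0.02)

  # corr = 1 with aligned (identical) block frequencies: same clade in two
  # blocks is a perfect chain, r2 = 1
  f <- c(0.35, 0.25, 0.2, 0.1, 0.06, 0.04)
  set.seed(7)
  states <- finemapsim:::chain_states(200, list(f, f), corr = 1)
  haps <- finemapsim:::build_hap_matrix(states, var_block = c(1L, 2L),
                                        subsets = list(c(1L, 2L), c(1L, 2L)),
                                        flip = c(FALSE, FALSE), K = 6)
  pnl <- manual_panel(haps)
  expect_equal(compute_r2(pnl, 1, 2), 1.0)
})

test_that("r-squared matches hand-computed haplotype examples", {
  # counts (AB, Ab, aB, ab) = (1,1,1,1): D = 0
  h <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  expect_equal(compute_r2(manual_panel(h), 1, 2), 0)
  # counts (40,10,10,40): r2 = 0.36
  h2 <- matrix(0L, 100, 2)
  h2[1:50, 1] <- 1L
  h2[c(1:40, 51:60), 2] <- 1L
  expect_equal(compute_r2(manual_panel(h2), 1, 2), 0.36)
  expect_equal(compute_r2(manual_panel(h2), 2, 2), 1.0)
  # monomorphic variants are an error, not zero
  h3 <- cbind(rep(1L, 10), rep(c(0L, 1L), 5))
  expect_error(compute_r2(manual_panel(h3), 1, 2), "monomorphic")
})

test_that("Balding-Nichols drift has the right variance and limits", {
  # frequency deviations are shared by all variants of a block-clade, so
  # the Monte-Carlo averages the variance ratio over many independent
  # panels rather than over (highly dependent) variants of one panel
  ratios <- vapply(1:10, function(s) {
    panel <- small_panel(seed = 100 + s, density = 400)
    p1 <- panel_freq(panel)
    d15 <- derive_diverged_panel(panel, fst = 0.15, recomb_scale = 1,
                                 seed = 21 + s)
    expect_identical(d15$variants$id, panel$variants$id)
    p2 <- panel_freq(d15)
    mean((p2 - p1)^2) / mean(0.15 * p1 * (1 - p1))
  }, 0)
  expect_gt(mean(ratios), 0.7)
  expect_lt(mean(ratios), 1.3)
  # no-drift limit: frequencies nearly reproduced
  panel <- small_panel(seed = 5, density = 1500)
  d0 <- derive_diverged_panel(panel, fst = 0, recomb_scale = 1, seed = 22)
  expect_lt(mean(abs(panel_freq(d0) - panel_freq(panel))), 0.02)
  expect_error(derive_diverged_panel(panel, fst = 1, seed = 1), "fst")
})

test_that("doubling the recombination scale shortens LD in the derived panel", {
  panel <- small_panel(seed = 6, density = 800)
  drv <- derive_diverged_panel(panel, fst = 0.15, recomb_scale = 2, seed = 3)
  pos <- panel$variants$position
  maf_src <- panel_maf(panel)
  maf_drv <- panel_maf(drv)
  set.seed(8)
  i <- sample(which(maf_src > 0.1 & maf_drv > 0.1), 150, replace = TRUE)
  j <- vapply(i, function(ii) {
    w <- which(abs(pos - pos[ii] - 5e4) < 2e4 & maf_src > 0.1 & maf_drv > 0.1)
    if (length(w)) w[sample.int(length(w), 1)] else NA_integer_
  }, 1L)
  keep <- !is.na(j)
  i <- i[keep]; j <- j[keep]
  expect_gte(length(i), 100)
  r_src <- mapply(function(a, b) compute_r2(panel, a, b), i, j)
  r_drv <- mapply(function(a, b) compute_r2(drv, a, b), i, j)
  expect_lt(mean(r_drv), mean(r_src))
})
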