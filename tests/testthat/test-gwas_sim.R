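test_that("penetrances solve the prevalence constraint", {
  panel <- small_panel(seed = 31, density = 400)
  # f0 = K / (q^2 + 2pq OR + p^2 OR^2); at p = 0.5, OR = 1.5:
  # denominator = 0.25 + 0.75 + 0.5625 = 1.5625
  f <- panel_freq(panel)
  raf_t <- f[which.min(abs(f - 0.5))]   # nearest achievable common RAF
  m <- build_disease_model(panel, data.frame(raf = raf_t, or = 1.5),
                           prevalence = 0.0055)
  expect_equal(m$causal$raf, raf_t, tolerance = 0.005)
  p <- m$causal$raf
  denom <- (1 - p)^2 + 2 * p * (1 - p) * 1.5 + p^2 * 1.5^2
  expect_equal(m$f0, 0.0055 / denom, tolerance = 1e-12)
  expect_lt(abs(sum(m$P_g * m$f_g) - 0.0055), 1e-10)
  # exact spec example value at p = 0.5
  expect_equal(0.0055 / 1.5625, 0.00352, tolerance = 1e-4)

  # null model: all penetrances equal the prevalence
  m0 <- build_disease_model(panel,
                            data.frame(raf = achievable_raf(panel, 0.2),
                                       or = 1.0))
  expect_equal(unname(m0$f_g), rep(0.0055, 3))
  expect_equal(m0$f0, 0.0055)

  # expected case RAF at p = 0.1, OR = 1.2 is 0.1176
  m1 <- build_disease_model(panel,
                            data.frame(raf = achievable_raf(panel, 0.1),
                                       or = 1.2))
  p1 <- m1$causal$raf
  or_mult <- 1.2^(0:2)
  P <- c((1 - p1)^2, 2 * p1 * (1 - p1), p1^2)
  expect_equal(expected_raf(m1, "case"),
               sum((0:2) * P * or_mult) / (2 * sum(P * or_mult)))
  expect_equal(sum((0:2) * c(0.81, 0.18 * 1.2, 0.01 * 1.44)) / (2 * 1.0404),
               0.1176, tolerance = 1e-3)
  raf_lo <- f[which.min(abs(pmin(f, 1 - f) - 0.05))]
  raf_lo <- min(raf_lo, 1 - raf_lo)
  expect_error(build_disease_model(panel, data.frame(raf = raf_lo, or = 100)),
               "penetrance")
})

test_that("case-control resampling reproduces the disease model", {
  panel <- small_panel(seed = 32, density = 300)
  m <- build_disease_model(panel,
                           data.frame(raf = achievable_raf(panel, 0.1),
                                      or = 1.2))
  ci <- m$causal$index
  raf_case <- raf_ctrl <- numeric(40)
  for (r in seq_len(40)) {
    st <- simulate_case_control(panel, m, 250, 250, seed = 100 + r)
    g <- st$dosages[, ci]
    if (m$causal$risk_allele == "ref") g <- 2 - g
    raf_case[r] <- mean(g[st$phenotype == 1]) / 2
    raf_ctrl[r] <- mean(g[st$phenotype == 0]) / 2
  }
  tgt <- expected_raf(m, "case")
  se <- sd(raf_case) / sqrt(40)
  expect_lt(abs(mean(raf_case) - tgt), 4 * se + 1e-4)
  expect_lt(abs(mean(raf_ctrl) - expected_raf(m, "control")), 4 * se + 1e-4)

  # null model: no case/control frequency difference
  m0 <- build_disease_model(panel,
                            data.frame(raf = achievable_raf(panel, 0.1),
                                       or = 1.0))
  d <- replicate(30, {
    st <- simulate_case_control(panel, m0, 250, 250,
                                seed = sample.int(1e6, 1))
    g <- st$dosages[, m0$causal$index]
    mean(g[st$phenotype == 1]) - mean(g[st$phenotype == 0])
  })
  expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(30) + 1e-3)
})

test_that("resampled controls preserve panel frequencies and LD", {
  panel <- small_panel(seed = 33, density = 300)
  m <- build_disease_model(panel,
                           data.frame(raf = achievable_raf(panel, 0.2),
                                      or = 1.2))
  st <- simulate_case_control(panel, m, 500, 1500, seed = 5)
  ctrl <- st$dosages[st$phenotype == 0, ]
  f_sim <- colMeans(ctrl) / 2
  f_pan <- panel_freq(panel)
  # binomial sampling screen on non-causal variants
  se <- sqrt(f_pan * (1 - f_pan) / (2 * 1500))
  zscores <- (f_sim - f_pan) / pmax(se, 1e-4)
  zscores <- zscores[-m$causal$index]
  expect_lt(mean(abs(zscores) > 3), 0.02)
  # LD preservation for a proxy pair
  maf <- panel_maf(panel)
  vb <- panel$model$var_block
  pair <- NULL
  for (b in unique(vb)) {
    cand <- which(vb == b & maf > 0.2)
    if (length(cand) >= 2) { pair <- cand[1:2]; break }
  }
  expect_false(is.null(pair))
  r2_panel <- compute_r2(panel, pair[1], pair[2])
  x <- ctrl[, pair[1]]; y <- ctrl[, pair[2]]
  r2_sim <- cor(x, y)^2
  expect_lt(abs(r2_sim - r2_panel), 0.1)
})

test_that("case enrichment is monotone in the odds ratio", {
  panel <- small_panel(seed = 34, density = 300)
  mean_raf <- vapply(c(1.0, 1.1, 1.2, 1.5), function(or) {
    m <- build_disease_model(panel,
                             data.frame(raf = achievable_raf(panel, 0.2),
                                        or = or))
    raf <- replicate(25, {
      st <- simulate_case_control(panel, m, 300, 100,
                                  seed = sample.int(1e6, 1))
      g <- st$dosages[st$phenotype == 1, m$causal$index]
      if (m$causal$risk_allele == "ref") g <- 2 - g
      mean(g) / 2
    })
    mean(raf)
  }, 0)
  expect_true(all(diff(mean_raf) > 0))
})

test_that("scenario transforms mask the intended genotypes", {
  panel <- small_panel(seed = 35, density = 500)
  m <- build_disease_model(panel,
                           data.frame(raf = achievable_raf(panel, 0.2),
                                      or = 1.2))
  st <- simulate_case_control(panel, m, 100, 100, seed = 1)

  gold <- apply_scenario(st, scenario_spec("gold"))
  expect_identical(gold$dosages, st$dosages)

  mask <- select_array_mask(panel, 150, seed = 2)
  sc <- scenario_spec("gwas", array_mask = mask)
  gw <- apply_scenario(st, sc)
  expect_identical(sum(!gw$typed), ncol(st$dosages) - length(mask))
  expect_true(all(is.na(gw$dosages[, !gw$typed])))
  expect_identical(gw$dosages[, gw$typed] * 1.0, st$dosages[, gw$typed] * 1.0)

  # per-cohort failure: expected fraction of cohorts failing a variant
  frac <- replicate(20, {
    scf <- scenario_spec("gwas_failure", array_mask = mask,
                         failure_fraction = 0.05,
                         seed = sample.int(1e6, 1))
    f <- apply_scenario(st, scf)
    sum(f$failed) / length(mask)
  })
  expect_equal(mean(frac), round(0.05 * length(mask)) / length(mask),
               tolerance = 1e-10)
  # failed variants differ between cohorts (independent draws)
  f1 <- apply_scenario(st, scenario_spec("gwas_failure", array_mask = mask,
                                         failure_fraction = 0.05, seed = 1))
  f2 <- apply_scenario(st, scenario_spec("gwas_failure", array_mask = mask,
                                         failure_fraction = 0.05, seed = 2))
  expect_false(identical(which(f1$failed), which(f2$failed)))
  expect_error(scenario_spec("gwas"), "mask")
  expect_error(scenario_spec("gold", array_mask = "x"), "gold")
})

test_that("array masks are MAF-weighted and sized to the target density", {
  panel <- synthesize_panel(panel_params(target_density = 3000, seed = 36),
                            1e6)
  m_panel <- ncol(panel$haplotypes)
  expect_identical(select_array_mask(panel, m_panel, seed = 1),
                   panel$variants$id)
  mask <- select_array_mask(panel, 800, seed = 1)
  expect_lt(abs(length(mask) - 800) / 800, 0.05)
  maf <- panel_maf(panel)
  expect_gt(mean(maf[panel$variants$id %in% mask]), mean(maf))
  expect_error(select_array_mask(panel, 99999, seed = 1), "density")
})

test_that("multi-causal pair selection respects MAF, LD and position limits", {
  # a panel of perfect proxies has no qualifying pair
  base <- rep(c(0L, 1L), 100)
  haps <- cbind(base, base, base, base)
  colnames(haps) <- NULL
  prox <- manual_panel(haps, positions = c(300000L, 400000L, 500000L,
                                           600000L),
                       region_length = 1e6)
  expect_error(select_multi_causal_pair(prox, maf_target = 0.5), "pair")

  # two independent blocks each holding a MAF-0.10 variant
  set.seed(9)
  v1 <- as.integer(runif(200) < 0.10)
  v2 <- sample(v1)
  toy <- manual_panel(cbind(v1, v2), positions = c(300000L, 600000L),
                      region_length = 1e6)
  got <- select_multi_causal_pair(toy, maf_target = mean(v1), maf_tol = 0.05)
  expect_setequal(got, toy$variants$id)

  # returned pairs always satisfy the LD bound
  panel <- small_panel(seed = 37, density = 600)
  ids <- select_multi_causal_pair(panel, maf_target = 0.10, seed = 4)
  expect_lt(compute_r2(panel, ids[1], ids[2]), 0.05)
  maf <- panel_maf(panel)[match(ids, panel$variants$id)]
  expect_true(all(abs(maf - 0.10) <= 0.02))
  pos <- panel$variants$position[match(ids, panel$variants$id)]
  expect_true(all(pos >= 125000 & pos <= 875000))
})

test_that("simulation is deterministic under seed", {
  panel <- small_panel(seed = 38, density = 200)
  set.seed(5)
  m <- build_disease_model(panel,
                           data.frame(raf = achievable_raf(panel, 0.2),
                                      or = 1.2))
  s1 <- simulate_case_control(panel, m, 50, 50, seed = 77)
  s2 <- simulate_case_control(panel, m, 50, 50, seed = 77)
  expect_identical(s1$dosages, s2$dosages)
})
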