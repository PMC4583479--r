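test_that("imputation model recognises perfect and absent proxies", {
  set.seed(11)
  H <- 200
  # block A: variants 1-3 identical (perfect proxies); block B independent
  a <- as.integer(runif(H) < 0.3)
  b <- as.integer(runif(H) < 0.4)
  c_ <- as.integer(runif(H) < 0.25)
  haps <- cbind(a, a, a, b, c_)
  colnames(haps) <- NULL
  pnl <- manual_panel(haps, positions = c(100L, 200L, 300L, 50000L, 50100L))
  # type variants 1 and 4; impute 2 (perfect proxy), 5 (proxy-free-ish), 3
  mask <- pnl$variants$id[c(1, 4)]
  mod <- fit_imputation_model(pnl, mask, k_neighbors = 2)
  i2 <- which(mod$untyped == 2)
  i5 <- which(mod$untyped == 5)
  expect_gte(mod$info_theo[i2], 0.99)
  co <- mod$coef[, i2]
  expect_equal(co[which(mod$nbr[, i2] == 1)], 1, tolerance = 0.01)
  expect_lte(mod$info_theo[i5], max(0.05, cor(c_, a)^2 + cor(c_, b)^2 + 0.05))

  # an untyped variant uncorrelated with every typed one: INFO ~ 0 and the
  # prediction is the panel mean dosage
  set.seed(12)
  ind <- as.integer(runif(H) < 0.35)
  pnl2 <- manual_panel(cbind(a, ind), positions = c(100L, 90000L))
  mod2 <- fit_imputation_model(pnl2, pnl2$variants$id[1], k_neighbors = 1)
  expect_lte(mod2$info_theo[1], 0.05)
})

test_that("dropping the best proxy never increases theoretical INFO", {
  panel <- small_panel(seed = 51, density = 300)
  mask <- select_array_mask(panel, 100, seed = 1)
  full <- fit_imputation_model(panel, mask, k_neighbors = 10)
  Hm <- panel$haplotypes
  Hn <- nrow(Hm)
  ridge_info <- function(cols, u) {
    y <- Hm[, u]
    X <- Hm[, cols, drop = FALSE]
    Xc <- sweep(X, 2, colMeans(X))
    yc <- y - mean(y)
    A <- crossprod(Xc) / Hn + diag(1e-4, ncol(X))
    b <- solve(A, crossprod(Xc, yc) / Hn)
    drop(crossprod(b, (crossprod(Xc) / Hn) %*% b)) / mean(yc^2)
  }
  set.seed(3)
  for (j in sample(seq_along(full$untyped), 10)) {
    if (full$unimputable[j]) next
    u <- full$untyped[j]
    cols <- full$nbr[, j]
    best <- which.max(abs(full$coef[, j]))
    expect_lte(ridge_info(cols[-best], u), ridge_info(cols, u) + 1e-3)
  }
})

test_that("study imputation fills expected dosages and empirical INFO", {
  panel <- small_panel(seed = 52, density = 400)
  m <- build_disease_model(panel,
                           data.frame(raf = achievable_raf(panel, 0.2),
                                      or = 1.2))
  st <- simulate_case_control(panel, m, 400, 400, seed = 9)

  # fully typed study: imputation is a no-op
  mask_all <- panel$variants$id
  mod_all <- fit_imputation_model(panel, mask_all)
  st_all <- impute_study(apply_scenario(st, scenario_spec("gwas",
                                                          array_mask = mask_all)),
                         mod_all)
  expect_equal(st_all$dosages * 1.0, st$dosages * 1.0, ignore_attr = TRUE)
  expect_true(all(st_all$info == 1))

  mask <- select_array_mask(panel, 120, seed = 4)
  sc <- scenario_spec("gwas", array_mask = mask)
  mod <- fit_imputation_model(panel, mask)
  imp <- impute_study(apply_scenario(st, sc), mod)
  # typed genotypes unchanged
  typed <- imp$typed
  expect_equal(imp$dosages[, typed], st$dosages[, typed] * 1.0,
               ignore_attr = TRUE)
  # all dosages in range, nothing missing
  expect_true(all(imp$dosages >= 0 & imp$dosages <= 2))
  expect_false(anyNA(imp$dosages))

  # perfect-proxy untyped variants recover the simulated genotypes
  near_perfect <- which(!typed)[
    mod$info_theo[match(which(!typed), mod$untyped)] > 0.999]
  for (u in head(near_perfect, 5)) {
    agree <- mean(abs(imp$dosages[, u] - st$dosages[, u]) < 0.01)
    expect_gte(agree, 0.99)
  }

  # empirical INFO tracks theoretical INFO (a sparse array spreads the
  # INFO distribution so the rank correlation is informative)
  mask_sp <- select_array_mask(panel, 60, seed = 4)
  mod_sp <- fit_imputation_model(panel, mask_sp)
  imp_sp <- impute_study(
    apply_scenario(st, scenario_spec("gwas", array_mask = mask_sp)), mod_sp)
  keep <- !mod_sp$unimputable
  expect_gt(cor(imp_sp$info[mod_sp$untyped][keep], mod_sp$info_theo[keep],
                method = "spearman"), 0.8)

  # mean imputed dosage matches twice the panel frequency in controls
  ctrl <- imp$dosages[imp$phenotype == 0, !typed, drop = FALSE]
  f_imp <- colMeans(ctrl) / 2
  f_pan <- panel_freq(panel)[!typed]
  expect_lt(median(abs(f_imp - f_pan)), 0.02)
})

test_that("failed variants are imputed like untyped ones", {
  panel <- small_panel(seed = 53, density = 300)
  m <- build_disease_model(panel,
                           data.frame(raf = achievable_raf(panel, 0.2),
                                      or = 1.2))
  st <- simulate_case_control(panel, m, 200, 200, seed = 10)
  mask <- select_array_mask(panel, 150, seed = 5)
  sc <- scenario_spec("gwas_failure", array_mask = mask,
                      failure_fraction = 0.1, seed = 6)
  stf <- apply_scenario(st, sc)
  expect_gt(sum(stf$failed), 0)
  mod <- fit_imputation_model(panel,
                              setdiff(mask, stf$variants$id[stf$failed]))
  impf <- impute_study(stf, mod)
  expect_false(anyNA(impf$dosages))
  expect_true(all(impf$imputed[stf$failed]))
})

test_that("QC filter applies strict INFO and non-strict MAF rules", {
  meta <- data.frame(id = paste0("v", 1:5), eaf = c(0.05, 0.005, 0.3, 0.3,
                                                    0.02),
                     info = c(1, 0.9, 0.4, 0.2, 1))
  keep <- qc_filter(meta, thresholds = qc_thresholds())
  expect_identical(sum(keep), 2L)
  expect_identical(meta$id[keep], c("v1", "v5"))
  # INFO exactly at the threshold is removed; MAF exactly 1% is retained
  m2 <- data.frame(id = c("a", "b"), eaf = c(0.25, 0.01),
                   info = c(0.4, 0.41))
  expect_identical(unname(qc_filter(m2)), c(FALSE, TRUE))
  expect_error(qc_thresholds(info_min = 0), "info_min")
})
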