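# small helper: phenotype records with one plot per accession
one_rec_per_acc <- function(ids, y, year = 2006L) {
  side <- ceiling(sqrt(length(ids)))
  data.frame(accession_id = ids, trait = "t", value = y, year = year,
             row = (seq_along(ids) - 1L) %/% side + 1L,
             col = (seq_along(ids) - 1L) %% side + 1L,
             stringsAsFactors = FALSE)
}

test_that("with negligible residual variance predictions equal phenotypes", {
  set.seed(1)
  n <- 20
  ids <- sprintf("a%02d", 1:n)
  K <- diag(n); dimnames(K) <- list(ids, ids)
  y <- rnorm(n)
  rec <- one_rec_per_acc(ids, y)
  fit <- fit_gblup(rec, K, "t", include_spatial = FALSE,
                   varcomp = c(genomic = 1, residual = 1e-8))
  expect_equal(fit$mu + fit$blups$blup, y, tolerance = 1e-3)
})

test_that("BLUPs are shrunken relative to accession means", {
  sim <- tiny_panel()
  G <- filter_markers(sim$genotypes)$genotypes
  K <- vanraden_kinship(G)
  fit <- fit_gblup(sim$phenotypes, K, "fruit_weight")
  means <- tapply(sim$phenotypes$value[sim$phenotypes$trait == "fruit_weight"],
                  sim$phenotypes$accession_id[sim$phenotypes$trait == "fruit_weight"],
                  mean)
  expect_lt(var(fit$blups$blup), var(means[fit$blups$accession_id]))
  expect_true(all(fit$varcomp >= 0))
  # recorded REML path: final model no worse than the starting point
  expect_gte(fit$loglik, fit$loglik_path[1] - 1e-6)
})

test_that("fit is invariant to record order", {
  sim <- tiny_panel()
  K <- vanraden_kinship(filter_markers(sim$genotypes)$genotypes)
  rec <- sim$phenotypes
  set.seed(4)
  f1 <- fit_gblup(rec, K, "yield")
  f2 <- fit_gblup(rec[sample(nrow(rec)), ], K, "yield")
  expect_equal(f1$blups$blup, f2$blups$blup, tolerance = 1e-6)
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-4)
})

test_that("GBLUPs recover true breeding values at h2 = 0.5", {
  cfg <- scenario_config(n_wld = 80, n_ns = 80, n_clt1 = 70, n_clt2 = 70,
                         n_markers = 500, n_founders_stage2 = 10,
                         n_polygenes = 150, years = 1, missing_rate = 0.05,
                         traits = data.frame(trait = "fruit_weight",
                                             mean = 1.72, gsd = 0.4,
                                             h2 = 0.5),
                         qtl = data.frame(trait = character(),
                                          effect = numeric()),
                         selection_traits = "fruit_weight")
  sim <- simulate_panel(cfg, seed = 88)
  G <- filter_markers(sim$genotypes)$genotypes
  K <- vanraden_kinship(G)
  fit <- fit_gblup(sim$phenotypes, K, "fruit_weight")
  bv <- sim$truth$breeding_values[fit$blups$accession_id, "fruit_weight"]
  expect_gte(cor(fit$blups$blup, bv), 0.6)
})

test_that("modelling a planted spatial field lowers the residual variance", {
  sim <- tiny_panel()   # generator plants a smooth field surface
  K <- vanraden_kinship(filter_markers(sim$genotypes)$genotypes)
  with_sp <- fit_gblup(sim$phenotypes, K, "yield", include_spatial = TRUE)
  without <- fit_gblup(sim$phenotypes, K, "yield", include_spatial = FALSE)
  expect_lt(with_sp$varcomp["residual"], without$varcomp["residual"])
})

test_that("subgroup comparison: null and strongly separated cases", {
  ids <- sprintf("a%02d", 1:40)
  meta <- data.frame(accession_id = ids,
                     subgroup = rep(c("A", "B"), each = 20),
                     origin = "x", stringsAsFactors = FALSE)
  # identical group distributions -> no signal
  set.seed(2)
  v <- rnorm(20)
  same <- data.frame(accession_id = ids, blup = c(v, v))
  cs <- subgroup_compare(same, meta)
  expect_gt(cs$omnibus_p, 0.99)
  # two groups shifted by 5 SD -> overwhelming signal
  shifted <- data.frame(accession_id = ids, blup = c(rnorm(20), rnorm(20) + 5))
  expect_lt(subgroup_compare(shifted, meta)$omnibus_p, 1e-6)
  expect_error(subgroup_compare(shifted, meta[1:21, ]), ">= 2 subgroups")
})

test_that("trait correlations: identity, anti-identity, sampling behaviour", {
  set.seed(77)
  x <- rnorm(50)
  tc <- trait_correlations(cbind(a = x, b = -x, c = rnorm(50)))
  expect_equal(tc$r["a", "a"], 1)
  expect_equal(tc$r["a", "b"], -1)
  expect_lt(tc$p["a", "b"], 1e-12)
  # bivariate normal with rho = 0.7 at n = 282
  rho <- 0.7; n <- 282
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  est <- trait_correlations(cbind(u = z1, v = z2))$r["u", "v"]
  se <- (1 - rho^2) / sqrt(n - 1)
  expect_lt(abs(est - rho), 3 * se)
  expect_error(trait_correlations(cbind(a = x, k = rep(1, 50))), "constant")
})
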