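test_that("VanRaden kinship matches the element-by-element oracle", {
  set.seed(13)
  M <- matrix(sample(0:2, 24, replace = TRUE), 4, 6,
              dimnames = list(letters[1:4], NULL))
  G <- toy_geno(M)
  A <- vanraden_kinship(G)
  expect_equal(unname(A), vanraden_oracle(M), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(A), unname(t(A)))
})

test_that("duplicated individuals share their diagonal relationship", {
  set.seed(14)
  proto <- sample(0:2, 40, replace = TRUE)
  dos <- rbind(proto, proto,
               sample(0:2, 40, replace = TRUE),
               sample(0:2, 40, replace = TRUE))
  rownames(dos) <- sprintf("d%d", 1:4)
  A <- vanraden_kinship(toy_geno(dos))
  expect_equal(A[1, 2], A[1, 1], tolerance = 1e-12)
  expect_equal(A[1, 2], A[2, 2], tolerance = 1e-12)
})

test_that("unrelated individuals have near-zero mean off-diagonal kinship", {
  set.seed(15)
  p <- runif(800, 0.1, 0.9)
  dos <- sapply(p, function(q) rbinom(40, 2, q))
  rownames(dos) <- sprintf("u%02d", 1:40)
  A <- vanraden_kinship(toy_geno(dos))
  off <- A[upper.tri(A)]
  # in-sample centering makes rows of W sum to ~0, so the off-diagonal
  # mean sits at -1/(n-1) rather than exactly 0
  expect_lt(abs(mean(off) + 1 / (nrow(A) - 1)), 0.01)
})

test_that("BH control matches the exhaustive step-up oracle", {
  p <- c(0.001, 0.02, 0.03, 0.5, 0.9)
  got <- bh_fdr(p, alpha = 0.1)
  expect_equal(got$discoveries, bh_oracle(p, 0.1))
  expect_length(bh_fdr(rep(1, 10), 0.1)$discoveries, 0)
  expect_equal(bh_fdr(c(1e-9, runif(999, 0.2, 1)), 0.1)$discoveries, 1L)
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    a <- runif(1, 0.01, 0.3)
    expect_equal(bh_fdr(p, a)$discoveries, bh_oracle(p, a))
  }
  # monotone q-values
  p <- sort(runif(30))
  q <- bh_fdr(p)$q
  expect_true(all(diff(q) >= -1e-12))
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("with identity kinship and no covariates the scan reduces to OLS", {
  set.seed(30)
  n <- 60; L <- 40
  dos <- matrix(rbinom(n * L, 2, 0.4), n, L,
                dimnames = list(sprintf("s%02d", 1:n), NULL))
  G <- toy_geno(dos)
  y <- setNames(rnorm(n) + 0.5 * dos[, 3], rownames(dos))
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  sc <- mlm_scan(G, y, K = K, min_maf = 0)
  for (j in c(1, 3, 10)) {
    ols <- summary(lm(y ~ dos[, j]))$coefficients
    expect_equal(sc$table$p[j], ols[2, 4], tolerance = 1e-8)
    expect_equal(sc$table$beta[j], ols[2, 1], tolerance = 1e-8)
  }
})

test_that("markers collinear with covariates are flagged, not tested", {
  set.seed(31)
  n <- 40
  dos <- matrix(rbinom(n * 20, 2, 0.5), n, 20,
                dimnames = list(sprintf("s%02d", 1:n), NULL))
  G <- toy_geno(dos)
  y <- setNames(rnorm(n), rownames(dos))
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  covar <- matrix(dos[, 5], n, 1, dimnames = list(names(y), "pc1"))
  sc <- mlm_scan(G, y, covariates = covar, K = K, min_maf = 0)
  expect_equal(sc$table$flag[5], "collinear")
  expect_true(is.na(sc$table$p[5]))
  expect_true(all(sc$table$flag[-5] == ""))
})

test_that("null scan p-values are approximately uniform", {
  # structured kinship, no QTL: fraction below 0.05 should be near nominal
  cfg <- scenario_config(n_wld = 40, n_ns = 40, n_clt1 = 20, n_clt2 = 20,
                         n_markers = 400, n_polygenes = 80, years = 1,
                         missing_rate = 0)
  sim <- simulate_panel(cfg, seed = 61)
  G <- filter_markers(sim$genotypes)$genotypes
  K <- vanraden_kinship(G)
  set.seed(62)
  y <- setNames(rnorm(nrow(G$dosages)), rownames(G$dosages))  # pure noise
  sc <- mlm_scan(G, y, K = K)
  pv <- sc$table$p[!is.na(sc$table$p)]
  expect_gt(length(pv), 200)
  expect_gt(mean(pv < 0.05), 0.01)
  expect_lt(mean(pv < 0.05), 0.10)
  expect_length(sc$discoveries, 0)
})

test_that("stratification audit flags confounded and clears genuine effects", {
  set.seed(44)
  n <- 120
  ids <- sprintf("s%03d", 1:n)
  sg <- rep(c("WLD", "CLT"), each = n / 2)
  meta <- data.frame(accession_id = ids, subgroup = sg, origin = "x",
                     stringsAsFactors = FALSE)
  # confounded marker: frequency differs by subgroup, trait driven by subgroup
  g_conf <- setNames(c(rbinom(n / 2, 2, 0.9), rbinom(n / 2, 2, 0.1)), ids)
  y_conf <- setNames(ifelse(sg == "WLD", 0, 2) + rnorm(n, 0, 0.5), ids)
  aud <- stratification_audit(g_conf, y_conf, meta)
  expect_true(aud$flagged)
  expect_lt(aud$pooled["p"], 0.05)
  # genuine within-subgroup additive effect
  g_true <- setNames(rbinom(n, 2, 0.5), ids)
  y_true <- setNames(0.8 * g_true + rnorm(n, 0, 0.5), ids)
  aud2 <- stratification_audit(g_true, y_true, meta)
  expect_false(aud2$flagged)
  expect_equal(sum(aud2$cells$n), n)
})
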