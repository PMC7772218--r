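test_that("PCA separates duplicated-genotype clusters on PC1", {
  set.seed(2)
  proto <- rbind(sample(0:2, 40, replace = TRUE),
                 sample(0:2, 40, replace = TRUE))
  dos <- proto[rep(1:2, each = 6), ]
  rownames(dos) <- sprintf("a%02d", 1:12)
  G <- toy_geno(dos)
  pc <- pca_genotypes(G)
  expect_gt(pc$explained[1], 0.999)
  s <- pc$scores[, 1]
  expect_true(all(sign(s[1:6]) == sign(s[1])) &&
                all(sign(s[7:12]) == -sign(s[1])))
})

test_that("PCA eigenvalues match an independent covariance eigendecomposition", {
  set.seed(9)
  dos <- matrix(sample(0:2, 12, replace = TRUE), 4, 3,
                dimnames = list(letters[1:4], NULL))
  G <- toy_geno(dos)
  pc <- pca_genotypes(G, n_comp = 3)
  # oracle: full eigendecomposition of the covariance of the coded matrix
  x <- scale(dos - 1, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(x) / (nrow(x) - 1), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(pc$sdev[seq_along(ev)]^2, ev, tolerance = 1e-10)
  expect_equal(pc$explained[seq_along(ev)], ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_error(pca_genotypes(toy_geno(matrix(1L, 3, 4,
                 dimnames = list(letters[1:3], NULL)))), "constant")
})

test_that("PCA scores are invariant to marker order up to component sign", {
  sim <- tiny_panel()
  G <- filter_markers(sim$genotypes)$genotypes
  pc1 <- pca_genotypes(G, n_comp = 4)
  set.seed(3)
  perm <- sample(ncol(G$dosages))
  # same dosages in permuted column order, coordinates refreshed
  G2 <- toy_geno(G$dosages[, perm])
  pc2 <- pca_genotypes(G2, n_comp = 4)
  for (k in 1:4)
    expect_equal(abs(cor(pc1$scores[, k], pc2$scores[, k])), 1,
                 tolerance = 1e-8)
})

test_that("Ward tree: duplicates merge at height 0; heights match the exhaustive oracle", {
  pts <- rbind(c(0, 0), c(0, 0), c(0.1, 0), c(10, 10), c(10, 10.2))
  rownames(pts) <- sprintf("p%d", 1:5)
  wt <- ward_tree(pts)
  expect_equal(min(wt$hclust$height), 0)      # exact duplicates merge first
  expect_true(all(diff(wt$hclust$height) >= -1e-12))
  expect_equal(sort(wt$hclust$height), ward_heights_oracle(pts),
               tolerance = 1e-10)
  # top split equals the planted partition {1,2,3} vs {4,5}
  top <- stats::cutree(wt$hclust, k = 2)
  expect_equal(unname(top), c(1L, 1L, 1L, 2L, 2L))
  expect_match(wt$newick, "^\\(.*\\);$")

  set.seed(11)
  m <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(sprintf("q%d", 1:8), NULL))
  expect_equal(sort(ward_tree(m)$hclust$height), ward_heights_oracle(m),
               tolerance = 1e-10)
})

test_that("ancestry fit: row-stochastic Q, monotone training loss, closed-form K = 1", {
  sim <- tiny_panel()
  G <- filter_markers(sim$genotypes)$genotypes
  fit <- snmf_fit(G, K = 2, n_replicates = 2, seed = 6, max_iter = 60)
  expect_equal(unname(rowSums(fit$Q)), rep(1, nrow(fit$Q)), tolerance = 1e-8)
  expect_true(all(fit$F >= 0 & fit$F <= 1))
  expect_true(all(diff(fit$loss_path) <= 1e-9))
  expect_gte(fit$cross_entropy, 0)

  f1 <- snmf_fit(G, K = 1, n_replicates = 1, seed = 6)
  expect_equal(unname(f1$Q[, 1]), rep(1, nrow(G$dosages)))
  # closed form: CE of the training-frequency model on the mask
  P <- G$dosages / 2
  expect_equal(f1$cross_entropy,
               local({
                 obs <- which(!is.na(P))
                 set.seed(derive_seed(6, 1))
                 mask <- sample(obs, max(1, round(0.05 * length(obs))))
                 W <- matrix(0, nrow(P), ncol(P)); W[obs] <- 1; W[mask] <- 0
                 Ptr <- P; Ptr[is.na(Ptr)] <- 0
                 f <- colSums(W * Ptr) / pmax(colSums(W), 1)
                 pred <- pmin(pmax(matrix(f, nrow(P), ncol(P),
                                          byrow = TRUE)[mask], 1e-6), 1 - 1e-6)
                 g <- 2 * P[mask]
                 -sum(g * log(pred) + (2 - g) * log(1 - pred)) / (2 * length(mask))
               }),
               tolerance = 1e-12)
})

test_that("ancestry recovery and K selection on a planted 3-population panel", {
  # three well-separated ancestral populations: strongly drifted allele
  # frequencies, mostly-pure individuals plus a 20% admixed fraction
  set.seed(40)
  n_per <- 25; K <- 3; n <- K * n_per; L <- 600
  Fm <- matrix(rbeta(K * L, 0.2, 0.2), K, L)
  Q <- matrix(0, n, K)
  Q[cbind(seq_len(n), rep(seq_len(K), each = n_per))] <- 1
  adm <- sample(n, round(0.2 * n))
  Q[adm, ] <- t(apply(matrix(rgamma(length(adm) * K, 1), ncol = K), 1,
                      function(v) v / sum(v)))
  dos <- matrix(rbinom(n * L, 2, as.vector(Q %*% Fm)), n, L,
                dimnames = list(sprintf("i%03d", seq_len(n)), NULL))
  keep <- which(apply(dos, 2, var) > 0)
  G <- toy_geno(dos)[, keep]
  fits <- lapply(1:5, function(k)
    snmf_fit(G, K = k, n_replicates = 3, mask_fraction = 0.1,
             seed = 20 + k, max_iter = 100))
  al <- align_ancestry(fits[[3]]$Q, Q)
  expect_lte(al$rmse, 0.10)
  expect_equal(select_k(fits)$K, 3)
  # single population: CE never rewards K > 1
  set.seed(41)
  dos1 <- matrix(rbinom(40 * 200, 2, rep(runif(200, 0.1, 0.9), each = 40)),
                 40, 200, dimnames = list(sprintf("j%02d", 1:40), NULL))
  G1 <- toy_geno(dos1)
  f1 <- lapply(1:3, function(k)
    snmf_fit(G1, k, n_replicates = 2, seed = 30 + k, max_iter = 60))
  expect_equal(select_k(f1)$K, 1)
})

test_that("select_k breaks ties toward the smallest K", {
  f <- function(k, ce) structure(list(K = k, cross_entropy = ce,
                                      ce_replicates = ce),
                                 class = "ancestry_fit")
  expect_equal(select_k(list(f(2, 0.5), f(3, 0.5), f(4, 0.6)))$K, 2)
  expect_equal(select_k(list(f(2, 0.6), f(3, 0.4), f(4, 0.5)))$K, 3)
  expect_error(select_k(list(f(2, 0.5))), "at least 2")
})
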