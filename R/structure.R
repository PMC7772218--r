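# -1/0/+1 coding with per-marker mean imputation of missing calls; the
# substrate for PCA and Ward clustering (ancestry estimation excludes
# missing entries instead of imputing)
code_genotypes <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  x <- G$dosages - 1
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  x[is.nan(x)] <- 0   # all-missing marker: impute to 0
  x
}

#' PCA of a genotype matrix
#'
#' Dosages are recoded to -1/0/+1, missing entries mean-imputed per marker,
#' columns centered, and the principal components extracted by singular
#' value decomposition. Explained-variance fractions are eigenvalues over
#' their sum.
#'
#' @param G a [geno_matrix()].
#' @param n_comp number of components to keep (default 10, capped at the
#'   matrix rank).
#' @return object of class `geno_pca`: `scores` (n x n_comp), `explained`
#'   (fraction per kept component), `sdev` (all singular values / sqrt(n-1)).
#' @export
pca_genotypes <- function(G, n_comp = 10) {
  x <- code_genotypes(G)
  x <- sweep(x, 2L, colMeans(x))
  if (all(abs(x) < 1e-12)) stop("constant genotype matrix: PCA undefined")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- min(n_comp, sum(ev > 1e-12 * ev[1]))
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 explained = ev[seq_len(k)] / sum(ev),
                 sdev = pc$sdev,
                 n_comp = k),
            class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat("genotype PCA: ", nrow(x$scores), " accessions, ", x$n_comp,
      " components; PC1 ", sprintf("%.2f%%", 100 * x$explained[1]),
      " of variance\n", sep = "")
  invisible(x)
}

#' Ward hierarchical clustering of accessions
#'
#' Ward minimum-variance agglomeration (`hclust`, method `ward.D2`) on
#' Euclidean distances over the -1/0/+1-coded, mean-imputed genotype matrix
#' (or any numeric score matrix). The tree is exported as a newick string.
#'
#' @param x a [geno_matrix()] or a numeric matrix (rows = accessions).
#' @return object of class `ward_tree`: `hclust` (the merge sequence),
#'   `phylo` (ape tree) and `newick`.
#' @export
ward_tree <- function(x) {
  m <- if (inherits(x, "geno_matrix")) code_genotypes(x) else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 accessions")
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  ph <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = ph,
                 newick = ape::write.tree(ph)),
            class = "ward_tree")
}

#' @export
print.ward_tree <- function(x, ...) {
  cat("Ward tree over", length(x$hclust$labels), "accessions;",
      "max merge height", fmt_num(max(x$hclust$height)), "\n")
  invisible(x)
}

#' Sparse-NMF-style ancestry estimation
#'
#' Factorises the individual allele-frequency matrix P = dosage / 2
#' (missing entries excluded from the loss) as Q F, with Q (n x K) row
#' stochastic - per-accession ancestry proportions - and F (K x L) in
#' \[0, 1\] - ancestral allele frequencies. The fit alternates projected
#' gradient steps on Q (simplex projection per row) and F (box clipping),
#' each with backtracking so the masked least-squares training loss never
#' increases. Per replicate, a random `mask_fraction` of the observed
#' entries is held out and the binomial cross-entropy on those entries
#' scores the replicate; the lowest-CE replicate is returned. This is the
#' same masked-prediction criterion family used by Structure-like
#' least-squares ancestry tools.
#'
#' @param G a [geno_matrix()].
#' @param K number of ancestral clusters (>= 1).
#' @param n_replicates independent restarts (default 5).
#' @param mask_fraction fraction of observed entries held out per replicate
#'   (default 0.05).
#' @param seed master seed; replicate seeds are derived from it.
#' @param max_iter,tol outer-iteration cap and relative-improvement
#'   stopping tolerance.
#' @return object of class `ancestry_fit`: `Q`, `F`, `K`,
#'   `cross_entropy` (masked CE of the best replicate), `ce_replicates`,
#'   `replicate`, `loss_path` (training loss per iteration), `converged`,
#'   `seed`.
#' @export
snmf_fit <- function(G, K, n_replicates = 5, mask_fraction = 0.05,
                     seed = NULL, max_iter = 200, tol = 1e-6) {
  stopifnot(inherits(G, "geno_matrix"), K >= 1, K <= nrow(G$dosages),
            mask_fraction > 0, mask_fraction < 1)
  P <- G$dosages / 2
  obs <- which(!is.na(P))
  if (length(obs) < 10L) stop("too few observed genotypes")
  seed <- seed %||% 1L
  fits <- lapply(seq_len(n_replicates), function(r) {
    snmf_one(P, obs, K, mask_fraction, derive_seed(seed, r),
             max_iter, tol, replicate = r)
  })
  ces <- vapply(fits, `[[`, numeric(1), "cross_entropy")
  best <- fits[[which.min(ces)]]
  best$ce_replicates <- ces
  best$seed <- seed
  best
}

snmf_one <- function(P, obs, K, mask_fraction, rep_seed, max_iter, tol,
                     replicate) {
  n <- nrow(P); L <- ncol(P)
  eps <- 1e-6
  with_seed(rep_seed, {
    mask <- sample(obs, max(1L, round(mask_fraction * length(obs))))
    W <- matrix(0, n, L)
    W[obs] <- 1
    W[mask] <- 0                      # training weight matrix
    Ptr <- P
    Ptr[is.na(Ptr)] <- 0

    if (K == 1L) {
      f <- colSums(W * Ptr) / pmax(colSums(W), 1)
      Q <- matrix(1, n, 1, dimnames = list(rownames(P), NULL))
      Fm <- matrix(f, 1, L, dimnames = list(NULL, colnames(P)))
      fit <- list(Q = Q, F = Fm, loss_path = masked_loss(Ptr, W, Q, Fm),
                  converged = TRUE)
    } else {
      fit <- snmf_pgd(Ptr, W, K, max_iter, tol)
    }
    ce <- masked_cross_entropy(P, mask, fit$Q, fit$F, eps)
    structure(list(K = K, Q = fit$Q, F = fit$F, cross_entropy = ce,
                   replicate = replicate, rep_seed = rep_seed,
                   loss_path = fit$loss_path, converged = fit$converged,
                   n_masked = length(mask)),
              class = "ancestry_fit")
  })
}

masked_loss <- function(P, W, Q, Fm) sum(W * (P - Q %*% Fm)^2)

# CE = -(1/(2|M|)) sum over masked entries of g log f + (2-g) log(1-f)
masked_cross_entropy <- function(P, mask, Q, Fm, eps = 1e-6) {
  pred <- (Q %*% Fm)[mask]
  pred <- pmin(pmax(pred, eps), 1 - eps)
  g <- 2 * P[mask]
  -sum(g * log(pred) + (2 - g) * log(1 - pred)) / (2 * length(mask))
}

# alternating projected-gradient blocks with backtracking; training loss is
# non-increasing by construction
snmf_pgd <- function(P, W, K, max_iter, tol) {
  n <- nrow(P); L <- ncol(P)
  # init: k-means on the leading PCs of the (training-weighted) matrix
  X <- P
  X[W == 0] <- mean(P[W == 1])
  pcs <- tryCatch(stats::prcomp(X, rank. = min(K + 2L, n - 1L))$x,
                  error = function(e) X[, seq_len(min(5L, L)), drop = FALSE])
  km <- tryCatch(stats::kmeans(pcs, centers = K, nstart = 3L),
                 error = function(e) list(cluster = sample(rep_len(seq_len(K), n))))
  Q <- matrix(0.1 / K, n, K)
  Q[cbind(seq_len(n), km$cluster)] <- Q[cbind(seq_len(n), km$cluster)] + 0.9
  Q <- Q / rowSums(Q)
  Fm <- crossprod(Q, W * P) / pmax(crossprod(Q, W), 1e-8)
  Fm <- pmin(pmax(Fm, 0.01), 0.99)

  loss <- masked_loss(P, W, Q, Fm)
  loss_path <- loss
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## F block
    R <- W * (Q %*% Fm - P)
    gF <- 2 * crossprod(Q, R)
    eta <- 1 / (2 * max(colSums(Q^2)) * max(colSums(W)) / n + 1e-8)
    repeat {
      Fn <- pmin(pmax(Fm - eta * gF, 0), 1)
      l1 <- masked_loss(P, W, Q, Fn)
      if (l1 <= loss || eta < 1e-12) break
      eta <- eta / 2
    }
    if (l1 <= loss) { Fm <- Fn; loss <- l1 }
    ## Q block
    R <- W * (Q %*% Fm - P)
    gQ <- 2 * tcrossprod(R, Fm)
    eta <- 1 / (2 * max(rowSums(Fm^2)) + 1e-8)
    repeat {
      Qn <- t(apply(Q - eta * gQ, 1L, project_simplex))
      l2 <- masked_loss(P, W, Qn, Fm)
      if (l2 <= loss || eta < 1e-12) break
      eta <- eta / 2
    }
    if (l2 <= loss) { Q <- Qn; loss <- l2 }
    loss_path <- c(loss_path, loss)
    prev <- loss_path[length(loss_path) - 1L]
    if (prev - loss <= tol * max(prev, 1e-12)) { converged <- TRUE; break }
  }
  rownames(Q) <- rownames(P); colnames(Fm) <- colnames(P)
  list(Q = Q, F = Fm, loss_path = loss_path, converged = converged)
}

# Euclidean projection onto the probability simplex (Duchi et al. 2008)
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  tau <- (css[rho] - 1) / rho
  pmax(v - tau, 0)
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat("ancestry fit: K = ", x$K, ", n = ", nrow(x$Q),
      "; masked cross-entropy ", fmt_num(x$cross_entropy),
      " (replicate ", x$replicate, ")\n", sep = "")
  invisible(x)
}

#' Choose the number of ancestral clusters by masked cross-entropy
#'
#' Given ancestry fits over a range of K (each carrying its replicate CE
#' values), returns the K minimising the mean masked cross-entropy;
#' ties go to the smallest K.
#'
#' @param fits list of [snmf_fit()] results (one element per K).
#' @return list with `K` (selected), `table` (data frame `K`, `mean_ce`,
#'   `best_ce`).
#' @export
select_k <- function(fits) {
  if (length(fits) < 2L) stop("need fits for at least 2 values of K")
  ks <- vapply(fits, `[[`, numeric(1), "K")
  mce <- vapply(fits, function(f)
    mean(f$ce_replicates %||% f$cross_entropy), numeric(1))
  bce <- vapply(fits, `[[`, numeric(1), "cross_entropy")
  ord <- order(ks)
  tab <- data.frame(K = ks[ord], mean_ce = mce[ord], best_ce = bce[ord])
  best <- tab$K[which(tab$mean_ce == min(tab$mean_ce))]
  list(K = min(best), table = tab)
}

#' Align an estimated Q matrix to a reference up to column permutation
#'
#' Ancestry components are identifiable only up to relabeling; this
#' searches all column permutations (K <= 8) for the one minimising the
#' root-mean-square difference to a reference Q.
#'
#' @param Q_hat,Q_ref n x K ancestry matrices.
#' @return list with `Q` (permuted `Q_hat`), `perm`, `rmse`.
#' @export
align_ancestry <- function(Q_hat, Q_ref) {
  stopifnot(ncol(Q_hat) == ncol(Q_ref), nrow(Q_hat) == nrow(Q_ref),
            ncol(Q_hat) <= 8L)
  perms <- permutations_of(ncol(Q_hat))
  best <- NULL; best_rmse <- Inf
  for (p in perms) {
    r <- sqrt(mean((Q_hat[, p, drop = FALSE] - Q_ref)^2))
    if (r < best_rmse) { best_rmse <- r; best <- p }
  }
  list(Q = Q_hat[, best, drop = FALSE], perm = best, rmse = best_rmse)
}

permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in permutations_of(k - 1L)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
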