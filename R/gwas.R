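#' VanRaden genomic relationship matrix
#'
#' A = W W' / (2 sum_j p_j (1 - p_j)) with W the mean-imputed dosage matrix
#' centred at twice the in-sample allele frequencies.
#'
#' @param G a [geno_matrix()].
#' @return n x n `kinship` matrix (symmetric, accession dimnames) with the
#'   allele-frequency vector as attribute `p`.
#' @export
vanraden_kinship <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  M <- G$dosages * 1.0
  p <- colMeans(M, na.rm = TRUE) / 2
  idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(idx)) M[idx] <- 2 * p[idx[, 2]]
  poly <- p > 0 & p < 1 & !is.na(p)
  if (sum(poly) < 2L) stop("need >= 2 polymorphic markers for kinship")
  W <- sweep(M, 2L, 2 * p)
  A <- tcrossprod(W) / (2 * sum(p[poly] * (1 - p[poly])))
  attr(A, "p") <- p
  A
}

#' Benjamini-Hochberg discovery control
#'
#' Step-up FDR control: monotone BH q-values and the discovery set at
#' level `alpha`.
#'
#' @param p_values p-values in (0, 1\]; `NA` entries are carried through.
#' @param alpha FDR level (default 0.1).
#' @return list with `q` (BH-adjusted p-values), `discoveries` (indices
#'   with q <= alpha), `alpha`.
#' @export
bh_fdr <- function(p_values, alpha = 0.1) {
  if (!length(p_values)) stop("empty p-value vector")
  ok <- !is.na(p_values)
  if (any(p_values[ok] <= 0 | p_values[ok] > 1))
    stop("p-values must lie in (0, 1]")
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  list(q = q, discoveries = which(!is.na(q) & q <= alpha), alpha = alpha)
}

# REML profile log-likelihood in delta = sigma2_e / sigma2_g for the
# rotated null model (EMMA-style); lambda = eigenvalues of the kinship
reml_delta <- function(y, X, U, lambda) {
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  n <- length(yt); p <- ncol(Xt)
  nll <- function(logd) {
    d <- exp(logd)
    w <- 1 / (lambda + d)
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    b <- backsolve(ch, forwardsolve(t(ch), crossprod(XtW, yt)))
    r <- yt - Xt %*% b
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    0.5 * ((n - p) * log(2 * pi * s2) - sum(log(w)) +
             2 * sum(log(diag(ch))) + (n - p))
  }
  opt <- stats::optimize(nll, c(-10, 10))
  delta <- exp(opt$minimum)
  w <- 1 / (lambda + delta)
  Xt <- crossprod(U, X); yt <- crossprod(U, y)
  XtWX <- crossprod(Xt, Xt * w)
  b <- solve(XtWX, crossprod(Xt * w, yt))
  s2g <- sum(w * (yt - Xt %*% b)^2) / (n - ncol(Xt))
  list(delta = delta, sigma2_g = s2g, sigma2_e = s2g * delta)
}

#' Mixed-linear-model association scan (EMMAX / P3D)
#'
#' Single-marker association testing under
#' `y = X b + g beta + u + e`, `u ~ N(0, K sigma2_g)`. The kinship is
#' eigendecomposed once, the variance ratio `delta` is REML-estimated
#' under the covariates-only null (the P3D approximation), and each
#' marker is then tested by generalized least squares with a Wald t-test.
#' Markers collinear with the covariates (or monomorphic / below the
#' subset MAF floor) are flagged and not tested. Ancestry (Q) covariates
#' should be supplied as K-1 columns to avoid the sum-to-one collinearity;
#' [run_pipeline()] does this automatically.
#'
#' @param G a [geno_matrix()].
#' @param y named numeric vector of per-accession trait values (typically
#'   GBLUPs); names are accession ids.
#' @param covariates optional matrix of per-accession covariates (rows
#'   named by accession), e.g. PC1-10 and ancestry proportions.
#' @param K kinship matrix (see [vanraden_kinship()]).
#' @param subset optional accession ids to restrict the scan to (e.g. one
#'   subgroup).
#' @param min_maf markers below this within-scan MAF are flagged
#'   `low_maf` and skipped (default 0.05).
#' @param alpha FDR level for the BH discovery set (default 0.1).
#' @return object of class `mlm_scan`: `table` (per marker: `chrom`,
#'   `pos`, `beta`, `se`, `p`, `q`, `flag`), `delta`, `sigma2_g`,
#'   `sigma2_e`, `n`, `discoveries`.
#' @export
mlm_scan <- function(G, y, covariates = NULL, K, subset = NULL,
                     min_maf = 0.05, alpha = 0.1) {
  stopifnot(inherits(G, "geno_matrix"))
  ids <- intersect(rownames(G$dosages), names(y)[!is.na(y)])
  if (!is.null(subset)) ids <- intersect(ids, subset)
  if (length(ids) < 30L)
    stop("trait defined for fewer than 30 accessions in scan subset")
  yv <- y[ids]
  Kss <- K[ids, ids]
  X <- matrix(1, length(ids), 1)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)[ids, , drop = FALSE]
    X <- cbind(X, cv)
  }
  # drop collinear covariate columns
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]

  eg <- eigen(Kss, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("kinship is not positive semi-definite on the scan subset")
  lambda <- pmax(eg$values, 0)
  U <- eg$vectors
  vc <- reml_delta(yv, X, U, lambda)
  w <- 1 / (lambda + vc$delta)
  sw <- sqrt(w)
  yt <- crossprod(U, yv) * sw
  Xt <- crossprod(U, X) * sw

  # per-marker dosages, mean-imputed within the scan subset
  M <- G$dosages[ids, , drop = FALSE] * 1.0
  pfr <- colMeans(M, na.rm = TRUE) / 2
  idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(idx)) M[idx] <- 2 * pfr[idx[, 2]]
  maf <- pmin(pfr, 1 - pfr)

  L <- ncol(M)
  beta <- se <- pval <- rep(NA_real_, L)
  flag <- rep("", L)
  XtX <- crossprod(Xt)
  Mt <- crossprod(U, M) * sw
  n <- length(yv); p0 <- ncol(Xt)
  for (j in seq_len(L)) {
    if (is.na(maf[j]) || maf[j] < min_maf) { flag[j] <- "low_maf"; next }
    g <- Mt[, j]
    Xa <- cbind(Xt, g)
    qra <- qr(Xa)
    if (qra$rank < ncol(Xa)) { flag[j] <- "collinear"; next }
    cf <- qr.coef(qra, yt)
    res <- yt - Xa %*% cf
    df <- n - ncol(Xa)
    s2 <- sum(res^2) / df
    Ri <- chol2inv(qr.R(qra))            # (Xa'Xa)^-1 in pivoted order
    pos <- which(qra$pivot == ncol(Xa))  # marker column after pivoting
    se_j <- sqrt(s2 * Ri[pos, pos])
    beta[j] <- cf[length(cf)]
    se[j] <- se_j
    pval[j] <- 2 * stats::pt(abs(beta[j] / se_j), df, lower.tail = FALSE)
  }
  fdr <- bh_fdr(ifelse(is.na(pval), NA, pmax(pval, .Machine$double.xmin)),
                alpha = alpha)
  tab <- data.frame(id = G$markers$id, chrom = G$markers$chrom,
                    pos = G$markers$pos, beta = beta, se = se, p = pval,
                    q = fdr$q, flag = flag, stringsAsFactors = FALSE)
  structure(list(table = tab, delta = vc$delta, sigma2_g = vc$sigma2_g,
                 sigma2_e = vc$sigma2_e, n = length(ids),
                 covariate_rank = ncol(X), alpha = alpha,
                 discoveries = fdr$discoveries, subset = subset),
            class = "mlm_scan")
}

#' @export
print.mlm_scan <- function(x, ...) {
  cat("MLM scan: ", x$n, " accessions, ", nrow(x$table), " markers; delta ",
      fmt_num(x$delta), "; ", length(x$discoveries),
      " discovery(ies) at FDR ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Stratification audit of a marker-trait association
#'
#' Cross-tabulates genotype classes by subgroup (counts and trait means)
#' and contrasts the pooled additive effect with within-subgroup effects.
#' An association is flagged as potentially stratification-driven when the
#' pooled effect is nominally significant but no subgroup shows a
#' same-direction nominally significant effect - the signature of an
#' effect carried entirely by between-subgroup differences.
#'
#' @param g named dosage vector for one marker.
#' @param y named trait vector.
#' @param meta metadata data frame.
#' @param p_threshold nominal significance level for the audit
#'   (default 0.05).
#' @return list of class `strat_audit`: `cells` (subgroup x genotype
#'   counts and means), `pooled` (effect, p), `within` (per-subgroup
#'   effect, p), `flagged`.
#' @export
stratification_audit <- function(g, y, meta, p_threshold = 0.05) {
  ids <- intersect(intersect(names(g), names(y)), meta$accession_id)
  ids <- ids[!is.na(g[ids]) & !is.na(y[ids])]
  sg <- meta$subgroup[match(ids, meta$accession_id)]
  gv <- g[ids]; yv <- y[ids]
  cells <- do.call(rbind, lapply(split(seq_along(ids), sg), function(ii) {
    do.call(rbind, lapply(split(ii, gv[ii]), function(jj)
      data.frame(subgroup = sg[jj[1]], genotype = gv[jj[1]],
                 n = length(jj), mean = mean(yv[jj]))))
  }))
  rownames(cells) <- NULL
  pooled_fit <- stats::lm(yv ~ gv)
  pooled <- c(effect = unname(stats::coef(pooled_fit)[2]),
              p = summary(pooled_fit)$coefficients[2, 4])
  within <- do.call(rbind, lapply(split(seq_along(ids), sg), function(ii) {
    if (length(unique(gv[ii])) < 2L || length(ii) < 3L)
      return(data.frame(subgroup = sg[ii[1]], effect = NA_real_,
                        p = NA_real_))
    f <- stats::lm(yv[ii] ~ gv[ii])
    data.frame(subgroup = sg[ii[1]],
               effect = unname(stats::coef(f)[2]),
               p = summary(f)$coefficients[2, 4])
  }))
  rownames(within) <- NULL
  same_dir <- !is.na(within$p) & within$p < p_threshold &
    sign(within$effect) == sign(pooled["effect"])
  flagged <- pooled["p"] < p_threshold && !any(same_dir)
  structure(list(cells = cells, pooled = pooled, within = within,
                 flagged = unname(flagged)),
            class = "strat_audit")
}

#' @export
print.strat_audit <- function(x, ...) {
  cat("stratification audit: pooled effect ", fmt_num(x$pooled["effect"]),
      " (p = ", format(x$pooled["p"]), "); ",
      if (x$flagged) "FLAGGED: no within-subgroup support"
      else "supported within subgroup(s)", "\n", sep = "")
  invisible(x)
}
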