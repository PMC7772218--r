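# Weir & Cockerham (1984) two-population theta-hat from per-group,
# per-locus summaries: n = individuals with calls, p = alt-allele frequency,
# h = observed heterozygote fraction. Vectorised over loci. Returns the
# variance components so callers can form either the per-locus ratio or the
# ratio-of-sums estimator.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  ok <- n1 >= 2 & n2 >= 2
  nbar <- (n1 + n2) / 2
  nC <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nC) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  list(a = a, b = b, c = cc)
}

wc_theta_from_components <- function(comp) {
  denom <- comp$a + comp$b + comp$c
  theta <- comp$a / denom
  theta[!is.na(denom) & denom == 0] <- NA_real_  # both groups fixed alike
  theta
}

# per-locus group summaries from a dosage submatrix
group_locus_stats <- function(d) {
  n <- colSums(!is.na(d))
  p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA_real_)
  h <- ifelse(n > 0, colSums(d == 1L, na.rm = TRUE) / n, NA_real_)
  list(n = n, p = p, h = h)
}

#' Weir-Cockerham F_ST at a single locus
#'
#' Two-population theta-hat of Weir & Cockerham (1984), computed from
#' genotype counts via the variance components a (among populations),
#' b (among individuals within populations) and c (within individuals).
#' Negative estimates are retained. Undefined (NA) when both groups are
#' fixed for the same allele or either group has fewer than two genotyped
#' individuals.
#'
#' @param counts_a,counts_b integer vectors `c(n_AA, n_Aa, n_aa)` of
#'   genotype counts in the two groups.
#' @param estimator `"wc"` (default) for Weir-Cockerham theta-hat or
#'   `"nei"` for Nei's G_ST (sensitivity switch).
#' @return a single F_ST estimate (possibly `NA`).
#' @examples
#' wc_fst_locus(c(10, 0, 0), c(0, 0, 10))  # complete fixation: 1
#' @export
wc_fst_locus <- function(counts_a, counts_b, estimator = c("wc", "nei")) {
  estimator <- match.arg(estimator)
  stopifnot(length(counts_a) == 3L, length(counts_b) == 3L,
            all(counts_a >= 0), all(counts_b >= 0))
  n1 <- sum(counts_a); n2 <- sum(counts_b)
  if (n1 < 2 || n2 < 2) return(NA_real_)
  p1 <- (2 * counts_a[3] + counts_a[2]) / (2 * n1)
  p2 <- (2 * counts_b[3] + counts_b[2]) / (2 * n2)
  h1 <- counts_a[2] / n1
  h2 <- counts_b[2] / n2
  if (estimator == "nei") return(nei_gst(p1, p2))
  wc_theta_from_components(wc_components(n1, p1, h1, n2, p2, h2))
}

# Nei-style G_ST = (Ht - Hs) / Ht with unweighted subpopulation means
nei_gst <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  Ht <- 2 * pbar * (1 - pbar)
  Hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  out <- (Ht - Hs) / Ht
  out[Ht == 0] <- NA_real_
  out
}

#' Genome-wide F_ST scan between two subgroups
#'
#' Per-locus Weir-Cockerham theta-hat for one subgroup pair, with the
#' arithmetic mean over defined loci (negative estimates retained), the
#' per-locus maximum, and the ratio-of-sums (Weir-Cockerham overall)
#' estimate as a companion summary.
#'
#' @param G a [geno_matrix()].
#' @param meta metadata data frame.
#' @param pair character vector of two subgroup labels.
#' @param estimator `"wc"` or `"nei"` (see [wc_fst_locus()]).
#' @return object of class `fst_scan`: per-locus `theta` (named by marker),
#'   `mean_fst`, `max_fst`, `fst_ratio_of_sums`, `n_defined`, `pair`.
#' @export
fst_scan <- function(G, meta, pair, estimator = c("wc", "nei")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(G, "geno_matrix"), length(pair) == 2L)
  meta <- check_metadata(G, meta)
  ids_a <- subgroup_ids(meta, pair[1])
  ids_b <- subgroup_ids(meta, pair[2])
  if (setequal(ids_a, ids_b)) stop("subgroup pair has identical membership")
  scan_from_ids(G, ids_a, ids_b, pair, estimator)
}

scan_from_ids <- function(G, ids_a, ids_b, pair, estimator = "wc") {
  sa <- group_locus_stats(G$dosages[ids_a, , drop = FALSE])
  sb <- group_locus_stats(G$dosages[ids_b, , drop = FALSE])
  if (estimator == "nei") {
    theta <- nei_gst(sa$p, sb$p)
    theta[sa$n < 2 | sb$n < 2] <- NA_real_
    ros <- NA_real_
  } else {
    comp <- wc_components(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
    theta <- wc_theta_from_components(comp)
    def <- !is.na(theta)
    ros <- sum(comp$a[def]) / sum((comp$a + comp$b + comp$c)[def])
  }
  names(theta) <- G$markers$id
  structure(list(pair = pair, theta = theta,
                 mean_fst = mean(theta, na.rm = TRUE),
                 max_fst = if (all(is.na(theta))) NA_real_ else
                   max(theta, na.rm = TRUE),
                 fst_ratio_of_sums = ros,
                 n_defined = sum(!is.na(theta)),
                 estimator = estimator,
                 markers = G$markers[c("id", "chrom", "pos")]),
            class = "fst_scan")
}

#' @export
print.fst_scan <- function(x, ...) {
  cat("F_ST scan ", x$pair[1], " vs ", x$pair[2], " (", x$estimator, "): ",
      x$n_defined, " defined loci; mean ", fmt_num(x$mean_fst),
      "; max ", fmt_num(x$max_fst), sep = "")
  if (!is.null(x$perm_threshold_p95))
    cat("; perm p95 ", fmt_num(x$perm_threshold_p95), " (",
        x$n_significant, " significant, R = ", x$R, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Permutation significance threshold for an F_ST scan
#'
#' Builds an empirical null for per-locus theta-hat by shuffling the pooled
#' membership labels of the two subgroups (group sizes preserved), and takes
#' the `q`-quantile. By default all defined per-locus permuted values across
#' all `R` iterations are pooled into one null distribution
#' (`mode = "pooled"`); `mode = "per_iteration_max"` instead collects each
#' iteration's genome-wide maximum (a family-wise variant).
#'
#' @inheritParams fst_scan
#' @param R number of permutation iterations (default 1000).
#' @param q quantile of the null (default 0.95).
#' @param seed RNG seed; the threshold is deterministic given the seed.
#' @param mode `"pooled"` (default) or `"per_iteration_max"`.
#' @return an `fst_scan` augmented with `perm_threshold_p95`,
#'   `n_significant` (observed loci strictly above the threshold), `R`,
#'   `q`, `seed`, `mode`.
#' @export
fst_permutation_threshold <- function(G, meta, pair, R = 1000, q = 0.95,
                                      seed = NULL,
                                      mode = c("pooled", "per_iteration_max"),
                                      estimator = c("wc", "nei")) {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  if (R < 1) stop("R must be >= 1")
  if (q <= 0 || q >= 1) stop("q must be in (0,1)")
  obs <- fst_scan(G, meta, pair, estimator = estimator)
  meta <- check_metadata(G, meta)
  ids_a <- subgroup_ids(meta, pair[1])
  ids_b <- subgroup_ids(meta, pair[2])
  pool <- c(ids_a, ids_b)
  n_a <- length(ids_a)
  null_vals <- with_seed(seed, {
    vals <- vector("list", R)
    for (r in seq_len(R)) {
      perm <- sample(pool)
      th <- scan_from_ids(G, perm[seq_len(n_a)], perm[-seq_len(n_a)],
                          pair, estimator)$theta
      th <- th[!is.na(th)]
      vals[[r]] <- if (mode == "pooled") th else
        if (length(th)) max(th) else NULL
    }
    unlist(vals, use.names = FALSE)
  })
  if (!length(null_vals)) stop("permutation null is empty")
  thr <- unname(stats::quantile(null_vals, q, names = FALSE))
  obs$perm_threshold_p95 <- thr
  obs$n_significant <- sum(obs$theta > thr, na.rm = TRUE)
  obs$null_mean <- mean(null_vals)
  obs$R <- R; obs$q <- q; obs$seed <- seed; obs$mode <- mode
  obs
}
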