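# Independent brute-force oracles used across the suite. These deliberately
# take a different computational route from the package implementation.

# Weir-Cockerham theta via the nested-ANOVA mean-squares route:
# alleles within individuals within populations.
wc_oracle <- function(counts_a, counts_b) {
  geno <- function(cnt) rep(c(0L, 1L, 2L), cnt)
  g <- list(geno(counts_a), geno(counts_b))
  n <- vapply(g, length, 0L)
  if (any(n < 2L)) return(NA_real_)
  N <- sum(n); r <- 2
  dos <- unlist(g)
  pop <- rep(1:2, n)
  p_ind <- dos / 2
  p_pop <- tapply(dos, pop, sum) / (2 * n)
  pbar <- sum(dos) / (2 * N)
  SSP <- sum(2 * n * (p_pop - pbar)^2)
  SSI <- sum(2 * (p_ind - p_pop[pop])^2)
  SSG <- sum(ifelse(dos == 1L, 0.5, 0))
  MSP <- SSP / (r - 1); MSI <- SSI / (N - r); MSG <- SSG / N
  nc <- (N - sum(n^2) / N) / (r - 1)
  a <- (MSP - MSI) / (2 * nc); b <- (MSI - MSG) / 2; cc <- MSG
  denom <- a + b + cc
  if (denom == 0) return(NA_real_)
  a / denom
}

# Pearson r^2 from the raw sum formulas
pearson_r2_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}

# Benjamini-Hochberg discoveries by exhaustive step-up
bh_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * alpha / m) k <- i
  if (k == 0L) return(integer(0))
  sort(o[seq_len(k)])
}

# VanRaden A by explicit element-by-element loops
vanraden_oracle <- function(M) {
  n <- nrow(M); L <- ncol(M)
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (l in seq_len(L)) s <- s + (M[i, l] - 2 * p[l]) * (M[j, l] - 2 * p[l])
    A[i, j] <- s / denom
  }
  A
}

# Ward (ward.D2) agglomeration by exhaustive Lance-Williams updates;
# returns the sorted merge heights
ward_heights_oracle <- function(x) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  active <- seq_len(n)
  size <- rep(1L, n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (d[i, j] < bd) { bd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bd)
    ni <- size[i]; nj <- size[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      d2 <- ((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
               nk * d[i, j]^2) / (ni + nj + nk)
      d[i, k] <- d[k, i] <- sqrt(d2)
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  sort(heights)
}

# small panel shared by several test files (memoised per session)
tiny_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scenario_config(n_wld = 24, n_ns = 24, n_clt1 = 10, n_clt2 = 16,
                             n_markers = 300, n_founders_stage2 = 5,
                             n_polygenes = 60, years = 2,
                             missing_rate = 0.08)
      cache <<- simulate_panel(cfg, seed = 421)
    }
    cache
  }
})

# build a geno_matrix from a bare dosage matrix (markers evenly spaced on
# one or more chromosomes)
toy_geno <- function(dos, chrom = "chr01", spacing = 1000L) {
  n <- nrow(dos); L <- ncol(dos)
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("acc%02d", seq_len(n))
  per <- ceiling(L / length(chrom))
  mk <- data.frame(
    chrom = rep(chrom, each = per)[seq_len(L)],
    pos = rep(seq_len(per) * spacing, length(chrom))[seq_len(L)])
  mk$id <- paste0(mk$chrom, "_", mk$pos)
  mk$ref <- "A"; mk$alt <- "G"
  geno_matrix(dos, mk[c("id", "chrom", "pos", "ref", "alt")])
}

# metadata with one subgroup label per accession
toy_meta <- function(G, subgroup) {
  data.frame(accession_id = rownames(G$dosages), subgroup = subgroup,
             origin = "toy", stringsAsFactors = FALSE)
}
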