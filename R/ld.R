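#' Composite LD between two loci
#'
#' Squared Pearson correlation of genotype dosages (unphased composite
#' r^2), on pairwise-complete observations. Undefined when fewer than
#' three complete pairs remain or either locus is monomorphic on the
#' complete subset.
#'
#' @param x,y dosage vectors for the two loci.
#' @return r^2 in \[0, 1\], or `NA` when undefined.
#' @export
pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Intra-chromosomal LD decay curve for one subgroup
#'
#' Computes r^2 for all intra-chromosomal marker pairs separated by at most
#' `max_bp`, bins pair distances into non-overlapping `bin_bp` windows
#' (default 10 kb), and pools pairs across chromosomes (per-chromosome
#' curves are also returned). The half-decay distance is the upper edge of
#' the first bin whose mean r^2 falls to half the first bin's mean - the
#' observed maximum; no asymptote is subtracted. A curve with no decay
#' structure (no bin ever reaches half the first-bin mean, as for unlinked
#' loci) reports the first bin's upper edge: LD is at its floor from the
#' start. Pairs at identical positions (distance 0) are excluded.
#'
#' @param G a [geno_matrix()].
#' @param meta metadata data frame.
#' @param subgroup subgroup label whose accessions are used.
#' @param bin_bp bin width in bp (default 10000).
#' @param max_bp maximum pair distance in bp (default 500000).
#' @return object of class `ld_decay`: `curve` (data frame `bin_start`,
#'   `bin_end`, `n_pairs`, `mean_r2`), `half_decay_bp`, `per_chromosome`
#'   (list of curves), `n_pairs_total`.
#' @export
ld_decay <- function(G, meta, subgroup, bin_bp = 10000, max_bp = 500000) {
  stopifnot(inherits(G, "geno_matrix"), bin_bp > 0, max_bp >= bin_bp)
  meta <- check_metadata(G, meta)
  d <- G$dosages[subgroup_ids(meta, subgroup), , drop = FALSE]
  n_bins <- as.integer(ceiling(max_bp / bin_bp))
  per_chrom <- list()
  tot_n <- numeric(n_bins); tot_s <- numeric(n_bins)
  for (ch in unique(G$markers$chrom)) {
    jj <- which(G$markers$chrom == ch)
    if (length(jj) < 2L) next
    dm <- d[, jj, drop = FALSE]
    pos <- G$markers$pos[jj]
    r <- suppressWarnings(stats::cor(dm, use = "pairwise.complete.obs"))
    cnt <- crossprod(!is.na(dm))           # complete-pair counts
    r2 <- r^2
    r2[cnt < 3L] <- NA_real_
    ut <- upper.tri(r2)
    dist <- abs(outer(pos, pos, "-"))[ut]
    vals <- r2[ut]
    keep <- !is.na(vals) & dist > 0 & dist <= max_bp
    if (!any(keep)) next
    bins <- pmin(floor(dist[keep] / bin_bp), n_bins - 1L) + 1L
    n_ch <- tabulate(bins, n_bins)
    s_ch <- numeric(n_bins)
    agg <- rowsum(vals[keep], bins)
    s_ch[as.integer(rownames(agg))] <- agg[, 1]
    tot_n <- tot_n + n_ch; tot_s <- tot_s + s_ch
    per_chrom[[ch]] <- make_ld_curve(n_ch, s_ch, bin_bp)
  }
  if (sum(tot_n) == 0) stop("no eligible marker pairs for subgroup ", subgroup)
  curve <- make_ld_curve(tot_n, tot_s, bin_bp)
  structure(list(subgroup = subgroup, curve = curve,
                 half_decay_bp = half_decay(curve),
                 per_chromosome = per_chrom,
                 bin_bp = bin_bp, max_bp = max_bp,
                 n_pairs_total = sum(tot_n)),
            class = "ld_decay")
}

make_ld_curve <- function(n, s, bin_bp) {
  b <- seq_along(n) - 1L
  data.frame(bin_start = b * bin_bp, bin_end = (b + 1L) * bin_bp,
             n_pairs = n, mean_r2 = ifelse(n > 0, s / n, NA_real_))
}

# upper edge of the first bin whose mean r2 <= half of the first
# (non-empty) bin's mean; when no bin ever falls that low (no decay
# structure, e.g. unlinked loci), LD is already at its floor within the
# first bin and its upper edge is returned
half_decay <- function(curve) {
  filled <- which(curve$n_pairs > 0)
  if (!length(filled)) return(NA_real_)
  base <- curve$mean_r2[filled[1]]
  hit <- filled[which(curve$mean_r2[filled] <= base / 2)]
  if (!length(hit)) return(curve$bin_end[filled[1]])
  curve$bin_end[hit[1]]
}

#' @export
print.ld_decay <- function(x, ...) {
  first <- x$curve$mean_r2[which(x$curve$n_pairs > 0)[1]]
  cat("LD decay, subgroup ", x$subgroup, ": ", x$n_pairs_total,
      " pairs in ", x$bin_bp / 1000, "-kb bins; first-bin mean r2 ",
      fmt_num(first), "; half-decay at ",
      ifelse(is.na(x$half_decay_bp), "NA",
             paste0(x$half_decay_bp / 1000, " kb")), "\n", sep = "")
  invisible(x)
}

#' @export
plot.ld_decay <- function(x, ...) {
  cv <- x$curve[x$curve$n_pairs > 0, ]
  graphics::plot((cv$bin_start + cv$bin_end) / 2000, cv$mean_r2, type = "b",
                 xlab = "distance (kb)", ylab = expression(mean ~ r^2),
                 main = paste("LD decay:", x$subgroup), ...)
  if (!is.na(x$half_decay_bp))
    graphics::abline(v = x$half_decay_bp / 1000, lty = 2)
  invisible(x)
}
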