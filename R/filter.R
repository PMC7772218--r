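#' Marker filtering by missingness and minor allele frequency
#'
#' Applies the two standard GBS marker filters in sequence: first drop
#' markers whose missing-call fraction exceeds `max_missing`, then drop
#' markers whose panel-wide minor allele frequency (computed on non-missing
#' calls) falls below `min_maf`. The order only affects how removals are
#' attributed in the report, not the retained set. Retained markers keep
#' their genomic order.
#'
#' @param G a [geno_matrix()].
#' @param max_missing maximum tolerated missing fraction per marker
#'   (default 0.30).
#' @param min_maf minimum panel-wide MAF (default 0.05).
#' @return list with `genotypes` (filtered `geno_matrix`) and `report`
#'   (a `filter_report`: input / removed / retained counts and the
#'   thresholds used).
#' @examples
#' g <- geno_matrix(matrix(c(0L,1L,2L,0L), 2, 2,
#'                         dimnames = list(c("a","b"), NULL)),
#'                  data.frame(id = c("m1","m2"), chrom = "chr1",
#'                             pos = c(1L,2L), ref = "A", alt = "C"))
#' filter_markers(g, max_missing = 1, min_maf = 0)$report
#' @export
filter_markers <- function(G, max_missing = 0.30, min_maf = 0.05) {
  stopifnot(inherits(G, "geno_matrix"))
  if (max_missing < 0 || max_missing > 1) stop("max_missing must be in [0,1]")
  if (min_maf < 0 || min_maf > 1) stop("min_maf must be in [0,1]")
  d <- G$dosages
  L <- ncol(d)
  miss_frac <- colMeans(is.na(d))
  pass_miss <- miss_frac <= max_missing

  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0           # all-missing marker: no defined frequency
  pass_maf <- maf >= min_maf

  keep <- pass_miss & pass_maf
  if (!any(keep)) stop("no markers retained by filters (max_missing = ",
                       max_missing, ", min_maf = ", min_maf, ")")
  report <- structure(list(
    n_input_snps = L,
    n_removed_missing = sum(!pass_miss),
    n_removed_maf = sum(pass_miss & !pass_maf),
    n_retained = sum(keep),
    max_missing = max_missing,
    min_maf = min_maf), class = "filter_report")
  list(genotypes = G[, keep], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("marker filter: ", x$n_input_snps, " input SNPs; ",
      x$n_removed_missing, " removed (missing > ", x$max_missing, "); ",
      x$n_removed_maf, " removed (MAF < ", x$min_maf, "); ",
      x$n_retained, " retained\n", sep = "")
  invisible(x)
}
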