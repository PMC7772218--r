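#' Per-subgroup allele-frequency table
#'
#' Computes, for each subgroup and marker, the alternate-allele frequency
#' `p`, the minor allele frequency `maf = min(p, 1 - p)`, the expected
#' heterozygosity `he = 2 p (1 - p)`, and the number of non-missing
#' accessions `n_obs`. Frequencies use non-missing dosages only; markers
#' with zero observations in a subgroup are flagged undefined (`p = NA`).
#'
#' @param G a [geno_matrix()].
#' @param meta metadata data frame (see [read_metadata()]).
#' @param subgroups subgroups to tabulate (default: all present).
#' @return data frame of class `freq_table` with columns `subgroup`, `id`,
#'   `chrom`, `pos`, `p`, `maf`, `he`, `n_obs`.
#' @export
subgroup_freqs <- function(G, meta, subgroups = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  meta <- check_metadata(G, meta)
  subgroups <- subgroups %||% unique(meta$subgroup)
  out <- lapply(subgroups, function(sg) {
    ids <- subgroup_ids(meta, sg)
    d <- G$dosages[ids, , drop = FALSE]
    n_obs <- colSums(!is.na(d))
    p <- ifelse(n_obs > 0, colMeans(d, na.rm = TRUE) / 2, NA_real_)
    data.frame(subgroup = sg, id = G$markers$id, chrom = G$markers$chrom,
               pos = G$markers$pos, p = p, maf = pmin(p, 1 - p),
               he = 2 * p * (1 - p), n_obs = n_obs,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  class(res) <- c("freq_table", "data.frame")
  res
}

#' Expected heterozygosity
#'
#' He = 2 p (1 - p) at a biallelic locus; the diversity measure behind the
#' reduction-of-diversity statistic.
#'
#' @param p allele frequency (vector allowed; `NA` propagates).
#' @return numeric vector of He values.
#' @export
expected_het <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  2 * p * (1 - p)
}

#' Polymorphic marker count and fraction in one subgroup
#'
#' A marker is polymorphic within a subgroup iff its within-subgroup allele
#' frequency satisfies 0 < p < 1. Two denominators are reported: the full
#' filtered marker set (`fraction_total`, the convention used for printed
#' panel percentages) and the markers with a defined frequency in the
#' subgroup (`fraction_defined`).
#'
#' @param freqs a `freq_table` from [subgroup_freqs()] built on the filtered
#'   panel-wide marker set.
#' @param subgroup subgroup label.
#' @return list with `count`, `n_total`, `n_defined`, `fraction_total`,
#'   `fraction_defined`.
#' @export
polymorphic_fraction <- function(freqs, subgroup) {
  f <- freqs[freqs$subgroup == subgroup, , drop = FALSE]
  if (!nrow(f)) stop("subgroup not present in frequency table: ", subgroup)
  defined <- !is.na(f$p)
  poly <- defined & f$p > 0 & f$p < 1
  list(count = sum(poly),
       n_total = nrow(f),
       n_defined = sum(defined),
       fraction_total = sum(poly) / nrow(f),
       fraction_defined = if (any(defined)) sum(poly) / sum(defined) else NA_real_)
}

#' Joint MAF contingency table for a pair of subgroups
#'
#' Bins the per-marker MAFs of two subgroups into a two-way contingency
#' table over half-open bins `[l, l + w)`, the final bin closed at 0.5.
#' Similar subgroups concentrate mass on the diagonal; the reported
#' `diagonal_mass` (fraction of markers falling in identical bins) is the
#' scalar summary used to compare domestication stages.
#'
#' @param freqs a `freq_table` from [subgroup_freqs()].
#' @param subgroup_a,subgroup_b subgroup labels.
#' @param bin_width bin width; must divide 0.5 exactly (default 0.05).
#' @return list of class `joint_maf` with `table` (B x B counts, subgroup A
#'   in rows), `breaks`, `diagonal_mass`, `n_markers`.
#' @export
joint_maf <- function(freqs, subgroup_a, subgroup_b, bin_width = 0.05) {
  nb <- 0.5 / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stop("bin_width must divide 0.5 exactly")
  nb <- as.integer(round(nb))
  fa <- freqs[freqs$subgroup == subgroup_a, , drop = FALSE]
  fb <- freqs[freqs$subgroup == subgroup_b, , drop = FALSE]
  if (!nrow(fa) || !nrow(fb)) stop("subgroup missing from frequency table")
  fb <- fb[match(fa$id, fb$id), , drop = FALSE]
  ok <- !is.na(fa$maf) & !is.na(fb$maf)
  if (!any(ok)) stop("no marker with defined MAF in both subgroups")
  bin_of <- function(m) pmin(floor(m / bin_width), nb - 1L) + 1L
  ia <- bin_of(fa$maf[ok]); ib <- bin_of(fb$maf[ok])
  breaks <- seq(0, 0.5, by = bin_width)
  tab <- matrix(0L, nb, nb,
                dimnames = list(a = paste0("[", utils::head(breaks, -1), ",",
                                           breaks[-1], ")"),
                                b = paste0("[", utils::head(breaks, -1), ",",
                                           breaks[-1], ")")))
  for (k in seq_along(ia)) tab[ia[k], ib[k]] <- tab[ia[k], ib[k]] + 1L
  structure(list(table = tab, breaks = breaks,
                 subgroups = c(subgroup_a, subgroup_b),
                 diagonal_mass = sum(diag(tab)) / sum(tab),
                 n_markers = sum(ok)),
            class = "joint_maf")
}

#' @export
print.joint_maf <- function(x, ...) {
  cat("joint MAF table ", x$subgroups[1], " vs ", x$subgroups[2], ": ",
      x$n_markers, " markers, diagonal mass ",
      fmt_num(x$diagonal_mass), "\n", sep = "")
  invisible(x)
}
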