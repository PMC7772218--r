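# breeding-step taxonomy of the cranberry panel: each step compares a
# derived stage against the stage it was selected from
ROD_STEPS <- list(
  step1  = c(ancestral = "WLD",  derived = "NS"),
  step2  = c(ancestral = "NS",   derived = "CLT1"),
  step3a = c(ancestral = "CLT1", derived = "CLT2"),
  step3b = c(ancestral = "NS",   derived = "CLT2"))

#' Reduction of diversity at a locus
#'
#' ROD = 1 - He_derived / He_ancestral, where He is expected
#' heterozygosity. 1 means complete loss of diversity in the derived group
#' at an ancestrally polymorphic locus; 0 means no reduction; negative
#' values (derived more diverse than ancestral) are retained, never
#' clamped. Undefined when the ancestral group is monomorphic.
#'
#' @param he_ancestral,he_derived expected heterozygosities (vectors allowed).
#' @return ROD values (NA where He_ancestral = 0).
#' @examples
#' rod_locus(0.5, 0)     # 1: total loss
#' rod_locus(0.5, 0.18)  # 0.64
#' @export
rod_locus <- function(he_ancestral, he_derived) {
  out <- 1 - he_derived / he_ancestral
  out[!is.na(he_ancestral) & he_ancestral == 0] <- NA_real_
  out
}

#' ROD scan across one breeding step
#'
#' Computes per-locus ROD for one of the four defined domestication /
#' breeding steps (step1: WLD -> NS, step2: NS -> CLT1, step3a:
#' CLT1 -> CLT2, step3b: NS -> CLT2), or for an explicit
#' (ancestral, derived) subgroup pair. Loci are counted into the four
#' headline bins ROD = 0, 0 < ROD <= 0.2, 0.8 <= ROD < 1 and ROD = 1;
#' loci in (0.2, 0.8), negative-ROD loci and undefined loci are reported
#' as separate categories so the six categories partition all L markers.
#'
#' `ROD = 1` is detected exactly as "derived group fixed at an ancestrally
#' polymorphic locus" (integer-count equivalence), not by floating-point
#' comparison.
#'
#' @param G a [geno_matrix()].
#' @param meta metadata data frame.
#' @param step one of `"step1"`, `"step2"`, `"step3a"`, `"step3b"`, or
#'   `NULL` when `pair` is given.
#' @param pair optional `c(ancestral, derived)` subgroup labels overriding
#'   `step`.
#' @return object of class `rod_scan`: per-locus table (`chrom`, `pos`,
#'   `he_anc`, `he_der`, `rod`) and `bin_counts`.
#' @export
rod_scan <- function(G, meta, step = NULL, pair = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  if (is.null(pair)) {
    if (is.null(step) || !step %in% names(ROD_STEPS))
      stop("unknown step label: ", step %||% "<missing>",
           " (expected one of ", paste(names(ROD_STEPS), collapse = ", "), ")")
    pair <- ROD_STEPS[[step]]
  } else {
    stopifnot(length(pair) == 2L)
    pair <- c(ancestral = pair[1], derived = pair[2])
  }
  meta <- check_metadata(G, meta)
  sa <- group_locus_stats(G$dosages[subgroup_ids(meta, pair[["ancestral"]]), ,
                                    drop = FALSE])
  sd_ <- group_locus_stats(G$dosages[subgroup_ids(meta, pair[["derived"]]), ,
                                     drop = FALSE])
  he_anc <- expected_het(sa$p)
  he_der <- expected_het(sd_$p)
  rod <- rod_locus(he_anc, he_der)

  anc_poly <- !is.na(sa$p) & sa$p > 0 & sa$p < 1
  der_fixed <- !is.na(sd_$p) & (sd_$p == 0 | sd_$p == 1)
  eps <- 1e-12
  undefined <- is.na(rod)
  rod1 <- !undefined & anc_poly & der_fixed          # exact: He_der == 0
  rod0 <- !undefined & !rod1 & abs(rod) <= eps
  negative <- !undefined & rod < -eps
  low  <- !undefined & !rod1 & rod > eps & rod <= 0.2
  high <- !undefined & !rod1 & rod >= 0.8 & rod < 1
  mid  <- !undefined & !rod1 & !rod0 & !negative & !low & !high

  bins <- c(rod_eq_0 = sum(rod0), rod_0_to_0.2 = sum(low),
            rod_0.8_to_1 = sum(high), rod_eq_1 = sum(rod1),
            rod_mid = sum(mid), rod_negative = sum(negative),
            undefined = sum(undefined))
  structure(list(step = step, pair = pair,
                 table = data.frame(id = G$markers$id,
                                    chrom = G$markers$chrom,
                                    pos = G$markers$pos,
                                    he_anc = he_anc, he_der = he_der,
                                    rod = rod, row.names = NULL),
                 bin_counts = bins, n_markers = ncol(G$dosages)),
            class = "rod_scan")
}

#' @export
print.rod_scan <- function(x, ...) {
  cat("ROD scan", if (!is.null(x$step)) paste0(" (", x$step, ")"), ": ",
      x$pair[["ancestral"]], " -> ", x$pair[["derived"]], ", ",
      x$n_markers, " markers\n", sep = "")
  print(x$bin_counts)
  invisible(x)
}
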