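#' Genotype matrix container
#'
#' Holds an accessions-by-markers allele-dosage matrix (counts of the
#' alternate allele: 0, 1, 2, or `NA` for missing calls) together with
#' aligned marker coordinates. Every statistic in the package runs off this
#' container. Markers must be in genomic order: strictly increasing position
#' within each chromosome.
#'
#' @param dosages integer matrix, n accessions x L markers; entries in
#'   \{0, 1, 2, NA\}. Row names are accession ids (required); column names
#'   are taken from `markers$id` if absent.
#' @param markers data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`;
#'   one row per column of `dosages`. Positions are 1-based, as in VCF.
#' @return an object of class `geno_matrix`: a list with elements `dosages`
#'   and `markers`.
#' @examples
#' mk <- data.frame(id = c("m1", "m2"), chrom = "chr1", pos = c(100L, 200L),
#'                  ref = "A", alt = "G")
#' d <- matrix(c(0L, 1L, 2L, NA), 2, 2, dimnames = list(c("s1", "s2"), NULL))
#' g <- geno_matrix(d, mk)
#' @export
geno_matrix <- function(dosages, markers) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(markers)))
    stop("markers must have columns: ", paste(req, collapse = ", "))
  if (nrow(markers) != ncol(dosages))
    stop("markers rows (", nrow(markers), ") != dosage columns (",
         ncol(dosages), ")")
  if (nrow(dosages) < 2L) stop("need at least 2 accessions")
  if (ncol(dosages) < 1L) stop("need at least 1 marker")
  if (is.null(rownames(dosages))) stop("dosages must carry accession ids as row names")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("non-missing dosages must be 0, 1 or 2")
  if (any(markers$pos < 1L)) stop("marker positions must be >= 1")
  if (any(markers$ref == markers$alt)) stop("ref and alt alleles must differ")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0))
      stop("marker positions not strictly increasing on chromosome ", ch)
  }
  if (is.null(colnames(dosages))) colnames(dosages) <- markers$id
  markers$pos <- as.integer(markers$pos)
  rownames(markers) <- NULL
  structure(list(dosages = dosages, markers = markers), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  d <- x$dosages
  miss <- mean(is.na(d))
  cat("geno_matrix: ", nrow(d), " accessions x ", ncol(d), " markers on ",
      length(unique(x$markers$chrom)), " chromosome(s); ",
      sprintf("%.1f%%", 100 * miss), " missing\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param i accession selector (names, indices or logical).
#' @param j marker selector.
#' @param ... unused.
#' @return a `geno_matrix` (validation re-run on the subset).
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  d <- x$dosages
  if (missing(i)) i <- seq_len(nrow(d))
  if (missing(j)) j <- seq_len(ncol(d))
  geno_matrix(d[i, j, drop = FALSE], x$markers[j, , drop = FALSE])
}

#' Read panel metadata
#'
#' Metadata assigns each accession to exactly one subgroup (breeding stage),
#' e.g. WLD / NS / CLT1 / CLT2 for the cranberry panel.
#'
#' @param path TSV with columns `accession_id`, `subgroup`, `origin`.
#' @return data frame with those columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  m <- read_tsv(path)
  req <- c("accession_id", "subgroup", "origin")
  if (!all(req %in% names(m)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(m$accession_id))
    stop("duplicated accession ids in metadata")
  m
}

# validate that metadata covers all accessions of G; returns meta aligned to G
check_metadata <- function(G, meta) {
  ids <- rownames(G$dosages)
  missing_ids <- setdiff(ids, meta$accession_id)
  if (length(missing_ids))
    stop("accessions absent from metadata: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) ", ...")
  meta[match(ids, meta$accession_id), , drop = FALSE]
}

# accession ids of one subgroup, with basic checks
subgroup_ids <- function(meta, subgroup) {
  ids <- meta$accession_id[meta$subgroup == subgroup]
  if (!length(ids)) stop("empty subgroup: ", subgroup)
  ids
}

#' Write / read a genotype matrix as TSV
#'
#' Lossless round-trip of dosages, coordinates and ids. The layout is
#' markers-as-rows: columns `chrom`, `pos`, `ref`, `alt`, then one column per
#' accession; missing dosages are written as `NA`.
#'
#' @param G a [geno_matrix()].
#' @param path output file.
#' @return `path`, invisibly (`write_matrix`); a `geno_matrix`
#'   (`read_matrix`).
#' @export
write_matrix <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  df <- cbind(G$markers[c("chrom", "pos", "ref", "alt")],
              as.data.frame(t(G$dosages)))
  write_tsv(df, path)
}

#' @rdname write_matrix
#' @param valid_chroms optional character vector; if supplied, any chromosome
#'   label outside it is an error (guards against malformed files).
#' @export
read_matrix <- function(path, valid_chroms = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- read_tsv(path)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(df)))
    stop("genotype matrix header must start with: ",
         paste(req, collapse = ", "))
  if (nrow(df) == 0L) stop("genotype matrix has no markers")
  if (!is.null(valid_chroms)) {
    bad <- setdiff(unique(df$chrom), valid_chroms)
    if (length(bad)) stop("unknown chromosome label(s): ",
                          paste(bad, collapse = ", "))
  }
  samp <- setdiff(names(df), req)
  if (!length(samp)) stop("no accession columns in genotype matrix")
  dos <- t(as.matrix(df[samp]))
  rownames(dos) <- samp
  mk <- data.frame(id = paste0(df$chrom, "_", df$pos), chrom = df$chrom,
                   pos = df$pos, ref = df$ref, alt = df$alt,
                   stringsAsFactors = FALSE)
  geno_matrix(dos, mk)
}
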