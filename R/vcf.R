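#' Read SNP genotypes from VCF
#'
#' Reads a VCF 4.x file into a [geno_matrix()] of alternate-allele dosages.
#' Non-biallelic or non-SNP records are skipped (their count is kept in the
#' `skipped` attribute and reported with a message), genotypes `./.` become
#' missing, and duplicate (chrom, pos) records are collapsed to the first
#' occurrence. Markers are returned in genomic order.
#'
#' @param path VCF file (plain or bgzipped).
#' @param metadata_path optional accession-metadata TSV
#'   (see [read_metadata()]); when given, every VCF sample must be present in
#'   the metadata and the function returns both objects.
#' @return a `geno_matrix` (with attributes `skipped`, `collapsed`), or, when
#'   `metadata_path` is supplied, a list with elements `genotypes` and
#'   `metadata`.
#' @export
read_vcf <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records")
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT != "." & !is.na(fix$ALT)
  n_skip <- sum(!is_snp)
  if (n_skip) message(n_skip, " non-biallelic-SNP record(s) skipped")
  if (!any(is_snp)) stop("no biallelic SNP records in VCF")

  gt <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
  if (is.null(gt)) stop("VCF has no GT genotype field")
  fix <- fix[is_snp, , drop = FALSE]
  if (nrow(fix) == 1L) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, colnames(v@gt)[-1]))

  key <- paste(fix$CHROM, fix$POS)
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup) {
    message(n_dup, " duplicate-position record(s) collapsed to first occurrence")
    gt <- gt[!dup, , drop = FALSE]
    fix <- fix[!dup, , drop = FALSE]
  }

  dos <- gt_to_dosage(gt)
  mk <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)

  ord <- order(mk$chrom, mk$pos)
  mk <- mk[ord, , drop = FALSE]
  dos <- dos[ord, , drop = FALSE]

  G <- geno_matrix(t(dos), mk)
  attr(G, "skipped") <- n_skip
  attr(G, "collapsed") <- n_dup

  if (is.null(metadata_path)) return(G)
  meta <- read_metadata(metadata_path)
  meta <- check_metadata(G, meta)
  list(genotypes = G, metadata = meta)
}

# GT strings ("0/1", "1|0", "./.", NA) -> integer alt-allele dosage matrix
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  d[clean == "0/0"] <- 0L
  d[clean == "0/1" | clean == "1/0"] <- 1L
  d[clean == "1/1"] <- 2L
  known <- is.na(clean) | clean %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  if (any(!known))
    stop("malformed genotype field(s), e.g. ", clean[which(!known)[1]])
  d
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF 4.2 file (GT field only) that [read_vcf()] round-trips
#' exactly. Dosage 1 is written as the unphased heterozygote `0/1`.
#'
#' @param G a [geno_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  mk <- G$markers
  dos <- t(G$dosages)  # markers x accessions
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- code[as.character(dos[ok])]
  contigs <- unique(mk$chrom)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bogdiv",
           paste0("##contig=<ID=", contigs, ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(G$dosages)), collapse = "\t"))
  body <- paste(mk$chrom, mk$pos, mk$id, mk$ref, mk$alt, ".", "PASS", ".",
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
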