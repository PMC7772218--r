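write_toy_vcf <- function(path, records, samples = c("s1", "s2", "s3")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr01>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

test_that("read_vcf skips non-biallelic records and maps ./. to missing", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(f, c(
    "chr01\t100\tm1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr01\t200\tm2\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",  # multiallelic
    "chr01\t300\tm3\tC\tT\t.\tPASS\t.\tGT\t./.\t0/1\t1|1",
    "chr01\t400\tm4\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1"))
  suppressMessages(G <- read_vcf(f))
  expect_s3_class(G, "geno_matrix")
  expect_equal(ncol(G$dosages), 3L)
  expect_equal(attr(G, "skipped"), 1L)
  expect_identical(unname(G$dosages[, "m3"]), c(NA_integer_, 1L, 2L))
  expect_identical(unname(G$dosages[, "m1"]), c(0L, 1L, 2L))
})

test_that("read_vcf collapses duplicate positions and rejects bad metadata", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(f, c(
    "chr01\t100\tm1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr01\t100\tm1b\tA\tC\t.\tPASS\t.\tGT\t1/1\t0/1\t0/0",
    "chr01\t300\tm3\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0"))
  suppressMessages(G <- read_vcf(f))
  expect_equal(ncol(G$dosages), 2L)
  expect_equal(attr(G, "collapsed"), 1L)
  expect_identical(unname(G$dosages[, 1]), c(0L, 1L, 2L))  # first kept

  meta <- withr::local_tempfile(fileext = ".tsv")
  writeLines("accession_id\tsubgroup\torigin\ns1\tWLD\tx\ns2\tWLD\tx", meta)
  expect_error(suppressMessages(read_vcf(f, meta)), "absent from metadata")
})

test_that("write_vcf / read_vcf round-trips a simulated panel exactly", {
  sim <- tiny_panel()
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, f)
  suppressMessages(G2 <- read_vcf(f))
  expect_identical(unname(G2$dosages), unname(sim$genotypes$dosages))
  expect_identical(G2$markers$pos, sim$genotypes$markers$pos)
  expect_identical(G2$markers$chrom, sim$genotypes$markers$chrom)
  expect_equal(attr(G2, "skipped"), 0L)
})

test_that("matrix TSV round-trip is lossless and validates chromosomes", {
  set.seed(7)
  dos <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 10, 20)
  rownames(dos) <- sprintf("a%02d", 1:10)
  G <- toy_geno(dos, chrom = c("chr01", "chr02"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(G, f)
  G2 <- read_matrix(f)
  expect_identical(unname(G2$dosages), unname(G$dosages))
  expect_identical(G2$markers$pos, G$markers$pos)
  expect_error(read_matrix(f, valid_chroms = "chr01"), "chr02")
})

test_that("geno_matrix validates its invariants", {
  mk <- data.frame(id = c("m1", "m2"), chrom = "chr01", pos = c(5L, 2L),
                   ref = "A", alt = "G")
  d <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_error(geno_matrix(d, mk), "strictly increasing")
  mk$pos <- c(2L, 5L)
  d[1, 1] <- 3L
  expect_error(geno_matrix(d, mk), "0, 1 or 2")
  d[1, 1] <- 2L
  expect_s3_class(geno_matrix(d, mk), "geno_matrix")
  expect_error(geno_matrix(d[1, , drop = FALSE], mk), "2 accessions")
})

test_that("filter_markers attributes removals sequentially and is idempotent", {
  # 5 markers: A 40% missing, B MAF 0.02 (1 alt allele in 25), C-E clean
  dos <- cbind(
    A = c(rep(NA_integer_, 10), rep(0L, 15)),
    B = c(1L, rep(0L, 24)),
    C = rep(c(0L, 1L, 2L), length.out = 25),
    D = rep(c(2L, 1L), length.out = 25),
    E = rep(c(0L, 2L), length.out = 25))
  G <- toy_geno(dos)
  out <- filter_markers(G, max_missing = 0.30, min_maf = 0.05)
  expect_equal(out$report$n_removed_missing, 1L)
  expect_equal(out$report$n_removed_maf, 1L)
  expect_equal(out$report$n_retained, 3L)
  expect_identical(colnames(out$genotypes$dosages),
                   colnames(dos[, 3:5]))          # order preserved
  again <- filter_markers(out$genotypes, 0.30, 0.05)
  expect_identical(again$genotypes$dosages, out$genotypes$dosages)
  expect_equal(again$report$n_removed_missing + again$report$n_removed_maf, 0L)

  ident <- filter_markers(G, max_missing = 1.0, min_maf = 0.0)
  expect_equal(ident$report$n_retained, 5L)
  expect_error(filter_markers(G, max_missing = 0, min_maf = 0.9),
               "no markers retained")
})

test_that("every retained marker satisfies the MAF floor on recomputation", {
  sim <- tiny_panel()
  out <- filter_markers(sim$genotypes, 0.30, 0.05)
  d <- out$genotypes$dosages
  p <- colMeans(d, na.rm = TRUE) / 2
  expect_true(all(pmin(p, 1 - p) >= 0.05))
  expect_true(all(colMeans(is.na(d)) <= 0.30))
  expect_equal(out$report$n_input_snps,
               out$report$n_removed_missing + out$report$n_removed_maf +
                 out$report$n_retained)
})
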