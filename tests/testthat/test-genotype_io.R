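vcf_header <- function(samples, contigs = NULL) {
  c("##fileformat=VCFv4.2",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

test_that("read_vcf encodes dosages, missingness, and phased separators", {
  lines <- c(vcf_header(c("s1", "s2", "s3"), c(chr1 = 50000)),
             "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
             "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0|1\t./.\t1|1",
             "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t1/0\t0/0\t0/1",
             "chr1\t400\t.\tT\tC\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1")
  ds <- read_vcf(write_vcf_text(lines))
  expect_s3_class(ds, "genotype_dataset")
  expect_equal(dim(ds$calls), c(3L, 4L))
  expect_equal(sum(is.na(ds$calls)), 1L)              # exactly one ./.
  expect_true(is.na(ds$calls["s2", 2]))
  expect_equal(unname(ds$calls[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(ds$calls[, 2]), c(1L, NA, 2L))  # phase discarded
  expect_equal(ds$contig_lengths, c(chr1 = 50000))
  expect_false(is.unsorted(ds$variants$pos))
})

test_that("read_vcf skips non-biallelic and non-SNP records with a count", {
  lines <- c(vcf_header("s1"),
             "chr1\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
             "chr1\t20\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/2",   # triallelic
             "chr1\t30\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1",    # indel
             "chr1\t40\t.\tC\tT\t.\tPASS\t.\tGT\t1/1",
             "chr1\t50\t.\tG\tC\t.\tPASS\t.\tGT\t0/0")
  expect_message(ds <- read_vcf(write_vcf_text(lines)), "skipped 2")
  expect_equal(nrow(ds$variants), 3L)
  expect_error(read_vcf(tempfile()), "not found")
})

test_that("write_vcf / read_vcf round-trip preserves calls and ordering", {
  sim <- small_sim(seed = 42, n_snps = 80, missing_rate = 0.15)
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$dataset, path)
  back <- read_vcf(path)
  expect_identical(back$calls, sim$dataset$calls)
  expect_identical(back$samples, sim$dataset$samples)
  expect_identical(back$variants[, c("chrom", "pos", "ref", "alt")],
                   sim$dataset$variants[, c("chrom", "pos", "ref", "alt")])
  expect_equal(back$contig_lengths, sim$dataset$contig_lengths)
})

test_that("compute_site_stats matches hand-counted allele frequencies", {
  # 10 samples: 6 hom-ref, 3 het, 1 hom-alt -> p = 5/20, full integrity
  calls <- matrix(c(rep(0L, 6), rep(1L, 3), 2L), nrow = 10)
  ds <- genotype_dataset(
    data.frame(chrom = "chr1", pos = 1L, id = ".", ref = "A", alt = "G"),
    sprintf("s%d", 1:10), calls)
  st <- compute_site_stats(ds)
  expect_equal(st$maf, 0.25)
  expect_equal(st$integrity, 1.0)
  expect_equal(st$n_called, 10L)

  # all missing -> integrity 0, maf undefined; all hom-ref -> maf 0
  calls2 <- cbind(rep(NA_integer_, 10), rep(0L, 10))
  ds2 <- genotype_dataset(
    data.frame(chrom = "chr1", pos = 1:2, id = ".", ref = "A", alt = "G"),
    sprintf("s%d", 1:10), calls2)
  st2 <- compute_site_stats(ds2)
  expect_true(is.na(st2$maf[1]))
  expect_equal(st2$integrity[1], 0)
  expect_equal(st2$maf[2], 0)
})

test_that("filter_sites applies inclusive MAF/INT thresholds and is idempotent", {
  # per-site targets (maf, integrity):
  # (0.0,1.0) (0.05,1.0) (0.19,0.4) (0.2,0.5) (0.5,1.0) (undef,0.0)
  n <- 20
  site <- function(maf, int) {
    nc <- round(int * n)
    g <- c(rep(1L, round(maf * 2 * nc)), rep(0L, nc - round(maf * 2 * nc)))
    c(g, rep(NA_integer_, n - nc))
  }
  calls <- cbind(site(0, 1), site(0.05, 1), site(0.2, 0.4), site(0.2, 0.5),
                 site(0.5, 1), site(0, 0))
  ds <- genotype_dataset(
    data.frame(chrom = "chr1", pos = 1:6, id = ".", ref = "A", alt = "G"),
    sprintf("s%d", 1:n), calls)
  st <- compute_site_stats(ds)
  expect_equal(st$maf[1:5], c(0, 0.05, 0.1875, 0.2, 0.5))
  expect_equal(st$integrity, c(1, 1, 0.4, 0.5, 1, 0))

  filtered <- suppressMessages(filter_sites(ds))
  expect_equal(nrow(filtered$variants), 3L)         # sites 2, 4, 5
  expect_equal(filtered$variants$pos, c(2L, 4L, 5L))
  rep <- attr(filtered, "filter_report")
  expect_equal(rep$n_retained, 3L)

  # boundary behaviour: maf 0.049 removed, integrity exactly 0.5 retained
  st_f <- compute_site_stats(filtered)
  expect_true(all(st_f$maf >= 0.05 & st_f$integrity >= 0.5))
  twice <- suppressMessages(filter_sites(filtered))
  expect_identical(twice$calls, filtered$calls)     # idempotent
  expect_error(suppressMessages(filter_sites(ds, maf_min = 0.9)), "no sites")
})

test_that("read_annotation normalizes BED and GFF3 coordinate conventions", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tgeneA", "chr2\t0\t50\tgeneB"), bed)
  gs <- read_annotation(bed)
  expect_equal(gs$start, c(100, 0))
  expect_equal(gs$end, c(200, 50))
  expect_equal(gs$gene_id, c("geneA", "geneB"))

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=geneA",
               "chr1\tsrc\texon\t101\t150\t.\t+\t.\tID=exon1"), gff)
  gg <- read_annotation(gff)
  expect_equal(nrow(gg), 1L)                 # exon feature dropped
  expect_equal(gg$start, 100)                # 1-based inclusive -> 0-based
  expect_equal(gg$end, 200)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tok", "chr1\t300\t300\tempty"), bad)
  expect_error(read_annotation(bad), "line 2")
})

test_that("popmap validation rejects broken hierarchies", {
  pm <- population_map(data.frame(sample = c("a", "b", "c"),
                                  population = c("P1", "P1", "P2"),
                                  group = c("g", "g", "g")))
  expect_s3_class(pm, "population_map")
  expect_error(population_map(data.frame(sample = c("a", "a"),
                                         population = "P1", group = "g")),
               "duplicated")
  expect_error(population_map(data.frame(sample = c("a", "b"),
                                         population = c("P1", "P1"),
                                         group = c("g1", "g2"))),
               "more than one group")
  path <- tempfile()
  write_popmap(pm, path)
  expect_equal(as.data.frame(read_popmap(path)), as.data.frame(pm))
})
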