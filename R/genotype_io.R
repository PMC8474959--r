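# Genotype data model, VCF/popmap/annotation I/O, and site filtering.
#
# Internal conventions:
#   * genotype calls are unphased dosage codes 0 (ref/ref), 1 (het),
#     2 (alt/alt), NA (missing); phase in input VCFs is discarded.
#   * all interval coordinates are 0-based half-open; 1-based inputs
#     (VCF positions, GFF3) are converted at the boundary.

#' Construct a genotype dataset
#'
#' Container for a samples x biallelic-SNP matrix of diploid genotype
#' dosages together with variant coordinates. Variants are sorted by
#' (chrom, pos) on construction.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp),
#'   `id`, `ref`, `alt`; one row per biallelic SNP.
#' @param samples Character vector of unique sample identifiers.
#' @param calls Integer matrix, `length(samples)` rows x `nrow(variants)`
#'   columns, entries in `{0, 1, 2, NA}`.
#' @param contig_lengths Optional named numeric vector of chromosome
#'   lengths in bp (used for window tiling and VCF contig headers).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(variants, samples, calls, contig_lengths = NULL) {
  variants <- as.data.frame(variants)
  req <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(req %in% names(variants)))
    stopf("variants must have columns: %s", paste(req, collapse = ", "))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stopf("sample identifiers must be unique")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(variants))
    stopf("calls must be %d samples x %d variants", length(samples), nrow(variants))
  if (any(variants$pos < 1)) stopf("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) stopf("ref and alt alleles must differ")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stopf("genotype codes must be 0, 1, 2 or NA")
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  calls <- calls[, ord, drop = FALSE]
  dimnames(calls) <- list(samples, NULL)
  structure(list(variants = variants, samples = samples, calls = calls,
                 contig_lengths = contig_lengths),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d biallelic SNPs on %d chromosome(s)\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$chrom))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

# Subset a dataset by variant and/or sample index, preserving order.
ds_subset <- function(ds, variants = NULL, samples = NULL) {
  v <- variants %||% seq_len(nrow(ds$variants))
  s <- samples %||% seq_along(ds$samples)
  structure(list(variants = ds$variants[v, , drop = FALSE],
                 samples = ds$samples[s],
                 calls = ds$calls[s, v, drop = FALSE],
                 contig_lengths = ds$contig_lengths),
            class = "genotype_dataset")
}

#' Read a multi-sample VCF into a genotype dataset
#'
#' Parses a VCF v4.x (via vcfR), retains biallelic SNP records only, and
#' encodes genotypes as unphased dosages 0/1/2 with NA for missing.
#' Multiallelic, indel and other non-SNP records are skipped with a
#' message stating the count. Phased (`|`) and unphased (`/`) genotype
#' separators are both accepted; partially missing genotypes (e.g. `./1`)
#' are treated as missing. Contig lengths are taken from `##contig`
#' header lines when present.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A [genotype_dataset].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  nt <- c("A", "C", "G", "T")
  keep <- !is.na(alt) & ref %in% nt & alt %in% nt
  n_skip <- sum(!keep)
  if (n_skip > 0)
    msgf("read_vcf: skipped %d non-biallelic-SNP record(s)", n_skip)
  if (!any(keep)) stopf("no biallelic SNP records retained from %s", path)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  g <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow = nrow(g), ncol = ncol(g))
  code[g == "0/0"] <- 0L
  code[g == "0/1" | g == "1/0"] <- 1L
  code[g == "1/1"] <- 2L

  meta <- vcf@meta
  cl <- NULL
  ctg <- grep("^##contig=", meta, value = TRUE)
  if (length(ctg)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", ctg)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg)))
    if (!all(is.na(lens))) cl <- stats::setNames(lens, ids)
  }

  genotype_dataset(
    variants = data.frame(chrom = fix[keep, "CHROM"],
                          pos = as.integer(fix[keep, "POS"]),
                          id = ifelse(is.na(fix[keep, "ID"]), ".", fix[keep, "ID"]),
                          ref = ref[keep], alt = alt[keep],
                          stringsAsFactors = FALSE),
    samples = colnames(gt),
    calls = t(code),
    contig_lengths = cl
  )
}

#' Write a genotype dataset to a plain-text VCF
#'
#' Emits a minimal VCF v4.2 with GT-only FORMAT and `##contig` headers
#' carrying chromosome lengths, so that `read_vcf(write_vcf(ds))`
#' round-trips the call matrix, sample order and variant order exactly.
#'
#' @param ds A [genotype_dataset].
#' @param path Output file path.
#' @param contig_lengths Optional named lengths; defaults to those stored
#'   in `ds`, else the maximum variant position per chromosome.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ds, path, contig_lengths = NULL) {
  cl <- contig_lengths %||% ds$contig_lengths
  chroms <- unique(ds$variants$chrom)
  if (is.null(cl))
    cl <- vapply(chroms, function(ch)
      max(ds$variants$pos[ds$variants$chrom == ch]), numeric(1))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(cl), as.integer(cl)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$samples), collapse = "\t")
  )
  gt_str <- c("0/0", "0/1", "1/1")
  gmat <- matrix("./.", nrow = nrow(ds$calls), ncol = ncol(ds$calls))
  ok <- !is.na(ds$calls)
  gmat[ok] <- gt_str[ds$calls[ok] + 1L]
  body <- paste(ds$variants$chrom, ds$variants$pos, ds$variants$id,
                ds$variants$ref, ds$variants$alt, ".", "PASS", ".", "GT",
                apply(gmat, 2, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "wb")  # binary connection: LF endings, byte-stable
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Per-site allele-frequency and call-rate statistics
#'
#' For each site, the alternate allele frequency is computed from
#' non-missing calls only, `p = (n_het + 2 n_homalt) / (2 n_called)`;
#' the minor allele frequency is `min(p, 1 - p)` and the integrity is the
#' fraction of samples with a called genotype. Sites with no called
#' genotypes get `maf = NA`.
#'
#' @param ds A [genotype_dataset].
#' @return data.frame with columns `chrom`, `pos`, `n_called`, `maf`,
#'   `integrity`, one row per variant.
#' @export
compute_site_stats <- function(ds) {
  if (length(ds$samples) < 1) stopf("dataset has no samples")
  g <- ds$calls
  n_called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  data.frame(chrom = ds$variants$chrom, pos = ds$variants$pos,
             n_called = n_called,
             maf = pmin(p, 1 - p),
             integrity = n_called / length(ds$samples),
             stringsAsFactors = FALSE)
}

#' Filter sites on minor allele frequency and integrity
#'
#' Retains sites with `maf >= maf_min` and `integrity >= int_min`
#' (boundaries inclusive), computed jointly over all samples. Sites with
#' undefined MAF (no called genotypes) never pass. Variant order is
#' preserved; a report of counts removed per criterion is attached as
#' attribute `"filter_report"` and echoed as a message.
#'
#' @param ds A [genotype_dataset].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param int_min Minimum fraction of called genotypes (default 0.5).
#' @return Filtered [genotype_dataset].
#' @export
filter_sites <- function(ds, maf_min = 0.05, int_min = 0.5) {
  stopifnot(maf_min >= 0, maf_min <= 1, int_min >= 0, int_min <= 1)
  st <- compute_site_stats(ds)
  undef <- is.na(st$maf)
  fail_maf <- !undef & st$maf < maf_min
  fail_int <- st$integrity < int_min
  keep <- !undef & !fail_maf & !fail_int
  if (!any(keep))
    stopf("no sites pass filters (maf >= %g, integrity >= %g): %d failed MAF, %d failed integrity, %d undefined",
          maf_min, int_min, sum(fail_maf), sum(fail_int), sum(undef))
  report <- list(n_input = nrow(st), n_retained = sum(keep),
                 n_fail_maf = sum(fail_maf & !fail_int),
                 n_fail_int = sum(fail_int & !fail_maf & !undef),
                 n_fail_both = sum(fail_maf & fail_int),
                 n_undefined = sum(undef & !fail_int),
                 maf_min = maf_min, int_min = int_min)
  msgf("filter_sites: retained %d / %d sites (MAF >= %g, INT >= %g)",
       report$n_retained, report$n_input, maf_min, int_min)
  out <- ds_subset(ds, variants = which(keep))
  attr(out, "filter_report") <- report
  out
}

#' Read a sample-to-population-to-group map
#'
#' Expects a TSV with header `sample<TAB>population<TAB>group`. Every
#' population must belong to exactly one group.
#'
#' @param path Path to the popmap TSV.
#' @return data.frame of class `population_map` with columns `sample`,
#'   `population`, `group`.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stopf("popmap file not found: %s", path)
  pm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  population_map(pm)
}

#' Construct a population map
#'
#' @param df data.frame with columns `sample`, `population`, `group`.
#' @return A `population_map`.
#' @export
population_map <- function(df) {
  req <- c("sample", "population", "group")
  if (!all(req %in% names(df)))
    stopf("popmap must have columns: %s", paste(req, collapse = ", "))
  df <- df[, req]
  if (anyDuplicated(df$sample)) stopf("duplicated sample(s) in popmap")
  pg <- unique(df[, c("population", "group")])
  if (anyDuplicated(pg$population))
    stopf("population assigned to more than one group: %s",
          paste(pg$population[duplicated(pg$population)], collapse = ", "))
  if (length(unique(df$group)) < 1) stopf("popmap must define at least one group")
  rownames(df) <- NULL
  class(df) <- c("population_map", "data.frame")
  df
}

#' @export
write_popmap <- function(pm, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("sample\tpopulation\tgroup",
               paste(pm$sample, pm$population, pm$group, sep = "\t")), con)
  invisible(path)
}

# Check every dataset sample is mapped exactly once; returns the popmap
# rows aligned to ds$samples.
align_popmap <- function(ds, pm) {
  idx <- match(ds$samples, pm$sample)
  if (anyNA(idx))
    stopf("samples missing from popmap: %s",
          paste(ds$samples[is.na(idx)], collapse = ", "))
  pm[idx, , drop = FALSE]
}

# Sample indices for a set of populations (or groups with by = "group").
pop_indices <- function(ds, pm, who, by = c("population", "group")) {
  by <- match.arg(by)
  al <- align_popmap(ds, pm)
  unknown <- setdiff(who, unique(al[[by]]))
  if (length(unknown))
    stopf("unknown %s(s): %s", by, paste(unknown, collapse = ", "))
  which(al[[by]] %in% who)
}

#' Read gene annotation intervals (BED4 or GFF3)
#'
#' BED input is interpreted as 0-based half-open; GFF3 as 1-based
#' inclusive and restricted to a feature type (default `"gene"`).
#' Coordinates are normalized to the internal 0-based half-open
#' convention. The format is auto-detected from the file extension
#' unless given.
#'
#' @param path Path to a `.bed` or `.gff`/`.gff3` file.
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @param feature GFF3 feature type to retain (column 3).
#' @return data.frame of class `gene_set` with columns `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open).
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff3"),
                            feature = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                     stopf("cannot infer annotation format from extension '.%s'; pass format=", ext))
  }
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) stopf("no records in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)

  if (format == "bed") {
    bad <- which(lengths(fields) < 3)
    if (length(bad)) stopf("malformed BED line %d in %s", lineno[bad[1]], path)
    chrom <- vapply(fields, `[`, "", 1)
    start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad)) stopf("non-numeric coordinates on line %d in %s", lineno[bad[1]], path)
    bad <- which(start >= end)
    if (length(bad)) stopf("start >= end on line %d in %s", lineno[bad[1]], path)
    id <- vapply(seq_along(fields), function(i)
      if (lengths(fields)[i] >= 4) fields[[i]][4] else sprintf("feature_%d", i), "")
  } else {
    bad <- which(lengths(fields) < 9)
    if (length(bad)) stopf("malformed GFF3 line %d in %s", lineno[bad[1]], path)
    type <- vapply(fields, `[`, "", 3)
    sel <- type == feature
    if (!any(sel)) stopf("no '%s' features in %s", feature, path)
    fields <- fields[sel]; lineno <- lineno[sel]
    chrom <- vapply(fields, `[`, "", 1)
    start1 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4)))
    end1 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5)))
    bad <- which(is.na(start1) | is.na(end1) | start1 > end1)
    if (length(bad)) stopf("bad coordinates on line %d in %s", lineno[bad[1]], path)
    start <- start1 - 1  # 1-based inclusive -> 0-based half-open
    end <- end1
    attrs <- vapply(fields, `[`, "", 9)
    id <- sub(".*ID=([^;]+).*", "\\1", attrs)
    noid <- !grepl("ID=", attrs)
    id[noid] <- sub(".*Name=([^;]+).*", "\\1", attrs[noid])
    id[!grepl("(ID|Name)=", attrs)] <- sprintf("feature_%d", which(!grepl("(ID|Name)=", attrs)))
  }
  gene_set(data.frame(gene_id = id, chrom = chrom, start = start, end = end,
                      stringsAsFactors = FALSE))
}

#' Construct a gene set
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   in the 0-based half-open convention.
#' @return A `gene_set`.
#' @export
gene_set <- function(df) {
  req <- c("gene_id", "chrom", "start", "end")
  if (!all(req %in% names(df)))
    stopf("gene set must have columns: %s", paste(req, collapse = ", "))
  df <- df[, req]
  if (any(df$start >= df$end)) stopf("gene interval with start >= end")
  if (anyDuplicated(df$gene_id))
    stopf("duplicated gene_id(s): %s",
          paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("gene_set", "data.frame")
  df
}

#' @export
write_gene_bed <- function(genes, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(genes$chrom, format(genes$start, scientific = FALSE, trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   genes$gene_id, sep = "\t"), con)
  invisible(path)
}
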