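# Per-population diversity statistics: nucleotide diversity, expected and
# observed heterozygosity, and polymorphism information content.

#' Unbiased gene diversity at one site
#'
#' Nei's unbiased estimator of expected heterozygosity,
#' `(2n / (2n - 1)) * (1 - sum(p^2))`, where `n` is the number of diploid
#' individuals sampled. At a biallelic site this equals the average number
#' of pairwise differences among the `2n` sampled alleles, i.e. per-site
#' nucleotide diversity.
#'
#' @param p Numeric vector of allele frequencies summing to 1.
#' @param n Diploid sample count (>= 2).
#' @param unbiased Apply the `2n/(2n-1)` small-sample correction
#'   (default TRUE).
#' @return Gene diversity in `[0, 1]`.
#' @export
site_gene_diversity <- function(p, n, unbiased = TRUE) {
  if (abs(sum(p) - 1) > 1e-8) stopf("allele frequencies must sum to 1")
  if (n < 2) stopf("gene diversity is undefined for n < 2 diploids")
  h <- 1 - sum(p^2)
  if (unbiased) h <- h * (2 * n) / (2 * n - 1)
  h
}

# Vectorised per-site gene diversity for biallelic sites.
# p: alt frequency per site; n: called diploids per site. NA where n < 2.
gene_div_vec <- function(p, n, unbiased = TRUE) {
  h <- 2 * p * (1 - p)
  if (unbiased) h <- h * (2 * n) / (2 * n - 1)
  h[n < 2] <- NA_real_
  h
}

# Per-site alt frequency, called count and het proportion for a sample
# subset. Returns list(p, n, h) over all variants.
site_freqs <- function(ds, samples = NULL) {
  g <- if (is.null(samples)) ds$calls else ds$calls[samples, , drop = FALSE]
  n <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  het <- colSums(g == 1L, na.rm = TRUE)
  p <- ifelse(n > 0, alt / (2 * n), NA_real_)
  list(p = p, n = n, h = ifelse(n > 0, het / n, NA_real_))
}

#' Nucleotide diversity for a sample subset
#'
#' Averages the unbiased per-site gene diversity over sites with at least
#' two called genotypes in the subset. Two conventions are returned:
#' `pi_snp`, the per-SNP mean (default reporting convention), and
#' `pi_bp = sum(site values) / surveyed_length` when a surveyed sequence
#' length in bp is supplied.
#'
#' @param ds A [genotype_dataset].
#' @param samples Optional integer indices or character names of the
#'   sample subset (default: all samples).
#' @param surveyed_length Optional surveyed length in bp for `pi_bp`.
#' @param unbiased Apply the small-sample correction (default TRUE).
#' @return list with `pi_snp`, `pi_bp` (NA unless a length is given) and
#'   `n_sites` used.
#' @export
nucleotide_diversity <- function(ds, samples = NULL, surveyed_length = NULL,
                                 unbiased = TRUE) {
  if (is.character(samples)) samples <- match(samples, ds$samples)
  sf <- site_freqs(ds, samples)
  vals <- gene_div_vec(sf$p, sf$n, unbiased)
  use <- !is.na(vals)
  if (!any(use)) stopf("no sites with >= 2 called genotypes in subset")
  list(pi_snp = mean(vals[use]),
       pi_bp = if (is.null(surveyed_length)) NA_real_
               else sum(vals[use]) / surveyed_length,
       n_sites = sum(use))
}

#' Observed heterozygosity for a sample subset
#'
#' Proportion of heterozygous calls among all non-missing calls, pooled
#' over sites and individuals.
#'
#' @inheritParams nucleotide_diversity
#' @return Observed heterozygosity in `[0, 1]`.
#' @export
observed_heterozygosity <- function(ds, samples = NULL) {
  if (is.character(samples)) samples <- match(samples, ds$samples)
  g <- if (is.null(samples)) ds$calls else ds$calls[samples, , drop = FALSE]
  called <- sum(!is.na(g))
  if (called == 0) stopf("no non-missing calls in subset")
  sum(g == 1L, na.rm = TRUE) / called
}

#' Polymorphism information content
#'
#' Botstein's PIC for a locus with allele frequencies `p`:
#' `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param p Numeric vector of allele frequencies summing to 1.
#' @return PIC in `[0, 1)`.
#' @export
pic <- function(p) {
  if (abs(sum(p) - 1) > 1e-8) stopf("allele frequencies must sum to 1")
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))
}

# Vectorised biallelic PIC from alt frequency.
pic_vec <- function(p) {
  s2 <- p^2 + (1 - p)^2
  s4 <- p^4 + (1 - p)^4
  1 - s2 - (s2^2 - s4)
}

#' Per-population diversity summary table
#'
#' One row per population with sample count, nucleotide diversity (per-SNP
#' mean, and per-bp when `surveyed_length` is given), expected
#' heterozygosity (Nei's unbiased gene diversity), observed
#' heterozygosity, and PIC, plus a final unweighted `Mean` row averaging
#' across populations. Within a population, allele frequencies use only
#' that population's non-missing calls; sites with fewer than two called
#' genotypes in the population are excluded from its averages.
#'
#' @param ds A [genotype_dataset].
#' @param popmap A [population_map] covering every sample.
#' @param surveyed_length Optional surveyed length in bp.
#' @param unbiased Use the small-sample correction for He and pi.
#' @return data.frame of class `diversity_summary` with columns `group`,
#'   `population`, `n`, `pi_snp`, `pi_bp`, `he`, `ho`, `pic`.
#' @export
population_summary <- function(ds, popmap, surveyed_length = NULL,
                               unbiased = TRUE) {
  al <- align_popmap(ds, popmap)
  pops <- unique(al$population)
  small <- unique(al$population[ave(seq_len(nrow(al)), al$population,
                                    FUN = length) < 2])
  if (length(small))
    warnf("population(s) with fewer than 2 samples: %s",
          paste(small, collapse = ", "))
  rows <- lapply(pops, function(pp) {
    idx <- which(al$population == pp)
    sf <- site_freqs(ds, idx)
    div <- gene_div_vec(sf$p, sf$n, unbiased)
    use <- !is.na(div)
    if (!any(use)) stopf("population %s has no usable sites", pp)
    he <- mean(div[use])
    data.frame(group = al$group[idx[1]], population = pp, n = length(idx),
               pi_snp = he,
               pi_bp = if (is.null(surveyed_length)) NA_real_
                       else sum(div[use]) / surveyed_length,
               he = he,
               ho = observed_heterozygosity(ds, idx),
               pic = mean(pic_vec(sf$p[use])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  mean_row <- data.frame(group = "", population = "Mean",
                         n = mean(out$n), pi_snp = mean(out$pi_snp),
                         pi_bp = mean(out$pi_bp), he = mean(out$he),
                         ho = mean(out$ho), pic = mean(out$pic),
                         stringsAsFactors = FALSE)
  out <- rbind(out, mean_row)
  rownames(out) <- NULL
  class(out) <- c("diversity_summary", "data.frame")
  out
}

#' @export
print.diversity_summary <- function(x, digits = 4, ...) {
  cat("Per-population genetic diversity\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
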