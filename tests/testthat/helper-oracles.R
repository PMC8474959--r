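# Independent oracles used across the suite. These are deliberately
# scalar, straight-line transcriptions of the published estimator
# equations (written before the vectorised package implementations), or
# brute-force enumerations; they share no code with the package paths
# they check.

# Weir & Cockerham (1984) diploid variance components at one biallelic
# site. counts: matrix pops x (hom_ref, het, hom_alt).
wc_ref <- function(counts) {
  r <- nrow(counts)
  n <- numeric(r); p <- numeric(r); h <- numeric(r)
  for (i in 1:r) {
    n[i] <- counts[i, 1] + counts[i, 2] + counts[i, 3]
    p[i] <- (counts[i, 2] + 2 * counts[i, 3]) / (2 * n[i])
    h[i] <- counts[i, 2] / n[i]
  }
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

# Brute-force per-site nucleotide diversity: average pairwise allele
# differences among the 2n sampled alleles at a biallelic site.
pi_site_bruteforce <- function(genos) {
  genos <- genos[!is.na(genos)]
  alleles <- unlist(lapply(genos, function(g) switch(g + 1, c(0, 0), c(0, 1), c(1, 1))))
  m <- length(alleles)
  diff <- 0; tot <- 0
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    tot <- tot + 1
    if (alleles[i] != alleles[j]) diff <- diff + 1
  }
  diff / tot
}

# Exhaustive hypergeometric over-representation tail:
# P(X >= k) with term size K, draw size m, universe N.
hyper_tail_enum <- function(k, K, N, m) {
  total <- choose(N, m)
  s <- 0
  for (j in k:min(K, m)) s <- s + choose(K, j) * choose(N - K, m - j)
  s / total
}

# Centroid-based AMOVA sums of squares at the allele level for
# complete-data dosage matrices: each diploid expands into its two
# allele rows (0/1 indicators per locus), then SS is deviation from the
# set centroid (independent of the allele-count route in the package).
ss_centroid_alleles <- function(x, pop, group_of_pop) {
  expand <- function(m) {
    out <- matrix(0, 2 * nrow(m), ncol(m))
    for (i in seq_len(nrow(m))) for (l in seq_len(ncol(m))) {
      al <- switch(m[i, l] + 1, c(0, 0), c(0, 1), c(1, 1))
      out[2 * i - 1, l] <- al[1]
      out[2 * i, l] <- al[2]
    }
    out
  }
  sweep_ss <- function(m) {
    mu <- colMeans(m)
    sum(sweep(m, 2, mu)^2)
  }
  ax <- expand(x)
  apop <- rep(pop, each = 2)
  ss_total <- sweep_ss(ax)
  ss_wp <- sum(vapply(unique(apop), function(pp)
    sweep_ss(ax[apop == pp, , drop = FALSE]), numeric(1)))
  grp <- group_of_pop[apop]
  ss_wg <- sum(vapply(unique(grp), function(gg)
    sweep_ss(ax[grp == gg, , drop = FALSE]), numeric(1)))
  list(total = ss_total, among_groups = ss_total - ss_wg,
       among_pops = ss_wg - ss_wp, within_pops = ss_wp)
}

# Small simulated dataset helper used by several files.
small_sim <- function(seed = 1, n_snps = 300, pops = c(P1 = 8, P2 = 8),
                      groups = NULL, f_ct = 0, f_sc = 0.1,
                      missing_rate = 0, sweeps = list(),
                      chrom_length = 2e5, n_chromosomes = 1) {
  if (is.null(groups)) groups <- list(gA = pops)
  simulate_dataset(sim_config(groups = groups, n_chromosomes = n_chromosomes,
                              chrom_length = chrom_length, n_snps = n_snps,
                              f_ct = f_ct, f_sc = f_sc,
                              missing_rate = missing_rate, sweeps = sweeps,
                              seed = seed))
}

# Random genotype-count configuration for estimator equivalence checks.
random_counts <- function(r = 2, nmax = 20) {
  repeat {
    counts <- matrix(0L, r, 3)
    for (i in 1:r) {
      n <- sample(2:nmax, 1)
      p <- runif(1, 0.05, 0.95)
      g <- sample(0:2, n, replace = TRUE, prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
      counts[i, ] <- tabulate(g + 1L, 3L)
    }
    # need a pooled-polymorphic site
    alt <- sum(counts[, 2] + 2 * counts[, 3])
    tot <- 2 * sum(counts)
    if (alt > 0 && alt < tot) return(counts)
  }
}

# Plain-text VCF fixture writer for io tests.
write_vcf_text <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}
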