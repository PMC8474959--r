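# Weir-Cockerham F_ST (per-site variance components and multi-locus
# ratio-of-sums theta) and genotype-matrix PCA.

# Vectorised Weir & Cockerham (1984) diploid variance components.
# N, P, H are r x L matrices of called diploid counts, alt allele
# frequencies and observed heterozygote proportions per population.
# Sites need every population called (n_i >= 1) and mean sample size > 1;
# sites monomorphic across the pool get (0,0,0) and informative = FALSE.
wc_components <- function(N, P, H) {
  r <- nrow(N)
  L <- ncol(N)
  nsum <- colSums(N)
  nbar <- nsum / r
  ok <- colSums(N >= 1) == r & nbar > 1
  nc <- (nsum - colSums(N^2) / nsum) / (r - 1)
  pbar <- colSums(N * P) / nsum
  dev <- P - rep(pbar, each = r)
  s2 <- colSums(N * dev^2) / ((r - 1) * nbar)
  hbar <- colSums(N * H) / nsum
  inner <- pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4
  a <- nbar / nc * (s2 - inner / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  mono <- pbar <= 0 | pbar >= 1
  a[mono] <- 0; b[mono] <- 0; c[mono] <- 0
  informative <- ok & !mono & is.finite(a) & is.finite(b) & is.finite(c)
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; c[!ok] <- NA_real_
  list(a = a, b = b, c = c, informative = informative)
}

#' Weir-Cockerham variance components at one site
#'
#' Computes the among-population (`a`), among-individual-within-population
#' (`b`) and within-individual (`c`) variance components of the Weir &
#' Cockerham (1984) F-statistics estimator for diploids at a biallelic
#' site, from observed genotype counts.
#'
#' @param counts Integer matrix with one row per population and columns
#'   `(hom_ref, het, hom_alt)`.
#' @return list with `a`, `b`, `c`, `theta = a / (a + b + c)` and
#'   `informative` (FALSE when the pooled site is monomorphic or sample
#'   sizes are insufficient).
#' @export
wc_site_components <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 3) stopf("counts must have columns (hom_ref, het, hom_alt)")
  if (nrow(counts) < 2) stopf("need >= 2 populations")
  n <- rowSums(counts)
  if (any(n < 1)) stopf("every population needs >= 1 called diploid")
  p <- (counts[, 2] + 2 * counts[, 3]) / (2 * n)
  h <- counts[, 2] / n
  cm <- wc_components(matrix(n, ncol = 1), matrix(p, ncol = 1), matrix(h, ncol = 1))
  denom <- cm$a + cm$b + cm$c
  list(a = cm$a, b = cm$b, c = cm$c,
       theta = if (isTRUE(cm$informative) && denom != 0) cm$a / denom else NA_real_,
       informative = cm$informative)
}

# Population-wise site frequency matrices for a list of sample-index sets.
pop_site_matrices <- function(ds, idx_list) {
  L <- ncol(ds$calls)
  r <- length(idx_list)
  N <- P <- H <- matrix(0, nrow = r, ncol = L)
  for (i in seq_len(r)) {
    sf <- site_freqs(ds, idx_list[[i]])
    N[i, ] <- sf$n
    P[i, ] <- ifelse(is.na(sf$p), 0, sf$p)
    H[i, ] <- ifelse(is.na(sf$h), 0, sf$h)
  }
  list(N = N, P = P, H = H)
}

# Multi-locus ratio-of-sums theta between two sets of sample indices.
theta_between <- function(ds, idx_a, idx_b, sites = NULL) {
  m <- pop_site_matrices(ds, list(idx_a, idx_b))
  if (!is.null(sites)) {
    m$N <- m$N[, sites, drop = FALSE]
    m$P <- m$P[, sites, drop = FALSE]
    m$H <- m$H[, sites, drop = FALSE]
  }
  cm <- wc_components(m$N, m$P, m$H)
  inf <- cm$informative
  if (!any(inf)) return(list(theta = NA_real_, n_sites = 0L,
                             a = 0, abc = 0))
  a <- sum(cm$a[inf]); abc <- sum((cm$a + cm$b + cm$c)[inf])
  list(theta = if (abc != 0) a / abc else NA_real_,
       n_sites = sum(inf), a = a, abc = abc)
}

#' Pairwise Weir-Cockerham F_ST matrix
#'
#' For each pair of populations the multi-locus estimate is the ratio of
#' sums `theta = sum(a) / sum(a + b + c)` over sites informative for the
#' pair (both populations called, pooled site polymorphic). Small
#' negative estimates are an expected property of the estimator and are
#' not floored by default.
#'
#' @param ds A [genotype_dataset].
#' @param popmap A [population_map].
#' @param floor_negative Truncate negative estimates at 0 (default FALSE).
#' @return Symmetric matrix of class `fst_matrix` with `NA` diagonal.
#' @export
pairwise_fst <- function(ds, popmap, floor_negative = FALSE) {
  al <- align_popmap(ds, popmap)
  pops <- unique(al$population)
  if (length(pops) < 2) stopf("need >= 2 populations")
  idx <- lapply(pops, function(pp) which(al$population == pp))
  k <- length(pops)
  m <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    th <- theta_between(ds, idx[[i]], idx[[j]])
    if (th$n_sites == 0)
      warnf("no informative sites for pair %s-%s", pops[i], pops[j])
    v <- th$theta
    if (floor_negative && !is.na(v)) v <- max(v, 0)
    m[i, j] <- m[j, i] <- v
  }
  structure(m, class = c("fst_matrix", "matrix"))
}

#' @export
print.fst_matrix <- function(x, digits = 4, ...) {
  cat("Pairwise Weir-Cockerham F_ST\n")
  y <- unclass(x)
  print(round(y, digits), na.print = "-")
  invisible(x)
}

#' Principal component analysis of the genotype matrix
#'
#' Patterson-style normalization: missing entries are mean-imputed, each
#' site is centred by its mean dosage `2*p` and scaled by
#' `sqrt(2*p*(1-p))` with `p` the sample allele frequency; sites that are
#' monomorphic (or entirely missing) are excluded with a warning. The
#' sample covariance across normalized sites is eigendecomposed.
#'
#' @param ds A [genotype_dataset].
#' @param k Number of leading axes to return (default 10, capped at
#'   `n_samples - 1`).
#' @return list of class `pca_result` with `eigenvalues` (descending),
#'   `scores` (samples x k eigenvector coordinates), `prop_var`, and
#'   `n_sites_used`.
#' @export
genotype_pca <- function(ds, k = 10) {
  n <- length(ds$samples)
  if (n < 2 || ncol(ds$calls) < 2) stopf("need >= 2 samples and >= 2 sites")
  g <- ds$calls
  sf <- site_freqs(ds)
  usable <- !is.na(sf$p) & sf$p > 0 & sf$p < 1
  n_drop <- sum(!usable)
  if (n_drop > 0)
    warnf("excluding %d monomorphic or all-missing site(s) from PCA", n_drop)
  if (sum(usable) < 2) stopf("fewer than 2 polymorphic sites for PCA")
  g <- g[, usable, drop = FALSE]
  p <- sf$p[usable]
  mu <- 2 * p
  x <- sweep(ifelse(is.na(g), rep(mu, each = n), g), 2, mu, "-")
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  covm <- tcrossprod(x) / ncol(x)
  e <- eigen(covm, symmetric = TRUE)
  k <- min(k, n - 1)
  ev <- pmax(e$values, 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE]
  rownames(scores) <- ds$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(eigenvalues = e$values[seq_len(k)],
                 scores = scores,
                 prop_var = ev[seq_len(k)] / sum(ev),
                 n_sites_used = ncol(x)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA on %d samples x %d polymorphic sites\n",
              nrow(x$scores), x$n_sites_used))
  cat("  proportion of variance:",
      paste(sprintf("%s %.1f%%", colnames(x$scores)[1:min(3, ncol(x$scores))],
                    100 * x$prop_var[1:min(3, ncol(x$scores))]),
            collapse = ", "), "\n")
  invisible(x)
}
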