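# Hierarchical AMOVA on allele units with level-appropriate permutation
# tests.
#
# Genotypic data are analysed at the allele level: each called diploid
# contributes two alleles per locus, and every sum of squares reduces to
# per-locus allele counts (for a set holding m called alleles of which y
# are the alternate, SS = y * (m - y) / m), which makes the computation
# phase-invariant. Variance components are estimated locus by locus with
# the standard unbalanced-design expected-mean-square coefficients and
# combined as ratios of sums across loci; this matches the genotypic
# AMOVA of the standard population-genetics tools and makes the
# single-group Phi_ST directly comparable to the Weir-Cockerham theta.

# Per-individual alt-dosage and called-allele-count matrices (N x L).
amova_prep <- function(calls) {
  g <- calls
  a <- 2L * !is.na(g)
  g[is.na(g)] <- 0L
  storage.mode(g) <- "double"
  storage.mode(a) <- "double"
  list(G = g, A = a)
}

# safe y(m - y)/m, 0 when m = 0
ss_part <- function(y, m) {
  out <- y * (m - y)
  pos <- m > 0
  out[pos] <- out[pos] / m[pos]
  out[!pos] <- 0
  out
}

# Per-locus SS and variance components for population allele-count
# matrices Y, C (P x L) under grouping group_of_pop (length P).
# usable: logical per-locus mask fixed at the observed data.
amova_locus_components <- function(Y, C, group_of_pop, usable) {
  P <- nrow(C)
  G <- length(unique(group_of_pop))
  Yt <- colSums(Y); Ct <- colSums(C)
  ss_wp_l <- colSums(ss_part(Y, C))
  ss_tot_l <- ss_part(Yt, Ct)
  df_wp_l <- Ct - P
  sum_c2_l <- colSums(C^2)
  if (G >= 2) {
    Yg <- rowsum(Y, group_of_pop); Cg <- rowsum(C, group_of_pop)
    ss_wg_l <- colSums(ss_part(Yg, Cg))
    ss_ag_l <- ss_tot_l - ss_wg_l
    ss_ap_l <- ss_wg_l - ss_wp_l
    df_ag <- G - 1; df_ap <- P - G
    C2g <- rowsum(C^2, group_of_pop)
    ratio <- C2g
    pos <- Cg > 0
    ratio[pos] <- C2g[pos] / Cg[pos]; ratio[!pos] <- 0
    sum_c2_over_Cg_l <- colSums(ratio)
    n1 <- (Ct - sum_c2_over_Cg_l) / df_ap
    n2 <- (sum_c2_over_Cg_l - sum_c2_l / Ct) / df_ag
    n3 <- (Ct - colSums(Cg^2) / Ct) / df_ag
    ok <- usable & df_wp_l > 0 & n1 > 0 & n3 > 0
    sigc <- ss_wp_l / df_wp_l
    sigb <- (ss_ap_l / df_ap - sigc) / n1
    siga <- (ss_ag_l / df_ag - sigc - n2 * sigb) / n3
    list(ok = ok,
         ss = c(among_groups = sum(ss_ag_l[ok]),
                among_pops = sum(ss_ap_l[ok]),
                within_pops = sum(ss_wp_l[ok]),
                total = sum(ss_tot_l[ok])),
         sigma = c(among_groups = sum(siga[ok]),
                   among_pops = sum(sigb[ok]),
                   within_pops = sum(sigc[ok])),
         df = c(among_groups = df_ag, among_pops = df_ap,
                within_pops = round(mean(df_wp_l[ok]))))
  } else {
    ss_ap_l <- ss_tot_l - ss_wp_l
    df_ap <- P - 1
    n0 <- (Ct - sum_c2_l / Ct) / df_ap
    ok <- usable & df_wp_l > 0 & n0 > 0
    sigc <- ss_wp_l / df_wp_l
    sigb <- (ss_ap_l / df_ap - sigc) / n0
    list(ok = ok,
         ss = c(among_groups = NA_real_,
                among_pops = sum(ss_ap_l[ok]),
                within_pops = sum(ss_wp_l[ok]),
                total = sum(ss_tot_l[ok])),
         sigma = c(among_groups = NA_real_,
                   among_pops = sum(sigb[ok]),
                   within_pops = sum(sigc[ok])),
         df = c(among_groups = NA, among_pops = df_ap,
                within_pops = round(mean(df_wp_l[ok]))))
  }
}

phi_from_sigma <- function(sigma) {
  sa <- sigma[["among_groups"]]; sb <- sigma[["among_pops"]]
  sc <- sigma[["within_pops"]]
  if (is.na(sa)) {
    tot <- sb + sc
    c(phi_ct = NA_real_, phi_sc = NA_real_,
      phi_st = if (isTRUE(tot != 0)) sb / tot else NA_real_)
  } else {
    tot <- sa + sb + sc
    c(phi_ct = if (isTRUE(tot != 0)) sa / tot else NA_real_,
      phi_sc = if (isTRUE((sb + sc) != 0)) sb / (sb + sc) else NA_real_,
      phi_st = if (isTRUE(tot != 0)) (sa + sb) / tot else NA_real_)
  }
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions allelic variation among groups, among populations within
#' groups, and within populations (single-group designs reduce to the
#' two-level partition with Phi_ST only). Sums of squares are computed
#' on allele units per locus and variance components estimated locus by
#' locus with the standard unbalanced-design coefficients, then combined
#' across loci as ratios of sums; loci where any population has no
#' called allele are excluded (count reported in `flags`). Negative
#' variance components are reported as estimated (not truncated), so
#' percentages can fall outside `[0, 100]`.
#'
#' Permutation significance uses level-appropriate schemes: Phi_ST
#' permutes individuals among populations across the whole sample;
#' Phi_SC permutes individuals among populations within their group;
#' Phi_CT permutes whole populations among groups. p-values are
#' `(#(permuted >= observed) + 1) / (n_perm + 1)` and are reproducible
#' given `(n_perm, seed)`.
#'
#' @param ds A [genotype_dataset].
#' @param popmap A [population_map].
#' @param grouping Optional named list mapping group names to character
#'   vectors of population names; defaults to the popmap's own groups.
#'   Must partition the populations.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutations (required; logged in
#'   the result).
#' @param perm_stats Which Phi statistics to test by permutation
#'   (default all three); untested ones get `NA` p-values.
#' @return Object of class `amova_result`: data.frame `table` (df, SS,
#'   variance component, percentage per stratum), `phi` and `p_value`
#'   vectors, `n_permutations`, `seed`, `grouping`, and `flags`.
#' @export
amova <- function(ds, popmap, grouping = NULL, n_perm = 10000, seed,
                  perm_stats = c("phi_st", "phi_sc", "phi_ct")) {
  if (missing(seed)) stopf("amova requires an explicit permutation seed")
  perm_stats <- match.arg(perm_stats, several.ok = TRUE)
  stopifnot(n_perm >= 1)
  al <- align_popmap(ds, popmap)
  pops <- unique(al$population)
  if (is.null(grouping)) {
    pg <- unique(al[, c("population", "group")])
    grouping <- split(pg$population, pg$group)
  }
  gp_pops <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(gp_pops) || !setequal(gp_pops, pops))
    stopf("grouping must partition the populations exactly")
  pop_levels <- gp_pops
  pop_of_ind <- match(al$population, pop_levels)
  group_of_pop <- rep(seq_along(grouping), lengths(grouping))
  sizes <- tabulate(pop_of_ind, length(pop_levels))
  if (any(sizes == 0)) stopf("population with no individuals: %s",
                             paste(pop_levels[sizes == 0], collapse = ", "))
  G <- length(grouping)
  if (length(pop_levels) == 1) {
    # degenerate partition: all variation is within the single population
    prep <- amova_prep(ds$calls)
    Yt <- colSums(prep$G); Ct <- colSums(prep$A)
    ss_tot <- sum(ss_part(Yt, Ct)[Ct > 0])
    tab <- data.frame(stratum = c("among_pops_within_groups", "within_pops", "total"),
                      df = c(0, sum(Ct > 0) * 0 + round(mean(Ct[Ct > 0])) - 1,
                             round(mean(Ct[Ct > 0])) - 1),
                      SS = c(0, ss_tot, ss_tot),
                      sigma2 = NA_real_, pct_variation = c(0, 100, 100),
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab,
                          phi = c(phi_ct = NA_real_, phi_sc = NA_real_,
                                  phi_st = NA_real_),
                          p_value = c(phi_ct = NA_real_, phi_sc = NA_real_,
                                      phi_st = NA_real_),
                          n_permutations = n_perm, seed = seed,
                          grouping = grouping,
                          flags = "single population: no among-population stratum"),
                     class = "amova_result"))
  }
  flags <- character(0)
  if (G >= 2 && any(lengths(grouping) == 1))
    flags <- c(flags, "group(s) with a single population: Phi_SC degenerate for that configuration")

  prep <- amova_prep(ds$calls)
  popY <- rowsum(prep$G, pop_of_ind)
  popC <- rowsum(prep$A, pop_of_ind)
  usable <- colSums(popC > 0) == length(pop_levels)
  n_drop <- sum(!usable)
  if (n_drop > 0)
    flags <- c(flags, sprintf("%d locus(i) excluded (a population has no called allele)", n_drop))
  if (!any(usable)) stopf("no usable loci for AMOVA")

  obs <- amova_locus_components(popY, popC, group_of_pop, usable)
  phi <- phi_from_sigma(obs$sigma)
  if (obs$ss[["total"]] <= 1e-12) {
    flags <- c(flags, "zero total sum of squares: Phi undefined")
    phi[] <- NA_real_
  }
  if (any(obs$sigma < 0, na.rm = TRUE))
    flags <- c(flags, "negative variance component estimate(s); percentages may fall outside [0, 100]")

  obs_ct <- phi[["phi_ct"]]; obs_sc <- phi[["phi_sc"]]; obs_st <- phi[["phi_st"]]
  do_st <- "phi_st" %in% perm_stats && !is.na(obs_st)
  do_sc <- "phi_sc" %in% perm_stats && G >= 2 && !is.na(obs_sc)
  do_ct <- "phi_ct" %in% perm_stats && G >= 2 && !is.na(obs_ct)
  pvals <- c(phi_ct = NA_real_, phi_sc = NA_real_, phi_st = NA_real_)
  if (do_st || do_sc || do_ct) {
    pvals <- with_seed(seed, {
      n_ge_st <- 0L; n_ge_sc <- 0L; n_ge_ct <- 0L
      grp_of_ind <- group_of_pop[pop_of_ind]
      for (b in seq_len(n_perm)) {
        if (do_st) {
          # Phi_ST: individuals among populations, whole sample
          perm <- sample(pop_of_ind)
          st <- amova_locus_components(rowsum(prep$G, perm),
                                       rowsum(prep$A, perm),
                                       group_of_pop, usable)
          if (phi_from_sigma(st$sigma)[["phi_st"]] >= obs_st)
            n_ge_st <- n_ge_st + 1L
        }
        if (do_sc) {
          # Phi_SC: individuals among populations within their group
          perm2 <- pop_of_ind
          for (gg in seq_len(G)) {
            in_g <- which(grp_of_ind == gg)
            perm2[in_g] <- sample(pop_of_ind[in_g])
          }
          st <- amova_locus_components(rowsum(prep$G, perm2),
                                       rowsum(prep$A, perm2),
                                       group_of_pop, usable)
          if (phi_from_sigma(st$sigma)[["phi_sc"]] >= obs_sc)
            n_ge_sc <- n_ge_sc + 1L
        }
        if (do_ct) {
          # Phi_CT: whole populations among groups (pops-per-group
          # counts preserved)
          gperm <- sample(group_of_pop)
          st <- amova_locus_components(popY, popC, gperm, usable)
          if (phi_from_sigma(st$sigma)[["phi_ct"]] >= obs_ct)
            n_ge_ct <- n_ge_ct + 1L
        }
      }
      c(phi_ct = if (do_ct) (n_ge_ct + 1) / (n_perm + 1) else NA_real_,
        phi_sc = if (do_sc) (n_ge_sc + 1) / (n_perm + 1) else NA_real_,
        phi_st = if (do_st) (n_ge_st + 1) / (n_perm + 1) else NA_real_)
    })
  }

  sig <- obs$sigma
  tot_sig <- sum(sig, na.rm = TRUE)
  pct <- if (isTRUE(tot_sig != 0)) 100 * sig / tot_sig else rep(NA_real_, 3)
  tab <- data.frame(
    stratum = c("among_groups", "among_pops_within_groups", "within_pops", "total"),
    df = c(obs$df, sum(obs$df, na.rm = TRUE)),
    SS = c(obs$ss[["among_groups"]], obs$ss[["among_pops"]],
           obs$ss[["within_pops"]], obs$ss[["total"]]),
    sigma2 = c(sig, tot_sig),
    pct_variation = c(pct, if (all(is.na(pct))) NA_real_ else 100),
    stringsAsFactors = FALSE)
  if (G < 2) tab <- tab[-1, ]
  rownames(tab) <- NULL
  structure(list(table = tab, phi = phi, p_value = pvals,
                 n_permutations = n_perm, seed = seed,
                 grouping = grouping, flags = flags),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, digits = 4, ...) {
  cat("AMOVA:", paste(sprintf("[%s]", vapply(x$grouping, paste, "",
                                             collapse = "; ")),
                      collapse = " "), "\n")
  tab <- x$table
  tab$SS <- round(tab$SS, digits); tab$sigma2 <- round(tab$sigma2, digits)
  tab$pct_variation <- round(tab$pct_variation, 2)
  print(tab, row.names = FALSE)
  phi <- x$phi[!is.na(x$phi)]
  p <- x$p_value[names(phi)]
  cat(paste(sprintf("  %s = %.4f (p = %s)", names(phi), phi,
                    format(p, digits = 3)), collapse = "\n"), "\n")
  cat(sprintf("  %d permutations, seed %d\n", x$n_permutations, x$seed))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}
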