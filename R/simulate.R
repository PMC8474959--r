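# Balding-Nichols structured-population genotype simulator with embedded
# sweep windows and ground truth for recovery testing.

#' Simulation configuration
#'
#' Defaults pin the study design the package targets: seven populations
#' with sample sizes (10, 5, 20, 12, 16, 10, 3) nested in two geographic
#' groups, group-level divergence `f_ct = 0.064` and
#' population-within-group divergence `f_sc = 0.058` (the hierarchical
#' fixation levels the AMOVA estimates), 10% missing calls, and a desk-
#' scale genome of 2 chromosomes x 1 Mb x 2000 SNPs each.
#'
#' @param groups Named list of groups; each group is a named list/vector
#'   of diploid sample counts per population.
#' @param n_chromosomes,chrom_length,n_snps Genome shape: chromosome
#'   count, length (bp), and SNPs per chromosome.
#' @param freq_law Ancestral allele-frequency law: `"uniform"` on
#'   `freq_par = c(min, max)` (default `c(0.05, 0.95)`) or `"beta"` with
#'   `freq_par = c(shape1, shape2)`.
#' @param freq_par Parameters of the frequency law.
#' @param f_ct Group-level Balding-Nichols divergence in `[0, 1)`.
#' @param f_sc Population-within-group divergence in `[0, 1)`.
#' @param missing_rate Probability a genotype call is missing.
#' @param sweeps List of sweep specifications, each a list with `chrom`
#'   (chromosome name), `start`, `end` (0-based half-open bp), `target`
#'   (population or group name) and `s` (intensity in `(0, 1]`).
#' @param gene_frac Fraction of each chromosome tiled by genes.
#' @param gene_len Gene length in bp.
#' @param seed Integer base seed; all draws derive from it through a
#'   hierarchical sub-stream scheme.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(groups = list(
                         north = c(AKS = 10, ALR = 5, KRL = 20),
                         southwest = c(TX = 12, AKT = 16, KS = 10, WQ = 3)),
                       n_chromosomes = 2, chrom_length = 1e6, n_snps = 2000,
                       freq_law = c("uniform", "beta"),
                       freq_par = NULL,
                       f_ct = 0.064, f_sc = 0.058, missing_rate = 0.1,
                       sweeps = list(), gene_frac = 0.3, gene_len = 3000,
                       seed = 1) {
  freq_law <- match.arg(freq_law)
  freq_par <- freq_par %||% if (freq_law == "uniform") c(0.05, 0.95) else c(1, 1)
  stopifnot(f_ct >= 0, f_ct < 1, f_sc >= 0, f_sc < 1,
            missing_rate >= 0, missing_rate < 1,
            n_snps >= 1, chrom_length >= n_snps, n_chromosomes >= 1,
            gene_frac > 0, gene_frac <= 1, gene_len >= 1)
  pops <- unlist(lapply(groups, names))
  if (anyDuplicated(pops)) stopf("population names must be unique")
  chroms <- paste0("chr", seq_len(n_chromosomes))
  for (sw in sweeps) {
    if (!all(c("chrom", "start", "end", "target", "s") %in% names(sw)))
      stopf("each sweep needs chrom, start, end, target, s")
    if (!sw$chrom %in% chroms) stopf("sweep on unknown chromosome %s", sw$chrom)
    if (sw$start < 0 || sw$end > chrom_length || sw$start >= sw$end)
      stopf("sweep interval outside chromosome bounds")
    if (!(sw$target %in% pops) && !(sw$target %in% names(groups)))
      stopf("sweep target '%s' is not a population or group", sw$target)
    if (sw$s <= 0 || sw$s > 1) stopf("sweep intensity must be in (0, 1]")
  }
  structure(list(groups = groups, n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length, n_snps = n_snps,
                 freq_law = freq_law, freq_par = freq_par,
                 f_ct = f_ct, f_sc = f_sc, missing_rate = missing_rate,
                 sweeps = sweeps, gene_frac = gene_frac,
                 gene_len = gene_len, seed = seed),
            class = "sim_config")
}

# Balding-Nichols draw of descendant frequencies around p with divergence
# f; exact identity when f = 0. Degenerate p in {0, 1} stays fixed.
bn_draw <- function(p, f) {
  if (f == 0) return(p)
  out <- p
  poly <- p > 0 & p < 1
  out[poly] <- stats::rbeta(sum(poly),
                            p[poly] * (1 - f) / f,
                            (1 - p[poly]) * (1 - f) / f)
  out
}

#' Simulate a structured genotype dataset with embedded sweeps
#'
#' Per site, an ancestral frequency `p0` is drawn from the configured
#' law; each group's frequency is a Balding-Nichols draw around `p0`
#' with divergence `f_ct`, and each population's frequency a draw around
#' its group's with `f_sc`. Genotypes are Binomial(2, p_pop) per
#' individual (Hardy-Weinberg within populations). Inside a sweep window
#' targeting `T` with intensity `s`, `T`'s frequency is pulled toward the
#' nearer boundary, `p' = (1 - s) p + s [p >= 0.5]`, which depletes
#' diversity and elevates differentiation proportionally to `s`.
#' Missingness is applied uniformly at random. A single base seed drives
#' hierarchical sub-streams (per chromosome, stage and population), so
#' identical configurations reproduce bit-for-bit and adding populations
#' does not perturb earlier draws.
#'
#' @param config A [sim_config].
#' @return list with elements `dataset` ([genotype_dataset]), `popmap`
#'   ([population_map]), `genes` ([gene_set]), `truth` (list of class
#'   `sim_truth` holding per-site ancestral/group/population frequencies,
#'   the sweep registry and the full configuration).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  group_names <- names(cfg$groups)
  pop_names <- unlist(lapply(cfg$groups, names), use.names = FALSE)
  pop_group <- rep(group_names, vapply(cfg$groups, length, 1L))
  pop_n <- unlist(cfg$groups, use.names = FALSE)
  samples <- unlist(lapply(seq_along(pop_names), function(i)
    sprintf("%s_%02d", pop_names[i], seq_len(pop_n[i]))))
  popmap <- population_map(data.frame(
    sample = samples,
    population = rep(pop_names, pop_n),
    group = rep(pop_group, pop_n), stringsAsFactors = FALSE))

  nt <- c("A", "C", "G", "T")
  var_list <- list(); call_list <- list()
  p0_all <- list(); gfreq_all <- list(); pfreq_all <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    pos <- with_seed(subseed(cfg$seed, "sites", ch), {
      sort(sample.int(cfg$chrom_length, cfg$n_snps))
    })
    alle <- with_seed(subseed(cfg$seed, "alleles", ch), {
      ref <- sample(nt, cfg$n_snps, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), "")
      list(ref = ref, alt = alt)
    })
    p0 <- with_seed(subseed(cfg$seed, "p0", ch), {
      if (cfg$freq_law == "uniform")
        stats::runif(cfg$n_snps, cfg$freq_par[1], cfg$freq_par[2])
      else stats::rbeta(cfg$n_snps, cfg$freq_par[1], cfg$freq_par[2])
    })
    gfreq <- vapply(group_names, function(g)
      with_seed(subseed(cfg$seed, "gfreq", ch, g), bn_draw(p0, cfg$f_ct)),
      numeric(cfg$n_snps))
    gfreq <- matrix(gfreq, ncol = length(group_names),
                    dimnames = list(NULL, group_names))

    # sweep distortion, p' = (1 - s) p + s [p >= 0.5]: group targets act
    # on the group frequency (before the population draws, so the whole
    # group sweeps together); population targets act after
    pos0 <- pos - 1
    pull <- function(p, s) (1 - s) * p + s * as.numeric(p >= 0.5)
    for (sw in cfg$sweeps) {
      if (sw$chrom != ch || !(sw$target %in% group_names)) next
      hit <- pos0 >= sw$start & pos0 < sw$end
      gfreq[hit, sw$target] <- pull(gfreq[hit, sw$target], sw$s)
    }

    pfreq <- vapply(seq_along(pop_names), function(i)
      with_seed(subseed(cfg$seed, "pfreq", ch, pop_names[i]),
                bn_draw(gfreq[, pop_group[i]], cfg$f_sc)),
      numeric(cfg$n_snps))
    pfreq <- matrix(pfreq, ncol = length(pop_names),
                    dimnames = list(NULL, pop_names))
    for (sw in cfg$sweeps) {
      if (sw$chrom != ch || sw$target %in% group_names) next
      hit <- pos0 >= sw$start & pos0 < sw$end
      pfreq[hit, sw$target] <- pull(pfreq[hit, sw$target], sw$s)
    }

    calls <- matrix(NA_integer_, nrow = length(samples), ncol = cfg$n_snps)
    row0 <- 0
    for (i in seq_along(pop_names)) {
      n <- pop_n[i]
      g <- with_seed(subseed(cfg$seed, "geno", ch, pop_names[i]), {
        matrix(stats::rbinom(n * cfg$n_snps, 2,
                             rep(pfreq[, i], each = n)), nrow = n)
      })
      if (cfg$missing_rate > 0) {
        g <- with_seed(subseed(cfg$seed, "miss", ch, pop_names[i]), {
          g[stats::runif(length(g)) < cfg$missing_rate] <- NA_integer_
          g
        })
      }
      calls[row0 + seq_len(n), ] <- g
      row0 <- row0 + n
    }
    var_list[[ci]] <- data.frame(chrom = ch, pos = pos,
                                 id = sprintf("%s_snp%d", ch, seq_along(pos)),
                                 ref = alle$ref, alt = alle$alt,
                                 stringsAsFactors = FALSE)
    call_list[[ci]] <- calls
    p0_all[[ch]] <- p0; gfreq_all[[ch]] <- gfreq; pfreq_all[[ch]] <- pfreq
  }

  cl <- stats::setNames(rep(cfg$chrom_length, length(chroms)), chroms)
  ds <- genotype_dataset(do.call(rbind, var_list), samples,
                         do.call(cbind, call_list), contig_lengths = cl)

  # non-overlapping gene intervals tiling gene_frac of each chromosome
  stride <- max(cfg$gene_len, round(cfg$gene_len / cfg$gene_frac))
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    starts <- seq(0, cfg$chrom_length - cfg$gene_len, by = stride)
    data.frame(gene_id = sprintf("%s_g%03d", ch, seq_along(starts)),
               chrom = ch, start = starts, end = starts + cfg$gene_len,
               stringsAsFactors = FALSE)
  }))
  genes <- gene_set(genes)

  truth <- structure(list(config = unclass(cfg), seed = cfg$seed,
                          ancestral_freq = p0_all,
                          group_freq = lapply(gfreq_all, as.data.frame),
                          pop_freq = lapply(pfreq_all, as.data.frame),
                          sweeps = cfg$sweeps),
                     class = "sim_truth")
  list(dataset = ds, popmap = popmap, genes = genes, truth = truth)
}

#' Write simulator outputs to disk
#'
#' Emits `<prefix>.vcf` (with contig-length headers), `<prefix>.popmap.tsv`,
#' `<prefix>.genes.bed`, and `<prefix>.truth.json`. All files are plain
#' text with LF endings and no timestamps, so identical inputs produce
#' byte-identical outputs.
#'
#' @param sim Result of [simulate_dataset] (or its four components).
#' @param prefix Output path prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim_outputs <- function(sim, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = paste0(prefix, ".vcf"),
             popmap = paste0(prefix, ".popmap.tsv"),
             genes = paste0(prefix, ".genes.bed"),
             truth = paste0(prefix, ".truth.json"))
  write_vcf(sim$dataset, paths[["vcf"]])
  write_popmap(sim$popmap, paths[["popmap"]])
  write_gene_bed(sim$genes, paths[["genes"]])
  json <- jsonlite::toJSON(unclass(sim$truth), digits = NA,
                           auto_unbox = TRUE, null = "null")
  con <- file(paths[["truth"]], "wb")
  writeLines(json, con)
  close(con)
  invisible(paths)
}

#' Read a simulator ground-truth JSON back into a list
#'
#' @param path Path to a `.truth.json` written by [write_sim_outputs].
#' @return list with the same structure as the in-memory `sim_truth`.
#' @export
read_sim_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
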