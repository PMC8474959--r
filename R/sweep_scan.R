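# Windowed selective-sweep scan: per-window F_ST and per-group pi over
# non-overlapping windows, log2 pi-ratio, joint empirical-tail outlier
# calling, gene overlap, and hypergeometric enrichment.

#' Tile chromosomes into non-overlapping windows
#'
#' Tiles `[0, L)` for each chromosome in steps of `size` bp (0-based
#' half-open); the terminal window is truncated at the chromosome length.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param size Window size in bp (default 10000).
#' @param offset Start coordinate of the first window (default 0; allows
#'   replication of 1-anchored tools).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, size = 10000, offset = 0) {
  stopifnot(size > 0, offset >= 0)
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    if (is.na(L) || L <= offset) return(NULL)
    starts <- seq(offset, L - 1, by = size)
    data.frame(chrom = ch, start = starts, end = pmin(starts + size, L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-window F_ST, per-group nucleotide diversity, and log2 pi ratio
#'
#' For each window: the between-group Weir-Cockerham F_ST is the
#' ratio-of-sums theta over in-window informative sites (the two contrast
#' groups treated as the two populations); per-group pi is the sum of
#' per-site unbiased gene diversities divided by the window length in bp;
#' `log2_ratio = log2(pi_a / pi_b)`. Windows with fewer than `min_snps`
#' SNPs, zero diversity in either group, or no informative F_ST sites are
#' flagged uninformative and excluded from downstream quantiles.
#'
#' @param ds A [genotype_dataset] (typically already site-filtered).
#' @param popmap A [population_map].
#' @param group_a,group_b Group labels (contrast direction: `group_a` is
#'   the numerator of the pi ratio — the control/contrast-A group).
#' @param windows Optional window table from [make_windows]; by default
#'   windows are tiled from the dataset's contig lengths (or the maximum
#'   SNP position per chromosome when lengths are unknown).
#' @param window_size Window size in bp when `windows` is NULL.
#' @param min_snps Minimum retained SNPs for an informative window
#'   (default 2).
#' @param pseudocount Value added to each window pi before the ratio
#'   (default 0; sensitivity option for zero-diversity windows).
#' @return data.frame of class `window_stats` with per-window columns
#'   `chrom`, `start`, `end`, `n_snps`, `fst`, `pi_a`, `pi_b`,
#'   `log2_ratio`, `informative`.
#' @export
window_stats <- function(ds, popmap, group_a, group_b, windows = NULL,
                         window_size = 10000, min_snps = 2,
                         pseudocount = 0) {
  if (identical(group_a, group_b)) stopf("contrast groups must differ")
  idx_a <- pop_indices(ds, popmap, group_a, by = "group")
  idx_b <- pop_indices(ds, popmap, group_b, by = "group")
  if (length(idx_a) < 2 || length(idx_b) < 2)
    stopf("each contrast group needs >= 2 samples")
  if (is.null(windows)) {
    cl <- ds$contig_lengths
    if (is.null(cl))
      cl <- tapply(ds$variants$pos, ds$variants$chrom, max)
    windows <- make_windows(as.list(cl) |> unlist(), size = window_size)
  }

  m <- pop_site_matrices(ds, list(idx_a, idx_b))
  cm <- wc_components(m$N, m$P, m$H)
  div_a <- gene_div_vec(m$P[1, ], m$N[1, ], unbiased = TRUE)
  div_b <- gene_div_vec(m$P[2, ], m$N[2, ], unbiased = TRUE)
  div_a[is.na(div_a)] <- 0
  div_b[is.na(div_b)] <- 0
  a <- ifelse(cm$informative, cm$a, 0)
  abc <- ifelse(cm$informative, cm$a + cm$b + cm$c, 0)

  # assign each SNP to a window (0-based position = pos - 1)
  pos0 <- ds$variants$pos - 1
  wi <- rep(NA_integer_, length(pos0))
  for (ch in unique(windows$chrom)) {
    wsel <- which(windows$chrom == ch)
    wsel <- wsel[order(windows$start[wsel])]
    ssel <- which(ds$variants$chrom == ch)
    if (!length(ssel)) next
    j <- findInterval(pos0[ssel], windows$start[wsel])
    ok <- j >= 1 & pos0[ssel] < windows$end[wsel][pmax(j, 1)]
    wi[ssel[ok]] <- wsel[j[ok]]
  }
  inw <- !is.na(wi)

  agg <- function(x) {
    out <- numeric(nrow(windows))
    s <- rowsum(x[inw], wi[inw])
    out[as.integer(rownames(s))] <- s
    out
  }
  n_snps <- agg(rep(1, length(wi)))
  sum_a <- agg(a)
  sum_abc <- agg(abc)
  len <- windows$end - windows$start
  pi_a <- agg(div_a) / len + pseudocount
  pi_b <- agg(div_b) / len + pseudocount
  fst <- ifelse(sum_abc > 0, sum_a / sum_abc, NA_real_)
  ratio <- ifelse(pi_a > 0 & pi_b > 0, log2(pi_a / pi_b), NA_real_)
  informative <- n_snps >= min_snps & pi_a > 0 & pi_b > 0 & !is.na(fst)
  n_zero <- sum(n_snps >= min_snps & (pi_a == 0 | pi_b == 0))
  if (n_zero > 0)
    msgf("window_stats: %d window(s) uninformative (zero diversity in a group)", n_zero)
  if (!any(informative)) stopf("no informative windows")
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, n_snps = as.integer(n_snps),
                    fst = fst, pi_a = pi_a, pi_b = pi_b,
                    log2_ratio = ratio, informative = informative,
                    stringsAsFactors = FALSE)
  attr(out, "groups") <- c(a = paste(group_a, collapse = "+"),
                           b = paste(group_b, collapse = "+"))
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Call selected windows by joint empirical-tail thresholds
#'
#' Realized cutoffs are the empirical (type-7) quantiles of the
#' informative windows: the F_ST cutoff at `fst_level` and the pi-ratio
#' cutoffs at `tail_level` and `1 - tail_level`. Windows selected for
#' group B (diversity depleted in B) satisfy `fst >= fst_cutoff` and
#' `log2_ratio >= upper cutoff`; selected for group A satisfy
#' `fst >= fst_cutoff` and `log2_ratio <= lower cutoff`. Comparisons are
#' inclusive, so ties at a cutoff are selected.
#'
#' @param stats A [window_stats] table.
#' @param fst_level Quantile level of the F_ST cutoff (default 0.95).
#' @param tail_level Tail mass of the ratio cutoffs (default 0.05).
#' @return list of class `sweep_call` with `cutoffs`, logical vectors
#'   `selected_a`/`selected_b` over the full window table, and the
#'   window table itself.
#' @export
call_selected_windows <- function(stats, fst_level = 0.95, tail_level = 0.05) {
  inf <- stats$informative
  if (sum(inf) < 20)
    stopf("only %d informative windows; >= 20 required for empirical quantiles",
          sum(inf))
  fst_cut <- stats::quantile(stats$fst[inf], fst_level, type = 7, names = FALSE)
  lo_cut <- stats::quantile(stats$log2_ratio[inf], tail_level, type = 7, names = FALSE)
  hi_cut <- stats::quantile(stats$log2_ratio[inf], 1 - tail_level, type = 7,
                            names = FALSE)
  pass_fst <- inf & stats$fst >= fst_cut
  sel_b <- pass_fst & stats$log2_ratio >= hi_cut
  sel_a <- pass_fst & stats$log2_ratio <= lo_cut
  structure(list(cutoffs = c(fst = fst_cut, ratio_low = lo_cut,
                             ratio_high = hi_cut),
                 levels = c(fst_level = fst_level, tail_level = tail_level),
                 selected_a = sel_a, selected_b = sel_b,
                 n_pass_fst = sum(pass_fst),
                 groups = attr(stats, "groups"),
                 windows = as.data.frame(stats)),
            class = "sweep_call")
}

#' @export
print.sweep_call <- function(x, ...) {
  g <- x$groups %||% c(a = "A", b = "B")
  cat(sprintf("Sweep scan %s vs %s: %d informative windows\n",
              g[["a"]], g[["b"]], sum(x$windows$informative)))
  cat(sprintf("  cutoffs: F_ST >= %.4f; log2 ratio <= %.4f | >= %.4f\n",
              x$cutoffs[["fst"]], x$cutoffs[["ratio_low"]],
              x$cutoffs[["ratio_high"]]))
  cat(sprintf("  selected: %d windows (%s-selected), %d windows (%s-selected)\n",
              sum(x$selected_a), g[["a"]], sum(x$selected_b), g[["b"]]))
  invisible(x)
}

#' Overlap selected windows with gene annotations
#'
#' A gene is a candidate for a direction iff its interval intersects at
#' least one selected window by >= 1 bp under the half-open convention
#' (windows and genes both 0-based half-open; adjacency is not overlap).
#'
#' @param call A [call_selected_windows] result.
#' @param genes A [gene_set].
#' @return list with data.frames `a` and `b`; columns `gene_id`, `chrom`,
#'   `start`, `end`, `windows` (semicolon-joined recruiting windows).
#' @export
overlap_genes <- function(call, genes) {
  hit <- function(sel) {
    w <- call$windows[sel, , drop = FALSE]
    rows <- lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      ov <- w$chrom == g$chrom & g$start < w$end & w$start < g$end
      if (!any(ov)) return(NULL)
      data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
                 end = g$end,
                 windows = paste(sprintf("%s:%d-%d", w$chrom[ov],
                                         w$start[ov], w$end[ov]),
                                 collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        windows = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  }
  list(a = hit(call$selected_a), b = hit(call$selected_b))
}

#' Hypergeometric gene-set over-representation test
#'
#' One-sided over-representation p-value per term: with universe size
#' `N`, term size `K`, candidate-set size `m` and overlap `k`,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, m)`. Terms are flagged
#' significant at raw `p < alpha`; no multiple-testing correction is
#' applied by default (a Benjamini-Hochberg column is available).
#'
#' @param candidates Character vector of candidate gene ids (must be a
#'   subset of `universe`).
#' @param universe Character vector of all gene ids considered.
#' @param term2gene data.frame with columns `term` and `gene` (rows
#'   outside the universe are dropped).
#' @param alpha Raw significance cutoff (default 0.05).
#' @param adjust Also report BH-adjusted p-values (default FALSE).
#' @return data.frame of class `enrichment_result` with per-term `term`,
#'   `term_size`, `overlap`, `n_candidates`, `n_universe`, `p`,
#'   `significant` (and `p_adj` when requested).
#' @export
enrich <- function(candidates, universe, term2gene, alpha = 0.05,
                   adjust = FALSE) {
  universe <- unique(universe)
  candidates <- unique(candidates)
  missing <- setdiff(candidates, universe)
  if (length(missing))
    stopf("candidate gene(s) absent from universe: %s",
          paste(missing, collapse = ", "))
  if (!all(c("term", "gene") %in% names(term2gene)))
    stopf("term2gene must have columns 'term' and 'gene'")
  t2g <- term2gene[term2gene$gene %in% universe, , drop = FALSE]
  t2g <- unique(t2g[, c("term", "gene")])
  terms <- unique(term2gene$term)
  N <- length(universe)
  m <- length(candidates)
  rows <- lapply(terms, function(tt) {
    genes_t <- t2g$gene[t2g$term == tt]
    K <- length(genes_t)
    if (K == 0) {
      warnf("term '%s' has no genes in the universe; skipped", tt)
      return(NULL)
    }
    k <- length(intersect(genes_t, candidates))
    p <- stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
    data.frame(term = tt, term_size = K, overlap = k, n_candidates = m,
               n_universe = N, p = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no usable terms")
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Read a term-to-gene mapping (two-column TSV or GMT)
#'
#' @param path `.gmt` file (term, description, genes...) or a TSV with
#'   header columns `term` and `gene`.
#' @return data.frame with columns `term`, `gene`.
#' @export
read_term2gene <- function(path) {
  if (!file.exists(path)) stopf("term mapping file not found: %s", path)
  if (tolower(tools::file_ext(path)) == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    rows <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
      if (length(f) < 3) return(NULL)
      data.frame(term = f[1], gene = f[-(1:2)], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stopf("no usable GMT records in %s", path)
    return(out)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("term", "gene") %in% names(df)))
    stopf("TSV term mapping must have columns 'term' and 'gene'")
  df[, c("term", "gene")]
}
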