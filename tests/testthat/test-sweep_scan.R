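test_that("window tiling covers chromosomes without overlap", {
  w <- make_windows(c(chrA = 25000), size = 10000)
  expect_equal(w$start, c(0, 10000, 20000))
  expect_equal(w$end, c(10000, 20000, 25000))
  expect_equal(nrow(make_windows(c(chrA = 10000))), 1L)
  w2 <- make_windows(c(chrA = 25000, chrB = 9000), size = 10000)
  expect_equal(sum(w2$chrom == "chrB"), 1L)
  # non-overlap and full coverage
  expect_true(all(w$start[-1] == w$end[-nrow(w)]))
})

sweep_sim <- function(seed = 70, sweeps = list(), n_snps = 600,
                      chrom_length = 3e5, f_ct = 0.05) {
  simulate_dataset(sim_config(
    groups = list(gA = c(P1 = 10, P2 = 10), gB = c(P3 = 10, P4 = 10)),
    n_chromosomes = 1, chrom_length = chrom_length, n_snps = n_snps,
    f_ct = f_ct, f_sc = 0.02, missing_rate = 0.05, sweeps = sweeps,
    seed = seed))
}

test_that("window stats: SNP assignment, per-bp pi, and guard cases", {
  sim <- sweep_sim()
  ds <- sim$dataset
  ws <- suppressMessages(window_stats(ds, sim$popmap, "gA", "gB",
                                      window_size = 10000))
  # every SNP falls in exactly one window
  expect_equal(sum(ws$n_snps), nrow(ds$variants))
  expect_equal(nrow(ws), 30L)
  # a SNP at 1-based position 10000 belongs to the first window
  ds1 <- genotype_dataset(
    data.frame(chrom = "chr1", pos = c(10000L, 10001L), id = ".",
               ref = "A", alt = "G"),
    ds$samples, ds$calls[, 1:2], contig_lengths = c(chr1 = 20000))
  ws1 <- suppressMessages(window_stats(ds1, sim$popmap, "gA", "gB",
                                       min_snps = 1))
  expect_equal(ws1$n_snps, c(1L, 1L))
  # zero-SNP windows are uninformative with zero diversity
  empty <- ws[ws$n_snps == 0, ]
  expect_true(all(!empty$informative))
  expect_true(all(empty$pi_a == 0 & empty$pi_b == 0))
  # pi is per-bp: bounded by n_snps / window length
  expect_true(all(ws$pi_a <= ws$n_snps / (ws$end - ws$start)))
})

test_that("identical group frequencies give fst ~ 0 and log2 ratio ~ 0", {
  # both groups drawn as one pool: copy group A's samples into group B
  sim <- sweep_sim()
  ds <- sim$dataset
  idx_a <- popsweep:::pop_indices(ds, sim$popmap, "gA", by = "group")
  calls <- ds$calls
  calls[popsweep:::pop_indices(ds, sim$popmap, "gB", by = "group"), ] <-
    calls[idx_a, ]
  ds2 <- genotype_dataset(ds$variants, ds$samples, calls,
                          contig_lengths = ds$contig_lengths)
  ws <- suppressMessages(window_stats(ds2, sim$popmap, "gA", "gB"))
  expect_true(all(abs(ws$log2_ratio[ws$informative]) < 1e-6))
})

test_that("empirical-tail selection: exact counts, intersection, saturation", {
  # 1000 informative windows with all-distinct values -> exactly 50 pass
  # the F_ST criterion at the 95th percentile
  set.seed(40)
  n <- 1000
  stats <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 1e4,
                      end = (1:n) * 1e4, n_snps = 5L,
                      fst = sample(seq(0.001, 1, length.out = n)),
                      pi_a = runif(n, 0.001, 0.01),
                      pi_b = runif(n, 0.001, 0.01))
  stats$log2_ratio <- log2(stats$pi_a / stats$pi_b)
  stats$informative <- TRUE
  class(stats) <- c("window_stats", "data.frame")
  call <- call_selected_windows(stats)
  expect_equal(call$n_pass_fst, 50L)
  expect_lte(sum(call$selected_b),
             min(call$n_pass_fst, sum(stats$log2_ratio >= call$cutoffs[["ratio_high"]])))
  expect_lte(sum(call$selected_a),
             min(call$n_pass_fst, sum(stats$log2_ratio <= call$cutoffs[["ratio_low"]])))
  # saturation: fst_level 0 and tail_level 0.5 select every window
  sat <- call_selected_windows(stats, fst_level = 0, tail_level = 0.5)
  expect_true(all(sat$selected_a | sat$selected_b))
  # too few informative windows is an error
  expect_error(call_selected_windows(stats[1:10, ]), "20")
})

test_that("scan is invariant to chromosome relabeling and sample order", {
  sim <- sweep_sim(seed = 91)
  ds <- sim$dataset
  ws <- suppressMessages(window_stats(ds, sim$popmap, "gA", "gB"))
  # relabel chromosome
  v2 <- ds$variants; v2$chrom <- "scaffold_9"
  ds2 <- genotype_dataset(v2, ds$samples, ds$calls,
                          contig_lengths = c(scaffold_9 = unname(ds$contig_lengths)))
  ws2 <- suppressMessages(window_stats(ds2, sim$popmap, "gA", "gB"))
  expect_equal(ws$fst, ws2$fst)
  expect_equal(ws$log2_ratio, ws2$log2_ratio)
  # permute sample order
  set.seed(1); ord <- sample(length(ds$samples))
  ds3 <- genotype_dataset(ds$variants, ds$samples[ord], ds$calls[ord, ],
                          contig_lengths = ds$contig_lengths)
  ws3 <- suppressMessages(window_stats(ds3, sim$popmap, "gA", "gB"))
  expect_equal(ws$fst, ws3$fst)
  expect_equal(ws$pi_a, ws3$pi_a)
})

test_that("gene overlap follows the half-open convention", {
  stats <- data.frame(chrom = "chr1", start = c(0, 10000), end = c(10000, 20000),
                      n_snps = 5L, fst = c(0.9, 0.1), pi_a = 0.01, pi_b = 0.001,
                      log2_ratio = c(3.3, 0), informative = TRUE)
  class(stats) <- c("window_stats", "data.frame")
  call <- list(selected_a = c(FALSE, FALSE), selected_b = c(TRUE, FALSE),
               windows = as.data.frame(stats))
  genes <- gene_set(data.frame(
    gene_id = c("contained", "partial", "adjacent"),
    chrom = "chr1",
    start = c(100, 9990, 10000),
    end = c(200, 10050, 10050)))
  ov <- overlap_genes(call, genes)
  expect_setequal(ov$b$gene_id, c("contained", "partial"))
  expect_false("adjacent" %in% ov$b$gene_id)
  expect_equal(nrow(ov$a), 0L)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # closed form: all 5 candidates in a 5-gene term of a 20-gene universe
  universe <- sprintf("g%02d", 1:20)
  term2gene <- data.frame(term = "T1", gene = universe[1:5])
  res <- enrich(universe[1:5], universe, term2gene)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(res$significant)

  # k = 0 -> p = 1; empty term skipped with warning
  res0 <- enrich(universe[6:10], universe, term2gene)
  expect_equal(res0$p, 1)
  expect_warning(
    enrich(universe[1:2], universe,
           data.frame(term = c("T1", "T2"), gene = c(universe[1], "absent"))),
    "skipped")
  expect_error(enrich(c("g01", "ghost"), universe, term2gene), "ghost")

  # exhaustive enumeration oracle on universes of <= 12 genes
  set.seed(33)
  for (i in 1:15) {
    N <- sample(5:12, 1)
    uni <- sprintf("u%02d", seq_len(N))
    K <- sample(1:N, 1)
    m <- sample(1:N, 1)
    t2g <- data.frame(term = "T", gene = sample(uni, K))
    cand <- sample(uni, m)
    k <- length(intersect(t2g$gene, cand))
    got <- enrich(cand, uni, t2g)
    expect_equal(got$overlap, k)
    expect_equal(got$p, hyper_tail_enum(k, K, N, m), tolerance = 1e-12)
  }
})

test_that("embedded sweeps are recovered in the correct direction", {
  # 3 sweep windows at s = 1 on group B: pi_B must be exactly 0 inside
  sw <- list(list(chrom = "chr1", start = 50000, end = 60000,
                  target = "gB", s = 1))
  sim <- sweep_sim(seed = 101, sweeps = sw)
  ws <- suppressMessages(window_stats(sim$dataset, sim$popmap, "gA", "gB"))
  hit <- ws$start == 50000
  expect_equal(ws$pi_b[hit], 0)
  expect_false(ws$informative[hit])   # zero diversity -> excluded

  # moderate intensity keeps the window informative and flags it jointly
  sw2 <- lapply(c(50000, 150000, 250000), function(s)
    list(chrom = "chr1", start = s, end = s + 10000, target = "gB", s = 0.9))
  sim2 <- sweep_sim(seed = 103, sweeps = sw2, n_snps = 1500, chrom_length = 3e5)
  ws2 <- suppressMessages(window_stats(sim2$dataset, sim2$popmap, "gA", "gB"))
  call <- call_selected_windows(ws2, fst_level = 0.9, tail_level = 0.1)
  sel_starts <- ws2$start[call$selected_b]
  expect_gte(length(intersect(sel_starts, c(50000, 150000, 250000))), 2)
})
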