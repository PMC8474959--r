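# End-to-end orchestration: filter -> diversity -> F_ST -> AMOVA -> PCA ->
# sweep contrasts -> optional enrichment, with TSV outputs and a
# machine-readable run manifest.

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with
#' entries: `vcf`, `popmap`, optional `genes` and `term2gene` paths;
#' `out_dir`; filter thresholds `maf_min` / `int_min`; `groupings` (list
#' of named group->populations lists for AMOVA; default: the popmap's own
#' grouping); `contrasts` (list of two-element group-label vectors for
#' the sweep scans); `window_size`, `fst_quantile`, `ratio_tail`,
#' `min_snps`, `n_perm`, `seed`, optional `surveyed_length`. Referenced
#' populations and groups are checked against the popmap before any
#' computation.
#'
#' @param config Named list or path to a YAML file.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(maf_min = 0.05, int_min = 0.5, window_size = 10000,
                   fst_quantile = 0.95, ratio_tail = 0.05, min_snps = 2,
                   n_perm = 10000, surveyed_length = NULL,
                   groupings = NULL, contrasts = list(), genes = NULL,
                   term2gene = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[nm] <- defaults[nm]
  for (req in c("vcf", "popmap", "out_dir", "seed"))
    if (is.null(config[[req]])) stopf("pipeline config is missing '%s'", req)
  if (!file.exists(config$vcf)) stopf("vcf not found: %s", config$vcf)
  if (!file.exists(config$popmap)) stopf("popmap not found: %s", config$popmap)
  pm <- read_popmap(config$popmap)
  pops <- unique(pm$population)
  groups <- unique(pm$group)
  if (!is.null(config$groupings)) {
    for (grp in config$groupings) {
      gpops <- unlist(grp, use.names = FALSE)
      bad <- setdiff(gpops, pops)
      if (length(bad))
        stopf("grouping references undefined population(s): %s",
              paste(bad, collapse = ", "))
    }
  }
  for (ct in config$contrasts) {
    if (length(ct) != 2) stopf("each contrast must name two groups")
    bad <- setdiff(unlist(ct), groups)
    if (length(bad))
      stopf("contrast references undefined group(s): %s",
            paste(bad, collapse = ", "))
  }
  class(config) <- c("pipeline_config", "list")
  config
}

write_tsv <- function(df, path, command = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(command)) writeLines(paste0("# ", command), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: site filtering, per-population diversity, pairwise F_ST, AMOVA
#' for each configured grouping, PCA, one sweep scan per contrast
#' (with gene overlap and optional enrichment when annotations are
#' supplied), each written as a TSV mirroring the standard summary-table
#' layouts, plus `manifest.json` recording package version, seed,
#' thresholds, realized cutoffs and input checksums. Outputs carry no
#' timestamps: identical config + seed reproduces byte-identical files.
#' Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config] (list or YAML path accepted).
#' @return Named list of stage results, invisibly; files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  ds_raw <- stage("read_vcf", read_vcf(cfg$vcf))
  pm <- stage("read_popmap", read_popmap(cfg$popmap))
  align_popmap(ds_raw, pm)

  ds <- stage("filter", filter_sites(ds_raw, cfg$maf_min, cfg$int_min))
  rep <- attr(ds, "filter_report")
  write_tsv(as.data.frame(rep), file.path(cfg$out_dir, "filter_report.tsv"),
            sprintf("filter_sites maf_min=%g int_min=%g", cfg$maf_min, cfg$int_min))
  results$filter_report <- rep

  div <- stage("diversity", population_summary(ds, pm,
                                               surveyed_length = cfg$surveyed_length))
  write_tsv(as.data.frame(div), file.path(cfg$out_dir, "diversity.tsv"),
            "population_summary")
  results$diversity <- div

  fst <- stage("fst", pairwise_fst(ds, pm))
  fst_df <- data.frame(population = rownames(fst),
                       round(unclass(fst), 6), check.names = FALSE)
  write_tsv(fst_df, file.path(cfg$out_dir, "fst.tsv"), "pairwise_fst")
  results$fst <- fst

  groupings <- cfg$groupings
  if (is.null(groupings)) {
    pg <- unique(as.data.frame(pm)[, c("population", "group")])
    groupings <- list(split(pg$population, pg$group))
  }
  results$amova <- list()
  for (i in seq_along(groupings)) {
    am <- stage(sprintf("amova_%d", i),
                amova(ds, pm, grouping = groupings[[i]],
                      n_perm = cfg$n_perm, seed = subseed(cfg$seed, "amova", i)))
    tab <- am$table
    lab <- paste(sprintf("[%s]", vapply(am$grouping, paste, "", collapse = "; ")),
                 collapse = " ")
    extra <- data.frame(stratum = names(am$phi), df = NA, SS = NA,
                        sigma2 = am$phi, pct_variation = am$p_value)
    names(extra) <- names(tab)
    write_tsv(rbind(tab, extra), file.path(cfg$out_dir, sprintf("amova_%d.tsv", i)),
              sprintf("amova grouping=%s n_perm=%d (phi rows: sigma2=Phi, pct=p-value)",
                      lab, cfg$n_perm))
    results$amova[[i]] <- am
  }

  pca <- stage("pca", genotype_pca(ds))
  coords <- data.frame(sample = rownames(pca$scores), pca$scores,
                       check.names = FALSE)
  write_tsv(coords, file.path(cfg$out_dir, "pca_coords.tsv"), "genotype_pca")
  write_tsv(data.frame(axis = colnames(pca$scores),
                       eigenvalue = pca$eigenvalues,
                       prop_var = pca$prop_var),
            file.path(cfg$out_dir, "pca_eigen.tsv"), "genotype_pca")
  results$pca <- pca

  genes <- if (!is.null(cfg$genes)) stage("genes", read_annotation(cfg$genes))
  t2g <- if (!is.null(cfg$term2gene)) stage("term2gene", read_term2gene(cfg$term2gene))
  results$sweeps <- list()
  for (ct in cfg$contrasts) {
    tag <- sprintf("%s_vs_%s", ct[[1]], ct[[2]])
    ws <- stage(paste0("sweep_", tag),
                window_stats(ds, pm, group_a = ct[[1]], group_b = ct[[2]],
                             window_size = cfg$window_size,
                             min_snps = cfg$min_snps))
    call <- stage(paste0("call_", tag),
                  call_selected_windows(ws, cfg$fst_quantile, cfg$ratio_tail))
    write_tsv(as.data.frame(ws),
              file.path(cfg$out_dir, sprintf("sweep_%s.windows.tsv", tag)),
              sprintf("window_stats %s window_size=%d", tag, cfg$window_size))
    sel <- as.data.frame(ws)[call$selected_a | call$selected_b, ]
    sel$direction <- ifelse(call$selected_a[call$selected_a | call$selected_b],
                            ct[[1]], ct[[2]])
    write_tsv(sel, file.path(cfg$out_dir, sprintf("sweep_%s.selected.tsv", tag)),
              sprintf("call_selected_windows fst_q=%g tail=%g cutoffs fst=%.6g lo=%.6g hi=%.6g",
                      cfg$fst_quantile, cfg$ratio_tail, call$cutoffs[["fst"]],
                      call$cutoffs[["ratio_low"]], call$cutoffs[["ratio_high"]]))
    out <- list(stats = ws, call = call)
    if (!is.null(genes)) {
      cand <- stage(paste0("genes_", tag), overlap_genes(call, genes))
      gdf <- rbind(if (nrow(cand$a)) cbind(direction = ct[[1]], cand$a),
                   if (nrow(cand$b)) cbind(direction = ct[[2]], cand$b))
      if (is.null(gdf))
        gdf <- data.frame(direction = character(), gene_id = character(),
                          chrom = character(), start = numeric(),
                          end = numeric(), windows = character())
      write_tsv(gdf, file.path(cfg$out_dir, sprintf("sweep_%s.genes.tsv", tag)),
                "overlap_genes")
      out$genes <- cand
      if (!is.null(t2g)) {
        cands <- unique(c(cand$a$gene_id, cand$b$gene_id))
        if (length(cands)) {
          en <- stage(paste0("enrich_", tag),
                      enrich(cands, genes$gene_id, t2g))
          write_tsv(as.data.frame(en),
                    file.path(cfg$out_dir, sprintf("sweep_%s.enrichment.tsv", tag)),
                    "enrich alpha=0.05")
          out$enrichment <- en
        }
      }
    }
    results$sweeps[[tag]] <- out
  }

  inputs <- c(vcf = cfg$vcf, popmap = cfg$popmap,
              genes = cfg$genes %||% NA, term2gene = cfg$term2gene %||% NA)
  inputs <- inputs[!is.na(inputs)]
  manifest <- list(
    package = "popsweep",
    version = as.character(utils::packageVersion("popsweep")),
    seed = cfg$seed,
    parameters = cfg[c("maf_min", "int_min", "window_size", "fst_quantile",
                       "ratio_tail", "min_snps", "n_perm")],
    contrasts = cfg$contrasts,
    input_md5 = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                        names(inputs))))
  con <- file(file.path(cfg$out_dir, "manifest.json"), "wb")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), con)
  close(con)
  invisible(results)
}
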