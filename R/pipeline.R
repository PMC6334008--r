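#' @include AllClasses.R
NULL

#' Assemble a pipeline configuration
#'
#' Either pass the settings directly or give \code{yaml_file}, whose keys
#' override the defaults.  The configuration round-trips losslessly through
#' \code{yaml::as.yaml}.
#'
#' @param yaml_file optional YAML file of settings.
#' @param cardiac_csvs named character vector (individual id -> CSV path) of
#'   cardiac traces or pre-windowed heart-rate series; the individual's line
#'   is taken from the prefix before the first underscore of its id.
#' @param counts_tsv,samples_tsv,annotation_tsv expression inputs (see
#'   \code{\link{readCounts}}); when \code{counts_tsv} is NULL a synthetic
#'   demonstration dataset is simulated.
#' @param sensitive,tolerant,control,heat design labels.
#' @param p_thr,lfc_thr DE filter thresholds.
#' @param alpha level for the line comparison letters.
#' @param min_seg,window_C,break_convention broken-stick settings.
#' @param n_simulated_individuals per line, used when no cardiac CSVs are
#'   given.
#' @param sim_n_genes genes in the simulated demonstration counts.
#' @param seed integer seed for all simulated inputs.
#' @return list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(yaml_file = NULL, cardiac_csvs = NULL,
                           counts_tsv = NULL, samples_tsv = NULL,
                           annotation_tsv = NULL,
                           sensitive = "sensitive", tolerant = "tolerant",
                           control = "control", heat = "heat",
                           p_thr = 0.05, lfc_thr = 1, alpha = 0.05,
                           min_seg = 4, window_C = 0.5,
                           break_convention = "intersection",
                           n_simulated_individuals = 8,
                           sim_n_genes = 2000, seed = 1L) {
  cfg <- list(cardiac_csvs = cardiac_csvs, counts_tsv = counts_tsv,
              samples_tsv = samples_tsv, annotation_tsv = annotation_tsv,
              sensitive = sensitive, tolerant = tolerant,
              control = control, heat = heat,
              p_thr = p_thr, lfc_thr = lfc_thr, alpha = alpha,
              min_seg = min_seg, window_C = window_C,
              break_convention = break_convention,
              n_simulated_individuals = n_simulated_individuals,
              sim_n_genes = sim_n_genes, seed = as.integer(seed))
  if (!is.null(yaml_file)) {
    user <- yaml::read_yaml(yaml_file)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("unknown configuration keys: ", paste(bad, collapse = ", "))
    cfg[names(user)] <- user
    cfg$seed <- as.integer(cfg$seed)
  }
  stopifnot(cfg$p_thr > 0, cfg$p_thr < 1, cfg$lfc_thr >= 0,
            cfg$alpha > 0, cfg$alpha < 1, cfg$min_seg >= 2,
            cfg$window_C > 0,
            cfg$break_convention %in% c("intersection", "split_midpoint"))
  structure(cfg, class = c("pipelineConfig", "list"))
}

#' Run the full heat-tolerance analysis pipeline
#'
#' Stages: (1) per-individual ABT estimation from cardiac inputs (or a
#' simulated two-line cohort); (2) line comparison with ANOVA, Duncan's test
#' and letters; (3) differential expression with the four line-by-condition
#' contrasts and the Venn partition of the two within-line heat responses;
#' (4) enrichment of the contrast-III DEGs (Wallenius with PWF weights when
#' gene lengths and categories are available).  All tables are written as
#' TSV plus a machine-readable JSON manifest; outputs are deterministic for
#' a fixed configuration and seed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
runPipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  ## -- stage 1: cardiac ------------------------------------------------------
  if (is.null(config$cardiac_csvs)) {
    lines_abt <- setNames(c(28.5, 31.9), c(config$sensitive, config$tolerant))
    ids <- unlist(lapply(names(lines_abt), function(ln)
      sprintf("%s_%02d", ln, seq_len(config$n_simulated_individuals))))
    series <- lapply(seq_along(ids), function(i) {
      ln <- sub("_.*", "", ids[i])
      simulateHeartRateSeries(cardiacSimParams(
        abt_true = lines_abt[[ln]],
        hr_at_20C = if (ln == config$sensitive) 30 else 34,
        seed = config$seed + i))
    })
    names(series) <- ids
  } else {
    series <- lapply(config$cardiac_csvs, function(p) {
      obj <- readCardiacCSV(p)
      if (is(obj, "CardiacTrace")) {
        beats <- detectBeats(obj)
        heartRateByTemperature(beats, obj, window_C = config$window_C)
      } else obj
    })
    ids <- names(config$cardiac_csvs)
    if (is.null(ids)) ids <- paste0("ind_", seq_along(series))
    names(series) <- ids
  }
  abt_tab <- do.call(rbind, lapply(names(series), function(id) {
    fit <- estimateABT(series[[id]], min_seg = config$min_seg,
                       convention = config$break_convention)
    mx <- maxHeartRate(series[[id]])
    data.frame(individual = id, line = sub("_.*", "", id),
               abt_C = round(fit@abt_C, 3),
               max_hr_bpm = round(mx$hr_bpm, 2),
               max_hr_temp_C = round(mx$temp_C, 2),
               rss = signif(fit@rss_total, 6),
               no_distinct_break = fit@no_distinct_break)
  }))
  wtsv(abt_tab, "abt_individuals.tsv")
  ## -- stage 2: line comparison ---------------------------------------------
  line_summary <- summarizeLines(abt_tab$abt_C, abt_tab$line,
                                 alpha = config$alpha)
  aov_res <- oneWayAnova(abt_tab$abt_C, abt_tab$line)
  line_summary$mean <- round(line_summary$mean, 3)
  line_summary$sd <- round(line_summary$sd, 3)
  wtsv(line_summary, "line_summary.tsv")
  ## -- stage 3: differential expression -------------------------------------
  if (is.null(config$counts_tsv)) {
    ce <- simulateCounts(countSimParams(
      n_genes = config$sim_n_genes,
      design = data.frame(
        line = rep(c(config$sensitive, config$tolerant), each = 2),
        condition = rep(c(config$control, config$heat), 2),
        n_replicates = 3L),
      seed = config$seed + 1000L))
  } else {
    ce <- readCounts(config$counts_tsv, config$samples_tsv,
                     config$annotation_tsv)
  }
  contrasts <- runContrasts(ce, sensitive = config$sensitive,
                            tolerant = config$tolerant,
                            control = config$control, heat = config$heat,
                            p_thr = config$p_thr, lfc_thr = config$lfc_thr)
  for (nm in names(contrasts)) {
    tb <- resultsTable(contrasts[[nm]])
    tb$base_mean_A <- round(tb$base_mean_A, 3)
    tb$base_mean_B <- round(tb$base_mean_B, 3)
    tb$log2_fc <- round(tb$log2_fc, 4)
    tb$p_value <- signif(tb$p_value, 6)
    tb$padj <- signif(tb$padj, 6)
    wtsv(tb, paste0("contrast_", nm, ".tsv"))
  }
  venn <- vennPartition(contrasts$III, contrasts$IV)
  venn_tab <- data.frame(
    partition = c("common", paste0("only_", venn$labels[1]),
                  paste0("only_", venn$labels[2]), "discordant"),
    n = c(length(venn$common), length(venn$only_A), length(venn$only_B),
          length(venn$discordant)))
  wtsv(venn_tab, "venn_partition.tsv")
  wtsv(venn$counts, "venn_updown.tsv")
  ## -- stage 4: enrichment ----------------------------------------------------
  enr <- NULL
  ann <- NULL
  if (!is.null(config$annotation_tsv)) {
    ann <- utils::read.delim(config$annotation_tsv)
    tb3 <- resultsTable(contrasts$III)
    if (all(c("gene_id", "length_bp", "category") %in% names(ann))) {
      m <- match(tb3$gene_id, ann$gene_id)
      lens <- ann$length_bp[m]
      de <- setNames(tb3$de_flag, tb3$gene_id)
      w <- fitPWF(de, lens)
      cats <- split(ann$gene_id, ann$category)
      enr <- walleniusEnrichment(names(de)[de], cats, w)
      wtsv(enr, "go_enrichment.tsv")
      hyp <- hypergeomEnrichment(names(de)[de], cats, names(de))
      wtsv(hyp, "kegg_enrichment.tsv")
    }
  }
  ## -- fixture reproduction ----------------------------------------------------
  fx <- fixtureReport()
  wtsv(fx$hsp_table, "hsp_family_summary.tsv")
  wtsv(fx$pathway_counts, "cellcycle_downregulation.tsv")
  ## -- manifest ---------------------------------------------------------------
  manifest <- list(
    package = "abtseq",
    version = as.character(utils::packageVersion("abtseq")),
    seed = config$seed,
    thresholds = list(p_thr = config$p_thr, lfc_thr = config$lfc_thr,
                      alpha = config$alpha, min_seg = config$min_seg,
                      window_C = config$window_C,
                      break_convention = config$break_convention),
    n_individuals = nrow(abt_tab),
    n_genes = nrow(ce),
    anova = list(f = aov_res$f_stat, p = aov_res$p_value),
    deg_counts = lapply(contrasts, function(r) sum(resultsTable(r)$de_flag)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(list(abt = abt_tab, line_summary = line_summary,
                 anova = aov_res, contrasts = contrasts, venn = venn,
                 enrichment = enr, manifest = manifest))
}

#' Reproduce the packaged fixture summaries
#'
#' Recomputes, from the packaged tables alone, the HSP family partition and
#' per-line average fold change and the per-line counts of down-regulated
#' cell cycle pathway genes.
#'
#' @return list with \code{hsp} (familySummary), \code{hsp_table},
#'   \code{pathway_counts} (data.frame) and \code{fc_check} (max absolute
#'   deviation of recomputed 1-dp log2 fold changes from the printed ones).
#' @export
fixtureReport <- function() {
  t1 <- loadFixture("table1")
  t2 <- loadFixture("table2")
  fc1 <- fixtureContrasts(t1)
  fc2 <- fixtureContrasts(t2)
  fam <- familySummary(fc1$sensitive, fc1$tolerant, fc1$families, "HSP")
  cc <- pathwayUpDownCounts(fc2$sensitive, fc2$tolerant, fc2$pathways,
                            "Cell cycle", "down")
  dev <- c(
    abs(round(log2FoldChange(t1$readcount_control_RL, t1$readcount_heat_RL),
              1) - t1$log2fc_RL),
    abs(round(log2FoldChange(t1$readcount_control_YL, t1$readcount_heat_YL),
              1) - t1$log2fc_YL))
  list(hsp = fam,
       hsp_table = fam$table,
       pathway_counts = data.frame(line = c("sensitive_RL", "tolerant_YL"),
                                   pathway = "Cell cycle",
                                   n_down = as.integer(cc)),
       fc_check = max(dev, na.rm = TRUE))
}
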