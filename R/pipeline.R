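#' Default pipeline configuration
#'
#' All tunable thresholds in one place: minimal bisulfite conversion rate
#' 0.97 (inclusive), coverage-filter CV 5% / SD 1%, significance p 0.05,
#' per-site Fisher FWER 5%, network FWER 10%. The simulate block holds the
#' synthetic cohort design (24 controls + 48 patients in three severity
#' strata, two tissues, technical duplicates) and truth-model parameters.
#'
#' @param out_dir Output directory.
#' @param seed Master RNG seed.
#' @return Nested configuration list (serializable as YAML).
#' @export
default_config <- function(out_dir = "methpanel_run", seed = 1) {
  list(
    seed = seed,
    out_dir = out_dir,
    paths = list(panel_fasta = NULL, panel_tsv = NULL,
                 reads = NULL, sample_sheet = NULL),
    simulate = list(
      enabled = TRUE,
      design = list(n_control = 24, n_mild = 23, n_intermediary = 13,
                    n_severe = 12, nec_missing_patients = 9,
                    duplicate_patients = 4, b_allele_freq = 0.3),
      truth = list(concentration = 50, gene_sd = 0.4, epsilon = 0.01,
                   seq_error = 0.002, depth_range = c(9, 2704),
                   dosage_gene = "GSTM3", dosage_slope = -0.7),
      group_effects = NULL,
      write_read_truth = FALSE
    ),
    thresholds = list(min_conversion = 0.97, cv = 0.05, sd = 0.01,
                      p = 0.05, fwer_sites = 0.05, fwer_network = 0.10,
                      max_mismatch_frac = 0.1),
    pls = list(ncomp = 2, cv = "loo", missing = "impute",
               sign_mapping = "coding"),
    stages = list(simulate = TRUE, call = TRUE, stats = TRUE,
                  plsda = TRUE, report = TRUE)
  )
}

#' Bundled fast demonstration configuration
#'
#' A scaled-down cohort (8 controls, 12 patients, capped read depth) so the
#' complete chain runs in minutes while exercising every stage, with one
#' planted differential gene so the report has content.
#'
#' @inheritParams default_config
#' @return Configuration list.
#' @export
demo_config <- function(out_dir = "methpanel_demo", seed = 1) {
  cfg <- default_config(out_dir, seed)
  cfg$simulate$design <- list(n_control = 8, n_mild = 5, n_intermediary = 4,
                              n_severe = 3, nec_missing_patients = 2,
                              duplicate_patients = 2, b_allele_freq = 0.3)
  cfg$simulate$truth$depth_range <- c(100, 800)
  cfg$simulate$group_effects <- data.frame(
    gene = "HMOX1", site = NA_integer_, offset = 1.5, shape = "case")
  cfg
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  ge <- config$simulate$group_effects
  if (!is.null(ge) && !is.data.frame(ge))
    config$simulate$group_effects <- as.data.frame(ge)
  config
}

pipeline_panel <- function(config) {
  if (!is.null(config$paths$panel_fasta))
    read_panel(config$paths$panel_fasta, config$paths$panel_tsv)
  else cf_panel()
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> call -> stats (group comparisons,
#' per-CpG Fisher, repeatability, networks, genotype association) ->
#' PLS-DA -> report, writing each stage's artifacts and a manifest with
#' versions, seed, input hashes and per-stage record counts into the
#' output directory. A rerun with the same config and seed is
#' byte-identical for the deterministic stages.
#'
#' @param config Configuration list (see [default_config()]) or the path
#'   of a YAML file holding one.
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- load_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(config$out_dir, "config.yaml"))
  manifest <- list(package = as.character(utils::packageVersion("methpanel")),
                   r_version = R.version.string, seed = config$seed,
                   stages = list())
  panel <- pipeline_panel(config)

  if (isTRUE(config$stages$simulate) && isTRUE(config$simulate$enabled)) {
    n <- stage_simulate(config, panel)
    manifest$stages$simulate <- n
  }
  if (isTRUE(config$stages$call)) {
    manifest$stages$call <- stage_call(config, panel)
  }
  if (isTRUE(config$stages$stats)) {
    manifest$stages$stats <- stage_stats(config, panel)
  }
  if (isTRUE(config$stages$plsda)) {
    manifest$stages$plsda <- stage_plsda(config)
  }
  inputs <- c(reads = pipeline_path(config, "reads", "reads.fastq"),
              sample_sheet = pipeline_path(config, "sample_sheet",
                                           "sample_sheet.tsv"))
  manifest$input_md5 <- as.list(tools::md5sum(inputs[file.exists(inputs)]))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (isTRUE(config$stages$report)) make_report(config$out_dir)
  invisible(config$out_dir)
}

pipeline_path <- function(config, key, default) {
  config$paths[[key]] %||% file.path(config$out_dir, default)
}

stage_simulate <- function(config, panel) {
  sc <- config$simulate
  design <- do.call(cohort_design, c(sc$design, list(seed = config$seed)))
  truth <- do.call(truth_model,
                   c(list(panel = panel, group_effects = sc$group_effects),
                     sc$truth))
  probs <- simulate_sample_methylation(design, truth, seed = config$seed)
  sim <- simulate_reads(probs, design, truth, seed = config$seed)
  write_fastq(sim, file.path(config$out_dir, "reads.fastq"))
  write_sample_sheet(design, file.path(config$out_dir, "sample_sheet.tsv"))
  write_tsv(probs, file.path(config$out_dir, "truth_probs.tsv"))
  if (isTRUE(sc$write_read_truth))
    write_tsv(sim$reads[, setdiff(names(sim$reads), "sequence")],
              file.path(config$out_dir, "truth_reads.tsv"))
  if (!is.null(sc$group_effects))
    write_tsv(sc$group_effects,
              file.path(config$out_dir, "truth_effects.tsv"))
  list(n_reads = nrow(sim$reads), n_libraries = nrow(design$libraries))
}

stage_call <- function(config, panel) {
  th <- config$thresholds
  reads <- pipeline_path(config, "reads", "reads.fastq")
  sheet <- read_tsv(pipeline_path(config, "sample_sheet", "sample_sheet.tsv"))
  mm <- call_methylation(reads, panel, sheet,
                         min_conversion = th$min_conversion,
                         max_mismatch_frac = th$max_mismatch_frac)
  write_tsv(mm$site, file.path(config$out_dir, "methylation_site.tsv"))
  write_tsv(mm$region, file.path(config$out_dir, "methylation_region.tsv"))
  write_tsv(mm$reads[, c("read_id", "library_id", "gene", "strand",
                         "orientation", "conversion_rate",
                         "pass_conversion", "calls")],
            file.path(config$out_dir, "read_calls.tsv"))
  write_tsv(mm$log, file.path(config$out_dir, "filter_log.tsv"))
  as.list(mm$log)
}

stage_stats <- function(config, panel) {
  th <- config$thresholds
  region <- read_tsv(file.path(config$out_dir, "methylation_region.tsv"))
  site <- read_tsv(file.path(config$out_dir, "methylation_site.tsv"))
  out <- analyze_methylation(region, site,
                             p_threshold = th$p,
                             fwer_sites = th$fwer_sites,
                             fwer_network = th$fwer_network)
  write_tsv(out$comparisons, file.path(config$out_dir,
                                       "region_comparisons.tsv"))
  write_tsv(out$per_cpg, file.path(config$out_dir, "per_cpg_fisher.tsv"))
  for (s in names(out$networks))
    write_tsv(out$networks[[s]]$edges,
              file.path(config$out_dir, paste0("network_edges_", s, ".tsv")))
  write_tsv(out$repeatability, file.path(config$out_dir, "repeatability.tsv"))
  write_tsv(out$genotype, file.path(config$out_dir,
                                    "genotype_association.tsv"))
  list(n_comparisons = nrow(out$comparisons),
       n_sites_tested = nrow(out$per_cpg),
       n_significant_sites = sum(out$per_cpg$significant))
}

#' Region- and site-level statistical analysis of a methylation matrix
#'
#' The statistics stage as a plain function: logit-scale group comparisons
#' (CF vs control, and the four severity strata) with data-driven test
#' selection per gene x tissue; per-CpG Fisher exact tests on pooled read
#' counts with per-tissue Bonferroni families; technical-duplicate
#' repeatability; control and CF co-methylation networks; genotype-dosage
#' association for the dosage gene in each tissue.
#'
#' @param region Region-level table (from [call_methylation()] or
#'   [simulate_counts()] aggregated): needs sample_id, tissue, gene,
#'   replicate, group, mean_methylation, n_reads, retained.
#' @param site Site-level counts: sample_id, tissue, gene, site, meth,
#'   total, plus group.
#' @param p_threshold,fwer_sites,fwer_network Significance thresholds.
#' @param dosage_column Column of `region` holding allele dosages.
#' @param dosage_gene Gene tested for genotype association.
#' @return list: `comparisons`, `per_cpg`, `repeatability`, `networks`
#'   (per stratum), `genotype`.
#' @export
analyze_methylation <- function(region, site, p_threshold = 0.05,
                                fwer_sites = 0.05, fwer_network = 0.10,
                                dosage_column = "dosage",
                                dosage_gene = "GSTM3") {
  region <- region[region$retained & !is.na(region$mean_methylation), ]
  region$logit <- as.numeric(logit_transform(region$mean_methylation,
                                             n = region$n_reads))
  region$cf <- ifelse(region$group == "control", "control", "CF")

  # repeatability from technical duplicates
  rep1 <- region[region$replicate == 1, ]
  rep2 <- region[region$replicate == 2, ]
  key1 <- paste(rep1$sample_id, rep1$tissue, rep1$gene)
  key2 <- paste(rep2$sample_id, rep2$tissue, rep2$gene)
  reptab <- if (nrow(rep2)) {
    i <- match(key2, key1)
    est <- tryCatch(estimate_repeatability(rep1$logit[i], rep2$logit),
                    error = function(e) NULL)
    if (is.null(est)) data.frame(sd = NA_real_, df = 0L, n_missing = NA_integer_)
    else data.frame(sd = est$sd, df = est$df, n_missing = est$n_missing)
  } else data.frame(sd = NA_real_, df = 0L, n_missing = NA_integer_)

  # group comparisons per gene x tissue, duplicates collapsed to replicate 1
  r1 <- region[region$replicate == 1, ]
  comp <- list()
  for (t in unique(r1$tissue)) for (g in unique(r1$gene)) {
    d <- r1[r1$tissue == t & r1$gene == g, ]
    for (strat in c("cf", "group")) {
      gc <- tryCatch(compare_groups(d$logit, d[[strat]]),
                     error = function(e) NULL)
      comp[[paste(t, g, strat)]] <- data.frame(
        tissue = t, gene = g,
        comparison = if (strat == "cf") "CF_vs_control" else "severity",
        test = if (is.null(gc)) NA_character_ else gc$test,
        statistic = if (is.null(gc)) NA_real_ else gc$statistic,
        p = if (is.null(gc)) NA_real_ else gc$p.value,
        significant = if (is.null(gc)) NA else gc$p.value < p_threshold,
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- do.call(rbind, c(comp, make.row.names = FALSE))

  # per-CpG Fisher on pooled read counts, per-tissue families
  site$cf <- ifelse(site$group == "control", "control", "CF")
  percpg <- list()
  for (t in unique(site$tissue)) {
    d <- site[site$tissue == t & site$total > 0, ]
    if (!nrow(d)) next
    key <- paste(d$gene, d$site)
    mc <- tapply(d$meth[d$cf == "CF"], key[d$cf == "CF"], sum)
    tc <- tapply(d$total[d$cf == "CF"], key[d$cf == "CF"], sum)
    mk <- tapply(d$meth[d$cf == "control"], key[d$cf == "control"], sum)
    tk <- tapply(d$total[d$cf == "control"], key[d$cf == "control"], sum)
    ids <- sort(unique(key))
    f <- per_cpg_fisher(
      meth_case = ifelse(is.na(mc[ids]), 0, mc[ids]),
      total_case = ifelse(is.na(tc[ids]), 0, tc[ids]),
      meth_control = ifelse(is.na(mk[ids]), 0, mk[ids]),
      total_control = ifelse(is.na(tk[ids]), 0, tk[ids]),
      ids = ids, fwer = fwer_sites)
    f$tissue <- t
    f$gene <- sub(" .*$", "", f$id)
    f$site <- as.integer(sub("^.* ", "", f$id))
    percpg[[t]] <- f[, c("tissue", "gene", "site", "p", "q", "direction",
                         "significant", "degenerate")]
  }
  per_cpg <- do.call(rbind, c(percpg, make.row.names = FALSE))
  per_cpg <- per_cpg[order(per_cpg$tissue, per_cpg$gene, per_cpg$site), ]
  rownames(per_cpg) <- NULL

  # co-methylation networks per stratum
  networks <- list()
  for (s in c("control", "CF")) {
    d <- r1[r1$cf == s, ]
    mat <- region_matrix(d)
    networks[[s]] <- if (ncol(mat) >= 2)
      comethylation_network(mat, fwer = fwer_network) else NULL
  }

  # genotype association per tissue
  geno <- list()
  if (dosage_column %in% names(r1)) {
    for (t in unique(r1$tissue)) {
      d <- r1[r1$tissue == t & r1$gene == dosage_gene, ]
      ga <- tryCatch(genotype_association(d$mean_methylation,
                                          d[[dosage_column]]),
                     error = function(e) list(r = NA_real_, p = NA_real_,
                                              n = nrow(d),
                                              monomorphic = NA))
      geno[[t]] <- data.frame(tissue = t, gene = dosage_gene, r = ga$r,
                              p = ga$p, n = ga$n,
                              monomorphic = ga$monomorphic,
                              stringsAsFactors = FALSE)
    }
  }
  genotype <- if (length(geno)) do.call(rbind, c(geno, make.row.names = FALSE))
              else data.frame()

  list(comparisons = comparisons, per_cpg = per_cpg,
       repeatability = reptab, networks = networks, genotype = genotype)
}

stage_plsda <- function(config) {
  region <- read_tsv(file.path(config$out_dir, "methylation_region.tsv"))
  region <- region[region$replicate == 1, ]
  mat <- region_matrix(region)
  sheet <- read_tsv(pipeline_path(config, "sample_sheet",
                                  "sample_sheet.tsv"))
  lab <- sheet[!duplicated(sheet$sample_id),
               c("sample_id", "group")]
  y <- ifelse(lab$group[match(rownames(mat), lab$sample_id)] == "control",
              "control", "CF")
  res <- evaluate_descriptor_sets(mat, y, ncomp = config$pls$ncomp,
                                  positive_class = "CF")
  write_tsv(res, file.path(config$out_dir, "pls_summary.tsv"))
  reports <- attr(res, "reports")
  both <- reports$both$samples
  write_tsv(both, file.path(config$out_dir, "pls_scores.tsv"))
  jsonlite::write_json(
    setNames(as.list(res$percent_correct_loo), res$set),
    file.path(config$out_dir, "pls_summary.json"),
    auto_unbox = TRUE, digits = NA)
  list(percent_correct_loo = setNames(as.list(res$percent_correct_loo),
                                      res$set))
}

#' Assemble the run report
#'
#' Bundles the differential-CpG listing (gene, site, tissue, +/-
#' direction), the network edge lists per stratum, the per-descriptor-set
#' classification accuracy, and the repeatability estimate into
#' `report.json` and `differential_sites.tsv` in the run directory.
#' Regenerating the report from the same run is byte-identical.
#'
#' @param out_dir A completed run directory.
#' @return Invisibly, the report as a list.
#' @export
make_report <- function(out_dir) {
  need <- c("per_cpg_fisher.tsv", "repeatability.tsv", "pls_summary.tsv")
  absent <- need[!file.exists(file.path(out_dir, need))]
  if (length(absent))
    stop("missing stage outputs: ", paste(absent, collapse = ", "))
  per_cpg <- read_tsv(file.path(out_dir, "per_cpg_fisher.tsv"))
  diff <- per_cpg[per_cpg$significant %in% TRUE,
                  c("gene", "site", "tissue", "direction", "p", "q")]
  write_tsv(diff, file.path(out_dir, "differential_sites.tsv"))
  reptab <- read_tsv(file.path(out_dir, "repeatability.tsv"))
  pls <- read_tsv(file.path(out_dir, "pls_summary.tsv"))
  nets <- list()
  for (s in c("control", "CF")) {
    f <- file.path(out_dir, paste0("network_edges_", s, ".tsv"))
    if (file.exists(f)) {
      e <- read_tsv(f)
      nets[[s]] <- e[e$significant %in% TRUE, , drop = FALSE]
    }
  }
  report <- list(
    differential_sites = diff,
    n_differential = nrow(diff),
    network_edges = nets,
    classification = setNames(as.list(pls$percent_correct_loo), pls$set),
    repeatability = as.list(reptab[1, ]))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
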