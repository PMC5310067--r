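#' Cohort design for the synthetic study
#'
#' Emulates a two-tissue case/control methylation study: nasal epithelial
#' cells (NEC) and blood from healthy controls and cystic fibrosis patients
#' stratified by lung-disease severity. Defaults reproduce the study design
#' the package targets: 24 controls and 48 patients (23 mild, 13
#' intermediary, 12 severe), blood collected from everyone, NEC missing for
#' 9 patients, and technical duplicate libraries in both tissues for 4
#' patients.
#'
#' @param n_control,n_mild,n_intermediary,n_severe Group sizes.
#' @param nec_missing_patients Number of patients without an NEC library.
#' @param duplicate_patients Number of patients whose measurements are
#'   duplicated (replicate libraries in both tissues).
#' @param b_allele_freq Population frequency of the minor allele at the
#'   genotyped locus; per-sample dosages in 0/1/2 are drawn binomially.
#' @param seed RNG seed; all downstream stages derive their streams from it.
#' @return A `cohort_design`: list with `samples` (sample_id, group,
#'   severity 0-3, dosage) and `libraries` (library_id, barcode, sample_id,
#'   group, severity, tissue, replicate, dosage). Severity is an ordinal
#'   covariate (0 = control ... 3 = severe) so monotone and non-monotone
#'   effect shapes can both be planted.
#' @export
cohort_design <- function(n_control = 24, n_mild = 23, n_intermediary = 13,
                          n_severe = 12, nec_missing_patients = 9,
                          duplicate_patients = 4, b_allele_freq = 0.3,
                          seed = 1) {
  stopifnot(n_control >= 0, n_mild >= 0, n_intermediary >= 0, n_severe >= 0)
  set.seed(split_seed(seed, 1L))
  groups <- rep(c("control", "mild", "intermediary", "severe"),
                c(n_control, n_mild, n_intermediary, n_severe))
  n <- length(groups)
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = groups,
    severity = match(groups, c("control", "mild", "intermediary", "severe")) - 1L,
    dosage = rbinom(n, 2, b_allele_freq),
    stringsAsFactors = FALSE
  )
  patients <- samples$sample_id[samples$group != "control"]
  nec_missing <- if (nec_missing_patients > 0)
    sample(patients, min(nec_missing_patients, length(patients))) else character(0)
  nec_samples <- setdiff(samples$sample_id, nec_missing)
  dup_pool <- setdiff(patients, nec_missing)
  dup <- if (duplicate_patients > 0)
    sample(dup_pool, min(duplicate_patients, length(dup_pool))) else character(0)

  lib <- rbind(
    data.frame(sample_id = samples$sample_id, tissue = "blood", replicate = 1L),
    data.frame(sample_id = nec_samples, tissue = "NEC", replicate = 1L),
    if (length(dup)) data.frame(sample_id = rep(dup, 2),
                                tissue = rep(c("blood", "NEC"), each = length(dup)),
                                replicate = 2L)
  )
  lib <- merge(lib, samples, by = "sample_id", sort = FALSE)
  lib <- lib[order(lib$tissue, lib$sample_id, lib$replicate), ]
  lib$library_id <- sprintf("L%03d", seq_len(nrow(lib)))
  lib$barcode <- make_barcodes(nrow(lib))
  rownames(lib) <- NULL
  structure(list(samples = samples,
                 libraries = lib[, c("library_id", "barcode", "sample_id",
                                     "group", "severity", "tissue",
                                     "replicate", "dosage")],
                 seed = seed),
            class = "cohort_design")
}

# distinct fixed-length multiplex identifiers (MIDs)
make_barcodes <- function(n, width = 8) {
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n * 2), function(i)
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = ""), character(1))
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Default per-gene baseline methylation of the synthetic cohort
#'
#' Gene-level methylation fractions per tissue: one near-fully methylated
#' gene (MUC5AC, ~95% blood / ~83% NEC), one intermediate (TLR5, ~38% /
#' ~26%), the rest below 20% in both tissues.
#'
#' @return data.frame `gene`, `blood`, `NEC`.
#' @export
default_baselines <- function() {
  rbind(
    data.frame(gene = "MUC5AC", blood = 0.95, NEC = 0.83),
    data.frame(gene = "TLR5", blood = 0.38, NEC = 0.26),
    data.frame(gene = c("ATF1", "CFTR", "DUOX2", "EDNRA", "SCNN1G", "GSTM1",
                        "GSTM3", "HMOX1", "IFRD1", "TGFB1", "TLR2", "YY1"),
               blood = c(0.03, 0.05, 0.08, 0.04, 0.06, 0.07,
                         0.12, 0.10, 0.05, 0.07, 0.04, 0.03),
               NEC = c(0.04, 0.06, 0.07, 0.05, 0.05, 0.08,
                       0.10, 0.09, 0.04, 0.06, 0.03, 0.03))
  )
}

#' Truth model for the synthetic cohort
#'
#' Describes the data-generating process: per-gene per-tissue baseline
#' methylation, beta-distributed between-sample variation, planted group
#' effects on the logit scale, a genotype-dosage slope, latent factors
#' creating inter-tissue correlation and co-methylation modules, bisulfite
#' conversion failure, sequencing error, and a log-uniform read-depth
#' distribution.
#'
#' @param panel An `amplicon_panel` (defines genes and CpG sites).
#' @param baselines data.frame `gene`, `blood`, `NEC` baseline fractions;
#'   defaults emulate the targeted panel's reported ranges.
#' @param concentration Beta concentration of between-sample site-level
#'   variation (`Inf` = none).
#' @param gene_sd SD (logit scale) of a per-(sample, tissue, gene) random
#'   effect shared by all sites of the gene.
#' @param epsilon Bisulfite conversion failure rate: probability an
#'   unmethylated cytosine reads C.
#' @param seq_error Per-base substitution error rate.
#' @param depth_range Reads per library x amplicon, log-uniform bounds.
#' @param group_effects data.frame `gene`, `site` (NA = all sites),
#'   `offset` (logit), `shape` ("case": all patients; "ordinal": offset
#'   scaled by severity/3). Planted effects are returned in truth tables.
#' @param dosage_gene,dosage_slope Gene whose methylation responds to
#'   genotype dosage, and the logit slope per allele.
#' @param intertissue data.frame `gene`, `loading`: per-sample latent
#'   factor shared across tissues (inter-tissue co-methylation).
#' @param modules data.frame `module`, `gene`, `loading`, `stratum`
#'   ("CF", "control" or "all") and optionally `tissue`: latent factors
#'   creating co-methylation modules restricted to a stratum (and tissue).
#' @return A `truth_model` list.
#' @export
truth_model <- function(panel,
                        baselines = default_baselines(),
                        concentration = 50,
                        gene_sd = 0.4,
                        epsilon = 0.01,
                        seq_error = 0.002,
                        depth_range = c(9, 2704),
                        group_effects = NULL,
                        dosage_gene = "GSTM3",
                        dosage_slope = -0.7,
                        intertissue = data.frame(gene = "GSTM3", loading = 1.0),
                        modules = NULL) {
  stopifnot(inherits(panel, "amplicon_panel"),
            concentration > 0, gene_sd >= 0,
            epsilon >= 0, epsilon <= 1, seq_error >= 0, seq_error < 1,
            depth_range[1] >= 0, depth_range[2] >= depth_range[1])
  base <- baselines[baselines$gene %in% panel$gene, ]
  missing <- setdiff(panel$gene, base$gene)
  if (length(missing)) {
    base <- rbind(base, data.frame(gene = missing, blood = 0.05, NEC = 0.05))
  }
  stopifnot(all(base$blood >= 0 & base$blood <= 1),
            all(base$NEC >= 0 & base$NEC <= 1))
  structure(list(panel = panel, baselines = base,
                 concentration = concentration, gene_sd = gene_sd,
                 epsilon = epsilon, seq_error = seq_error,
                 depth_range = depth_range,
                 group_effects = group_effects,
                 dosage_gene = dosage_gene, dosage_slope = dosage_slope,
                 intertissue = intertissue, modules = modules),
            class = "truth_model")
}

planted_offset <- function(truth, gene, site, severity) {
  ge <- truth$group_effects
  if (is.null(ge) || nrow(ge) == 0) return(numeric(length(severity)))
  off <- numeric(length(severity))
  rows <- which(ge$gene == gene & (is.na(ge$site) | ge$site == site))
  for (r in rows) {
    scale <- if (identical(ge$shape[r], "ordinal")) severity / 3
             else as.numeric(severity > 0)
    off <- off + ge$offset[r] * scale
  }
  off
}

#' Simulate per-sample per-CpG methylation probabilities
#'
#' For each biological sample, tissue, gene and CpG site, draws the latent
#' methylation probability p from a beta distribution whose logit-scale mean
#' combines the gene/tissue baseline, planted group offsets, the genotype
#' dosage slope, and latent-factor terms. Technical duplicate libraries
#' share the biological sample's p.
#'
#' @param design A `cohort_design`.
#' @param truth A `truth_model`.
#' @param seed RNG seed (defaults to the design's).
#' @return data.frame `sample_id`, `tissue`, `gene`, `site`, `p` (the truth
#'   table for recovery tests).
#' @export
simulate_sample_methylation <- function(design, truth, seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"), inherits(truth, "truth_model"))
  set.seed(split_seed(seed, 2L))
  panel <- truth$panel
  samples <- design$samples
  ncpg <- panel$declared_n_cpg
  names(ncpg) <- panel$gene
  tissues <- c("blood", "NEC")

  # latent factors per sample
  it <- truth$intertissue
  u_it <- if (!is.null(it) && nrow(it))
    matrix(rnorm(nrow(samples) * nrow(it)), nrow(samples),
           dimnames = list(samples$sample_id, it$gene)) else NULL
  mods <- truth$modules
  u_mod <- if (!is.null(mods) && nrow(mods)) {
    ids <- unique(mods$module)
    matrix(rnorm(nrow(samples) * length(ids)), nrow(samples),
           dimnames = list(samples$sample_id, ids))
  } else NULL

  out <- vector("list", length(tissues) * nrow(panel))
  k <- 0
  for (t in tissues) {
    for (g in panel$gene) {
      k <- k + 1
      ns <- ncpg[[g]]
      base <- truth$baselines[truth$baselines$gene == g, t]
      eta0 <- qlogis(min(max(base, 1e-6), 1 - 1e-6))
      # per-sample gene-level pieces
      eta_s <- rep(eta0, nrow(samples))
      if (g == truth$dosage_gene)
        eta_s <- eta_s + truth$dosage_slope * samples$dosage
      if (!is.null(u_it) && g %in% colnames(u_it))
        eta_s <- eta_s + it$loading[match(g, it$gene)] * u_it[, g]
      if (!is.null(u_mod)) {
        rows <- which(mods$gene == g)
        if (!is.null(mods$tissue))
          rows <- rows[is.na(mods$tissue[rows]) | mods$tissue[rows] == t]
        for (r in rows) {
          on <- switch(mods$stratum[r],
                       all = rep(TRUE, nrow(samples)),
                       CF = samples$severity > 0,
                       control = samples$severity == 0)
          eta_s <- eta_s + ifelse(on, mods$loading[r] * u_mod[, mods$module[r]], 0)
        }
      }
      eta_s <- eta_s + rnorm(nrow(samples), 0, truth$gene_sd)
      # per-site planted offsets then beta draw
      eta <- outer(eta_s, rep(0, ns), `+`)
      for (j in seq_len(ns))
        eta[, j] <- eta[, j] + planted_offset(truth, g, j, samples$severity)
      mu <- plogis(eta)
      p <- if (is.finite(truth$concentration)) {
        matrix(rbeta(length(mu), mu * truth$concentration,
                     (1 - mu) * truth$concentration), nrow(mu))
      } else mu
      out[[k]] <- data.frame(
        sample_id = rep(samples$sample_id, ns),
        tissue = t, gene = g,
        site = rep(seq_len(ns), each = nrow(samples)),
        p = as.vector(p), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate bisulfite reads for a cohort
#'
#' Emits bisulfite-converted reads from the top strand of each amplicon:
#' CpG cytosines read C with the site's methylation probability (plus
#' conversion failure on unmethylated sites), non-CpG cytosines read T
#' except for conversion failures, independent substitution errors, and
#' about half the reads emitted as reverse complements. Each read carries
#' its library's barcode as a prefix. Read depth per library x amplicon is
#' log-uniform over the truth model's `depth_range`.
#'
#' @param probs Truth table from [simulate_sample_methylation()].
#' @param design A `cohort_design`.
#' @param truth A `truth_model` (with sequences in its panel).
#' @param seed RNG seed.
#' @param libraries Optional subset of `design$libraries` to simulate.
#' @param depth Optional fixed depth overriding the log-uniform draw.
#' @return list with `reads` (truth table: read_id, library_id, sample_id,
#'   tissue, gene, orientation, conversion_rate, sequence with barcode) and
#'   `fastq` (character vector of FASTQ lines).
#' @export
simulate_reads <- function(probs, design, truth, seed = design$seed,
                           libraries = design$libraries, depth = NULL) {
  stopifnot(inherits(truth, "truth_model"))
  panel <- truth$panel
  if (any(is.na(panel$sequence))) stop("panel sequences required")
  set.seed(split_seed(seed, 3L))
  refs <- lapply(setNames(panel$sequence, panel$gene), bisulfite_convert)
  probs <- probs[order(probs$site), ]
  p_lookup <- split(probs$p, paste(probs$sample_id, probs$tissue, probs$gene))
  chunks <- vector("list", nrow(libraries) * nrow(panel))
  k <- 0
  for (li in seq_len(nrow(libraries))) {
    lib <- libraries[li, ]
    for (g in panel$gene) {
      k <- k + 1
      ref <- refs[[g]]
      ps <- p_lookup[[paste(lib$sample_id, lib$tissue, g)]]
      n <- if (!is.null(depth)) depth else {
        lo <- max(truth$depth_range[1], 1)
        round(exp(runif(1, log(lo), log(truth$depth_range[2]))))
      }
      if (n == 0) next
      L <- nchar(ref$sequence)
      m <- matrix(rep(strsplit(ref$converted, "", fixed = TRUE)[[1]], n), L, n)
      # CpG sites: C if methylated, else conversion failure keeps C
      for (j in seq_along(ref$cpg_positions)) {
        meth <- runif(n) < ps[j]
        fail <- runif(n) < truth$epsilon
        m[ref$cpg_positions[j], ] <- ifelse(meth | fail, "C", "T")
      }
      # non-CpG C: conversion failures read C
      cp <- ref$converted_positions
      if (length(cp)) {
        fail <- matrix(runif(length(cp) * n) < truth$epsilon, length(cp), n)
        block <- m[cp, , drop = FALSE]
        block[fail] <- "C"
        m[cp, ] <- block
      }
      conv <- if (length(cp)) colSums(m[cp, , drop = FALSE] == "T") / length(cp)
              else rep(NA_real_, n)
      # substitution errors
      if (truth$seq_error > 0) {
        err <- which(matrix(runif(L * n) < truth$seq_error, L, n))
        if (length(err)) {
          alt <- c("A", "C", "G", "T")
          cur <- m[err]
          m[err] <- vapply(cur, function(b)
            sample(setdiff(alt, b), 1), character(1))
        }
      }
      seqs <- collapse_matrix(m)
      rev <- runif(n) < 0.5
      if (any(rev))
        seqs[rev] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(seqs[rev])))
      chunks[[k]] <- data.frame(
        read_id = sprintf("%s_%s_%04d", lib$library_id, g, seq_len(n)),
        library_id = lib$library_id, sample_id = lib$sample_id,
        tissue = lib$tissue, gene = g,
        orientation = ifelse(rev, "reverse", "forward"),
        conversion_rate = conv,
        sequence = paste0(lib$barcode, seqs),
        stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, chunks)
  fq <- as.vector(rbind(paste0("@", reads$read_id),
                        reads$sequence, "+",
                        strrep("I", nchar(reads$sequence))))
  list(reads = reads, fastq = fq)
}

#' Write simulated reads to a FASTQ file
#' @param sim Result of [simulate_reads()].
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(sim, path) {
  writeLines(sim$fastq, path)
  invisible(path)
}

#' Simulate site-level read counts directly (no read emission)
#'
#' A fast count-level shortcut through the generative model: for each
#' library, gene and site, draws the number of methylated read calls as
#' Binomial(depth, p + (1 - p) * epsilon). Used for statistical
#' calibration studies where per-read sequences are irrelevant.
#'
#' @param probs Truth table from [simulate_sample_methylation()].
#' @param design A `cohort_design`.
#' @param truth A `truth_model`.
#' @param depth Fixed depth, or `NULL` for the log-uniform draw per
#'   library x gene.
#' @param seed RNG seed.
#' @return Long data.frame: library_id, sample_id, group, severity, tissue,
#'   replicate, dosage, gene, site, meth, total, fraction.
#' @export
simulate_counts <- function(probs, design, truth, depth = NULL,
                            seed = design$seed) {
  set.seed(split_seed(seed, 4L))
  lib <- design$libraries
  key <- paste(probs$sample_id, probs$tissue)
  idx <- split(seq_len(nrow(probs)), key)
  out <- vector("list", nrow(lib))
  for (li in seq_len(nrow(lib))) {
    rows <- idx[[paste(lib$sample_id[li], lib$tissue[li])]]
    sub <- probs[rows, ]
    genes <- unique(sub$gene)
    n_g <- if (!is.null(depth)) setNames(rep(depth, length(genes)), genes)
    else {
      lo <- max(truth$depth_range[1], 1)
      setNames(round(exp(runif(length(genes), log(lo),
                               log(truth$depth_range[2])))), genes)
    }
    tot <- n_g[sub$gene]
    p_obs <- sub$p + (1 - sub$p) * truth$epsilon
    meth <- rbinom(nrow(sub), tot, p_obs)
    out[[li]] <- data.frame(
      library_id = lib$library_id[li], sample_id = lib$sample_id[li],
      group = lib$group[li], severity = lib$severity[li],
      tissue = lib$tissue[li], replicate = lib$replicate[li],
      dosage = lib$dosage[li], gene = sub$gene, site = sub$site,
      meth = meth, total = unname(tot),
      fraction = meth / unname(tot), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write the sample sheet for a design
#' @param design A `cohort_design`.
#' @param path Output TSV path.
#' @export
write_sample_sheet <- function(design, path) {
  write_tsv(design$libraries, path)
  invisible(path)
}
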