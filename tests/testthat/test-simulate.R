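test_that("degenerate dispersion gives p equal to the baseline", {
  panel <- tiny_panel()
  design <- cohort_design(n_control = 3, n_mild = 2, n_intermediary = 0,
                          n_severe = 0, nec_missing_patients = 0,
                          duplicate_patients = 0, seed = 5)
  base <- data.frame(gene = c("GA1", "GA2"), blood = c(0.2, 0.6),
                     NEC = c(0.3, 0.5))
  truth <- truth_model(panel, baselines = base, concentration = Inf,
                       gene_sd = 0, dosage_slope = 0, intertissue = NULL)
  probs <- simulate_sample_methylation(design, truth, seed = 5)
  expected <- ifelse(probs$tissue == "blood",
                     base$blood[match(probs$gene, base$gene)],
                     base$NEC[match(probs$gene, base$gene)])
  expect_equal(probs$p, expected, tolerance = 1e-12)
})

test_that("negative dosage slope makes mean methylation decrease in dosage", {
  panel <- tiny_panel()
  design <- cohort_design(n_control = 300, n_mild = 0, n_intermediary = 0,
                          n_severe = 0, nec_missing_patients = 0,
                          duplicate_patients = 0, b_allele_freq = 0.5,
                          seed = 9)
  truth <- truth_model(panel, concentration = 200, gene_sd = 0.1,
                       dosage_gene = "GA1", dosage_slope = -1,
                       intertissue = NULL)
  probs <- simulate_sample_methylation(design, truth, seed = 9)
  d <- merge(probs[probs$gene == "GA1" & probs$tissue == "blood", ],
             design$samples, by = "sample_id")
  means <- tapply(d$p, d$dosage, mean)
  expect_true(all(diff(means) < 0))
})

test_that("a shared latent factor creates inter-tissue correlation", {
  panel <- tiny_panel()
  design <- cohort_design(n_control = 60, n_mild = 0, n_intermediary = 0,
                          n_severe = 0, nec_missing_patients = 0,
                          duplicate_patients = 0, seed = 13)
  truth <- truth_model(panel, gene_sd = 0.2, dosage_slope = 0,
                       intertissue = data.frame(gene = "GA1", loading = 1.0))
  probs <- simulate_sample_methylation(design, truth, seed = 13)
  gm <- tapply(probs$p[probs$gene == "GA1"],
               list(probs$sample_id[probs$gene == "GA1"],
                    probs$tissue[probs$gene == "GA1"]), mean)
  expect_gt(cor(gm[, "blood"], gm[, "NEC"], method = "spearman"), 0.3)
  # no factor on GA2: correlation near zero
  gm2 <- tapply(probs$p[probs$gene == "GA2"],
                list(probs$sample_id[probs$gene == "GA2"],
                     probs$tissue[probs$gene == "GA2"]), mean)
  expect_lt(abs(cor(gm2[, "blood"], gm2[, "NEC"], method = "spearman")), 0.3)
})

test_that("read emission respects methylation state and conversion", {
  panel <- tiny_panel()
  design <- cohort_design(n_control = 1, n_mild = 0, n_intermediary = 0,
                          n_severe = 0, nec_missing_patients = 0,
                          duplicate_patients = 0, seed = 2)
  base1 <- data.frame(gene = c("GA1", "GA2"), blood = 1, NEC = 1)
  truth1 <- truth_model(panel, baselines = base1, concentration = Inf,
                        gene_sd = 0, epsilon = 0, seq_error = 0,
                        dosage_slope = 0, intertissue = NULL,
                        depth_range = c(30, 30))
  probs1 <- simulate_sample_methylation(design, truth1, seed = 2)
  sim1 <- simulate_reads(probs1, design, truth1, seed = 2)
  w <- nchar(design$libraries$barcode[1])
  for (g in c("GA1", "GA2")) {
    ref <- bisulfite_convert(panel$sequence[panel$gene == g], "top")
    rr <- sim1$reads[sim1$reads$gene == g, ]
    ins <- substr(rr$sequence, w + 1, nchar(rr$sequence))
    ins[rr$orientation == "reverse"] <- rc(ins[rr$orientation == "reverse"])
    chars <- strsplit(ins, "")
    for (s in chars) {
      expect_true(all(s[ref$cpg_positions] == "C"))       # fully methylated
      expect_true(all(s[ref$converted_positions] == "T")) # fully converted
    }
  }
  expect_true(all(sim1$reads$conversion_rate == 1))

  # p = 0, epsilon = 0: zero observed methylation
  base0 <- data.frame(gene = c("GA1", "GA2"), blood = 0, NEC = 0)
  truth0 <- truth_model(panel, baselines = base0, concentration = Inf,
                        gene_sd = 0, epsilon = 0, seq_error = 0,
                        dosage_slope = 0, intertissue = NULL,
                        depth_range = c(30, 30))
  probs0 <- simulate_sample_methylation(design, truth0, seed = 2)
  sim0 <- simulate_reads(probs0, design, truth0, seed = 2)
  ins <- substr(sim0$reads$sequence, w + 1, nchar(sim0$reads$sequence))
  fwd <- sim0$reads$orientation == "forward"
  ins[!fwd] <- rc(ins[!fwd])
  for (g in c("GA1", "GA2")) {
    ref <- bisulfite_convert(panel$sequence[panel$gene == g], "top")
    s <- seq_matrix(ins[sim0$reads$gene == g])
    expect_true(all(s[ref$cpg_positions, ] == "T"))
  }

  # high conversion failure: most reads miss the 0.97 threshold
  # (on an amplicon with 40 informative non-CpG cytosines)
  seq40 <- paste0("A", strrep("CA", 40), "CG")
  panel40 <- amplicon_panel(
    data.frame(gene = "G40", chrom = "chr1", start = 1, end = nchar(seq40),
               declared_n_cpg = 1, declared_size = nchar(seq40)),
    c(G40 = seq40))
  truth_eps <- truth_model(panel40,
                           baselines = data.frame(gene = "G40", blood = 0,
                                                  NEC = 0),
                           concentration = Inf, gene_sd = 0, epsilon = 0.05,
                           seq_error = 0, dosage_slope = 0,
                           intertissue = NULL, depth_range = c(500, 500))
  probs40 <- simulate_sample_methylation(design, truth_eps, seed = 2)
  sim_eps <- simulate_reads(probs40, design, truth_eps, seed = 3)
  expect_lt(mean(sim_eps$reads$conversion_rate >= 0.97), 0.5)
  expect_equal(mean(sim_eps$reads$conversion_rate), 0.95, tolerance = 0.01)
})

test_that("same seed gives byte-identical FASTQ output", {
  panel <- tiny_panel()
  design <- cohort_design(n_control = 2, n_mild = 1, n_intermediary = 0,
                          n_severe = 0, nec_missing_patients = 0,
                          duplicate_patients = 1, seed = 21)
  truth <- truth_model(panel, depth_range = c(10, 50))
  probs <- simulate_sample_methylation(design, truth, seed = 21)
  s1 <- simulate_reads(probs, design, truth, seed = 21)
  s2 <- simulate_reads(probs, design, truth, seed = 21)
  expect_identical(s1$fastq, s2$fastq)
  s3 <- simulate_reads(probs, design, truth, seed = 22)
  expect_false(identical(s3$fastq, s1$fastq))
})

test_that("empirical per-CpG methylation converges to the truth table", {
  panel <- tiny_panel()
  design <- cohort_design(n_control = 2, n_mild = 2, n_intermediary = 0,
                          n_severe = 0, nec_missing_patients = 0,
                          duplicate_patients = 0, seed = 31)
  truth <- truth_model(panel, epsilon = 0, seq_error = 0,
                       depth_range = c(1000, 1000))
  probs <- simulate_sample_methylation(design, truth, seed = 31)
  sim <- simulate_reads(probs, design, truth, seed = 31)
  w <- nchar(design$libraries$barcode[1])
  ok <- 0; total <- 0
  for (li in seq_len(nrow(design$libraries))) {
    lib <- design$libraries[li, ]
    for (g in c("GA1", "GA2")) {
      ref <- bisulfite_convert(panel$sequence[panel$gene == g], "top")
      rr <- sim$reads[sim$reads$library_id == lib$library_id &
                        sim$reads$gene == g, ]
      ins <- substr(rr$sequence, w + 1, nchar(rr$sequence))
      ins[rr$orientation == "reverse"] <- rc(ins[rr$orientation == "reverse"])
      m <- seq_matrix(ins)
      p_true <- probs$p[probs$sample_id == lib$sample_id &
                          probs$tissue == lib$tissue & probs$gene == g]
      p_true <- p_true[order(probs$site[probs$sample_id == lib$sample_id &
                                          probs$tissue == lib$tissue &
                                          probs$gene == g])]
      for (j in seq_along(ref$cpg_positions)) {
        frac <- mean(m[ref$cpg_positions[j], ] == "C")
        tol <- 3 * sqrt(p_true[j] * (1 - p_true[j]) / nrow(rr)) + 1e-9
        total <- total + 1
        if (abs(frac - p_true[j]) <= tol) ok <- ok + 1
      }
    }
  }
  expect_gte(ok / total, 0.95)   # 3-SD bound holds for almost all entries
})

test_that("cohort design reproduces the study structure", {
  d <- cohort_design(seed = 1)
  expect_equal(nrow(d$samples), 72)
  expect_equal(as.vector(table(d$samples$group)[c("control", "mild",
                                                  "intermediary", "severe")]),
               c(24, 23, 13, 12))
  lib <- d$libraries
  expect_equal(sum(lib$tissue == "blood" & lib$replicate == 1), 72)
  expect_equal(sum(lib$tissue == "NEC" & lib$replicate == 1), 63)
  expect_equal(sum(lib$replicate == 2), 8)     # 4 patients x 2 tissues
  expect_false(anyDuplicated(lib$barcode) > 0)
  expect_true(all(d$samples$dosage %in% 0:2))
})
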