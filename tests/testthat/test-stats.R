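test_that("logit transform values, clamping, and monotonicity", {
  expect_equal(as.numeric(logit_transform(0.5)), 0)
  expect_equal(as.numeric(logit_transform(0.95)), log(19), tolerance = 1e-12)
  expect_equal(round(as.numeric(logit_transform(0.95)), 4), 2.9444)

  lt <- logit_transform(0, n = 100)            # clamp at 1/(2n) = 0.005
  expect_equal(as.numeric(lt), log(0.005 / 0.995), tolerance = 1e-12)
  expect_true(attr(lt, "clamped"))
  expect_false(attr(logit_transform(0.3, n = 100), "clamped"))

  # round trip for unclamped values
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(inv_logit(as.numeric(logit_transform(p))), p,
               tolerance = 1e-12)
  # strictly increasing
  expect_true(all(diff(as.numeric(logit_transform(p))) > 0))
})

test_that("logit transform homogenizes between-sample variance", {
  # between-sample methylation variation is modelled on the logit scale;
  # on the fraction scale its variance peaks at 50% and vanishes at the
  # boundaries, while the logit brings it back to a common scale
  set.seed(8)
  n <- 500
  var_p <- var_l <- numeric(3)
  baselines <- c(0.05, 0.5, 0.95)
  for (i in seq_along(baselines)) {
    eta <- qlogis(baselines[i]) + rnorm(4000, 0, 0.4)
    phat <- rbinom(4000, n, plogis(eta)) / n
    var_p[i] <- var(phat)
    var_l[i] <- var(as.numeric(logit_transform(phat, n = n)))
  }
  expect_lt(max(var_l) / min(var_l), 2)
  expect_gt(max(var_p) / min(var_p), 5)
})

test_that("repeatability estimator: closed forms and sampling behavior", {
  expect_equal(estimate_repeatability(c(1, 2, 3), c(1, 2, 3))$sd, 0)
  r <- estimate_repeatability(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 4.5))
  expect_equal(r$sd, 0.5 / sqrt(2))
  expect_equal(r$df, 4)
  # missing pairs are dropped and counted
  r2 <- estimate_repeatability(c(1, NA, 3), c(1.2, 2, 3.2))
  expect_equal(r2$df, 2)
  expect_equal(r2$n_missing, 1)
  expect_error(estimate_repeatability(NA, 1), "no complete")

  # with 112 pairs the estimate is within 20% of sigma in ~95%+ of runs
  set.seed(99)
  sigma <- 0.44
  hit <- replicate(200, {
    mu <- rnorm(112)
    est <- estimate_repeatability(mu + rnorm(112, 0, sigma),
                                  mu + rnorm(112, 0, sigma))$sd
    abs(est - sigma) / sigma < 0.2
  })
  expect_gte(mean(hit), 0.95)
})

test_that("group comparison selects tests from data diagnostics", {
  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")

  # identical groups: no signal, p near 1
  v <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  g <- rep(c("a", "b"), each = 5)
  expect_gt(compare_groups(v, g)$p.value, 0.99)

  # Gaussian, equal variance, large separation: Student's t, tiny p
  set.seed(12)
  x <- c(rnorm(20, 0, 1), rnorm(20, 3, 1))
  gc <- compare_groups(x, rep(c("a", "b"), each = 20))
  expect_equal(gc$test, "Student")
  expect_lt(gc$p.value, 0.001)
  expect_true(gc$diagnostics$normal)
  expect_true(gc$diagnostics$homoscedastic)

  # heavy-tailed four-group data: Kruskal-Wallis in the majority of runs
  set.seed(13)
  picks <- replicate(100, {
    v <- rt(72, df = 2)
    g4 <- rep(c("a", "b", "c", "d"), c(24, 23, 13, 12))
    compare_groups(v, g4)$test
  })
  expect_gt(mean(picks == "Kruskal-Wallis"), 0.5)

  # gaussian four groups, equal variance: ANOVA available
  set.seed(14)
  found <- replicate(50, compare_groups(rnorm(72),
                                        rep(c("a", "b", "c", "d"),
                                            c(24, 23, 13, 12)))$test)
  expect_gt(mean(found == "ANOVA"), 0.5)
})

test_that("per-CpG Fisher tests match the hypergeometric oracle", {
  f <- per_cpg_fisher(10, 10, 0, 10)
  expect_equal(f$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(f$direction, "+")

  f2 <- per_cpg_fisher(5, 10, 5, 10)
  expect_equal(f2$p, 1)
  expect_equal(f2$direction, "")

  # all-zero table: degenerate, p = 1, flagged
  f3 <- per_cpg_fisher(0, 0, 0, 0)
  expect_true(f3$degenerate)
  expect_equal(f3$p, 1)

  # random tables vs brute-force enumeration
  set.seed(15)
  for (i in 1:50) {
    tc <- sample(0:30, 1); tk <- sample(0:30, 1)
    if (tc + tk == 0) next
    mc <- if (tc) sample(0:tc, 1) else 0
    mk <- if (tk) sample(0:tk, 1) else 0
    got <- per_cpg_fisher(mc, tc, mk, tk)$p
    expect_equal(got, fisher_oracle(mc, tc - mc, mk, tk - mk),
                 tolerance = 1e-9)
  }

  # Bonferroni monotonicity: shrinking the family never de-selects
  set.seed(16)
  mc <- rbinom(20, 50, 0.5); mk <- rbinom(20, 50, 0.2)
  full <- per_cpg_fisher(mc, rep(50, 20), mk, rep(50, 20))
  sub <- per_cpg_fisher(mc[1:10], rep(50, 10), mk[1:10], rep(50, 10))
  expect_true(all(sub$significant >= full$significant[1:10]))
})

test_that("co-methylation network edges, skips, and FWER bookkeeping", {
  set.seed(17)
  n <- 30
  x <- matrix(rnorm(n * 4), n,
              dimnames = list(NULL, c("blood.A", "blood.B", "NEC.A",
                                      "NEC.C")))
  x[, "blood.B"] <- x[, "blood.A"]          # duplicated variable
  net <- comethylation_network(x)
  e <- net$edges
  expect_equal(nrow(e), choose(4, 2))       # no self-edges
  dupe <- e[e$var1 == "blood.A" & e$var2 == "blood.B", ]
  expect_equal(dupe$r, 1)
  expect_true(dupe$significant)
  expect_equal(dupe$type, "intra-tissue")
  inter <- e[e$var1 == "blood.A" & e$var2 == "NEC.A", ]
  expect_equal(inter$type, "inter-tissue")

  # p-values track cor.test's evaluation at moderate correlations and are
  # monotone decreasing in |r|
  ct <- suppressWarnings(cor.test(x[, "blood.A"], x[, "NEC.C"],
                                  method = "spearman", exact = TRUE))
  got <- e[e$var1 == "blood.A" & e$var2 == "NEC.C", ]
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(got$p, ct$p.value, tolerance = 0.05)
  rs <- seq(0.1, 0.9, by = 0.1)
  ps <- vapply(rs, methpanel:::spearman_mc_p, numeric(1), n = 30)
  expect_true(all(diff(ps) <= 0))
  expect_lt(ps[9], ps[1])
  # permutation null p-values are valid: P(p <= alpha) <= alpha (approx)
  set.seed(19)
  pnull <- replicate(2000, {
    a <- rnorm(20)
    methpanel:::spearman_mc_p(cor(a, rnorm(20), method = "spearman"), 20)
  })
  expect_lte(mean(pnull <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))

  # constant variable: pair skipped and logged
  x2 <- cbind(x[, 1:2], const = 1)
  net2 <- comethylation_network(x2)
  expect_equal(nrow(net2$skipped), 2)
  expect_equal(net2$m, 1)

  # too few pairwise-complete observations: skipped
  x3 <- x[, 1:3]
  x3[1:27, 3] <- NA
  net3 <- comethylation_network(x3, min_pairs = 5)
  expect_true(all(c("blood.A", "blood.B") %in%
                    c(net3$skipped$var1, net3$skipped$var2)))
})

test_that("genotype association sign convention and degenerate input", {
  ga <- genotype_association(c(0.3, 0.2, 0.1), c(0, 1, 2))
  expect_equal(ga$r, -1)
  gm <- genotype_association(c(0.3, 0.2, 0.1, 0.4), c(1, 1, 1, 1))
  expect_true(gm$monomorphic)
  expect_true(is.na(gm$r))
  expect_error(genotype_association(c(0.1, 0.2), c(0, 1)), "at least 3")

  # permutation calibration: ~5% rejections under the null
  set.seed(18)
  meth <- rnorm(48)
  rej <- replicate(400, {
    genotype_association(meth, sample(rep(0:2, c(24, 18, 6))))$p < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("region matrix averages replicates and respects retention", {
  region <- data.frame(
    sample_id = c("S1", "S1", "S1", "S2", "S2"),
    tissue = c("blood", "blood", "NEC", "blood", "NEC"),
    gene = c("G1", "G1", "G1", "G1", "G1"),
    replicate = c(1, 2, 1, 1, 1),
    mean_methylation = c(0.2, 0.4, 0.5, 0.1, NA),
    retained = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  m <- region_matrix(region)
  expect_equal(m["S1", "blood.G1"], 0.3)    # replicates averaged
  expect_equal(m["S1", "NEC.G1"], 0.5)
  expect_true(is.na(m["S2", "blood.G1"]))   # filtered out
  expect_true(is.na(m["S2", "NEC.G1"]))     # missing value
})
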