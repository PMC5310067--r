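#' Logit transform of methylation fractions
#'
#' The sampling variance of a methylation percentage is maximal at 50% and
#' vanishes at 0 or 100%; working on the logit scale `ln(p/(1-p))`
#' homogenizes it. Fractions are clamped into `[eps, 1-eps]` before the
#' transform so boundary values stay finite; by default `eps` is half the
#' smallest observable fraction for a measurement of `n` reads, `1/(2n)`,
#' which is depth-adaptive and preserves ordering.
#'
#' @param p Fractions in `[0,1]`.
#' @param n Read counts used for the default clamp (recycled).
#' @param eps Explicit clamp; overrides `n`. `0` disables clamping.
#' @return Numeric vector of logit values with a logical `clamped`
#'   attribute marking values that hit the clamp.
#' @export
logit_transform <- function(p, n = NULL, eps = NULL) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  if (is.null(eps)) eps <- if (!is.null(n)) 1 / (2 * n) else 0
  lo <- pmax(p, eps)
  hi <- pmin(lo, 1 - eps)
  out <- qlogis(hi)
  attr(out, "clamped") <- !is.na(p) & hi != p
  out
}

#' Inverse logit
#' @param x Logit values.
#' @return Fractions in `(0,1)`.
#' @export
inv_logit <- function(x) plogis(x)

#' Repeatability from duplicated measurements
#'
#' Pooled within-pair standard deviation of technical duplicates on the
#' logit scale: `sqrt(sum(d_i^2) / (2k))` over the `k` complete pairs,
#' where `d_i` is the difference within pair `i`. Each complete duplicate
#' pair contributes one degree of freedom; incomplete pairs are dropped
#' and counted.
#'
#' @param x,y Paired measurements (logit scale), one value per pair member.
#' @return A `repeatability_estimate`: list with `sd`, `df`, `n_pairs`,
#'   `n_missing`.
#' @export
estimate_repeatability <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  k <- sum(ok)
  if (k == 0) stop("no complete duplicate pairs")
  d <- x[ok] - y[ok]
  structure(list(sd = sqrt(sum(d^2) / (2 * k)), df = k, n_pairs = k,
                 n_missing = sum(!ok)),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("repeatability: pooled SD %.3f (logit units), %d df, %d pair(s) dropped\n",
              x$sd, x$df, x$n_missing))
  invisible(x)
}

#' Group comparison with data-driven test selection
#'
#' Chooses between parametric and non-parametric tests from the data's own
#' diagnostics: per-group normality (Shapiro-Wilk at `alpha_normal`) and
#' homoscedasticity across groups (median-centered Levene at `alpha_var`).
#' Two groups: Student's t when normal and homoscedastic, Welch's t when
#' normal only, otherwise Wilcoxon rank-sum. More than two groups: one-way
#' ANOVA when normal and homoscedastic, otherwise Kruskal-Wallis. Groups
#' too small for a Shapiro-Wilk test (n < 3) are treated as non-normal.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 groups, each with >= 2 values).
#' @param alpha_normal,alpha_var Diagnostic significance levels.
#' @return A `group_comparison`: list with `test` (one of "Student",
#'   "Welch", "Wilcoxon", "ANOVA", "Kruskal-Wallis"), `statistic`,
#'   `p.value`, and `diagnostics` (Shapiro p per group, Levene p, the two
#'   boolean verdicts), so the selection is reproducible.
#' @export
compare_groups <- function(values, groups, alpha_normal = 0.05,
                           alpha_var = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  groups <- droplevels(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2))
    stop("group(s) with fewer than 2 values: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  sw <- vapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (length(v) < 3 || length(unique(v)) == 1) NA_real_
    else shapiro.test(v)$p.value
  }, numeric(1))
  normal <- all(!is.na(sw) & sw > alpha_normal)
  lev <- tryCatch(
    suppressWarnings(car::leveneTest(values ~ groups,
                                     center = median)[1, "Pr(>F)"]),
    error = function(e) NA_real_)
  homosced <- !is.na(lev) && lev > alpha_var
  k <- length(levels(groups))
  if (k == 2) {
    if (normal && homosced) {
      ht <- t.test(values ~ groups, var.equal = TRUE); test <- "Student"
    } else if (normal) {
      ht <- t.test(values ~ groups); test <- "Welch"
    } else {
      ht <- suppressWarnings(wilcox.test(values ~ groups, exact = FALSE))
      test <- "Wilcoxon"
    }
  } else {
    if (normal && homosced) {
      fit <- anova(aov(values ~ groups))
      ht <- list(statistic = c(F = fit[1, "F value"]),
                 p.value = fit[1, "Pr(>F)"])
      test <- "ANOVA"
    } else {
      ht <- kruskal.test(values, groups); test <- "Kruskal-Wallis"
    }
  }
  structure(list(test = test, statistic = unname(ht$statistic),
                 p.value = ht$p.value,
                 diagnostics = list(shapiro_p = sw, levene_p = lev,
                                    normal = normal,
                                    homoscedastic = homosced,
                                    group_sizes = as.vector(sizes))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test: statistic %.4g, p = %.4g\n",
              x$test, x$statistic, x$p.value))
  invisible(x)
}

#' Per-CpG Fisher exact tests with Bonferroni FWER control
#'
#' For each CpG site, tests association between methylation state and
#' case/control status on the 2x2 table of methylated/unmethylated read
#' calls pooled within each group (two-sided Fisher exact test). A site is
#' significant when `p <= fwer / m`, with `m` the number of sites tested
#' in the family. Direction is `+` (hypermethylated in cases) or `-`
#' (hypomethylated in cases).
#'
#' @param meth_case,total_case Methylated and total read calls per site in
#'   the case group.
#' @param meth_control,total_control Same for controls.
#' @param ids Optional site identifiers.
#' @param fwer Family-wise error rate (default 5%).
#' @param m Bonferroni denominator; defaults to the number of sites tested.
#' @return data.frame `id`, `p`, `q` (Bonferroni-adjusted `min(1, m*p)`),
#'   `direction`, `significant`, `degenerate` (all-zero table, `p = 1`).
#' @export
per_cpg_fisher <- function(meth_case, total_case, meth_control,
                           total_control, ids = NULL, fwer = 0.05,
                           m = NULL) {
  ns <- length(meth_case)
  stopifnot(length(total_case) == ns, length(meth_control) == ns,
            length(total_control) == ns,
            all(meth_case <= total_case), all(meth_control <= total_control),
            all(c(meth_case, meth_control, total_case, total_control) >= 0))
  if (is.null(ids)) ids <- seq_len(ns)
  if (is.null(m)) m <- ns
  p <- numeric(ns)
  degenerate <- total_case + total_control == 0
  for (i in seq_len(ns)) {
    if (degenerate[i]) { p[i] <- 1; next }
    tab <- matrix(c(meth_case[i], total_case[i] - meth_case[i],
                    meth_control[i], total_control[i] - meth_control[i]), 2)
    p[i] <- fisher.test(tab)$p.value
  }
  fc <- ifelse(total_case > 0, meth_case / total_case, NA_real_)
  fk <- ifelse(total_control > 0, meth_control / total_control, NA_real_)
  dirn <- ifelse(is.na(fc) | is.na(fk) | fc == fk, "",
                 ifelse(fc > fk, "+", "-"))
  data.frame(id = ids, p = p, q = pmin(1, m * p), direction = dirn,
             significant = p <= fwer / m, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Spearman co-methylation network
#'
#' Computes Spearman correlations between all pairs of mean-methylation
#' variables (gene x tissue) over pairwise-complete observations, and keeps
#' as network edges the pairs significant under Bonferroni control of the
#' family-wise error rate. P-values are evaluated against the exact
#' permutation null distribution of the Spearman coefficient, approximated
#' by Monte Carlo (`B` draws, add-one estimator, cached per sample size
#' under a fixed internal seed): the usual t and Edgeworth approximations
#' are anticonservative in the far tails that Bonferroni control relies on
#' at these sample sizes, while the add-one Monte Carlo p-value is valid
#' by construction. With tied data the tie-free null makes the p-values
#' mildly conservative. Pairs with fewer than `min_pairs` complete
#' observations or a constant variable are skipped and logged.
#'
#' @param x Numeric matrix, samples x variables; column names of the form
#'   `tissue.gene` let the edge type (inter- vs intra-tissue) be derived.
#' @param fwer Family-wise error rate (default 10%).
#' @param min_pairs Minimum pairwise-complete observations per pair.
#' @param B Monte Carlo draws for the permutation null.
#' @return A `comethylation_network`: list with `edges` (var1, var2, r, n,
#'   p, significant, type), `skipped` (pairs without a defined
#'   correlation), `m` (family size), `fwer`.
#' @export
comethylation_network <- function(x, fwer = 0.10, min_pairs = 5,
                                  B = 50000) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  vars <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- vars
  k <- ncol(x)
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  v1 <- vars[pairs[, 1]]; v2 <- vars[pairs[, 2]]
  np <- nrow(pairs)
  rv <- pv <- rep(NA_real_, np)
  nv <- integer(np)
  for (i in seq_len(np)) {
    a <- x[, pairs[i, 1]]; b <- x[, pairs[i, 2]]
    ok <- !is.na(a) & !is.na(b)
    nv[i] <- sum(ok)
    if (nv[i] < min_pairs) next
    if (length(unique(a[ok])) < 2 || length(unique(b[ok])) < 2) next
    rv[i] <- cor(a[ok], b[ok], method = "spearman")
    pv[i] <- spearman_mc_p(rv[i], nv[i], B)
  }
  usable <- !is.na(rv)
  m <- sum(usable)
  edges <- data.frame(var1 = v1[usable], var2 = v2[usable], r = rv[usable],
                      n = nv[usable], p = pv[usable],
                      significant = pv[usable] <= fwer / max(m, 1),
                      stringsAsFactors = FALSE)
  split1 <- strsplit(edges$var1, ".", fixed = TRUE)
  split2 <- strsplit(edges$var2, ".", fixed = TRUE)
  if (all(lengths(split1) == 2) && all(lengths(split2) == 2)) {
    t1 <- vapply(split1, `[`, character(1), 1)
    g1 <- vapply(split1, `[`, character(1), 2)
    t2 <- vapply(split2, `[`, character(1), 1)
    g2 <- vapply(split2, `[`, character(1), 2)
    edges$type <- ifelse(t1 != t2 & g1 == g2, "inter-tissue",
                         ifelse(t1 == t2, "intra-tissue", "cross"))
  }
  structure(list(edges = edges,
                 skipped = data.frame(var1 = v1[!usable], var2 = v2[!usable],
                                      n = nv[!usable]),
                 m = m, fwer = fwer),
            class = "comethylation_network")
}

#' @export
print.comethylation_network <- function(x, ...) {
  cat(sprintf("co-methylation network: %d/%d significant edge(s) at FWER %.0f%% (m = %d)\n",
              sum(x$edges$significant), nrow(x$edges), 100 * x$fwer, x$m))
  invisible(x)
}

# cached sorted |rho| samples from the tie-free permutation null, one per
# sample size; a fixed internal seed keeps results reproducible and the
# caller's RNG stream untouched
.spearman_null <- new.env(parent = emptyenv())

spearman_null_abs <- function(n, B = 50000) {
  key <- paste(n, B)
  hit <- .spearman_null[[key]]
  if (!is.null(hit)) return(hit)
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, globalenv()))
  set.seed(104729L + n)
  base <- seq_len(n)
  denom <- n * (n^2 - 1)
  draws <- vapply(seq_len(B), function(i) {
    1 - 6 * sum((base - sample.int(n))^2) / denom
  }, numeric(1))
  out <- sort(abs(draws))
  .spearman_null[[key]] <- out
  out
}

# add-one Monte Carlo p-value: (1 + #{|rho*| >= |rho|}) / (B + 1)
spearman_mc_p <- function(r, n, B = 50000) {
  null_abs <- spearman_null_abs(n, B)
  hits <- length(null_abs) - findInterval(abs(r) - 1e-12, null_abs)
  (1 + hits) / (length(null_abs) + 1)
}

#' Genotype dosage vs methylation association
#'
#' Spearman correlation between allele dosage (0/1/2 copies of the named
#' allele) and methylation. A negative coefficient means methylation
#' decreases with each additional allele copy.
#'
#' @param methylation Numeric vector (region means, or per-site fractions).
#' @param dosage Integer vector in 0/1/2.
#' @return list `r`, `p`, `n`, `monomorphic` (correlation undefined when
#'   the dosage does not vary).
#' @export
genotype_association <- function(methylation, dosage) {
  ok <- !is.na(methylation) & !is.na(dosage)
  if (sum(ok) < 3) stop("need at least 3 samples with genotype and methylation")
  if (length(unique(dosage[ok])) < 2)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok), monomorphic = TRUE))
  ct <- suppressWarnings(cor.test(methylation[ok], dosage[ok],
                                  method = "spearman", exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       monomorphic = FALSE)
}

#' Build a samples x (tissue.gene) descriptor matrix of region means
#'
#' Collapses a region-level methylation table to one row per biological
#' sample, averaging technical replicates. Only measurements passing the
#' coverage filter contribute (when a `retained` column is present).
#'
#' @param region Region-level data.frame with `sample_id`, `tissue`,
#'   `gene`, `mean_methylation` (and optionally `retained`, `replicate`).
#' @param tissues Tissues to include (columns are named `tissue.gene`).
#' @return Numeric matrix with rownames = sample ids; missing measurements
#'   are `NA`.
#' @export
region_matrix <- function(region, tissues = unique(region$tissue)) {
  d <- region[region$tissue %in% tissues, ]
  if ("retained" %in% names(d)) d <- d[d$retained, ]
  d <- d[!is.na(d$mean_methylation), ]
  key <- paste(d$tissue, d$gene, sep = ".")
  samples <- sort(unique(region$sample_id))
  cols <- sort(unique(key))
  out <- matrix(NA_real_, length(samples), length(cols),
                dimnames = list(samples, cols))
  agg <- tapply(d$mean_methylation, list(d$sample_id, key), mean)
  out[rownames(agg), colnames(agg)] <- agg
  out
}
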