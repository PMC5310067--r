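prepare_descriptors <- function(x, missing = c("impute", "drop")) {
  missing <- match.arg(missing)
  x <- as.matrix(x)
  dropped <- integer(0)
  if (anyNA(x)) {
    if (missing == "drop") {
      dropped <- which(!complete.cases(x))
      x <- x[complete.cases(x), , drop = FALSE]
    } else {
      mu <- colMeans(x, na.rm = TRUE)
      mu[is.nan(mu)] <- 0            # descriptor missing everywhere
      for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
    }
  }
  list(x = x, dropped = dropped)
}

#' Fit a PLS discriminant model
#'
#' PLS1 regression (NIPALS) of a two-level discrete response, coded -1 for
#' the negative class and +1 for the positive class, on autoscaled
#' descriptors (zero mean, unit variance each). Successive score vectors
#' are mutually orthogonal and each component deflates the descriptor
#' matrix.
#'
#' @param x Numeric matrix, samples x descriptors (e.g. normalized mean
#'   methylation per gene x tissue, see [region_matrix()]).
#' @param y Class labels with exactly two levels.
#' @param ncomp Number of latent components (default 2, matching the two
#'   score axes usually plotted).
#' @param positive_class Label coded +1; default the second sorted level.
#' @param missing Missing-descriptor policy: impute by the class-agnostic
#'   descriptor mean (default) or drop incomplete samples.
#' @return A `pls_model` with weights `W`, loadings `P`, coefficients `q`,
#'   training scores `T`, regression vector `b`, centering/scaling
#'   parameters and the class coding.
#' @export
fit_plsda <- function(x, y, ncomp = 2, positive_class = NULL,
                      missing = c("impute", "drop")) {
  prep <- prepare_descriptors(x, missing)
  x <- prep$x
  if (length(prep$dropped)) y <- y[-prep$dropped]
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("y must have exactly two classes")
  if (is.null(positive_class)) positive_class <- classes[2]
  stopifnot(positive_class %in% classes)
  negative_class <- setdiff(classes, positive_class)
  yv <- ifelse(y == positive_class, 1, -1)
  if (min(table(y)) < 2) stop("need >= 2 samples per class")
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev == 0] <- 1
  xs <- scale(x, center = mu, scale = sdev)
  if (ncomp > min(nrow(x) - 1, ncol(x)))
    stop("ncomp exceeds descriptor matrix rank")
  ymean <- mean(yv)
  yc <- yv - ymean
  E <- xs
  W <- P <- matrix(0, ncol(x), ncomp)
  Tm <- matrix(0, nrow(x), ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, yc))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-10) stop("ncomp exceeds descriptor matrix rank")
    w <- w / wn
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-10) stop("ncomp exceeds descriptor matrix rank")
    p_a <- drop(crossprod(E, t_a)) / tt
    q[a] <- sum(t_a * yc) / tt
    E <- E - tcrossprod(t_a, p_a)
    yc <- yc - q[a] * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
  }
  b <- W %*% solve(crossprod(P, W), q)
  structure(list(W = W, P = P, q = q, T = Tm, b = drop(b), ncomp = ncomp,
                 center = mu, scale = sdev, y_mean = ymean,
                 positive_class = positive_class,
                 negative_class = negative_class,
                 descriptors = colnames(x)),
            class = "pls_model")
}

#' Predict the continuous PLS response
#' @param object A `pls_model`.
#' @param newdata Descriptor matrix (columns matching the training set).
#' @param ... Unused.
#' @return Numeric vector of predicted responses (sign carries the class).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$descriptors) && !is.null(colnames(x)))
    x <- x[, object$descriptors, drop = FALSE]
  xs <- scale(x, center = object$center, scale = object$scale)
  drop(xs %*% object$b) + object$y_mean
}

pls_scores <- function(model, x) {
  xs <- scale(as.matrix(x), center = model$center, scale = model$scale)
  Tm <- matrix(0, nrow(xs), model$ncomp)
  E <- xs
  for (a in seq_len(model$ncomp)) {
    Tm[, a] <- drop(E %*% model$W[, a])
    E <- E - tcrossprod(Tm[, a], model$P[, a])
  }
  colnames(Tm) <- paste0("v", seq_len(model$ncomp))
  Tm
}

#' Classify samples with a fitted PLS discriminant model
#'
#' Thresholds the predicted continuous response at zero. Under the default
#' `"coding"` mapping a positive estimate is assigned to the +1-coded
#' (positive) class; `"reversed"` flips the assignment. A predicted
#' response of exactly zero is a tie: it is assigned to the negative
#' (control-side) class and flagged.
#'
#' @param model A `pls_model`.
#' @param x Descriptor matrix.
#' @param truth Optional true labels for scoring.
#' @param sign_mapping `"coding"` (consistent with the -1/+1 response
#'   coding) or `"reversed"`.
#' @param missing Missing-descriptor policy, as in [fit_plsda()].
#' @return A `classification_report`: `samples` data.frame (sample, v1,
#'   v2, predicted, class, correct, tie), `percent_correct`, `n_classified`,
#'   `n_dropped`.
#' @export
classify <- function(model, x, truth = NULL,
                     sign_mapping = c("coding", "reversed"),
                     missing = c("impute", "drop")) {
  sign_mapping <- match.arg(sign_mapping)
  prep <- prepare_descriptors(x, missing)
  xm <- prep$x
  if (length(prep$dropped) && !is.null(truth)) truth <- truth[-prep$dropped]
  pred <- predict(model, xm)
  pos <- if (sign_mapping == "coding") model$positive_class else model$negative_class
  neg <- setdiff(c(model$positive_class, model$negative_class), pos)
  cls <- ifelse(pred > 0, pos, neg)
  tie <- pred == 0
  cls[tie] <- model$negative_class
  scores <- pls_scores(model, xm)
  samples <- data.frame(
    sample = rownames(xm) %||% seq_len(nrow(xm)),
    scores[, seq_len(min(2, ncol(scores))), drop = FALSE],
    predicted = pred, class = cls, tie = tie, stringsAsFactors = FALSE)
  pc <- NA_real_
  if (!is.null(truth)) {
    samples$correct <- samples$class == as.character(truth)
    pc <- 100 * mean(samples$correct)
  }
  structure(list(samples = samples, percent_correct = pc,
                 n_classified = nrow(samples),
                 n_dropped = length(prep$dropped)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("PLS-DA classification: %d sample(s)", x$n_classified))
  if (!is.na(x$percent_correct))
    cat(sprintf(", %.1f%% correct", x$percent_correct))
  if (x$n_dropped) cat(sprintf(", %d dropped", x$n_dropped))
  cat("\n")
  invisible(x)
}

#' Leave-one-out cross-validated PLS-DA accuracy
#'
#' Refits the model without each sample in turn and classifies the held-out
#' sample, so the reported percent correct is protected against
#' resubstitution optimism. Missing descriptors are imputed within each
#' training fold.
#'
#' @inheritParams fit_plsda
#' @param sign_mapping See [classify()].
#' @return list `percent_correct`, `predicted` (classes), `response`
#'   (continuous predictions).
#' @export
plsda_loo <- function(x, y, ncomp = 2, positive_class = NULL,
                      sign_mapping = c("coding", "reversed")) {
  sign_mapping <- match.arg(sign_mapping)
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  pred <- numeric(n)
  cls <- character(n)
  for (i in seq_len(n)) {
    # degenerate folds (rank-deficient after imputation) fall back to
    # fewer components; a completely uninformative fold predicts the
    # training majority class
    fit <- NULL
    for (nc in rev(seq_len(ncomp))) {
      fit <- tryCatch(fit_plsda(x[-i, , drop = FALSE], y[-i], ncomp = nc,
                                positive_class = positive_class,
                                missing = "impute"),
                      error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) {
      tab <- table(y[-i])
      cls[i] <- names(tab)[which.max(tab)]
      pred[i] <- NA_real_
      next
    }
    xi <- x[i, , drop = FALSE]
    if (anyNA(xi)) {  # impute from training-fold descriptor means
      mu <- fit$center
      xi[is.na(xi)] <- mu[is.na(xi)]
    }
    pred[i] <- predict(fit, xi)
    pos <- if (sign_mapping == "coding") fit$positive_class else fit$negative_class
    neg <- setdiff(c(fit$positive_class, fit$negative_class), pos)
    cls[i] <- if (pred[i] > 0) pos else neg
  }
  list(percent_correct = 100 * mean(cls == y), predicted = cls,
       response = pred)
}

#' Compare descriptor sets (blood, NEC, both) by classification accuracy
#'
#' Runs the identical fit/classify protocol on tissue-restricted descriptor
#' subsets and reports percent correct per subset, by leave-one-out
#' cross-validation and by resubstitution.
#'
#' @param x Descriptor matrix with `tissue.gene` column names (see
#'   [region_matrix()]).
#' @param y Class labels.
#' @param sets Named list of column-selection regexes; the default derives
#'   blood / NEC / both subsets from the column-name prefixes.
#' @param ncomp,positive_class As in [fit_plsda()].
#' @return data.frame `set`, `n_descriptors`, `percent_correct_loo`,
#'   `percent_correct_resub`; scores per set attached as the `reports`
#'   attribute.
#' @export
evaluate_descriptor_sets <- function(x, y, sets = NULL, ncomp = 2,
                                     positive_class = NULL) {
  x <- as.matrix(x)
  if (is.null(sets))
    sets <- list(blood = "^blood\\.", NEC = "^NEC\\.", both = ".")
  rows <- list(); reports <- list()
  for (nm in names(sets)) {
    cols <- grep(sets[[nm]], colnames(x))
    if (!length(cols)) stop("empty descriptor set: ", nm)
    xs <- x[, cols, drop = FALSE]
    nc <- min(ncomp, length(cols))   # small subsets: cap the components
    loo <- plsda_loo(xs, y, ncomp = nc, positive_class = positive_class)
    fit <- NULL
    for (k in rev(seq_len(nc))) {
      fit <- tryCatch(fit_plsda(xs, y, ncomp = k,
                                positive_class = positive_class),
                      error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stop("descriptor set '", nm, "' is degenerate")
    rep <- classify(fit, xs, truth = y)
    rows[[nm]] <- data.frame(set = nm, n_descriptors = length(cols),
                             percent_correct_loo = loo$percent_correct,
                             percent_correct_resub = rep$percent_correct,
                             stringsAsFactors = FALSE)
    reports[[nm]] <- rep
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}
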