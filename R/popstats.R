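# Population-level statistics over a cells x features table.
#
# A "population table" is a plain data.frame with one row per cell, a
# `condition` column (plus optional `cell_id`), and the feature columns named
# as in feature_registry(). Missing feature values are allowed and excluded
# pairwise.

feature_columns <- function(table) {
  intersect(feature_registry()$feature, colnames(table))
}

check_population_table <- function(table, groups) {
  if (!"condition" %in% colnames(table))
    stop("population table needs a 'condition' column", call. = FALSE)
  missing_groups <- setdiff(groups, unique(table$condition))
  if (length(missing_groups))
    stop("condition(s) not in table: ", paste(missing_groups, collapse = ", "),
         call. = FALSE)
  if (length(feature_columns(table)) == 0L)
    stop("population table contains no known feature columns", call. = FALSE)
  invisible(table)
}

#' Rank features by Fisher's discriminant ratio
#'
#' For each feature, `FDR = (mean_A - mean_B)^2 / (var_A + var_B)` (sample
#' variances), measuring its power to separate the two conditions at the
#' single-cell level. Features are sorted by decreasing FDR (ties broken by
#' feature name) and average FDRs are reported per biomarker and per
#' coordinate frame. A feature with zero pooled variance gets FDR 0 when the
#' means agree and `Inf` (flagged) when they differ.
#'
#' @param table population table (see above).
#' @param group_a,group_b condition labels to contrast.
#' @return object of class `ranking_result`: list with `per_feature`
#'   (data.frame: feature, biomarker, frame, fdr, n_a, n_b, sorted),
#'   `by_biomarker`, `by_frame` (average FDR data.frames) and `groups`.
#' @export
rank_features <- function(table, group_a, group_b) {
  check_population_table(table, c(group_a, group_b))
  reg <- feature_registry()
  feats <- feature_columns(table)
  xa <- table[table$condition == group_a, , drop = FALSE]
  xb <- table[table$condition == group_b, , drop = FALSE]
  rows <- lapply(feats, function(fn) {
    a <- xa[[fn]]; a <- a[is.finite(a)]
    b <- xb[[fn]]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L)
      stop("need >= 2 finite values per group for feature ", fn, call. = FALSE)
    denom <- var(a) + var(b)
    num <- (mean(a) - mean(b))^2
    fdr <- if (denom > 0) num / denom else if (num == 0) 0 else Inf
    data.frame(feature = fn,
               biomarker = reg$biomarker[reg$feature == fn],
               frame = reg$frame[reg$feature == fn],
               fdr = fdr, n_a = length(a), n_b = length(b),
               stringsAsFactors = FALSE)
  })
  per_feature <- do.call(rbind, rows)
  per_feature <- per_feature[order(-per_feature$fdr, per_feature$feature), ]
  rownames(per_feature) <- NULL
  avg_by <- function(key) {
    agg <- aggregate(per_feature$fdr, by = list(group = per_feature[[key]]),
                     FUN = mean)
    names(agg) <- c(key, "mean_fdr")
    agg[order(-agg$mean_fdr), , drop = FALSE]
  }
  structure(list(per_feature = per_feature,
                 by_biomarker = avg_by("biomarker"),
                 by_frame = avg_by("frame"),
                 groups = c(a = group_a, b = group_b)),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("<ranking_result> ", x$groups["a"], " vs ", x$groups["b"], "\n", sep = "")
  print(head(x$per_feature, 5))
  cat("biomarker averages:\n"); print(x$by_biomarker)
  invisible(x)
}

#' Compare a treated condition against a control
#'
#' Per feature: the percentage variation of the medians,
#' `PV = 100 * (median_treated - median_control) / median_control`, and a
#' two-sided Mann-Whitney U test (exact for small untied samples, normal
#' approximation with tie correction otherwise). Significance stars follow
#' the usual 0.05 / 0.01 / 0.001 thresholds. p-values are reported per
#' feature without family-wise correction; a Benjamini-Hochberg adjusted
#' column (`p_bh`) is added as a labelled extension.
#'
#' @param table population table.
#' @param treated,control condition labels.
#' @return object of class `comparison_result`: data.frame with columns
#'   feature, biomarker, frame, median_treated, median_control, pv, u,
#'   p_value, stars, p_bh, n_treated, n_control.
#' @export
compare_conditions <- function(table, treated, control) {
  check_population_table(table, c(treated, control))
  reg <- feature_registry()
  feats <- feature_columns(table)
  xt <- table[table$condition == treated, , drop = FALSE]
  xc <- table[table$condition == control, , drop = FALSE]
  rows <- lapply(feats, function(fn) {
    a <- xt[[fn]]; a <- a[is.finite(a)]
    b <- xc[[fn]]; b <- b[is.finite(b)]
    if (length(a) == 0L || length(b) == 0L)
      stop("empty group for feature ", fn, call. = FALSE)
    med_t <- median(a); med_c <- median(b)
    pv <- if (med_c == 0) NA_real_ else 100 * (med_t - med_c) / med_c
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
    data.frame(feature = fn,
               biomarker = reg$biomarker[reg$feature == fn],
               frame = reg$frame[reg$feature == fn],
               median_treated = med_t, median_control = med_c,
               pv = pv, u = unname(wt$statistic), p_value = wt$p.value,
               n_treated = length(a), n_control = length(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- cut(out$p_value, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", "ns"))
  out$stars <- as.character(out$stars)
  out$p_bh <- p.adjust(out$p_value, method = "BH")
  out$flag_pv_undefined <- is.na(out$pv)
  attr(out, "groups") <- c(treated = treated, control = control)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Standardize feature columns (z-score over the pooled table)
#'
#' @param table population table.
#' @return table with each feature column centred to mean 0 and scaled to
#'   unit sample variance over all cells (columns with zero variance are left
#'   centred only).
#' @export
zscore_features <- function(table) {
  for (fn in feature_columns(table)) {
    x <- table[[fn]]
    mu <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    table[[fn]] <- if (is.finite(s) && s > 0) (x - mu) / s else x - mu
  }
  table
}

#' Joint t-SNE embedding and treatment-effectiveness scores
#'
#' Z-scores every feature over the pooled table, embeds all cells together
#' in 2D with t-SNE (exact gradient, PCA initialization, fixed seed), and
#' reports per-condition centroids plus the treatment effectiveness
#' `TE = ||centroid(treated) - centroid(control)||` in embedding space for
#' every requested pair. t-SNE distances are reproducible per seed only;
#' between-run orderings, not absolute values, are meaningful.
#'
#' @param table population table (>= 2 conditions; rows with missing feature
#'   values are dropped with a warning).
#' @param pairs data.frame with columns `treated` and `control`, or `NULL`
#'   for all ordered condition pairs.
#' @param perplexity t-SNE perplexity (reduced automatically with a warning
#'   when `3 * perplexity > n - 1`). Default 30.
#' @param seed RNG seed, recorded in the result. Default 0.
#' @param max_iter gradient-descent iterations. Default 1000.
#' @return object of class `embedding_result`: list with `embedding`
#'   (data.frame: cell_id, condition, tsne1, tsne2), `centroids`, `te`
#'   (data.frame: treated, control, te) and `params`.
#' @export
embed_and_score <- function(table, pairs = NULL, perplexity = 30, seed = 0,
                            max_iter = 1000) {
  check_population_table(table, character())
  conds <- unique(table$condition)
  if (length(conds) < 2L) stop("need >= 2 conditions", call. = FALSE)
  feats <- feature_columns(table)
  complete <- rowSums(!is.finite(as.matrix(table[, feats, drop = FALSE]))) == 0L
  if (!all(complete)) {
    warning(sum(!complete), " cell(s) with missing features dropped from the embedding")
    table <- table[complete, , drop = FALSE]
  }
  table_z <- zscore_features(table)
  X <- as.matrix(table_z[, feats, drop = FALSE])
  n <- nrow(X)
  if (3 * perplexity > n - 1) {
    perplexity <- max(2, floor((n - 1) / 3))
    warning("perplexity reduced to ", perplexity, " for n = ", n)
  }
  set.seed(seed)
  Y <- tsne_exact(X, perplexity = perplexity, max_iter = max_iter)
  emb <- data.frame(cell_id = if ("cell_id" %in% colnames(table))
    table$cell_id else seq_len(n),
    condition = table$condition, tsne1 = Y[, 1], tsne2 = Y[, 2],
    stringsAsFactors = FALSE)
  cent <- aggregate(cbind(tsne1, tsne2) ~ condition, data = emb, FUN = mean)
  if (is.null(pairs)) {
    cc <- unique(emb$condition)
    pairs <- expand.grid(treated = cc, control = cc,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$treated != pairs$control, , drop = FALSE]
  }
  te <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- cent[cent$condition == pairs$treated[i], c("tsne1", "tsne2")]
    b <- cent[cent$condition == pairs$control[i], c("tsne1", "tsne2")]
    if (nrow(a) == 0L || nrow(b) == 0L)
      stop("unknown condition in pairs", call. = FALSE)
    sqrt(sum((as.numeric(a) - as.numeric(b))^2))
  }, numeric(1))
  te_df <- data.frame(treated = pairs$treated, control = pairs$control,
                      te = te, stringsAsFactors = FALSE)
  structure(list(embedding = emb, centroids = cent, te = te_df,
                 params = list(perplexity = perplexity, seed = seed,
                               max_iter = max_iter, n = n)),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("<embedding_result> n =", x$params$n, "cells, perplexity",
      x$params$perplexity, ", seed", x$params$seed, "\n")
  print(x$te)
  invisible(x)
}

# ---------------------------------------------------------------------------
# exact t-SNE (O(n^2) gradient), sufficient for desk-scale populations.
# PCA initialization makes the run deterministic given the RNG seed set by
# the caller (the only stochastic part is the tiny init jitter).

tsne_exact <- function(X, perplexity = 30, max_iter = 1000,
                       early_exaggeration = 12, stop_lying_iter = 250,
                       eta = 200) {
  n <- nrow(X)
  P <- tsne_input_similarities(X, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, .Machine$double.eps)

  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  Y <- matrix(0, n, 2)
  Y[, seq_len(k)] <- pc$x[, seq_len(k), drop = FALSE]
  Y <- scale(Y, center = TRUE, scale = FALSE)
  sdy <- apply(Y, 2, sd)
  sdy[sdy == 0] <- 1
  Y <- sweep(Y, 2, sdy, "/") * 1e-4
  Y <- Y + matrix(rnorm(2 * n, sd = 1e-6), n, 2)

  G <- P * early_exaggeration
  vel <- matrix(0, n, 2)
  momentum <- 0.5
  for (it in seq_len(max_iter)) {
    if (it == stop_lying_iter) G <- P
    if (it == stop_lying_iter + 1) momentum <- 0.8
    d2 <- as.matrix(dist(Y))^2
    W <- 1 / (1 + d2)
    diag(W) <- 0
    Q <- pmax(W / sum(W), .Machine$double.eps)
    M <- (G - Q) * W
    grad <- 4 * (diag(rowSums(M)) %*% Y - M %*% Y)
    vel <- momentum * vel - eta * grad
    Y <- Y + vel
    Y <- scale(Y, center = TRUE, scale = FALSE)
  }
  Y
}

# conditional similarities with per-point precision calibrated to the target
# perplexity by bisection on log(beta)
tsne_input_similarities <- function(X, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(X)
  d2 <- as.matrix(dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf; beta_max <- Inf
    di <- d2[i, -i]
    for (tr in seq_len(max_tries)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0; p <- w } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      diff_h <- h - target
      if (abs(diff_h) < tol) break
      if (diff_h > 0) { # entropy too high -> increase beta
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}
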