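# builds a minimal population table with the full feature-column contract
fake_table <- function(values_by_cond, feature = "NLNSA") {
  reg <- feature_registry()
  rows <- do.call(rbind, lapply(names(values_by_cond), function(cond) {
    v <- values_by_cond[[cond]]
    df <- as.data.frame(setNames(rep(list(rep(0.5, length(v))), 17),
                                 reg$feature))
    df[[feature]] <- v
    cbind(data.frame(cell_id = paste0(cond, seq_along(v)), condition = cond,
                     stringsAsFactors = FALSE), df)
  }))
  rows
}

test_that("Fisher-ratio ranking follows its closed form and invariances", {
  # identical groups: every FDR is zero
  set.seed(1)
  x <- rnorm(40)
  tb <- fake_table(list(A = x, B = x))
  rk <- rank_features(tb, "A", "B")
  expect_true(all(rk$per_feature$fdr == 0))

  # N(0,1) vs N(1,1): FDR -> 1 / (1 + 1) = 0.5
  set.seed(2)
  tb2 <- fake_table(list(A = rnorm(1e4), B = rnorm(1e4, mean = 1)))
  rk2 <- rank_features(tb2, "A", "B")
  got <- rk2$per_feature$fdr[rk2$per_feature$feature == "NLNSA"]
  expect_lt(abs(got - 0.5), 0.05)

  # affine rescaling of a feature leaves its FDR unchanged
  tb3 <- tb2
  tb3$NLNSA <- -3.7 * tb3$NLNSA + 11
  rk3 <- rank_features(tb3, "A", "B")
  expect_equal(rk3$per_feature$fdr[rk3$per_feature$feature == "NLNSA"],
               got, tolerance = 1e-12)

  # biomarker averages are plain means of member features
  pf <- rk2$per_feature
  for (bm in unique(pf$biomarker)) {
    expect_equal(rk2$by_biomarker$mean_fdr[rk2$by_biomarker$biomarker == bm],
                 mean(pf$fdr[pf$biomarker == bm]))
  }

  # zero-variance degenerate cases
  tb4 <- fake_table(list(A = rep(1, 5), B = rep(1, 5)))
  expect_identical(
    rank_features(tb4, "A", "B")$per_feature$fdr[
      rank_features(tb4, "A", "B")$per_feature$feature == "NLNSA"], 0)
  tb5 <- fake_table(list(A = rep(1, 5), B = rep(2, 5)))
  expect_identical(
    max(rank_features(tb5, "A", "B")$per_feature$fdr), Inf)
})

test_that("percentage variation is median arithmetic with sign antisymmetry", {
  tb <- fake_table(list(ctrl = c(9, 10, 11), trt = c(11, 12, 13)))
  cc <- compare_conditions(tb, "trt", "ctrl")
  row <- cc[cc$feature == "NLNSA", ]
  expect_equal(row$pv, 20)
  expect_equal(row$median_treated, 12)
  expect_equal(row$median_control, 10)

  # swapping roles flips the sign (not the magnitude)
  rev <- compare_conditions(tb, "ctrl", "trt")
  expect_lt(rev$pv[rev$feature == "NLNSA"], 0)

  # treated == control: PV 0 and p ~ 1
  set.seed(3)
  x <- rnorm(20)
  tb2 <- fake_table(list(A = x, B = x))
  cc2 <- compare_conditions(tb2, "A", "B")
  expect_equal(cc2$pv[cc2$feature == "NLNSA"], 0)
  expect_gt(cc2$p_value[cc2$feature == "NLNSA"], 0.9)

  # zero control median is flagged undefined
  tb3 <- fake_table(list(A = c(1, 2, 3), B = c(-1, 0, 1)))
  cc3 <- compare_conditions(tb3, "A", "B")
  expect_true(is.na(cc3$pv[cc3$feature == "NLNSA"]))
  expect_true(cc3$flag_pv_undefined[cc3$feature == "NLNSA"])
})

test_that("Mann-Whitney results match exact enumeration for small groups", {
  set.seed(4)
  for (rep in 1:5) {
    n_a <- sample(3:8, 1); n_b <- sample(3:8, 1)
    a <- round(runif(n_a, 0, 100), 6) # continuous: no ties
    b <- round(runif(n_b, 0, 100), 6)
    tb <- fake_table(list(T = a, C = b))
    cc <- compare_conditions(tb, "T", "C")
    oracle <- exact_mannwhitney(a, b)
    row <- cc[cc$feature == "NLNSA", ]
    expect_equal(row$u, oracle$u)
    expect_equal(row$p_value, oracle$p, tolerance = 1e-12)
  }
  # tied toy case: the U statistic still matches midrank enumeration
  tb <- fake_table(list(T = c(1, 2, 3), C = c(2, 3, 4)))
  cc <- compare_conditions(tb, "T", "C")
  expect_equal(cc$u[cc$feature == "NLNSA"], exact_mannwhitney(c(1, 2, 3), c(2, 3, 4))$u)
})

test_that("z-scoring standardizes every feature over the pooled table", {
  set.seed(5)
  tb <- fake_table(list(A = rnorm(30, 5, 3), B = rnorm(30, 9, 1)))
  tb$HLVR <- runif(60)
  z <- zscore_features(tb)
  for (fn in c("NLNSA", "HLVR")) {
    expect_equal(mean(z[[fn]]), 0, tolerance = 1e-12)
    expect_equal(var(z[[fn]]), 1, tolerance = 1e-12)
  }
})

test_that("embedding separates distinct clusters and collapses duplicates", {
  reg <- feature_registry()
  set.seed(6)
  mk_cells <- function(cond, center, n = 40, sd = 0.3) {
    m <- matrix(rnorm(n * 17, mean = center, sd = sd), ncol = 17)
    df <- as.data.frame(m)
    names(df) <- reg$feature
    cbind(data.frame(cell_id = paste0(cond, 1:n), condition = cond,
                     stringsAsFactors = FALSE), df)
  }
  far <- rbind(mk_cells("A", 0), mk_cells("B", 3))       # well separated
  near <- rbind(mk_cells("A", 0), mk_cells("B", 0.3))    # overlapping
  emb_far <- suppressWarnings(
    embed_and_score(far, pairs = data.frame(treated = "B", control = "A"),
                    seed = 0))
  emb_near <- suppressWarnings(
    embed_and_score(near, pairs = data.frame(treated = "B", control = "A"),
                    seed = 0))
  expect_gt(emb_far$te$te, emb_near$te$te)
  expect_gte(min(emb_far$te$te), 0)

  # duplicated condition sits on top of the original
  dup <- rbind(mk_cells("A", 0), mk_cells("A2", 0), mk_cells("B", 3))
  emb <- embed_and_score(dup, pairs = data.frame(treated = c("A2", "B"),
                                                 control = c("A", "A")), seed = 1)
  te <- setNames(emb$te$te, emb$te$treated)
  expect_lt(te[["A2"]], 0.1 * te[["B"]])

  # reproducible per seed; perplexity auto-reduction warns
  emb_b <- suppressWarnings(
    embed_and_score(far, pairs = data.frame(treated = "B", control = "A"),
                    seed = 0))
  expect_identical(emb_far$embedding$tsne1, emb_b$embedding$tsne1)
  small <- rbind(mk_cells("A", 0, n = 10), mk_cells("B", 3, n = 10))
  expect_warning(embed_and_score(small, seed = 0), "perplexity reduced")
})
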