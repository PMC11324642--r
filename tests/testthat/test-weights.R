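y6 <- c("control", "control", "control", "stress", "stress", "stress")

test_that("correlation weighting matches the direct Pearson formula", {
  X <- rbind(label_like = c(0, 0, 0, 1, 1, 1),
             ramp = c(1, 2, 3, 4, 5, 6),
             flat = c(2, 2, 2, 2, 2, 2),
             noise = c(5, 1, 4, 2, 6, 3))
  wt <- weight_by_correlation(X, y6)
  w <- setNames(wt$weight, wt$gene_id)
  expect_equal(unname(w["label_like"]), 1)
  expect_equal(unname(w["flat"]), 0)
  # independent oracle: raw |r| by the textbook formula, then min-max
  y01 <- c(0, 0, 0, 1, 1, 1)
  raw <- apply(X, 1, function(x) {
    num <- sum((x - mean(x)) * (y01 - mean(y01)))
    den <- sqrt(sum((x - mean(x))^2) * sum((y01 - mean(y01))^2))
    if (den == 0) 0 else abs(num / den)
  })
  expect_equal(unname(w), unname((raw - min(raw)) / (max(raw) - min(raw))),
               tolerance = 1e-12)
  expect_error(weight_by_correlation(X, rep("stress", 6)), "binary")
})

test_that("symmetric uncertainty is 1 for a label-aligned gene and matches enumeration", {
  # 8-sample worked table, 2 bins: gene g2's joint (bin, class) counts are
  # enumerated by the independent oracle
  y8 <- rep(c("control", "stress"), each = 4)
  X <- rbind(g1 = c(1, 2, 3, 4, 10, 11, 12, 13),   # bins == class
             g2 = c(1, 9, 2, 8, 3, 10, 4, 11),     # mixed
             g3 = rep(4, 8))                       # degenerate
  wt <- weight_by_uncertainty(X, y8, bins = 2)
  w <- setNames(wt$weight, wt$gene_id)
  expect_equal(unname(w["g1"]), 1)
  expect_equal(unname(w["g3"]), 0)
  raw2 <- su_oracle(cut(X["g2", ], breaks = quantile(X["g2", ], c(0, .5, 1)),
                        include.lowest = TRUE, labels = FALSE),
                    y8)
  expect_equal(unname(w["g2"]), raw2 / 1, tolerance = 1e-12)  # minmax anchors 0 and 1 present
})

test_that("uncertainty weight of a label-independent gene vanishes with n", {
  set.seed(42)
  n <- 200
  y <- rep(c("control", "stress"), each = n / 2)
  perfect <- as.numeric(y == "stress") + rnorm(n, 0, 1e-3)
  flat <- rep(1, n)
  vals <- replicate(100, {
    noise <- sample(perfect)   # label-permuted copy
    wt <- weight_by_uncertainty(rbind(anchor = perfect, zero = flat,
                                      g = noise), y, bins = 5)
    wt$weight[wt$gene_id == "g"]
  })
  expect_lt(mean(vals), 0.05)
})

test_that("relief reproduces an explicit nested-loop trace and its edge cases", {
  X <- rbind(sep = c(1, 2, 3, 10, 11, 12),    # perfectly separating
             flat = c(5, 5, 5, 5, 5, 5),
             mix = c(4, 9, 1, 8, 2, 7))
  y01 <- c(0, 0, 0, 1, 1, 1)
  wt <- weight_by_relief(X, y6, n_neighbors = 1)
  w <- setNames(wt$weight, wt$gene_id)
  expect_equal(unname(w["sep"]), 1)
  expect_equal(unname(attr(wt, "raw")["flat"]), 0)   # constant feature: raw 0
  raw <- relief_oracle(X, y01)
  expect_equal(unname(w), unname((raw - min(raw)) / (max(raw) - min(raw))),
               tolerance = 1e-12)
  expect_error(weight_by_relief(X, c("control", rep("stress", 5))),
               "n_neighbors \\+ 1")
})

test_that("svm weights match the analytic hard-margin solution", {
  # standardized feature 1 separates at z = +/- sqrt(3)/2; feature 2 is
  # class-symmetric noise; feature 3 constant. Max-margin solution:
  # w = (2 / (2 * sqrt(3)/2), 0, 0) = (2/sqrt(3), 0, 0)
  X <- rbind(f1 = c(0, 0, 2, 2),
             f2 = c(0, 1, 1, 0),
             f3 = c(7, 7, 7, 7))
  y <- c("control", "control", "stress", "stress")
  wt <- weight_by_svm(X, y, regularization = 1e4)
  w <- setNames(wt$weight, wt$gene_id)
  expect_equal(unname(w[c("f1", "f2", "f3")]), c(1, 0, 0), tolerance = 1e-6)
  raw <- attr(wt, "raw")
  expect_equal(unname(raw[1]), 2 / sqrt(3), tolerance = 1e-3)
  expect_error(weight_by_svm(X, c("control", rep("stress", 3))),
               ">= 2 samples")
})

test_that("svm gives pure-noise features low weight across seeds", {
  ok <- 0
  for (s in 1:100) {
    set.seed(s)
    n <- 100
    y <- rep(c("control", "stress"), each = n / 2)
    shift <- as.numeric(y == "stress")
    X <- rbind(a = shift * 2 + rnorm(n),
               b = shift * 2 + rnorm(n),
               noise = rnorm(n))
    wt <- weight_by_svm(X, y)
    ok <- ok + (wt$weight[wt$gene_id == "noise"] < 0.2)
  }
  expect_gte(ok, 95)
})

test_that("threshold selection keeps weights above tau plus the top gene", {
  wt <- data.frame(gene_id = c("A", "B", "C"), weight = c(1, 0.95, 0.89))
  expect_equal(select_by_threshold(wt, 0.90), c("A", "B"))
  wt2 <- data.frame(gene_id = c("A", "B"), weight = c(1, 0.2))
  expect_equal(select_by_threshold(wt2, 0.90), "A")
  expect_error(select_by_threshold(wt, 1.01), "tau")
  # published correlation panel: all 21 listed genes clear 0.90
  ref <- cucumber_reference()
  corw <- ref$weights[ref$weights$method == "correlation", ]
  expect_length(select_by_threshold(
    data.frame(gene_id = corw$gene_id, weight = corw$weight), 0.90), 21)
})

test_that("every method bounds weights in [0,1] with max 1 and favors planted genes", {
  recovered <- matrix(NA, 50, 4,
                      dimnames = list(NULL, c("uncertainty", "relief",
                                              "correlation", "svm")))
  for (s in 1:50) {
    ds <- generate_dataset(sim_config(n_genes = 200, n_control = 18,
                                      n_stress = 18, seed = s,
                                      de_fraction = 0.05, lfc_sd = 2,
                                      output_mode = "gaussian"))
    planted <- ds$truth$de_genes$gene_id
    wts <- list(uncertainty = weight_by_uncertainty(ds$matrix, ds$design),
                relief = weight_by_relief(ds$matrix, ds$design),
                correlation = weight_by_correlation(ds$matrix, ds$design),
                svm = weight_by_svm(ds$matrix, ds$design))
    for (m in names(wts)) {
      w <- wts[[m]]
      expect_true(all(w$weight >= 0 & w$weight <= 1))
      expect_equal(max(w$weight), 1)
      top_decile <- w$gene_id[rank(-w$weight, ties.method = "first") <= 20]
      recovered[s, m] <- mean(planted %in% top_decile)
    }
  }
  # planted strong genes sit in the top decile of every method's ranking:
  # across seeds, at least 90% of planted-gene placements land there
  expect_true(all(colMeans(recovered) >= 0.9))
})

test_that("permuted labels rarely push genes over the threshold", {
  passes_signal <- passes_null <- numeric(20)
  for (s in 1:20) {
    ds <- generate_dataset(sim_config(n_genes = 500, n_control = 18,
                                      n_stress = 18, seed = s,
                                      de_fraction = 0.05, lfc_sd = 2,
                                      output_mode = "gaussian"))
    y <- ds$design$condition
    set.seed(s)
    yperm <- sample(y)
    for (f in list(weight_by_correlation, weight_by_uncertainty)) {
      passes_signal[s] <- passes_signal[s] +
        length(select_by_threshold(f(ds$matrix, y), 0.90))
      passes_null[s] <- passes_null[s] +
        length(select_by_threshold(f(ds$matrix, yperm), 0.90))
    }
  }
  # min-max normalization guarantees one pass per run (the top gene), so
  # the comparison is on the excess above that floor
  runs <- 20 * 2
  excess_null <- sum(passes_null) - runs
  excess_signal <- sum(passes_signal) - runs
  expect_lt(excess_null, 0.5 * excess_signal)
})
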