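test_that("copula transform maps rows to scaled average ranks", {
  m <- rbind(a = c(5, 1, 9), b = c(2, 2, 5))
  colnames(m) <- paste0("s", 1:3)
  ct <- copula_transform(m)
  expect_equal(unname(ct["a", ]), c(0.5, 0.25, 0.75))
  expect_equal(unname(ct["b", ]), c(0.375, 0.375, 0.75))
  expect_true(all(ct > 0 & ct < 1))

  tiefree <- toy_counts(10, 8, seed = 41) + matrix(runif(80), 10)
  expect_equal(copula_transform(copula_transform(tiefree)),
               copula_transform(tiefree))
})

test_that("correlation estimators store |r| with the sign kept aside", {
  x <- rnorm(30)
  m <- rbind(a = x, b = 2 * x + 3, c = -x + rnorm(30, sd = 1e-6))
  colnames(m) <- sprintf("s%02d", 1:30)
  A <- pcc_matrix(m)
  expect_equal(A["a", "b"], 1)
  expect_equal(attr(A, "signs")["a", "c"], -1)
  expect_equal(A, t(A), ignore_attr = TRUE)
  expect_equal(diag(A), setNames(rep(0, 3), rownames(m)))

  shuf <- withr::with_seed(5, rbind(a = rnorm(1000),
                                    b = rnorm(1000)))
  colnames(shuf) <- sprintf("s%04d", 1:1000)
  shuf <- rbind(shuf, c = runif(1000))
  expect_lt(pcc_matrix(shuf)["a", "b"], 0.1)

  const <- rbind(a = rep(2, 10), b = rnorm(10), c = rnorm(10))
  colnames(const) <- sprintf("s%02d", 1:10)
  expect_warning(Ac <- pcc_matrix(const), "constant")
  expect_equal(unname(Ac["a", "b"]), 0)
})

test_that("Spearman equals Pearson on copula-transformed data", {
  m <- toy_counts(8, 20, seed = 42) + matrix(runif(160), 8)  # tie-free
  expect_equal(scc_matrix(m), pcc_matrix(copula_transform(m)),
               ignore_attr = TRUE, tolerance = 1e-12)
  # and SCC itself is invariant under the copula transform
  expect_equal(scc_matrix(copula_transform(m)), scc_matrix(m),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("PBG follows the Gaussian closed form -0.5 log(1 - r^2)", {
  p <- exact_corr_pair(50, 0.8)
  m <- rbind(a = p$x, b = p$y, c = rnorm(50))
  colnames(m) <- sprintf("s%02d", 1:50)
  A <- pbg_matrix(m)
  expect_equal(A["a", "b"], -0.5 * log(1 - 0.8^2), tolerance = 1e-10)
  expect_equal(A["a", "b"], 0.5108256, tolerance = 1e-6)

  z <- exact_corr_pair(50, 0)
  mz <- rbind(a = z$x, b = z$y, c = rnorm(50))
  colnames(mz) <- sprintf("s%02d", 1:50)
  expect_equal(pbg_matrix(mz)["a", "b"], 0, tolerance = 1e-12)

  # strictly increasing in |r|
  scores <- sapply(c(0.2, 0.5, 0.8, 0.95), function(r) {
    p <- exact_corr_pair(60, r, seed = 3)
    m <- rbind(a = p$x, b = p$y, c = seq_len(60))
    colnames(m) <- sprintf("s%02d", 1:60)
    pbg_matrix(m)["a", "b"]
  })
  expect_true(all(diff(scores) > 0))
})

test_that("B-spline MI: hard-binning limit, constants, independence", {
  x <- rep(1:4, each = 25)
  expect_equal(bspline_mi(x, x, bins = 4, spline_order = 1), log(4),
               tolerance = 1e-12)
  # order-1 reduction equals a plug-in histogram MI on any data
  y <- withr::with_seed(6, runif(100))
  bx <- floor((x - min(x)) / (max(x) - min(x)) * 4) + 1
  bx <- pmin(bx, 4)
  by <- floor((y - min(y)) / (max(y) - min(y)) * 4) + 1
  by <- pmin(by, 4)
  expect_equal(bspline_mi(x, y, bins = 4, spline_order = 1),
               max(plugin_mi(bx, by, 4), 0), tolerance = 1e-12)

  expect_equal(bspline_mi(rep(3, 50), rnorm(50)), 0)
  indep <- withr::with_seed(7, list(x = runif(2000), y = runif(2000)))
  expect_lt(bspline_mi(indep$x, indep$y), 0.05)

  w <- gnibench:::bspline_memberships(runif(40), 10, 2)
  expect_equal(rowSums(w), rep(1, 40), tolerance = 1e-9)
})

test_that("Chao-Shen MI: coverage-adjusted entropies behave as derived", {
  # sample {a, a, b}: f1 = 1, C = 2/3, ptilde = (4/9, 2/9) -> ~1.066 nats
  expect_equal(gnibench:::chao_shen_entropy(c(2, 1)),
               sum(-c(4, 2) / 9 * log(c(4, 2) / 9) /
                     (1 - (1 - c(4, 2) / 9)^3)),
               tolerance = 1e-12)
  expect_equal(gnibench:::chao_shen_entropy(c(2, 1)), 1.0662, tolerance = 1e-4)

  # no singletons -> plug-in entropy with C = 1
  cnt <- c(5, 3, 2)
  p <- cnt / 10
  expect_equal(gnibench:::chao_shen_entropy(cnt),
               sum(-p * log(p) / (1 - (1 - p)^10)), tolerance = 1e-12)

  expect_equal(chao_shen_mi(rep(1, 30), rnorm(30)), 0)
  indep <- withr::with_seed(8, list(x = runif(2000), y = runif(2000)))
  expect_lt(chao_shen_mi(indep$x, indep$y), 0.05)
})

test_that("MI estimators increase with the underlying correlation", {
  for (est in c("bspline", "CS")) {
    scores <- sapply(c(0, 0.3, 0.6, 0.9), function(r) {
      p <- exact_corr_pair(1000, r, seed = 10)
      if (est == "bspline") bspline_mi(p$x, p$y) else chao_shen_mi(p$x, p$y)
    })
    expect_true(all(diff(scores) > 0), info = est)
  }
})

test_that("association_matrix is symmetric and matches per-pair calls", {
  m <- toy_counts(5, 30, seed = 44)
  A <- association_matrix(m, estimator_config("PCC"))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(A[i, j], abs(cor(m[i, ], m[j, ])))

  em <- toy_counts(20, 50, seed = 45)
  B <- association_matrix(em, estimator_config("bspline"))
  expect_equal(B, t(B), ignore_attr = TRUE)
  for (pair in list(c(1, 2), c(3, 17), c(9, 20)))
    expect_equal(B[pair[1], pair[2]],
                 bspline_mi(em[pair[1], ], em[pair[2], ]))
  CS <- association_matrix(em, estimator_config("CS"))
  for (pair in list(c(2, 5), c(4, 18)))
    expect_equal(CS[pair[1], pair[2]],
                 chao_shen_mi(em[pair[1], ], em[pair[2], ]))
  expect_true(all(B >= 0) && all(CS >= 0))

  expect_error(association_matrix(em, estimator_config("XYZ")), "unknown")
  expect_error(estimator_config("bspline", bins = 1, spline_order = 2),
               "bins")
})
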