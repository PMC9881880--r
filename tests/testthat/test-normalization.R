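test_that("TMM factors: fixed points, depth invariance, oracle agreement", {
  m <- toy_counts(100, 4, seed = 11) + 1
  ident <- m[, c(1, 1, 1)]
  colnames(ident) <- paste0("s", 1:3)
  expect_equal(unname(tmm_factors(ident)$factors), rep(1, 3))

  depth <- cbind(a = m[, 1], b = 2 * m[, 1])
  expect_equal(unname(tmm_factors(depth)$factors), c(1, 1))

  for (seed in c(1, 2, 3)) {
    r <- toy_counts(200, 5, mu = 80, size = 2, seed = seed)
    f <- tmm_factors(r)
    expect_equal(unname(f$factors), unname(tmm_oracle(r)), tolerance = 1e-8)
    expect_equal(prod(f$factors), 1, tolerance = 1e-10)
    expect_equal(unname(f$effective_lib_size),
                 unname(colSums(r) * f$factors))
    # invariance to a global rescaling of all columns
    expect_equal(tmm_factors(r * 3)$factors, f$factors, tolerance = 1e-8)
  }
  expect_error(tmm_factors(m[, 1, drop = FALSE]), "2 samples")
})

test_that("RLE factors: geometric-mean reference and median of ratios", {
  m <- toy_counts(100, 4, seed = 12) + 1
  ident <- m[, c(1, 1, 1)]
  colnames(ident) <- paste0("s", 1:3)
  expect_equal(unname(rle_factors(ident)$factors), rep(1, 3))

  depth <- cbind(a = m[, 1], b = 2 * m[, 1])
  expect_equal(unname(rle_factors(depth)$factors),
               c(1 / sqrt(2), sqrt(2)))

  for (seed in 4:6) {
    r <- toy_counts(150, 5, mu = 60, size = 3, seed = seed)
    f <- rle_factors(r)$factors
    expect_equal(unname(f), unname(rle_oracle(r)), tolerance = 1e-12)
    expect_equal(prod(f), 1, tolerance = 1e-10)
    expect_equal(rle_factors(r * 7)$factors, rle_factors(r)$factors)
  }

  allzero <- matrix(c(0, 1, 1, 0), 2,
                    dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(rle_factors(allzero), "nonzero")
})

test_that("RLE agrees with the DESeq2 size-factor cross-check", {
  # odd gene count so the median over genes is a single observed ratio
  r <- toy_counts(151, 5, mu = 60, size = 3, seed = 9) + 1
  sf <- DESeq2::estimateSizeFactorsForMatrix(r)
  sf <- sf / exp(mean(log(sf)))  # same product-1 standardization
  expect_equal(unname(rle_factors(r)$factors), unname(sf),
               tolerance = 1e-10)
})

test_that("apply_factors rescales columns by their factor", {
  m <- toy_counts(20, 3) + 1
  one <- structure(list(factors = rep(1, 3),
                        effective_lib_size = colSums(m)),
                   class = "norm_factors")
  expect_equal(apply_factors(m, one), m)
  halved <- structure(list(factors = c(2, 1, 1),
                           effective_lib_size = colSums(m) * c(2, 1, 1)),
                      class = "norm_factors")
  out <- apply_factors(m, halved)
  expect_equal(out[, 1], m[, 1] / 2)
  expect_equal(unname(colSums(out)), unname(colSums(m) / c(2, 1, 1)))
})

test_that("VST is monotone and approaches log2 with unit slope", {
  m <- toy_counts(200, 10, mu = 100, size = 5, seed = 21)
  fit <- vst_fit(m)
  expect_gt(fit$a0, 0)
  expect_gte(fit$a1, 0)
  x <- sort(runif(100, 1, 1e4))
  v <- vst_apply(matrix(x, 1), fit)[1, ]
  expect_true(all(diff(v) > 0))
  # numeric derivative wrt log2(x) at large x -> 1
  for (x0 in c(1e4, 1e5)) {
    h <- x0 * 1e-4
    slope <- (vst_apply(matrix(x0 + h), fit) -
                vst_apply(matrix(x0 - h), fit)) /
      (log2(x0 + h) - log2(x0 - h))
    expect_equal(as.numeric(slope), 1, tolerance = 1e-3)
  }
})

test_that("VST flattens the NB mean-variance trend where log2 does not", {
  # genes with means spanning 1..1e4 (filtered data still reaches well below
  # 10 counts) and constant dispersion 0.05
  mus <- 10^seq(0, 4, length.out = 200)
  counts <- withr::with_seed(31, {
    m <- t(vapply(mus, function(mu) rnbinom(100, mu = mu, size = 1 / 0.05),
                  numeric(100)))
    dimnames(m) <- list(sprintf("g%03d", 1:200), sprintf("s%03d", 1:100))
    m
  })
  v_vst <- apply(vst_transform(counts), 1, var)
  v_log <- apply(log2(counts + 1), 1, var)
  bin <- cut(log10(mus), 5)
  ratio <- function(v) {
    bv <- tapply(v, bin, mean)
    max(bv) / min(bv)
  }
  expect_lt(ratio(v_vst), 3)
  expect_gt(ratio(v_log), 3)
  expect_lt(ratio(v_vst), ratio(v_log) / 2)
})

test_that("VST falls back to log2(x + 1) when the trend cannot be fitted", {
  m <- matrix(rep(c(2, 2, 2), each = 12), 12, 3,
              dimnames = list(sprintf("g%02d", 1:12), paste0("s", 1:3)))
  expect_warning(fit <- vst_fit(m), "falling back")
  expect_true(fit$fallback)
  expect_equal(vst_apply(matrix(7), fit), matrix(3))
})

test_that("quantile normalization equalizes column distributions", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3,
              dimnames = list(letters[1:3], c("s1", "s2")))
  q <- quantile_normalize(m)
  expect_equal(unname(q), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  ident <- cbind(s1 = c(3, 1, 2), s2 = c(3, 1, 2))
  rownames(ident) <- letters[1:3]
  expect_equal(quantile_normalize(ident), ident)

  # tie-free input: every column ends up with the same multiset of values
  # and the map is exactly idempotent (ties are averaged, which breaks the
  # multiset identity on tied data by design)
  r <- toy_counts(50, 4, seed = 13) + matrix(runif(200), 50)
  q1 <- quantile_normalize(r)
  expect_equal(quantile_normalize(q1), q1)  # idempotent
  sorted <- apply(q1, 2, sort)
  for (j in 2:4) expect_equal(sorted[, j], sorted[, 1])
})

test_that("apply_normalization routes methods and handles NoNorm", {
  counts <- toy_counts(60, 4, seed = 14) + 1
  em <- log2(counts + matrix(runif(240), 60))  # tie-free for the QN check
  expect_equal(apply_normalization(em, counts, "NoNorm"), em)
  ident <- counts[, c(1, 1, 1)]
  colnames(ident) <- paste0("s", 1:3)
  expect_equal(apply_normalization(log2(ident), ident, "TMM"), log2(ident))
  qn <- apply_normalization(em, counts, "QN")
  sorted <- apply(qn, 2, sort)
  for (j in 2:4) expect_equal(sorted[, j], sorted[, 1])
  vst <- apply_normalization(em, counts, "VST")
  expect_equal(dim(vst), dim(em))
  expect_error(apply_normalization(em, counts, "UQ"), "arg")
})
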