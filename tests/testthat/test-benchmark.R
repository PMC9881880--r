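test_that("grid enumeration produces the exact combination counts", {
  full <- enumerate_grid()
  expect_equal(nrow(full), 300L)  # 6 x 5 x 2 x 5
  expect_false(anyDuplicated(full$label) > 0)
  reduced <- enumerate_grid(exclude_estimators = "CS",
                            exclude_normalizations = "QN")
  expect_equal(nrow(reduced), 192L)
  one <- enumerate_grid(exclude_estimators = c("SCC", "PBG", "bspline", "CS"),
                        exclude_normalizations = setdiff(norm_methods(),
                                                         "NoNorm"),
                        exclude_datatypes = setdiff(data_types(), "l2cpm"))
  expect_equal(nrow(one), 2L)  # CT and noCT
  expect_error(enumerate_grid(exclude_estimators = "KNN"), "unknown")
  expect_true("PBG_CT_NoNorm_l2tpm" %in% full$label)
})

small_bench <- function() {
  cfg <- synthetic_config(n_genes = 40, n_samples = 30, n_hubs = 2,
                          targets_per_hub = 5, reference_coverage = 1,
                          reference_noise_edges = 0, seed = 3)
  sim <- generate_planted_dataset(cfg)
  list(sim = sim,
       combo = enumerate_grid()[enumerate_grid()$label ==
                                  "PCC_CT_NoNorm_l2cpm", ],
       gcfg = gni_config("c3net", threshold_mode = "top_k", k = 10))
}

test_that("run_combo labels records like the performance tables", {
  b <- small_bench()
  rec <- run_combo(b$sim$counts, b$combo, b$gcfg, b$sim$truth)
  expect_equal(rec$combination, "c3.PCC_CT_NoNorm_l2cpm")
  expect_named(rec, c("combination", "gni", "dataset", "precision", "tp",
                      "predicted", "p_value"))
  expect_true(rec$precision >= 0 && rec$precision <= 1)
  expect_equal(rec$tp / rec$predicted, rec$precision)
  rec2 <- run_combo(b$sim$counts, b$combo, b$gcfg, b$sim$truth)
  expect_identical(rec, rec2)
  # a strong-signal combo clears the random baseline by a wide margin
  bl <- random_baseline(rownames(b$sim$counts), rec$predicted,
                        n_networks = 10, ref = b$sim$truth, seed = 4)
  expect_gt(rec$precision, 10 * max(bl$mean_precision, 1e-9))
})

test_that("run_grid yields one record per dataset-combo-algorithm and resumes", {
  b <- small_bench()
  combos <- enumerate_grid(
    exclude_estimators = c("SCC", "PBG", "bspline", "CS"),
    exclude_normalizations = setdiff(norm_methods(), "NoNorm"),
    exclude_datatypes = setdiff(data_types(), "l2cpm"))
  counts_list <- list(D1 = b$sim$counts, D2 = b$sim$counts[, 1:20])
  recs <- run_grid(counts_list, combos, gni = c("c3net", "relnet"),
                   ref = b$sim$truth, gni_cfg = b$gcfg)
  expect_equal(nrow(recs), 2L * 2L * 2L)  # combos x gni x datasets
  expect_setequal(unique(recs$dataset), c("D1", "D2"))

  # resume: completed records are skipped, result identical
  partial <- recs[1:3, ]
  resumed <- run_grid(counts_list, combos, gni = c("c3net", "relnet"),
                      ref = b$sim$truth, gni_cfg = b$gcfg, done = partial)
  expect_equal(nrow(resumed), nrow(recs))
  expect_setequal(paste(resumed$combination, resumed$dataset),
                  paste(recs$combination, recs$dataset))
})

test_that("rank aggregation uses min-rank ties and median sorting", {
  recs <- expand.grid(combination = c("c1", "c2", "c3"),
                      dataset = c("D1", "D2"), stringsAsFactors = FALSE)
  recs$gni <- "c3net"
  recs$precision <- c(0.3, 0.2, 0.1, 0.1, 0.3, 0.2)
  rt <- rank_combos(recs)
  expect_equal(rt$combination[rt$median_rank == 1.5], "c2")
  expect_equal(sort(rt$median_rank), c(1.5, 2, 2.5))
  expect_equal(rt$best_rank[rt$combination == "c1"], 1)
  expect_equal(rt$worst_rank[rt$combination == "c3"], 3)
  expect_named(rt, c("combination", "median_rank", "mean_rank", "best_rank",
                     "worst_rank", "rank_D1", "rank_D2"))

  # invariant to row order
  shuffled <- recs[withr::with_seed(1, sample(nrow(recs))), ]
  expect_equal(rank_combos(shuffled), rt)

  # all-equal precisions share the minimum rank 1
  tied <- recs
  tied$precision <- 0.2
  expect_true(all(rank_combos(tied)$median_rank == 1))

  expect_error(rank_combos(recs[-1, ]), "missing combination-dataset")
})

test_that("sample-size curves reduce to the full run at full size", {
  b <- small_bench()
  full <- run_combo(b$sim$counts, b$combo, b$gcfg, b$sim$truth)
  curve <- sample_size_curve(b$sim$counts, b$combo, gni = "c3net",
                             sizes = c(10, 30), reps = 1, seed = 5,
                             ref = b$sim$truth, gni_cfg = b$gcfg)
  expect_equal(curve$precision[curve$size == 30], full$precision)
  again <- sample_size_curve(b$sim$counts, b$combo, gni = "c3net",
                             sizes = c(10, 30), reps = 1, seed = 5,
                             ref = b$sim$truth, gni_cfg = b$gcfg)
  expect_identical(curve, again)
  expect_warning(
    sample_size_curve(b$sim$counts, b$combo, gni = "c3net",
                      sizes = c(5, 30), reps = 1, seed = 5,
                      ref = b$sim$truth, gni_cfg = b$gcfg),
    "unstable")
  expect_error(
    sample_size_curve(b$sim$counts, b$combo, sizes = c(10, 500),
                      ref = b$sim$truth, gni_cfg = b$gcfg),
    "exceeds")
})

test_that("variance comparison pairs each dataset with its HV arm", {
  b <- small_bench()
  combos <- enumerate_grid(
    exclude_estimators = c("SCC", "PBG", "bspline", "CS"),
    exclude_normalizations = setdiff(norm_methods(), "NoNorm"),
    exclude_datatypes = setdiff(data_types(), "l2cpm"))
  recs <- variance_filter_comparison(list(D2 = b$sim$counts), combos,
                                     gni = "c3net", ref = b$sim$truth,
                                     gni_cfg = b$gcfg)
  expect_setequal(unique(recs$dataset), c("D2", "D2HV"))
  expect_equal(nrow(recs), 2L * nrow(combos) * 1L)
  hv <- variance_filter(b$sim$counts)
  expect_equal(nrow(hv), nrow(b$sim$counts) -
                 floor(0.2 * nrow(b$sim$counts)))
})
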