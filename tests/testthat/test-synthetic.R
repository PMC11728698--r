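test_that("generators are pure functions of the seed", {
  cfg <- sim_config(n_samples = 20, n_features = 150, richness_mean = 40,
                    seed = 7, fp_injection_rate = 10,
                    dropout_rate_at_min = 0.2, noise_sigma = 0.1,
                    unmapped_fraction = 0.1, split_fraction = 0.2)
  s1 <- generate_scenario(cfg)
  s2 <- generate_scenario(cfg)
  expect_identical(unclass(s1$truth), unclass(s2$truth))
  expect_identical(unclass(s1$est), unclass(s2$est))
  expect_identical(s1$mapping$common_id, s2$mapping$common_id)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  # different seed, different draw
  s3 <- generate_truth(sim_config(n_samples = 20, n_features = 150,
                                  richness_mean = 40, seed = 8))
  expect_false(identical(unclass(s1$truth), unclass(s3)))
})

test_that("truth tables hit the configured richness and are normalized", {
  cfg <- sim_config(n_samples = 343, n_features = 1000,
                    richness_mean = 200, seed = 11)
  truth <- generate_truth(cfg)
  expect_equal(dim(truth), c(1000L, 343L))
  expect_lt(max(abs(colSums(truth) - 1)), 1e-9)
  rich <- colSums(truth > 0)
  expect_lt(abs(median(rich) - 200) / 200, 0.1)
  # long-tailed abundances give Shannon diversity of the expected order
  shan <- apply(unclass(truth), 2, function(x) {
    x <- x[x > 0]; -sum(x * log(x))
  })
  expect_gt(median(shan), 4)
  expect_lt(median(shan), log(max(rich)))
})

test_that("degenerate abundance law gives uniform communities", {
  cfg <- sim_config(n_samples = 10, n_features = 100, richness_mean = 30,
                    abundance_sigma = 0, seed = 3)
  truth <- generate_truth(cfg)
  for (j in 1:10) {
    x <- unclass(truth)[, j]
    rs <- richness_shannon(x)
    expect_equal(unname(rs["shannon"]), log(rs["richness"]),
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("a zero error model reproduces the truth exactly", {
  cfg <- sim_config(n_samples = 10, n_features = 100, richness_mean = 30,
                    seed = 5)
  truth <- generate_truth(cfg)
  est <- simulate_profiler(truth, cfg)
  expect_identical(unclass(est), unclass(truth))
})

test_that("error modes push the expected metrics in the expected direction", {
  base <- sim_config(n_samples = 30, n_features = 300, richness_mean = 80,
                     seed = 13)
  truth <- generate_truth(base)

  over <- sim_config(n_samples = 30, n_features = 300, richness_mean = 80,
                     seed = 13, fp_injection_rate = 50)
  est <- simulate_profiler(truth, over)
  ev <- evaluate_sample_set(truth, est)
  expect_true(all(ev$per_sample$richness_diff > 0))
  expect_true(all(ev$per_sample$precision < 1))
  expect_true(all(ev$per_sample$sensitivity == 1))

  under <- sim_config(n_samples = 30, n_features = 300, richness_mean = 80,
                      seed = 13, dropout_rate_at_min = 0.8)
  ev2 <- evaluate_sample_set(truth, simulate_profiler(truth, under))
  expect_lt(median(ev2$per_sample$sensitivity), 1)
  expect_equal(median(ev2$per_sample$fpra), 0)
})

test_that("an injected confusion pair propagates through detection", {
  cfg <- sim_config(n_samples = 120, n_features = 120, richness_mean = 60,
                    seed = 17,
                    confusion_pairs = list(list("sp0001", "sp0002", 1.0)))
  truth <- generate_truth(cfg)
  est <- simulate_profiler(truth, cfg)
  # wherever the source was present it became an FN; the sink an FP when
  # absent from the truth
  src_present <- unclass(truth)["sp0001", ] > 0
  expect_true(all(unclass(est)["sp0001", src_present] == 0))
  sink_clean <- src_present & unclass(truth)["sp0002", ] == 0
  expect_true(all(unclass(est)["sp0002", sink_clean] > 0))
  pairs <- find_confused_pairs(truth, est, min_samples = 10,
                               r_threshold = 0.5)
  expect_true(any(pairs$fn_feature == "sp0001" &
                    pairs$fp_feature == "sp0002"))
  # a source outside the universe is an error
  bad <- sim_config(n_samples = 5, n_features = 10, richness_mean = 5,
                    confusion_pairs = list(list("nope", "sp0002", 1)))
  expect_error(simulate_profiler(generate_truth(bad), bad),
               "absent from feature universe")
})

test_that("generated mappings meet their structural contract", {
  cfg <- sim_config(n_samples = 5, n_features = 100, richness_mean = 20,
                    seed = 19, unmapped_fraction = 0.1, split_fraction = 0.2)
  ids <- sprintf("sp%04d", 1:100)
  m <- generate_mapping(ids, cfg)
  mapped <- unique(m$native_id)
  expect_equal(length(setdiff(ids, mapped)), 10L)   # exactly 10% unmapped
  k <- table(m$native_id)
  expect_equal(sum(k == 2), 20L)                    # exactly 20% split
  expect_true(all(m$weight[m$native_id %in% names(k)[k == 2]] == 0.5))
  expect_gt(max(table(m$common_id)), 1)             # some many-to-one
  # pure renaming when both fractions are zero
  cfg0 <- sim_config(n_samples = 5, n_features = 50, richness_mean = 20,
                     seed = 19)
  m0 <- generate_mapping(sprintf("x%02d", 1:50), cfg0)
  expect_equal(sort(unique(m0$native_id)), sort(sprintf("x%02d", 1:50)))
  expect_true(all(m0$weight == 1))
  expect_equal(length(unique(m0$common_id)), 50L)   # bijection
  expect_equal(nrow(m0), 50L)
})

test_that("mass conservation holds for generated mappings", {
  cfg <- sim_config(n_samples = 10, n_features = 80, richness_mean = 30,
                    seed = 23, unmapped_fraction = 0.15,
                    split_fraction = 0.25)
  truth <- generate_truth(cfg)
  m <- generate_mapping(rownames(truth), cfg)
  res <- project(truth, m)
  expect_lt(max(abs(res$projected_mass + res$lost_abundance -
                      colSums(truth))), 1e-9)
})

test_that("generated trees support the UniFrac contract", {
  ids <- c("a", "b", "c")
  tr <- generate_tree(ids, seed = 29)
  expect_equal(sort(tr$tip.label), ids)
  expect_equal(nrow(tr$edge), 4L)      # rooted binary: 2n - 2 edges
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(generate_tree(ids, seed = 29)),
                   ape::write.tree(tr))
  set.seed(31)
  u <- rand_profile(ids, p_zero = 0)
  expect_equal(weighted_unifrac(u, u, tr), 0)
  expect_error(generate_tree("only_one"), "at least 2")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(richness_mean = 2000, n_features = 1000),
               "richness_mean")
  expect_error(sim_config(dropout_rate_at_min = 1.5), "dropout")
  expect_error(sim_config(unmapped_fraction = 0.7, split_fraction = 0.5),
               "unmapped_fraction")
  expect_error(sim_config(confusion_pairs = list(list("a", "b", 2))),
               "fraction")
})
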