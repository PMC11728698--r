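test_that("confusion counts partition the support sets", {
  cc <- confusion_counts(c(0.5, 0.5, 0), c(0.4, 0, 0.6))
  expect_equal(cc, list(tp = 1L, fp = 1L, fn = 1L))
  ref <- c(a = 0.2, b = 0.3, c = 0.5)
  expect_equal(confusion_counts(ref, ref), list(tp = 3L, fp = 0L, fn = 0L))
  expect_equal(confusion_counts(ref, ref * 0), list(tp = 0L, fp = 0L, fn = 3L))
  expect_error(confusion_counts(ref, c(x = 1, y = 0, z = 0)),
               "mismatched feature indices")
  # named vectors are realigned before comparison
  expect_equal(confusion_counts(ref, ref[c("c", "a", "b")]),
               list(tp = 3L, fp = 0L, fn = 0L))
})

test_that("sensitivity and precision follow TP/(TP+FN), TP/(TP+FP)", {
  expect_equal(sensitivity_precision(list(tp = 3, fn = 1, fp = 0)),
               c(sensitivity = 0.75, precision = 1))
  expect_equal(sensitivity_precision(list(tp = 1, fn = 1, fp = 1)),
               c(sensitivity = 0.5, precision = 0.5))
  # zero denominators are undefined, not errors
  sp <- sensitivity_precision(list(tp = 0, fn = 0, fp = 2))
  expect_true(is.na(sp["sensitivity"]))
  expect_equal(unname(sp["precision"]), 0)
})

test_that("FPRA and FNRA sum abundances over the FP and FN sets", {
  ff <- fpra_fnra(c(0.5, 0.5, 0), c(0.4, 0, 0.6))
  expect_equal(ff, c(fpra = 0.6, fnra = 0.5))
  ref <- c(a = 0.3, b = 0.7)
  expect_equal(fpra_fnra(ref, ref), c(fpra = 0, fnra = 0))
  # estimate entirely on false positives
  expect_equal(fpra_fnra(c(1, 0, 0), c(0, 0.5, 0.5)),
               c(fpra = 1, fnra = 1))
  expect_error(fpra_fnra(c(0.5, 0.2), c(0.5, 0.5)), "normalized")
  # complement identity: FPRA + abundance over TP features = 1
  set.seed(2)
  for (i in 1:50) {
    u <- rand_profile(letters[1:8])
    v <- rand_profile(letters[1:8])
    ff <- fpra_fnra(u, v)
    expect_equal(unname(ff["fpra"] + sum(v[u > 0])), 1, tolerance = 1e-12)
  }
})

test_that("richness and Shannon diversity match closed forms", {
  expect_equal(richness_shannon(rep(0.25, 4)),
               c(richness = 4, shannon = log(4)))
  expect_equal(richness_shannon(c(1, 0, 0)), c(richness = 1, shannon = 0))
  expect_equal(richness_shannon(c(0.5, 0.25, 0.25)),
               c(richness = 3, shannon = 1.5 * log(2)))
})

test_that("Bray-Curtis matches hand values and stays in [0, 1]", {
  u <- c(a = 0.7, b = 0.3)
  expect_equal(bray_curtis(u, u), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(0.7, 0.3), c(0.5, 0.5)), 0.2)
  expect_true(is.na(bray_curtis(c(0, 0), c(0, 0))))
})

test_that("Bray-Curtis agrees with vegan and the brute-force oracle", {
  skip_if_not_installed("vegan")
  set.seed(31)
  for (i in 1:50) {
    u <- rand_profile(letters[1:10])
    v <- rand_profile(letters[1:10])
    expect_equal(bray_curtis(u, v), brute_bray(u, v), tolerance = 1e-12)
    expect_equal(bray_curtis(u, v),
                 as.numeric(vegan::vegdist(rbind(u, v), method = "bray")),
                 tolerance = 1e-9)
  }
})

test_that("weighted UniFrac behaves on elementary trees", {
  star2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(weighted_unifrac(c(A = 1, B = 0), c(A = 0, B = 1), star2), 1)
  expect_equal(weighted_unifrac(c(A = 0.5, B = 0.5), c(A = 0.5, B = 0.5),
                                star2), 0)
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  tr$edge.length <- NULL
  expect_error(weighted_unifrac(c(A = 1, B = 0, C = 0),
                                c(A = 0, B = 0, C = 1), tr),
               "branch lengths")
})

test_that("UniFrac reduces to Bray-Curtis on unit-branch star trees", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    labs <- sprintf("t%02d", 1:n)
    star <- ape::read.tree(
      text = paste0("(", paste0(labs, ":1", collapse = ","), ");"))
    u <- rand_profile(labs)
    v <- rand_profile(labs)
    expect_equal(weighted_unifrac(u, v, star), bray_curtis(u, v),
                 tolerance = 1e-12)
  }
})

test_that("metric implementations match brute-force oracles on random trees", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    tr <- rand_tree(n)
    u <- rand_profile(tr$tip.label)
    v <- rand_profile(tr$tip.label)
    expect_equal(weighted_unifrac(u, v, tr), brute_unifrac(u, v, tr),
                 tolerance = 1e-9)
    expect_equal(bray_curtis(u, v), brute_bray(u, v), tolerance = 1e-9)
    expect_equal(aitchison(u, v), brute_aitchison(u, v), tolerance = 1e-9)
  }
})

test_that("features missing from the tree are dropped with renormalization", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  u <- c(A = 0.5, B = 0.25, X = 0.25)
  v <- c(A = 0.25, B = 0.5, X = 0.25)
  expect_warning(d <- weighted_unifrac(u, v, tr), "absent from tree")
  expect_equal(d, weighted_unifrac(c(A = 2/3, B = 1/3),
                                   c(A = 1/3, B = 2/3), tr))
  expect_error(weighted_unifrac(u, v, tr, strict = TRUE), "absent from tree")
})

test_that("Aitchison distance matches its closed form and clr properties", {
  expect_equal(aitchison(c(0.4, 0.6), c(0.6, 0.4)),
               sqrt(2) * abs(log(0.4 / 0.6)), tolerance = 1e-12)
  u <- c(0.2, 0.3, 0.5)
  expect_equal(aitchison(u, u), 0)
  # scale invariance for zero-free vectors
  v <- c(0.5, 0.1, 0.4)
  expect_equal(aitchison(u, v), aitchison(3 * u, 3 * v), tolerance = 1e-12)
  # replacement must not exceed unit mass
  expect_error(aitchison(c(1, 0, 0), c(0.5, 0.25, 0.25), delta = 0.6),
               "exceeds unit mass")
})

test_that("distances satisfy the metric axioms on random profiles", {
  set.seed(41)
  tr <- rand_tree(8)
  for (i in 1:50) {
    u <- rand_profile(tr$tip.label)
    v <- rand_profile(tr$tip.label)
    for (f in list(bray_curtis,
                   function(a, b) weighted_unifrac(a, b, tr),
                   aitchison)) {
      expect_gte(f(u, v), 0)
      expect_equal(f(u, v), f(v, u), tolerance = 1e-12)
      expect_equal(f(u, u), 0, tolerance = 1e-12)
    }
    expect_lte(bray_curtis(u, v), 1)
    expect_lte(weighted_unifrac(u, v, tr), 1)
  }
})

test_that("support-set metrics ignore abundance rescaling", {
  set.seed(53)
  u <- rand_profile(letters[1:10])
  v <- rand_profile(letters[1:10])
  w <- v * 5
  cc1 <- confusion_counts(u, v)
  cc2 <- confusion_counts(u, w)
  expect_equal(cc1, cc2)
  expect_equal(sensitivity_precision(cc1), sensitivity_precision(cc2))
})

test_that("sample-set evaluation assembles per-sample metrics and medians", {
  set.seed(61)
  ref <- rand_table(15, 3)
  tree <- rand_tree(15, labels = rownames(ref))

  # perfect profiler: every metric at its ideal value
  ev <- evaluate_sample_set(ref, ref, tree = tree)
  expect_equal(ev$per_sample$sensitivity, rep(1, 3))
  expect_equal(ev$per_sample$precision, rep(1, 3))
  expect_equal(ev$per_sample$bray_curtis, rep(0, 3))
  expect_equal(ev$per_sample$unifrac, rep(0, 3))
  expect_equal(ev$per_sample$aitchison, rep(0, 3))
  expect_equal(ev$per_sample$richness_diff, rep(0, 3))
  expect_equal(unname(ev$medians["fpra"]), 0)

  # single sample: medians equal that sample's metrics
  one <- abundance_table(unclass(ref)[, 1, drop = FALSE], normalized = TRUE)
  est1 <- rand_table(15, 1)
  rownames(est1) <- rownames(ref)
  colnames(est1) <- colnames(one)
  ev1 <- evaluate_sample_set(one, abundance_table(est1, normalized = TRUE))
  expect_equal(unname(ev1$medians["bray_curtis"]),
               ev1$per_sample$bray_curtis[1])

  # disjoint sample sets are an error
  est2 <- ref
  colnames(est2) <- paste0("other_", colnames(ref))
  expect_error(evaluate_sample_set(ref, abundance_table(unclass(est2),
               normalized = TRUE)), "no shared samples")

  # features present in only one table are imputed as zero
  extra <- rbind(unclass(ref) * 0.5, extra_sp = rep(0.5, 3))
  ev3 <- evaluate_sample_set(ref, abundance_table(extra, normalized = TRUE))
  expect_equal(ev3$per_sample$fpra, rep(0.5, 3))
})

test_that("odd and even medians use the midpoint convention", {
  df <- data.frame(sample_id = c("a", "b", "c"),
                   tp = 1L, fp = 0L, fn = 0L,
                   bray_curtis = c(0.1, 0.2, 0.9))
  s <- summarize_tool(df)
  expect_equal(unname(s$medians["bray_curtis"]), 0.2)
  s2 <- summarize_tool(df[1:2, ])
  expect_equal(unname(s2$medians["bray_curtis"]), 0.15)
})
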