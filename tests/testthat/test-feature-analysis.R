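test_that("class entropy matches its closed form", {
  expect_equal(class_entropy(rep(c("agonist", "non-agonist"), c(53, 53))), 1.0)
  expect_equal(class_entropy(rep("agonist", 10)), 0.0)
  expect_equal(class_entropy(rep(c("a", "b"), c(75, 25))),
               -0.75 * log2(0.75) - 0.25 * log2(0.25))
  expect_error(class_entropy(character(0)), "empty")
})

test_that("information gain reproduces hand-countable contingencies", {
  labels <- factor(rep(c("agonist", "non-agonist"), each = 53))
  # perfect separator of balanced classes
  perfect <- c(rep(1, 53), rep(0, 53))
  expect_equal(unname(information_gain(perfect, labels)), 1.0)
  # constant feature carries nothing, under either discretizer
  expect_equal(unname(information_gain(rep(2.5, 106), labels)), 0.0)
  expect_equal(unname(information_gain(rep(2.5, 106), labels, "split")), 0.0)
  # 2x2 presence table 40/13 vs 10/43 against the direct-counting oracle
  v <- c(rep(1, 40), rep(0, 13), rep(1, 10), rep(0, 43))
  expect_equal(unname(information_gain(v, labels)),
               oracle_ig(v > 0, labels))
})

test_that("IG is bounded by H(C), agrees with the oracle, and ignores class naming", {
  set.seed(2024)
  for (rep in 1:40) {
    panel <- random_panel(n_per_class = sample(3:12, 1),
                          n_features = 8)
    H <- class_entropy(panel$labels)
    for (disc in c("presence", "split")) {
      ig <- information_gain(panel$x, panel$labels, disc)
      expect_true(all(ig >= 0 & ig <= H + 1e-12))
      flipped <- factor(panel$labels,
                        levels = rev(levels(panel$labels)))
      expect_equal(information_gain(panel$x, flipped, disc), ig)
    }
    ig_pres <- information_gain(panel$x, panel$labels, "presence")
    brute <- apply(panel$x > 0, 2, oracle_ig, labels = panel$labels)
    expect_equal(unname(ig_pres), unname(brute), tolerance = 1e-12)
  }
})

test_that("the best binary split dominates presence coding and finds clean cuts", {
  labels <- factor(rep(c("a", "b"), each = 20))
  # all molecules nonzero: presence coding is blind, a threshold is not —
  # the situation behind features present in every molecule yet informative
  v <- c(runif(20, 1, 2), runif(20, 3, 4))
  expect_equal(unname(information_gain(v, labels, "presence")), 0)
  expect_equal(unname(information_gain(v, labels, "split")), 1.0)
  set.seed(9)
  panel <- random_panel(8, 10)
  expect_true(all(information_gain(panel$x, panel$labels, "split") + 1e-12 >=
                    information_gain(panel$x, panel$labels, "presence")))
})

test_that("ranking recovers planted corrals and orders ties by index", {
  sc <- corral_scheme()
  labels <- factor(rep(c("agonist", "non-agonist"), each = 6))
  x <- matrix(0, 12, 800, dimnames = list(NULL, feature_label(1:800)))
  planted <- c(100, 350, 717)
  x[1:6, planted] <- 1            # noiseless: present in all agonists only
  x[, 50] <- 2                    # constant everywhere
  rk <- rank_features(x, labels, scheme = sc)
  expect_setequal(rk$index[rk$ig_bits > 0], planted)
  expect_equal(rk$index[1:3], planted)   # equal IG = 1 ties break by index
  expect_equal(rk$ig_bits[1:3], rep(1, 3))
  expect_equal(rk$range_low[rk$index == 601], 3000)
})

test_that("two disjoint single-molecule classes make every occupied corral perfect", {
  labels <- factor(c("agonist", "non-agonist"))
  x <- matrix(0, 2, 800, dimnames = list(NULL, feature_label(1:800)))
  x[1, c(10, 20)] <- 1
  x[2, c(30, 40)] <- 1
  rk <- rank_features(x, labels)
  expect_setequal(rk$index[rk$ig_bits > 0], c(10, 20, 30, 40))
  expect_equal(rk$ig_bits[rk$ig_bits > 0], rep(1, 4))
})

test_that("presence counts, zero-corral counts and their set identity hold", {
  panel <- random_panel(5, 20)
  x <- panel$x
  labels <- panel$labels
  expect_equal(unname(presence_counts(x)), unname(colSums(x > 0)))
  x[, 3] <- 0
  expect_equal(unname(presence_counts(x)[3]), 0)
  x2 <- x
  x2[, 1] <- 1
  expect_equal(unname(presence_counts(x2)[1]), 10L)

  all_zero <- matrix(0, 4, 800)
  expect_equal(zero_corral_count(all_zero), 800L)
  # class occupying exactly k corrals leaves 800 - k empty
  y <- matrix(0, 3, 800)
  y[1, 1:5] <- 1
  y[2, 3:9] <- 1
  expect_equal(zero_corral_count(y), 800L - 9L)
  # dataset zero set = intersection of the per-class zero sets
  za <- zero_corral_count(x, labels, "agonist")
  zn <- zero_corral_count(x, labels, "non-agonist")
  both <- sum(colSums(x[labels == "agonist", ] > 0) == 0 &
                colSums(x[labels == "non-agonist", ] > 0) == 0)
  expect_equal(zero_corral_count(x), both)
  expect_true(zero_corral_count(x) <= min(za, zn))
  expect_error(zero_corral_count(x, labels, "nope"), "empty")
})

test_that("mean profiles are idempotent, linear and match the brute mean", {
  v <- runif(30)
  x <- rbind(v, v)
  labels <- factor(c("a", "a"))
  expect_equal(unname(mean_intensity_profile(x, labels, "a")), v)
  x2 <- rbind(0 * v, v)
  expect_equal(unname(mean_intensity_profile(x2, labels, "a")), v / 2)
  set.seed(3)
  panel <- random_panel(10, 15)
  prof <- mean_intensity_profile(panel$x, panel$labels, "agonist")
  expect_equal(unname(prof),
               unname(apply(panel$x[panel$labels == "agonist", ], 2, mean)))
})

test_that("the fitted model reports its panel and classifies new molecules", {
  sim <- simulate_spectra(n_per_class = 12, seed = 21)
  m <- cimvf_matrix(sim$spectra)
  fit <- cimvf_fit(m, sim$labels)
  expect_s3_class(fit, "cimvf_fit")
  expect_equal(fit$entropy, 1.0)
  expect_true(all(sim$truth$planted$feature %in% fit$selected))
  sm <- summary(fit)
  expect_true(all(c("feature", "frequency", "ig_bits") %in%
                    names(sm$informative)))
  expect_equal(length(coef(fit)), 800L)
  expect_output(print(fit), "informative corrals")
  # a training descriptor is its own nearest neighbour
  pred <- predict(fit, m[3, ])
  expect_equal(as.character(pred), as.character(sim$labels[3]))
  expect_error(cimvf_fit(m, rep("agonist", nrow(m))), "two non-empty classes")
})
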