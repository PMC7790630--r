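# The three-source worked case: prey-group sets {A}, {A,B}, {C}.
three_source_records <- function() {
  make_records(4, source_id = c("s1", "s2", "s2", "s3"),
               prey_name = c("A", "A", "B", "C"),
               predator_name = "pred")
}

test_that("the {A},{A,B},{C} case gives expectations 4/3, 7/3, 3", {
  recs <- three_source_records()
  # oracle: exhaustive enumeration of all 6 source orderings
  oracle <- enum_accumulation(list(s1 = "A", s2 = c("A", "B"), s3 = "C"))
  expect_equal(oracle, c(4 / 3, 7 / 3, 3))
  exact <- accumulation_expectation(recs)
  expect_equal(exact$expected_count, oracle)
  # Monte Carlo converges to the same values
  mc <- accumulation_curve(recs, n_perm = 3000, seed = 2)
  expect_equal(mc$curve$mean_count, oracle, tolerance = 0.05)
})

test_that("closed form matches exhaustive enumeration on random source sets", {
  set.seed(51)
  for (rep in 1:5) {
    n <- sample(3:5, 1)
    sets <- lapply(seq_len(n), function(i) {
      sample(LETTERS[1:6], sample(1:4, 1))
    })
    names(sets) <- paste0("s", seq_len(n))
    recs <- do.call(rbind, lapply(names(sets), function(s) {
      make_records(length(sets[[s]]), source_id = s, prey_name = sets[[s]],
                   record_id = paste(s, sets[[s]]))
    }))
    expect_equal(accumulation_expectation(recs)$expected_count,
                 enum_accumulation(sets))
  }
})

test_that("mean curve is monotone, exact at x = n, and seed-reproducible", {
  cfg <- default_synthetic_config(seed = 9)
  recs <- simulate_dataset(cfg)
  grouped <- map_taxa(recs, synthetic_group_scheme(cfg))$records
  acc <- accumulation_curve(grouped, n_perm = 50, seed = 7)
  expect_true(all(diff(acc$curve$mean_count) >= 0))
  expect_equal(acc$curve$mean_count[acc$n_sources], acc$total_groups)
  # permutation-independent endpoint for any seed
  acc2 <- accumulation_curve(grouped, n_perm = 50, seed = 99)
  expect_equal(acc2$curve$mean_count[acc2$n_sources], acc$total_groups)
  # identical seed, identical output; caller RNG untouched
  expect_equal(accumulation_curve(grouped, n_perm = 50, seed = 7), acc)
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(accumulation_curve(grouped, n_perm = 5, seed = 1))
  expect_equal(runif(1), before)
})

test_that("sources sharing a single prey group give a flat unit curve", {
  recs <- make_records(3, source_id = c("s1", "s2", "s3"), prey_name = "A")
  acc <- accumulation_curve(recs, n_perm = 20, seed = 1)
  expect_equal(acc$curve$mean_count, rep(1, 3))
  expect_error(accumulation_curve(make_records(0)), "no sources")
})

test_that("implementation agrees with vegan's accumulation estimators", {
  # independent cross-check: build the source x group incidence matrix and
  # compare against vegan's analytic and permutation estimators
  cfg <- default_synthetic_config(seed = 13)
  recs <- simulate_dataset(cfg)
  grouped <- map_taxa(recs, synthetic_group_scheme(cfg))$records
  inc <- table(grouped$source_id, grouped$prey_name) > 0
  exact <- accumulation_expectation(grouped)
  # suppressWarnings: vegan warns from an internal cor() on a constant
  # incidence column, unrelated to the richness estimate compared here
  veg <- suppressWarnings(
    vegan::specaccum(as.matrix(inc) * 1, method = "exact"))
  expect_equal(exact$expected_count, as.numeric(veg$richness),
               tolerance = 1e-10)
  mc <- accumulation_curve(grouped, n_perm = 500, seed = 3)
  veg_r <- vegan::specaccum(as.matrix(inc) * 1, method = "random",
                            permutations = 500)
  expect_equal(mc$curve$mean_count, as.numeric(veg_r$richness),
               tolerance = 0.15)
})

test_that("negative-exponential fit recovers parameters from noiseless curves", {
  for (truth in list(c(20, 0.5), c(45, 0.12), c(8, 1.4))) {
    x <- 1:10
    y <- truth[1] * (1 - exp(-truth[2] * x))
    fit <- fit_negative_exponential(data.frame(x = x, mean_count = y))
    expect_false(fit$flagged)
    expect_equal(fit$S_max, truth[1], tolerance = 1e-6)
    expect_equal(fit$k, truth[2], tolerance = 1e-6)
    expect_lt(fit$rss, 1e-10)
  }
})

test_that("a flat curve yields a flagged boundary fit at the plateau value", {
  fit <- fit_negative_exponential(data.frame(x = 1:6, mean_count = rep(7, 6)))
  expect_true(fit$flagged)
  expect_equal(fit$S_max, 7, tolerance = 1e-3)
  expect_error(fit_negative_exponential(data.frame(x = 1:2, y = 1:2)),
               "at least 3")
})

test_that("fitted asymptotes order two synthetic regions by generative richness", {
  set.seed(61)
  rich <- sector_sim(predators = c("p1", "p2"),
                     prey = paste0("q", 1:12),
                     p = matrix(runif(24, 0.05, 0.3), nrow = 2),
                     n_sources = 10, miss_occurrence = 0, miss_diet = 0)
  poor <- sector_sim(predators = c("p1", "p2"),
                     prey = paste0("q", 1:3),
                     p = matrix(0.3, nrow = 2, ncol = 3),
                     n_sources = 10, miss_occurrence = 0, miss_diet = 0)
  cfg <- synthetic_config(list(Atlantic = rich, Indian = poor), seed = 17)
  recs <- simulate_dataset(cfg)
  parts <- split_by_sector(recs)
  fits <- lapply(parts[c("Atlantic", "Indian")], function(r) {
    fit_negative_exponential(accumulation_curve(r, n_perm = 100, seed = 1))
  })
  expect_gt(fits$Atlantic$S_max, fits$Indian$S_max)
})
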