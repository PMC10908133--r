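std_pair <- function() {
  ch <- tiny_cohort()
  list(A = standardize_plot(ch$serotonin[[1]]),
       B = standardize_plot(ch$dopamine[[1]]))
}

test_that("convex mixing endpoints are bit-exact and midpoints average", {
  p <- std_pair()
  expect_identical(mix_plots(p$A, p$B, 1)$plot$current, p$A$current)
  expect_identical(mix_plots(p$A, p$B, 0)$plot$current, p$B$current)
  half <- mix_plots(p$A, p$B, 0.5)
  expect_equal(half$plot$current, (p$A$current + p$B$current) / 2)
  expect_lt(abs(mean(half$plot$current)), 1e-12)
  expect_equal(half$ratio, 0.5)
})

test_that("mixing validates shapes, standardization and the ratio range", {
  p <- std_pair()
  expect_error(mix_plots(p$A, p$B, 1.2), "\\[0, 1\\]")
  expect_error(mix_plots(p$A, p$B, -0.1), "\\[0, 1\\]")
  raw <- tiny_cohort()$serotonin[[2]]
  expect_error(mix_plots(raw, p$B, 0.5), "standardized")
  small <- p$B
  small$current <- small$current[1:8, , drop = FALSE]
  small$potential_axis <- small$potential_axis[1:8]
  expect_error(mix_plots(p$A, small, 0.5), "shape")
})

test_that("any convex mixture of standardized plots keeps zero mean", {
  p <- std_pair()
  for (r in c(0.1, 0.33, 0.77)) {
    expect_lt(abs(mean(mix_plots(p$A, p$B, r)$plot$current)), 1e-12)
  }
})

test_that("training-set generation sizes, labels and determinism", {
  ch <- tiny_cohort()
  one_animal <- ch$serotonin[1:4] # single animal's repetitions
  set_a <- generate_training_set(one_animal, ch$dopamine, seed = 3)
  expect_equal(length(set_a$ratio), 5000L) # 5000 per animal, one animal
  expect_true(all(set_a$ratio >= 0 & set_a$ratio <= 1))
  small1 <- generate_training_set(ch$serotonin, ch$dopamine, n_total = 50,
                                  seed = 8)
  small2 <- generate_training_set(ch$serotonin, ch$dopamine, n_total = 50,
                                  seed = 8)
  expect_identical(small1$x, small2$x)
  expect_identical(small1$ratio, small2$ratio)
  expect_error(generate_training_set(list(), ch$dopamine), "non-empty")
})

test_that("the source cohort reproduces the study's group structure", {
  ch <- tiny_cohort()
  expect_length(ch$serotonin, 28L) # 7 animals x 4 repetitions
  expect_length(ch$dopamine, 21L)  # 3 animals x 7 repetitions
  ser_animals <- unique(vapply(ch$serotonin, function(p) p$meta$animal, ""))
  dop_animals <- unique(vapply(ch$dopamine, function(p) p$meta$animal, ""))
  expect_length(ser_animals, 7L)
  expect_length(dop_animals, 3L)
  expect_true(all(vapply(ch$serotonin, function(p) p$meta$analyte, "") ==
                    "serotonin"))
})
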