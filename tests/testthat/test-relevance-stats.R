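test_that("frequency_profile tabulates counts and degeneracies", {
  fp <- frequency_profile(rep("x", 5))
  expect_identical(fp$m_k, c(`5` = 1L))
  expect_identical(fp$n_obs, 5L)

  fp <- frequency_profile(letters[1:4])
  expect_identical(fp$m_k, c(`1` = 4L))

  fp <- frequency_profile(c("a", "a", "b", "c"))
  expect_identical(sort(as.integer(fp$counts)), c(1L, 1L, 2L))
  expect_identical(fp$m_k, c(`1` = 2L, `2` = 1L))

  expect_error(frequency_profile(character(0)), "empty sample")
  expect_error(new_freq_profile(c(a = 2, b = 2), n_states = 1), "n_states")
  # matrix rows as observations
  fp <- frequency_profile(rbind(c(1, -1), c(1, -1), c(-1, 1)))
  expect_identical(fp$m_k, c(`1` = 1L, `2` = 1L))
})

test_that("resolution and relevance match hand-evaluated entropies", {
  expect_equal(resolution(frequency_profile(rep("x", 7))), 0)
  expect_equal(resolution(frequency_profile(letters[1:4])), log(4))
  fp <- frequency_profile(c("a", "a", "b", "c"))
  expect_equal(resolution(fp), -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(resolution(fp), 1.0397208, tolerance = 1e-6)
  expect_equal(relevance(fp), log(2), tolerance = 1e-12)
  # constant and all-distinct samples carry no relevance
  expect_equal(relevance(frequency_profile(rep("x", 7))), 0)
  expect_equal(relevance(frequency_profile(letters[1:4])), 0)
})

test_that("entropies are label-invariant and obey 0 <= H[k] <= H[s] <= log N", {
  set.seed(11)
  for (i in 1:50) {
    k <- random_partition(sample(5:60, 1))
    fp <- new_freq_profile(k)
    br <- brute_entropies(k)
    expect_equal(resolution(fp), unname(br["hs"]), tolerance = 1e-12)
    expect_equal(relevance(fp), unname(br["hk"]), tolerance = 1e-12)
    expect_gte(relevance(fp), 0)
    expect_lte(relevance(fp), resolution(fp) + 1e-12)
    expect_lte(resolution(fp), log(fp$n_obs) + 1e-12)
    # relabeling outcomes changes nothing
    fp2 <- new_freq_profile(sample(k))
    expect_equal(resolution(fp2), resolution(fp))
    expect_equal(relevance(fp2), relevance(fp))
  }
})

test_that("coding cost is N * resolution plus regret", {
  fp <- frequency_profile(rep("x", 9))
  expect_equal(coding_cost(fp, 0), 0)
  fp <- frequency_profile(c("a", "a", "b", "c"))
  expect_equal(coding_cost(fp, 1), 4 * 1.0397208 + 1, tolerance = 1e-6)
  expect_equal(coding_cost(fp, 2.5) - 2.5, 4 * resolution(fp))
  expect_error(coding_cost(fp, -0.1), "non-negative")
})

test_that("random ball-in-box baseline has the right limits", {
  bl <- random_baseline(40, c(1, 5, 40^3), reps = 30, seed = 7)
  expect_equal(bl$resolution[1], 0)
  expect_equal(bl$relevance[1], 0)
  # L >> N^2: collisions vanish, all balls distinct
  expect_equal(bl$resolution[3], log(40), tolerance = 0.01)
  expect_lt(bl$relevance[3], 0.05)
  expect_true(all(bl$relevance <= bl$resolution + 1e-12))
  # reproducible under the seed
  bl2 <- random_baseline(40, c(1, 5, 40^3), reps = 30, seed = 7)
  expect_identical(bl, bl2)
})
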