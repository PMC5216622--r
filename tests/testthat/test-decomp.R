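two_species_asm <- function(w_warm, w_cold, total = 100) {
  tibble::tibble(
    species = rep(c("A", "B"), 2),
    period = rep(c("warm", "cold"), each = 2),
    count = as.integer(c(w_warm * total, w_cold * total))
  )
}

test_that("species weights are counts over the included-species total", {
  asm <- two_species_asm(c(0.5, 0.5), c(0.3, 0.7))
  expect_equal(species_weights(asm, "warm")$weight, c(0.5, 0.5))
  expect_equal(species_weights(asm, "cold")$weight, c(0.3, 0.7))
  expect_equal(species_weights(asm, "cold", "B")$weight, 1)
  expect_error(species_weights(asm, "warm", c("A", "C")),
               class = "paleosize_missing_species_error")
  zero <- tibble::tibble(species = "A", period = "warm", count = 0L)
  expect_error(species_weights(zero, "warm"), class = "paleosize_degenerate_error")
})

test_that("observation weights spread species weight over measured cysts", {
  w <- tibble::tibble(species = c("A", "B"), period = "warm",
                      weight = c(0.3, 0.7))
  obs <- tibble::tibble(species = c("A", "A", "B"), period = "warm",
                        diameter = c(10, 12, 20))
  ow <- observation_weights(obs, w)
  expect_equal(ow$weight, c(0.15, 0.15, 0.7))
  expect_equal(sum(ow$weight), 1)

  w_one <- tibble::tibble(species = "A", period = "warm", weight = 1)
  one <- observation_weights(obs[obs$species == "A", ], w_one)
  expect_equal(one$weight, c(0.5, 0.5))

  # weighted species without observations: warn, drop, renormalise
  expect_warning(ow2 <- observation_weights(obs[obs$species == "A", ], w),
                 "no observations")
  expect_equal(sum(ow2$weight), 1)
  # observation without a weight: error
  expect_error(observation_weights(obs, w[1, ]),
               class = "paleosize_missing_species_error")
})

test_that("zero-SD community mean reduces to the weighted species means", {
  specs <- tibble::tibble(species = c("A", "B"), period = "warm",
                          mean = c(10, 20), n = c(4L, 6L))
  obs <- zero_sd_obs(specs)
  asm <- two_species_asm(c(0.3, 0.7), c(0.5, 0.5))
  cm <- community_mean_intra_inter(obs, asm, "warm")
  expect_equal(cm$mean, 0.3 * 10 + 0.7 * 20)
  expect_equal(cm$level, "intra+inter")
  expect_equal(cm$n_obs, 10L)
})

test_that("equal species and measurement weights give the grand mean", {
  obs <- tibble::tibble(species = rep(c("A", "B"), each = 5), period = "warm",
                        diameter = c(rnorm(5, 10), rnorm(5, 20)))
  asm <- two_species_asm(c(0.5, 0.5), c(0.5, 0.5))
  cm <- community_mean_intra_inter(obs, asm, "warm")
  expect_equal(cm$mean, mean(obs$diameter))
})

test_that("pooled species means weight periods by sample size", {
  specs <- tibble::tibble(species = "Islandinium minutum",
                          period = c("warm", "cold"),
                          mean = c(34.08, 37.96), n = c(52L, 51L))
  obs <- zero_sd_obs(specs)
  expect_equal(unname(species_pooled_means(obs)),
               (52 * 34.08 + 51 * 37.96) / 103)
  expect_equal(unname(species_pooled_means(obs, pooling = "period_mean")),
               (34.08 + 37.96) / 2)
  single <- tibble::tibble(species = "X", period = "warm", diameter = 31.2)
  expect_equal(unname(species_pooled_means(single)), 31.2)
  expect_error(species_pooled_means(single, "Y"),
               class = "paleosize_missing_species_error")
})

test_that("interspecific mean is the weighted mean of fixed trait values", {
  w <- tibble::tibble(species = c("A", "B"), period = "warm",
                      weight = c(0.25, 0.75))
  cm <- community_mean_inter(c(A = 10, B = 20), w)
  expect_equal(cm$mean, 17.5)
  expect_equal(cm$n_obs, 2L)
  expect_error(community_mean_inter(c(A = 10), w),
               class = "paleosize_missing_species_error")
})

test_that("pure composition shift is all interspecific", {
  specs <- tibble::tibble(species = rep(c("A", "B"), 2),
                          period = rep(c("warm", "cold"), each = 2),
                          mean = c(10, 20, 10, 20), n = 5L)
  obs <- zero_sd_obs(specs)
  asm <- two_species_asm(c(0.5, 0.5), c(0.25, 0.75))
  d <- decompose_size_change(obs, asm, "warm", "cold")$decomposition
  expect_equal(d$delta_total, 2.5)
  expect_equal(d$delta_inter, 2.5)
  expect_equal(d$delta_intra, 0)
})

test_that("pure within-species shift under fixed weights is all intraspecific", {
  specs <- tibble::tibble(species = rep(c("A", "B"), 2),
                          period = rep(c("warm", "cold"), each = 2),
                          mean = c(10, 20, 12, 22), n = 5L)
  obs <- zero_sd_obs(specs)
  asm <- two_species_asm(c(0.5, 0.5), c(0.5, 0.5))
  d <- decompose_size_change(obs, asm, "warm", "cold")$decomposition
  expect_equal(d$delta_total, 2)
  expect_equal(d$delta_inter, 0)
  expect_equal(d$delta_intra, 2)
})

test_that("decomposition arithmetic reproduces the published community rows", {
  d <- decompose_from_means(31.80, 36.24, 33.30, 34.53)
  expect_equal(d$delta_total, 4.44)
  expect_equal(d$delta_intra, 4.44 - 1.23)
  expect_equal(d$fraction_intra + d$fraction_inter, 1)
  # delta_total = 0: fractions undefined, reported missing
  d0 <- decompose_from_means(30, 30, 28, 29)
  expect_true(is.na(d0$fraction_intra))
})

test_that("conservation identity holds exactly on random inputs", {
  set.seed(99)
  for (i in 1:25) {
    n_sp <- sample(2:6, 1)
    sp <- paste0("S", seq_len(n_sp))
    obs <- dplyr::bind_rows(lapply(sp, function(s) {
      dplyr::bind_rows(lapply(c("warm", "cold"), function(p) {
        m <- sample(3:9, 1)
        tibble::tibble(species = s, period = p,
                       diameter = abs(rnorm(m, runif(1, 20, 50), 5)) + 1)
      }))
    }))
    asm <- tibble::tibble(species = rep(sp, 2),
                          period = rep(c("warm", "cold"), each = n_sp),
                          count = sample(1:200, 2 * n_sp, replace = TRUE))
    d <- decompose_size_change(obs, asm, "warm", "cold")$decomposition
    expect_identical(d$delta_intra + d$delta_inter, d$delta_total)
    if (d$delta_total != 0) {
      expect_equal(d$fraction_intra + d$fraction_inter, 1)
    }
  }
})

test_that("interspecific delta vanishes when per-period weights are equal", {
  set.seed(5)
  sp <- c("A", "B", "C")
  obs <- dplyr::bind_rows(lapply(sp, function(s) {
    tibble::tibble(species = s, period = rep(c("warm", "cold"), each = 5),
                   diameter = abs(rnorm(10, runif(1, 20, 50), 4)) + 1)
  }))
  asm <- tibble::tibble(species = rep(sp, 2),
                        period = rep(c("warm", "cold"), each = 3),
                        count = rep(c(40L, 25L, 35L), 2))
  d <- decompose_size_change(obs, asm, "warm", "cold")$decomposition
  expect_equal(d$delta_inter, 0)
})

test_that("linear and volume percent changes follow the sphere model", {
  expect_equal(round(linear_change_percent(34.08, 37.96), 1), 11.4)
  expect_equal(linear_change_percent(30, 30), 0)
  expect_equal(linear_change_percent(1, 2), 100)
  expect_equal(round(volume_change_percent(34.08, 37.96)), 38)
  expect_equal(round(volume_change_percent(47.75, 51.68)), 27)
  expect_equal(volume_change_percent(1, 2), 700)
})
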