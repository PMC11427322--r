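test_that("Sierpinski carpet follows the 8^level recurrence exactly", {
  expect_equal(sum(gen_sierpinski(1)), 8)
  expect_equal(dim(gen_sierpinski(1)), c(3L, 3L))
  expect_equal(sum(gen_sierpinski(2)), 64)
  for (lev in 1:4)
    expect_equal(mean(gen_sierpinski(lev)), (8 / 9)^lev)
  expect_error(gen_sierpinski(0), "between 1 and 6")
  expect_error(gen_sierpinski(7), "between 1 and 6")
})

test_that("fBm surfaces are seeded, bounded, and smoother at higher H", {
  f1 <- gen_fbm_surface(0.5, 128, seed = 10)
  f2 <- gen_fbm_surface(0.5, 128, seed = 10)
  expect_identical(unclass(f1), unclass(f2))
  expect_gte(min(f1), 0); expect_lte(max(f1), 1)
  expect_false(identical(unclass(f1), unclass(gen_fbm_surface(0.5, 128, seed = 11))))

  rough <- statistical_fractal(gen_fbm_surface(0.1, 256, seed = 1))
  smooth <- statistical_fractal(gen_fbm_surface(0.9, 256, seed = 1))
  expect_gt(rough, smooth)
  expect_error(gen_fbm_surface(1.2, 128, 1), "\\(0, 1\\)")
  expect_error(gen_fbm_surface(0.5, 100, 1), "power of 2")
})

test_that("spectral images carry their planted exponent", {
  expect_error(gen_spectral_image(4, 128, 1), "\\[0, 3\\]")
  flat <- gen_spectral_image(0, 256, seed = 2)
  expect_equal(one_over_f_fluctuation(flat), 0, tolerance = 0.15)
  pink <- gen_spectral_image(1, 256, seed = 2)
  expect_equal(one_over_f_fluctuation(pink), 1, tolerance = 0.15)
})

test_that("office scenes hit their greenery target within tolerance", {
  zero <- gen_office_scene(scene_spec(0, seed = 5))
  expect_equal(greenery_percentage(zero), 0)

  for (target in c(10, 30, 55)) {
    sc <- gen_office_scene(scene_spec(target, background = "texture",
                                      seed = target))
    measured <- greenery_percentage(sc)   # extractor re-measures the scene
    expect_lte(abs(measured - target), 2)
    expect_equal(attr(sc, "greenery_measured"), measured)
  }

  ## bit-reproducible per seed
  a <- gen_office_scene(scene_spec(25, seed = 3))
  b <- gen_office_scene(scene_spec(25, seed = 3))
  expect_identical(a$pixels, b$pixels)
})

test_that("photo sets are dealt in snake order with balanced greenery", {
  specs <- default_scene_specs(n = 12, max_green = 55, width = 128,
                               height = 64, seed = 40)
  ps <- gen_photo_set(specs, n_groups = 4)
  expect_length(ps$images, 12)
  expect_equal(as.vector(table(ps$manifest$group)), rep(3L, 4))
  grand <- mean(ps$manifest$greenery_target)
  group_means <- tapply(ps$manifest$greenery_target, ps$manifest$group, mean)
  expect_true(all(abs(group_means - grand) <= 5))

  ps2 <- gen_photo_set(specs, n_groups = 4)
  expect_equal(ps$manifest, ps2$manifest)
  expect_error(gen_photo_set(specs, n_groups = 5), "divide")
})

test_that("rating generator honours its latent model", {
  feats <- tibble::tibble(photo_id = sprintf("p%02d", 1:12),
                          sqrt_greenery = seq(0, 7.5, length.out = 12),
                          color_fractal = rep(2.5, 12))
  ## degenerate: no noise, no effects -> every response is the intercept
  spec0 <- rating_sim_spec(n_photos = 12, n_groups = 4, photos_per_group = 3,
                           raters_per_group = 5, a = 3, b = 0, c = 0,
                           sigma = 0, seed = 1)
  r0 <- gen_ratings(feats, spec0)
  expect_true(all(r0$response == 3L))
  expect_equal(nrow(r0), 4 * 5 * 3 * 11)

  ## positive greenery slope, tiny noise: photo means track sqrt greenery
  specb <- rating_sim_spec(n_photos = 12, n_groups = 4, photos_per_group = 3,
                           raters_per_group = 30, a = 2, b = 0.25, c = 0,
                           sigma = 0.1, seed = 2)
  rb <- gen_ratings(feats, specb)
  agg <- aggregate_by_photo(score_ratings(rb)[, c("photo_id", "overall")])
  merged <- dplyr::inner_join(feats, agg, by = "photo_id")
  expect_gt(correlate(merged$sqrt_greenery, merged$overall_mean), 0.9)

  ## responses stay on the 1-5 scale with no mass loss
  expect_true(all(rb$response %in% 1:5))

  ## determinism
  expect_equal(gen_ratings(feats, specb), rb)
})

test_that("rating noise weakens the greenery correlation monotonically", {
  feats <- tibble::tibble(photo_id = sprintf("p%02d", 1:12),
                          sqrt_greenery = seq(0, 7.5, length.out = 12),
                          color_fractal = rep(2.5, 12))
  mean_abs_r <- vapply(c(0.1, 1, 3), function(sg) {
    rs <- vapply(1:8, function(s) {
      sp <- rating_sim_spec(n_photos = 12, n_groups = 4, photos_per_group = 3,
                            raters_per_group = 10, a = 3, b = 0.15, c = 0,
                            sigma = sg, seed = 100 + s)
      agg <- aggregate_by_photo(
        score_ratings(gen_ratings(feats, sp))[, c("photo_id", "overall")])
      m <- dplyr::inner_join(feats, agg, by = "photo_id")
      correlate(m$sqrt_greenery, m$overall_mean)
    }, numeric(1))
    mean(abs(rs))
  }, numeric(1))
  expect_true(all(diff(mean_abs_r) < 0))
})
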