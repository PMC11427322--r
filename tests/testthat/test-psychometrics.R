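test_that("reverse scoring reflects the scale and is an involution", {
  expect_equal(reverse_score(5), 1)
  expect_equal(reverse_score(3), 3)
  expect_equal(reverse_score(1), 5)
  for (x in 1:5) expect_equal(reverse_score(reverse_score(x)), x)
  expect_error(reverse_score(0), "\\[1, 5\\]")
  expect_error(reverse_score(2.5), "\\[1, 5\\]")
})

test_that("the default scale has the 4+4+3 layout with reversals only in Extent", {
  sc <- ircs_scale()
  expect_equal(nrow(sc$items), 11)
  expect_equal(as.vector(table(sc$items$subscale)[c("BeingAway", "Fascination", "Extent")]),
               c(4L, 4L, 3L))
  expect_true(all(sc$items$subscale[sc$items$reverse] == "Extent"))
  expect_error(ircs_scale(reverse = "BA1"), "only allowed on Extent")
})

test_that("IRCS scoring follows the subscale-mean rule", {
  sc <- ircs_scale(reverse = character())   # no reversals for clean arithmetic
  expect_equal(score_ircs(flat_response(3, sc), sc),
               list(being_away = 3, fascination = 3, extent = 3, overall = 3))

  resp <- flat_response(4, sc)
  resp[c("FS2", "FS3", "FS4", "FS8")] <- 2
  resp[c("EX1", "EX2", "EX3")] <- 3
  expect_equal(score_ircs(resp, sc)$overall, 3)

  ## all three Extent items reversed: 5 -> 1
  sc_rev <- ircs_scale()
  all5 <- flat_response(5, sc_rev)
  s <- score_ircs(all5, sc_rev)
  expect_equal(s$extent, 1)
  expect_equal(s$overall, (5 + 5 + 1) / 3)

  ## midpoint pattern is reverse-invariant
  expect_equal(score_ircs(flat_response(3, sc_rev), sc_rev)$overall, 3)

  expect_error(score_ircs(flat_response(3)[-1]), "missing item")
})

test_that("scoring is invariant to item presentation order and bounded", {
  resp <- withr::with_seed(12, {
    r <- flat_response(3); r[] <- sample(1:5, 11, replace = TRUE); r
  })
  shuffled <- withr::with_seed(13, resp[sample(names(resp))])
  expect_equal(score_ircs(resp), score_ircs(shuffled))
  s <- score_ircs(resp)
  expect_gte(s$overall, min(s$being_away, s$fascination, s$extent))
  expect_lte(s$overall, max(s$being_away, s$fascination, s$extent))
})

test_that("restorative experience score is the 5-item mean", {
  expect_equal(score_restorative_experience(rep(1, 5)), 1)
  expect_equal(score_restorative_experience(5:1), 3)
  expect_equal(score_restorative_experience(c(2, 3, 2, 4, 3)), 2.8)
  expect_error(score_restorative_experience(1:4), "exactly 5")
})

test_that("long-format scoring matches per-response scoring", {
  sc <- ircs_scale()
  resp <- withr::with_seed(7, {
    r <- flat_response(3); r[] <- sample(1:5, 11, replace = TRUE); r
  })
  long <- tibble::tibble(participant_id = "p1", photo_id = "ph1",
                         item_id = names(resp), response = unname(resp))
  tab <- score_ratings(long, sc)
  ref <- score_ircs(resp, sc)
  expect_equal(tab$overall, ref$overall)
  expect_equal(tab$extent, ref$extent)

  incomplete <- long[-1, ]
  expect_error(score_ratings(incomplete, sc), "incomplete")
})

test_that("photo aggregation uses mean and sample SD, ordered by photo", {
  scores <- tibble::tibble(photo_id = c("a", "a", "a"),
                           overall = c(2, 3, 4))
  agg <- aggregate_by_photo(scores)
  expect_equal(agg$overall_mean, 3)
  expect_equal(agg$overall_sd, 1)

  one <- aggregate_by_photo(tibble::tibble(photo_id = "b", overall = 4.2))
  expect_equal(one$overall_mean, 4.2)
  expect_equal(one$overall_sd, 0)

  two <- aggregate_by_photo(tibble::tibble(
    photo_id = c("z", "y", "z", "y"), overall = c(1, 2, 3, 4)))
  expect_equal(two$photo_id, c("y", "z"))       # order-stable by photo id
  expect_equal(two$overall_mean, c(3, 2))
  expect_error(aggregate_by_photo(scores[0, ]), "empty")
})

test_that("identical raters give zero photo SDs", {
  ratings <- dplyr::bind_rows(lapply(1:6, function(p)
    tibble::tibble(participant_id = paste0("p", p), photo_id = "ph1",
                   item_id = ircs_scale()$items$item_id,
                   response = rep(c(4L, 2L, 3L), c(4, 4, 3)))))
  agg <- aggregate_by_photo(score_ratings(ratings))
  expect_equal(agg$overall_sd, 0)
  expect_equal(agg$being_away_mean, 4)
})

test_that("correlate matches closed forms and validates input", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate(x, 2 * x + 1), 1)
  expect_equal(correlate(x, -x), -1)
  expect_equal(correlate(x, c(1, 3, 2, 4)), 0.8)
  expect_error(correlate(x, rep(2, 4)), "zero variance")
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("scale JSON round trip preserves the definition", {
  path <- withr::local_tempfile(fileext = ".json")
  sc <- ircs_scale(reverse = c("EX1", "EX3"))
  write_scale(sc, path)
  back <- read_scale(path)
  expect_equal(back$items, sc$items)
})
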