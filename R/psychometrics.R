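#' IRCS scale definition
#'
#' The 11-item Indoor Restorative Characteristic Scale: four Being Away
#' items, four Fascination items, and three Extent items, each rated 1
#' ("not at all") to 5 ("very much"). Reverse-keyed items occur only in the
#' Extent subscale; which Extent items are reversed is configurable (all
#' three by default) because item wording travels with the survey, not with
#' the scoring code.
#'
#' @param reverse Character vector of reverse-keyed item ids (must be
#'   Extent items).
#' @return An object of class `ircs_scale` with a tibble `items`
#'   (`item_id`, `subscale`, `reverse`) and `response_range`.
#' @export
ircs_scale <- function(reverse = c("EX1", "EX2", "EX3")) {
  items <- tibble::tibble(
    item_id = c("BA1", "BA7", "BA9", "BA10",
                "FS2", "FS3", "FS4", "FS8",
                "EX1", "EX2", "EX3"),
    subscale = c(rep("BeingAway", 4), rep("Fascination", 4), rep("Extent", 3)))
  if (!all(reverse %in% items$item_id))
    stop("unknown reverse item id(s): ",
         paste(setdiff(reverse, items$item_id), collapse = ", "))
  bad <- reverse[items$subscale[match(reverse, items$item_id)] != "Extent"]
  if (length(bad))
    stop("reverse flags are only allowed on Extent items: ",
         paste(bad, collapse = ", "))
  items$reverse <- items$item_id %in% reverse
  structure(list(items = items, response_range = c(1L, 5L)),
            class = "ircs_scale")
}

#' Read / write a scale definition as JSON
#'
#' @param path JSON file with fields `items` (item_id, subscale, reverse)
#'   and `response_range`.
#' @return [read_scale()]: an `ircs_scale`; [write_scale()]: `path`.
#' @export
read_scale <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- ircs_scale(reverse = x$items$item_id[as.logical(x$items$reverse)])
  if (!identical(sort(sc$items$item_id), sort(x$items$item_id)))
    stop("scale JSON does not match the 11-item IRCS layout")
  sc
}

#' @rdname read_scale
#' @param scale An `ircs_scale`.
#' @export
write_scale <- function(scale, path) {
  jsonlite::write_json(list(items = scale$items,
                            response_range = scale$response_range),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Reverse-score a Likert response
#'
#' Reflects a response on the 1-5 scale: `6 - x`. Applying it twice is the
#' identity.
#'
#' @param x Integer response(s) in `[1, 5]`.
#' @return `6 - x`.
#' @export
reverse_score <- function(x) {
  if (any(x != round(x)) || any(x < 1) || any(x > 5))
    stop("responses must be integers in [1, 5]")
  6 - x
}

#' Score one IRCS response
#'
#' Inverts reverse-keyed items, averages items within each subscale, and
#' takes the overall restorativeness score as the mean of the three subscale
#' means (not the mean of all 11 items). Missing items are an error, never
#' imputed.
#'
#' @param responses Named integer vector (names are item ids) with all 11
#'   items present and values in `[1, 5]`.
#' @param scale An [ircs_scale()] definition.
#' @return List with `being_away`, `fascination`, `extent`, `overall`.
#' @export
score_ircs <- function(responses, scale = ircs_scale()) {
  items <- scale$items
  missing <- setdiff(items$item_id, names(responses))
  if (length(missing))
    stop("missing item response(s): ", paste(missing, collapse = ", "))
  x <- responses[items$item_id]
  if (any(x != round(x)) || any(x < 1) || any(x > 5))
    stop("responses must be integers in [1, 5]")
  x[items$reverse] <- reverse_score(x[items$reverse])
  sub <- tapply(x, items$subscale, mean)
  res <- list(being_away = unname(sub["BeingAway"]),
              fascination = unname(sub["Fascination"]),
              extent = unname(sub["Extent"]))
  res$overall <- mean(c(res$being_away, res$fascination, res$extent))
  res
}

#' Score the 5-item restorative experience scale
#'
#' @param responses Five integer responses in `[1, 5]`.
#' @return Their arithmetic mean.
#' @export
score_restorative_experience <- function(responses) {
  if (length(responses) != 5) stop("exactly 5 item responses required")
  if (any(responses != round(responses)) || any(responses < 1) ||
      any(responses > 5))
    stop("responses must be integers in [1, 5]")
  mean(responses)
}

#' Score a long-format rating table
#'
#' Scores every (participant, photo) response set in a long-format table.
#' Incomplete response sets (fewer than the 11 scale items) are an error.
#'
#' @param ratings Data frame with columns `participant_id`, `photo_id`,
#'   `item_id`, `response`.
#' @param scale An [ircs_scale()] definition.
#' @return Tibble with one row per (participant, photo):
#'   `participant_id`, `photo_id`, `being_away`, `fascination`, `extent`,
#'   `overall`.
#' @export
score_ratings <- function(ratings, scale = ircs_scale()) {
  req <- c("participant_id", "photo_id", "item_id", "response")
  if (!all(req %in% names(ratings)))
    stop("ratings must contain ", paste(req, collapse = ", "))
  items <- scale$items
  unknown <- setdiff(unique(ratings$item_id), items$item_id)
  if (length(unknown))
    stop("unknown item id(s): ", paste(unknown, collapse = ", "))
  r <- ratings
  if (any(r$response != round(r$response)) || any(r$response < 1) ||
      any(r$response > 5))
    stop("responses must be integers in [1, 5]")
  idx <- match(r$item_id, items$item_id)
  r$value <- ifelse(items$reverse[idx], 6 - r$response, r$response)
  r$subscale <- items$subscale[idx]
  counts <- dplyr::count(r, .data$participant_id, .data$photo_id)
  if (any(counts$n != nrow(items)))
    stop("incomplete response set(s): every (participant, photo) pair must ",
         "answer all ", nrow(items), " items")
  wide <- dplyr::summarise(
    dplyr::group_by(r, .data$participant_id, .data$photo_id, .data$subscale),
    score = mean(.data$value), .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(wide, .data$participant_id, .data$photo_id),
    being_away = .data$score[.data$subscale == "BeingAway"],
    fascination = .data$score[.data$subscale == "Fascination"],
    extent = .data$score[.data$subscale == "Extent"],
    .groups = "drop")
  out$overall <- (out$being_away + out$fascination + out$extent) / 3
  dplyr::arrange(out, .data$participant_id, .data$photo_id)
}

#' Aggregate participant scores to photo-level summaries
#'
#' Per-photo arithmetic mean and sample standard deviation (n - 1
#' denominator; SD = 0 when a photo has a single rater) of each score.
#'
#' @param scores Data frame with `photo_id` and one or more numeric score
#'   columns (e.g. the output of [score_ratings()]).
#' @return Tibble ordered by `photo_id` with `n_raters` and
#'   `<score>_mean` / `<score>_sd` columns.
#' @export
aggregate_by_photo <- function(scores) {
  if (nrow(scores) == 0) stop("empty score table")
  if (!"photo_id" %in% names(scores)) stop("scores must contain photo_id")
  num_cols <- names(scores)[vapply(scores, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "photo_id")
  if (length(num_cols) == 0) stop("no numeric score columns")
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  out <- dplyr::summarise(
    dplyr::group_by(scores, .data$photo_id),
    n_raters = dplyr::n(),
    dplyr::across(dplyr::all_of(num_cols),
                  list(mean = mean, sd = sd0),
                  .names = "{.col}_{.fn}"),
    .groups = "drop")
  dplyr::arrange(out, .data$photo_id)
}

#' Pearson correlation with validation
#'
#' @param x,y Numeric vectors of equal length, at least 3, each with
#'   nonzero variance.
#' @return Pearson product-moment correlation in `[-1, 1]`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}
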