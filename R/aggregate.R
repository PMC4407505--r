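#' Z-score reaction times within participants
#'
#' Standardizes each participant's RTs to mean 0 and sample SD 1, removing
#' individual differences in overall judgment speed before RTs are averaged
#' across participants.
#'
#' @param ratings tibble with at least `participant_id` and `rt`.
#' @return `ratings` with an added `z_rt` column.
#' @export
zscore_rt <- function(ratings) {
  stopifnot(all(c("participant_id", "rt") %in% names(ratings)))
  dplyr::mutate(
    dplyr::group_by(tibble::as_tibble(ratings), .data$participant_id),
    z_rt = {
      if (dplyr::n() < 2) {
        stop("participant ", .data$participant_id[1],
             " has fewer than 2 reaction times", call. = FALSE)
      }
      s <- stats::sd(.data$rt)
      if (s == 0) {
        stop("participant ", .data$participant_id[1],
             " has zero reaction-time variance", call. = FALSE)
      }
      (.data$rt - mean(.data$rt)) / s
    }
  ) |> dplyr::ungroup()
}

#' Per-image mean ratings and mean z-scored RT
#'
#' Averages preference, naturalness and within-participant z-scored RT over
#' participants for each image. RTs are z-scored first (via [zscore_rt()] if
#' the column is absent); missing ratings are tolerated (means are over the
#' available raters).
#'
#' @param ratings tibble with `participant_id`, `image_id`, `preference`,
#'   `naturalness`, `rt` and optionally `z_rt`.
#' @return Tibble with `image_id`, `mean_preference`, `mean_naturalness`,
#'   `mean_z_rt`.
#' @export
aggregate_means <- function(ratings) {
  if (!"z_rt" %in% names(ratings)) ratings <- zscore_rt(ratings)
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ratings), .data$image_id),
    mean_preference = mean(.data$preference, na.rm = TRUE),
    mean_naturalness = mean(.data$naturalness, na.rm = TRUE),
    mean_z_rt = mean(.data$z_rt, na.rm = TRUE),
    .groups = "drop"
  )
}

#' Counterbalance-order check
#'
#' For every image, compares the ratings given by the two task-order groups
#' (preference-first vs. naturalness-first) with a two-sample t test. A
#' nonsignificant minimum p across images supports pooling the groups when
#' averaging. The default is Welch's unequal-variance test; `"paired"` pairs
#' the i-th participant (by id order) of each group and uses a paired t test
#' (df = group size - 1).
#'
#' @param ratings tibble with `participant_id`, `image_id`, `group` and the
#'   rating column.
#' @param measure which rating to compare.
#' @param variant `"welch"` or `"paired"`.
#' @return List with `per_image` (tibble: `image_id`, `t`, `df`, `p`),
#'   `min_p`, `t_at_min` and `variant`. Images where a group has fewer than
#'   two raters are skipped with a warning.
#' @export
order_effect_test <- function(ratings,
                              measure = c("preference", "naturalness"),
                              variant = c("welch", "paired")) {
  measure <- match.arg(measure)
  variant <- match.arg(variant)
  stopifnot(all(c("image_id", "group", measure) %in% names(ratings)))
  groups <- sort(unique(ratings$group))
  if (length(groups) != 2) stop("exactly two counterbalance groups required")
  ratings <- tibble::as_tibble(ratings)
  skipped <- 0L
  rows <- lapply(split(ratings, ratings$image_id), function(d) {
    a <- d[d$group == groups[1], ]
    b <- d[d$group == groups[2], ]
    if (nrow(a) < 2 || nrow(b) < 2) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    xa <- a[[measure]][order(a$participant_id)]
    xb <- b[[measure]][order(b$participant_id)]
    tt <- if (variant == "paired") {
      if (nrow(a) != nrow(b)) {
        skipped <<- skipped + 1L
        return(NULL)
      }
      stats::t.test(xa, xb, paired = TRUE)
    } else {
      stats::t.test(xa, xb)
    }
    tibble::tibble(image_id = d$image_id[1],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
  if (skipped > 0) {
    warning(skipped, " image(s) skipped (a group had fewer than 2 raters)")
  }
  per_image <- dplyr::bind_rows(rows)
  if (nrow(per_image) == 0) stop("no image had enough raters in both groups")
  i_min <- which.min(per_image$p)
  list(per_image = per_image, min_p = per_image$p[i_min],
       t_at_min = per_image$t[i_min], variant = variant)
}
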