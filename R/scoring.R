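#' Scale scoring and internal consistency
#'
#' Each item's distress code is rescaled to \[0, 1\] so the 30-item total
#' ranges 0-30, higher meaning more family distress.
#'
#' @name fts_scoring
NULL

#' Rescale a distress code to the unit interval
#'
#' Ladder codes map by `(code - 1)/9` (1 -> 0, 10 -> 1); comm4 codes by
#' `code/3`. Both maps are the unique affine rescalings of the code range
#' onto \[0, 1\] and are monotone in distress. Vectorised; `NA` passes
#' through.
#'
#' @param code Distress code(s) from [code_response()].
#' @param item Item definition row.
#' @return Value(s) in \[0, 1\].
#' @export
transform_item <- function(code, item) {
  if (item$format == "ladder10") {
    ok <- is.na(code) | (code %in% 1:10)
    if (!all(ok)) stop("invalid ladder code for ", item$item_id,
                       call. = FALSE)
    (code - 1) / 9
  } else {
    ok <- is.na(code) | (code %in% 0:3)
    if (!all(ok)) stop("invalid comm4 code for ", item$item_id,
                       call. = FALSE)
    code / 3
  }
}

#' Total scale score for one informant
#'
#' Sums the 0-1 transformed values over the final scale items. When some
#' items are missing but the answered fraction is at least the
#' completeness threshold, the sum is prorated by `k / n_answered` (so a
#' fully-missing-at-random informant keeps the 0-30 metric); below the
#' threshold the score is marked invalid.
#'
#' @param codes Named vector of distress codes, names are item ids; `NA`
#'   for missing. All names must be known item ids.
#' @param items Item-definition table; only rows with
#'   `in_final_scale = TRUE` are scored.
#' @param completeness Minimum answered fraction for a valid score
#'   (default 0.9).
#' @return List with `total` (in \[0, 30\], `NA` if invalid),
#'   `n_items_answered`, and `valid`.
#' @export
total_score <- function(codes, items, completeness = 0.9) {
  scale_items <- items[items$in_final_scale, ]
  unknown <- setdiff(names(codes), items$item_id)
  if (length(unknown) > 0) {
    stop("responses to unknown item ids: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  k <- nrow(scale_items)
  vals <- vapply(seq_len(k), function(i) {
    item <- scale_items[i, ]
    code <- codes[item$item_id]
    if (is.null(code) || length(code) == 0 || is.na(code)) {
      return(NA_real_)
    }
    transform_item(as.numeric(code), item)
  }, numeric(1))
  n_ans <- sum(!is.na(vals))
  if (n_ans / k >= completeness) {
    total <- sum(vals, na.rm = TRUE) * k / n_ans
    list(total = total, n_items_answered = n_ans, valid = TRUE)
  } else {
    list(total = NA_real_, n_items_answered = n_ans, valid = FALSE)
  }
}

#' Score every informant in a cohort
#'
#' @param responses Long raw response table (`family_id`, `informant_id`,
#'   `role`, `item_id`, `response`).
#' @param items Item-definition table.
#' @param completeness Passed to [total_score()].
#' @param comm_map Distress coding map for comm4 items.
#' @return Tibble of scale scores: `informant_id`, `family_id`,
#'   `reporter_group`, `n_items_answered`, `total`, `valid`.
#' @export
score_cohort <- function(responses, items, completeness = 0.9,
                         comm_map = comm4_map()) {
  check_items(items)
  responses <- tibble::as_tibble(responses)
  scale_ids <- items$item_id[items$in_final_scale]
  resp <- responses[responses$item_id %in% scale_ids, ]
  informants <- unique(resp[, c("informant_id", "family_id", "role")])
  item_rows <- split(items, items$item_id)

  dplyr::bind_rows(lapply(seq_len(nrow(informants)), function(i) {
    inf <- informants[i, ]
    d <- resp[resp$informant_id == inf$informant_id, ]
    codes <- stats::setNames(rep(NA_real_, length(scale_ids)), scale_ids)
    for (j in seq_len(nrow(d))) {
      item <- item_rows[[d$item_id[j]]]
      codes[d$item_id[j]] <- code_response(d$response[j], item, comm_map)
    }
    sc <- total_score(codes, items, completeness)
    tibble::tibble(
      informant_id = inf$informant_id,
      family_id = inf$family_id,
      reporter_group = ifelse(inf$role == "child", "child", "adult"),
      n_items_answered = sc$n_items_answered,
      total = sc$total,
      valid = sc$valid
    )
  }))
}

#' Standardized Cronbach's alpha
#'
#' Internal consistency from the mean off-diagonal inter-item Pearson
#' correlation: `k * rbar / (1 + (k - 1) * rbar)` for `k` items.
#'
#' @param x Numeric matrix of transformed item values, informants in rows
#'   and items in columns. Needs >= 2 items, >= 3 informants, and
#'   non-degenerate item variances.
#' @return Alpha in (-Inf, 1\].
#' @export
standardized_alpha <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 items", call. = FALSE)
  if (nrow(x) < 3) stop("need at least 3 informants", call. = FALSE)
  v <- apply(x, 2, stats::var)
  if (any(v == 0 | is.na(v))) {
    bad <- colnames(x)[v == 0 | is.na(v)]
    if (is.null(bad)) bad <- which(v == 0 | is.na(v))
    stop("degenerate item (zero variance): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(x)
  k <- ncol(x)
  rbar <- mean(r[lower.tri(r)])
  k * rbar / (1 + (k - 1) * rbar)
}
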