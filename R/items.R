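#' Item definitions for the Family Togetherness Scale
#'
#' The FTS is a 30-item screener of family relational distress. Twenty-six
#' items use a visual 10-step ladder (integer responses 1-10); four items
#' about communication in the face of specific stressors use a categorical
#' response ("Quarrel", "Not talk about it", "Talk calmly", "You have not
#' had the problem") coded to a 0-3 distress scale.
#'
#' Positively worded ladder items (where a high raw response means good
#' functioning, e.g. "How much love is in your family?") are reverse coded
#' so that, after coding, higher numbers always represent more distress.
#' Negatively worded items (quarrels, blame, misunderstanding, idleness,
#' unequal punishment, members going their own way) are kept as answered.
#' Communication items are never reverse coded: their distress coding is
#' fixed by the option map (see [comm4_map()]).
#'
#' @return A tibble with one row per item and columns `item_id`
#'   (`"FTS01"`..`"FTS30"`), `format` (`"ladder10"` or `"comm4"`),
#'   `reverse_coded` (logical), `label_key` (short mnemonic), and
#'   `in_final_scale` (all `TRUE` here).
#' @seealso [battery_items()] for the 66-item development battery,
#'   [code_response()] for the coding rules.
#' @export
fts_items <- function() {
  path <- system.file("extdata", "fts_items.csv", package = "ftsvalid",
                      mustWork = TRUE)
  defs <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(defs) |>
    dplyr::mutate(
      reverse_coded = as.logical(.data$reverse_coded),
      in_final_scale = as.logical(.data$in_final_scale)
    )
}

#' The 66-item development battery template
#'
#' The scale was trimmed from a battery of 66 candidate items shared by the
#' adult and child forms. The original non-selected item wordings are not
#' reproduced here; the template carries the 30 final items plus 36
#' placeholder ladder items (`BAT31`..`BAT66`) so that item screening can be
#' exercised end to end on simulated cohorts of the study's shape.
#'
#' @return A tibble with the same columns as [fts_items()]; the 30 final
#'   items have `in_final_scale = TRUE`, the 36 placeholders `FALSE`.
#' @export
battery_items <- function() {
  extra <- tibble::tibble(
    item_id = sprintf("BAT%02d", 31:66),
    format = "ladder10",
    reverse_coded = FALSE,
    label_key = sprintf("placeholder_%02d", 31:66),
    in_final_scale = FALSE
  )
  dplyr::bind_rows(fts_items(), extra)
}

#' Distress coding map for the categorical communication items
#'
#' The four communication items ask how the family responds to a specific
#' stressor (money, school, extended family, the biggest recent problem).
#' Responses are coded onto a 0-3 distress scale in which endorsement means
#' a code of 2 or 3. Qualitative findings identified avoidant and
#' aggressive communication as distress indicators, so "Quarrel" (3) and
#' "Not talk about it" (2) endorse, while "Talk calmly" (0) and "You have
#' not had the problem" (0) do not. The map is a package default, not a
#' published key; pass an alternative named vector to [code_response()] to
#' override it.
#'
#' @return A named integer vector mapping response labels to distress codes.
#' @export
comm4_map <- function() {
  c("Talk calmly" = 0L,
    "You have not had the problem" = 0L,
    "Not talk about it" = 2L,
    "Quarrel" = 3L)
}

# internal: validate an item-definition table
check_items <- function(items) {
  req <- c("item_id", "format", "reverse_coded")
  missing_cols <- setdiff(req, names(items))
  if (length(missing_cols) > 0) {
    stop("item definition table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(items$format), c("ladder10", "comm4"))
  if (length(bad) > 0) {
    stop("unknown item format(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(items$reverse_coded & items$format == "comm4")) {
    stop("comm4 items cannot be reverse coded", call. = FALSE)
  }
  if (anyDuplicated(items$item_id)) {
    stop("duplicate item_id in item definitions", call. = FALSE)
  }
  invisible(items)
}
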