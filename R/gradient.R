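#' Item coding, endorsement, and gradient scores
#'
#' Candidate items are screened with the Goldberg gradient technique: each
#' item's endorsement proportion among informants from case families is
#' compared with the proportion among informants from non-case families.
#' Ladder items (1-10) endorse in the 6-10 range; coded communication
#' items (0-3) endorse in the 2-3 range. Items are first coded so that a
#' higher number always means more distress.
#'
#' @name item_analysis
NULL

#' Code a raw item response to the distress orientation
#'
#' Ladder responses stay on 1-10, reverse coded (`11 - raw`) when a high
#' raw response means good functioning. Communication responses are mapped
#' onto 0-3 via the option map (default [comm4_map()]). Vectorised over
#' `raw`.
#'
#' @param raw Raw response: integer 1-10 for `ladder10` items, an option
#'   label for `comm4` items. `NA` passes through as `NA`.
#' @param item One-row item definition (as in [fts_items()]), or a list
#'   with `format` and `reverse_coded`.
#' @param comm_map Named integer vector mapping comm4 option labels to
#'   distress codes.
#' @return Integer distress code(s): 1-10 (ladder) or 0-3 (comm4).
#' @export
code_response <- function(raw, item, comm_map = comm4_map()) {
  fmt <- item$format
  if (fmt == "ladder10") {
    raw <- suppressWarnings(as.numeric(raw))
    ok <- is.na(raw) | (raw %in% 1:10)
    if (!all(ok)) {
      stop("invalid response for ladder item ", item$item_id,
           ": must be an integer in 1-10", call. = FALSE)
    }
    code <- as.integer(raw)
    if (isTRUE(item$reverse_coded)) code <- 11L - code
    code
  } else if (fmt == "comm4") {
    raw <- as.character(raw)
    ok <- is.na(raw) | raw %in% names(comm_map)
    if (!all(ok)) {
      stop("invalid response for communication item ", item$item_id,
           ": unknown option \"", raw[!ok][1], "\"", call. = FALSE)
    }
    unname(comm_map[raw])
  } else {
    stop("unknown item format: ", fmt, call. = FALSE)
  }
}

#' Is a distress code an endorsement?
#'
#' @param code Distress-oriented code (output of [code_response()]).
#' @param item Item definition row (only `format` is used).
#' @return Logical: `TRUE` in the 6-10 range for ladder items, the 2-3
#'   range for comm4 items; `NA` stays `NA`.
#' @export
endorsed <- function(code, item) {
  if (item$format == "ladder10") code >= 6 else code >= 2
}

#' Endorsement proportion over non-missing codes
#'
#' @param codes Vector of distress codes, possibly with `NA`.
#' @param item Item definition row.
#' @return List with `proportion` (fraction of non-missing codes endorsed)
#'   and `n` (the denominator used).
#' @export
endorsement_proportion <- function(codes, item) {
  e <- endorsed(codes, item)
  n <- sum(!is.na(e))
  if (n == 0) {
    stop("undefined endorsement proportion: all responses missing for ",
         item$item_id, call. = FALSE)
  }
  list(proportion = sum(e, na.rm = TRUE) / n, n = n)
}

#' Gradient score of an item
#'
#' The difference between the endorsement proportion among case informants
#' and among non-case informants. Positive gradients indicate
#' discrimination in the expected direction (cases endorse more).
#'
#' @param p_case,p_noncase Endorsement proportions in \[0, 1\].
#' @return `p_case - p_noncase`, a difference in \[-1, 1\].
#' @examples
#' gradient_score(0.59, 0) # the quarrels item: 59 percentage points
#' @export
gradient_score <- function(p_case, p_noncase) {
  stopifnot(all(p_case >= 0 & p_case <= 1),
            all(p_noncase >= 0 & p_noncase <= 1))
  p_case - p_noncase
}

#' Gradient table over a cohort
#'
#' Computes, for every item and reporter group (adults pooled across
#' families; children likewise), the endorsement proportions among case and
#' non-case informants and their gradient. Informants from dropped families
#' are excluded; missing responses are excluded item-wise.
#'
#' @param responses Long response table: `family_id`, `informant_id`,
#'   `role`, `item_id`, `response` (raw). Each informant contributes at
#'   most one response per item.
#' @param labels Caseness table from [triangulate_cohort()].
#' @param items Item-definition table (e.g. [battery_items()]).
#' @param comm_map Distress coding map for comm4 items.
#' @return Tibble with one row per (item, reporter group): `item_id`,
#'   `reporter_group`, `p_case`, `p_noncase`, `gradient`, `n_case`,
#'   `n_noncase`.
#' @export
gradient_table <- function(responses, labels, items,
                           comm_map = comm4_map()) {
  check_items(items)
  responses <- tibble::as_tibble(responses)
  unlabeled <- setdiff(unique(responses$family_id), labels$family_id)
  if (length(unlabeled) > 0) {
    stop("informants from unlabeled family: ",
         paste(unlabeled, collapse = ", "), call. = FALSE)
  }
  lab <- labels[labels$label != "dropped", c("family_id", "label")]
  dat <- dplyr::inner_join(responses, lab, by = "family_id")
  dat$reporter_group <- ifelse(dat$role == "child", "child", "adult")

  out <- lapply(seq_len(nrow(items)), function(i) {
    item <- items[i, ]
    d <- dat[dat$item_id == item$item_id, ]
    if (nrow(d) == 0) return(NULL)
    code <- code_response(d$response, item, comm_map)
    e <- endorsed(code, item)
    d <- tibble::tibble(reporter_group = d$reporter_group,
                        label = d$label, e = e)
    d <- d[!is.na(d$e), ]
    dplyr::bind_rows(lapply(c("adult", "child"), function(g) {
      dg <- d[d$reporter_group == g, ]
      nc <- sum(dg$label == "case")
      nn <- sum(dg$label == "noncase")
      if (nc == 0 || nn == 0) return(NULL)
      p1 <- sum(dg$e[dg$label == "case"]) / nc
      p0 <- sum(dg$e[dg$label == "noncase"]) / nn
      tibble::tibble(item_id = item$item_id, reporter_group = g,
                     p_case = p1, p_noncase = p0,
                     gradient = gradient_score(p1, p0),
                     n_case = nc, n_noncase = nn)
    }))
  })
  dplyr::bind_rows(out)
}
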