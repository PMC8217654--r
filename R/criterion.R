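#' Criterion reference: triangulated caseness for family distress
#'
#' The study classifies each family as a case of family relational distress,
#' a non-case, or dropped, by triangulating three imperfect criterion
#' sources: the community leader's 4-point rating of the family, 4-point
#' self-ratings from each participating family member, and a consensus
#' clinical GARF score (1-99) derived from interviews. A family is a case
#' if flagged as distressed by at least two sources, a non-case if flagged
#' by none, and dropped from analysis if flagged by exactly one.
#'
#' @name criterion_reference
NULL

check_rating <- function(rating, what) {
  if (length(rating) == 0 || anyNA(rating) ||
      !all(rating %in% 1:4)) {
    stop("invalid ", what, " rating: must be 1, 2, 3 or 4", call. = FALSE)
  }
  invisible(rating)
}

check_garf <- function(garf) {
  if (length(garf) != 1 || is.na(garf) || !is.numeric(garf) ||
      garf != round(garf) || garf < 1 || garf > 99) {
    stop("invalid GARF rating: must be an integer in 1-99", call. = FALSE)
  }
  invisible(garf)
}

#' Case flag from the community leader's rating
#'
#' Leaders rated each family's overall functioning relative to other
#' families on a 4-point scale (1 = worst, 4 = best). A rating of 1 or 2
#' flags the family as distressed.
#'
#' @param rating Integer rating in 1-4.
#' @return `TRUE` if the rating is 1 or 2.
#' @export
leader_case_flag <- function(rating) {
  check_rating(rating, "leader")
  if (length(rating) != 1) stop("one leader rating per family", call. = FALSE)
  rating <= 2
}

#' Case flag from family members' self-ratings
#'
#' Each participating member rated the family on the same 4-point scale.
#' The family is flagged if at least one member rated it 1 or 2.
#'
#' @param ratings Non-empty integer vector of ratings in 1-4, one per
#'   participating member.
#' @return `TRUE` if any rating is 1 or 2.
#' @export
self_case_flag <- function(ratings) {
  if (length(ratings) == 0) {
    stop("missing self-ratings: family cannot be triangulated",
         call. = FALSE)
  }
  check_rating(ratings, "self")
  any(ratings <= 2)
}

#' Case flag from the consensus clinical GARF score
#'
#' A consensus GARF of 60 or less (the Somewhat/Critically/Most
#' Dysfunctional bands) flags the family as a potential clinical case.
#'
#' @param garf Integer consensus GARF score in 1-99.
#' @return `TRUE` if `garf <= 60`.
#' @export
clinical_case_flag <- function(garf) {
  check_garf(garf)
  garf <= 60
}

#' GARF functioning category
#'
#' Maps a 1-99 GARF score onto its five functioning bands.
#'
#' @param garf Integer GARF score in 1-99.
#' @return One of `"Most Dysfunctional"` (1-20), `"Critically
#'   Dysfunctional"` (21-40), `"Somewhat Dysfunctional"` (41-60),
#'   `"Somewhat Functional"` (61-80), `"Most Functional"` (81-99).
#' @export
garf_category <- function(garf) {
  check_garf(garf)
  cats <- c("Most Dysfunctional", "Critically Dysfunctional",
            "Somewhat Dysfunctional", "Somewhat Functional",
            "Most Functional")
  cats[findInterval(garf, c(1, 21, 41, 61, 81))]
}

#' Triangulate the three criterion sources for one family
#'
#' @param leader_rating Leader's 4-point rating.
#' @param self_ratings Non-empty vector of member self-ratings (1-4).
#' @param garf_consensus Consensus GARF score (1-99).
#' @param family_id Optional identifier carried into the result.
#' @return A one-row tibble with the three source flags, `n_sources`
#'   (0-3), and `label` (`"case"` if flagged by >= 2 sources, `"noncase"`
#'   if by 0, `"dropped"` if by exactly 1).
#' @export
triangulate <- function(leader_rating, self_ratings, garf_consensus,
                        family_id = NA_character_) {
  if (missing(leader_rating) || is.null(leader_rating) || anyNA(leader_rating))
    stop("missing source: leader rating", call. = FALSE)
  if (missing(self_ratings) || is.null(self_ratings) || length(self_ratings) == 0)
    stop("missing source: self-ratings", call. = FALSE)
  if (missing(garf_consensus) || is.null(garf_consensus) || anyNA(garf_consensus))
    stop("missing source: consensus GARF", call. = FALSE)
  lf <- leader_case_flag(leader_rating)
  sf <- self_case_flag(self_ratings)
  cf <- clinical_case_flag(garf_consensus)
  n <- sum(lf, sf, cf)
  tibble::tibble(
    family_id = family_id,
    leader_flag = lf,
    self_flag = sf,
    clinical_flag = cf,
    n_sources = n,
    label = if (n >= 2) "case" else if (n == 0) "noncase" else "dropped"
  )
}

#' Triangulate a cohort of families
#'
#' Applies [triangulate()] to each family in a criterion-source table.
#'
#' @param families Data frame with one row per family: `family_id`,
#'   `leader_rating`, `garf_consensus` (GARF domain subscores, if present,
#'   are carried but unused: only the overall consensus enters
#'   triangulation).
#' @param members Long-format data frame of member self-ratings:
#'   `family_id`, `member_id`, `role` (`"adult-female"`, `"adult-male"` or
#'   `"child"`), `self_rating`.
#' @return A tibble of per-family caseness labels (columns as in
#'   [triangulate()]). Summary counts are available via
#'   [caseness_counts()].
#' @export
triangulate_cohort <- function(families, members) {
  families <- tibble::as_tibble(families)
  members <- tibble::as_tibble(members)
  if (anyDuplicated(families$family_id)) {
    stop("duplicate family_id in criterion-source table", call. = FALSE)
  }
  if (nrow(families) == 0) {
    return(tibble::tibble(
      family_id = character(), leader_flag = logical(),
      self_flag = logical(), clinical_flag = logical(),
      n_sources = integer(), label = character()
    ))
  }
  orphans <- setdiff(families$family_id, members$family_id)
  if (length(orphans) > 0) {
    stop("missing source: self-ratings for family ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  dplyr::bind_rows(lapply(seq_len(nrow(families)), function(i) {
    fam <- families[i, ]
    self <- members$self_rating[members$family_id == fam$family_id]
    triangulate(fam$leader_rating, self, fam$garf_consensus,
                family_id = as.character(fam$family_id))
  }))
}

#' Summary counts for a caseness table
#'
#' @param labels Output of [triangulate_cohort()].
#' @return Named integer vector: `cases`, `noncases`, `dropped`,
#'   `retained` (cases + noncases).
#' @export
caseness_counts <- function(labels) {
  cases <- sum(labels$label == "case")
  noncases <- sum(labels$label == "noncase")
  dropped <- sum(labels$label == "dropped")
  c(cases = cases, noncases = noncases, dropped = dropped,
    retained = cases + noncases)
}
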