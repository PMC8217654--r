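#' Item selection by cross-validated importance and gradient evidence
#'
#' Tree-based classifiers are trained to predict family caseness from the
#' coded item battery, separately for adult and child reporters, under
#' repeated stratified k-fold cross-validation with folds grouped by
#' family (so no family contributes to both the training and the held-out
#' side of any split). Each item's importance is the model's built-in
#' variable-importance measure — surrogate-credited split goodness for the
#' single tree, Gini impurity decrease for the bagged and random forests —
#' averaged over the cross-validation training fits and scaled to 0-100
#' within each model. Built-in measures are used rather than held-out
#' permutation importance because permutation importance masks redundant
#' discriminating items: when several items separate the classes, greedy
#' trees use only the strongest and permuting the others changes nothing.
#' Item rankings across models are combined with gradient scores and
#' manual theory flags to pick the final item set.
#'
#' @name item_selection
NULL

#' Cross-validation specification
#'
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeats (default 5).
#' @return List of class `cv_spec`.
#' @export
cv_spec <- function(folds = 10, repeats = 5) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = folds, repeats = repeats), class = "cv_spec")
}

# internal: stratified assignment of families to folds, one column per repeat
assign_family_folds <- function(family_labels, folds, repeats) {
  fams <- family_labels$family_id
  y <- family_labels$case
  out <- lapply(seq_len(repeats), function(r) {
    fold <- integer(length(fams))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(sample(folds), length(idx))
    }
    tibble::tibble(rep = r, family_id = fams, fold = fold)
  })
  dplyr::bind_rows(out)
}

# internal: fit one model on a training fold and return its built-in
# variable importance as a full named vector (unused items get 0).
# rpart's measure credits surrogate splits, so items masked by a stronger
# correlate still accrue importance; the forest models use the Gini
# impurity decrease accumulated over all splits of all trees.
model_importance <- function(model, x, y, ntree) {
  imp <- switch(model,
    tree = {
      fit <- rpart::rpart(y ~ ., method = "class",
                          data = data.frame(as.data.frame(x), y = y))
      fit$variable.importance
    },
    bagged = {
      fit <- randomForest::randomForest(x, y, mtry = ncol(x),
                                        ntree = ntree)
      fit$importance[, "MeanDecreaseGini"]
    },
    forest = {
      fit <- randomForest::randomForest(x, y, ntree = ntree)
      fit$importance[, "MeanDecreaseGini"]
    },
    stop("unknown model: ", model, call. = FALSE)
  )
  out <- stats::setNames(numeric(ncol(x)), colnames(x))
  if (!is.null(imp)) out[names(imp)] <- imp
  out
}

#' Cross-validated variable importance of battery items
#'
#' @param x Data frame of coded item responses (one column per item, one
#'   row per informant). Missing codes are imputed to the per-item median.
#' @param y Caseness of each informant's family: logical or two-level
#'   factor (`TRUE`/`"case"` = case).
#' @param family Family id per informant, used to group the folds.
#' @param reporter_group Tag recorded in the output (`"adult"`/`"child"`).
#' @param cv A [cv_spec()].
#' @param models Character vector of model ids among `"tree"` (CART),
#'   `"bagged"` (bagged trees), `"forest"` (random forest).
#' @param ntree Trees per forest-type model (default 100).
#' @param seed Integer seed; results are deterministic given it.
#' @return Tibble of `item_id`, `reporter_group`, `model_id`,
#'   `importance` (0-100 within model), `rank` (1 = most important; a
#'   permutation of 1..n within model). Fold assignments are attached as
#'   attribute `"folds"`.
#' @export
fit_importance_models <- function(x, y, family, reporter_group = "adult",
                                  cv = cv_spec(),
                                  models = c("tree", "bagged", "forest"),
                                  ntree = 100, seed = 1) {
  x <- as.data.frame(x)
  if (is.logical(y)) y <- factor(ifelse(y, "case", "noncase"),
                                 levels = c("noncase", "case"))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) {
    stop("degenerate labels: both classes required", call. = FALSE)
  }
  if (min(table(y)) < 2) {
    stop("degenerate labels: need >= 2 informants per class",
         call. = FALSE)
  }
  stopifnot(length(y) == nrow(x), length(family) == nrow(x))

  # family-level labels for stratification (families are label-pure)
  fam_lab <- dplyr::distinct(tibble::tibble(family_id = family,
                                            case = as.character(y)))
  if (anyDuplicated(fam_lab$family_id)) {
    stop("families must have a single caseness label", call. = FALSE)
  }
  if (nrow(fam_lab) < cv$folds) {
    stop("cv configuration error: fewer families (", nrow(fam_lab),
         ") than folds (", cv$folds, ")", call. = FALSE)
  }

  # median imputation per item
  for (j in seq_along(x)) {
    if (anyNA(x[[j]])) {
      x[[j]][is.na(x[[j]])] <- stats::median(x[[j]], na.rm = TRUE)
    }
  }
  xm <- as.matrix(x)
  if (!is.numeric(xm)) {
    stop("item columns must be numeric distress codes", call. = FALSE)
  }

  set.seed(seed)
  fold_tab <- assign_family_folds(fam_lab, cv$folds, cv$repeats)
  items <- colnames(xm)
  p <- length(items)

  res <- lapply(models, function(model) {
    total <- stats::setNames(numeric(p), items)
    n_fits <- 0
    for (r in seq_len(cv$repeats)) {
      ftab <- fold_tab[fold_tab$rep == r, ]
      row_fold <- ftab$fold[match(family, ftab$family_id)]
      for (f in sort(unique(row_fold))) {
        train <- which(row_fold != f)
        if (nlevels(droplevels(y[train])) < 2) next
        total <- total + model_importance(model,
                                          xm[train, , drop = FALSE],
                                          y[train], ntree)
        n_fits <- n_fits + 1
      }
    }
    raw <- pmax(total / n_fits, 0)
    scaled <- if (max(raw) > 0) 100 * raw / max(raw) else raw
    ord <- order(-scaled, items)
    rank <- integer(p)
    rank[ord] <- seq_len(p)
    tibble::tibble(item_id = items, reporter_group = reporter_group,
                   model_id = model, importance = unname(scaled),
                   rank = rank)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "folds") <- fold_tab
  out
}

#' Aggregate importance across models
#'
#' Mean rank per item across models within each reporter group, plus
#' top-k membership. Ordering ties on mean rank are broken by mean scaled
#' importance, then item id.
#'
#' @param records Importance table from [fit_importance_models()]
#'   (possibly several groups bound together).
#' @param k Top-k cut (default 20).
#' @return Tibble of `item_id`, `reporter_group`, `mean_rank`,
#'   `mean_importance`, `in_top_k`.
#' @export
aggregate_importance <- function(records, k = 20) {
  per_model <- split(records$item_id,
                     interaction(records$model_id, records$reporter_group,
                                 drop = TRUE))
  sets <- lapply(per_model, sort)
  if (length(unique(sets)) != 1) {
    stop("alignment error: models cover different item sets",
         call. = FALSE)
  }
  agg <- records |>
    dplyr::group_by(.data$reporter_group, .data$item_id) |>
    dplyr::summarise(mean_rank = mean(.data$rank),
                     mean_importance = mean(.data$importance),
                     .groups = "drop") |>
    dplyr::arrange(.data$reporter_group, .data$mean_rank,
                   -.data$mean_importance, .data$item_id) |>
    dplyr::group_by(.data$reporter_group) |>
    dplyr::mutate(in_top_k = dplyr::row_number() <= k) |>
    dplyr::ungroup()
  agg
}

#' Select the final item set
#'
#' Items are ordered by a composite, auditable rule: the count of evidence
#' wins (top-k importance among adults; among children; adult gradient at
#' or above the threshold; child gradient likewise), ties broken by mean
#' gradient and then item id. Theory flags force inclusion or exclusion
#' before the composite ordering fills the remaining slots.
#'
#' @param gradients Gradient table from [gradient_table()].
#' @param importance Aggregated importance from [aggregate_importance()].
#' @param theory_flags Optional named character vector mapping item ids to
#'   `"include"` or `"exclude"`.
#' @param target_size Number of items to select (default 30).
#' @param gradient_threshold Gradient counted as an evidence win at or
#'   above this value (default 0.15).
#' @return Tibble with the full evidence trail per item (`gradient_adult`,
#'   `gradient_child`, `in_top20_adult`, `in_top20_child`, `theory_flag`,
#'   `evidence_wins`, `mean_gradient`, `selected`), ordered by the
#'   composite rule.
#' @export
select_items <- function(gradients, importance, theory_flags = NULL,
                         target_size = 30, gradient_threshold = 0.15) {
  g <- tidyr::pivot_wider(
    gradients[, c("item_id", "reporter_group", "gradient")],
    names_from = "reporter_group", values_from = "gradient",
    names_prefix = "gradient_"
  )
  imp <- tidyr::pivot_wider(
    importance[, c("item_id", "reporter_group", "in_top_k")],
    names_from = "reporter_group", values_from = "in_top_k",
    names_prefix = "top_"
  )
  ev <- dplyr::inner_join(g, imp, by = "item_id")
  missing_ev <- unique(c(setdiff(g$item_id, imp$item_id),
                         setdiff(imp$item_id, g$item_id)))
  if (length(missing_ev) > 0) {
    stop("evidence missing for item(s): ",
         paste(missing_ev, collapse = ", "), call. = FALSE)
  }
  if (target_size > nrow(ev)) {
    stop("configuration error: target_size exceeds item count",
         call. = FALSE)
  }
  tf <- rep(NA_character_, nrow(ev))
  if (!is.null(theory_flags)) {
    stopifnot(all(theory_flags %in% c("include", "exclude")))
    tf <- unname(theory_flags[match(ev$item_id, names(theory_flags))])
  }
  ev <- ev |>
    dplyr::rename(gradient_adult = "gradient_adult",
                  gradient_child = "gradient_child",
                  in_top20_adult = "top_adult",
                  in_top20_child = "top_child") |>
    dplyr::mutate(
      theory_flag = tf,
      evidence_wins = .data$in_top20_adult + .data$in_top20_child +
        (.data$gradient_adult >= gradient_threshold) +
        (.data$gradient_child >= gradient_threshold),
      mean_gradient = (.data$gradient_adult + .data$gradient_child) / 2
    ) |>
    dplyr::arrange(-.data$evidence_wins, -.data$mean_gradient,
                   .data$item_id)
  forced_in <- !is.na(ev$theory_flag) & ev$theory_flag == "include"
  forced_out <- !is.na(ev$theory_flag) & ev$theory_flag == "exclude"
  if (sum(forced_in) > target_size) {
    stop("configuration error: more forced inclusions than target_size",
         call. = FALSE)
  }
  selected <- forced_in
  slots <- target_size - sum(selected)
  eligible <- which(!forced_in & !forced_out)
  selected[eligible[seq_len(min(slots, length(eligible)))]] <- TRUE
  ev$selected <- selected
  ev
}
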