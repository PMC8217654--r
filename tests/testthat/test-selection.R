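test_that("a perfectly separating item ranks first in every model", {
  set.seed(5)
  n <- 40
  y <- rep(c(TRUE, FALSE), each = n / 2)
  fam <- rep(sprintf("G%02d", 1:(n / 2)), each = 2)
  x <- data.frame(
    A = ifelse(y, 9, 2),
    B = sample(1:10, n, TRUE), C = sample(1:10, n, TRUE),
    D = sample(1:10, n, TRUE), E = sample(1:10, n, TRUE)
  )
  imp <- fit_importance_models(x, y, fam, cv = cv_spec(5, 2), seed = 2)
  expect_true(all(imp$rank[imp$item_id == "A"] == 1))
  expect_true(all(imp$importance[imp$item_id == "A"] == 100))
})

test_that("importance tables are deterministic given the seed", {
  d <- planted_cls_data(31, nfam = 20, n_items = 10, planted = 2)
  a <- fit_importance_models(d$x, d$y, d$fam, cv = cv_spec(5, 2), seed = 9)
  b <- fit_importance_models(d$x, d$y, d$fam, cv = cv_spec(5, 2), seed = 9)
  expect_identical(a, b)
  # scaled to 100 within each model, ranks a permutation
  for (m in unique(a$model_id)) {
    sub <- a[a$model_id == m, ]
    expect_equal(max(sub$importance), 100)
    expect_setequal(sub$rank, seq_len(nrow(sub)))
  }
})

test_that("folds are grouped by family: a family never straddles a split", {
  d <- planted_cls_data(13, nfam = 20, n_items = 8, planted = 2)
  imp <- fit_importance_models(d$x, d$y, d$fam, cv = cv_spec(5, 3),
                               seed = 4)
  folds <- attr(imp, "folds")
  expect_equal(nrow(folds), 3 * 20)
  # each family has exactly one fold per repeat, so its informants are
  # all on one side of every split
  per <- table(folds$family_id, folds$rep)
  expect_true(all(per == 1))
  # stratification keeps every fold's family count balanced
  expect_true(all(table(folds$fold, folds$rep) == 4))
})

test_that("degenerate label and fold configurations are rejected", {
  d <- planted_cls_data(17, nfam = 6, n_items = 4, planted = 1)
  expect_error(
    fit_importance_models(d$x, rep(TRUE, length(d$y)), d$fam,
                          cv = cv_spec(3, 1)),
    "degenerate"
  )
  expect_error(
    fit_importance_models(d$x, d$y, d$fam, cv = cv_spec(10, 1)),
    "fewer families"
  )
})

test_that("no item persistently tops the ranking when labels are pure noise", {
  always_top5 <- NULL
  for (s in 1:5) {
    d <- planted_cls_data(100 + s, nfam = 30, n_items = 20, planted = 0)
    imp <- fit_importance_models(d$x, d$y, d$fam, cv = cv_spec(5, 2),
                                 seed = s)
    agg <- aggregate_importance(imp, k = 5)
    top <- agg$item_id[agg$in_top_k]
    always_top5 <- if (is.null(always_top5)) top else
      intersect(always_top5, top)
  }
  expect_length(always_top5, 0)
})

test_that("aggregation averages ranks and breaks ties as documented", {
  rec <- tibble::tibble(
    item_id = rep(c("A", "B"), 3),
    reporter_group = "adult",
    model_id = rep(c("m1", "m2", "m3"), each = 2),
    importance = c(100, 50, 40, 100, 80, 60),
    rank = c(1, 3, 2, 1, 1, 2)
  )
  agg <- aggregate_importance(rec, k = 1)
  expect_equal(agg$mean_rank[agg$item_id == "A"], mean(c(1, 2, 1)))
  expect_equal(agg$mean_rank[agg$item_id == "B"], 2)
  expect_true(agg$in_top_k[agg$item_id == "A"])
  expect_false(agg$in_top_k[agg$item_id == "B"])

  # equal mean ranks: the higher mean importance wins the top-k slot
  tie <- tibble::tibble(
    item_id = rep(c("A", "B"), 2), reporter_group = "adult",
    model_id = rep(c("m1", "m2"), each = 2),
    importance = c(100, 90, 10, 100), rank = c(1, 2, 2, 1)
  )
  agg <- aggregate_importance(tie, k = 1)
  expect_true(agg$in_top_k[agg$item_id == "B"])

  # models covering different item sets cannot be aggregated
  bad <- rec
  bad$item_id[1] <- "Z"
  expect_error(aggregate_importance(bad), "alignment")
})

test_that("top-k flags exactly k items per reporter group", {
  d <- planted_cls_data(7, nfam = 30, n_items = 66, planted = 5)
  imp_a <- fit_importance_models(d$x, d$y, d$fam, reporter_group = "adult",
                                 cv = cv_spec(5, 1), seed = 1)
  imp_c <- fit_importance_models(d$x, d$y, d$fam, reporter_group = "child",
                                 cv = cv_spec(5, 1), seed = 2)
  agg <- aggregate_importance(dplyr::bind_rows(imp_a, imp_c), k = 20)
  flagged <- tapply(agg$in_top_k, agg$reporter_group, sum)
  expect_equal(as.integer(flagged[c("adult", "child")]), c(20L, 20L))
})

make_evidence <- function(n = 10, strong = 5) {
  ids <- sprintf("E%02d", seq_len(n))
  g <- ifelse(seq_len(n) <= strong, 0.5, -0.1)
  gradients <- tibble::tibble(
    item_id = rep(ids, 2),
    reporter_group = rep(c("adult", "child"), each = n),
    p_case = 0.5, p_noncase = 0.2,
    gradient = rep(g, 2), n_case = 20, n_noncase = 20
  )
  importance <- tibble::tibble(
    item_id = rep(ids, 2),
    reporter_group = rep(c("adult", "child"), each = n),
    mean_rank = rep(seq_len(n), 2), mean_importance = 50,
    in_top_k = rep(seq_len(n) <= strong, 2)
  )
  list(gradients = gradients, importance = importance, ids = ids)
}

test_that("selection keeps dominating items and honors the target size", {
  ev <- make_evidence(n = 10, strong = 6)
  sel <- select_items(ev$gradients, ev$importance, target_size = 6)
  expect_equal(sum(sel$selected), 6)
  expect_setequal(sel$item_id[sel$selected], ev$ids[1:6])
  expect_error(select_items(ev$gradients, ev$importance, target_size = 11),
               "target_size")
})

test_that("an item with negative gradients in both groups is never selected", {
  ev <- make_evidence(n = 10, strong = 5)
  sel <- select_items(ev$gradients, ev$importance, target_size = 5)
  neg <- sel$item_id[sel$gradient_adult < 0 & sel$gradient_child < 0]
  expect_false(any(sel$selected[sel$item_id %in% neg]))
})

test_that("theory flags force inclusion and displace the weakest pick", {
  ev <- make_evidence(n = 10, strong = 6)
  forced <- ev$ids[9]
  sel <- select_items(ev$gradients, ev$importance,
                      theory_flags = c("E09" = "include"), target_size = 6)
  expect_true(sel$selected[sel$item_id == forced])
  expect_equal(sum(sel$selected), 6)
  # the lowest-ranked unforced former pick is displaced
  expect_false(sel$selected[sel$item_id == ev$ids[6]])

  sel2 <- select_items(ev$gradients, ev$importance,
                       theory_flags = c("E01" = "exclude"),
                       target_size = 6)
  expect_false(sel2$selected[sel2$item_id == "E01"])
  expect_equal(sum(sel2$selected), 6)
})

test_that("selection respects dominance on all four evidence dimensions", {
  ev <- make_evidence(n = 8, strong = 4)
  # item A dominates item B everywhere; B selected implies A selected
  sel <- select_items(ev$gradients, ev$importance, target_size = 4)
  dom <- function(a, b) {
    ra <- sel[sel$item_id == a, ]
    rb <- sel[sel$item_id == b, ]
    ra$gradient_adult >= rb$gradient_adult &&
      ra$gradient_child >= rb$gradient_child &&
      ra$in_top20_adult >= rb$in_top20_adult &&
      ra$in_top20_child >= rb$in_top20_child
  }
  for (a in ev$ids) for (b in ev$ids) {
    if (a != b && dom(a, b)) {
      if (sel$selected[sel$item_id == b]) {
        expect_true(sel$selected[sel$item_id == a])
      }
    }
  }
})
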