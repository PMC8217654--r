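# Shared builders for test cohorts and independent oracles.

# One ladder item definition
ladder_item <- function(id = "L01", reverse = FALSE) {
  tibble::tibble(item_id = id, format = "ladder10",
                 reverse_coded = reverse, label_key = id,
                 in_final_scale = TRUE)
}

comm_item <- function(id = "C01") {
  tibble::tibble(item_id = id, format = "comm4", reverse_coded = FALSE,
                 label_key = id, in_final_scale = TRUE)
}

# Single-item response table with exact endorsement counts per group.
# Each informant is their own family so labels are trivially family-pure.
exact_endorsement_cohort <- function(item_id, role,
                                     n_case, n_case_endorse,
                                     n_noncase, n_noncase_endorse) {
  n <- n_case + n_noncase
  fam <- sprintf("F%04d", seq_len(n))
  label <- rep(c("case", "noncase"), c(n_case, n_noncase))
  endorse <- c(rep(c(TRUE, FALSE), c(n_case_endorse,
                                     n_case - n_case_endorse)),
               rep(c(TRUE, FALSE), c(n_noncase_endorse,
                                     n_noncase - n_noncase_endorse)))
  labels <- tibble::tibble(
    family_id = fam, leader_flag = label == "case",
    self_flag = label == "case", clinical_flag = FALSE,
    n_sources = ifelse(label == "case", 2L, 0L), label = label
  )
  responses <- tibble::tibble(
    family_id = fam,
    informant_id = paste0(fam, "-1"),
    role = role,
    item_id = item_id,
    response = ifelse(endorse, "7", "2")
  )
  list(responses = responses, labels = labels)
}

# Brute-force gradient oracle: explicit counting, no shared code with
# gradient_table.
brute_gradient <- function(responses, labels, item, comm_map = comm4_map()) {
  lab <- setNames(labels$label, labels$family_id)
  p <- c(case = NA_real_, noncase = NA_real_)
  out <- list()
  for (g in c("adult", "child")) {
    num <- c(case = 0, noncase = 0)
    den <- c(case = 0, noncase = 0)
    for (i in seq_len(nrow(responses))) {
      row <- responses[i, ]
      if (row$item_id != item$item_id) next
      grp <- if (row$role == "child") "child" else "adult"
      if (grp != g) next
      l <- lab[[row$family_id]]
      if (l == "dropped") next
      if (is.na(row$response)) next
      code <- if (item$format == "ladder10") {
        v <- as.numeric(row$response)
        if (item$reverse_coded) 11 - v else v
      } else {
        comm_map[[row$response]]
      }
      e <- if (item$format == "ladder10") code >= 6 else code >= 2
      num[l] <- num[l] + e
      den[l] <- den[l] + 1
    }
    if (all(den > 0)) {
      out[[g]] <- list(p_case = num[["case"]] / den[["case"]],
                       p_noncase = num[["noncase"]] / den[["noncase"]])
    }
  }
  out
}

# Classification fixture: nfam families x 2 informants, first `planted`
# items discriminate (p 0.8 vs 0.1), the rest are null at 0.2.
planted_cls_data <- function(seed, nfam = 50, n_items = 66, planted = 5) {
  set.seed(seed)
  fam <- rep(sprintf("F%03d", seq_len(nfam)), each = 2)
  y <- rep(rep(c(TRUE, FALSE), length.out = nfam), each = 2)
  n <- length(y)
  p_case <- c(rep(0.8, planted), rep(0.2, n_items - planted))
  p_non <- c(rep(0.1, planted), rep(0.2, n_items - planted))
  x <- sapply(seq_len(n_items), function(j) {
    e <- stats::runif(n) < ifelse(y, p_case[j], p_non[j])
    ifelse(e, sample(6:10, n, TRUE), sample(1:5, n, TRUE))
  })
  colnames(x) <- sprintf("I%02d", seq_len(n_items))
  list(x = as.data.frame(x), y = y, fam = fam)
}

# Random small score/label instance for ROC oracle checks
random_roc_instance <- function() {
  n1 <- sample(2:8, 1)
  n0 <- sample(2:8, 1)
  scores <- c(sample(1:12, n1, replace = TRUE),
              sample(1:12, n0, replace = TRUE))
  labels <- rep(c(TRUE, FALSE), c(n1, n0))
  list(scores = scores, labels = labels)
}

# Exhaustive-counting Se/Sp at a threshold (rule: score >= t -> case)
count_se_sp <- function(scores, labels, t) {
  c(se = mean(scores[labels] >= t), sp = mean(scores[!labels] < t))
}

# Trapezoidal area under the empirical ROC curve
trapezoid_auc <- function(roc) {
  fpr <- 1 - roc$specificity
  tpr <- roc$sensitivity
  ord <- order(fpr, tpr)
  fpr <- c(fpr[ord])
  tpr <- c(tpr[ord])
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Pairwise-counting AUC oracle
pairwise_auc <- function(scores, labels) {
  cs <- scores[labels]
  ns <- scores[!labels]
  tot <- 0
  for (a in cs) for (b in ns) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cs) * length(ns))
}
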