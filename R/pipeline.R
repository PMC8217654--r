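#' End-to-end validation pipeline
#'
#' Orchestrates the full analysis: (optionally) simulate a cohort, build
#' the triangulated criterion reference, compute gradient scores, fit the
#' cross-validated importance models, select the item set, score
#' informants, and estimate diagnostic validity. Every stage writes its
#' table under the run directory and the run ends with a manifest
#' recording the configuration hash, seed and outputs.
#'
#' @name cli_reporting
NULL

#' Pipeline configuration
#'
#' @param out_dir Run directory (created if absent).
#' @param seed Integer master seed for all stochastic stages.
#' @param generator A [generator_config()] used when `simulate = TRUE`
#'   (its own seed is overridden by `seed`).
#' @param simulate Generate the cohort (`TRUE`) or read it from
#'   `input_dir` (expects `families.csv`, `members.csv`, `responses.csv`).
#' @param input_dir Directory with input CSVs when `simulate = FALSE`.
#' @param items Item-definition/battery table used for gradients,
#'   importance and selection.
#' @param cv A [cv_spec()] for the importance models.
#' @param models Model set for [fit_importance_models()].
#' @param ntree Trees per forest-type model.
#' @param top_k Top-k importance cut (default 20).
#' @param target_size Final item-set size (default 30).
#' @param gradient_threshold Evidence-win gradient threshold.
#' @param theory_flags Optional named vector of manual overrides for
#'   [select_items()].
#' @param completeness Scoring completeness threshold.
#' @param cutpoint_method Method for [optimal_cutpoint()].
#' @param level Confidence level for all intervals.
#' @param run_selection Toggle the importance/selection stage (when off,
#'   the final scale items in `items` are scored directly).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1,
                            generator = generator_config(),
                            simulate = TRUE,
                            input_dir = NULL,
                            items = battery_items(),
                            cv = cv_spec(),
                            models = c("tree", "bagged", "forest"),
                            ntree = 100,
                            top_k = 20,
                            target_size = 30,
                            gradient_threshold = 0.15,
                            theory_flags = NULL,
                            completeness = 0.9,
                            cutpoint_method = "equal_se_sp",
                            level = 0.95,
                            run_selection = TRUE) {
  structure(list(
    out_dir = out_dir, seed = seed, generator = generator,
    simulate = simulate, input_dir = input_dir, items = items,
    cv = cv, models = models, ntree = ntree, top_k = top_k,
    target_size = target_size, gradient_threshold = gradient_threshold,
    theory_flags = theory_flags, completeness = completeness,
    cutpoint_method = cutpoint_method, level = level,
    run_selection = run_selection
  ), class = "pipeline_config")
}

write_stage <- function(x, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(x, path, row.names = FALSE)
  path
}

# internal: wide coded matrix for one reporter group
coded_matrix <- function(responses, items, group,
                         comm_map = comm4_map()) {
  is_child <- responses$role == "child"
  resp <- responses[(if (group == "child") is_child else !is_child) &
                      responses$item_id %in% items$item_id, ]
  item_rows <- split(items, items$item_id)
  coded <- resp
  coded$code <- NA_real_
  for (id in unique(resp$item_id)) {
    sel <- resp$item_id == id
    coded$code[sel] <- code_response(resp$response[sel], item_rows[[id]],
                                     comm_map)
  }
  wide <- tidyr::pivot_wider(
    coded[, c("informant_id", "family_id", "item_id", "code")],
    names_from = "item_id", values_from = "code"
  )
  wide
}

#' Run the validation pipeline
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result (`cohort`, `labels`,
#'   `gradients`, `importance`, `selection`, `scores`, `validity`,
#'   `manifest`). Side effect: stage CSVs, a plain-text report and
#'   `manifest.json` under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()

  # --- inputs -------------------------------------------------------------
  if (config$simulate) {
    gen <- config$generator
    gen$seed <- config$seed
    cohort <- generate_cohort(gen)
    outputs <- c(outputs,
                 write_stage(cohort$families, config$out_dir, "families.csv"),
                 write_stage(cohort$members, config$out_dir, "members.csv"),
                 write_stage(cohort$responses, config$out_dir,
                             "responses.csv"),
                 write_stage(cohort$truth, config$out_dir,
                             "ground_truth.csv"))
  } else {
    read_in <- function(name) {
      path <- file.path(config$input_dir, name)
      if (!file.exists(path)) {
        stop("missing input file: ", path, call. = FALSE)
      }
      tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    }
    cohort <- list(families = read_in("families.csv"),
                   members = read_in("members.csv"))
    cohort$responses <- tryCatch(read_in("responses.csv"),
                                 error = function(e) NULL)
  }

  # --- criterion reference ------------------------------------------------
  labels <- triangulate_cohort(cohort$families, cohort$members)
  counts <- caseness_counts(labels)
  outputs <- c(outputs, write_stage(labels, config$out_dir, "caseness.csv"))

  gradients <- NULL
  selection <- NULL
  importance <- NULL
  scores <- NULL
  validity <- NULL

  if (!is.null(cohort$responses)) {
    # --- item screening ---------------------------------------------------
    gradients <- gradient_table(cohort$responses, labels, config$items)
    outputs <- c(outputs,
                 write_stage(gradients, config$out_dir, "gradients.csv"))

    if (config$run_selection) {
      retained <- labels[labels$label != "dropped", ]
      resp <- cohort$responses[cohort$responses$family_id %in%
                                 retained$family_id, ]
      imp <- lapply(c("adult", "child"), function(g) {
        wide <- coded_matrix(resp, config$items, g)
        xy <- dplyr::left_join(wide,
                               retained[, c("family_id", "label")],
                               by = "family_id")
        fit_importance_models(
          xy[, setdiff(names(xy),
                       c("informant_id", "family_id", "label"))],
          xy$label == "case", xy$family_id, reporter_group = g,
          cv = config$cv, models = config$models, ntree = config$ntree,
          seed = config$seed + match(g, c("adult", "child"))
        )
      })
      importance <- aggregate_importance(dplyr::bind_rows(imp),
                                         k = config$top_k)
      outputs <- c(outputs, write_stage(importance, config$out_dir,
                                        "importance.csv"))
      selection <- select_items(gradients, importance,
                                theory_flags = config$theory_flags,
                                target_size = config$target_size,
                                gradient_threshold =
                                  config$gradient_threshold)
      outputs <- c(outputs, write_stage(selection, config$out_dir,
                                        "selection.csv"))
      scale_ids <- selection$item_id[selection$selected]
    } else {
      scale_ids <- config$items$item_id[config$items$in_final_scale]
    }

    # --- scoring ----------------------------------------------------------
    scored_items <- config$items
    scored_items$in_final_scale <- scored_items$item_id %in% scale_ids
    scores <- score_cohort(cohort$responses, scored_items,
                           completeness = config$completeness)
    outputs <- c(outputs, write_stage(scores, config$out_dir, "scores.csv"))

    # --- diagnostic validity ----------------------------------------------
    retained <- labels[labels$label != "dropped",
                       c("family_id", "label")]
    sc <- dplyr::inner_join(scores[scores$valid, ], retained,
                            by = "family_id")
    validity <- dplyr::bind_rows(lapply(c("adult", "child"), function(g) {
      d <- sc[sc$reporter_group == g, ]
      if (nrow(d) == 0 || length(unique(d$label)) < 2) return(NULL)
      alpha <- tryCatch({
        wide <- coded_matrix(
          cohort$responses[cohort$responses$informant_id %in%
                             d$informant_id, ],
          scored_items[scored_items$in_final_scale, ], g)
        mat <- as.matrix(wide[, setdiff(names(wide),
                                        c("informant_id", "family_id"))])
        item_rows <- split(scored_items, scored_items$item_id)
        for (id in colnames(mat)) {
          mat[, id] <- transform_item(mat[, id], item_rows[[id]])
        }
        keep <- apply(mat, 2, stats::var, na.rm = TRUE) > 0
        standardized_alpha(mat[, keep, drop = FALSE])
      }, error = function(e) NA_real_)
      roc <- roc_curve(d$total, d$label == "case")
      cut <- optimal_cutpoint(roc, method = config$cutpoint_method)
      evaluate(d$total, d$label == "case", cut$threshold, alpha = alpha,
               reporter_group = g, level = config$level)
    }))
    outputs <- c(outputs, write_stage(validity, config$out_dir,
                                      "validity.csv"))
    report_path <- file.path(config$out_dir, "report.txt")
    writeLines(format_validity_report(validity, counts), report_path)
    outputs <- c(outputs, report_path)
  }

  # --- manifest -----------------------------------------------------------
  # the hash covers the analysis configuration, not the run location
  cfg_json <- jsonlite::toJSON(
    config[setdiff(names(config),
                   c("out_dir", "input_dir", "items"))],
    auto_unbox = TRUE, null = "null", force = TRUE, digits = NA
  )
  cfg_path <- file.path(config$out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ftsvalid")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    caseness = as.list(counts),
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, labels = labels, counts = counts,
                 gradients = gradients, importance = importance,
                 selection = selection, scores = scores,
                 validity = validity, manifest = manifest))
}

#' Format the diagnostic-validity report table
#'
#' Plain-text table with the published layout: Range, Cutoff, Alpha,
#' False positive, False negative, Accuracy, AUC (95% CI), Sensitivity
#' (95% CI), Specificity (95% CI), one row per reporter group.
#'
#' @param validity Table from [evaluate()] rows.
#' @param counts Optional caseness counts shown as a header.
#' @return Character vector of report lines.
#' @export
format_validity_report <- function(validity, counts = NULL) {
  lines <- character()
  if (!is.null(counts)) {
    lines <- c(lines, sprintf(
      "Criterion reference: %d cases, %d non-cases, %d dropped (%d retained)",
      counts[["cases"]], counts[["noncases"]], counts[["dropped"]],
      counts[["retained"]]), "")
  }
  header <- sprintf(
    "%-6s %-6s %-7s %-6s %-9s %-9s %-9s %-22s %-18s %-18s",
    "Group", "Range", "Cutoff", "Alpha", "False pos", "False neg",
    "Accuracy", "AUC (95% CI)", "Se (95% CI)", "Sp (95% CI)")
  lines <- c(lines, header)
  if (!is.null(validity) && nrow(validity) > 0) {
    for (i in seq_len(nrow(validity))) {
      v <- validity[i, ]
      lines <- c(lines, sprintf(
        "%-6s %-6s %-7.1f %-6.2f %-9d %-9d %-9.2f %-22s %-18s %-18s",
        v$reporter_group, "0-30", v$cutoff, v$alpha, v$false_positives,
        v$false_negatives, v$accuracy,
        sprintf("%.3f (%.3f, %.3f)", v$auc, v$auc_lower, v$auc_upper),
        sprintf("%.2f (%.2f-%.2f)", v$sensitivity, v$se_lower, v$se_upper),
        sprintf("%.2f (%.2f-%.2f)", v$specificity, v$sp_lower,
                v$sp_upper)))
    }
  }
  lines
}
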