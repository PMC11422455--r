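#' Read a cohort table from CSV
#'
#' Expects the subject-record columns: `subject`, `group` (HC, PDnoRBD, iRBD,
#' PD_RBD), the RWA parameters (`phasic_pct`, `tonic_pct`, `any_pct`,
#' `auto_rwa`), and optionally `sex`, `age`, `ahi`, `plmi` and imaging columns
#' (`caudate_sbr`, `putamen_sbr`, `caudate_z`, `putamen_z`); missing imaging
#' values may be `NA`.
#'
#' @param path CSV file.
#' @return A tibble with an added logical `rbd` column (iRBD / PD_RBD).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("cohort CSV lacks columns: %s",
                                 paste(miss, collapse = ", ")))
  bad <- setdiff(unique(df$group), c("HC", "PDnoRBD", "iRBD", "PD_RBD"))
  if (length(bad)) stop(sprintf("unknown group label(s): %s",
                                paste(bad, collapse = ", ")))
  df$rbd <- df$group %in% c("iRBD", "PD_RBD")
  tibble::as_tibble(df)
}

#' Write a cohort table to CSV
#' @param data Cohort tibble.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pool clinical groups into RBD vs non-RBD
#'
#' Reproduces the published pooling step: if Bonferroni post-hoc comparisons
#' of the RWA parameters find no significant difference within
#' \{HC, PDnoRBD\} and within \{iRBD, PD_RBD\} (all adjusted p >= `alpha`),
#' the four groups are collapsed to subjects without and with RBD. The
#' decision and the post-hoc p-values are attached as attributes.
#'
#' @param data Cohort tibble with `group` and the RWA parameter columns.
#' @param params RWA parameters to test (default all four).
#' @param alpha Significance level for the within-pair post-hoc tests
#'   (default 0.05).
#' @param force Pool regardless of the test outcome (default FALSE).
#' @return `data` with a logical `rbd` column; attributes `pooling_ok`
#'   (logical) and `pooling_tests` (tibble of within-pair adjusted p-values).
#' @export
pool_rbd_groups <- function(data, params = c("phasic_pct", "tonic_pct",
                                             "any_pct", "auto_rwa"),
                            alpha = 0.05, force = FALSE) {
  params <- intersect(params, names(data))
  within_pair <- purrr::map_dfr(params, function(p) {
    res <- anova_bonferroni(data[[p]], data$group)
    pw <- res$pairwise
    pair_sel <- (pw$group1 == "HC" & pw$group2 == "PDnoRBD") |
      (pw$group1 == "PDnoRBD" & pw$group2 == "HC") |
      (pw$group1 == "iRBD" & pw$group2 == "PD_RBD") |
      (pw$group1 == "PD_RBD" & pw$group2 == "iRBD")
    dplyr::mutate(pw[pair_sel, , drop = FALSE], parameter = p)
  })
  ok <- nrow(within_pair) == 0L || all(within_pair$p_adj >= alpha)
  if (!ok && !force) {
    warning("within-pair post-hoc differences significant; pooling anyway is not advised (use force = TRUE to insist)")
  }
  data$rbd <- data$group %in% c("iRBD", "PD_RBD")
  attr(data, "pooling_ok") <- ok
  attr(data, "pooling_tests") <- within_pair
  data
}

#' Cohort-level RWA validation report
#'
#' The full statistics layer over a cohort table: per-variable group summary
#' (means and SDs with one-way ANOVA p; Fisher's exact test for sex), ROC
#' analysis of each RWA parameter for separating RBD from non-RBD subjects,
#' paired DeLong comparison of every parameter against the gold parameter,
#' and Bonferroni-corrected Pearson correlations of the RWA parameters with
#' AHI, PLMI and the imaging values.
#'
#' @param data Cohort tibble (see [read_cohort_csv()]); needs at least the
#'   four RWA parameter columns and `group` or `rbd`.
#' @param gold Gold-standard parameter the others are compared against
#'   (default `"any_pct"`).
#' @param params RWA parameters to analyse.
#' @param pool Apply [pool_rbd_groups()] first when `rbd` is absent
#'   (default TRUE).
#' @return An object of class `cohort_report`: list with `summary`, `roc`
#'   (tibble, one row per parameter), `comparisons` (vs gold), `correlations`,
#'   `gold`, `n`.
#' @export
cohort_stats <- function(data, gold = "any_pct",
                         params = c("any_pct", "tonic_pct", "phasic_pct",
                                    "auto_rwa"),
                         pool = TRUE) {
  params <- intersect(params, names(data))
  if (!gold %in% params) {
    stop(sprintf("unknown gold parameter '%s'; valid: %s",
                 gold, paste(params, collapse = ", ")))
  }
  if (!"rbd" %in% names(data)) {
    if (!pool || !"group" %in% names(data)) {
      stop("cohort table needs an `rbd` or `group` column")
    }
    data <- pool_rbd_groups(data)
  }
  if (length(unique(data$rbd)) < 2L) stop("both classes required (RBD and non-RBD)")

  # Table-1-style group summary
  num_vars <- intersect(
    c(params, "age", "ahi", "plmi",
      "caudate_sbr", "putamen_sbr", "caudate_z", "putamen_z"),
    names(data)
  )
  grp_col <- if ("group" %in% names(data)) "group" else "rbd"
  summary_tbl <- purrr::map_dfr(num_vars, function(v) {
    ok <- !is.na(data[[v]])
    groups_present <- unique(data[[grp_col]][ok])
    p <- if (length(groups_present) >= 2L) {
      tryCatch(anova_bonferroni(data[[v]][ok], data[[grp_col]][ok])$p,
               error = function(e) NA_real_)
    } else NA_real_
    stats_by <- dplyr::summarise(
      dplyr::group_by(data[ok, , drop = FALSE], .data[[grp_col]]),
      mean = mean(.data[[v]]), sd = stats::sd(.data[[v]]), n = dplyr::n(),
      .groups = "drop"
    )
    stats_by <- dplyr::rename(stats_by, group = 1)
    dplyr::mutate(stats_by, variable = v, anova_p = p,
                  group = as.character(.data$group))
  })
  sex_p <- if ("sex" %in% names(data) && "group" %in% names(data)) {
    tab <- table(data$group, data$sex)
    if (all(dim(tab) >= 2)) tryCatch(fisher_exact(t(tab)), error = function(e) NA_real_)
    else NA_real_
  } else NA_real_

  roc_tbl <- purrr::map(params, function(p) roc(data[[p]], data$rbd))
  names(roc_tbl) <- params
  roc_rows <- purrr::map_dfr(params, function(p) {
    r <- roc_tbl[[p]]
    tibble::tibble(
      parameter = p, auc = r$auc, se = r$se,
      ci_low = r$ci95[1], ci_high = r$ci95[2],
      cut_point = r$cut_point, sensitivity = r$sensitivity,
      specificity = r$specificity,
      cut_point_spec1 = r$cut_point_spec1,
      sensitivity_spec1 = r$sensitivity_spec1
    )
  })

  cmp <- purrr::map_dfr(setdiff(params, gold), function(p) {
    res <- compare_auc(data[[p]], data[[gold]], data$rbd)
    tibble::tibble(parameter = p, gold = gold, z = res$z, p_value = res$p,
                   auc = res$auc_a, auc_gold = res$auc_b)
  })

  corr_targets <- intersect(
    c("ahi", "plmi", "caudate_sbr", "putamen_sbr", "caudate_z", "putamen_z"),
    names(data)
  )
  corr <- if (length(corr_targets)) {
    correlation_table(data, params, corr_targets)
  } else {
    tibble::tibble(x = character(), y = character(), r = numeric(),
                   p_raw = numeric(), p_adj = numeric(), n = integer())
  }

  structure(
    list(
      summary = summary_tbl,
      sex_fisher_p = sex_p,
      roc = roc_rows,
      roc_objects = roc_tbl,
      comparisons = cmp,
      correlations = corr,
      gold = gold,
      n = c(rbd = sum(data$rbd), non_rbd = sum(!data$rbd)),
      pooling_ok = attr(data, "pooling_ok"),
      pooling_tests = attr(data, "pooling_tests")
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf(
    "<cohort_report> %d RBD vs %d non-RBD subjects; gold parameter: %s\n",
    x$n[["rbd"]], x$n[["non_rbd"]], x$gold
  ))
  cat("ROC per RWA parameter:\n")
  print(x$roc[, c("parameter", "auc", "se", "ci_low", "ci_high",
                  "cut_point", "sensitivity", "specificity")])
  if (nrow(x$comparisons)) {
    cat(sprintf("AUC comparisons vs %s (paired DeLong):\n", x$gold))
    print(x$comparisons)
  }
  invisible(x)
}

#' Write a cohort report to JSON
#' @param report A `cohort_report`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  out <- list(
    n = as.list(report$n),
    gold = report$gold,
    summary = report$summary,
    sex_fisher_p = report$sex_fisher_p,
    roc = report$roc,
    comparisons = report$comparisons,
    correlations = report$correlations
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
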