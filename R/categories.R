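.pprl_levels <- c("none", "permissive_only", "permissive_balanced", "all_three")

#' Classify a patient into one of the 8 exclusive agreement categories
#'
#' The cross-classification of the rule-engine outcome (match / no match)
#' with the nested token-engine level (`none`, `permissive_only`,
#' `permissive_balanced`, `all_three`) yields 8 mutually exclusive
#' categories numbered 1-8: 1-4 are the no-rule-match rows and 5-8 the
#' rule-match rows, ordered by increasing token-engine stringency.
#'
#' @param ce_matched logical vector; did the rule engine match the patient.
#' @param pprl_level character vector over `r paste(pprlaudit:::.pprl_levels, collapse = ", ")`.
#' @return integer category ids in 1-8.
#' @export
#' @examples
#' classify_patient(FALSE, "none")            # 1
#' classify_patient(TRUE, "permissive_only")  # 6
#' classify_patient(FALSE, "all_three")       # 4
classify_patient <- function(ce_matched, pprl_level) {
  lv <- match(pprl_level, .pprl_levels)
  if (anyNA(lv)) {
    config_error("invalid pprl_level value(s): %s",
      paste(unique(pprl_level[is.na(lv)]), collapse = ", "))
  }
  if (!is.logical(ce_matched) || anyNA(ce_matched)) {
    config_error("'ce_matched' must be logical without NA")
  }
  as.integer(lv + 4L * ce_matched)
}

## per-patient token-engine level from the three nested match sets
pprl_level_for <- function(cohort_ids, match_sets) {
  in_set <- function(s) cohort_ids %in% s$record_id_a
  strict <- in_set(match_sets$strict)
  balanced <- in_set(match_sets$balanced)
  permissive <- in_set(match_sets$permissive)
  if (any(strict & !balanced) || any(balanced & !permissive)) {
    invariant_error("threshold containment violated: stricter match set is not nested")
  }
  ifelse(strict, "all_three",
    ifelse(balanced, "permissive_balanced",
      ifelse(permissive, "permissive_only", "none")))
}

new_category_table <- function(counts, cohort_size, members = NULL,
                               assignment = NULL) {
  if (sum(counts$count) != cohort_size) {
    invariant_error("category counts sum to %d, cohort size is %d",
      sum(counts$count), cohort_size)
  }
  structure(list(
    counts = counts, cohort_size = cohort_size,
    members = members, assignment = assignment
  ), class = "category_table")
}

#' Build the 8-category partition table for a cohort
#'
#' Cross-classifies every cohort patient by rule-engine outcome and nested
#' token-engine level, verifying threshold containment and the partition
#' property (counts sum to the cohort size).
#'
#' @param cohort_ids character vector of cohort (site A) record ids.
#' @param rule_outcomes output of [rule_match_all()] covering the cohort.
#' @param match_sets the `match_sets` element of a [pprl_match()] result
#'   (pairs outside the cohort are ignored).
#' @return an object of class `category_table` with `counts` (8 rows:
#'   `category_id`, `ce_matched`, `pprl_level`, `count`), `cohort_size`,
#'   `members` (list of record-id vectors per category), and `assignment`
#'   (per-patient category plus proposed partners used for adjudication).
#' @export
build_category_table <- function(cohort_ids, rule_outcomes, match_sets) {
  cohort_ids <- unique(as.character(cohort_ids))
  ro <- data.table::as.data.table(rule_outcomes)
  if (!all(cohort_ids %in% ro$record_id)) {
    config_error("rule outcomes do not cover the whole cohort")
  }
  sets <- lapply(match_sets, function(s) {
    data.table::as.data.table(s)[record_id_a %in% cohort_ids]
  })
  i <- match(cohort_ids, ro$record_id)
  ce <- ro$status[i] == "matched"
  lv <- pprl_level_for(cohort_ids, sets)
  cat_id <- classify_patient(ce, lv)

  assignment <- data.table::data.table(
    record_id = cohort_ids, category_id = cat_id,
    ce_matched = ce, pprl_level = lv,
    ce_partner = ro$matched_record_id[i],
    pprl_partner = sets$permissive$record_id_b[
      match(cohort_ids, sets$permissive$record_id_a)]
  )
  counts <- data.table::data.table(
    category_id = 1:8,
    ce_matched = rep(c("no", "yes"), each = 4L),
    pprl_level = rep(.pprl_levels, 2L),
    count = tabulate(cat_id, nbins = 8L)
  )
  members <- split(cohort_ids, factor(cat_id, levels = 1:8))
  names(members) <- as.character(1:8)
  new_category_table(counts, length(cohort_ids), members, assignment)
}

#' Build a category table directly from printed counts
#'
#' Replication-mode entry point: accepts the 8 exclusive category counts
#' (columns `category_id`, `count`; `ce_matched`/`pprl_level` optional) as
#' a data.frame or CSV path.
#'
#' @param counts data.frame or CSV path.
#' @return a `category_table` (no membership lists).
#' @export
category_table_from_counts <- function(counts) {
  dt <- if (is.character(counts)) data.table::fread(counts) else data.table::as.data.table(counts)
  if (!all(c("category_id", "count") %in% names(dt))) {
    config_error("category counts need 'category_id' and 'count' columns")
  }
  dt <- dt[order(category_id)]
  if (!identical(as.integer(dt$category_id), 1:8)) {
    config_error("category counts must cover category_id 1..8 exactly once")
  }
  if (any(dt$count < 0)) config_error("category counts must be non-negative")
  counts8 <- data.table::data.table(
    category_id = 1:8,
    ce_matched = rep(c("no", "yes"), each = 4L),
    pprl_level = rep(.pprl_levels, 2L),
    count = as.numeric(dt$count)
  )
  new_category_table(counts8, sum(counts8$count))
}

#' Default algorithm-to-category row map
#'
#' Which exclusive categories constitute each algorithm's match set:
#' rule engine rows 5-8; strict rows 4, 8; balanced rows 3, 4, 7, 8;
#' permissive rows 2-4, 6-8.
#'
#' @return named list of integer category-id vectors.
#' @export
default_row_map <- function() {
  list(
    ce = 5:8,
    strict = c(4L, 8L),
    balanced = c(3L, 4L, 7L, 8L),
    permissive = c(2:4, 6:8)
  )
}

#' Per-algorithm total matches from a category table
#'
#' @param category_table a `category_table`.
#' @param row_map see [default_row_map()].
#' @return named numeric vector of totals.
#' @export
algorithm_totals <- function(category_table, row_map = default_row_map()) {
  cnt <- category_table$counts$count
  vapply(row_map, function(rows) sum(cnt[rows]), numeric(1))
}

#' @export
print.category_table <- function(x, ...) {
  cat(sprintf("<category_table> cohort %s patients\n",
    format(x$cohort_size, big.mark = " ")))
  df <- as.data.frame(x$counts)
  df$pct <- sprintf("%.1f", round_half_up(100 * df$count / x$cohort_size, 1))
  print(df, row.names = FALSE)
  tot <- algorithm_totals(x)
  cat("algorithm totals: ",
    paste(sprintf("%s=%s", names(tot), format(tot, big.mark = " ", trim = TRUE)),
      collapse = ", "), "\n")
  invisible(x)
}

#' Write a category table as CSV
#'
#' @param category_table a `category_table`.
#' @param path file path.
#' @export
write_category_table <- function(category_table, path) {
  data.table::fwrite(category_table$counts, path, eol = "\n")
  invisible(path)
}
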