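#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from the binomial tail probabilities, computed through
#' the beta-quantile closed form: `lo = qbeta(alpha/2, x, n - x + 1)`,
#' `hi = qbeta(1 - alpha/2, x + 1, n - x)`, with `lo = 0` when `x = 0` and
#' `hi = 1` when `x = n`.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials; `n = 0` yields an undefined interval
#'   (`NA`, `NA`).
#' @param confidence confidence level, default 0.95.
#' @return numeric vector `c(lo, hi)`.
#' @export
#' @examples
#' exact_binomial_ci(0, 200)  # upper bound ~1.8%
exact_binomial_ci <- function(successes, n, confidence = 0.95) {
  if (any(n < 0) || any(successes < 0) || any(successes > n)) {
    config_error("need 0 <= successes <= n")
  }
  check_rate(confidence, "confidence")
  if (n == 0) return(c(lo = NA_real_, hi = NA_real_))
  alpha <- 1 - confidence
  lo <- if (successes == 0) 0 else qbeta(alpha / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lo = lo, hi = hi)
}

#' Audit false-match rate with exact confidence interval
#'
#' The FM rate is the number of false matches divided by the reviewed
#' sample minus the uncertain verdicts (uncertains are excluded from the
#' denominator). A zero denominator yields an explicit `"inestimable"`
#' status, never a silent zero.
#'
#' @param fm_count,um_count,sample_reviewed non-negative counts with
#'   `fm_count + um_count <= sample_reviewed`.
#' @param confidence CI level for the exact interval.
#' @return an object of class `fm_rate_estimate`: a list with the counts,
#'   `denominator`, `rate`, `ci_lo`, `ci_hi`, and `status`
#'   (`"ok"`/`"inestimable"`).
#' @export
#' @examples
#' fm_rate(30, 35, 200)  # denominator 165, rate 18.18%
fm_rate <- function(fm_count, um_count, sample_reviewed, confidence = 0.95) {
  for (v in list(fm_count, um_count, sample_reviewed)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v != floor(v)) {
      config_error("counts must be single non-negative integers")
    }
  }
  if (fm_count + um_count > sample_reviewed) {
    config_error("fm_count + um_count exceeds sample_reviewed")
  }
  denominator <- sample_reviewed - um_count
  if (denominator == 0) {
    est <- list(
      fm_count = fm_count, um_count = um_count,
      sample_reviewed = sample_reviewed, denominator = 0L,
      rate = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
      confidence = confidence, status = "inestimable"
    )
    return(structure(est, class = "fm_rate_estimate"))
  }
  ci <- exact_binomial_ci(fm_count, denominator, confidence)
  structure(list(
    fm_count = fm_count, um_count = um_count,
    sample_reviewed = sample_reviewed, denominator = denominator,
    rate = fm_count / denominator, ci_lo = unname(ci[1]), ci_hi = unname(ci[2]),
    confidence = confidence, status = "ok"
  ), class = "fm_rate_estimate")
}

#' @export
print.fm_rate_estimate <- function(x, ...) {
  if (x$status == "inestimable") {
    cat("<fm_rate_estimate> inestimable (zero denominator after excluding uncertains)\n")
  } else {
    cat(sprintf("<fm_rate_estimate> %d/%d = %s%% (%s CI %s%%-%s%%)\n",
      x$fm_count, x$denominator, format_rate_pct(x$rate),
      paste0(100 * x$confidence, "%"),
      format_rate_pct(x$ci_lo), format_rate_pct(x$ci_hi)))
  }
  invisible(x)
}

#' Project an audited FM rate to a category population
#'
#' Multiplies the category count by the FM rate and by the CI bounds.
#' Values are kept unrounded; rounding happens only at display. A category
#' with zero population contributes zero regardless of estimability; a
#' populated category with an inestimable rate propagates `NA` with an
#' `"inestimable"` status.
#'
#' @param estimate an [fm_rate()] result.
#' @param category_count population count of the category.
#' @return list with `projected`, `lo`, `hi`, `status`.
#' @export
project_to_population <- function(estimate, category_count) {
  if (!inherits(estimate, "fm_rate_estimate")) {
    config_error("'estimate' must come from fm_rate()")
  }
  if (!is.numeric(category_count) || length(category_count) != 1L ||
      is.na(category_count) || category_count < 0) {
    config_error("'category_count' must be a single non-negative number")
  }
  if (category_count == 0) {
    return(list(projected = 0, lo = 0, hi = 0, status = "ok"))
  }
  if (estimate$status == "inestimable") {
    return(list(projected = NA_real_, lo = NA_real_, hi = NA_real_,
      status = "inestimable"))
  }
  list(
    projected = category_count * estimate$rate,
    lo = category_count * estimate$ci_lo,
    hi = category_count * estimate$ci_hi,
    status = "ok"
  )
}

#' Sum projected FM counts into per-algorithm totals
#'
#' Unrounded category projections are summed over each algorithm's
#' constituent categories; categories absent from `projections` (the
#' unreviewed full-agreement categories) contribute zero on the assumption
#' that unanimous matches/non-matches are correct. An inestimable
#' constituent makes the algorithm inestimable.
#'
#' @param projections `data.table`/data.frame with `category_id`,
#'   `projected`, `proj_lo`, `proj_hi`, `status`.
#' @param row_map see [default_row_map()].
#' @return `data.table` with one row per algorithm: `fm`, `fm_lo`,
#'   `fm_hi`, `status`.
#' @export
algorithm_errors <- function(projections, row_map = default_row_map()) {
  pr <- data.table::as.data.table(projections)
  rows <- lapply(names(row_map), function(alg) {
    sub <- pr[category_id %in% row_map[[alg]]]
    if (nrow(sub) && any(sub$status == "inestimable")) {
      return(data.table::data.table(algorithm = alg, fm = NA_real_,
        fm_lo = NA_real_, fm_hi = NA_real_, status = "inestimable"))
    }
    data.table::data.table(
      algorithm = alg,
      fm = sum(sub$projected), fm_lo = sum(sub$proj_lo), fm_hi = sum(sub$proj_hi),
      status = "ok"
    )
  })
  data.table::rbindlist(rows)
}

#' Precision of an algorithm from projected false matches
#'
#' `precision = (M - FM) / M`; the CI endpoints come from the projected-FM
#' bounds: `lo = (M - FM_hi)/M`, `hi = (M - FM_lo)/M`, clipped to \[0, 1\].
#'
#' @param total_matches algorithm total matches M (> 0).
#' @param fm,fm_lo,fm_hi projected false matches and 95% bounds.
#' @return list with `precision`, `lo`, `hi`.
#' @export
precision_estimate <- function(total_matches, fm, fm_lo = fm, fm_hi = fm) {
  if (total_matches <= 0) config_error("'total_matches' must be positive")
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  list(
    precision = clip01((total_matches - fm) / total_matches),
    lo = clip01((total_matches - fm_hi) / total_matches),
    hi = clip01((total_matches - fm_lo) / total_matches)
  )
}

#' Recall of an algorithm against the union proxy gold standard
#'
#' `recall = (M - FM) / matches_any`, where `matches_any` is the number of
#' patients matched by either engine (cohort minus the nothing-matched
#' category). The CI combines the normal-approximation binomial bounds on
#' the recall proportion with the projected-FM bounds:
#' `lo = (M - FM_hi)/matches_any - z*SE` and
#' `hi = (M - FM_lo)/matches_any + z*SE`, with
#' `SE = sqrt(r(1-r)/matches_any)` at the point recall r. The verbal
#' definition this implements is ambiguous in its source; endpoints should
#' be read as approximate.
#'
#' @param total_matches algorithm total matches M.
#' @param fm,fm_lo,fm_hi projected false matches and bounds.
#' @param matches_any union proxy gold-standard count (> 0).
#' @param confidence CI level.
#' @return list with `recall`, `lo`, `hi`.
#' @export
recall_estimate <- function(total_matches, fm, fm_lo = fm, fm_hi = fm,
                            matches_any, confidence = 0.95) {
  if (matches_any <= 0) config_error("'matches_any' must be positive")
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  r <- (total_matches - fm) / matches_any
  z <- qnorm(1 - (1 - confidence) / 2)
  se <- sqrt(clip01(r) * (1 - clip01(r)) / matches_any)
  list(
    recall = clip01(r),
    lo = clip01((total_matches - fm_hi) / matches_any - z * se),
    hi = clip01((total_matches - fm_lo) / matches_any + z * se)
  )
}

#' Full accuracy report: projections, precision and recall per algorithm
#'
#' Runs the estimation chain end to end: per-category FM rates with exact
#' CIs from the review table, projection to the category populations,
#' per-algorithm summation (unreviewed full-agreement categories contribute
#' zero), precision, and recall against the union proxy gold standard
#' (`matches_any = cohort - category-1 count`). All sums use unrounded
#' values; rounding is applied only when printing.
#'
#' @param category_table a `category_table`.
#' @param review_table a `review_table`.
#' @param row_map see [default_row_map()].
#' @param confidence CI level.
#' @return an object of class `accuracy_report` with elements `categories`
#'   (per-category review/projection table), `algorithms` (per-algorithm
#'   totals, FM, precision, recall with bounds), `matches_any`,
#'   `cohort_size`, `confidence`.
#' @export
full_report <- function(category_table, review_table,
                        row_map = default_row_map(), confidence = 0.95) {
  if (!inherits(category_table, "category_table")) {
    config_error("'category_table' must be a category_table")
  }
  rt <- data.table::as.data.table(review_table)
  counts <- category_table$counts
  matches_any <- category_table$cohort_size - counts$count[1]

  empty_cats <- data.table::data.table(
    category_id = integer(0), category_count = numeric(0),
    sample_reviewed = integer(0), fm_count = integer(0), um_count = integer(0),
    denominator = integer(0), rate = numeric(0), ci_lo = numeric(0),
    ci_hi = numeric(0), projected = numeric(0), proj_lo = numeric(0),
    proj_hi = numeric(0), status = character(0)
  )
  cats <- lapply(seq_len(nrow(rt)), function(i) {
    est <- fm_rate(rt$fm_count[i], rt$um_count[i], rt$sample_reviewed[i],
      confidence)
    cnt <- counts$count[counts$category_id == rt$category_id[i]]
    proj <- project_to_population(est, cnt)
    data.table::data.table(
      category_id = rt$category_id[i],
      category_count = cnt,
      sample_reviewed = rt$sample_reviewed[i],
      fm_count = rt$fm_count[i], um_count = rt$um_count[i],
      denominator = est$denominator,
      rate = est$rate, ci_lo = est$ci_lo, ci_hi = est$ci_hi,
      projected = proj$projected, proj_lo = proj$lo, proj_hi = proj$hi,
      status = proj$status
    )
  })
  cats <- data.table::rbindlist(c(list(empty_cats), cats))

  errs <- algorithm_errors(cats, row_map)
  totals <- algorithm_totals(category_table, row_map)
  algs <- lapply(seq_len(nrow(errs)), function(i) {
    alg <- errs$algorithm[i]
    M <- totals[[alg]]
    if (errs$status[i] == "inestimable" || M <= 0) {
      return(data.table::data.table(
        algorithm = alg, rows = paste(row_map[[alg]], collapse = ","),
        total_matches = M, fm = errs$fm[i], fm_lo = errs$fm_lo[i],
        fm_hi = errs$fm_hi[i], precision = NA_real_, precision_lo = NA_real_,
        precision_hi = NA_real_, net_matches = NA_real_, net_lo = NA_real_,
        net_hi = NA_real_, recall = NA_real_, recall_lo = NA_real_,
        recall_hi = NA_real_,
        status = if (M <= 0) "no_matches" else "inestimable"
      ))
    }
    pr <- precision_estimate(M, errs$fm[i], errs$fm_lo[i], errs$fm_hi[i])
    rc <- recall_estimate(M, errs$fm[i], errs$fm_lo[i], errs$fm_hi[i],
      matches_any, confidence)
    data.table::data.table(
      algorithm = alg, rows = paste(row_map[[alg]], collapse = ","),
      total_matches = M, fm = errs$fm[i], fm_lo = errs$fm_lo[i],
      fm_hi = errs$fm_hi[i],
      precision = pr$precision, precision_lo = pr$lo, precision_hi = pr$hi,
      net_matches = M - errs$fm[i], net_lo = M - errs$fm_hi[i],
      net_hi = M - errs$fm_lo[i],
      recall = rc$recall, recall_lo = rc$lo, recall_hi = rc$hi,
      status = "ok"
    )
  })
  algs <- data.table::rbindlist(algs)

  structure(list(
    categories = cats, algorithms = algs,
    matches_any = matches_any, cohort_size = category_table$cohort_size,
    confidence = confidence
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> cohort %s; union proxy gold standard %s\n",
    format(x$cohort_size, big.mark = " "),
    format(x$matches_any, big.mark = " ")))
  cat("\nPer-category review and projection:\n")
  ct <- x$categories
  disp <- data.frame(
    category = ct$category_id, count = ct$category_count,
    reviewed = ct$sample_reviewed, fm = ct$fm_count, um = ct$um_count,
    denom = ct$denominator,
    fm_rate = paste0(format_rate_pct(ct$rate), "%"),
    ci = sprintf("%s%%-%s%%", format_rate_pct(ct$ci_lo), format_rate_pct(ct$ci_hi)),
    projected = round_half_up(ct$projected),
    proj_ci = sprintf("%.0f-%.0f", round_half_up(ct$proj_lo), round_half_up(ct$proj_hi))
  )
  print(disp, row.names = FALSE)
  cat("\nPer-algorithm accuracy:\n")
  a <- x$algorithms
  disp <- data.frame(
    algorithm = a$algorithm, rows = a$rows,
    total = a$total_matches,
    proj_errors = sprintf("%.0f (%.0f, %.0f)", round_half_up(a$fm),
      round_half_up(a$fm_lo), round_half_up(a$fm_hi)),
    precision = sprintf("%.1f (%.1f%%-%.1f%%)",
      round_half_up(100 * a$precision, 1), round_half_up(100 * a$precision_lo, 1),
      round_half_up(100 * a$precision_hi, 1)),
    recall = sprintf("%.1f (%.1f%%-%.1f%%)",
      round_half_up(100 * a$recall, 1), round_half_up(100 * a$recall_lo, 1),
      round_half_up(100 * a$recall_hi, 1)),
    status = a$status
  )
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Serialize an accuracy report to JSON
#'
#' @param report an `accuracy_report`.
#' @param path JSON file path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(
    cohort_size = report$cohort_size,
    matches_any = report$matches_any,
    confidence = report$confidence,
    categories = report$categories,
    algorithms = report$algorithms
  ), path, digits = NA, na = "null", auto_unbox = TRUE, dataframe = "rows")
  invisible(path)
}
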