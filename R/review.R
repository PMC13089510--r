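#' Stratified audit-review plan
#'
#' By default 200 patients are sampled from each of the 6 disagreement
#' categories (2-7), excluding the two full-agreement categories (1 and 8)
#' on the assumption that unanimous verdicts are correct.
#'
#' @param categories category ids to sample.
#' @param n_per_category simple-random-sample size per category.
#' @param seed sampling seed.
#' @return an object of class `review_plan`.
#' @export
review_plan <- function(categories = 2:7, n_per_category = 200L, seed = 1L) {
  categories <- as.integer(categories)
  if (anyNA(categories) || any(categories < 1L | categories > 8L) ||
      anyDuplicated(categories)) {
    config_error("'categories' must be distinct ids in 1..8")
  }
  structure(list(
    categories = categories,
    n_per_category = check_count(n_per_category, "n_per_category"),
    seed = as.integer(seed)
  ), class = "review_plan")
}

#' Draw the stratified audit samples
#'
#' Simple random sampling without replacement within each planned
#' category; categories smaller than the requested size are taken whole
#' with a warning. Reproducible from the plan's seed.
#'
#' @param category_table a [build_category_table()] result with membership
#'   lists.
#' @param plan a [review_plan()].
#' @return `data.table` of `record_id`, `category_id`.
#' @export
draw_samples <- function(category_table, plan = review_plan()) {
  if (is.null(category_table$members)) {
    config_error("category table has no membership lists (counts-only table)")
  }
  with_seed(plan$seed, {
    out <- lapply(plan$categories, function(cid) {
      members <- category_table$members[[as.character(cid)]]
      n <- length(members)
      take <- min(plan$n_per_category, n)
      if (n == 0L) {
        warning(sprintf("category %d is empty; nothing to sample", cid))
        return(data.table::data.table(record_id = character(0),
          category_id = integer(0)))
      }
      if (take < plan$n_per_category) {
        warning(sprintf("category %d has only %d members (< %d); sampling all",
          cid, n, plan$n_per_category))
      }
      data.table::data.table(
        record_id = sort(members)[sample.int(n, take)],
        category_id = cid
      )
    })
    data.table::rbindlist(out)
  })
}

#' Simulate manual adjudication of sampled patients against ground truth
#'
#' Stands in for human chart review. Each sampled patient's proposed
#' cross-site partner(s) are compared with the truth ledger: the verdict is
#' `true_match` when every proposed pair is a truth pair and `false_match`
#' otherwise (a patient whose rule and token engines proposed different
#' partners has at least one wrong pair). Independently, the verdict is
#' replaced by `uncertain` with probability `uncertainty_rate` (reviewers
#' could not decide) and by `excluded_restricted` with probability
#' `restricted_rate` (privacy-restricted chart; takes precedence).
#' A sampled patient with no proposed partner (category 5 sampled for its
#' rule-engine pair, say) is adjudicated on whichever partner exists.
#'
#' @param samples output of [draw_samples()].
#' @param assignment the `assignment` element of a [build_category_table()]
#'   result (carries `ce_partner` / `pprl_partner`).
#' @param truth the truth ledger (`record_id_a`, `record_id_b`).
#' @param uncertainty_rate,restricted_rate noise probabilities; defaults
#'   reflect observed review attrition (about 2.25% restricted charts and
#'   5% uncertain verdicts).
#' @param seed RNG seed.
#' @return `data.table` of `record_id`, `category_id`, `verdict`.
#' @export
simulate_adjudication <- function(samples, assignment, truth,
                                  uncertainty_rate = 0.05,
                                  restricted_rate = 0.0225,
                                  seed = 1L) {
  check_rate(uncertainty_rate, "uncertainty_rate")
  check_rate(restricted_rate, "restricted_rate")
  s <- data.table::as.data.table(samples)
  a <- data.table::as.data.table(assignment)
  tr <- data.table::as.data.table(truth)
  i <- match(s$record_id, a$record_id)
  if (anyNA(i)) config_error("samples contain ids absent from the assignment")
  truth_key <- paste(tr$record_id_a, tr$record_id_b)
  pair_true <- function(partner) {
    ifelse(is.na(partner), NA, paste(s$record_id, partner) %in% truth_key)
  }
  ce_ok <- pair_true(a$ce_partner[i])
  pprl_ok <- pair_true(a$pprl_partner[i])
  ## all proposed pairs must be genuine for a true match
  is_true <- ifelse(is.na(ce_ok) & is.na(pprl_ok), NA,
    (is.na(ce_ok) | ce_ok) & (is.na(pprl_ok) | pprl_ok))
  if (anyNA(is_true)) {
    ## no proposed partner at all: only possible for category 1 patients,
    ## which the default plan never samples; treat as a true non-match pair
    is_true[is.na(is_true)] <- TRUE
  }
  with_seed(seed, {
    n <- nrow(s)
    verdict <- ifelse(is_true, "true_match", "false_match")
    verdict[runif(n) < uncertainty_rate] <- "uncertain"
    verdict[runif(n) < restricted_rate] <- "excluded_restricted"
    data.table::data.table(
      record_id = s$record_id, category_id = s$category_id, verdict = verdict
    )
  })
}

#' Summarize adjudications into a review table
#'
#' Restricted exclusions reduce the reviewed sample (they are not
#' resampled); the remaining verdicts are tallied per category.
#'
#' @param adjudications output of [simulate_adjudication()] or a
#'   compatible `data.table` (`record_id`, `category_id`, `verdict`).
#' @return an object of class `review_table`: `category_id`,
#'   `sample_reviewed`, `fm_count`, `um_count`.
#' @export
summarize_reviews <- function(adjudications) {
  adj <- data.table::as.data.table(adjudications)
  if (nrow(adj) == 0L) {
    return(structure(data.table::data.table(
      category_id = integer(0), sample_reviewed = integer(0),
      fm_count = integer(0), um_count = integer(0)
    ), class = c("review_table", "data.table", "data.frame")))
  }
  ok <- c("true_match", "false_match", "uncertain", "excluded_restricted")
  bad <- setdiff(unique(adj$verdict), ok)
  if (length(bad)) config_error("unknown verdicts: %s", paste(bad, collapse = ", "))
  out <- adj[, .(
    sample_reviewed = sum(verdict != "excluded_restricted"),
    fm_count = sum(verdict == "false_match"),
    um_count = sum(verdict == "uncertain")
  ), by = category_id][order(category_id)]
  structure(out, class = c("review_table", "data.table", "data.frame"))
}

#' Read a completed review table from CSV
#'
#' Replication-mode ingest: columns `category_id`, `sample_reviewed`,
#' `fm_count`, `um_count`.
#'
#' @param path CSV path.
#' @return a `review_table`.
#' @export
read_review_table <- function(path) {
  dt <- data.table::fread(path)
  need <- c("category_id", "sample_reviewed", "fm_count", "um_count")
  miss <- setdiff(need, names(dt))
  if (length(miss)) config_error("review table lacks columns: %s", paste(miss, collapse = ", "))
  if (any(dt$fm_count + dt$um_count > dt$sample_reviewed)) {
    config_error("fm_count + um_count exceeds sample_reviewed")
  }
  structure(dt[order(category_id), need, with = FALSE],
    class = c("review_table", "data.table", "data.frame"))
}
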