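#' Weight table for the rule-based deterministic matcher
#'
#' The rule engine sums points over 12 identifier comparisons and declares
#' a match when the sum exceeds `match_threshold` (strictly) for exactly
#' one candidate. The default weights are a documented stand-in for a
#' production EHR matching module whose weights are not published: exact
#' date of birth and exact full name carry the most weight; SSN is
#' deliberately absent from the comparison list (production deployments of
#' the rule engine at the studied sites do not use it), while the token
#' schema does include SSN — that asymmetry drives the recall gap between
#' the engines.
#'
#' @param weights named non-negative numeric vector over the 12 comparisons.
#' @param match_threshold positive points threshold ("exceeds" is strict).
#' @return an object of class `weight_table`.
#' @export
weight_table <- function(weights, match_threshold) {
  need <- c(
    "exact_full_name", "exact_first_name", "soundex_first", "soundex_last",
    "exact_dob", "year_of_birth", "exact_email", "exact_phone",
    "exact_address", "exact_zip", "exact_gender", "exact_middle_initial"
  )
  if (!is.numeric(weights) || is.null(names(weights)) ||
      !setequal(names(weights), need)) {
    config_error("weights must be named over the 12 comparisons: %s",
      paste(need, collapse = ", "))
  }
  if (any(weights < 0)) config_error("weights must be non-negative")
  if (!is.numeric(match_threshold) || length(match_threshold) != 1L ||
      match_threshold <= 0) {
    config_error("'match_threshold' must be a single positive number")
  }
  structure(list(weights = weights[need], match_threshold = match_threshold),
    class = "weight_table")
}

#' @rdname weight_table
#' @export
default_weight_table <- function() {
  weight_table(
    weights = c(
      exact_full_name = 25, exact_first_name = 10,
      soundex_first = 5, soundex_last = 5,
      exact_dob = 30, year_of_birth = 10,
      exact_email = 15, exact_phone = 15,
      exact_address = 10, exact_zip = 5,
      exact_gender = 5, exact_middle_initial = 5
    ),
    match_threshold = 70
  )
}

## normalized records + derived comparison fields (soundex, yob, initials)
prep_rule_fields <- function(records) {
  r <- normalize_pii(records)
  r$sdx_first <- ifelse(is_blank(r$first_name), "", soundex(r$first_name))
  r$sdx_last <- ifelse(is_blank(r$last_name), "", soundex(r$last_name))
  r$yob <- ifelse(is_blank(r$dob), "", substr(r$dob, 7L, 10L))
  r$first_initial <- substr(r$first_name, 1L, 1L)
  r$middle_initial <- substr(r$middle_name, 1L, 1L)
  r
}

field_agrees <- function(xa, xb) !is_blank(xa) & !is_blank(xb) & xa == xb

## vectorized points over aligned field vectors from the two sides
score_rule_pairs <- function(a, b, weights) {
  w <- weights$weights
  first_eq <- field_agrees(a$first_name, b$first_name)
  last_eq <- field_agrees(a$last_name, b$last_name)
  w[["exact_full_name"]] * (first_eq & last_eq) +
    w[["exact_first_name"]] * first_eq +
    w[["soundex_first"]] * field_agrees(a$sdx_first, b$sdx_first) +
    w[["soundex_last"]] * field_agrees(a$sdx_last, b$sdx_last) +
    w[["exact_dob"]] * field_agrees(a$dob, b$dob) +
    w[["year_of_birth"]] * field_agrees(a$yob, b$yob) +
    w[["exact_email"]] * field_agrees(a$email, b$email) +
    w[["exact_phone"]] * field_agrees(a$phone, b$phone) +
    w[["exact_address"]] * field_agrees(a$street_address, b$street_address) +
    w[["exact_zip"]] * field_agrees(a$zip, b$zip) +
    w[["exact_gender"]] * field_agrees(a$gender, b$gender) +
    w[["exact_middle_initial"]] * field_agrees(a$middle_initial, b$middle_initial)
}

#' Match one query record against candidates with the rule engine
#'
#' Sums identifier-agreement weights per candidate. The outcome is
#' `matched` if and only if exactly one candidate's points exceed the
#' threshold; zero candidates above threshold, or more than one
#' (ambiguity), yield `unsuccessful`.
#'
#' @param query a one-row registry `data.table`.
#' @param candidates registry `data.table` of candidate records.
#' @param weights a [weight_table()].
#' @return a one-row `data.table`: `record_id`, `status`
#'   (`matched`/`unsuccessful`), `matched_record_id`, `points` (best
#'   candidate's points, 0 when no candidates).
#' @export
rule_match <- function(query, candidates, weights = default_weight_table()) {
  if (!inherits(weights, "weight_table")) config_error("'weights' must be a weight_table")
  q <- prep_rule_fields(query)
  if (nrow(q) != 1L) config_error("'query' must be a single record")
  out <- data.table::data.table(
    record_id = q$record_id, status = "unsuccessful",
    matched_record_id = NA_character_, points = 0
  )
  if (is.null(candidates) || nrow(candidates) == 0L) return(out)
  cand <- prep_rule_fields(candidates)
  qa <- q[rep(1L, nrow(cand))]
  pts <- score_rule_pairs(qa, cand, weights)
  above <- which(pts > weights$match_threshold)
  out$points <- max(pts)
  if (length(above) == 1L) {
    out$status <- "matched"
    out$matched_record_id <- cand$record_id[above]
  }
  out
}

## blocked pair generation for the rule engine: a pair is compared when it
## shares dob, phone, email, or (soundex(last), first initial)
rule_candidate_pairs <- function(a, b) {
  keys <- list(
    dob = function(r) r$dob,
    phone = function(r) r$phone,
    email = function(r) r$email,
    name = function(r) ifelse(is_blank(r$sdx_last) | is_blank(r$first_initial),
      "", paste(r$sdx_last, r$first_initial))
  )
  pieces <- lapply(keys, function(kf) {
    ka <- data.table::data.table(record_id_a = a$record_id, key_value = kf(a))
    kb <- data.table::data.table(record_id_b = b$record_id, key_value = kf(b))
    ka <- ka[!is_blank(key_value)]
    kb <- kb[!is_blank(key_value)]
    merge(ka, kb, by = "key_value", allow.cartesian = TRUE)[
      , .(record_id_a, record_id_b)]
  })
  unique(data.table::rbindlist(pieces))
}

#' Run the rule engine for a whole cohort of queries
#'
#' Applies [rule_match()] semantics to every query record, using blocking
#' (shared DOB, phone, email, or soundex(last)+first-initial) to limit the
#' comparison space.
#'
#' @param queries registry `data.table` of query records (the cohort).
#' @param candidates registry `data.table` of the other site's records.
#' @param weights a [weight_table()].
#' @return `data.table` with one row per query: `record_id`, `status`,
#'   `matched_record_id`, `points`.
#' @export
rule_match_all <- function(queries, candidates, weights = default_weight_table()) {
  if (!inherits(weights, "weight_table")) config_error("'weights' must be a weight_table")
  qa <- prep_rule_fields(queries)
  cb <- prep_rule_fields(candidates)
  out <- data.table::data.table(
    record_id = qa$record_id, status = "unsuccessful",
    matched_record_id = NA_character_, points = 0
  )
  if (nrow(qa) == 0L || nrow(cb) == 0L) return(out[])
  pairs <- rule_candidate_pairs(qa, cb)
  if (nrow(pairs) == 0L) return(out[])
  ia <- match(pairs$record_id_a, qa$record_id)
  ib <- match(pairs$record_id_b, cb$record_id)
  pairs$points <- score_rule_pairs(qa[ia], cb[ib], weights)
  thr <- weights$match_threshold
  per <- pairs[, .(
    best_points = max(points),
    n_above = sum(points > thr),
    matched_record_id = if (sum(points > thr) == 1L) record_id_b[which(points > thr)]
      else NA_character_
  ), by = record_id_a]
  i <- match(per$record_id_a, out$record_id)
  out$points[i] <- per$best_points
  out$matched_record_id[i] <- per$matched_record_id
  out$status[i] <- ifelse(per$n_above == 1L, "matched", "unsuccessful")
  out[]
}
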