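#' Nested score thresholds for the token-overlap matcher
#'
#' Cutoffs on the 0-100 calibrated score. A pair "matches at" a threshold
#' when its score is greater than or equal to the cutoff, so the strict set
#' is structurally contained in the balanced set, which is contained in the
#' permissive set.
#'
#' @param strict,balanced,permissive score cutoffs (defaults 98, 95, 90).
#' @return an object of class `threshold_set`.
#' @export
threshold_set <- function(strict = 98, balanced = 95, permissive = 90) {
  v <- c(strict = strict, balanced = balanced, permissive = permissive)
  if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v > 100)) {
    config_error("thresholds must be scores in [0, 100]")
  }
  if (!(strict >= balanced && balanced >= permissive)) {
    config_error("thresholds must satisfy strict >= balanced >= permissive")
  }
  structure(as.list(v), class = "threshold_set")
}

token_cols <- function(tokens) setdiff(names(tokens), "record_id")

#' Weighted Jaccard similarity between two token arrays
#'
#' Agreement weight over templates where both tokens are non-null and
#' equal, divided by the weight of templates where at least one token is
#' non-null. Templates null on both sides are ignored; if every template is
#' null on both sides the similarity is 0.
#'
#' @param a,b one-row token `data.table`s (or named lists) over the same
#'   schema.
#' @param token_weights optional named non-negative weights per template;
#'   default all 1.
#' @return raw similarity in \[0, 1\].
#' @export
token_similarity <- function(a, b, token_weights = NULL) {
  a <- data.table::as.data.table(a)
  b <- data.table::as.data.table(b)
  ca <- token_cols(a)
  if (!setequal(ca, token_cols(b))) {
    config_error("token arrays use different schemas")
  }
  w <- token_weights %||% setNames(rep(1, length(ca)), ca)
  if (!all(ca %in% names(w)) || any(w < 0)) {
    config_error("'token_weights' must cover every template with non-negative weights")
  }
  va <- unlist(a[1L, ca, with = FALSE])
  vb <- unlist(b[1L, ca, with = FALSE])
  w <- w[ca]
  both <- !is.na(va) & !is.na(vb)
  either <- !is.na(va) | !is.na(vb)
  uw <- sum(w[either])
  if (uw == 0) return(0)
  sum(w[both & va == vb]) / uw
}

## vectorized similarity for candidate pairs (ia/ib row indices into the
## token tables); same definition as token_similarity
score_token_pairs <- function(tok_a, tok_b, ia, ib, token_weights = NULL) {
  cols <- token_cols(tok_a)
  w <- token_weights %||% setNames(rep(1, length(cols)), cols)
  agree_w <- numeric(length(ia))
  union_w <- numeric(length(ia))
  for (cl in cols) {
    va <- tok_a[[cl]][ia]
    vb <- tok_b[[cl]][ib]
    both <- !is.na(va) & !is.na(vb)
    union_w <- union_w + w[[cl]] * ((!is.na(va)) | (!is.na(vb)))
    agree_w <- agree_w + w[[cl]] * (both & va == vb)
  }
  ifelse(union_w > 0, agree_w / union_w, 0)
}

## ---- score calibration -------------------------------------------------

#' Calibrate raw token similarities to a 0-100 match-probability score
#'
#' Fits a monotone non-decreasing map from raw weighted-Jaccard similarity
#' to the empirical probability of being a true pair, via isotonic
#' regression on labeled pairs, scaled to 0-100. This is a transparent
#' stand-in for proprietary score adjustment against benchmarking datasets:
#' a score of s is calibrated so that pairs scoring around s are true
#' matches about s% of the time on data resembling the training pairs.
#'
#' @param labeled_pairs data.frame with numeric `raw` in \[0,1\] and logical
#'   (or 0/1) `label`; both classes must be present.
#' @return an object of class `pprl_calibration`.
#' @export
calibrate_scores <- function(labeled_pairs) {
  lp <- data.table::as.data.table(labeled_pairs)
  if (!all(c("raw", "label") %in% names(lp))) {
    config_error("'labeled_pairs' needs columns 'raw' and 'label'")
  }
  lab <- as.logical(lp$label)
  if (anyNA(lab) || anyNA(lp$raw)) config_error("labeled pairs contain NA")
  if (length(unique(lab)) < 2L) {
    config_error("calibration requires both true and false pairs")
  }
  ord <- order(lp$raw)
  x <- lp$raw[ord]
  y <- as.numeric(lab)[ord]
  fit <- stats::isoreg(x, y)
  dt <- data.table::data.table(x = x, p = fit$yf)
  knots <- dt[, .(p = mean(p)), by = x]  # tie-average keeps monotonicity
  structure(list(x = knots$x, p = pmin(pmax(knots$p, 0), 1)),
    class = "pprl_calibration")
}

#' @export
print.pprl_calibration <- function(x, ...) {
  cat(sprintf("<pprl_calibration> %d knots; raw [%.3f, %.3f] -> score [%.1f, %.1f]\n",
    length(x$x), min(x$x), max(x$x), 100 * min(x$p), 100 * max(x$p)))
  invisible(x)
}

#' Apply a calibration map
#'
#' Linear interpolation between isotonic knots (flat extrapolation beyond
#' the training range); monotone by construction.
#'
#' @param object a `pprl_calibration`.
#' @param raw numeric raw similarities.
#' @param ... unused.
#' @return calibrated scores in \[0, 100\].
#' @export
predict.pprl_calibration <- function(object, raw, ...) {
  if (length(object$x) == 1L) {
    return(rep(100 * object$p, length(raw)))
  }
  100 * stats::approx(object$x, object$p, xout = raw, method = "linear",
    rule = 2, ties = "ordered")$y
}

#' Serialize / restore a calibration map
#'
#' @param calibration a `pprl_calibration`.
#' @param path JSON file path.
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(list(x = calibration$x, p = calibration$p), path,
    digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(x = as.numeric(obj$x), p = as.numeric(obj$p)),
    class = "pprl_calibration")
}

## ---- matching ----------------------------------------------------------

## candidate pairs sharing at least one token value; complete for any pair
## with raw similarity > 0, since agreement on a template IS a shared token
pprl_candidate_pairs <- function(tok_a, tok_b) {
  cols <- token_cols(tok_a)
  la <- data.table::melt(tok_a, id.vars = "record_id", measure.vars = cols,
    variable.name = "template_id", value.name = "token", na.rm = TRUE)
  lb <- data.table::melt(tok_b, id.vars = "record_id", measure.vars = cols,
    variable.name = "template_id", value.name = "token", na.rm = TRUE)
  m <- merge(
    la[, .(record_id_a = record_id, template_id, token)],
    lb[, .(record_id_b = record_id, template_id, token)],
    by = c("template_id", "token"), allow.cartesian = TRUE
  )
  unique(m[, .(record_id_a, record_id_b)])
}

## deterministic greedy one-to-one assignment by descending score,
## ties broken lexicographically by record ids
greedy_assign <- function(scored) {
  sp <- scored[order(-score, record_id_a, record_id_b)]
  ua <- unique(sp$record_id_a)
  ub <- unique(sp$record_id_b)
  fa <- match(sp$record_id_a, ua)
  fb <- match(sp$record_id_b, ub)
  taken_a <- logical(length(ua))
  taken_b <- logical(length(ub))
  keep <- logical(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    if (!taken_a[fa[i]] && !taken_b[fb[i]]) {
      taken_a[fa[i]] <- TRUE
      taken_b[fb[i]] <- TRUE
      keep[i] <- TRUE
    }
  }
  sp[keep]
}

#' Match two tokenized registries with the calibrated token-overlap engine
#'
#' Generates candidate pairs by blocking (pairs sharing at least one token
#' value), scores them by calibrated weighted-Jaccard token agreement,
#' performs a deterministic greedy one-to-one assignment by descending
#' score, and derives the per-threshold match sets from that single
#' assignment — so the strict set is structurally a subset of the balanced
#' set, which is a subset of the permissive set.
#'
#' @param tokens_a,tokens_b token `data.table`s from [tokenize_registry()]
#'   over the same schema and salt.
#' @param calibration a [calibrate_scores()] map.
#' @param thresholds a [threshold_set()].
#' @param token_weights optional per-template weights.
#' @param blocking set `FALSE` to score all cross pairs (small fixtures
#'   only).
#' @return a list of class `pprl_result`: `scored_pairs` (all candidates
#'   with `raw_similarity` and `score`), `assignment` (the one-to-one
#'   pairs), `match_sets` (named list `strict`/`balanced`/`permissive` of
#'   assigned pairs at each cutoff), and `thresholds`.
#' @export
pprl_match <- function(tokens_a, tokens_b, calibration,
                       thresholds = threshold_set(), token_weights = NULL,
                       blocking = TRUE) {
  if (!inherits(calibration, "pprl_calibration")) {
    config_error("'calibration' must be a pprl_calibration")
  }
  if (!inherits(thresholds, "threshold_set")) {
    config_error("'thresholds' must be a threshold_set")
  }
  if (!setequal(token_cols(tokens_a), token_cols(tokens_b))) {
    config_error("token arrays use different schemas")
  }
  if (nrow(tokens_a) == 0L || nrow(tokens_b) == 0L) {
    empty <- data.table::data.table(
      record_id_a = character(0), record_id_b = character(0),
      raw_similarity = numeric(0), score = numeric(0)
    )
    return(structure(list(
      scored_pairs = empty, assignment = empty,
      match_sets = list(strict = empty, balanced = empty, permissive = empty),
      thresholds = thresholds
    ), class = "pprl_result"))
  }
  pairs <- if (blocking) {
    pprl_candidate_pairs(tokens_a, tokens_b)
  } else {
    data.table::CJ(record_id_a = tokens_a$record_id,
                   record_id_b = tokens_b$record_id)
  }
  ia <- match(pairs$record_id_a, tokens_a$record_id)
  ib <- match(pairs$record_id_b, tokens_b$record_id)
  pairs$raw_similarity <- score_token_pairs(tokens_a, tokens_b, ia, ib,
    token_weights)
  pairs$score <- predict(calibration, pairs$raw_similarity)
  assignment <- greedy_assign(pairs)
  match_sets <- lapply(thresholds, function(cut) assignment[score >= cut])
  structure(list(
    scored_pairs = pairs[order(record_id_a, record_id_b)],
    assignment = assignment,
    match_sets = match_sets,
    thresholds = thresholds
  ), class = "pprl_result")
}

#' @export
print.pprl_result <- function(x, ...) {
  cat(sprintf(
    "<pprl_result> %d candidate pairs; assigned %d; matches: strict %d / balanced %d / permissive %d\n",
    nrow(x$scored_pairs), nrow(x$assignment),
    nrow(x$match_sets$strict), nrow(x$match_sets$balanced),
    nrow(x$match_sets$permissive)
  ))
  invisible(x)
}
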