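test_that("threshold_set enforces ordering", {
  expect_s3_class(threshold_set(), "threshold_set")
  expect_error(threshold_set(90, 95, 98), class = "pprl_config_error")
  expect_error(threshold_set(101, 95, 90), class = "pprl_config_error")
})

make_tokens <- function(record_id, values) {
  dt <- data.table::data.table(record_id = record_id)
  for (i in seq_along(values)) dt[[sprintf("T%02d", i)]] <- values[[i]]
  dt
}

test_that("token_similarity is a weighted Jaccard over token agreement", {
  a <- make_tokens("a", as.list(sprintf("h%d", 1:10)))
  b_same <- make_tokens("b", as.list(sprintf("h%d", 1:10)))
  b_disj <- make_tokens("b", as.list(sprintf("x%d", 1:10)))
  expect_equal(token_similarity(a, b_same), 1.0)
  expect_equal(token_similarity(a, b_disj), 0.0)

  ## 6 agreeing of 10 non-null-union templates -> 0.6, vs brute-force oracle
  vals_b <- c(sprintf("h%d", 1:6), sprintf("x%d", 7:10))
  b_six <- make_tokens("b", as.list(vals_b))
  expect_equal(token_similarity(a, b_six), 0.6)
  va <- stats::setNames(sprintf("h%d", 1:10), sprintf("T%02d", 1:10))
  vb <- stats::setNames(vals_b, sprintf("T%02d", 1:10))
  expect_equal(token_similarity(a, b_six), jaccard_oracle(va, vb))

  ## both-null templates are ignored; all-null overlap -> 0
  a2 <- make_tokens("a", list("h1", NA_character_, NA_character_))
  b2 <- make_tokens("b", list("h1", NA_character_, "z"))
  expect_equal(token_similarity(a2, b2), 0.5)
  a3 <- make_tokens("a", list(NA_character_, NA_character_))
  b3 <- make_tokens("b", list(NA_character_, NA_character_))
  expect_equal(token_similarity(a3, b3), 0)

  ## weights shift the ratio
  w <- stats::setNames(c(3, rep(1, 9)), sprintf("T%02d", 1:10))
  expect_equal(token_similarity(a, b_six, w), (3 + 5) / 12)

  ## schema mismatch errors
  expect_error(token_similarity(a, make_tokens("b", list("h1"))),
    class = "pprl_config_error")
})

test_that("token_similarity is symmetric on random arrays", {
  withr::with_seed(9, {
    for (rep in 1:25) {
      va <- ifelse(runif(12) < 0.3, NA, sample(letters[1:5], 12, TRUE))
      vb <- ifelse(runif(12) < 0.3, NA, sample(letters[1:5], 12, TRUE))
      a <- make_tokens("a", as.list(va))
      b <- make_tokens("b", as.list(vb))
      expect_identical(token_similarity(a, b), token_similarity(b, a))
      nm <- stats::setNames(va, sprintf("T%02d", 1:12))
      nb <- stats::setNames(vb, sprintf("T%02d", 1:12))
      expect_equal(token_similarity(a, b), jaccard_oracle(nm, nb))
    }
  })
})

test_that("calibration is monotone, preserves separability, and round-trips", {
  expect_error(calibrate_scores(data.frame(raw = c(.1, .9), label = c(TRUE, TRUE))),
    class = "pprl_config_error")

  withr::with_seed(4, {
    raw <- c(runif(300, 0, 0.5), runif(300, 0.4, 1))
    label <- rep(c(FALSE, TRUE), each = 300)
  })
  cal <- calibrate_scores(data.frame(raw = raw, label = label))
  grid <- seq(0, 1, by = 0.01)
  s <- predict(cal, grid)
  expect_true(all(diff(s) >= -1e-12))
  expect_true(all(s >= 0 & s <= 100))
  ## raw 1.0 scores at least as high as anything below it
  expect_true(all(predict(cal, 1) >= s))

  ## perfectly separable labels stay separated under the monotone map
  cal2 <- calibrate_scores(data.frame(
    raw = c(runif(100, 0, 0.3), runif(100, 0.7, 1)),
    label = rep(c(FALSE, TRUE), each = 100)
  ))
  expect_true(min(predict(cal2, runif(50, 0.7, 1))) >
    max(predict(cal2, runif(50, 0, 0.3))))

  f <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, f)
  cal_back <- read_calibration(f)
  expect_equal(predict(cal_back, grid), s)
})

test_that("calibrated scores track held-out empirical precision", {
  ## overlapping raw distributions with known structure
  gen <- function(n, seed) withr::with_seed(seed, {
    lab <- runif(n) < 0.5
    raw <- ifelse(lab, stats::rbeta(n, 6, 2), stats::rbeta(n, 2, 6))
    data.frame(raw = raw, label = lab)
  })
  cal <- calibrate_scores(gen(4000, 1))
  held <- gen(4000, 2)
  s <- predict(cal, held$raw)
  for (cut in c(50, 70, 90)) {
    sel <- s >= cut
    prec <- mean(held$label[sel])
    n_sel <- sum(sel)
    ## precision at cutoff s should be at least about s/100
    expect_gt(prec, cut / 100 - 3 * sqrt(0.25 / n_sel) - 0.02)
  }
})

test_that("pprl_match yields nested match sets and honors determinism", {
  run <- small_run()
  ms <- run$pprl$match_sets
  key <- function(s) paste(s$record_id_a, s$record_id_b)
  expect_true(all(key(ms$strict) %in% key(ms$balanced)))
  expect_true(all(key(ms$balanced) %in% key(ms$permissive)))
  ## one-to-one
  expect_false(anyDuplicated(run$pprl$assignment$record_id_a) > 0)
  expect_false(anyDuplicated(run$pprl$assignment$record_id_b) > 0)
})

test_that("error-free registries with full overlap match truth exactly at all thresholds", {
  cfg <- sim_config(
    n_site_a = 250L, n_site_b = 250L, overlap_fraction = 1,
    twin_rate = 0, household_rate = 0, compound_surname_fraction = 0,
    ssn_missing_rate = 0, email_missing_rate = 0, phone_missing_rate = 0,
    typo_rate = 0, compound_name_variant_rate = 0, nickname_rate = 0,
    middle_name_inclusion_rate = 1, stale_contact_rate = 0, seed = 77L
  )
  regs <- render_registries(generate_population(cfg), cfg)
  ta <- tokenize_registry(regs$site_a, salt = cfg$salt, quiet = TRUE)
  tb <- tokenize_registry(regs$site_b, salt = cfg$salt, quiet = TRUE)
  cal <- train_calibration(cfg)
  res <- pprl_match(ta, tb, cal)
  for (nm in c("strict", "balanced", "permissive")) {
    got <- res$match_sets[[nm]][order(record_id_a), .(record_id_a, record_id_b)]
    expect_equal(as.data.frame(got),
      as.data.frame(regs$truth[order(record_id_a)]))
  }
})

test_that("blocking never drops a pair with positive raw similarity", {
  cfg <- sim_config(n_site_a = 150L, n_site_b = 150L, seed = 5L)
  regs <- render_registries(generate_population(cfg), cfg)
  ta <- tokenize_registry(regs$site_a, salt = cfg$salt, quiet = TRUE)
  tb <- tokenize_registry(regs$site_b, salt = cfg$salt, quiet = TRUE)
  cal <- train_calibration(cfg)
  blocked <- pprl_match(ta, tb, cal)
  exhaustive <- pprl_match(ta, tb, cal, blocking = FALSE)
  pos <- exhaustive$scored_pairs[raw_similarity > 0]
  expect_true(all(
    paste(pos$record_id_a, pos$record_id_b) %in%
      paste(blocked$scored_pairs$record_id_a, blocked$scored_pairs$record_id_b)
  ))
})
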