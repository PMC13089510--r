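test_that("review_plan validates and defaults to the 6 disagreement categories", {
  p <- review_plan()
  expect_identical(p$categories, 2:7)
  expect_equal(p$n_per_category, 200L)
  expect_error(review_plan(categories = c(2, 2)), class = "pprl_config_error")
  expect_error(review_plan(categories = 9), class = "pprl_config_error")
  expect_error(review_plan(n_per_category = 0), class = "pprl_config_error")
})

test_that("draw_samples is a reproducible within-stratum SRS", {
  run <- small_run()
  plan <- review_plan(n_per_category = 25L, seed = 101L)
  s1 <- suppressWarnings(draw_samples(run$category_table, plan))
  s2 <- suppressWarnings(draw_samples(run$category_table, plan))
  expect_identical(s1, s2)
  ## no duplicates, membership respected, per-category cap
  expect_false(anyDuplicated(s1$record_id) > 0)
  for (cid in unique(s1$category_id)) {
    ids <- s1$record_id[s1$category_id == cid]
    expect_true(all(ids %in% run$category_table$members[[as.character(cid)]]))
    expect_lte(length(ids), 25L)
  }
  ## a short category is taken whole, with a warning
  short_cat <- run$category_table$counts[count > 0 & count < 25]$category_id[1]
  expect_warning(draw_samples(run$category_table,
    review_plan(categories = short_cat, n_per_category = 25L, seed = 1L)),
    "sampling all")
  ## counts-only tables cannot be sampled
  ct0 <- category_table_from_counts(pprl_example("twosite_category_counts.csv"))
  expect_error(draw_samples(ct0, plan), class = "pprl_config_error")
})

test_that("within-stratum inclusion probabilities are uniform (chi-square sanity)", {
  members <- sprintf("A%03d", 1:30)
  ct <- structure(list(
    counts = data.table::data.table(category_id = 1:8,
      count = c(0, 30, rep(0, 6))),
    cohort_size = 30L,
    members = stats::setNames(c(list(character(0)), list(members),
      rep(list(character(0)), 6)), as.character(1:8))
  ), class = "category_table")
  hits <- integer(30)
  for (seed in 1:300) {
    s <- draw_samples(ct, review_plan(categories = 2L, n_per_category = 10L,
      seed = seed))
    hits <- hits + (members %in% s$record_id)
  }
  ## expected 100 inclusions each under SRS
  p <- suppressWarnings(stats::chisq.test(hits)$p.value)
  expect_gt(p, 1e-4)
})

test_that("noiseless adjudication equals truth; noise rates act as configured", {
  assignment <- data.table::data.table(
    record_id = c("A1", "A2", "A3", "A4"),
    category_id = c(2L, 2L, 6L, 7L),
    ce_matched = c(FALSE, FALSE, TRUE, TRUE),
    pprl_level = c("permissive_only", "permissive_only", "permissive_only",
      "permissive_balanced"),
    ce_partner = c(NA, NA, "B3", "B9"),
    pprl_partner = c("B1", "B2", "B3", "B4")
  )
  truth <- data.table::data.table(
    record_id_a = c("A1", "A3", "A4"),
    record_id_b = c("B1", "B3", "B4")
  )
  samples <- assignment[, .(record_id, category_id)]
  adj <- simulate_adjudication(samples, assignment, truth,
    uncertainty_rate = 0, restricted_rate = 0, seed = 1L)
  ## A1 true; A2 false (pair not in truth); A3 true (both partners agree with
  ## truth); A4 false: rule engine proposed B9, contradicting truth
  expect_identical(adj$verdict,
    c("true_match", "false_match", "true_match", "false_match"))

  ## uncertainty_rate = 1 makes every verdict uncertain
  adj_u <- simulate_adjudication(samples, assignment, truth,
    uncertainty_rate = 1, restricted_rate = 0, seed = 1L)
  expect_true(all(adj_u$verdict == "uncertain"))

  ## restricted exclusions land near their configured rate (3 SE)
  big <- data.table::data.table(
    record_id = sprintf("A%04d", 1:1200), category_id = 2L,
    ce_matched = FALSE, pprl_level = "permissive_only",
    ce_partner = NA_character_, pprl_partner = sprintf("B%04d", 1:1200)
  )
  big_truth <- data.table::data.table(record_id_a = big$record_id,
    record_id_b = big$pprl_partner)
  adj_r <- simulate_adjudication(big[, .(record_id, category_id)], big,
    big_truth, uncertainty_rate = 0, restricted_rate = 27 / 1200, seed = 8L)
  n_exc <- sum(adj_r$verdict == "excluded_restricted")
  se <- sqrt(1200 * (27 / 1200) * (1 - 27 / 1200))
  expect_lt(abs(n_exc - 27), 3 * se)
})

test_that("summarize_reviews drops restricted charts from the denominator", {
  adj <- data.table::data.table(
    record_id = sprintf("A%03d", 1:200),
    category_id = 5L,
    verdict = c(rep("excluded_restricted", 24), rep("false_match", 1),
      rep("uncertain", 1), rep("true_match", 174))
  )
  rt <- summarize_reviews(adj)
  expect_equal(rt$sample_reviewed, 176L)
  expect_equal(rt$fm_count, 1L)
  expect_equal(rt$um_count, 1L)

  ## independent recount via table()
  tab <- table(adj$verdict)
  expect_equal(rt$sample_reviewed, 200L - unname(tab["excluded_restricted"]))

  expect_equal(nrow(summarize_reviews(adj[0])), 0L)
  adj$verdict[1] <- "maybe"
  expect_error(summarize_reviews(adj), class = "pprl_config_error")
})

test_that("noiseless audit recovers per-category FM counts exactly", {
  run <- small_run()
  plan <- review_plan(n_per_category = 200L, seed = 55L)
  samples <- suppressWarnings(draw_samples(run$category_table, plan))
  adj <- simulate_adjudication(samples, run$category_table$assignment,
    run$registries$truth, uncertainty_rate = 0, restricted_rate = 0, seed = 2L)
  rt <- summarize_reviews(adj)
  expect_true(all(rt$um_count == 0))

  ## independent recount: proposed partners vs the truth ledger
  truth_key <- paste(run$registries$truth$record_id_a,
    run$registries$truth$record_id_b)
  a <- run$category_table$assignment
  for (i in seq_len(nrow(rt))) {
    ids <- samples$record_id[samples$category_id == rt$category_id[i]]
    sub <- a[match(ids, a$record_id)]
    ok_ce <- is.na(sub$ce_partner) |
      paste(sub$record_id, sub$ce_partner) %in% truth_key
    ok_pprl <- is.na(sub$pprl_partner) |
      paste(sub$record_id, sub$pprl_partner) %in% truth_key
    expect_equal(rt$fm_count[i], sum(!(ok_ce & ok_pprl)))
  }
})

test_that("review tables round-trip and validate from CSV", {
  rt <- read_review_table(pprl_example("twosite_review_counts.csv"))
  expect_equal(rt$category_id, 2:7)
  expect_equal(rt$sample_reviewed, c(200L, 200L, 200L, 176L, 200L, 197L))
  expect_equal(sum(rt$sample_reviewed), 1173L)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("category_id,sample_reviewed,fm_count,um_count\n2,10,8,5", bad)
  expect_error(read_review_table(bad), class = "pprl_config_error")
})
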