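#' Path to a packaged example data file
#'
#' The package ships the exclusive-category counts and the audit review
#' counts from a large published two-site patient-matching evaluation
#' (849 157-patient query cohort) as plain-CSV fixtures, so replication
#' mode needs no input authoring.
#'
#' @param file file name under `extdata/`; `NULL` lists the available
#'   files.
#' @return a file path, or a character vector of file names.
#' @export
#' @examples
#' pprl_example()
#' pprl_example("twosite_category_counts.csv")
pprl_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "pprlaudit")))
  }
  path <- system.file("extdata", file, package = "pprlaudit")
  if (!nzchar(path)) config_error("no packaged example file '%s'", file)
  path
}

#' Replication mode: accuracy report from printed count tables
#'
#' Rebuilds the per-algorithm accuracy analysis from a category-count
#' table and a completed review table (no record-level data needed). With
#' the packaged fixtures this reproduces the published two-site
#' evaluation's totals, projected errors, precision and recall.
#'
#' @param categories CSV path or data.frame of the 8 exclusive category
#'   counts; default: packaged fixture.
#' @param reviews CSV path or data.frame of the review counts; default:
#'   packaged fixture.
#' @param row_map see [default_row_map()].
#' @param confidence CI level.
#' @return an `accuracy_report`.
#' @export
#' @examples
#' rep <- run_replication()
#' rep$algorithms[, c("algorithm", "total_matches", "precision", "recall")]
run_replication <- function(categories = pprl_example("twosite_category_counts.csv"),
                            reviews = pprl_example("twosite_review_counts.csv"),
                            row_map = default_row_map(), confidence = 0.95) {
  ct <- category_table_from_counts(categories)
  rt <- if (is.character(reviews)) read_review_table(reviews) else {
    structure(data.table::as.data.table(reviews),
      class = c("review_table", "data.table", "data.frame"))
  }
  full_report(ct, rt, row_map = row_map, confidence = confidence)
}

## labeled calibration pairs: blocked candidates plus random cross pairs
## (the blocked set under-represents clear non-matches)
calibration_pairs <- function(tokens_a, tokens_b, truth, n_random = 2000L,
                              seed = 1L, token_weights = NULL) {
  cand <- pprl_candidate_pairs(tokens_a, tokens_b)
  rnd <- with_seed(seed, data.table::data.table(
    record_id_a = sample(tokens_a$record_id, n_random, replace = TRUE),
    record_id_b = sample(tokens_b$record_id, n_random, replace = TRUE)
  ))
  pairs <- unique(rbind(cand, rnd))
  ia <- match(pairs$record_id_a, tokens_a$record_id)
  ib <- match(pairs$record_id_b, tokens_b$record_id)
  pairs$raw <- score_token_pairs(tokens_a, tokens_b, ia, ib, token_weights)
  truth_key <- paste(truth$record_id_a, truth$record_id_b)
  pairs$label <- paste(pairs$record_id_a, pairs$record_id_b) %in% truth_key
  pairs[, .(raw, label)]
}

#' Train a calibration map on a freshly simulated labeled world
#'
#' Emulates calibrating the matcher against benchmarking datasets: a
#' registry pair is generated from `config` under a derived seed, its
#' candidate pairs (plus random non-candidate pairs) are labeled by its
#' own truth ledger, and a monotone isotonic map is fitted.
#'
#' @param config a [sim_config()].
#' @param schema token schema used for the run.
#' @param token_weights optional per-template weights.
#' @return a `pprl_calibration`.
#' @export
train_calibration <- function(config, schema = default_token_schema(),
                              token_weights = NULL) {
  cal_cfg <- config
  cal_cfg$seed <- as.integer(derive_seed(config$seed, 7L))
  pop <- generate_population(cal_cfg)
  regs <- render_registries(pop, cal_cfg)
  ta <- tokenize_registry(regs$site_a, schema, config$salt, quiet = TRUE)
  tb <- tokenize_registry(regs$site_b, schema, config$salt, quiet = TRUE)
  lp <- calibration_pairs(ta, tb, regs$truth,
    seed = derive_seed(config$seed, 8L), token_weights = token_weights)
  calibrate_scores(lp)
}

#' Run the full synthetic evaluation pipeline
#'
#' simulate two site registries -> tokenize -> match with both engines ->
#' partition into the 8 exclusive categories -> draw stratified audit
#' samples -> simulate adjudication against ground truth -> estimate FM
#' rates, precision and recall. Fully determined by the config seed.
#'
#' @param config a [sim_config()].
#' @param schema a [token_schema()].
#' @param weights a [weight_table()].
#' @param thresholds a [threshold_set()].
#' @param plan a [review_plan()]; default samples 200 from each
#'   disagreement category with a seed derived from the config seed.
#' @param uncertainty_rate,restricted_rate adjudication noise (see
#'   [simulate_adjudication()]).
#' @param out_dir optional directory to write all intermediate artifacts
#'   plus a run manifest.
#' @param quiet suppress per-stage log messages.
#' @return a list of class `synthetic_run` with the registries, engine
#'   outputs, category table, review table and final `accuracy_report`
#'   (element `report`).
#' @export
run_synthetic <- function(config = sim_config(),
                          schema = default_token_schema(),
                          weights = default_weight_table(),
                          thresholds = threshold_set(),
                          plan = NULL,
                          uncertainty_rate = 0.05,
                          restricted_rate = 0.0225,
                          out_dir = NULL,
                          quiet = TRUE) {
  if (!inherits(config, "sim_config")) config_error("'config' must be a sim_config")
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  say("simulating population and registries (seed %d)", config$seed)
  pop <- generate_population(config)
  regs <- render_registries(pop, config)

  say("tokenizing %d + %d records", nrow(regs$site_a), nrow(regs$site_b))
  tokens_a <- tokenize_registry(regs$site_a, schema, config$salt, quiet = TRUE)
  tokens_b <- tokenize_registry(regs$site_b, schema, config$salt, quiet = TRUE)

  say("training calibration on a derived labeled world")
  calibration <- train_calibration(config, schema)

  say("matching with the token engine")
  pprl <- pprl_match(tokens_a, tokens_b, calibration, thresholds)

  cohort <- regs$site_a$record_id
  if (config$cohort_fraction < 1) {
    cohort <- with_seed(derive_seed(config$seed, 9L),
      sort(sample(cohort, round(config$cohort_fraction * length(cohort)))))
  }
  say("matching %d cohort queries with the rule engine", length(cohort))
  rule <- rule_match_all(regs$site_a[record_id %in% cohort], regs$site_b, weights)

  say("partitioning into exclusive categories")
  ct <- build_category_table(cohort, rule, pprl$match_sets)

  if (is.null(plan)) {
    plan <- review_plan(seed = as.integer(derive_seed(config$seed, 11L)))
  }
  samples <- draw_samples(ct, plan)
  adj <- simulate_adjudication(samples, ct$assignment, regs$truth,
    uncertainty_rate, restricted_rate, seed = derive_seed(config$seed, 13L))
  rt <- summarize_reviews(adj)

  say("estimating accuracy")
  report <- full_report(ct, rt)

  run <- structure(list(
    config = config, registries = regs,
    tokens_a = tokens_a, tokens_b = tokens_b,
    calibration = calibration, pprl = pprl, rule = rule,
    cohort = cohort, category_table = ct, plan = plan,
    samples = samples, adjudications = adj, review_table = rt,
    report = report
  ), class = "synthetic_run")

  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

#' @export
print.synthetic_run <- function(x, ...) {
  cat(sprintf("<synthetic_run> seed %d; sites %d/%d; truth links %d\n",
    x$config$seed, nrow(x$registries$site_a), nrow(x$registries$site_b),
    nrow(x$registries$truth)))
  print(x$report)
  invisible(x)
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_registry(run$registries$site_a, p("site_a.csv"))
  write_registry(run$registries$site_b, p("site_b.csv"))
  write_truth(run$registries$truth, p("truth.csv"))
  write_tokens(run$tokens_a, p("tokens_a.csv"))
  write_tokens(run$tokens_b, p("tokens_b.csv"))
  write_calibration(run$calibration, p("calibration.json"))
  data.table::fwrite(run$pprl$scored_pairs, p("scored_pairs.csv"), eol = "\n")
  for (nm in names(run$pprl$match_sets)) {
    data.table::fwrite(run$pprl$match_sets[[nm]],
      p(sprintf("matches_%s.csv", nm)), eol = "\n")
  }
  data.table::fwrite(run$rule, p("rule_outcomes.csv"), eol = "\n")
  write_category_table(run$category_table, p("category_table.csv"))
  data.table::fwrite(run$category_table$assignment, p("assignment.csv"), eol = "\n")
  data.table::fwrite(run$samples, p("samples.csv"), eol = "\n")
  data.table::fwrite(run$adjudications, p("adjudications.csv"), eol = "\n")
  data.table::fwrite(run$review_table, p("review_table.csv"), eol = "\n")
  write_report(run$report, p("report.json"))

  files <- setdiff(dir(out_dir), "manifest.json")
  cfg <- unclass(run$config)
  cfg$as_of <- format(cfg$as_of)
  manifest <- list(
    package = "pprlaudit",
    version = as.character(utils::packageVersion("pprlaudit")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = cfg,
    thresholds = unclass(run$pprl$thresholds),
    plan = unclass(run$plan),
    file_md5 = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$file_md5) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
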