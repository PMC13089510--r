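test_that("sim_config validates rates, counts and seed", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(typo_rate = 1.2), class = "pprl_config_error")
  expect_error(sim_config(n_site_a = 0), class = "pprl_config_error")
  expect_error(sim_config(overlap_fraction = -0.1), class = "pprl_config_error")
  expect_error(sim_config(salt = ""), class = "pprl_config_error")
  expect_error(sim_config(age_bin_probs = 1:3), class = "pprl_config_error")
})

test_that("sim_config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_site_a: 300", "n_site_b: 400", "overlap_fraction: 0.5",
    "typo_rate: 0.1", "seed: 99"
  ), path)
  cfg <- sim_config_from_yaml(path)
  expect_equal(cfg$n_site_a, 300L)
  expect_equal(cfg$typo_rate, 0.1)
  expect_equal(cfg$seed, 99L)
  writeLines("not_a_field: 1", path)
  expect_error(sim_config_from_yaml(path), class = "pprl_config_error")
})

test_that("generation is deterministic and registry files byte-identical", {
  cfg <- sim_config(n_site_a = 400L, n_site_b = 400L, seed = 11L)
  r1 <- render_registries(generate_population(cfg), cfg)
  r2 <- render_registries(generate_population(cfg), cfg)
  expect_identical(r1$site_a, r2$site_a)
  expect_identical(r1$truth, r2$truth)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_registry(r1$site_b, f1)
  write_registry(r2$site_b, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("population marginals match config within Monte-Carlo error", {
  cfg <- sim_config(n_site_a = 8000L, n_site_b = 4000L, seed = 5L)
  pop <- generate_population(cfg)
  n <- nrow(pop)
  expect_equal(n, 8000L + 4000L - round(0.3 * 4000L))

  ## gender: published two-site marginal, 53.6% female
  p_f <- cfg$gender_probs[["F"]]
  se <- sqrt(p_f * (1 - p_f) / n)
  expect_lt(abs(mean(pop$gender == "F") - p_f), 3 * se)

  ## ssn unique among persons possessing one
  expect_false(anyDuplicated(pop$ssn) > 0)
  expect_false(anyDuplicated(pop$person_id) > 0)

  ## common names: configured fraction carries a top-100 first or last name.
  ## isolated from households/twins, whose surname sharing inflates carriage
  cfg2 <- sim_config(n_site_a = 8000L, n_site_b = 4000L, seed = 5L,
    twin_rate = 0, household_rate = 0)
  pop2 <- generate_population(cfg2)
  p_c <- cfg2$common_name_fraction
  has_rank <- !is.na(pop2$name_commonness_rank) & pop2$name_commonness_rank <= 100
  se <- sqrt(p_c * (1 - p_c) / nrow(pop2))
  expect_lt(abs(mean(has_rank) - p_c), 3 * se)
})

test_that("twin pairs are symmetric, share dob and surname, and match an independent scan", {
  cfg <- sim_config(n_site_a = 6000L, n_site_b = 6000L, twin_rate = 0.02,
    overlap_fraction = 0.5, seed = 3L)
  pop <- generate_population(cfg)
  twins <- pop[!is.na(pop$is_twin_of), ]
  ## brute-force scan: every link resolves, symmetrically
  j <- match(twins$is_twin_of, pop$person_id)
  expect_false(anyNA(j))
  expect_identical(pop$is_twin_of[j], twins$person_id)
  expect_identical(pop$dob[j], twins$dob)
  expect_identical(pop$last_name[j], twins$last_name)
  n <- nrow(pop)
  expect_equal(nrow(twins), 2L * floor(n * 0.02 / 2))

  ## zero-rate case: no one carries a twin link
  pop0 <- generate_population(sim_config(n_site_a = 2000L, n_site_b = 1000L,
    twin_rate = 0, seed = 3L))
  expect_true(all(is.na(pop0$is_twin_of)))
})

test_that("truth ledger is consistent and controlled by overlap_fraction", {
  cfg <- sim_config(n_site_a = 600L, n_site_b = 500L, overlap_fraction = 0.4,
    seed = 21L)
  regs <- render_registries(generate_population(cfg), cfg)
  expect_equal(nrow(regs$truth), round(0.4 * 500))
  ## pairs reference existing records from opposite sites, at most once each
  expect_true(all(regs$truth$record_id_a %in% regs$site_a$record_id))
  expect_true(all(regs$truth$record_id_b %in% regs$site_b$record_id))
  expect_false(anyDuplicated(regs$truth$record_id_a) > 0)
  expect_false(anyDuplicated(regs$truth$record_id_b) > 0)
  ## registries never leak person ids
  expect_false("person_id" %in% names(regs$site_a))

  cfg0 <- sim_config(n_site_a = 300L, n_site_b = 300L, overlap_fraction = 0,
    seed = 21L)
  regs0 <- render_registries(generate_population(cfg0), cfg0)
  expect_equal(nrow(regs0$truth), 0L)
})

test_that("zero corruption with full overlap renders field-identical pairs", {
  cfg <- sim_config(
    n_site_a = 300L, n_site_b = 300L, overlap_fraction = 1,
    ssn_missing_rate = 0, email_missing_rate = 0, phone_missing_rate = 0,
    typo_rate = 0, compound_name_variant_rate = 0, nickname_rate = 0,
    middle_name_inclusion_rate = 1, stale_contact_rate = 0, seed = 13L
  )
  regs <- render_registries(generate_population(cfg), cfg)
  expect_equal(nrow(regs$truth), 300L)
  a <- regs$site_a[match(regs$truth$record_id_a, regs$site_a$record_id)]
  b <- regs$site_b[match(regs$truth$record_id_b, regs$site_b$record_id)]
  for (col in setdiff(names(a), "record_id")) {
    expect_identical(a[[col]], b[[col]])
  }
})

test_that("corruption operators realize their configured rates (3 SE)", {
  ## isolate the typo process on >= 10k persons
  cfg <- sim_config(
    n_site_a = 10000L, n_site_b = 10000L, overlap_fraction = 0.5,
    twin_rate = 0, household_rate = 0, compound_surname_fraction = 0,
    typo_rate = 0.05, compound_name_variant_rate = 0, nickname_rate = 0,
    middle_name_inclusion_rate = 1, stale_contact_rate = 0,
    ssn_missing_rate = 0.35, email_missing_rate = 0, phone_missing_rate = 0,
    seed = 17L
  )
  regs <- render_registries(generate_population(cfg), cfg)

  ## brute-force recount over truth pairs: last names differ iff a typo hit
  ## either site (collisions of identical edits are negligible)
  a <- regs$site_a[match(regs$truth$record_id_a, regs$site_a$record_id)]
  b <- regs$site_b[match(regs$truth$record_id_b, regs$site_b$record_id)]
  p_mismatch <- 1 - (1 - 0.05)^2
  obs <- mean(a$last_name != b$last_name)
  se <- sqrt(p_mismatch * (1 - p_mismatch) / nrow(a))
  expect_lt(abs(obs - p_mismatch), 3 * se)

  ## ssn missingness per site
  obs_ssn <- mean(regs$site_a$ssn == "")
  se <- sqrt(0.35 * 0.65 / nrow(regs$site_a))
  expect_lt(abs(obs_ssn - 0.35), 3 * se)
  ## ssn is never corrupted, only missing
  have <- a$ssn != "" & b$ssn != ""
  expect_identical(a$ssn[have], b$ssn[have])
})

test_that("registry and truth files round-trip through CSV", {
  cfg <- sim_config(n_site_a = 50L, n_site_b = 50L, seed = 2L)
  regs <- render_registries(generate_population(cfg), cfg)
  rf <- withr::local_tempfile(fileext = ".csv")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_registry(regs$site_a, rf)
  write_truth(regs$truth, tf)
  back <- read_registry(rf)
  expect_equal(as.data.frame(back), as.data.frame(regs$site_a))
  expect_equal(as.data.frame(read_truth(tf)), as.data.frame(regs$truth))
  expect_error(read_registry(file.path(tempdir(), "nope.csv")),
    class = "pprl_config_error")
})
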