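#' Simulation configuration for the two-site registry generator
#'
#' Collects every tunable parameter of the synthetic world: registry sizes,
#' the fraction of site-B patients who also attend site A, identity
#' confounders (twins, common names), per-field missingness, and the
#' site-specific PII error processes (typos, nickname use, compound-surname
#' variants, middle-name inclusion, stale contact details). A config plus its
#' seed fully determines the generated registries.
#'
#' Defaults describe a plausible pair of neighbouring health systems: ~30%
#' of site-B patients shared, gender and age marginals taken from a large
#' published two-site cohort (53.6% female; piecewise-uniform ages over
#' decade bins), SSN missing for 30% of records at each site, and low
#' single-digit error rates for each name-corruption process.
#'
#' @param n_site_a,n_site_b number of patients registered at each site.
#' @param overlap_fraction proportion of site-B patients who are also site-A
#'   patients (the cross-site truth links).
#' @param twin_rate proportion of persons who are one member of a twin pair
#'   (twins share date of birth, surname and household contact details).
#' @param household_rate proportion of persons who share a household with
#'   another (non-twin) person: same surname, street address, phone and
#'   zip. Together with twins these are the classic partial-agreement
#'   confounders that make match scores — and false matches — non-trivial.
#' @param common_name_fraction proportion of persons whose first and last
#'   names are drawn from the packaged top-100 frequency-ranked lists.
#' @param compound_surname_fraction proportion of persons with a hyphenated
#'   two-part surname.
#' @param ssn_missing_rate,email_missing_rate,phone_missing_rate per-site
#'   probability that the field is absent from a record.
#' @param typo_rate per-site probability that a name field (first or last)
#'   receives one typographic edit.
#' @param compound_name_variant_rate per-site probability that a hyphenated
#'   surname is rendered with one component dropped ("Smith-Jones" ->
#'   "Smith").
#' @param nickname_rate per-site probability that the first name is rendered
#'   as a nickname ("Robert" -> "Bob") when one is known.
#' @param middle_name_inclusion_rate per-site probability that a person's
#'   middle name appears on the record.
#' @param stale_contact_rate per-site probability that phone, email and
#'   street address are an out-of-date set (regenerated independently).
#' @param gender_probs named probabilities for gender categories `F`, `M`
#'   and `U` (unknown/missing); renormalised to sum to one.
#' @param age_bin_probs probabilities of the eleven decade age bins 0-10,
#'   11-20, ..., 101-110; renormalised.
#' @param as_of reference date ("yyyy-mm-dd") at which ages are measured.
#' @param cohort_fraction fraction of site-A records forming the query
#'   cohort for the rule-based engine.
#' @param salt shared tokenization secret for the linkage run.
#' @param seed integer master seed; all stage seeds derive from it.
#' @return an object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_site_a = 500, n_site_b = 500, seed = 1)
#' cfg$overlap_fraction
sim_config <- function(n_site_a = 5000L,
                       n_site_b = 5000L,
                       overlap_fraction = 0.30,
                       twin_rate = 0.02,
                       household_rate = 0.10,
                       common_name_fraction = 0.30,
                       compound_surname_fraction = 0.08,
                       ssn_missing_rate = 0.35,
                       email_missing_rate = 0.30,
                       phone_missing_rate = 0.15,
                       typo_rate = 0.05,
                       compound_name_variant_rate = 0.30,
                       nickname_rate = 0.07,
                       middle_name_inclusion_rate = 0.75,
                       stale_contact_rate = 0.15,
                       gender_probs = c(F = 0.536, M = 0.458, U = 0.006),
                       age_bin_probs = c(
                         7.1, 9.4, 12.3, 16.4, 13.8, 12.9,
                         12.8, 9.2, 4.4, 1.3, 0.1
                       ),
                       as_of = "2023-06-30",
                       cohort_fraction = 1.0,
                       salt = "pprlaudit-default-salt",
                       seed = 1L) {
  cfg <- list(
    n_site_a = check_count(n_site_a, "n_site_a"),
    n_site_b = check_count(n_site_b, "n_site_b"),
    overlap_fraction = check_rate(overlap_fraction, "overlap_fraction"),
    twin_rate = check_rate(twin_rate, "twin_rate"),
    household_rate = check_rate(household_rate, "household_rate"),
    common_name_fraction = check_rate(common_name_fraction, "common_name_fraction"),
    compound_surname_fraction = check_rate(compound_surname_fraction, "compound_surname_fraction"),
    ssn_missing_rate = check_rate(ssn_missing_rate, "ssn_missing_rate"),
    email_missing_rate = check_rate(email_missing_rate, "email_missing_rate"),
    phone_missing_rate = check_rate(phone_missing_rate, "phone_missing_rate"),
    typo_rate = check_rate(typo_rate, "typo_rate"),
    compound_name_variant_rate = check_rate(compound_name_variant_rate, "compound_name_variant_rate"),
    nickname_rate = check_rate(nickname_rate, "nickname_rate"),
    middle_name_inclusion_rate = check_rate(middle_name_inclusion_rate, "middle_name_inclusion_rate"),
    stale_contact_rate = check_rate(stale_contact_rate, "stale_contact_rate"),
    gender_probs = gender_probs,
    age_bin_probs = age_bin_probs,
    as_of = as_of,
    cohort_fraction = check_rate(cohort_fraction, "cohort_fraction"),
    salt = salt,
    seed = seed
  )
  if (!is.numeric(gender_probs) || is.null(names(gender_probs)) ||
      !all(c("F", "M", "U") %in% names(gender_probs)) ||
      any(gender_probs < 0) || sum(gender_probs) <= 0) {
    config_error("'gender_probs' must be non-negative with names F, M, U")
  }
  if (!is.numeric(age_bin_probs) || length(age_bin_probs) != 11L ||
      any(age_bin_probs < 0) || sum(age_bin_probs) <= 0) {
    config_error("'age_bin_probs' must be 11 non-negative decade-bin weights")
  }
  cfg$gender_probs <- gender_probs[c("F", "M", "U")] / sum(gender_probs)
  cfg$age_bin_probs <- age_bin_probs / sum(age_bin_probs)
  asof <- as.Date(as_of)
  if (is.na(asof)) config_error("'as_of' is not a parseable date: %s", as_of)
  cfg$as_of <- asof
  if (!is.character(salt) || length(salt) != 1L || !nzchar(salt)) {
    config_error("'salt' must be a non-empty string")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    config_error("'seed' must be a single integer")
  }
  cfg$seed <- as.integer(seed %% 2147483647)
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take [sim_config()] defaults.
#'
#' @param path path to a YAML file of `sim_config` fields.
#' @return a `sim_config` object.
#' @export
sim_config_from_yaml <- function(path) {
  if (!file.exists(path)) config_error("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) config_error("unknown config keys: %s", paste(bad, collapse = ", "))
  if (!is.null(vals$gender_probs)) vals$gender_probs <- unlist(vals$gender_probs)
  if (!is.null(vals$age_bin_probs)) vals$age_bin_probs <- unlist(vals$age_bin_probs)
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  sites: A=%d, B=%d (overlap %.0f%% of B)\n",
    x$n_site_a, x$n_site_b, 100 * x$overlap_fraction))
  cat(sprintf("  confounders: twins %.1f%%, common names %.0f%%, compound surnames %.0f%%\n",
    100 * x$twin_rate, 100 * x$common_name_fraction, 100 * x$compound_surname_fraction))
  cat(sprintf("  errors: typo %.1f%%, nickname %.1f%%, compound-variant %.0f%%, stale contact %.0f%%\n",
    100 * x$typo_rate, 100 * x$nickname_rate,
    100 * x$compound_name_variant_rate, 100 * x$stale_contact_rate))
  cat(sprintf("  missing: ssn %.0f%%, email %.0f%%, phone %.0f%%\n",
    100 * x$ssn_missing_rate, 100 * x$email_missing_rate, 100 * x$phone_missing_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
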