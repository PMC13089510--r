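## shared fixtures, built in code and memoized per test session

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

## a small but fully featured simulated world shared across test files
small_config <- function(seed = 42L, ...) {
  sim_config(n_site_a = 1500L, n_site_b = 1500L, seed = seed, ...)
}

small_run <- function() {
  memo("small_run", suppressWarnings(run_synthetic(small_config())))
}

## zero-corruption world: both engines should recover truth exactly
perfect_config <- function(seed = 7L) {
  sim_config(
    n_site_a = 800L, n_site_b = 800L, overlap_fraction = 0.4,
    twin_rate = 0, common_name_fraction = 0.2, compound_surname_fraction = 0,
    ssn_missing_rate = 0, email_missing_rate = 0, phone_missing_rate = 0,
    typo_rate = 0, compound_name_variant_rate = 0, nickname_rate = 0,
    middle_name_inclusion_rate = 1, stale_contact_rate = 0, seed = seed
  )
}

perfect_run <- function() {
  memo("perfect_run",
    suppressWarnings(run_synthetic(perfect_config(),
      uncertainty_rate = 0, restricted_rate = 0)))
}

## a tiny hand-built registry for unit tests
toy_registry <- function() {
  data.table::data.table(
    record_id = c("A000001", "A000002", "A000003"),
    first_name = c("Maria", "James", "Lin"),
    middle_name = c("Luisa", "", "Q"),
    last_name = c("Garcia-Lopez", "Smith", "Chen"),
    gender = c("F", "M", "F"),
    dob = c("02/01/1980", "1975-11-30", "07/15/1992"),
    ssn = c("123-45-6789", "", "987-65-4321"),
    phone = c("310-555-0147", "213-555-0112", ""),
    email = c("maria.garcialopez@example.com", "", "lin.chen@example.com"),
    street_address = c("12 Oak St", "440 Main St", "77 Hill St"),
    zip = c("90025", "90012", "90210")
  )
}

## ---- independent oracles -----------------------------------------------

## American Soundex via a regex/chartr route, independent of the package's
## vector implementation
soundex_oracle <- function(name) {
  s <- tolower(gsub("[^A-Za-z]", "", name))
  if (!nzchar(s)) return("0000")
  f <- toupper(substr(s, 1, 1))
  body <- chartr("bfpvcgjkqsxzdtlmnr", "111122222222334556", s)
  body <- gsub("[hw]", "", body)
  body <- gsub("([1-6])\\1+", "\\1", body)
  if (!substr(s, 1, 1) %in% c("h", "w")) body <- substr(body, 2, nchar(body))
  body <- gsub("[aeiouy]", "", body)
  paste0(f, substr(paste0(body, "000"), 1, 3))
}

## Clopper-Pearson endpoints by bisection on the binomial tail equations
cp_bisect <- function(x, n, conf = 0.95, tol = 1e-12) {
  alpha <- 1 - conf
  solve_p <- function(fun) {
    lo <- 0; hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (fun(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    solve_p(function(p) (1 - pbinom(x - 1, n, p)) - alpha / 2)
  upper <- if (x == n) 1 else
    solve_p(function(p) alpha / 2 - pbinom(x, n, p))
  c(lower, upper)
}

## brute-force weighted Jaccard over token agreement sets
jaccard_oracle <- function(a, b, w = NULL) {
  stopifnot(identical(names(a), names(b)))
  w <- w %||% stats::setNames(rep(1, length(a)), names(a))
  either <- names(a)[!is.na(a) | !is.na(b)]
  agree <- names(a)[!is.na(a) & !is.na(b) & a == b]
  if (!length(either)) return(0)
  sum(w[agree]) / sum(w[either])
}

`%||%` <- function(x, y) if (is.null(x)) y else x
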