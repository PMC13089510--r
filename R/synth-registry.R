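## ---- packaged name resources -------------------------------------------

#' Load a packaged frequency-ranked name list
#'
#' The package ships 120-entry ranked lists of common US given names and
#' surnames (columns `name`, `rank`). Any CSV with those columns can be
#' substituted via `path`.
#'
#' @param which `"first"` or `"last"`.
#' @param path optional path to an alternative ranked list.
#' @return a `data.table` with columns `name` and `rank`.
#' @export
load_name_list <- function(which = c("first", "last"), path = NULL) {
  which <- match.arg(which)
  if (is.null(path)) {
    file <- if (which == "first") "given_names_ranked.csv" else "surnames_ranked.csv"
    path <- system.file("extdata", file, package = "pprlaudit")
  }
  dt <- data.table::fread(path, colClasses = list(character = "name", integer = "rank"))
  if (!all(c("name", "rank") %in% names(dt))) {
    config_error("name list %s lacks 'name'/'rank' columns", path)
  }
  dt[order(rank)]
}

## small nickname map exercising the "Robert vs Bob" failure mode
.nicknames <- c(
  james = "Jim", robert = "Bob", john = "Jack", michael = "Mike",
  william = "Bill", david = "Dave", richard = "Rick", joseph = "Joe",
  thomas = "Tom", christopher = "Chris", charles = "Chuck", daniel = "Dan",
  matthew = "Matt", anthony = "Tony", steven = "Steve", andrew = "Andy",
  kenneth = "Ken", edward = "Ed", timothy = "Tim", nicholas = "Nick",
  jonathan = "Jon", benjamin = "Ben", samuel = "Sam", gregory = "Greg",
  alexander = "Alex", patrick = "Pat", raymond = "Ray", jacob = "Jake",
  zachary = "Zack", jennifer = "Jen", elizabeth = "Liz", patricia = "Pat",
  barbara = "Barb", susan = "Sue", jessica = "Jess", sarah = "Sally",
  margaret = "Peggy", deborah = "Deb", stephanie = "Steph", rebecca = "Becky",
  kimberly = "Kim", katherine = "Kate", christine = "Chris", pamela = "Pam",
  samantha = "Sam", victoria = "Vicky", kathleen = "Kathy", amanda = "Mandy"
)

.street_names <- c(
  "Oak St", "Maple Ave", "Cedar Blvd", "Pine St", "Elm Dr", "Sunset Blvd",
  "Wilshire Blvd", "Olympic Blvd", "Main St", "Hill St", "Vermont Ave",
  "Western Ave", "Highland Ave", "Lincoln Blvd", "Washington Blvd",
  "Venice Blvd", "Beverly Dr", "Robertson Blvd", "La Brea Ave", "Fairfax Ave"
)

.rare_syllables <- c(
  "bel", "cor", "dal", "fen", "gar", "hol", "jas", "kel", "lor", "mar",
  "nor", "pel", "quin", "ros", "sel", "tor", "ven", "wil", "yar", "zan"
)

## pronounceable names guaranteed off the top-100 lists
rare_names <- function(n) {
  a <- sample(.rare_syllables, n, replace = TRUE)
  b <- sample(.rare_syllables, n, replace = TRUE)
  c3 <- sample(c("", "a", "o", "in", "er"), n, replace = TRUE)
  out <- paste0(toupper(substr(a, 1, 1)), substr(a, 2, nchar(a)), b, c3)
  ## prefix marks them as synthetic so they can never collide with the lists
  paste0("Z", tolower(out))
}

weighted_rank_sample <- function(n, n_ranks) {
  ## Zipf-ish draw from a ranked list: rank r with weight 1/r
  if (n == 0L) return(integer(0))
  sample.int(n_ranks, n, replace = TRUE, prob = 1 / seq_len(n_ranks))
}

## ---- population --------------------------------------------------------

#' Generate a synthetic patient population with ground-truth identity
#'
#' Creates the underlying persons later rendered as site registries:
#' names drawn either from the packaged top-100 frequency-ranked lists
#' (with probability `common_name_fraction`) or from a synthetic rare-name
#' generator, gender and decade-binned age marginals from the config, unique
#' SSNs, contact details, hyphenated surnames, and symmetric twin pairs
#' sharing date of birth and surname. These confounders (twins, shared
#' common names with shared DOB) are the substrate of audit false matches.
#'
#' @param config a [sim_config()] object.
#' @param first_name_list,last_name_list optional overrides for the packaged
#'   ranked name lists (paths or `data.table`s with `name`/`rank`).
#' @return a `data.table` of person profiles, one row per person, with
#'   columns `person_id`, name fields, `gender`, `dob` (mm/dd/yyyy), `ssn`,
#'   `phone`, `email`, `street_address`, `zip`, `is_twin_of`, and
#'   `name_commonness_rank` (best rank among first/last, `NA` if unranked).
#' @export
generate_population <- function(config, first_name_list = NULL, last_name_list = NULL) {
  if (!inherits(config, "sim_config")) config_error("'config' must be a sim_config")
  firsts <- if (is.data.frame(first_name_list)) data.table::as.data.table(first_name_list) else load_name_list("first", first_name_list)
  lasts <- if (is.data.frame(last_name_list)) data.table::as.data.table(last_name_list) else load_name_list("last", last_name_list)
  n_top_f <- min(100L, nrow(firsts))
  n_top_l <- min(100L, nrow(lasts))

  n_shared <- round(config$overlap_fraction * config$n_site_b)
  n <- config$n_site_a + config$n_site_b - n_shared

  with_seed(derive_seed(config$seed, 1L), {
    common <- runif(n) < config$common_name_fraction
    nc <- sum(common)

    first_name <- rare_names(n)
    last_name <- rare_names(n)
    first_name[common] <- firsts$name[weighted_rank_sample(nc, n_top_f)]
    last_name[common] <- lasts$name[weighted_rank_sample(nc, n_top_l)]

    ## hyphenated surnames (second component always drawn from the full list)
    compound <- runif(n) < config$compound_surname_fraction
    second <- lasts$name[sample.int(nrow(lasts), sum(compound), replace = TRUE)]
    last_name[compound] <- paste0(last_name[compound], "-", second)

    middle_name <- firsts$name[sample.int(nrow(firsts), n, replace = TRUE)]
    gender <- sample(c("F", "M", ""), n, replace = TRUE, prob = config$gender_probs)

    ## age: decade bin then uniform within the bin
    bin <- sample.int(11L, n, replace = TRUE, prob = config$age_bin_probs)
    age_days <- round(((bin - 1) * 10 + runif(n) * 10) * 365.25)
    dob <- config$as_of - age_days

    ## sample.int avoids materializing the 8e8-wide SSN range
    ssn_int <- sample.int(799999999L, n) + 99999999L
    ssn <- sprintf("%03d-%02d-%04d",
      ssn_int %/% 1000000L, (ssn_int %/% 10000L) %% 100L, ssn_int %% 10000L)
    phone <- sprintf("%03d-%03d-%04d",
      sample(200:989, n, TRUE), sample(200:999, n, TRUE), sample(0:9999, n, TRUE))
    email <- paste0(
      tolower(first_name), ".", tolower(gsub("-", "", last_name)),
      sample.int(9999L, n, replace = TRUE), "@example.com"
    )
    street_address <- paste(sample(100:9999, n, TRUE), sample(.street_names, n, TRUE))
    zip <- sprintf("%05d", sample(90001:90899, n, TRUE))
    person_id <- sprintf("P%07d", seq_len(n))
    dob <- format(dob, "%m/%d/%Y")
    is_twin_of <- rep(NA_character_, n)

    ## twin pairs: symmetric, share dob, surname and household (address,
    ## phone, zip), with distinct first names; household pairs: non-twin
    ## co-residents sharing surname and household contact details. both
    ## produce the partial-agreement false-candidate structure that drives
    ## audit false matches (similar common names with a shared birth date,
    ## twins, family members at one address)
    n_tw <- floor(n * config$twin_rate / 2)
    n_hh <- floor(n * config$household_rate / 2)
    if (n_tw + n_hh > 0) {
      idx <- sample.int(n, 2L * (n_tw + n_hh))
      a <- idx[seq_len(n_tw + n_hh)]
      b <- idx[n_tw + n_hh + seq_len(n_tw + n_hh)]
      last_name[b] <- last_name[a]
      street_address[b] <- street_address[a]
      phone[b] <- phone[a]
      zip[b] <- zip[a]
      same <- which(first_name[b] == first_name[a])
      first_name[b[same]] <- rare_names(length(same))
      if (n_tw > 0) {
        tw <- seq_len(n_tw)
        dob[b[tw]] <- dob[a[tw]]
        ## a realistic share of twins get matching-initial given names
        ## ("Jayden"/"Jaylen"), the hardest confounder for initial-based
        ## identifier combinations
        ini <- tw[runif(n_tw) < 0.4]
        first_name[b[ini]] <- paste0(substr(first_name[a[ini]], 1L, 1L),
          substring(rare_names(length(ini)), 2L))
        is_twin_of[a[tw]] <- person_id[b[tw]]
        is_twin_of[b[tw]] <- person_id[a[tw]]
      }
    }

    base_last <- sub("-.*$", "", last_name)
    rf <- firsts$rank[match(first_name, firsts$name)]
    rl <- lasts$rank[match(base_last, lasts$name)]
    name_commonness_rank <- pmin(rf, rl, na.rm = TRUE)
    name_commonness_rank[is.na(rf) & is.na(rl)] <- NA_integer_

    pop <- data.table::data.table(
      person_id, first_name, middle_name, last_name, gender, dob,
      ssn, phone, email, street_address, zip, is_twin_of,
      name_commonness_rank
    )
    data.table::setattr(pop, "n_shared", n_shared)
    pop[]
  })
}

## ---- site rendering ----------------------------------------------------

apply_typos <- function(x, hit) {
  idx <- which(hit & !is_blank(x))
  if (!length(idx)) return(x)
  for (i in idx) {
    s <- strsplit(x[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(s), 1L)
    op <- sample(c("sub", "del", "trans"), 1L)
    if (op == "trans" && length(s) < 2L) op <- "sub"
    if (op == "sub") {
      repl <- sample(letters, 1L)
      if (tolower(s[pos]) == repl) repl <- sample(setdiff(letters, repl), 1L)
      s[pos] <- if (s[pos] %in% LETTERS) toupper(repl) else repl
    } else if (op == "del" && length(s) > 1L) {
      s <- s[-pos]
    } else if (op == "trans") {
      if (pos == length(s)) pos <- pos - 1L
      s[c(pos, pos + 1L)] <- s[c(pos + 1L, pos)]
    }
    x[i] <- paste(s, collapse = "")
  }
  x
}

render_site <- function(pop, site, config) {
  n <- nrow(pop)
  r <- pop[, .(person_id, first_name, middle_name, last_name, gender, dob,
               ssn, phone, email, street_address, zip)]

  ## nickname substitution before typos: typos hit whatever is rendered
  nick <- .nicknames[tolower(r$first_name)]
  use_nick <- !is.na(nick) & runif(n) < config$nickname_rate
  r$first_name[use_nick] <- nick[use_nick]

  ## compound-surname variants: drop one component of a hyphenated surname
  hyph <- grepl("-", r$last_name, fixed = TRUE)
  vary <- hyph & runif(n) < config$compound_name_variant_rate
  if (any(vary)) {
    parts <- strsplit(r$last_name[vary], "-", fixed = TRUE)
    keep_first <- runif(sum(vary)) < 0.5
    r$last_name[vary] <- vapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      if (keep_first[i]) p[1L] else p[length(p)]
    }, character(1))
  }

  r$first_name <- apply_typos(r$first_name, runif(n) < config$typo_rate)
  r$last_name <- apply_typos(r$last_name, runif(n) < config$typo_rate)

  ## middle name recorded only sometimes; stale contact sets replace
  ## phone/email/address wholesale (moves, carrier changes)
  r$middle_name[runif(n) >= config$middle_name_inclusion_rate] <- ""
  stale <- runif(n) < config$stale_contact_rate
  ns <- sum(stale)
  if (ns) {
    r$phone[stale] <- sprintf("%03d-%03d-%04d",
      sample(200:989, ns, TRUE), sample(200:999, ns, TRUE), sample(0:9999, ns, TRUE))
    r$email[stale] <- paste0(tolower(sub("-.*$", "", r$last_name[stale])),
      sample.int(99999L, ns, replace = TRUE), "@mail.example.org")
    r$street_address[stale] <- paste(sample(100:9999, ns, TRUE),
      sample(.street_names, ns, TRUE))
  }

  r$ssn[runif(n) < config$ssn_missing_rate] <- ""
  r$email[runif(n) < config$email_missing_rate] <- ""
  r$phone[runif(n) < config$phone_missing_rate] <- ""

  ## shuffle row order and assign site-local record ids
  r <- r[sample.int(n)]
  r[, record_id := sprintf("%s%06d", site, .I)]
  data.table::setcolorder(r, c("record_id", "person_id"))
  r[]
}

#' Render two site registries and the truth ledger from a population
#'
#' Each site sees an independently corrupted view of its patients: the
#' configured error and missingness processes are applied per record per
#' site, record order is shuffled, and opaque site-local record ids are
#' assigned. The returned registries carry no `person_id`; the ground-truth
#' identity mapping lives only in the truth ledger of cross-site record-id
#' pairs.
#'
#' @param population output of [generate_population()].
#' @param config the same [sim_config()] used for the population.
#' @param seed RNG seed for the corruption processes; defaults to a stream
#'   derived from `config$seed`.
#' @return a list of class `registry_pair`: `site_a`, `site_b` (record
#'   `data.table`s), and `truth` (`record_id_a`, `record_id_b` pairs).
#' @export
render_registries <- function(population, config, seed = derive_seed(config$seed, 2L)) {
  if (!inherits(config, "sim_config")) config_error("'config' must be a sim_config")
  n_shared <- attr(population, "n_shared")
  if (is.null(n_shared)) config_error("'population' must come from generate_population()")
  n <- nrow(population)
  n_a <- config$n_site_a
  if (n != n_a + config$n_site_b - n_shared) {
    config_error("population size inconsistent with config counts")
  }
  idx_a <- seq_len(n_a)
  idx_shared <- seq.int(n_a - n_shared + 1L, length.out = n_shared)
  idx_b <- c(idx_shared, seq.int(n_a + 1L, length.out = n - n_a))

  with_seed(seed, {
    rec_a <- render_site(population[idx_a], "A", config)
    rec_b <- render_site(population[idx_b], "B", config)
  })

  shared_ids <- population$person_id[idx_shared]
  truth <- merge(
    rec_a[person_id %in% shared_ids, .(person_id, record_id_a = record_id)],
    rec_b[person_id %in% shared_ids, .(person_id, record_id_b = record_id)],
    by = "person_id"
  )[order(record_id_a), .(record_id_a, record_id_b)]

  rec_a[, person_id := NULL]
  rec_b[, person_id := NULL]
  structure(list(site_a = rec_a[], site_b = rec_b[], truth = truth),
    class = "registry_pair")
}

#' @export
print.registry_pair <- function(x, ...) {
  cat(sprintf("<registry_pair> site A: %d records, site B: %d records, truth links: %d\n",
    nrow(x$site_a), nrow(x$site_b), nrow(x$truth)))
  invisible(x)
}

## ---- registry I/O ------------------------------------------------------

.registry_cols <- c(
  "record_id", "first_name", "middle_name", "last_name", "gender", "dob",
  "ssn", "phone", "email", "street_address", "zip"
)

#' Write / read a registry file
#'
#' Registries are plain CSV with a fixed column order (`record_id`,
#' `first_name`, `middle_name`, `last_name`, `gender`, `dob` as mm/dd/yyyy,
#' `ssn`, `phone`, `email`, `street_address`, `zip`); the empty string
#' encodes a missing field. Writing is byte-deterministic.
#'
#' @param records a registry `data.table`.
#' @param path file path.
#' @return `write_registry` returns `path` invisibly; `read_registry`
#'   returns a `data.table`.
#' @export
write_registry <- function(records, path) {
  miss <- setdiff(.registry_cols, names(records))
  if (length(miss)) config_error("registry lacks columns: %s", paste(miss, collapse = ", "))
  out <- records[, .registry_cols, with = FALSE]
  data.table::fwrite(out, path, na = "", quote = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) config_error("registry file not found: %s", path)
  dt <- data.table::fread(path, colClasses = "character", na.strings = NULL)
  miss <- setdiff(.registry_cols, names(dt))
  if (length(miss)) config_error("registry %s lacks columns: %s", path, paste(miss, collapse = ", "))
  dt
}

#' Write / read a truth ledger of cross-site record-id pairs
#'
#' @param truth `data.table` with `record_id_a`, `record_id_b`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth[, .(record_id_a, record_id_b)], path, eol = "\n")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  data.table::fread(path, colClasses = "character")
}
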