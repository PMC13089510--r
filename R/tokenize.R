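## ---- feature extractors ------------------------------------------------

## each extractor maps a normalized registry data.table to a character
## vector; "" marks a missing feature (propagates to a null token)
.token_features <- list(
  last_name = function(r) r$last_name,
  first_name = function(r) r$first_name,
  first_initial = function(r) substr(r$first_name, 1L, 1L),
  middle_initial = function(r) substr(r$middle_name, 1L, 1L),
  soundex_last = function(r) ifelse(is_blank(r$last_name), "", soundex(r$last_name)),
  soundex_first = function(r) ifelse(is_blank(r$first_name), "", soundex(r$first_name)),
  gender = function(r) r$gender,
  dob = function(r) r$dob,
  yob = function(r) ifelse(is_blank(r$dob), "", substr(r$dob, 7L, 10L)),
  ssn = function(r) r$ssn,
  phone = function(r) r$phone,
  email = function(r) r$email,
  zip = function(r) r$zip,
  street_address = function(r) r$street_address
)

#' Token schema: ordered hashed feature-combination templates
#'
#' A schema is an ordered list of templates; each template names the PII
#' features whose normalized values are concatenated and HMAC-hashed into
#' one token. Records agree on a template exactly when they agree on every
#' constituent feature.
#'
#' @param templates a named list: `template_id = c(feature, ...)`. Valid
#'   features: `r paste(names(pprlaudit:::.token_features), collapse = ", ")`.
#' @return an object of class `token_schema`.
#' @seealso [default_token_schema()]
#' @export
token_schema <- function(templates) {
  if (!is.list(templates) || is.null(names(templates)) ||
      anyDuplicated(names(templates)) || any(!nzchar(names(templates)))) {
    config_error("'templates' must be a uniquely named list")
  }
  for (id in names(templates)) {
    feats <- templates[[id]]
    bad <- setdiff(feats, names(.token_features))
    if (length(bad)) {
      config_error("template '%s' uses unknown features: %s", id,
        paste(bad, collapse = ", "))
    }
    if (!length(feats)) config_error("template '%s' has no features", id)
  }
  structure(templates, class = "token_schema")
}

#' Default 18-template token schema
#'
#' Eighteen feature combinations built from the canonical published
#' combination (last name + first initial + gender + DOB) plus standard
#' hashed-linkage practice: exact-name, phonetic-name, SSN-, phone-, email-,
#' and address-anchored combinations. The exact template set used by
#' commercial tokenizers is proprietary; this schema is a documented,
#' overridable stand-in with comparable richness.
#'
#' @return a `token_schema` of 18 templates.
#' @export
default_token_schema <- function() {
  token_schema(list(
    T01 = c("last_name", "first_initial", "gender", "dob"),
    T02 = c("last_name", "first_name", "gender", "dob"),
    T03 = c("soundex_last", "soundex_first", "gender", "dob"),
    T04 = c("last_name", "first_name", "dob"),
    T05 = c("ssn"),
    T06 = c("last_name", "first_name", "ssn"),
    T07 = c("ssn", "dob"),
    T08 = c("ssn", "first_initial", "gender"),
    T09 = c("last_name", "first_name", "gender", "yob", "zip"),
    T10 = c("email"),
    T11 = c("email", "dob"),
    T12 = c("phone"),
    T13 = c("phone", "last_name"),
    T14 = c("first_name", "gender", "dob", "zip"),
    T15 = c("last_name", "first_name", "gender", "phone"),
    T16 = c("soundex_last", "first_initial", "gender", "dob"),
    T17 = c("street_address", "zip", "last_name"),
    T18 = c("first_name", "last_name", "email")
  ))
}

## ---- normalization -----------------------------------------------------

#' Normalize PII fields prior to tokenization
#'
#' Hyphens are removed from SSNs and phone numbers and dates of birth are
#' standardized to mm/dd/yyyy (ISO yyyy-mm-dd input is accepted). As a
#' documented extension beyond that minimal preprocessing, name and email
#' fields are whitespace-trimmed and case-folded to lower case and gender
#' to upper case, so that hashed exact-match tokens are not defeated by
#' case or spacing. Missing fields stay missing; the operation is
#' idempotent. Records whose DOB cannot be parsed are dropped with a
#' message and recorded in the `"invalid_records"` attribute.
#'
#' @param records a registry `data.table` (see [read_registry()]).
#' @return the normalized `data.table`; attribute `invalid_records` holds
#'   the `record_id`s excluded for unparseable dates.
#' @export
normalize_pii <- function(records) {
  r <- data.table::as.data.table(records)
  trimlow <- function(x) tolower(trimws(x))
  for (col in c("first_name", "middle_name", "last_name", "email",
                "street_address")) {
    if (col %in% names(r)) r[[col]] <- trimlow(r[[col]])
  }
  if ("gender" %in% names(r)) r$gender <- toupper(trimws(r$gender))
  for (col in c("ssn", "phone")) {
    if (col %in% names(r)) r[[col]] <- gsub("-", "", trimws(r[[col]]), fixed = TRUE)
  }
  if ("zip" %in% names(r)) r$zip <- trimws(r$zip)
  if ("dob" %in% names(r)) {
    raw <- trimws(r$dob)
    out <- rep(NA_character_, length(raw))
    blank <- is_blank(raw)
    out[blank] <- ""
    mdy <- grepl("^\\d{2}/\\d{2}/\\d{4}$", raw)
    out[mdy] <- raw[mdy]
    iso <- !blank & !mdy & grepl("^\\d{4}-\\d{2}-\\d{2}$", raw)
    if (any(iso)) {
      d <- as.Date(raw[iso], format = "%Y-%m-%d")
      out[iso] <- ifelse(is.na(d), NA_character_, format(d, "%m/%d/%Y"))
    }
    ## validate the mm/dd/yyyy strings actually parse as dates
    chk <- which(!is.na(out) & nzchar(out))
    bad_date <- chk[is.na(as.Date(out[chk], format = "%m/%d/%Y"))]
    out[bad_date] <- NA_character_
    invalid <- which(is.na(out))
    r$dob <- out
    if (length(invalid)) {
      ids <- if ("record_id" %in% names(r)) r$record_id[invalid] else invalid
      message(sprintf("normalize_pii: excluded %d record(s) with unparseable dob",
        length(invalid)))
      r <- r[-invalid]
      data.table::setattr(r, "invalid_records", ids)
      return(r[])
    }
  }
  data.table::setattr(r, "invalid_records", character(0))
  r[]
}

## ---- hashing -----------------------------------------------------------

## canonical pre-hash string: template id and features joined by the unit
## separator (0x1F); token = lowercase hex HMAC-SHA256 keyed by the salt
token_canonical <- function(template_id, features) {
  paste(c(template_id, features), collapse = "\x1f")
}

hmac_hex <- function(msg, salt) {
  as.character(openssl::sha256(msg, key = salt))
}

#' Build one hashed token for a record
#'
#' Extracts the template's features from a normalized record and returns
#' the keyed one-way hash (HMAC-SHA256) of the canonical string
#' `template_id<US>feature1<US>...` where `<US>` is the unit separator
#' (0x1F). If any constituent feature is missing the token is `NA`.
#'
#' @param record a one-row normalized registry `data.table` (or list).
#' @param template character vector of feature names.
#' @param salt shared secret string for the linkage run.
#' @param template_id id mixed into the canonical string.
#' @return a 64-character hex digest, or `NA_character_`.
#' @export
build_token <- function(record, template, salt, template_id = "T") {
  r <- data.table::as.data.table(record)
  if (nrow(r) != 1L) config_error("build_token expects a single record")
  feats <- vapply(template, function(f) .token_features[[f]](r), character(1))
  if (any(is_blank(feats))) return(NA_character_)
  hmac_hex(token_canonical(template_id, feats), salt)
}

#' Tokenize a registry into per-template hashed token arrays
#'
#' Records are normalized (see [normalize_pii()]) and each template of the
#' schema is hashed per record. Tokens are `NA` wherever any constituent
#' feature is missing; a per-template null count is attached as the
#' `"null_counts"` attribute and reported via `message()`.
#'
#' @param records registry `data.table`.
#' @param schema a [token_schema()]; default [default_token_schema()].
#' @param salt shared secret string; must be non-empty.
#' @param quiet suppress the null-count log line.
#' @return a `data.table`: `record_id` plus one token column per template,
#'   row order matching the (valid) input records.
#' @export
tokenize_registry <- function(records, schema = default_token_schema(), salt,
                              quiet = FALSE) {
  if (!inherits(schema, "token_schema")) config_error("'schema' must be a token_schema")
  if (missing(salt) || !is.character(salt) || length(salt) != 1L || !nzchar(salt)) {
    config_error("'salt' must be a non-empty string")
  }
  r <- normalize_pii(records)
  out <- data.table::data.table(record_id = r$record_id)
  if (nrow(r) == 0L) {
    for (id in names(schema)) out[[id]] <- character(0)
    return(out[])
  }
  nulls <- integer(length(schema))
  names(nulls) <- names(schema)
  for (id in names(schema)) {
    feats <- lapply(schema[[id]], function(f) .token_features[[f]](r))
    missing_any <- Reduce(`|`, lapply(feats, is_blank))
    canon <- do.call(paste, c(list(id), feats, sep = "\x1f"))
    tok <- hmac_hex(canon, salt)
    tok[missing_any] <- NA_character_
    out[[id]] <- tok
    nulls[[id]] <- sum(missing_any)
  }
  if (!quiet) {
    message(sprintf("tokenize_registry: %d records; null tokens per template: %s",
      nrow(out), paste(sprintf("%s=%d", names(nulls), nulls), collapse = " ")))
  }
  data.table::setattr(out, "null_counts", nulls)
  out[]
}

#' Write / read token arrays
#'
#' CSV with `record_id` plus one column per template; empty string encodes
#' a null token. The salt is never written.
#'
#' @param tokens output of [tokenize_registry()].
#' @param path file path.
#' @export
write_tokens <- function(tokens, path) {
  data.table::fwrite(tokens, path, na = "", quote = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_tokens
#' @export
read_tokens <- function(path) {
  dt <- data.table::fread(path, colClasses = "character", na.strings = NULL)
  for (col in setdiff(names(dt), "record_id")) {
    dt[[col]][!nzchar(dt[[col]])] <- NA_character_
  }
  dt
}
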