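`%||%` <- function(x, y) if (is.null(x)) y else x

## missing PII is encoded as NA or "" throughout
is_blank <- function(x) is.na(x) | !nzchar(x)

#' Round half away from zero
#'
#' Display rounding used for all printed counts and percentages. Unlike
#' [base::round()], which rounds half to even, 0.5 always rounds up, so a
#' projected count of 1745.85 prints as 1746 and a precision of 0.99586
#' prints as 99.6%.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  ## pre-round far below the target precision to absorb binary float fuzz
  sign(x) * floor(round(abs(x) * p, 8) + 0.5) / p
}

## percent formatting as in the printed review tables: >= 10% integer, else 1 dp
format_rate_pct <- function(x) {
  ifelse(is.na(x), "NA",
    ifelse(x == 0, "0",
      ifelse(round_half_up(100 * x, 1) >= 10,
        sprintf("%.0f", round_half_up(100 * x, 0)),
        sprintf("%.1f", round_half_up(100 * x, 1))
      )
    )
  )
}

## evaluate code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

## deterministic per-stage seed streams below 2^31
derive_seed <- function(seed, offset) {
  ((as.numeric(seed) %% 2147483647) * 31 + offset * 10007) %% 2147483629 + 1
}

config_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
    class = c("pprl_config_error", "error", "condition")
  ))
}

invariant_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
    class = c("pprl_invariant_error", "error", "condition")
  ))
}

inestimable_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
    class = c("pprl_inestimable_error", "error", "condition")
  ))
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    config_error("'%s' must be a single number in [0, 1], got %s", name,
      paste(format(x), collapse = ","))
  }
  as.numeric(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    config_error("'%s' must be a single positive integer, got %s", name,
      paste(format(x), collapse = ","))
  }
  as.integer(x)
}
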