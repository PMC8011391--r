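#' Sentinel returned by classifiers that decline to assign a species
#'
#' All five classifiers return this string instead of a species name when
#' their decision rule reaches no qualifying majority. It is reserved: species
#' names in a [label_set()] may not equal it.
#'
#' @export
AMBIGUOUS <- "AMBIGUOUS"

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# `seed = NULL` uses (and advances) the current RNG stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# round() in R is round-half-even; benchmark designs need half-up.
round_half_up <- function(x) floor(x + 0.5)

stop_specurate <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "specurate_error")))
}

# Shared error for pipelines that complete but retain nothing (e.g. all
# markers filtered away); callers can distinguish it from hard failures.
stop_empty <- function(msg) stop_specurate(msg, "specurate_empty_result")

`%||%` <- function(a, b) if (is.null(a)) b else a
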