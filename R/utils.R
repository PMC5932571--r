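# Internal helpers: argument checking and seeded RNG scoping.

stop_invalid <- function(...) {
  stop(structure(
    class = c("larvatk_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_boundary = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid("`", name, "` must be a single non-missing number")
  }
  if (finite && !is.finite(x)) stop_invalid("`", name, "` must be finite")
  ok <- if (allow_boundary) x >= lower && x <= upper else x > lower && x < upper
  if (!ok) {
    rel <- if (allow_boundary) c("in [", "]") else c("in (", ")")
    stop_invalid("`", name, "` must be ", rel[1L], lower, ", ", upper, rel[2L],
                 " (got ", format(x), ")")
  }
  invisible(x)
}

check_positive <- function(x, name) check_number(x, name, lower = 0, allow_boundary = FALSE)
check_non_negative <- function(x, name) check_number(x, name, lower = 0)

check_times <- function(times) {
  if (!is.numeric(times) || length(times) == 0L || anyNA(times)) {
    stop_invalid("`times` must be a non-empty numeric vector without NAs")
  }
  if (any(times < 0)) stop_invalid("`times` must be non-negative (hours since exposure start)")
  if (is.unsorted(times)) stop_invalid("`times` must be sorted in increasing order")
  invisible(times)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_invalid("`seed` must be a single integer (explicit seeds, no global state)")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
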