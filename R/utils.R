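## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

revcumsum <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    x[n:1, , drop = FALSE] -> xr
    apply(xr, 2, cumsum)[n:1, , drop = FALSE]
  } else {
    rev(cumsum(rev(x)))
  }
}

## validate a (time, event) outcome table
check_outcomes <- function(outcomes, n = NULL) {
  if (!is.data.frame(outcomes) || !all(c("time", "event") %in% names(outcomes)))
    stop("`outcomes` must be a data frame with columns `time` and `event`",
         call. = FALSE)
  if (any(!is.finite(outcomes$time)) || any(outcomes$time <= 0))
    stop("all outcome times must be finite and > 0", call. = FALSE)
  if (!all(outcomes$event %in% c(0, 1)))
    stop("`event` must be 0/1", call. = FALSE)
  if (!is.null(n) && nrow(outcomes) != n)
    stop("`outcomes` has ", nrow(outcomes), " rows but expected ", n, call. = FALSE)
  invisible(outcomes)
}

## derive a reproducible 32-bit child seed from a master seed and a counter,
## so increasing the number of repeats never changes earlier repeats
child_seed <- function(seed, k) {
  as.integer((as.double(seed) + 7919 * as.double(k)) %% 2147483629)
}
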