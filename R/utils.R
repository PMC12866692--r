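#' Derive an independent sub-seed from a master seed
#'
#' Simulation, rendering and noise each draw from their own RNG stream so
#' that, e.g., adding image rendering to a run does not perturb the particle
#' trajectories. Sub-seeds are derived deterministically from the master
#' seed and a purpose label, and stay below 2^31.
#'
#' @param seed integer master seed.
#' @param purpose character label ("init", "noise", "render", ...).
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((abs(seed) * 69069 + h * 7919 + 12345) %% 2147483647)
}

#' Evaluate an expression under a temporary RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Centered moving average, NA-aware
#' @keywords internal
moving_average <- function(x, window) {
  stopifnot(window >= 1)
  if (window == 1) return(x)
  n <- length(x)
  half <- floor(window / 2)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    v <- x[lo:hi]
    if (any(is.finite(v))) out[i] <- mean(v, na.rm = TRUE)
  }
  out
}

# half-open bin lookup: index of bin [breaks[k], breaks[k+1]) containing x,
# NA outside range
bin_index <- function(x, breaks) {
  idx <- findInterval(x, breaks, left.open = FALSE, rightmost.closed = FALSE)
  idx[x >= breaks[length(breaks)]] <- NA_integer_
  idx[idx == 0L] <- NA_integer_
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
  invisible(TRUE)
}
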