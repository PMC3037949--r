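# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}

# Derive a reproducible child seed from a master seed and a sequence of
# labels (strings or integers). Kept below 2^31 so it is a valid R integer.
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483629
  h <- (abs(as.double(master)) %% m)
  parts <- unlist(lapply(list(...), function(x) {
    utf8ToInt(paste(as.character(x), collapse = "|"))
  }), use.names = FALSE)
  for (v in c(1L, parts)) h <- (h * 48271 + as.double(v)) %% m
  as.integer(max(1, h))
}

# Round half up at `digits` decimals (R's round() rounds half to even).
# Inputs here are ratios of small integers, so snapping the scaled value to
# 7 decimals first removes binary representation error before the floor.
round_half_up <- function(x, digits = 2L) {
  scaled <- round(x * 10^digits, 7)
  floor(scaled + 0.5) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
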