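#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores whatever state existed before, so seeded helpers do not disturb
#' the caller's random stream. A `NULL` seed evaluates `code` unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage seed from a master seed; kept strictly below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% (.Machine$integer.max - 1L)) + 1L
}

wn_log <- function(fmt, ...) message(sprintf(paste0("[wnorm] ", fmt), ...))

# Clamp a numeric vector to [lo, hi], logging how many values were moved.
clamp_logged <- function(x, lo = -Inf, hi = Inf, what = "value") {
  n_bad <- sum(x < lo | x > hi, na.rm = TRUE)
  if (n_bad > 0L)
    wn_log("clamped %d %s value(s) to [%g, %g]", n_bad, what, lo, hi)
  pmin(pmax(x, lo), hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_wnorm <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_wnorm("%s is missing required column(s): %s",
               what, paste(missing, collapse = ", "))
  invisible(df)
}
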