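# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log(sum(exp(x)))
#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Two-sided normal p-value from an estimate and its standard error
#' @noRd
z_pvalue <- function(estimate, se) {
  2 * stats::pnorm(-abs(estimate / se))
}

#' Derive a child RNG seed from a base seed and a stream label.
#'
#' All randomness in the package flows from one integer seed; independent
#' streams (per gene, per ancestry, per replicate) get reproducible child
#' seeds without global state. Kept strictly below 2^31.
#' @noRd
child_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (k in utf8ToInt(lab)) h <- (h * 33 + k) %% 2147483629
  as.integer(h)
}

#' Evaluate an expression under a local RNG state
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Not-applicable sentinel used throughout the cascade
#'
#' Methods that cannot be evaluated (too few instruments, empty overlap)
#' return this flag instead of failing; the causal-call conjunction skips
#' not-applicable criteria.
#' @param reason short explanation
#' @return object of class `mr_na`
#' @export
not_applicable <- function(reason = "") {
  structure(list(reason = reason), class = "mr_na")
}

#' Test for the not-applicable sentinel
#' @param x object
#' @return logical
#' @export
is_na_result <- function(x) inherits(x, "mr_na")

#' @export
print.mr_na <- function(x, ...) {
  cat("<not applicable>", if (nzchar(x$reason)) paste0(" (", x$reason, ")"),
      "\n", sep = "")
  invisible(x)
}

stop_if_not_scalar_prob <- function(x, name, open_left = TRUE,
                                    open_right = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) stop(sprintf("`%s` must be a probability in %s0,1%s", name,
                        if (open_left) "(" else "[",
                        if (open_right) ")" else "]"), call. = FALSE)
  invisible(x)
}
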