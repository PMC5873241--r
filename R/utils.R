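# internal helpers

#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means: use (and advance) the current
# stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ds <- function(...) stop(..., call. = FALSE)

# Monte Carlo p-value, (r + 1) / (R + 1) convention; ties count as extreme.
mc_pvalue <- function(null, observed, tail = c("lower", "upper", "two_sided"),
                      tol = 1e-12) {
  tail <- match.arg(tail)
  r <- switch(tail,
    lower = sum(null <= observed + tol),
    upper = sum(null >= observed - tol),
    two_sided = sum(abs(null) >= abs(observed) - tol)
  )
  (r + 1) / (length(null) + 1)
}

first_appearance_factor <- function(x) factor(x, levels = unique(x))
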