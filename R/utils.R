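# Internal helpers: logging and argument checks.

n4d_verbose <- function() isTRUE(getOption("nodule4d.verbose", FALSE))

#' @keywords internal
n4d_log <- function(...) {
  if (n4d_verbose()) message("[nodule4d] ", sprintf(...))
  invisible(NULL)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}

# Run `expr` under a locally-seeded RNG without disturbing the caller's
# random stream. All generator entry points route through this.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
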