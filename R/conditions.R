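# Structured error conditions shared across the package.
# Every user-facing failure carries a class so callers (and the CLI) can
# map failure categories to distinct exit codes.

lf_abort <- function(message, class, call = sys.call(-1), ...) {
  cond <- structure(
    class = c(class, "latticefit_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

lf_domain_error <- function(message, ...) {
  lf_abort(message, "latticefit_domain_error", call = sys.call(-1), ...)
}

lf_invalid_structure <- function(message, ...) {
  lf_abort(message, "latticefit_invalid_structure", call = sys.call(-1), ...)
}

lf_parse_error <- function(message, ...) {
  lf_abort(message, "latticefit_parse_error", call = sys.call(-1), ...)
}

lf_not_found <- function(message, ...) {
  lf_abort(message, "latticefit_not_found", call = sys.call(-1), ...)
}

lf_unsupported_lattice <- function(message, ...) {
  lf_abort(message, "latticefit_unsupported_lattice", call = sys.call(-1), ...)
}

lf_unsupported_input <- function(message, ...) {
  lf_abort(message, "latticefit_unsupported_input", call = sys.call(-1), ...)
}

lf_fit_failure <- function(message, ...) {
  lf_abort(message, "latticefit_fit_failure", call = sys.call(-1), ...)
}

# Run code with a temporarily seeded RNG, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
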