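#' Signal a classed psrbdash error
#'
#' All package errors carry a subclass (e.g. `psrb_empty_mask_error`) so
#' callers and tests can discriminate failure modes without string matching.
#'
#' @param msg message text.
#' @param class error subclass, prefixed internally with `psrb_`.
#' @param call. call to report.
#' @keywords internal
#' @noRd
psrb_stop <- function(msg, class, call. = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("psrb_", class, "_error"), "psrb_error"),
                      call = call.))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's random stream.
#'
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed
#'
#' Each synthetic artifact draws from its own sub-stream so adding a new
#' generator never shifts the draws of an existing one. Kept below 2^31.
#'
#' @keywords internal
#' @noRd
sub_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream)
}
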