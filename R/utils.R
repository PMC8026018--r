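#' Derive a stage seed from a master seed
#'
#' Per-stage seeds are split off a single master seed so that individual
#' pipeline stages can be rerun independently while the end-to-end run
#' stays reproducible. The rule is `(master * 101 + offset) mod (2^31 - 1)`,
#' which keeps every derived seed a valid 32-bit integer.
#'
#' @param master integer master seed.
#' @param offset integer stage offset (each pipeline stage has a fixed one).
#' @return An integer seed.
#' @export
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((abs(master) * 101 + offset) %% (2^31 - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
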