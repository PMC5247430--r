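# Classed conditions used across the registry. Every user-facing failure is a
# condition inheriting from "seedledger_error" plus a specific subclass, so
# callers (and the CLI exit-code mapping) can dispatch on the failure kind.

sl_abort <- function(subclass, message, ...) {
  data <- list(...)
  cond <- errorCondition(
    message,
    class = c(paste0("seedledger_", subclass), "seedledger_error"),
    ...
  )
  stop(cond)
}

#' Map a seedledger condition to a CLI exit code
#'
#' Exit codes: 0 success, 2 validation/format problems, 3 authorization,
#' 4 not found, 1 anything else.
#'
#' @param cond A condition object.
#' @return An integer exit code.
#' @keywords internal
sl_exit_code <- function(cond) {
  cls <- class(cond)
  if (any(grepl("authorization", cls))) return(3L)
  if (any(grepl("not_found", cls))) return(4L)
  if (any(cls %in% paste0("seedledger_", c(
    "validation_error", "format_error", "conflict_error", "dependency_error",
    "category_error", "consistency_error", "species_error", "pattern_error",
    "field_error", "vocabulary_error", "in_use_error", "immutability_error",
    "locked_error", "reserved_error", "degraded_error"
  )))) {
    return(2L)
  }
  1L
}
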