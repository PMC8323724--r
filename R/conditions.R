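# Structured error conditions. Every error raised by the package carries the
# class "fcki_error" plus a specific subclass so callers can branch on the
# failure mode rather than match message text.

.err <- function(class, msg, ...) {
  stop(errorCondition(
    message = msg,
    class = c(paste0("fcki_", class), "fcki_error"),
    ...
  ))
}

.errParse <- function(msg, row = NA_integer_, col = NA_integer_) {
  .err("parse_error", msg, row = row, col = col)
}
.errShape <- function(msg) .err("shape_error", msg)
.errEmptyInput <- function(msg) .err("empty_input_error", msg)
.errSpec <- function(msg) .err("spec_error", msg)
.errPrefilled <- function(msg) .err("prefilled_input_error", msg)
.errPoolTooSmall <- function(msg) .err("pool_too_small_error", msg)
.errSubsetTooSmall <- function(msg) .err("subset_too_small_error", msg)
.errColumnAllMissing <- function(msg) .err("column_all_missing_error", msg)
.errNoComparableDonors <- function(msg) .err("no_comparable_donors_error", msg)
.errDegenerateRange <- function(msg) .err("degenerate_range_error", msg)
.errEmptyMask <- function(msg) .err("empty_mask_error", msg)
.errIO <- function(msg) .err("io_error", msg)
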