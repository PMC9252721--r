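# Classed conditions. Every error signalled by the package carries the class
# "fibkmer_error" plus a specific subclass such as "fibkmer_range_error".

fk_stop <- function(subclass, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c(paste0("fibkmer_", subclass), "fibkmer_error")))
}

# The C++ layer throws plain errors whose messages start with a tag such as
# "RangeError:"; map those onto the same condition classes.
.cpp_error_classes <- c(
  RangeError = "range_error",
  LengthError = "length_error",
  AmbiguousBaseError = "ambiguous_base",
  ParseError = "parse_error",
  CapacityError = "capacity_error",
  FormatError = "format_error",
  EmptyInputError = "empty_input",
  DuplicateContigNameError = "duplicate_contig"
)

wrap_cpp <- function(expr) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    tag <- sub(":.*$", "", msg)
    sub_cls <- .cpp_error_classes[[tag]]
    if (is.null(sub_cls)) stop(e)
    fk_stop(sub_cls, "%s", msg)
  })
}
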