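# shared internal helpers

# strip an optional leading "chr"/"Chr" so "Chr9", "chr9" and "9" compare equal
norm_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# structured validation errors: every user-facing failure carries a subclass
# so callers (and tests) can distinguish error classes programmatically
stop_lx <- function(subclass, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(subclass, "lx_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_lx("lx_missing_columns", "%s is missing column(s): %s",
            what, paste(miss, collapse = ", "))
}
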