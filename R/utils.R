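# Internal helpers shared across modules.

# Classed conditions so callers (and tests) can distinguish contract failures:
#   rt_name_error       unknown column / key
#   rt_integrity_error  coordinate or genome-bound violation
#   rt_contract_error   misuse of an operation's interface
#   rt_pairing_error    parallel-op length/seqname mismatch
#   rt_parse_error      malformed input file
#   rt_shape_error      aggregation returned a non-scalar
#   rt_spec_error       invalid simulation spec
#   rt_usage_error      CLI usage problem
rt_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "rt_error"), call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

# Recycle a per-row value to n rows (length 1 or n only).
recycle_to <- function(value, n, what) {
  if (length(value) == n) return(value)
  if (length(value) == 1L) return(rep(value, n))
  rt_stop(sprintf("`%s` must have length 1 or %d, not %d", what, n, length(value)),
          "rt_shape_error")
}

# Stable multi-key order; radix is stable and type-safe for atomic keys.
stable_order <- function(...) {
  keys <- list(...)
  for (k in keys) {
    if (!is.atomic(k)) {
      rt_stop("sort keys must be atomic vectors", "rt_contract_error")
    }
  }
  do.call(order, c(keys, list(method = "radix")))
}
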