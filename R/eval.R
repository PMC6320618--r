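# Column-expression evaluation.
#
# Verbs capture their `...` unevaluated and evaluate each expression against a
# data mask built from the table's columns plus the derived `width` and a few
# aggregation helpers (n(), n_distinct(), first(), last(), desc()). Symbols
# not found in the mask fall through to the caller's environment, so local
# variables work as expected. Evaluation is pure: the input table is never
# modified.

mask_helpers <- function(n_rows) {
  list(
    n = function() n_rows,
    n_distinct = function(...) length(unique(do.call(paste, list(...)))),
    first = function(x) x[[1L]],
    last = function(x) x[[length(x)]],
    desc = function(x) -xtfrm(x)
  )
}

# Build the evaluation mask for a set of rows of x.
build_mask <- function(x, rows = NULL) {
  df <- as.data.frame(x)
  if (!is.null(rows)) df <- df[rows, , drop = FALSE]
  mask <- as.list(df)
  mask$width <- df$end - df$start + 1L
  c(mask, mask_helpers(nrow(df)))
}

eval_in_mask <- function(expr, mask, env) {
  tryCatch(
    eval(expr, mask, enclos = env),
    error = function(e) {
      m <- regmatches(conditionMessage(e),
                      regexec("object '([^']+)' not found", conditionMessage(e)))[[1L]]
      if (length(m) == 2L) {
        rt_stop(sprintf("unknown column or object '%s'", m[2L]), "rt_name_error")
      }
      stop(e)
    }
  )
}

# Evaluate expr once per group (list of integer row vectors); each result must
# be scalar. Returns a vector of length(groups).
eval_per_group_scalar <- function(x, expr, groups, env, what) {
  vals <- lapply(groups, function(rows) {
    v <- eval_in_mask(expr, build_mask(x, rows), env)
    if (length(v) != 1L) {
      rt_stop(sprintf("aggregation `%s` must return a single value per group, got length %d",
                      what, length(v)), "rt_shape_error")
    }
    v
  })
  unlist(vals, use.names = FALSE)
}

# Group bookkeeping ----------------------------------------------------------

group_keys_of <- function(x) attr(x, "group_keys", exact = TRUE)

# Row-index lists in first-appearance order of the key combinations.
group_rows <- function(x) {
  keys <- group_keys_of(x)
  if (is.null(keys) || !length(keys)) return(list(seq_len(nrow(x))))
  ids <- do.call(paste, c(lapply(keys, function(k) as.data.frame(x)[[k]]),
                          list(sep = "\r")))
  uid <- match(ids, unique(ids))
  unname(split(seq_len(nrow(x)), factor(uid, levels = seq_len(max(uid, 0L)))))
}

as_grouped <- function(x, keys) {
  missing <- setdiff(keys, names(x))
  if (length(missing)) {
    rt_stop(sprintf("unknown grouping column '%s'", missing[1L]), "rt_name_error")
  }
  attr(x, "group_keys") <- keys
  class(x) <- unique(c("GroupedRangeTable", class(x)))
  x
}

drop_groups <- function(x) {
  attr(x, "group_keys") <- NULL
  class(x) <- setdiff(class(x), "GroupedRangeTable")
  x
}
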