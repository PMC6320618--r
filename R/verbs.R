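#' Column verbs for range tables
#'
#' `RangeTable`s support the dplyr column verbs: `filter()`, `mutate()`,
#' `select()`, `arrange()`, `group_by()`/`ungroup()` and `summarise()`.
#' Expressions are evaluated in the context of the table: any column may be
#' referenced by name, plus the derived `width`, and the helpers `n()`,
#' `n_distinct()`, `first()`, `last()` and `desc()`. All verbs except
#' `summarise()` are endomorphic (the result is a valid `RangeTable` with the
#' genome preserved); `summarise()` returns a plain data.frame because
#' aggregated rows no longer describe single genomic features.
#'
#' `mutate()` understands the coordinate columns: assigning `start` or `end`
#' implicitly recomputes `width`; assigning `width` moves `end` (for a plain
#' table) or whichever coordinates the anchor dictates (see [anchor_start()]).
#' A mutation that would breach coordinate 1, the sequence length, or
#' `end >= start - 1` raises an integrity error naming the offending row.
#'
#' Grouped tables evaluate filter/mutate/summarise expressions per group;
#' `summarise()` emits groups in first-appearance order.
#'
#' @param .data A `RangeTable`.
#' @param ... Column expressions (see Details); for `group_by()`, bare column
#'   names; for `select()`, bare metadata-column names, optionally all
#'   prefixed with `-` to drop instead of keep.
#' @param .preserve,.add Ignored; present for generic compatibility.
#' @name range-verbs
#' @examples
#' rng <- range_table("chr1", start = c(1, 20, 40), end = c(10, 29, 44),
#'                    score = c(7, 9, 12))
#' filter(rng, score > 8)
#' mutate(rng, dens = score / width)
#' summarise(group_by(rng, seqnames), total = sum(score))
NULL

#' @rdname range-verbs
#' @export
filter.RangeTable <- function(.data, ..., .preserve = FALSE) {
  exprs <- as.list(substitute(list(...)))[-1L]
  if (!length(exprs)) return(.data)
  env <- parent.frame()
  keep <- rep(TRUE, nrow(.data))
  for (rows in group_rows(.data)) {
    mask <- build_mask(.data, rows)
    for (ex in exprs) {
      v <- eval_in_mask(ex, mask, env)
      if (!is.logical(v)) {
        rt_stop(sprintf("filter condition `%s` must be logical", deparse1(ex)),
                "rt_contract_error")
      }
      v <- recycle_to(v, length(rows), deparse1(ex))
      keep[rows] <- keep[rows] & !is.na(v) & v
    }
  }
  out <- .data[keep, , drop = FALSE]
  restore_groups(out, .data)
}

#' @rdname range-verbs
#' @export
mutate.RangeTable <- function(.data, ...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  mutate_impl(.data, exprs, parent.frame(), anchor = NULL)
}

mutate_impl <- function(.data, exprs, env, anchor = NULL) {
  if (length(exprs) && (is.null(names(exprs)) || any(names(exprs) == ""))) {
    rt_stop("mutate() expressions must be named", "rt_contract_error")
  }
  df <- as.data.frame(.data)
  n <- nrow(df)
  grouping <- group_rows(.data)
  for (nm in names(exprs)) {
    vals <- vector("list", length(grouping))
    for (g in seq_along(grouping)) {
      rows <- grouping[[g]]
      tmp <- new_range_table(df, validate = FALSE)
      v <- eval_in_mask(exprs[[nm]], build_mask(tmp, rows), env)
      vals[[g]] <- recycle_to(v, length(rows), nm)
    }
    full <- vals[[1L]][0]
    full[unlist(grouping)] <- unlist(vals)
    if (nm == "width") {
      w <- as.integer(full)
      if (anyNA(w) || any(w < 0L)) {
        rt_stop(sprintf("row %d: width must be a non-negative integer",
                        which(is.na(w) | w < 0L)[1L]), "rt_integrity_error")
      }
      se <- apply_anchor_width(df$start, df$end, df$strand, anchor %||% "start", w)
      df$start <- se$start; df$end <- se$end
    } else if (nm %in% c("start", "end")) {
      df[[nm]] <- as.integer(full)
    } else if (nm == "seqnames" || nm == "strand") {
      df[[nm]] <- as.character(full)
    } else {
      df[[nm]] <- full
    }
  }
  out <- new_range_table(df, genome_info = get_genome_info(.data))
  restore_groups(out, .data)
}

#' @rdname range-verbs
#' @export
select.RangeTable <- function(.data, ...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  if (!length(exprs)) return(.data)
  neg <- vapply(exprs, function(e) is.call(e) && identical(e[[1L]], as.name("-")),
                logical(1L))
  if (any(neg) && !all(neg)) {
    rt_stop("select() cannot mix kept and dropped columns", "rt_contract_error")
  }
  name_of <- function(e) {
    if (is.call(e)) e <- e[[2L]]
    if (is.name(e)) return(as.character(e))
    if (is.character(e)) return(e)
    rt_stop(sprintf("select() expects column names, not `%s`", deparse1(e)),
            "rt_contract_error")
  }
  cols <- vapply(exprs, name_of, character(1L))
  if (any(cols %in% RESERVED_COLS)) {
    rt_stop(paste0("the coordinate columns (seqnames, start, end, strand) are part ",
                   "of every RangeTable and cannot be selected away"),
            "rt_contract_error")
  }
  meta <- setdiff(names(.data), CORE_COLS)
  missing <- setdiff(cols, meta)
  if (length(missing)) {
    rt_stop(sprintf("unknown metadata column '%s'", missing[1L]), "rt_name_error")
  }
  keep <- if (all(neg)) setdiff(meta, cols) else cols
  out <- .data[, c(CORE_COLS, keep), drop = FALSE]
  keys <- group_keys_of(.data)
  if (!is.null(keys) && !all(keys %in% names(out))) {
    rt_stop("cannot select away a grouping column", "rt_contract_error")
  }
  restore_groups(out, .data)
}

#' @rdname range-verbs
#' @export
arrange.RangeTable <- function(.data, ...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  if (!length(exprs)) return(.data)
  env <- parent.frame()
  mask <- build_mask(.data)
  keys <- lapply(exprs, function(ex) {
    v <- eval_in_mask(ex, mask, env)
    if (!is.atomic(v)) {
      rt_stop(sprintf("arrange key `%s` is not sortable", deparse1(ex)),
              "rt_contract_error")
    }
    recycle_to(v, nrow(.data), deparse1(ex))
  })
  out <- .data[do.call(stable_order, keys), , drop = FALSE]
  restore_groups(out, .data)
}

#' @rdname range-verbs
#' @export
group_by.RangeTable <- function(.data, ..., .add = FALSE) {
  exprs <- as.list(substitute(list(...)))[-1L]
  keys <- vapply(exprs, function(e) {
    if (is.name(e)) as.character(e)
    else if (is.character(e)) e
    else rt_stop(sprintf("group_by() expects column names, not `%s`", deparse1(e)),
                 "rt_name_error")
  }, character(1L))
  if (isTRUE(.add)) keys <- union(group_keys_of(.data), keys)
  as_grouped(drop_groups(.data), keys)
}

#' @rdname range-verbs
#' @param x A grouped `RangeTable`.
#' @export
ungroup.RangeTable <- function(x, ...) drop_groups(x)

#' @rdname range-verbs
#' @param .groups Ignored; present for generic compatibility.
#' @export
summarise.RangeTable <- function(.data, ..., .groups = NULL) {
  exprs <- as.list(substitute(list(...)))[-1L]
  if (length(exprs) && (is.null(names(exprs)) || any(names(exprs) == ""))) {
    rt_stop("summarise() expressions must be named", "rt_contract_error")
  }
  env <- parent.frame()
  keys <- group_keys_of(.data) %||% character()
  grouping <- group_rows(.data)
  firsts <- vapply(grouping, function(r) if (length(r)) r[1L] else NA_integer_,
                   integer(1L))
  out <- as.data.frame(.data)[firsts, keys, drop = FALSE]
  rownames(out) <- NULL
  for (nm in names(exprs)) {
    out[[nm]] <- eval_per_group_scalar(.data, exprs[[nm]], grouping, env, nm)
  }
  out
}

#' @rdname range-verbs
#' @export
summarise.GroupedRangeTable <- summarise.RangeTable

# Re-apply the grouping of `template` (if any) onto `out`.
restore_groups <- function(out, template) {
  keys <- group_keys_of(template)
  if (is.null(keys)) drop_groups(out) else as_grouped(drop_groups(out), keys)
}
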