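#' Verbs re-exported from dplyr
#'
#' The grammar's column verbs are methods on the dplyr generics, re-exported
#' here so `library(rangetable)` suffices.
#'
#' @importFrom dplyr filter
#' @export
#' @name reexports
#' @keywords internal
#' @aliases filter
dplyr::filter

#' @importFrom dplyr mutate
#' @export
#' @rdname reexports
dplyr::mutate

#' @importFrom dplyr select
#' @export
#' @rdname reexports
dplyr::select

#' @importFrom dplyr arrange
#' @export
#' @rdname reexports
dplyr::arrange

#' @importFrom dplyr group_by
#' @export
#' @rdname reexports
dplyr::group_by

#' @importFrom dplyr ungroup
#' @export
#' @rdname reexports
dplyr::ungroup

#' @importFrom dplyr summarise
#' @export
#' @rdname reexports
dplyr::summarise

#' @importFrom dplyr summarize
#' @export
#' @rdname reexports
dplyr::summarize

#' @importFrom dplyr n_distinct
#' @export
#' @rdname reexports
dplyr::n_distinct

#' @importFrom dplyr desc
#' @export
#' @rdname reexports
dplyr::desc

#' @importFrom dplyr %>%
#' @export
#' @rdname reexports
dplyr::`%>%`
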