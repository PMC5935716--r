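#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# first element or default for possibly-empty subsets
`%0%` <- function(x, default) if (length(x) == 0) default else x[[1]]

#' @export
generics::tidy

#' @export
generics::glance
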