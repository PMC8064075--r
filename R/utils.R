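#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Levels used throughout; junction sides are listed 5' first.
JUNCTION_LEVELS <- c("EE", "EM", "ME", "MM")
LOCUS_LEVELS <- c("READ_THROUGH", "INTRA_OTHERS", "INTERCHR")
FRAME_LEVELS <- c("IN_FRAME", "FRAME_SHIFT", "NA", "BOTH")

chs_warn <- function(...) warning(..., call. = FALSE)
chs_stop <- function(...) stop(..., call. = FALSE)

# tabulate a character vector against a fixed level set, zero-filled
count_levels <- function(x, levels) {
  out <- setNames(integer(length(levels)), levels)
  t <- table(factor(x, levels = levels))
  out[names(t)] <- as.integer(t)
  out
}
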