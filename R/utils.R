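# Shared constants and small helpers.

#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
NULL

# 20 canonical amino acids, one-letter codes
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

GAP <- "-"
UNKNOWN <- "X"

MAJOR_CLADES <- c("vertebrate", "invertebrate", "protist", "fungus",
                  "plant", "prokaryote")

is_gaplike <- function(x) x == GAP | x == UNKNOWN

`%||%` <- function(a, b) if (is.null(a)) b else a

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
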