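# Shared internal helpers.

# The 20 standard amino acids, alphabetical one-letter codes.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

ACIDIC_AA <- c("D", "E")
BASIC_AA  <- c("H", "K", "R")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(..., call. = FALSE)
}

check_sequence_alphabet <- function(seq, allow_x = TRUE) {
  allowed <- AA_ALPHABET
  if (allow_x) allowed <- c(allowed, "X")
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), allowed)
  if (length(bad) > 0) {
    stop_input("sequence contains invalid residue(s): ",
               paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}
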