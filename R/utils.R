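# internal helpers: condition constructors and sequence utilities

delbin_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "delbin_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

validation_error <- function(message, ...) {
  delbin_error("delbin_validation_error", message, ...)
}

contradiction_error <- function(message, conflicts = NULL) {
  delbin_error("delbin_contradiction_error", message, conflicts = conflicts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a nucleotide string
#'
#' @param x a single DNA sequence (character scalar, ACGT alphabet).
#' @return the reverse complement, upper case.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

check_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  if (!nzchar(x)) validation_error(sprintf("%s is empty", what))
  bad <- gsub("[ACGT]", "", x)
  if (nzchar(bad)) {
    validation_error(sprintf("%s contains non-ACGT characters: %s", what,
                             paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")))
  }
  x
}

# fraction of G/C in a sequence, percent to 0.1
gc_percent <- function(x) {
  x <- check_dna(x)
  n <- nchar(x)
  gc <- nchar(gsub("[AT]", "", x))
  round(100 * gc / n, 1)
}

# random DNA with a target GC fraction
random_dna <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# normalize a wheat chromosome-arm label like "7as" -> list(chromosome="7A", arm="S")
parse_arm_label <- function(label) {
  label <- toupper(trimws(label))
  if (!grepl("^[1-7][ABD][SL]$", label)) {
    validation_error(sprintf("not a wheat chromosome-arm label: '%s'", label))
  }
  list(chromosome = substr(label, 1, 2), arm = substr(label, 3, 3))
}

check_chromosome <- function(chromosome) {
  chromosome <- toupper(trimws(chromosome))
  if (!grepl("^[1-7][ABD]$", chromosome)) {
    validation_error(sprintf("not a wheat chromosome label: '%s'", chromosome))
  }
  chromosome
}
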