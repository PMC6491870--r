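# Amplicon merging and ATG-anchored gene models.
#
# Gene coordinates follow the cloning-table convention: the A of the
# initiation ATG is +1, 5' UTR positions are negative, and there is no
# position 0. A region (-20, 468) therefore spans 488 bp.

#' Length of an ATG-anchored coordinate region
#'
#' Counts the positions in `[start, end]` under the no-zero convention:
#' `end - start + 1` when both coordinates share a sign, `end - start`
#' when the region crosses the (absent) zero.
#'
#' @param start,end nonzero integer gene coordinates, `start <= end`.
#' @return region length in bp.
#' @examples
#' region_length(-20, 468)  # 488
#' region_length(450, 1104) # 655
#' @export
region_length <- function(start, end) {
  if (start == 0 || end == 0) {
    validation_error("gene coordinates have no position 0")
  }
  if (start > end) validation_error("region start must precede end")
  if (sign(start) == sign(end)) end - start + 1 else end - start
}

# gene coordinate -> 1-based index in a sequence whose 5' UTR has utr5_len bases
coord_to_index <- function(pos, utr5_len) {
  if (any(pos == 0)) validation_error("gene coordinates have no position 0")
  ifelse(pos > 0, pos + utr5_len, pos + utr5_len + 1)
}

index_to_coord <- function(idx, utr5_len) {
  ifelse(idx > utr5_len, idx - utr5_len, idx - utr5_len - 1)
}

#' Merge two overlapping amplicons
#'
#' Joins two amplicon sequences on an exact suffix/prefix overlap of at
#' least `min_overlap` bp; when several overlap lengths qualify, the
#' longest is used. With `expected_overlap` given (e.g. implied by cloning
#' coordinates), that exact length is checked instead, and the first
#' discordant offset is reported on mismatch.
#'
#' @param a,b nucleotide sequences, `a` upstream of `b`.
#' @param min_overlap minimum exact overlap in bp (default 15).
#' @param expected_overlap optional known overlap length to enforce.
#' @return merged sequence of length `nchar(a) + nchar(b) - overlap`, with
#'   the overlap length in attribute `overlap`.
#' @export
merge_amplicons <- function(a, b, min_overlap = 15, expected_overlap = NULL) {
  a <- check_dna(a, "amplicon a"); b <- check_dna(b, "amplicon b")
  la <- nchar(a); lb <- nchar(b)
  if (!is.null(expected_overlap)) {
    k <- expected_overlap
    if (k > min(la, lb)) {
      delbin_error("delbin_merge_error",
                   sprintf("expected overlap %d exceeds an input length", k))
    }
    sa <- substr(a, la - k + 1L, la); sb <- substr(b, 1L, k)
    if (sa != sb) {
      diff <- which(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])[1L]
      delbin_error("delbin_merge_error", sprintf(
        "overlap regions differ at overlap offset %d (%s vs %s)",
        diff, substr(sa, diff, diff), substr(sb, diff, diff)))
    }
    return(structure(paste0(a, substr(b, k + 1L, lb)), overlap = k))
  }
  for (k in seq(min(la, lb), min_overlap)) {
    if (substr(a, la - k + 1L, la) == substr(b, 1L, k)) {
      return(structure(paste0(a, substr(b, k + 1L, lb)), overlap = k))
    }
  }
  delbin_error("delbin_merge_error", sprintf(
    "no exact suffix/prefix overlap of >= %d bp between amplicons",
    min_overlap))
}

# Kozak context check: lenient single-criterion rule — purine at -3 or G
# at +4 relative to the A of the ATG. Positions outside the sequence do
# not count as passing.
kozak_context <- function(sequence, atg_index) {
  n <- nchar(sequence)
  m3 <- if (atg_index >= 4L) substr(sequence, atg_index - 3L, atg_index - 3L) else NA
  p4 <- if (atg_index + 3L <= n) substr(sequence, atg_index + 3L, atg_index + 3L) else NA
  list(minus3 = m3, plus4 = p4,
       pass = isTRUE(m3 %in% c("A", "G")) || isTRUE(p4 == "G"))
}

# first in-frame stop at/after atg_index; returns index of last stop base or NA
find_inframe_stop <- function(sequence, atg_index) {
  n <- nchar(sequence)
  starts <- seq(atg_index, n - 2L, by = 3L)
  for (s in starts) {
    if (substr(sequence, s, s + 2L) %in% c("TAA", "TAG", "TGA")) {
      return(s + 2L)
    }
  }
  NA_integer_
}

#' Build an ATG-anchored gene model
#'
#' Partitions a genomic sequence into 5' UTR, ORF and 3' UTR. With
#' `utr5_len = "auto"` the initiation codon is the 5'-most ATG whose
#' context satisfies the (lenient) Kozak rule — purine at -3 or G at +4 —
#' and which is followed by an in-frame stop; the ORF runs to the first
#' in-frame stop. The model also reports the translated protein, GC
#' content (percent, 0.1 resolution) and protein molecular weight in kDa.
#'
#' @param sequence genomic nucleotide sequence (one exon assumed).
#' @param utr5_len 5' UTR length in bp, or "auto".
#' @param name gene name carried in the model.
#' @return a `gene_model` list: `name`, `sequence`, `utr5_len`, `orf_len`,
#'   `utr3_len`, `orf`, `protein`, `kozak_ok`, `kozak`, `gc_pct`, `mw_kda`.
#' @export
build_gene_model <- function(sequence, utr5_len = "auto", name = "gene") {
  sequence <- check_dna(sequence)
  n <- nchar(sequence)
  if (identical(utr5_len, "auto")) {
    atg_hits <- gregexpr("ATG", sequence)[[1L]]
    if (atg_hits[1L] == -1L) {
      delbin_error("delbin_model_error", "no ATG codon in sequence")
    }
    chosen <- NA_integer_
    for (i in as.integer(atg_hits)) {
      if (kozak_context(sequence, i)$pass && !is.na(find_inframe_stop(sequence, i))) {
        chosen <- i
        break
      }
    }
    if (is.na(chosen)) {
      delbin_error("delbin_model_error",
                   "no ATG with passing Kozak context and in-frame stop")
    }
    utr5_len <- chosen - 1L
  } else {
    stopifnot(is.numeric(utr5_len), utr5_len >= 0)
    utr5_len <- as.integer(utr5_len)
    if (substr(sequence, utr5_len + 1L, utr5_len + 3L) != "ATG") {
      delbin_error("delbin_model_error",
                   sprintf("no ATG at position %d", utr5_len + 1L))
    }
  }
  atg <- utr5_len + 1L
  stop_end <- find_inframe_stop(sequence, atg)
  if (is.na(stop_end)) {
    delbin_error("delbin_model_error", "no in-frame stop codon after ATG")
  }
  orf <- substr(sequence, atg, stop_end)
  protein <- translate_orf(orf)
  kozak <- kozak_context(sequence, atg)
  model <- list(
    name = name, sequence = sequence,
    utr5_len = utr5_len, orf_len = nchar(orf),
    utr3_len = n - stop_end, orf = orf, protein = protein,
    kozak_ok = kozak$pass, kozak = kozak,
    gc_pct = gc_percent(sequence),
    mw_kda = molecular_weight(protein)
  )
  stopifnot(model$utr5_len + model$orf_len + model$utr3_len == n)
  structure(model, class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene model '%s': %d bp = 5'UTR %d + ORF %d + 3'UTR %d\n",
              x$name, nchar(x$sequence), x$utr5_len, x$orf_len, x$utr3_len))
  cat(sprintf("  protein %d aa, %.1f kDa; GC %.1f%%; Kozak %s (-3: %s, +4: %s)\n",
              nchar(x$protein), x$mw_kda, x$gc_pct,
              if (x$kozak_ok) "pass" else "fail",
              x$kozak$minus3 %||% "-", x$kozak$plus4 %||% "-"))
  invisible(x)
}

#' Translate an ORF with the standard genetic code
#'
#' The ORF must be a whole number of codons, end in a stop codon, and
#' contain no internal stop; the terminal stop is not included in the
#' protein, so an ORF of `3n` bp yields `n - 1` residues.
#'
#' @param orf nucleotide sequence of the ORF, stop codon included.
#' @return the protein as an amino-acid string.
#' @examples
#' translate_orf("ATGGCTTAA") # "MA"
#' @export
translate_orf <- function(orf) {
  orf <- check_dna(orf, "ORF")
  if (nchar(orf) %% 3L != 0L) {
    validation_error(sprintf("ORF length %d is not a multiple of 3", nchar(orf)))
  }
  starts <- seq(1L, nchar(orf), by = 3L)
  codons <- substring(orf, starts, starts + 2L)
  aas <- Biostrings::GENETIC_CODE[codons]
  internal_stop <- which(aas[-length(aas)] == "*")
  if (length(internal_stop)) {
    validation_error(sprintf("internal stop codon at codon %d", internal_stop[1L]))
  }
  if (aas[length(aas)] != "*") {
    validation_error("ORF does not end in a stop codon")
  }
  paste(aas[-length(aas)], collapse = "")
}

# average residue masses (Da) of the 20 standard amino acids; protein MW =
# sum of residue masses + one water
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

#' Average molecular weight of a protein, in kDa
#'
#' @param protein amino-acid string (standard 20-letter alphabet). An
#'   empty string returns the mass of water, with a warning.
#' @return molecular weight in kilodaltons.
#' @examples
#' molecular_weight("G") # 0.07507
#' @export
molecular_weight <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (!nzchar(protein)) {
    warning("empty protein: returning the mass of water")
    return(WATER_MASS / 1000)
  }
  residues <- strsplit(toupper(protein), "")[[1L]]
  unknown <- setdiff(residues, names(RESIDUE_MASS))
  if (length(unknown)) {
    validation_error(paste("unknown residue(s):", paste(unknown, collapse = ", ")))
  }
  (sum(RESIDUE_MASS[residues]) + WATER_MASS) / 1000
}
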