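# In-silico PCR with allele-specific 3'-end discrimination, and genotype
# calls from a pair of complementary dominant STS markers.
#
# Discrimination model: a primer binds a site iff its 3'-terminal
# `three_prime_exact` bases match the template exactly and the remaining
# positions carry at most `max_mismatch` mismatches. No melting
# temperature model; annealing temperatures are metadata.

#' Find primer binding sites on a template
#'
#' Scans the plus strand for forward-orientation sites (primer written
#' 5'->3' matching the template text) and the minus strand for
#' reverse-orientation sites (the reverse complement of the primer
#' matching the template text).
#'
#' @param primer primer sequence, 5'->3'.
#' @param template plus-strand template sequence.
#' @param orientation "forward" or "reverse".
#' @param max_mismatch mismatches tolerated outside the 3' clamp (default 2).
#' @param three_prime_exact number of 3'-terminal primer bases that must
#'   match exactly (default 3).
#' @return data.frame of sites: `start`, `end` (plus-strand, 1-based,
#'   inclusive), `strand` ("+" forward / "-" reverse), `mismatches`.
#' @export
find_binding_sites <- function(primer, template, orientation = c("forward", "reverse"),
                               max_mismatch = 2, three_prime_exact = 3) {
  orientation <- match.arg(orientation)
  primer <- check_dna(primer, "primer")
  template <- check_dna(template, "template")
  k <- nchar(primer); n <- nchar(template)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (k > n) return(empty)
  site <- if (orientation == "forward") primer else revcomp(primer)
  # positions of the 3'-terminal clamp within the plus-strand site text:
  # rightmost bases for a forward primer, leftmost for a reverse primer
  clamp <- if (orientation == "forward") seq(k - three_prime_exact + 1L, k)
           else seq_len(three_prime_exact)
  site_chars <- strsplit(site, "")[[1L]]
  tmpl_chars <- strsplit(template, "")[[1L]]
  hits <- empty
  for (s in seq_len(n - k + 1L)) {
    window <- tmpl_chars[s:(s + k - 1L)]
    mism <- which(window != site_chars)
    if (any(mism %in% clamp)) next
    if (length(mism) > max_mismatch) next
    hits <- rbind(hits, data.frame(
      start = s, end = s + k - 1L,
      strand = if (orientation == "forward") "+" else "-",
      mismatches = length(mism), stringsAsFactors = FALSE))
  }
  hits
}

#' Simulate PCR of a marker assay on a template
#'
#' Reports one product per convergent forward/reverse site pair within
#' `max_product_size`. Product size is measured between the primers' 5'
#' ends, both primers included. Both template orientations are scanned,
#' so the result is invariant under reverse-complementing the template.
#'
#' @param assay a list or one-row data.frame with `forward` and `reverse`
#'   primer sequences (helper: [marker_assay()]).
#' @param template template sequence.
#' @param max_mismatch,three_prime_exact binding model, see
#'   [find_binding_sites()].
#' @param max_product_size longest product reported (default 5000 bp).
#' @return data.frame of products: `start`, `end` (plus strand), `size`.
#' @export
insilico_pcr <- function(assay, template, max_mismatch = 2,
                         three_prime_exact = 3, max_product_size = 5000) {
  template <- check_dna(template, "template")
  scan_one <- function(tmpl) {
    f <- find_binding_sites(assay$forward, tmpl, "forward",
                            max_mismatch, three_prime_exact)
    r <- find_binding_sites(assay$reverse, tmpl, "reverse",
                            max_mismatch, three_prime_exact)
    out <- data.frame(start = integer(), end = integer(), size = integer())
    for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
      if (r$start[j] <= f$start[i]) next           # must converge
      size <- r$end[j] - f$start[i] + 1L
      if (size < nchar(assay$forward) + nchar(assay$reverse)) next
      if (size > max_product_size) next
      out <- rbind(out, data.frame(start = f$start[i], end = r$end[j],
                                   size = size))
    }
    out
  }
  n <- nchar(template)
  plus <- scan_one(template)
  minus <- scan_one(revcomp(template))
  if (nrow(minus)) {
    # map minus-orientation products back onto plus-strand coordinates
    minus <- data.frame(start = n - minus$end + 1L,
                        end = n - minus$start + 1L, size = minus$size)
  }
  out <- unique(rbind(plus, minus))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a marker assay
#'
#' @param name assay name (e.g. "POD-7D1").
#' @param forward,reverse primer sequences, 5'->3'.
#' @param expected_size expected product size in bp.
#' @param diagnostic_allele allele amplified by this assay.
#' @param annealing_temp annealing temperature, degrees C (metadata).
#' @return a `marker_assay` list.
#' @export
marker_assay <- function(name, forward, reverse, expected_size,
                         diagnostic_allele = NA_character_,
                         annealing_temp = NA_real_) {
  forward <- check_dna(forward, "forward primer")
  reverse <- check_dna(reverse, "reverse primer")
  if (expected_size <= nchar(forward) + nchar(reverse)) {
    validation_error("expected product size must exceed the primer lengths")
  }
  structure(list(name = name, forward = forward, reverse = reverse,
                 expected_size = expected_size,
                 diagnostic_allele = diagnostic_allele,
                 annealing_temp = annealing_temp), class = "marker_assay")
}

#' Read a primer table into marker assays
#'
#' Expects columns `assay`, `orientation`, `sequence`, `expected_size`
#' and optionally `annealing_c`, `diagnostic_allele`, with one forward
#' and one reverse row per assay.
#'
#' @param table data.frame, file path or literal tabular text.
#' @return named list of `marker_assay` objects.
#' @export
read_primer_table <- function(table) {
  df <- read_table_auto(table)
  names(df) <- tolower(names(df))
  out <- list()
  for (nm in unique(df$assay)) {
    rows <- df[df$assay == nm, ]
    fwd <- rows$sequence[tolower(rows$orientation) == "forward"]
    rev <- rows$sequence[tolower(rows$orientation) == "reverse"]
    if (length(fwd) != 1L || length(rev) != 1L) {
      validation_error(sprintf(
        "assay %s needs exactly one forward and one reverse primer", nm))
    }
    diag_allele <- if ("diagnostic_allele" %in% names(rows))
      rows$diagnostic_allele[1L] else NA_character_
    if (isTRUE(diag_allele == "")) diag_allele <- NA_character_
    out[[nm]] <- marker_assay(
      nm, fwd, rev, expected_size = rows$expected_size[1L],
      diagnostic_allele = diag_allele,
      annealing_temp = if ("annealing_c" %in% names(rows))
        rows$annealing_c[1L] else NA_real_)
  }
  out
}

#' Call a genotype from two complementary dominant assays
#'
#' The two assays each amplify one allele only; the joint pattern behaves
#' like a codominant marker. A product is accepted for an assay when its
#' size is within `size_tol` of that assay's expected size; off-size
#' products are ignored with a warning.
#'
#' @param products_b products (from [insilico_pcr()] or a data.frame with
#'   a `size` column) of the assay diagnostic for allele b.
#' @param products_a products of the assay diagnostic for allele a.
#' @param assay_b,assay_a the two `marker_assay`s (supply expected sizes
#'   and allele labels).
#' @param size_tol size tolerance in bp (default 10, a gel-resolution
#'   analogue).
#' @param variety variety name carried through.
#' @return a `genotype_call` list: `variety`, `allele` (label of allele a
#'   or b, "ambiguous" if both assays amplify, "null" if neither),
#'   `evidence` (product sizes per assay).
#' @export
call_genotype <- function(products_b, products_a, assay_b, assay_a,
                          size_tol = 10, variety = NA_character_) {
  match_expected <- function(products, assay) {
    sizes <- products$size
    ok <- abs(sizes - assay$expected_size) <= size_tol
    if (any(!ok)) {
      warning(sprintf("%s: ignoring %d product(s) of unexpected size (%s)",
                      assay$name, sum(!ok),
                      paste(sizes[!ok], collapse = ", ")))
    }
    any(ok)
  }
  has_b <- match_expected(products_b, assay_b)
  has_a <- match_expected(products_a, assay_a)
  allele_a <- assay_a$diagnostic_allele %||% "allele_a"
  allele_b <- assay_b$diagnostic_allele %||% "allele_b"
  allele <- if (has_a && has_b) "ambiguous"
            else if (has_b) allele_b
            else if (has_a) allele_a
            else "null"
  structure(list(variety = variety, allele = allele,
                 evidence = list(sizes_b = products_b$size,
                                 sizes_a = products_a$size)),
            class = "genotype_call")
}

#' Genotype a panel of templates with a complementary assay pair
#'
#' @param templates named character vector of template sequences (one per
#'   variety).
#' @param assay_b,assay_a the complementary `marker_assay` pair.
#' @param ... passed to [insilico_pcr()] and [call_genotype()].
#' @return data.frame: `variety`, `allele`.
#' @export
genotype_panel <- function(templates, assay_b, assay_a, ...) {
  calls <- vapply(names(templates), function(v) {
    pb <- insilico_pcr(assay_b, templates[[v]])
    pa <- insilico_pcr(assay_a, templates[[v]])
    call_genotype(pb, pa, assay_b, assay_a, variety = v, ...)$allele
  }, character(1))
  data.frame(variety = names(templates), allele = unname(calls),
             stringsAsFactors = FALSE)
}
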