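# Pairwise allele comparison: global alignment, SNP/InDel extraction,
# identity, and protein-level consequences.

#' Global pairwise alignment with affine gap scoring
#'
#' Needleman-Wunsch global alignment (affine gaps) of two nucleotide or
#' amino-acid sequences, via Biostrings. Default scoring is conservative
#' (gap opening is expensive relative to a mismatch) so that a single
#' multi-base InDel stays intact rather than being split.
#'
#' @param seq_a,seq_b sequences to align (a is the reference allele).
#' @param match,mismatch substitution scores (default +2 / -3).
#' @param gap_open,gap_extend affine gap penalties, as negative scores
#'   (default -7 / -2 per extended position; a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param alphabet "dna" or "protein".
#' @return a `pairwise_alignment` list: `aligned_a`, `aligned_b` (equal
#'   length, "-" for gaps), `score`, and the scoring `params`.
#' @export
global_align <- function(seq_a, seq_b, match = 2, mismatch = -3,
                         gap_open = -7, gap_extend = -2,
                         alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    validation_error("cannot align an empty sequence")
  }
  if (alphabet == "dna") {
    seq_a <- check_dna(seq_a, "seq_a"); seq_b <- check_dna(seq_b, "seq_b")
    submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = TRUE)
    pa <- Biostrings::DNAString(seq_a); sb <- Biostrings::DNAString(seq_b)
  } else {
    letters_aa <- c(names(RESIDUE_MASS), "*", "X")
    submat <- matrix(mismatch, length(letters_aa), length(letters_aa),
                     dimnames = list(letters_aa, letters_aa))
    diag(submat) <- match
    pa <- Biostrings::AAString(seq_a); sb <- Biostrings::AAString(seq_b)
  }
  aln <- Biostrings::pairwiseAlignment(
    pa, sb, type = "global", substitutionMatrix = submat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  structure(list(
    aligned_a = as.character(Biostrings::alignedPattern(aln)),
    aligned_b = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln),
    params = list(match = match, mismatch = mismatch,
                  gap_open = gap_open, gap_extend = gap_extend,
                  alphabet = alphabet)
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Global alignment: %d columns, score %.1f\n",
              nchar(x$aligned_a), x$score))
  invisible(x)
}

# left-align an indel within its repeat context (VCF-style normalization):
# rotate the indel bases leftwards while the base preceding the event
# equals the last indel base.
left_align_indel <- function(ref_seq, after_index, bases) {
  while (after_index >= 1L) {
    last <- substr(bases, nchar(bases), nchar(bases))
    if (substr(ref_seq, after_index, after_index) != last) break
    bases <- paste0(last, substr(bases, 1L, nchar(bases) - 1L))
    after_index <- after_index - 1L
  }
  list(after_index = after_index, bases = bases)
}

#' Call SNPs and InDels from a pairwise alignment
#'
#' Each mismatching column becomes one SNP (adjacent substituted columns
#' are counted separately); each maximal gap run becomes one InDel,
#' left-aligned within its repeat context. Positions are reported on the
#' reference allele (sequence a) in ATG-anchored coordinates: pass the
#' reference 5' UTR length as `coordinate_anchor` (0 means the sequence
#' starts at the ATG).
#'
#' @param alignment a `pairwise_alignment` of the two allele sequences.
#' @param coordinate_anchor 5' UTR length of the reference allele in bp.
#' @return a `variant_set` list: `variants` (data.frame with `kind`,
#'   `position` in ATG-anchored coordinates, `ref_index` on the ungapped
#'   reference, `ref`, `alt`), `n_snp`, `n_indel`, `identity_pct`.
#' @export
call_variants <- function(alignment, coordinate_anchor = 0L) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  a <- strsplit(alignment$aligned_a, "")[[1L]]
  b <- strsplit(alignment$aligned_b, "")[[1L]]
  ref_seq <- paste(a[a != "-"], collapse = "")
  n <- length(a)
  kind <- character(); ref_index <- integer()
  refb <- character(); altb <- character()
  i <- 1L; ref_pos <- 0L
  while (i <= n) {
    if (a[i] != "-" && b[i] != "-") {
      ref_pos <- ref_pos + 1L
      if (a[i] != b[i]) {
        kind <- c(kind, "SNP"); ref_index <- c(ref_index, ref_pos)
        refb <- c(refb, a[i]); altb <- c(altb, b[i])
      }
      i <- i + 1L
    } else if (a[i] == "-") {
      j <- i
      while (j <= n && a[j] == "-") j <- j + 1L
      ins <- paste(b[i:(j - 1L)], collapse = "")
      norm <- left_align_indel(ref_seq, ref_pos, ins)
      kind <- c(kind, "insertion"); ref_index <- c(ref_index, norm$after_index)
      refb <- c(refb, ""); altb <- c(altb, norm$bases)
      i <- j
    } else {
      j <- i
      while (j <= n && b[j] == "-") j <- j + 1L
      del <- paste(a[i:(j - 1L)], collapse = "")
      norm <- left_align_indel(ref_seq, ref_pos, del)
      kind <- c(kind, "deletion"); ref_index <- c(ref_index, norm$after_index)
      refb <- c(refb, norm$bases); altb <- c(altb, "")
      ref_pos <- ref_pos + (j - i)
      i <- j
    }
  }
  variants <- data.frame(kind = kind, ref_index = ref_index,
                         ref = refb, alt = altb, stringsAsFactors = FALSE)
  # ATG-anchored position: for insertions, the base after which the bases
  # are inserted (0-length events at the very 5' end keep index 0)
  variants$position <- ifelse(
    variants$ref_index == 0L, NA_integer_,
    index_to_coord(variants$ref_index, coordinate_anchor))
  variants <- variants[order(variants$ref_index,
                             match(variants$kind, c("SNP", "deletion", "insertion"))),
                       c("kind", "position", "ref_index", "ref", "alt")]
  rownames(variants) <- NULL
  structure(list(
    variants = variants,
    n_snp = sum(variants$kind == "SNP"),
    n_indel = sum(variants$kind != "SNP"),
    identity_pct = identity_pct(alignment)
  ), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("Variant set: %d SNP(s), %d InDel(s); identity %.1f%%\n",
              x$n_snp, x$n_indel, x$identity_pct))
  if (nrow(x$variants)) print.data.frame(x$variants)
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' 100 x (matching columns) / (all alignment columns, gap columns
#' included), reported to 0.1%.
#'
#' @param alignment a `pairwise_alignment`.
#' @return identity percentage.
#' @export
identity_pct <- function(alignment) {
  a <- strsplit(alignment$aligned_a, "")[[1L]]
  b <- strsplit(alignment$aligned_b, "")[[1L]]
  round(100 * sum(a == b & a != "-") / length(a), 1)
}

#' Apply a called variant set to the reference allele
#'
#' Reconstructs the alternate allele from the reference sequence and a
#' `variant_set`; with variants called from an alignment of a vs b,
#' `apply_variants(a, vs)` returns b (patch round-trip).
#'
#' @param seq_a the ungapped reference allele.
#' @param variant_set a `variant_set` from [call_variants()].
#' @return the reconstructed alternate allele sequence.
#' @export
apply_variants <- function(seq_a, variant_set) {
  v <- variant_set$variants
  v <- v[order(v$ref_index), , drop = FALSE]
  out <- character(); cursor <- 1L
  for (i in seq_len(nrow(v))) {
    kind <- v$kind[i]; idx <- v$ref_index[i]
    if (kind == "SNP") {
      out <- c(out, substr(seq_a, cursor, idx - 1L), v$alt[i])
      cursor <- idx + 1L
    } else if (kind == "insertion") {
      out <- c(out, substr(seq_a, cursor, idx), v$alt[i])
      cursor <- idx + 1L
    } else { # deletion of bases starting at idx + 1 after left alignment
      out <- c(out, substr(seq_a, cursor, idx))
      cursor <- idx + nchar(v$ref[i]) + 1L
    }
  }
  paste0(paste(out, collapse = ""), substr(seq_a, cursor, nchar(seq_a)))
}

#' Protein-level consequences of allele variants
#'
#' Translates both allele gene models, aligns the proteins, and reports
#' amino-acid substitutions and inserted/deleted residues. If any InDel in
#' the variant set is not a multiple of 3 bp the event disrupts the
#' reading frame and consequences are reported as undefined.
#'
#' @param variant_set a `variant_set` between the two allele gDNAs/ORFs.
#' @param gene_model_a,gene_model_b `gene_model`s of the two alleles.
#' @return a list: `frameshift` (logical), `aa_substitutions` (count of
#'   missense differences), `aa_inserted`, `aa_deleted` (residue strings),
#'   `protein_length_a`, `protein_length_b`.
#' @export
protein_consequences <- function(variant_set, gene_model_a, gene_model_b) {
  stopifnot(inherits(variant_set, "variant_set"),
            inherits(gene_model_a, "gene_model"),
            inherits(gene_model_b, "gene_model"))
  indels <- variant_set$variants[variant_set$variants$kind != "SNP", , drop = FALSE]
  lens <- nchar(ifelse(indels$kind == "insertion", indels$alt, indels$ref))
  if (any(lens %% 3L != 0L)) {
    return(list(frameshift = TRUE, aa_substitutions = NA_integer_,
                aa_inserted = NA_character_, aa_deleted = NA_character_,
                protein_length_a = nchar(gene_model_a$protein),
                protein_length_b = nchar(gene_model_b$protein)))
  }
  paln <- global_align(gene_model_a$protein, gene_model_b$protein,
                       match = 1, mismatch = -1, gap_open = -5,
                       gap_extend = -1, alphabet = "protein")
  a <- strsplit(paln$aligned_a, "")[[1L]]
  b <- strsplit(paln$aligned_b, "")[[1L]]
  list(
    frameshift = FALSE,
    aa_substitutions = sum(a != "-" & b != "-" & a != b),
    aa_inserted = paste(b[a == "-"], collapse = ""),
    aa_deleted = paste(a[b == "-"], collapse = ""),
    protein_length_a = nchar(gene_model_a$protein),
    protein_length_b = nchar(gene_model_b$protein)
  )
}

#' Write a variant set as a TSV table
#'
#' VCF-style columns (kind, position, ref, alt) without a VCF header; an
#' optional minimal VCF flavour uses the gene name as CHROM and the
#' ATG-anchored position as POS.
#'
#' @param variant_set a `variant_set`.
#' @param path output path.
#' @param format "tsv" (default) or "vcf".
#' @param gene_name CHROM field for the VCF flavour.
#' @return the path, invisibly.
#' @export
write_variants <- function(variant_set, path, format = c("tsv", "vcf"),
                           gene_name = "gene") {
  format <- match.arg(format)
  v <- variant_set$variants
  if (format == "tsv") {
    utils::write.table(v, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("##fileformat=VCFv4.2", con)
    writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
    for (i in seq_len(nrow(v))) {
      writeLines(sprintf("%s\t%s\t.\t%s\t%s\t.\t.\tKIND=%s", gene_name,
                         v$position[i], ifelse(v$ref[i] == "", ".", v$ref[i]),
                         ifelse(v$alt[i] == "", ".", v$alt[i]), v$kind[i]), con)
    }
  }
  invisible(path)
}
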