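# Generators for every input the pipeline consumes, with recorded ground
# truth: deletion panels, amplification matrices, allele pairs, PCR
# templates and variety phenotype panels.
#
# Every generator takes an optional integer `seed`; when given, the RNG
# state is set locally and restored afterwards, so identical seed +
# configuration gives byte-identical output.

local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Generate a synthetic aneuploid stock panel
#'
#' Builds NT lines (one per requested chromosome, compensated by the next
#' homoeologous genome), a Dt pair per chromosome carrying Del lines, and
#' Del lines at the given breakpoints.
#'
#' @param del_breakpoints named list: arm label (e.g. "7DS") -> numeric
#'   vector of breakpoint FL values in (0,1).
#' @param nt_chromosomes chromosomes to represent with NT lines (e.g.
#'   `c("7A", "7B", "7D")`); default: none.
#' @return a `stock_panel`.
#' @examples
#' gen_stock_panel(list(`7DS` = c(0.36, 0.37, 0.61)))
#' @export
gen_stock_panel <- function(del_breakpoints = list(), nt_chromosomes = character()) {
  rows <- list()
  genomes <- c("A", "B", "D")
  for (chr in nt_chromosomes) {
    chr <- check_chromosome(chr)
    tet <- paste0(substr(chr, 1, 1),
                  genomes[match(substr(chr, 2, 2), genomes) %% 3L + 1L])
    rows[[length(rows) + 1L]] <- data.frame(
      line = sprintf("N%sT%s", chr, tet), stock_class = "NT",
      chromosome = chr, arm = NA_character_, fl = NA_real_,
      tetrasomic = tet, stringsAsFactors = FALSE)
  }
  del_chroms <- unique(vapply(names(del_breakpoints),
                              function(l) parse_arm_label(l)$chromosome, ""))
  for (chr in del_chroms) {
    for (arm in c("S", "L")) {
      rows[[length(rows) + 1L]] <- data.frame(
        line = sprintf("Dt%s%s", chr, arm), stock_class = "Dt",
        chromosome = chr, arm = arm, fl = NA_real_,
        tetrasomic = NA_character_, stringsAsFactors = FALSE)
    }
  }
  for (lab in names(del_breakpoints)) {
    arm <- parse_arm_label(lab)
    fls <- del_breakpoints[[lab]]
    if (any(fls <= 0 | fls >= 1)) {
      validation_error(sprintf("breakpoints for %s must lie strictly in (0,1)", lab))
    }
    for (i in seq_along(fls)) {
      rows[[length(rows) + 1L]] <- data.frame(
        line = sprintf("Del%s%s-%d", arm$chromosome, arm$arm, i),
        stock_class = "Del", chromosome = arm$chromosome, arm = arm$arm,
        fl = fls[i], tetrasomic = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_stock_panel())
  out <- do.call(rbind, rows)
  class(out) <- c("stock_panel", "data.frame")
  out
}

#' Generate an amplification matrix from known marker positions
#'
#' The error-free call is "present" iff the line retains the marker
#' position (Del: marker FL <= breakpoint on the marker's arm; Dt: the
#' retained arm is not the complement of the marker's arm on its
#' chromosome; NT: the marker's chromosome is not the nullisomic one).
#' Calls are then flipped independently with the stated error
#' probabilities.
#'
#' @param panel a `stock_panel`.
#' @param markers data.frame with `marker`, `chromosome`, `arm`, `fl`
#'   (true FL position in (0, 1]).
#' @param false_absent probability a truly present call is flipped to
#'   absent (default 0).
#' @param false_present probability a truly absent call is flipped to
#'   present (default 0).
#' @param seed optional integer seed.
#' @return an `amp_matrix`; the truth matrix (pre-error calls) is carried
#'   in attribute `truth`.
#' @export
gen_amplification_matrix <- function(panel, markers, false_absent = 0,
                                     false_present = 0, seed = NULL) {
  stopifnot(inherits(panel, "stock_panel"),
            all(c("marker", "chromosome", "arm", "fl") %in% names(markers)))
  stopifnot(false_absent >= 0, false_absent <= 1,
            false_present >= 0, false_present <= 1)
  local_seed(seed, {
    truth <- matrix(NA_character_, nrow(panel), nrow(markers),
                    dimnames = list(panel$line, markers$marker))
    for (m in seq_len(nrow(markers))) {
      mk <- markers[m, ]
      mk$chromosome <- check_chromosome(mk$chromosome)
      present <- vapply(seq_len(nrow(panel)), function(i) {
        ln <- panel[i, ]
        switch(ln$stock_class,
          NT = ln$chromosome != mk$chromosome,
          Dt = !(ln$chromosome == mk$chromosome && ln$arm != mk$arm),
          Del = !(ln$chromosome == mk$chromosome && ln$arm == mk$arm &&
                    mk$fl > ln$fl),
          euploid = TRUE)
      }, TRUE)
      truth[, m] <- ifelse(present, "present", "absent")
    }
    calls <- truth
    if (false_absent > 0 || false_present > 0) {
      flip_p <- ifelse(truth == "present", false_absent, false_present)
      flip <- matrix(stats::runif(length(truth)) < flip_p, nrow(truth))
      calls[flip] <- ifelse(truth[flip] == "present", "absent", "present")
    }
    structure(calls, panel = panel, truth = truth,
              class = c("amp_matrix", class(calls)))
  })
}

# 61 sense codons of the standard code
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Generate a synthetic allele pair with known variants
#'
#' Builds a random valid gene (5' UTR + ORF + 3' UTR) as allele a, then
#' applies a configured set of substitutions and one insertion to obtain
#' allele b. Defaults reproduce the scale of a wheat POD allele pair: a
#' 1074-bp ORF (357 residues), 21 non-adjacent exon SNPs, and one in-frame
#' 6-bp insertion "GCTGTG" between ORF bases 42 and 43 (adding two
#' residues, Ala-Val, to the protein). SNPs avoid the start/stop codons,
#' a guard window around the insertion, and never create a stop codon;
#' the 5' UTR is ATG-free and the initiation codon satisfies the Kozak
#' rule, so the gene model is recoverable automatically.
#'
#' @param orf_len ORF length in bp, a multiple of 3 (stop included).
#' @param utr5_len,utr3_len UTR lengths in bp.
#' @param n_snps number of substitutions to plant in the ORF.
#' @param indel_pos ORF base after which the insertion is planted
#'   (NULL for no insertion).
#' @param indel_bases inserted bases.
#' @param min_spacing minimum distance in bp between planted SNPs
#'   (2 = non-adjacent).
#' @param gc GC fraction used for the random background.
#' @param seed optional integer seed.
#' @return a list: `seq_a`, `seq_b`, `utr5_len`, and `truth` (data.frame
#'   `kind`, `position` (ATG-anchored), `ref_index`, `ref`, `alt`, sorted
#'   by reference index).
#' @export
gen_allele_pair <- function(orf_len = 1074, utr5_len = 20, utr3_len = 27,
                            n_snps = 21, indel_pos = 42,
                            indel_bases = "GCTGTG", min_spacing = 2,
                            gc = 0.65, seed = NULL) {
  stopifnot(orf_len %% 3L == 0L, orf_len >= 9L)
  if (!is.null(indel_pos) && (indel_pos < 1L || indel_pos >= orf_len)) {
    validation_error("indel_pos must lie inside the ORF")
  }
  local_seed(seed, {
    codons <- sense_codons()
    repeat {
      repeat {
        utr5 <- random_dna(utr5_len, gc)
        if (utr5_len >= 3L) {
          # purine at -3 so the initiation codon passes the Kozak check
          substr(utr5, utr5_len - 2L, utr5_len - 2L) <- sample(c("A", "G"), 1L)
        }
        if (!grepl("ATG", utr5)) break   # keep the planted ATG 5'-most
      }
      # codon probabilities tilted toward the requested GC fraction
      ngc <- vapply(strsplit(codons, ""), function(b) sum(b %in% c("G", "C")), 0L)
      w <- gc^ngc * (1 - gc)^(3L - ngc)
      body <- paste(sample(codons, orf_len / 3L - 2L, replace = TRUE, prob = w),
                    collapse = "")
      if (utr5_len < 3L) {
        # no -3 context available: guarantee the +4 G of the Kozak rule
        g_codons <- codons[startsWith(codons, "G")]
        substr(body, 1L, 3L) <- sample(g_codons, 1L)
      }
      orf <- paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L))
      utr3 <- random_dna(utr3_len, gc)
      if (!is.null(indel_pos)) {
        # forbid repeat context at the insertion point so the planted
        # event is already left-aligned and cannot shift
        last <- substr(indel_bases, nchar(indel_bases), nchar(indel_bases))
        first <- substr(indel_bases, 1L, 1L)
        if (substr(orf, indel_pos, indel_pos) == last) next
        if (substr(orf, indel_pos + 1L, indel_pos + 1L) == first) next
      }
      break
    }
    # place SNPs in the ORF away from start/stop codons and the insertion
    candidates <- setdiff(seq(4L, orf_len - 3L), integer(0))
    if (!is.null(indel_pos)) {
      guard <- seq(max(1L, indel_pos - 5L), min(orf_len, indel_pos + 6L))
      candidates <- setdiff(candidates, guard)
    }
    chosen <- integer(0)
    for (p in sample(candidates)) {
      if (length(chosen) == n_snps) break
      if (all(abs(chosen - p) >= min_spacing)) chosen <- c(chosen, p)
    }
    if (length(chosen) < n_snps) {
      validation_error(sprintf(
        "cannot place %d SNPs with spacing %d in a %d-bp ORF",
        n_snps, min_spacing, orf_len))
    }
    chosen <- sort(chosen)
    orf_chars <- strsplit(orf, "")[[1L]]
    ref <- alt <- character(length(chosen))
    for (i in seq_along(chosen)) {
      p <- chosen[i]
      cstart <- 3L * ((p - 1L) %/% 3L) + 1L
      off <- p - cstart + 1L
      codon <- orf_chars[cstart:(cstart + 2L)]
      repeat {
        b <- sample(setdiff(c("A", "C", "G", "T"), orf_chars[p]), 1L)
        mutated <- codon; mutated[off] <- b
        if (Biostrings::GENETIC_CODE[paste(mutated, collapse = "")] != "*") break
      }
      ref[i] <- orf_chars[p]; alt[i] <- b
    }
    seq_a <- paste0(utr5, orf, utr3)
    truth <- data.frame(kind = rep("SNP", length(chosen)),
                        position = chosen,
                        ref_index = utr5_len + chosen,
                        ref = ref, alt = alt, stringsAsFactors = FALSE)
    if (!is.null(indel_pos)) {
      truth <- rbind(truth, data.frame(
        kind = "insertion", position = indel_pos,
        ref_index = utr5_len + indel_pos, ref = "", alt = indel_bases,
        stringsAsFactors = FALSE))
    }
    truth <- truth[order(truth$ref_index), , drop = FALSE]
    rownames(truth) <- NULL
    vs <- structure(list(variants = truth), class = "variant_set")
    list(seq_a = seq_a, seq_b = apply_variants(seq_a, vs),
         utr5_len = utr5_len, truth = truth)
  })
}

#' Generate a PCR template with planted primer sites
#'
#' Plants the forward primer site and the reverse complement of the
#' reverse primer site at a distance giving the configured product size.
#' For a non-target template (`target = FALSE`) the 3'-terminal base of
#' the allele-specific primer's site is mutated, which abolishes binding
#' under the 3'-exact rule.
#'
#' @param assay a `marker_assay`.
#' @param product_size desired product size in bp.
#' @param flank random sequence added on each side (length-2 vector).
#' @param target TRUE for the allele the assay amplifies.
#' @param allele_specific which primer carries the diagnostic 3' SNP
#'   ("forward" or "reverse").
#' @param gc background GC fraction.
#' @param seed optional integer seed.
#' @return the template sequence; attribute `product_start` gives the
#'   1-based offset of the planted forward site.
#' @export
gen_pcr_template <- function(assay, product_size, flank = c(50L, 50L),
                             target = TRUE,
                             allele_specific = c("forward", "reverse"),
                             gc = 0.5, seed = NULL) {
  allele_specific <- match.arg(allele_specific)
  lf <- nchar(assay$forward); lr <- nchar(assay$reverse)
  inner <- product_size - lf - lr
  if (inner < 0) validation_error("product size smaller than the primers")
  local_seed(seed, {
    repeat {
      fsite <- assay$forward
      rsite <- revcomp(assay$reverse)
      if (!target) {
        if (allele_specific == "forward") {
          # last base of the forward site is the primer's 3' terminus
          old <- substr(fsite, lf, lf)
          substr(fsite, lf, lf) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        } else {
          # first base of the plus-strand rsite is the reverse primer's 3' terminus
          old <- substr(rsite, 1L, 1L)
          substr(rsite, 1L, 1L) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
      }
      tmpl <- paste0(random_dna(flank[1L], gc), fsite,
                     random_dna(inner, gc), rsite,
                     random_dna(flank[2L], gc))
      # reject templates with spurious binding sites
      nf <- nrow(find_binding_sites(assay$forward, tmpl, "forward"))
      nr <- nrow(find_binding_sites(assay$reverse, tmpl, "reverse"))
      if (target && nf == 1L && nr == 1L) break
      if (!target) {
        expected <- if (allele_specific == "forward") c(0L, 1L) else c(1L, 0L)
        if (nf == expected[1L] && nr == expected[2L]) break
      }
    }
    structure(tmpl, product_start = flank[1L] + 1L)
  })
}

#' Generate a genotyped, phenotyped variety panel
#'
#' Draws a variety mean for each allele group from a normal law and
#' replicate measurements around it with a configured replicate CV; the
#' allele assignment is the recorded truth.
#'
#' @param group_sizes named list: region -> named integer vector of group
#'   sizes per allele. Defaults follow a two-region wheat panel (147 +
#'   77 = 224 varieties split 83/64 and 32/45 between two alleles).
#' @param mu named vector of allele group means, U min^-1 g^-1.
#' @param sd between-variety standard deviation (default 80).
#' @param rep_cv_pct replicate CV in percent (default 5).
#' @param n_reps replicates per variety (default 2). A third measurement
#'   is drawn automatically whenever the duplicate CV exceeds
#'   `retest_cv_pct`, emulating the assay's retest rule.
#' @param retest_cv_pct duplicate-CV threshold triggering the extra
#'   replicate (default 10; NA disables retesting).
#' @param heavy_tails if TRUE, variety effects are drawn from a scaled t
#'   distribution (df 4) instead of the normal.
#' @param seed optional integer seed.
#' @return a list: `calls` (variety, allele), `phenotypes` (variety,
#'   region, rep1..repk), `truth` (the generating parameters).
#' @export
gen_variety_panel <- function(
    group_sizes = list(
      YHRVWWR = c("TaPod-D1b" = 83L, "TaPod-D1a" = 64L),
      NWWR = c("TaPod-D1b" = 32L, "TaPod-D1a" = 45L)),
    mu = c("TaPod-D1a" = 676, "TaPod-D1b" = 708),
    sd = 80, rep_cv_pct = 5, n_reps = 2L, retest_cv_pct = 10,
    heavy_tails = FALSE, seed = NULL) {
  stopifnot(sd >= 0, rep_cv_pct >= 0, n_reps >= 1L)
  local_seed(seed, {
    calls <- list(); phen <- list(); idx <- 0L
    for (region in names(group_sizes)) {
      for (allele in names(group_sizes[[region]])) {
        n <- group_sizes[[region]][[allele]]
        if (n < 1L) validation_error("group sizes must be >= 1")
        for (v in seq_len(n)) {
          idx <- idx + 1L
          variety <- sprintf("V%03d", idx)
          eff <- if (heavy_tails) stats::rt(1L, df = 4) * sd / sqrt(2)
                 else stats::rnorm(1L, 0, sd)
          m <- mu[[allele]] + eff
          while (m <= 0) m <- mu[[allele]] + stats::rnorm(1L, 0, sd)
          draw <- function(k) {
            r <- stats::rnorm(k, m, rep_cv_pct / 100 * m)
            while (any(r <= 0)) r <- stats::rnorm(k, m, rep_cv_pct / 100 * m)
            r
          }
          reps <- draw(n_reps)
          if (!is.na(retest_cv_pct) && n_reps >= 2L &&
              replicate_cv(reps[1:2]) > retest_cv_pct) {
            reps <- c(reps, draw(1L))
          }
          calls[[idx]] <- data.frame(variety = variety, allele = allele,
                                     stringsAsFactors = FALSE)
          row <- data.frame(variety = variety, region = region,
                            stringsAsFactors = FALSE)
          row[paste0("rep", seq_along(reps))] <- as.list(reps)
          phen[[idx]] <- row
        }
      }
    }
    cols <- unique(unlist(lapply(phen, names)))
    phen <- lapply(phen, function(r) {
      r[setdiff(cols, names(r))] <- NA_real_
      r[cols]
    })
    list(calls = do.call(rbind, calls), phenotypes = do.call(rbind, phen),
         truth = list(group_sizes = group_sizes, mu = mu, sd = sd,
                      rep_cv_pct = rep_cv_pct))
  })
}
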