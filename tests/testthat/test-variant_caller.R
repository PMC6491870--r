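test_that("trivial alignments behave as expected", {
  aln <- global_align("ACGT", "ACGT")
  expect_equal(identity_pct(aln), 100.0)
  expect_equal(aln$aligned_a, aln$aligned_b)
  aln2 <- global_align("ACGT", "ACGA")
  expect_equal(identity_pct(aln2), 75.0)
  vs2 <- call_variants(aln2)
  expect_equal(vs2$n_snp, 1L)
  expect_equal(vs2$variants$ref, "T")
  expect_equal(vs2$variants$alt, "A")
  expect_error(global_align("", "ACGT"), class = "delbin_validation_error")
})

test_that("alignment scores match the independent affine-gap oracle", {
  set.seed(61)
  for (rep in 1:40) {
    la <- sample(1:12, 1); lb <- sample(1:12, 1)
    a <- random_dna(la); b <- random_dna(lb)
    expect_equal(global_align(a, b)$score,
                 oracle_align_score(a, b),
                 info = sprintf("a=%s b=%s", a, b))
  }
})

test_that("de-gapping a global alignment recovers both inputs", {
  set.seed(71)
  for (rep in 1:20) {
    ap <- gen_allele_pair(orf_len = 3 * sample(40:80, 1),
                          n_snps = sample(0:8, 1), indel_pos = 12)
    aln <- global_align(ap$seq_a, ap$seq_b)
    expect_equal(gsub("-", "", aln$aligned_a), ap$seq_a)
    expect_equal(gsub("-", "", aln$aligned_b), ap$seq_b)
  }
})

test_that("identical alleles give an empty variant set", {
  set.seed(81)
  ap <- gen_allele_pair(n_snps = 0, indel_pos = NULL)
  expect_equal(ap$seq_a, ap$seq_b)
  vs <- call_variants(global_align(ap$seq_a, ap$seq_b))
  expect_equal(vs$n_snp, 0L)
  expect_equal(vs$n_indel, 0L)
  expect_equal(nrow(vs$variants), 0L)
  expect_equal(vs$identity_pct, 100.0)
})

test_that("the default allele pair is recovered exactly", {
  # 21 exon SNPs and one 6-bp insertion after ORF base 42
  ap <- gen_allele_pair(seed = 91)
  aln <- global_align(ap$seq_a, ap$seq_b)
  vs <- call_variants(aln, coordinate_anchor = ap$utr5_len)
  expect_equal(vs$n_snp, 21L)
  expect_equal(vs$n_indel, 1L)
  ins <- vs$variants[vs$variants$kind == "insertion", ]
  expect_equal(ins$alt, "GCTGTG")
  expect_equal(ins$position, 42L)
  expect_equal(vs$variants[, c("kind", "position", "ref", "alt")],
               ap$truth[, c("kind", "position", "ref", "alt")])
})

test_that("planted variants are recovered across many seeds", {
  for (seed in 1:25) {
    k <- 3 + seed %% 6
    ap <- gen_allele_pair(orf_len = 300, n_snps = k, indel_pos = NULL,
                          min_spacing = 8, seed = seed)
    vs <- call_variants(global_align(ap$seq_a, ap$seq_b),
                        coordinate_anchor = ap$utr5_len)
    expect_equal(vs$n_snp, k, info = paste("seed", seed))
    expect_equal(vs$variants$position, ap$truth$position)
  }
})

test_that("applying the called variants reconstructs the other allele", {
  for (seed in 1:15) {
    ap <- gen_allele_pair(seed = seed)
    vs <- call_variants(global_align(ap$seq_a, ap$seq_b))
    expect_identical(apply_variants(ap$seq_a, vs), ap$seq_b)
  }
})

test_that("identity decreases monotonically with planted mutation load", {
  set.seed(111)
  idents <- vapply(c(0, 5, 15, 30, 60), function(k) {
    ap <- gen_allele_pair(orf_len = 600, n_snps = k, indel_pos = NULL,
                          min_spacing = 2)
    identity_pct(global_align(ap$seq_a, ap$seq_b))
  }, 1)
  expect_true(all(diff(idents) < 0))
})

test_that("indels are left-aligned within repeat context", {
  # insertion of "AG" after a run: ...C AGAGAG C... vs ...C AG AGAGAG C...
  a <- "TTTCCAGAGAGCCTTTGGGAAACCCTTT"
  b <- "TTTCCAGAGAGAGCCTTTGGGAAACCCTTT"
  vs <- call_variants(global_align(a, b))
  ins <- vs$variants[vs$variants$kind == "insertion", ]
  expect_equal(nrow(ins), 1L)
  # shifted to the 5'-most equivalent placement: after the C at index 5
  expect_equal(ins$ref_index, 5L)
  expect_equal(ins$alt, "AG")
  expect_identical(apply_variants(a, vs), b)
})

test_that("protein consequences separate missense from synonymous", {
  set.seed(121)
  # default pair: in-frame 6-bp insertion adds Ala-Val after residue 14
  ap <- gen_allele_pair(seed = 131)
  vs <- call_variants(global_align(ap$seq_a, ap$seq_b),
                      coordinate_anchor = ap$utr5_len)
  ma <- build_gene_model(ap$seq_a)
  mb <- build_gene_model(ap$seq_b)
  pc <- protein_consequences(vs, ma, mb)
  expect_false(pc$frameshift)
  expect_equal(pc$aa_inserted, "AV")
  expect_equal(pc$protein_length_a, 357L)
  expect_equal(pc$protein_length_b, 359L)

  # hand-built: 1 missense + 1 synonymous SNP
  seq_a <- paste0("AA", "ATGGCTGGAACCTAA", "CC")  # M A G T *
  seq_b <- paste0("AA", "ATGGTTGGTACCTAA", "CC")  # M V G T *
  vs2 <- call_variants(global_align(seq_a, seq_b), coordinate_anchor = 2)
  expect_equal(vs2$n_snp, 2L)
  pc2 <- protein_consequences(vs2,
                              build_gene_model(seq_a, utr5_len = 2),
                              build_gene_model(seq_b, utr5_len = 2))
  expect_equal(pc2$aa_substitutions, 1L)
  expect_equal(pc2$aa_inserted, "")

  # frame-disrupting indel is flagged, consequences undefined
  seq_c <- paste0("AA", "ATGGCTTGGAACCTAA", "CC")
  vs3 <- call_variants(global_align(seq_a, seq_c), coordinate_anchor = 2)
  expect_equal(vs3$n_indel, 1L)
  pc3 <- protein_consequences(vs3,
                              build_gene_model(seq_a, utr5_len = 2),
                              build_gene_model(seq_a, utr5_len = 2))
  expect_true(pc3$frameshift)
  expect_true(is.na(pc3$aa_substitutions))
})

test_that("variant tables round-trip through the TSV and VCF writers", {
  ap <- gen_allele_pair(seed = 141)
  vs <- call_variants(global_align(ap$seq_a, ap$seq_b),
                      coordinate_anchor = ap$utr5_len)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_variants(vs, tsv)
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(vs$variants))
  expect_equal(back$kind, vs$variants$kind)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants(vs, vcf, format = "vcf", gene_name = "TaPod-D1")
  lines <- readLines(vcf)
  expect_match(lines[1], "fileformat")
  expect_equal(length(lines), nrow(vs$variants) + 2L)
})
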