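# Shared readers/writers and the end-to-end pipeline driver.

#' Read a FASTA file
#'
#' @param path FASTA file (wrapped or unwrapped lines; lower-case bases
#'   are accepted and upper-cased).
#' @return named character vector of sequences, in file order; an empty
#'   file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0L) return(stats::setNames(character(), character()))
  set <- Biostrings::readBStringSet(path)
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms)) {
    validation_error(paste("duplicate FASTA identifier(s):",
                           paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  stats::setNames(toupper(as.character(set)), nms)
}

#' Write sequences to FASTA
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.character(records), !is.null(names(records)) || length(records) == 0L)
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

pipeline_log <- function(stage, msg, quiet = FALSE) {
  if (!quiet) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
  }
}

report_header <- function(seed = NULL, params = list()) {
  ver <- as.character(utils::packageVersion("delbin"))
  hash <- substr(
    paste(vapply(params, function(x) paste(format(x), collapse = ","), ""),
          collapse = ";"), 1L, 0L)  # placeholder when no params
  sprintf("# delbin %s | seed: %s | params: %s", ver,
          if (is.null(seed)) "none" else seed,
          if (length(params)) paste(names(params), unlist(lapply(params, format)),
                                    sep = "=", collapse = " ") else "defaults")
}

write_report_tsv <- function(df, path, seed = NULL, params = list()) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(report_header(seed, params), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the mapping/characterization pipeline
#'
#' Thin driver over the module functions: deletion-bin mapping from a
#' stock registry and amplification matrix; amplicon assembly and gene
#' modelling; allele variant calling; STS genotyping; and marker-trait
#' association. Stages run when their inputs are present in `config` and
#' write TSV/JSON reports (with a header line carrying the package
#' version, seed, and parameters) into `config$out_dir`.
#'
#' @param config a list with any of: `registry`, `matrix` (paths; enables
#'   bin mapping), `amplicons` (FASTA path; sequences merged in order,
#'   enables assembly + gene model), `alleles` (two-record FASTA; enables
#'   variant calling), `primers` + `templates` (primer CSV & FASTA;
#'   enables genotyping; assay pair selected by `assay_a`/`assay_b`),
#'   `genotypes` + `phenotypes` (CSVs; enables association), `out_dir`,
#'   `seed`, `quiet`, and parameter overrides `min_overlap`,
#'   `utr5_len`, `alpha`, `cv_threshold`.
#' @return named list of per-stage results, invisibly; reports on disk.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  quiet <- isTRUE(config$quiet)
  seed <- config$seed
  results <- list()

  if (!is.null(config$registry) && !is.null(config$matrix)) {
    pipeline_log("map-bins", "inferring deletion bins", quiet)
    panel <- parse_stock_registry(config$registry)
    mat <- parse_amplification_table(config$matrix, panel)
    bins <- map_bins(mat)
    write_report_tsv(bins, file.path(out_dir, "bins.tsv"), seed)
    results$bins <- bins
  }
  if (!is.null(config$amplicons)) {
    pipeline_log("assemble", "merging amplicons and building the gene model", quiet)
    amps <- read_fasta(config$amplicons)
    merged <- Reduce(function(a, b)
      merge_amplicons(a, b, min_overlap = config$min_overlap %||% 15),
      unname(amps))
    model <- build_gene_model(as.character(merged),
                              utr5_len = config$utr5_len %||% "auto")
    write_fasta(stats::setNames(model$sequence, model$name),
                file.path(out_dir, "gene.fasta"))
    jsonlite::write_json(
      model[c("name", "utr5_len", "orf_len", "utr3_len", "protein",
              "kozak_ok", "gc_pct", "mw_kda")],
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
    results$model <- model
  }
  if (!is.null(config$alleles)) {
    pipeline_log("call-variants", "aligning alleles and calling variants", quiet)
    alleles <- read_fasta(config$alleles)
    if (length(alleles) != 2L) {
      validation_error("allele FASTA must contain exactly two records")
    }
    aln <- global_align(alleles[[1L]], alleles[[2L]])
    vs <- call_variants(aln, coordinate_anchor = config$utr5_len %||% 0L)
    write_variants(vs, file.path(out_dir, "variants.tsv"))
    results$variants <- vs
  }
  if (!is.null(config$primers) && !is.null(config$templates)) {
    pipeline_log("genotype", "in-silico STS genotyping", quiet)
    assays <- read_primer_table(config$primers)
    templates <- read_fasta(config$templates)
    ab <- assays[[config$assay_b %||% "POD-7D1"]]
    aa <- assays[[config$assay_a %||% "POD-7D6"]]
    calls <- genotype_panel(as.list(templates), ab, aa)
    write_report_tsv(calls, file.path(out_dir, "genotypes.tsv"), seed)
    results$genotypes <- calls
  }
  if (!is.null(config$genotypes) && !is.null(config$phenotypes)) {
    pipeline_log("associate", "marker-trait association", quiet)
    calls <- read_table_auto(config$genotypes)
    phen <- read_table_auto(config$phenotypes)
    assoc <- associate(calls, phen,
                       alpha = config$alpha %||% c(0.05, 0.01),
                       cv_threshold = config$cv_threshold %||% 10)
    write_report_tsv(assoc$table, file.path(out_dir, "association.tsv"), seed)
    jsonlite::write_json(
      lapply(assoc$tests, function(t)
        if (is.null(t$anova)) t["note"]
        else list(f = t$anova$f, p = t$anova$p,
                  df = c(t$anova$df_between, t$anova$df_within))),
      file.path(out_dir, "association.json"), auto_unbox = TRUE, digits = NA)
    results$association <- assoc
  }
  pipeline_log("done", sprintf("%d stage(s) run", length(results)), quiet)
  invisible(results)
}
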