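# Aneuploid stock registry and marker-amplification evidence matrix.
#
# Stock classes:
#   NT  - nullisomic-tetrasomic: missing one chromosome, compensated by a
#         homoeologous tetrasome; `chromosome` holds the nullisomic
#         chromosome, `tetrasomic` the compensating one.
#   Dt  - ditelosomic: retains a single arm (`arm`).
#   Del - terminal deletion: retains the proximal fraction [0, fl] of `arm`.

STOCK_CLASSES <- c("NT", "Dt", "Del", "euploid")

read_table_auto <- function(x) {
  # accept a data.frame, a file path, or literal CSV/TSV text
  if (is.data.frame(x)) return(x)
  stopifnot(is.character(x))
  if (length(x) == 1L && file.exists(x)) {
    first <- readLines(x, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    return(utils::read.csv(x, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#"))
  }
  txt <- if (length(x) > 1L) paste(x, collapse = "\n") else x
  sep <- if (grepl("\t", strsplit(txt, "\n")[[1]][1])) "\t" else ","
  utils::read.csv(text = txt, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, comment.char = "#")
}

#' Parse an aneuploid stock registry
#'
#' Reads a registry of Chinese Spring-type cytogenetic stocks into a
#' validated stock panel. Expected columns: `line`, `stock_class`
#' (NT/Dt/Del/euploid), `chromosome` (e.g. "7D"; the nullisomic chromosome
#' for NT lines), `arm` (S or L, Dt/Del only), `fl` (breakpoint fraction
#' arm length in (0,1), Del only). An optional `tetrasomic` column gives
#' the compensating chromosome of NT lines.
#'
#' @param table a data.frame, a CSV/TSV file path, or literal tabular text.
#' @return a `stock_panel`: a data.frame with one validated row per line.
#' @examples
#' reg <- system.file("extdata", "cs_stock_registry.csv", package = "delbin")
#' panel <- parse_stock_registry(reg)
#' table(panel$stock_class)
#' @export
parse_stock_registry <- function(table) {
  df <- read_table_auto(table)
  if (nrow(df) == 0L) {
    return(empty_stock_panel())
  }
  names(df) <- tolower(names(df))
  needed <- c("line", "stock_class", "chromosome", "arm")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    validation_error(paste("registry is missing column(s):",
                           paste(missing_cols, collapse = ", ")))
  }
  if (!"fl" %in% names(df)) df$fl <- NA_real_
  if (!"tetrasomic" %in% names(df)) df$tetrasomic <- NA_character_

  out <- data.frame(
    line = trimws(as.character(df$line)),
    stock_class = trimws(as.character(df$stock_class)),
    chromosome = toupper(trimws(as.character(df$chromosome))),
    arm = toupper(trimws(as.character(df$arm))),
    fl = suppressWarnings(as.numeric(df$fl)),
    tetrasomic = toupper(trimws(as.character(df$tetrasomic))),
    stringsAsFactors = FALSE
  )
  out$arm[out$arm == ""] <- NA_character_
  out$tetrasomic[out$tetrasomic %in% c("", "NA")] <- NA_character_

  dup <- out$line[duplicated(out$line)]
  if (length(dup)) {
    validation_error(paste("duplicate line name(s) in registry:",
                           paste(unique(dup), collapse = ", ")))
  }
  for (i in seq_len(nrow(out))) {
    row <- out[i, ]
    if (!row$stock_class %in% STOCK_CLASSES) {
      validation_error(sprintf("row '%s': unknown stock class '%s'",
                               row$line, row$stock_class))
    }
    if (row$stock_class %in% c("NT", "Dt", "Del")) {
      check_chromosome(row$chromosome)
    }
    if (row$stock_class %in% c("Dt", "Del")) {
      if (is.na(row$arm) || !row$arm %in% c("S", "L")) {
        validation_error(sprintf("row '%s': arm must be S or L", row$line))
      }
    }
    if (row$stock_class == "Del") {
      if (is.na(row$fl) || row$fl <= 0 || row$fl >= 1) {
        validation_error(sprintf(
          "row '%s': Del breakpoint FL must be strictly in (0,1), got %s",
          row$line, format(df$fl[i])))
      }
    } else if (!is.na(row$fl)) {
      validation_error(sprintf(
        "row '%s': FL breakpoint is only meaningful for Del lines", row$line))
    }
    if (row$stock_class == "NT" && !is.na(row$tetrasomic)) {
      tet <- check_chromosome(row$tetrasomic)
      if (substr(tet, 1, 1) != substr(row$chromosome, 1, 1)) {
        validation_error(sprintf(
          "row '%s': tetrasomic %s is not homoeologous to nullisomic %s",
          row$line, tet, row$chromosome))
      }
    }
  }
  class(out) <- c("stock_panel", "data.frame")
  out
}

empty_stock_panel <- function() {
  out <- data.frame(line = character(), stock_class = character(),
                    chromosome = character(), arm = character(),
                    fl = numeric(), tetrasomic = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("stock_panel", "data.frame")
  out
}

#' @export
print.stock_panel <- function(x, ...) {
  cat(sprintf("Aneuploid stock panel: %d lines (%s)\n", nrow(x),
              paste(sprintf("%s %d", names(table(x$stock_class)),
                            table(x$stock_class)), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Parse a marker-amplification matrix
#'
#' Reads a presence/absence table of PCR amplification calls (lines as
#' rows, markers as columns). Cells are `+` (present), `-` (absent) or
#' `NA`/`/`/empty (missing; missing never contributes evidence).
#'
#' @param table a data.frame, file path, or literal tabular text with a
#'   `line` column followed by one column per marker.
#' @param panel a `stock_panel`; every line in the table must exist in it.
#' @return an `amp_matrix`: a character matrix (rows = lines, columns =
#'   markers) with entries "present"/"absent"/NA, carrying the panel as
#'   attribute `panel`.
#' @examples
#' reg <- system.file("extdata", "cs_stock_registry.csv", package = "delbin")
#' amp <- system.file("extdata", "cs_amplification.csv", package = "delbin")
#' m <- parse_amplification_table(amp, parse_stock_registry(reg))
#' dim(m)
#' @export
parse_amplification_table <- function(table, panel) {
  stopifnot(inherits(panel, "stock_panel"))
  df <- read_table_auto(table)
  names(df)[1] <- tolower(names(df)[1])
  if (names(df)[1] != "line") {
    validation_error("first column of the amplification table must be 'line'")
  }
  lines <- trimws(as.character(df$line))
  markers <- names(df)[-1]
  unknown <- setdiff(lines, panel$line)
  if (length(unknown)) {
    validation_error(paste("amplification table names unknown line(s):",
                           paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(lines)) {
    validation_error("duplicate line rows in amplification table")
  }
  calls <- matrix(NA_character_, nrow = length(lines), ncol = length(markers),
                  dimnames = list(lines, markers))
  for (m in markers) {
    raw <- trimws(as.character(df[[m]]))
    ok_missing <- raw %in% c("NA", "/", "") | is.na(raw)
    bad <- !(raw %in% c("+", "-")) & !ok_missing
    if (any(bad)) {
      validation_error(sprintf(
        "marker %s: cell value(s) %s not in {+, -, NA}", m,
        paste(sQuote(unique(raw[bad])), collapse = ", ")))
    }
    calls[, m] <- ifelse(raw == "+", "present",
                         ifelse(raw == "-", "absent", NA_character_))
  }
  structure(calls, panel = panel, class = c("amp_matrix", class(calls)))
}

#' Write an amplification matrix back to CSV
#'
#' Inverse of [parse_amplification_table()]: "present" becomes `+`,
#' "absent" becomes `-`, missing becomes `NA`.
#'
#' @param matrix an `amp_matrix`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_amplification_table <- function(matrix, path) {
  stopifnot(inherits(matrix, "amp_matrix"))
  sym <- ifelse(is.na(matrix), "NA",
                ifelse(matrix == "present", "+", "-"))
  df <- data.frame(line = rownames(matrix), sym, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("line", colnames(matrix))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

amp_panel <- function(matrix) attr(matrix, "panel")

# subset of panel rows corresponding to matrix rows, in matrix order
matrix_lines <- function(matrix) {
  panel <- amp_panel(matrix)
  panel[match(rownames(matrix), panel$line), , drop = FALSE]
}

#' Merge the calls of several markers assaying the same gene
#'
#' Markers amplifying the same gene (e.g. two primer sets spanning one
#' locus) are expected to agree line by line. Agreeing calls are kept; a
#' disagreeing line is set to missing with a warning.
#'
#' @param matrix an `amp_matrix`.
#' @param markers character vector of marker names to merge.
#' @param name name of the merged column (default: markers joined by "+").
#' @return an `amp_matrix` with a single merged column.
#' @export
merge_marker_calls <- function(matrix, markers, name = paste(markers, collapse = "+")) {
  stopifnot(inherits(matrix, "amp_matrix"), all(markers %in% colnames(matrix)))
  sub <- matrix[, markers, drop = FALSE]
  merged <- apply(sub, 1L, function(v) {
    u <- unique(v[!is.na(v)])
    if (length(u) == 1L) u else if (length(u) == 0L) NA_character_ else "conflict"
  })
  if (any(merged == "conflict", na.rm = TRUE)) {
    bad <- names(merged)[which(merged == "conflict")]
    warning(sprintf("markers %s disagree for line(s) %s; treated as missing",
                    paste(markers, collapse = "/"), paste(bad, collapse = ", ")))
    merged[merged == "conflict"] <- NA_character_
  }
  out <- matrix(merged, ncol = 1, dimnames = list(rownames(matrix), name))
  structure(out, panel = amp_panel(matrix), class = c("amp_matrix", class(out)))
}
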