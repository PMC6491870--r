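# Deletion-bin inference.
#
# Geometry: a Del line with breakpoint FL f retains the proximal [0, f] of
# its arm (centromere = 0, telomere = 1). A marker absent in that line is
# therefore distal to f; a marker present is at or proximal to f. The bin
# is the half-open interval (lower, upper] with
#   lower = max breakpoint over absent Del lines (0 if none),
#   upper = min breakpoint over present Del lines (1.0 if none, justified
#           by presence in the whole-arm Dt line).

marker_calls <- function(matrix, marker) {
  if (!marker %in% colnames(matrix)) {
    validation_error(sprintf("marker '%s' not in matrix", marker))
  }
  calls <- matrix[, marker]
  names(calls) <- rownames(matrix)
  calls
}

#' Assign a marker to a chromosome from NT-line evidence
#'
#' A nullisomic-tetrasomic (NT) line lacks one chromosome; failure to
#' amplify in exactly the lines nullisomic for chromosome C, with
#' amplification in all other NT lines, places the marker on C.
#'
#' @param matrix an `amp_matrix` containing NT lines.
#' @param marker marker name.
#' @return a `chromosome_assignment` list: `marker`, `chromosome` (label or
#'   NA if unresolved), `status` ("assigned", "unresolved", "multi_locus"),
#'   `diagnostic`, and the NT `evidence` used.
#' @export
assign_chromosome <- function(matrix, marker) {
  calls <- marker_calls(matrix, marker)
  lines <- matrix_lines(matrix)
  nt <- lines$stock_class == "NT"
  if (!any(nt)) validation_error("matrix contains no NT lines")
  ev <- data.frame(line = lines$line[nt],
                   nullisomic = lines$chromosome[nt],
                   call = unname(calls[nt]),
                   stringsAsFactors = FALSE)
  absent_chr <- unique(ev$nullisomic[!is.na(ev$call) & ev$call == "absent"])
  res <- list(marker = marker, chromosome = NA_character_, evidence = ev)
  if (length(absent_chr) == 0L) {
    res$status <- "unresolved"
    res$diagnostic <- "marker present in all NT lines"
  } else if (length(absent_chr) > 1L) {
    res$status <- "multi_locus"
    res$diagnostic <- sprintf(
      "absent in nullisomics of %s: multi-locus or contradictory",
      paste(absent_chr, collapse = " and "))
  } else {
    others <- ev[ev$nullisomic != absent_chr & !is.na(ev$call), ]
    if (all(others$call == "present")) {
      res$chromosome <- absent_chr
      res$status <- "assigned"
      res$diagnostic <- sprintf("absent in all %s nullisomics, present elsewhere",
                                absent_chr)
    } else {
      res$status <- "unresolved"
      res$diagnostic <- sprintf("absent outside %s nullisomics too", absent_chr)
    }
  }
  structure(res, class = "chromosome_assignment")
}

#' Assign a marker to a chromosome arm from Dt-line evidence
#'
#' A ditelosomic (Dt) line retains only one arm; absence of amplification
#' in the line retaining arm X places the marker on the complementary arm.
#'
#' @param matrix an `amp_matrix` containing Dt lines of `chromosome`.
#' @param marker marker name.
#' @param chromosome chromosome label (e.g. "7D").
#' @return an `arm_assignment` list: `marker`, `chromosome`, `arm` ("S",
#'   "L" or NA), `status`, `diagnostic`, `evidence`.
#' @export
assign_arm <- function(matrix, marker, chromosome) {
  chromosome <- check_chromosome(chromosome)
  calls <- marker_calls(matrix, marker)
  lines <- matrix_lines(matrix)
  dt <- lines$stock_class == "Dt" & lines$chromosome == chromosome
  res <- list(marker = marker, chromosome = chromosome, arm = NA_character_,
              evidence = data.frame(line = lines$line[dt],
                                    retained_arm = lines$arm[dt],
                                    call = unname(calls[dt]),
                                    stringsAsFactors = FALSE))
  if (!any(dt)) {
    res$status <- "unresolved"
    res$diagnostic <- sprintf("no Dt lines for chromosome %s", chromosome)
    return(structure(res, class = "arm_assignment"))
  }
  call_on <- function(arm) {
    v <- calls[dt & lines$arm == arm]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_character_ else v[[1L]]
  }
  on_s <- call_on("S"); on_l <- call_on("L")
  if (identical(on_l, "absent") && identical(on_s, "present")) {
    res$arm <- "S"; res$status <- "assigned"
    res$diagnostic <- "absent in the L-arm telosome, present in the S-arm telosome"
  } else if (identical(on_s, "absent") && identical(on_l, "present")) {
    res$arm <- "L"; res$status <- "assigned"
    res$diagnostic <- "absent in the S-arm telosome, present in the L-arm telosome"
  } else {
    res$status <- "unresolved"
    res$diagnostic <- sprintf("Dt calls uninformative (S: %s, L: %s)",
                              on_s %||% NA, on_l %||% NA)
  }
  structure(res, class = "arm_assignment")
}

del_evidence <- function(matrix, marker, chromosome, arm) {
  calls <- marker_calls(matrix, marker)
  lines <- matrix_lines(matrix)
  sel <- lines$stock_class == "Del" & lines$chromosome == chromosome &
    lines$arm == arm & !is.na(calls)
  data.frame(line = lines$line[sel], fl = lines$fl[sel],
             call = unname(calls[sel]), stringsAsFactors = FALSE)
}

new_physical_bin <- function(marker, chromosome, arm, lower, upper, ev) {
  structure(list(
    marker = marker, chromosome = chromosome, arm = arm,
    lower_fl = lower, upper_fl = upper,
    distal_fraction = if (upper == 1) 1 - lower else NA_real_,
    supporting_absent = ev$line[ev$call == "absent"],
    supporting_present = ev$line[ev$call == "present"]
  ), class = "physical_bin")
}

#' @export
print.physical_bin <- function(x, ...) {
  cat(sprintf("Physical bin for %s on %s%s: (%.2f, %.2f]%s\n",
              x$marker, x$chromosome, x$arm, x$lower_fl, x$upper_fl,
              if (!is.na(x$distal_fraction))
                sprintf(" — distal %.2f of the arm", x$distal_fraction) else ""))
  cat(sprintf("  absent in %d line(s), present in %d line(s)\n",
              length(x$supporting_absent), length(x$supporting_present)))
  invisible(x)
}

#' Infer the deletion bin of a marker on an assigned arm
#'
#' Computes the fraction-arm-length interval compatible with every Del-line
#' call on the arm: the bin is bounded below by the largest breakpoint
#' among lines lacking the marker (exclusive) and above by the smallest
#' breakpoint among lines retaining it (inclusive). With no retaining Del
#' line the upper bound 1.0 is taken from presence in the whole-arm Dt
#' line, which must then be present.
#'
#' @param matrix an `amp_matrix`.
#' @param marker marker name.
#' @param chromosome chromosome label.
#' @param arm "S" or "L".
#' @param tolerant if TRUE, a contradictory panel is resolved by greedily
#'   dropping the fewest calls (deterministic order: by line name) and the
#'   dropped lines are reported in attribute `dropped`; if FALSE (default)
#'   a contradiction raises an error listing the conflicting line pairs.
#' @return a `physical_bin` with bounds `lower_fl` (exclusive), `upper_fl`
#'   (inclusive) and, for telomeric bins, `distal_fraction = 1 - lower_fl`.
#' @examples
#' reg <- system.file("extdata", "cs_stock_registry.csv", package = "delbin")
#' amp <- system.file("extdata", "cs_amplification.csv", package = "delbin")
#' m <- parse_amplification_table(amp, parse_stock_registry(reg))
#' infer_bin(m, "P1", "7D", "S")
#' @export
infer_bin <- function(matrix, marker, chromosome, arm, tolerant = FALSE) {
  chromosome <- check_chromosome(chromosome)
  stopifnot(arm %in% c("S", "L"))
  ev <- del_evidence(matrix, marker, chromosome, arm)
  if (nrow(ev) == 0L) {
    validation_error(sprintf("no Del-line calls for %s on %s%s",
                             marker, chromosome, arm))
  }
  dropped <- character()
  repeat {
    absent <- ev[ev$call == "absent", , drop = FALSE]
    present <- ev[ev$call == "present", , drop = FALSE]
    lower <- if (nrow(absent)) max(absent$fl) else 0
    upper <- if (nrow(present)) min(present$fl) else 1.0
    if (lower < upper) break
    conflicts <- merge(absent[absent$fl >= upper, c("line", "fl")],
                       present[present$fl <= lower, c("line", "fl")],
                       by = NULL, suffixes = c("_absent", "_present"))
    if (!tolerant) {
      contradiction_error(sprintf(
        "contradictory calls for %s on %s%s: %s",
        marker, chromosome, arm,
        paste(sprintf("%s (absent, FL %.2f) vs %s (present, FL %.2f)",
                      conflicts$line_absent, conflicts$fl_absent,
                      conflicts$line_present, conflicts$fl_present),
              collapse = "; ")), conflicts = conflicts)
    }
    # tolerant: drop the single call implicated in most conflicts;
    # ties broken by line name for determinism
    cand <- sort(c(conflicts$line_absent, conflicts$line_present))
    hits <- table(cand)
    victim <- names(hits)[order(-hits, names(hits))][1L]
    dropped <- c(dropped, victim)
    ev <- ev[ev$line != victim, , drop = FALSE]
    if (nrow(ev) == 0L) {
      contradiction_error(sprintf(
        "tolerant mode dropped every call for %s on %s%s", marker,
        chromosome, arm))
    }
  }
  if (nrow(ev[ev$call == "present", , drop = FALSE]) == 0L) {
    # whole-arm upper bound requires the arm's telosome to amplify
    lines <- matrix_lines(matrix)
    calls <- marker_calls(matrix, marker)
    dt_ok <- lines$stock_class == "Dt" & lines$chromosome == chromosome &
      lines$arm == arm & !is.na(calls) & calls == "present"
    if (!any(dt_ok)) {
      validation_error(sprintf(
        "no present Del line on %s%s and its Dt line does not amplify %s: upper bound unsupported",
        chromosome, arm, marker))
    }
  }
  bin <- new_physical_bin(marker, chromosome, arm, lower, upper, ev)
  if (length(dropped)) attr(bin, "dropped") <- dropped
  bin
}

#' Brute-force deletion-bin oracle
#'
#' Enumerates candidate marker positions on a regular FL grid and keeps
#' every position consistent with each Del-line call (a retaining line
#' forces position <= its breakpoint; a lacking line forces position >
#' its breakpoint). Returns the hull of surviving grid positions; exists
#' as an independent cross-check of [infer_bin()].
#'
#' @inheritParams infer_bin
#' @param grid_step grid resolution in FL units (default 0.001).
#' @return a `physical_bin` whose bounds are the surviving-position hull.
#' @export
brute_force_bin <- function(matrix, marker, chromosome, arm, grid_step = 0.001) {
  stopifnot(grid_step > 0)
  chromosome <- check_chromosome(chromosome)
  ev <- del_evidence(matrix, marker, chromosome, arm)
  grid <- seq(grid_step, 1, by = grid_step)
  ok <- rep(TRUE, length(grid))
  for (i in seq_len(nrow(ev))) {
    ok <- ok & if (ev$call[i] == "present") grid <= ev$fl[i] + 1e-12
               else grid > ev$fl[i] + 1e-12
  }
  if (!any(ok)) {
    contradiction_error(sprintf(
      "no grid position on %s%s is consistent with every call for %s",
      chromosome, arm, marker))
  }
  surv <- grid[ok]
  new_physical_bin(marker, chromosome, arm,
                   lower = round(min(surv) - grid_step, 10),
                   upper = round(max(surv), 10), ev)
}

#' Count amplified lines of a stock class
#'
#' @param matrix an `amp_matrix`.
#' @param marker marker name.
#' @param stock_class one of "NT", "Dt", "Del", "euploid".
#' @return number of lines of that class in which the marker amplifies.
#' @export
count_amplified <- function(matrix, marker, stock_class) {
  if (nrow(matrix) == 0L) return(0L)
  calls <- marker_calls(matrix, marker)
  lines <- matrix_lines(matrix)
  sum(lines$stock_class == stock_class & !is.na(calls) & calls == "present")
}

#' Map every marker of a matrix to its deletion bin
#'
#' Runs arm assignment (Dt evidence) and bin inference (Del evidence) for
#' each marker; chromosome assignment from NT lines is used when NT lines
#' are present, otherwise the chromosome is taken from the informative Dt
#' line. This is the whole-panel driver behind the `map-bins` workflow.
#'
#' @param matrix an `amp_matrix`.
#' @param markers markers to map (default: all columns).
#' @param tolerant passed to [infer_bin()].
#' @return a data.frame with one row per marker: `marker`, `chromosome`,
#'   `arm`, `lower_fl`, `upper_fl`, `distal_fraction`, `n_present`,
#'   `n_absent`, `status`.
#' @examples
#' reg <- system.file("extdata", "cs_stock_registry.csv", package = "delbin")
#' amp <- system.file("extdata", "cs_amplification.csv", package = "delbin")
#' m <- parse_amplification_table(amp, parse_stock_registry(reg))
#' map_bins(m)
#' @export
map_bins <- function(matrix, markers = colnames(matrix), tolerant = FALSE) {
  lines <- matrix_lines(matrix)
  has_nt <- any(lines$stock_class == "NT")
  rows <- lapply(markers, function(mk) {
    out <- data.frame(marker = mk, chromosome = NA_character_,
                      arm = NA_character_, lower_fl = NA_real_,
                      upper_fl = NA_real_, distal_fraction = NA_real_,
                      n_present = NA_integer_, n_absent = NA_integer_,
                      status = "unresolved", stringsAsFactors = FALSE)
    chrom <- NA_character_
    if (has_nt) {
      ca <- assign_chromosome(matrix, mk)
      if (ca$status != "assigned") {
        out$status <- ca$status
        return(out)
      }
      chrom <- ca$chromosome
    } else {
      # fall back on the Dt line that fails to amplify
      calls <- marker_calls(matrix, mk)
      dt <- lines$stock_class == "Dt" & !is.na(calls) & calls == "absent"
      chroms <- unique(lines$chromosome[dt])
      if (length(chroms) != 1L) {
        out$status <- if (length(chroms)) "multi_locus" else "unresolved"
        return(out)
      }
      chrom <- chroms
    }
    aa <- assign_arm(matrix, mk, chrom)
    if (aa$status != "assigned") {
      out$chromosome <- chrom
      out$status <- "arm_unresolved"
      return(out)
    }
    bin <- infer_bin(matrix, mk, chrom, aa$arm, tolerant = tolerant)
    data.frame(marker = mk, chromosome = chrom, arm = aa$arm,
               lower_fl = bin$lower_fl, upper_fl = bin$upper_fl,
               distal_fraction = bin$distal_fraction,
               n_present = length(bin$supporting_present),
               n_absent = length(bin$supporting_absent),
               status = "mapped", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
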