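# Replicate QC, one-way ANOVA and Fisher's LSD for marker-trait
# association on a variety panel.
#
# QC rule: enzyme activity is assayed in duplicate; if the duplicate CV
# exceeds 10% a third measurement is made and the mean of the two closest
# values is reported.

#' Coefficient of variation of replicate measurements
#'
#' @param values numeric vector of >= 2 replicate activities; mean must be
#'   positive.
#' @return 100 * sample sd / mean, in percent.
#' @examples
#' replicate_cv(c(100, 110))
#' @export
replicate_cv <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) validation_error("need at least 2 replicates")
  m <- mean(values)
  if (m <= 0) validation_error("replicate mean must be positive")
  100 * stats::sd(values) / m
}

#' Replicate QC and accepted mean
#'
#' Applies the duplicate-CV rule: if the CV of the first two replicates is
#' within the threshold their mean is accepted (status "pass"); above the
#' threshold with a third measurement available, the mean of the two
#' closest values is accepted (status "retested"); above the threshold
#' with no retest the record fails.
#'
#' @param values replicate activities (first two form the duplicate).
#' @param cv_threshold CV threshold in percent (default 10).
#' @return a `replicate_set` list: `values`, `cv_pct` (duplicate CV),
#'   `accepted_mean` (NA on fail), `qc_status`.
#' @examples
#' qc_mean(c(100, 150, 148))
#' @export
qc_mean <- function(values, cv_threshold = 10) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  if (any(values <= 0)) validation_error("activities must be positive")
  cv <- replicate_cv(values[1:2])
  if (cv <= cv_threshold) {
    res <- list(accepted_mean = mean(values[1:2]), qc_status = "pass")
  } else if (length(values) >= 3L) {
    pairs <- utils::combn(seq_along(values), 2L)
    gaps <- abs(values[pairs[1L, ]] - values[pairs[2L, ]])
    best <- which.min(gaps)
    res <- list(accepted_mean = mean(values[pairs[, best]]),
                qc_status = "retested")
  } else {
    res <- list(accepted_mean = NA_real_, qc_status = "fail")
  }
  structure(c(list(values = values, cv_pct = cv), res),
            class = "replicate_set")
}

#' Fixed-effects one-way ANOVA
#'
#' Unbalanced one-way analysis of variance via `stats::lm`/`anova`.
#' Degenerate panels with zero within-group variance return F = 0 (equal
#' means) or p = 0 (unequal means).
#'
#' @param groups a named list of numeric vectors (one per group, each with
#'   >= 2 values).
#' @return a list: `f`, `p`, `df_between`, `df_within`, `ms_within`,
#'   `group_means`, `group_n`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4)))
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 2L)) {
    validation_error("every group needs at least 2 values")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, 1L)))
  )
  # zero-residual panels warn inside anova(); the degenerate F/p values
  # are replaced below, so the warning is noise here
  tab <- suppressWarnings(stats::anova(stats::lm(y ~ g, data = df)))
  f <- tab$`F value`[1L]; p <- tab$`Pr(>F)`[1L]
  if (tab$`Mean Sq`[2L] == 0) {
    means <- vapply(groups, mean, 1)
    if (max(means) - min(means) == 0) { f <- 0; p <- 1 } else { f <- Inf; p <- 0 }
  }
  list(f = f, p = p,
       df_between = tab$Df[1L], df_within = tab$Df[2L],
       ms_within = tab$`Mean Sq`[2L],
       group_means = vapply(groups, mean, 1),
       group_n = vapply(groups, length, 1L))
}

#' Fisher's least significant difference with letter grouping
#'
#' Post-ANOVA pairwise comparisons: groups i and j differ when
#' `|mean_i - mean_j| > t(1 - alpha/2, df_within) * sqrt(MSW (1/n_i + 1/n_j))`.
#' Letters are assigned by the standard descending-mean line method
#' (groups sharing a letter are not significantly different).
#'
#' @param groups named list of numeric vectors, as in [one_way_anova()].
#' @param alpha significance level (default 0.05).
#' @return a list: `letters` (named character vector, descending-mean
#'   order of assignment), `lsd` (pairwise LSD matrix), `significant`
#'   (logical pairwise matrix), `alpha`, `anova`.
#' @export
fisher_lsd <- function(groups, alpha = 0.05) {
  if (length(groups) == 1L) {
    return(list(letters = stats::setNames("a", names(groups)),
                lsd = NULL, significant = NULL, alpha = alpha, anova = NULL))
  }
  aov <- one_way_anova(groups)
  k <- length(groups); nm <- names(groups)
  n <- aov$group_n; means <- aov$group_means
  tcrit <- stats::qt(1 - alpha / 2, aov$df_within)
  lsd <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  sig <- matrix(NA, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    lsd[i, j] <- tcrit * sqrt(aov$ms_within * (1 / n[i] + 1 / n[j]))
    sig[i, j] <- abs(means[i] - means[j]) > lsd[i, j]
  }
  # line method over means sorted in descending order
  ord <- order(-means)
  ranges <- list()
  for (ii in seq_len(k)) {
    jj <- ii
    while (jj < k) {
      cand <- ord[ii:(jj + 1)]
      if (any(sig[cand, cand], na.rm = TRUE)) break
      jj <- jj + 1
    }
    ranges[[ii]] <- c(ii, jj)
  }
  # drop ranges nested in an earlier one, then letter the rest
  keep <- ranges[!vapply(seq_along(ranges), function(r) {
    any(vapply(ranges[-r], function(o)
      o[1] <= ranges[[r]][1] && ranges[[r]][2] <= o[2] &&
        !identical(o, ranges[[r]]), TRUE))
  }, TRUE)]
  keep <- unique(keep)
  lett <- stats::setNames(rep("", k), nm[ord])
  for (r in seq_along(keep)) {
    idx <- seq(keep[[r]][1], keep[[r]][2])
    lett[idx] <- paste0(lett[idx], letters[r])
  }
  list(letters = lett, lsd = lsd, significant = sig, alpha = alpha,
       anova = aov)
}

#' Marker-trait association on a genotyped, phenotyped variety panel
#'
#' Joins per-variety genotype calls with phenotype records, applies the
#' replicate-CV QC to each record, and summarises POD activity per allele
#' group within each region and for the combined panel (n, mean, range),
#' with one-way ANOVA and Fisher's LSD letters at the requested alpha
#' levels. Ambiguous/null genotype calls and QC failures are excluded and
#' counted.
#'
#' @param calls data.frame with `variety`, `allele`.
#' @param phenotypes data.frame with `variety`, `region` and replicate
#'   columns `rep1`, `rep2` (optionally `rep3`).
#' @param alpha significance levels (default c(0.05, 0.01)).
#' @param cv_threshold replicate-CV threshold in percent (default 10).
#' @return an `association_result` list: `table` (one row per region x
#'   allele plus combined rows: `region`, `allele`, `n`, `mean`,
#'   `range_low`, `range_high`, significance letters per alpha), `tests`
#'   (per region: ANOVA F/p and LSD), `excluded` counts.
#' @export
associate <- function(calls, phenotypes, alpha = c(0.05, 0.01),
                      cv_threshold = 10) {
  stopifnot(all(c("variety", "allele") %in% names(calls)),
            all(c("variety", "region") %in% names(phenotypes)))
  repcols <- grep("^rep[0-9]+$", names(phenotypes), value = TRUE)
  if (length(repcols) < 2L) validation_error("need replicate columns rep1, rep2, ...")
  missing_geno <- setdiff(phenotypes$variety, calls$variety)
  if (length(missing_geno)) {
    validation_error(paste("no genotype call for variety(ies):",
                           paste(utils::head(missing_geno, 5), collapse = ", ")))
  }
  merged <- merge(phenotypes, calls, by = "variety")
  informative <- !merged$allele %in% c("ambiguous", "null")
  n_excluded_geno <- sum(!informative)
  merged <- merged[informative, , drop = FALSE]

  qc <- lapply(seq_len(nrow(merged)), function(i) {
    v <- as.numeric(merged[i, repcols])
    qc_mean(v[!is.na(v)], cv_threshold = cv_threshold)
  })
  merged$pod <- vapply(qc, function(x) x$accepted_mean, 1)
  n_excluded_qc <- sum(is.na(merged$pod))
  merged <- merged[!is.na(merged$pod), , drop = FALSE]

  scopes <- c(stats::setNames(nm = unique(merged$region)), Combined = "Combined")
  rows <- list(); tests <- list()
  for (sc in names(scopes)) {
    sub <- if (sc == "Combined") merged else merged[merged$region == sc, ]
    groups <- split(sub$pod, sub$allele)
    groups <- groups[order(names(groups))]
    sig <- list()
    if (length(groups) >= 2L && all(vapply(groups, length, 1L) >= 2L)) {
      for (a in alpha) sig[[paste0("alpha_", a)]] <- fisher_lsd(groups, a)
      tests[[sc]] <- list(anova = one_way_anova(groups), lsd = sig)
    } else {
      tests[[sc]] <- list(anova = NULL, lsd = NULL,
                          note = "single allele class: test skipped")
    }
    for (a_name in names(groups)) {
      g <- groups[[a_name]]
      row <- data.frame(region = sc, allele = a_name, n = length(g),
                        mean = mean(g), range_low = min(g),
                        range_high = max(g), stringsAsFactors = FALSE)
      for (a in alpha) {
        col <- paste0("sig_", a)
        row[[col]] <- if (length(sig)) {
          unname(sig[[paste0("alpha_", a)]]$letters[a_name])
        } else NA_character_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  structure(list(
    table = do.call(rbind, rows),
    tests = tests,
    excluded = c(genotype = n_excluded_geno, qc = n_excluded_qc)
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("Marker-trait association\n")
  cat(sprintf("  excluded: %d uninformative genotype(s), %d QC failure(s)\n",
              x$excluded["genotype"], x$excluded["qc"]))
  tab <- x$table
  tab$mean <- round(tab$mean, 1)
  tab$range_low <- round(tab$range_low, 1)
  tab$range_high <- round(tab$range_high, 1)
  print.data.frame(tab, row.names = FALSE)
  for (sc in names(x$tests)) {
    t <- x$tests[[sc]]
    if (!is.null(t$anova)) {
      cat(sprintf("  %s: F(%d, %d) = %.2f, p = %.3g\n", sc,
                  t$anova$df_between, t$anova$df_within, t$anova$f, t$anova$p))
    }
  }
  invisible(x)
}
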