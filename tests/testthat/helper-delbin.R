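# shared fixtures and independent oracles

fixture <- function(name) {
  system.file("extdata", name, package = "delbin", mustWork = TRUE)
}

cs_matrix <- function() {
  panel <- parse_stock_registry(fixture("cs_stock_registry.csv"))
  parse_amplification_table(fixture("cs_amplification.csv"), panel)
}

random_dna <- function(n, gc = 0.5) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Independent affine-gap global alignment score: plain recursive search
# over the three column types with memoization. Usable for short
# sequences only; exists to cross-check the package aligner.
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = -7, gap_extend = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  la <- length(a); lb <- length(b)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, prev) {
    if (i > la && j > lb) return(0)
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= la && j <= lb) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= la) { # a base against a gap in b
      cost <- gap_extend + if (prev != "gb") gap_open else 0
      best <- max(best, cost + rec(i + 1, j, "gb"))
    }
    if (j <= lb) { # gap in a
      cost <- gap_extend + if (prev != "ga") gap_open else 0
      best <- max(best, cost + rec(i, j + 1, "ga"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "m")
}

# random deletion panel on one arm with an error-free matrix for a marker
# at known position; breakpoints on a 0.01 grid
random_panel_case <- function(arm_label = "7DS", n_del = 6, marker_fl = NULL) {
  fls <- sort(unique(round(runif(n_del, 0.02, 0.98), 2)))
  fls <- fls[fls > 0 & fls < 1]
  panel <- gen_stock_panel(setNames(list(fls), arm_label))
  pos <- marker_fl %||% round(runif(1, 0.01, 1), 2)
  arm <- substr(arm_label, 3, 3)
  chrom <- substr(arm_label, 1, 2)
  markers <- data.frame(marker = "M1", chromosome = chrom, arm = arm, fl = pos)
  list(matrix = gen_amplification_matrix(panel, markers),
       chromosome = chrom, arm = arm, fl = pos, breakpoints = fls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
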