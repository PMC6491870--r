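test_that("replicate CV matches the closed form", {
  expect_equal(replicate_cv(c(100, 100)), 0.0)
  expect_equal(replicate_cv(c(100, 110)), 100 * sd(c(100, 110)) / 105)
  expect_equal(replicate_cv(c(100, 110)), 6.734, tolerance = 1e-3)
  expect_equal(replicate_cv(c(100, 150)), 28.284, tolerance = 1e-3)
  expect_error(replicate_cv(100), class = "delbin_validation_error")
  expect_error(replicate_cv(c(-5, 5)), class = "delbin_validation_error")
})

test_that("the duplicate-CV rule accepts, retests or fails a record", {
  ok <- qc_mean(c(100, 105))
  expect_equal(ok$qc_status, "pass")
  expect_equal(ok$accepted_mean, 102.5)
  re <- qc_mean(c(100, 150, 148))
  expect_equal(re$qc_status, "retested")
  expect_equal(re$accepted_mean, 149.0)
  bad <- qc_mean(c(100, 150))
  expect_equal(bad$qc_status, "fail")
  expect_true(is.na(bad$accepted_mean))
  # once the retest fires, the accepted mean ignores replicate order
  set.seed(191)
  for (rep in 1:20) {
    x <- runif(1, 50, 150)
    v <- cumprod(c(x, 1.4 + runif(1) / 2, 1.4 + runif(1) / 2))
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    means <- vapply(perms, function(p) qc_mean(v[p])$accepted_mean, 1)
    expect_equal(length(unique(round(means, 9))), 1L)
  }
})

test_that("one-way ANOVA matches hand computation and the t-test", {
  res <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4)))
  expect_equal(res$f, 1.5)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)
  # identical groups: F = 0 under zero within-variance convention
  same <- one_way_anova(list(a = c(5, 5), b = c(5, 5)))
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)
  degenerate <- one_way_anova(list(a = c(5, 5), b = c(7, 7)))
  expect_equal(degenerate$p, 0)
  # two-group ANOVA is the square of the pooled t statistic
  set.seed(201)
  for (rep in 1:10) {
    x <- rnorm(sample(5:40, 1), 600, 70)
    y <- rnorm(sample(5:40, 1), 650, 70)
    f <- one_way_anova(list(x = x, y = y))$f
    t2 <- unname(t.test(x, y, var.equal = TRUE)$statistic^2)
    expect_equal(f, t2)
  }
})

test_that("LSD letters follow the pairwise threshold rule", {
  set.seed(211)
  close_a <- rnorm(50, 600, 5)
  close_b <- rnorm(50, 601, 5)
  far_c <- rnorm(50, 700, 5)
  res <- fisher_lsd(list(a = close_a, b = close_b, c = far_c), alpha = 0.05)
  expect_equal(unname(res$letters[names(res$letters) == "c"]), "a")
  expect_equal(sort(unname(res$letters[names(res$letters) != "c"])),
               c("b", "b"))
  # two indistinguishable groups share a letter
  res2 <- fisher_lsd(list(a = close_a, b = close_b))
  expect_equal(unname(res2$letters), c("a", "a"))
  # LSD value matches its formula
  aov <- one_way_anova(list(a = close_a, b = close_b))
  lsd_hand <- qt(0.975, aov$df_within) *
    sqrt(aov$ms_within * (1 / 50 + 1 / 50))
  expect_equal(unname(res2$lsd["a", "b"]), lsd_hand)
  # single group: single letter
  expect_equal(unname(fisher_lsd(list(only = 1:5))$letters), "a")
})

test_that("association summarises a panel like the published table shape", {
  vp <- gen_variety_panel(seed = 221)
  res <- associate(vp$calls, vp$phenotypes)
  tab <- res$table
  combined <- tab[tab$region == "Combined", ]
  expect_equal(sort(combined$n), c(109L, 115L))
  expect_equal(sum(combined$n), 224L)
  expect_equal(sum(tab$n[tab$region != "Combined"]), 224L)
  expect_true(all(c("sig_0.05", "sig_0.01") %in% names(tab)))
  expect_true(all(tab$range_low <= tab$mean & tab$mean <= tab$range_high))
  comb_test <- res$tests$Combined$anova
  expect_equal(comb_test$df_between, 1L)
  expect_equal(comb_test$df_within, 222L)
  expect_true(comb_test$p > 0 && comb_test$p < 1)
})

test_that("ambiguous and null calls are excluded and counted", {
  vp <- gen_variety_panel(seed = 231)
  calls <- vp$calls
  calls$allele[1:3] <- "ambiguous"
  calls$allele[4:5] <- "null"
  res <- associate(calls, vp$phenotypes)
  expect_equal(unname(res$excluded["genotype"]), 5L)
  expect_equal(sum(res$table$n[res$table$region == "Combined"]), 219L)
  # a missing genotype is an error, not silent exclusion
  expect_error(associate(calls[-1, ], vp$phenotypes),
               class = "delbin_validation_error")
})

test_that("a single-allele region reports summaries but skips the test", {
  vp <- gen_variety_panel(
    group_sizes = list(R1 = c(X = 5L), R2 = c(X = 4L, Y = 6L)),
    mu = c(X = 650, Y = 700), seed = 241)
  res <- associate(vp$calls, vp$phenotypes)
  expect_match(res$tests$R1$note, "skipped")
  expect_equal(res$table$n[res$table$region == "R1"], 5L)
})

test_that("type-I error of the association test is near alpha", {
  # null panel: both alleles share one mean; modest panel size for speed
  sizes <- list(R1 = c(a = 30L, b = 30L))
  rejections <- vapply(1:200, function(seed) {
    vp <- gen_variety_panel(group_sizes = sizes, mu = c(a = 700, b = 700),
                            sd = 80, rep_cv_pct = 0, seed = seed)
    g <- split(vp$phenotypes$rep1, vp$calls$allele)
    one_way_anova(g)$p < 0.05
  }, TRUE)
  rate <- mean(rejections)
  se3 <- 3 * sqrt(0.05 * 0.95 / 200)
  expect_gt(rate, 0.05 - se3)
  expect_lt(rate, 0.05 + se3)
})

test_that("the planted effect is recovered within its standard error", {
  set.seed(251)
  diffs <- vapply(1:30, function(seed) {
    vp <- gen_variety_panel(seed = seed)
    res <- associate(vp$calls, vp$phenotypes)
    comb <- res$table[res$table$region == "Combined", ]
    comb$mean[comb$allele == "TaPod-D1b"] -
      comb$mean[comb$allele == "TaPod-D1a"]
  }, 1)
  se <- 80 * sqrt(1 / 115 + 1 / 109)
  expect_lt(abs(mean(diffs) - 32), 3 * se / sqrt(30))
})
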