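test_that("species summaries report mean, sample CV, min and max", {
  d <- data.frame(species = rep("sp", 6), kmax = c(2, 2, 2, 2, 2, 2))
  s <- summarize_species(d, variables = "kmax")
  expect_equal(s$kmax_mean, 2)
  expect_equal(s$kmax_cv, 0)
  expect_equal(s$kmax_min, 2)
  expect_equal(s$kmax_max, 2)
  expect_error(summarize_species(d[0, ]), "no records")
  expect_error(summarize_species(data.frame(species = "x", kmax = 1)),
               "at least 2")
  # the CV is the sample (n-1) flavor
  d2 <- data.frame(species = rep("sp", 4), W = c(1, 2, 3, 4))
  expect_equal(summarize_species(d2, variables = "W")$W_cv,
               100 * sd(1:4) / 2.5)
})

test_that("one-way ANOVA from sums of squares matches aov", {
  vals <- c(1, 2, 3, 2, 3, 4, 10, 11, 12)
  grp <- rep(c("A", "B", "C"), each = 3)
  # brute-force reference from the definition
  gm <- mean(vals)
  ssb <- sum(3 * (tapply(vals, grp, mean) - gm)^2)
  ssw <- sum((vals - ave(vals, grp))^2)
  f_ref <- (ssb / 2) / (ssw / 6)
  an <- anova_oneway(vals, grp)
  expect_equal(an$F, f_ref, tolerance = 1e-12)
  # independent route: stats::aov
  fit <- summary(aov(vals ~ factor(grp)))[[1]]
  expect_equal(an$F, fit[1, "F value"], tolerance = 1e-10)
  expect_equal(an$p, fit[1, "Pr(>F)"], tolerance = 1e-10)
  # identical groups: F = 0, p = 1
  same <- anova_oneway(rep(c(5, 6), 4), rep(c("A", "B"), each = 4))
  expect_equal(unname(tapply(rep(c(5, 6), 4), rep(c("A", "B"), each = 4),
                             mean)), c(5.5, 5.5), ignore_attr = TRUE)
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_error(anova_oneway(1:5, rep("A", 5)), "2 groups")
  expect_error(anova_oneway(1:3, c("A", "A", "B")), "at least 2 values")
})

test_that("Tukey HSD agrees with the stats reference implementation", {
  set.seed(21)
  vals <- c(rnorm(8, 0), rnorm(6, 0.5), rnorm(7, 4)) # unbalanced
  grp <- rep(c("A", "B", "C"), c(8, 6, 7))
  tk <- tukey_hsd(vals, grp)
  ref <- TukeyHSD(aov(vals ~ factor(grp)))[[1]]
  expect_equal(tk$p, unname(ref[, "p adj"]), tolerance = 1e-8)
  expect_equal(tk$diff, unname(ref[, "diff"]), tolerance = 1e-10)
  # identical groups: nothing significant; far-separated: significant
  none <- tukey_hsd(rep(c(1, 2), 6), rep(c("A", "B", "C"), each = 4))
  expect_false(any(none$significant))
  far <- tukey_hsd(c(rnorm(6), rnorm(6, 10)), rep(c("A", "B"), each = 6))
  expect_true(all(far$significant))
})

test_that("compact letters encode exactly the significance relation", {
  lev <- c("A", "B", "C")
  none <- matrix(FALSE, 3, 3, dimnames = list(lev, lev))
  expect_equal(unname(compact_letter_display(none, c(A = 1, B = 2, C = 3))),
               c("a", "a", "a"))
  all_sig <- !diag(3); dimnames(all_sig) <- list(lev, lev)
  expect_equal(unname(compact_letter_display(all_sig,
                                             c(A = 1, B = 2, C = 3))),
               c("a", "b", "c"))
  chain <- none; chain["A", "C"] <- chain["C", "A"] <- TRUE
  expect_equal(unname(compact_letter_display(chain, c(A = 1, B = 2, C = 3))),
               c("a", "ab", "b"))
  # property: random relations reconstruct exactly, with minimal letters
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    g <- LETTERS[1:k]
    sig <- matrix(FALSE, k, k, dimnames = list(g, g))
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      sig[i, j] <- sig[j, i] <- runif(1) < 0.4
    }
    letts <- compact_letter_display(sig, setNames(seq_len(k), g))
    expect_true(letters_match_relation(letts, sig))
  }
})

test_that("letters order by group mean, smallest mean lettered first", {
  vals <- c(rnorm(10, 10), rnorm(10, 0))
  grp <- rep(c("high", "low"), each = 10)
  letts <- compact_letter_display(tukey_hsd(vals, grp))
  expect_equal(unname(letts[c("low", "high")]), c("a", "b"))
})

test_that("pooled group statistics agree between raw and summary routes", {
  ds <- make_species_dataset(seed = 3)
  rec <- cbind(ds$labels,
               S = 200 * ds$labels$H_true / ds$labels$W_true)
  rec$W <- rec$W_true; rec$H <- rec$H_true
  pooled <- pooled_group_stats(rec, "type", variables = c("W", "H", "S"))
  summ <- summarize_species(rec, by = "species",
                            variables = c("W", "H", "S"))
  summ$type <- rec$type[match(summ$species, rec$species)]
  wm <- weighted_group_means(summ, by = "type",
                             variables = c("W", "H", "S"))
  ord <- match(pooled$summary$type, wm$type)
  expect_equal(pooled$summary$W_mean, wm$W_mean[ord], tolerance = 1e-9)
  expect_equal(pooled$summary$S_mean, wm$S_mean[ord], tolerance = 1e-9)
  # letters differ only because the ANOVA is significant
  expect_true(all(c("W_letter", "H_letter") %in% names(pooled$summary)))
  expect_error(pooled_group_stats(transform(rec, type = NA), "type"),
               "unlabeled")
})

test_that("ANOVA power grows with effect size", {
  set.seed(13)
  rej <- vapply(c(0, 0.5, 1.5), function(delta) {
    mean(replicate(200, {
      v <- c(rnorm(10), rnorm(10, delta))
      anova_oneway(v, rep(c("A", "B"), each = 10))$p < 0.05
    }))
  }, numeric(1))
  expect_true(all(diff(rej) > 0))
  expect_gt(rej[3], 0.8)
})
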