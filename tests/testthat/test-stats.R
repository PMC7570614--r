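test_that("the packaged accuracy fixture has the published shape and values", {
  tab <- table1_fixture()
  expect_equal(nrow(tab), 240)  # 8 subjects x 6 locations x 5 windows
  expect_equal(length(unique(tab$subject)), 8)
  expect_setequal(unique(tab$location), location_channels())
  expect_setequal(unique(tab$window_s), c(5, 10, 20, 25, 48))
  pick <- function(s, l, w)
    tab$accuracy_pct[tab$subject == s & tab$location == l & tab$window_s == w]
  expect_equal(pick("Sub5", "Mid", 20), 98.3)
  expect_equal(pick("Sub3", "Right", 5), 72.1)
  expect_equal(pick("Sub7", "Left-Mid", 25), 97.5)
})

test_that("summary statistics use mean, n-1 SD and SE = SD/sqrt(n)", {
  tab <- table1_fixture()
  s <- accuracy_summary(tab)
  expect_equal(nrow(s), 30)
  expect_equal(unique(s$n), 8)
  expect_equal(s$se, s$sd / sqrt(8))
  whole5 <- s[s$location == "Whole" & s$window_s == 5, ]
  v <- tab$accuracy_pct[tab$location == "Whole" & tab$window_s == 5]
  expect_equal(whole5$mean, mean(v))
  expect_equal(whole5$sd, sd(v))
  # identical values -> SD 0, SE 0
  const <- data.frame(subject = paste0("s", 1:4),
                      location = "Mid", window_s = 10, accuracy_pct = 90)
  sc <- accuracy_summary(const)
  expect_equal(sc$sd, 0); expect_equal(sc$se, 0)
})

test_that("pooled t-tests vs Whole have 14 df and no multiplicity correction", {
  tab <- table1_fixture()
  comp <- ttest_vs_whole(tab)
  expect_equal(nrow(comp), 25)  # 5 locations x 5 windows
  expect_equal(unique(comp$df), 14)
  right10 <- comp[comp$location == "Right" & comp$window_s == 10, ]
  ref <- tab$accuracy_pct[tab$location == "Whole" & tab$window_s == 10]
  v <- tab$accuracy_pct[tab$location == "Right" & tab$window_s == 10]
  tt <- t.test(v, ref, var.equal = TRUE)
  expect_equal(right10$t, unname(tt$statistic))
  expect_equal(right10$p, tt$p.value)  # raw p, uncorrected
  expect_true(right10$significant)
})

test_that("identical groups give t = 0; equal-mean zero-variance is not significant", {
  tab <- data.frame(subject = rep(paste0("s", 1:4), 2),
                    location = rep(c("Mid", "Whole"), each = 4),
                    window_s = 10,
                    accuracy_pct = rep(c(91, 93, 95, 97), 2))
  comp <- ttest_vs_whole(tab)
  expect_equal(comp$t, 0)
  expect_false(comp$significant)
  expect_equal(count_significant(comp), 0L)
  # zero pooled variance with unequal means -> significant, warned
  tab$accuracy_pct <- rep(c(90, 95), each = 4)
  expect_warning(comp2 <- ttest_vs_whole(tab), "zero pooled variance")
  expect_true(comp2$significant)
})

test_that("an all-identical synthetic table yields zero significant contrasts", {
  tab <- expand.grid(subject = paste0("s", 1:8),
                     location = location_channels(), window_s = c(5, 10),
                     stringsAsFactors = FALSE)
  tab$accuracy_pct <- 88
  expect_equal(count_significant(ttest_vs_whole(tab)), 0L)
})

test_that("Welch flips the borderline Right 20 s contrast, pooled keeps it", {
  tab <- table1_fixture()
  pooled <- ttest_vs_whole(tab, var_equal = TRUE)
  welch <- ttest_vs_whole(tab, var_equal = FALSE)
  r20 <- function(x) x[x$location == "Right" & x$window_s == 20, "significant"]
  expect_true(r20(pooled))
  expect_false(r20(welch))
})

test_that("the report writes round-trippable tables and stars only significant rows", {
  out <- withr::local_tempdir()
  tab <- table1_fixture()
  files <- location_report(tab, out)
  expect_true(all(file.exists(files)))
  comp_in <- read.csv(files["comparisons"], check.names = FALSE)
  comp <- ttest_vs_whole(tab)
  expect_equal(nrow(comp_in), 25)
  expect_equal(comp_in$significant, comp$significant)
  expect_equal(comp_in$p, comp$p, tolerance = 1e-12)
  expect_equal(sum(comp_in$significant), count_significant(comp))
  acc_in <- read.csv(files["accuracies"], check.names = FALSE)
  expect_equal(acc_in$accuracy_pct, as.data.frame(tab)$accuracy_pct)
  wide <- read.csv(files["summary"], check.names = FALSE)
  expect_equal(dim(wide), c(5, 7))
})
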