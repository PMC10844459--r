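test_that("Cohen's d from published group summaries matches printed values", {
  # speech-to-pause ratio, HD vs control
  expect_lt(abs(cohensD(0.92, 0.51, 18, 1.91, 0.46, 11) - (-2)), 0.05)
  # total pause time, HD vs control
  expect_lt(abs(cohensD(15.91, 6.94, 18, 6.01, 1.63, 11) - 1.77), 0.05)
  # similarity DTW, HD vs control
  expect_lt(abs(cohensD(0.37, 0.24, 18, 0.92, 0.14, 11) - (-2.6)), 0.05)
})

test_that("Cohen's d is antisymmetric and degenerates sensibly", {
  expect_equal(cohensD(5, 1, 10, 3, 2, 12),
               -cohensD(3, 2, 12, 5, 1, 10))
  expect_equal(cohensD(4.2, 1.1, 9, 4.2, 1.1, 9), 0)
  expect_true(is.na(cohensD(1, 0, 5, 2, 0, 5)))
})

test_that("t statistic and d are consistent for the pooled-variance test", {
  set.seed(31)
  for (i in 1:20) {
    na <- sample(5:30, 1); nb <- sample(5:30, 1)
    xa <- rnorm(na, 1, 2); xb <- rnorm(nb, 0, 2)
    d <- cohensD(mean(xa), sd(xa), na, mean(xb), sd(xb), nb)
    t <- t.test(xa, xb, var.equal = TRUE)$statistic
    expect_equal(unname(t), d * sqrt(na * nb / (na + nb)), tolerance = 1e-10)
  }
})

test_that("the pairwise table covers all pairs with no adjustment", {
  set.seed(37)
  visits <- data.frame(
    group = rep(c("HD", "pHD", "CTR"), c(18, 7, 11)),
    f1 = c(rnorm(18, 3), rnorm(7, 1.5), rnorm(11, 1)),
    f2 = rnorm(36))
  tab <- pairwiseGroupTable(visits, c("f1", "f2"))
  expect_equal(nrow(tab), 6)
  expect_setequal(paste(tab$group_a, tab$group_b),
                  rep(c("HD pHD", "HD CTR", "pHD CTR"), 2))
  expect_false("p_adj" %in% names(tab))
  hdctr <- tab[tab$feature == "f1" & tab$group_b == "CTR" &
                 tab$group_a == "HD", ]
  expect_gt(hdctr$d, 1)
  expect_lt(hdctr$p, 0.01)
  # adjustment only on request
  tabBH <- pairwiseGroupTable(visits, c("f1", "f2"), adjust = "BH")
  expect_true(all(tabBH$p_adj >= tabBH$p - 1e-12))
  expect_error(pairwiseGroupTable(visits, "nope"), "unknown feature")
})

test_that("identical groups give near-zero d and large p", {
  set.seed(41)
  x <- rnorm(20)
  visits <- data.frame(group = rep(c("A", "B"), each = 20), f = c(x, x))
  tab <- pairwiseGroupTable(visits, "f", groups = c("A", "B"))
  expect_equal(tab$d, 0)
  expect_gt(tab$p, 0.99)
})

test_that("groups with fewer than two observations are marked missing", {
  visits <- data.frame(group = c("A", "A", "B"), f = c(1, 2, 3))
  tab <- pairwiseGroupTable(visits, "f", groups = c("A", "B"))
  expect_true(is.na(tab$d) && is.na(tab$p))
  expect_equal(tab$n_b, 1)
})

test_that("correlation methods follow the scale of the clinical score", {
  set.seed(43)
  n <- 40
  visits <- data.frame(
    moca = round(runif(n, 15, 30)),
    uhdrs_functional = round(runif(n, 10, 25)),
    uhdrs_motor = round(runif(n, 0, 60)),
    dysarthria = sample(0:2, n, replace = TRUE))
  visits$lin <- 2 * visits$moca + 1
  visits$dysmono <- exp(visits$dysarthria)   # monotone transform
  visits$noise <- rnorm(n)
  tab <- correlationTable(visits, c("lin", "dysmono", "noise"))
  expect_true(all(tab$method[tab$clinical_score == "dysarthria"] ==
                    "spearman"))
  expect_true(all(tab$method[tab$clinical_score != "dysarthria"] ==
                    "pearson"))
  expect_equal(tab$coefficient[tab$feature == "lin" &
                                 tab$clinical_score == "moca"], 1.0)
  expect_equal(tab$coefficient[tab$feature == "dysmono" &
                                 tab$clinical_score == "dysarthria"], 1.0)
  expect_true(all(abs(tab$coefficient) <= 1, na.rm = TRUE))
})

test_that("independent feature and score are nearly uncorrelated", {
  set.seed(49)
  n <- 200
  visits <- data.frame(moca = round(runif(n, 10, 30)),
                       uhdrs_functional = round(runif(n, 5, 25)),
                       uhdrs_motor = round(runif(n, 0, 80)),
                       dysarthria = sample(0:4, n, replace = TRUE),
                       f = rnorm(n))
  tab <- correlationTable(visits, "f")
  expect_true(all(abs(tab$coefficient) < 0.15))
})

test_that("constant features yield missing coefficients, not errors", {
  visits <- data.frame(moca = c(20, 25, 30), uhdrs_functional = c(20, 22, 24),
                       uhdrs_motor = c(5, 10, 20), dysarthria = c(0, 1, 2),
                       f = c(1, 1, 1))
  tab <- correlationTable(visits, "f")
  expect_true(all(is.na(tab$coefficient)))
})

test_that("Spearman results are invariant under monotone transforms", {
  set.seed(53)
  visits <- data.frame(moca = 1, uhdrs_functional = 1, uhdrs_motor = 1,
                       dysarthria = sample(0:4, 30, replace = TRUE),
                       f = rnorm(30))
  t1 <- correlationTable(visits, "f", scores = "dysarthria")
  visits$f <- visits$f^3    # strictly monotone
  t2 <- correlationTable(visits, "f", scores = "dysarthria")
  expect_equal(t1$coefficient, t2$coefficient)
})
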