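test_that("confusion-matrix metrics match hand arithmetic", {
  m <- metrics_from_confusion(confusion_matrix(matrix(c(8, 2, 4, 6), 2,
                                                      byrow = TRUE)))
  expect_equal(m$precision, c(8 / 12, 6 / 8), tolerance = 1e-12)
  expect_equal(m$recall, c(0.8, 0.6), tolerance = 1e-12)
  expect_equal(attr(m, "accuracy"), 0.7, tolerance = 1e-12)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  # diagonal matrix: everything perfect
  d <- metrics_from_confusion(confusion_matrix(diag(c(5L, 3L, 9L))))
  expect_true(all(d$precision == 1 & d$recall == 1 & d$f1 == 1))
  expect_equal(attr(d, "accuracy"), 1)
  # never-predicted class gets precision 0
  z <- metrics_from_confusion(confusion_matrix(matrix(c(0, 3, 0, 5), 2,
                                                      byrow = TRUE)))
  expect_identical(z$precision[1], 0)
  expect_error(confusion_matrix(matrix(c(1, -1, 0, 2), 2)), "nonnegative")
  expect_error(confusion_matrix(matrix(numeric(0), 0, 0)), "square")
})

test_that("accuracy equals the support-weighted recall identity on random matrices", {
  set.seed(41)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    counts <- matrix(rpois(k * k, 5) + diag(k) * 10, k)
    cm <- confusion_matrix(counts)
    m <- metrics_from_confusion(cm)
    expect_equal(attr(m, "accuracy"),
                 weighted_accuracy_from_recalls(m$recall, m$support),
                 tolerance = 1e-14)
    # permuting class order leaves accuracy and aggregates unchanged
    p <- sample(k)
    mp <- metrics_from_confusion(confusion_matrix(counts[p, p]))
    expect_equal(attr(mp, "accuracy"), attr(m, "accuracy"))
    expect_equal(aggregate_metrics(mp, "macro"), aggregate_metrics(m, "macro"),
                 tolerance = 1e-12)
    expect_equal(aggregate_metrics(mp, "weighted"),
                 aggregate_metrics(m, "weighted"), tolerance = 1e-12)
  }
  expect_error(weighted_accuracy_from_recalls(c(1, 1), c(10, 20, 30)), "length")
  expect_error(weighted_accuracy_from_recalls(c(1, 1), c(10, 0)), "positive")
})

test_that("macro and weighted aggregation coincide exactly for equal supports", {
  cm <- confusion_matrix(matrix(c(7, 3, 2, 8), 2, byrow = TRUE))
  m <- metrics_from_confusion(cm)
  expect_equal(aggregate_metrics(m, "macro"), aggregate_metrics(m, "weighted"),
               tolerance = 1e-12)
  perfect <- metrics_from_confusion(confusion_matrix(diag(c(4L, 4L, 4L))))
  expect_equal(unname(aggregate_metrics(perfect, "macro")), c(1, 1, 1))
  expect_equal(unname(aggregate_metrics(perfect, "weighted")), c(1, 1, 1))
  expect_error(aggregate_metrics(m, "median"), "arg")
})

test_that("two-factor ANOVA without replication decomposes sums of squares correctly", {
  # all columns identical: no column effect at all
  x <- matrix(rep(c(3, 5, 9, 2), 3), ncol = 3)
  a <- anova_two_factor_no_rep(x)
  expect_equal(a$table$ss[2], 0, tolerance = 1e-12)
  expect_equal(a$table$f[2], 0, tolerance = 1e-12)
  expect_equal(a$table$p[2], 1, tolerance = 1e-12)
  # additive table (consecutive integers filled row-wise): zero residual
  add <- matrix(1:9, 3, 3, byrow = TRUE)
  expect_equal(anova_two_factor_no_rep(add)$table$ss[3], 0, tolerance = 1e-9)
  expect_error(anova_two_factor_no_rep(matrix(1:2, 1, 2)), "at least 2")
  xm <- x; xm[2, 2] <- NA
  expect_error(anova_two_factor_no_rep(xm), "complete")
})

test_that("the ANOVA partition matches a brute-force textbook oracle on random tables", {
  set.seed(43)
  for (rep in 1:5) {
    x <- matrix(rnorm(16 * 3, mean = 85, sd = 8), 16, 3)
    a <- anova_two_factor_no_rep(x)
    r <- nrow(x); cc <- ncol(x); g <- mean(x)
    ss_rows <- ss_cols <- ss_tot <- 0
    for (i in 1:r) ss_rows <- ss_rows + cc * (mean(x[i, ]) - g)^2
    for (j in 1:cc) ss_cols <- ss_cols + r * (mean(x[, j]) - g)^2
    for (i in 1:r) for (j in 1:cc) ss_tot <- ss_tot + (x[i, j] - g)^2
    expect_equal(a$table$ss[1], ss_rows, tolerance = 1e-9)
    expect_equal(a$table$ss[2], ss_cols, tolerance = 1e-9)
    expect_equal(a$table$ss[3], ss_tot - ss_rows - ss_cols, tolerance = 1e-9)
    expect_equal(sum(a$table$ss[1:3]), a$table$ss[4], tolerance = 1e-9)
    expect_equal(a$table$df, c(15, 2, 30, 47))
    # F statistics invariant to adding a constant to every cell
    b <- anova_two_factor_no_rep(x + 17.3)
    expect_equal(b$table$f[1:2], a$table$f[1:2], tolerance = 1e-9)
    # p-values are the F distribution's upper tail
    expect_equal(a$table$p[1],
                 pf(a$table$f[1], 15, 30, lower.tail = FALSE), tolerance = 1e-12)
  }
})

test_that("confusion matrices round-trip through labelled CSV", {
  tmp <- withr::local_tempdir()
  cm <- confusion_matrix(matrix(c(18, 2, 0, 5, 30, 5, 1, 4, 35), 3,
                                byrow = TRUE),
                         classes = c("normal", "cancer", "varicose"))
  p <- file.path(tmp, "cm.csv")
  write_confusion(cm, p)
  back <- read_confusion(p)
  expect_equal(unname(back$counts), unname(cm$counts))
  expect_identical(back$classes, cm$classes)
  # a negative cell is rejected
  txt <- readLines(p)
  writeLines(sub("18", "-18", txt), p)
  expect_error(read_confusion(p), "negative")
})
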