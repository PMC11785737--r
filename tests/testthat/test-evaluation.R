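test_that("confusion counts agree with an exhaustive tally oracle", {
  classes <- c("a", "b", "c")
  truth <- rep(classes, each = 4)
  cm <- confusion(truth, truth, classes)
  expect_equal(unname(diag(cm)), rep(4L, 3))
  expect_equal(sum(cm), 12)
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  one_col <- confusion(truth, rep("b", 12), classes)
  expect_equal(unname(colSums(one_col)), c(0L, 12L, 0L))

  # hand-listed labels with two swaps, checked by brute-force counting
  tr <- c("a", "a", "b", "b", "c", "c")
  pr <- c("a", "b", "b", "c", "c", "c")
  cm2 <- confusion(tr, pr, classes)
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      expect_equal(cm2[i, j], sum(tr == classes[i] & pr == classes[j]))
    }
  }
  expect_error(confusion(c("a", "z"), c("a", "a"), classes),
               class = "fm_label_error")
  expect_error(confusion(c("a"), c("a", "a"), classes),
               class = "fm_label_error")
})

test_that("metrics match direct formulas on a hand-computed binary matrix", {
  ident <- matrix(diag(c(3L, 5L, 2L)), 3, 3,
                  dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  m0 <- compute_metrics(ident)
  expect_equal(m0$tp_accuracy, 1)
  expect_equal(m0$precision, 1)
  expect_equal(m0$f1, 1)

  # rows (3,1) and (0,2): TP_1=3, FN_1=1, FP_2=1
  m <- matrix(c(3L, 0L, 1L, 2L), 2, 2,
              dimnames = list(c("neg", "pos"), c("neg", "pos")))
  rep_ <- compute_metrics(m)
  expect_equal(rep_$tp_accuracy, 5 / 6)
  p1 <- 3 / 3; r1 <- 3 / 4; p2 <- 2 / 3; r2 <- 2 / 2
  expect_equal(rep_$per_class$precision, c(p1, p2))
  expect_equal(rep_$per_class$recall, c(r1, r2))
  expect_equal(rep_$precision, (4 * p1 + 2 * p2) / 6)
  expect_equal(rep_$recall, 5 / 6)
  expect_equal(rep_$f1,
               (4 * 2 * p1 * r1 / (p1 + r1) + 2 * 2 * p2 * r2 / (p2 + r2)) / 6)
  expect_error(compute_metrics(matrix(0L, 2, 2)), class = "fm_data_error")
})

test_that("support-weighted recall equals TP accuracy on random matrices", {
  set.seed(33)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    m <- matrix(rpois(k * k, 3), k, k)
    if (sum(m) == 0) m[1, 1] <- 1
    rep_ <- compute_metrics(m)
    expect_equal(rep_$recall, rep_$tp_accuracy, tolerance = 1e-12)
  }
})

test_that("an unpredicted class flags undefined precision", {
  m <- matrix(c(2L, 1L, 0L, 0L), 2, 2)   # second column never predicted
  rep_ <- expect_silent(compute_metrics(m))
  expect_true(rep_$undefined_precision)
  expect_equal(rep_$per_class$precision[2], 0)
})

test_that("repetition stats reproduce the feasibility-study table", {
  rs <- repetition_stats(table1_counts, participants = 8, max_attempts = 3)
  expect_equal(rs$denominator, 24)
  expect_equal(rs$per_class$percent_of_max,
               c(37.50, 37.50, 25.00, 29.17, 50.00, 0.00, 66.67),
               tolerance = 0.01)
  expect_equal(rs$median, 37.50, tolerance = 0.01)
  expect_equal(rs$q1, 26.04, tolerance = 0.01)
  expect_equal(rs$q3, 46.87, tolerance = 0.01)
  expect_equal(rs$iqr, 20.83, tolerance = 0.01)
  expect_error(repetition_stats(c(a = 30), 8, 3), class = "fm_data_error")
  expect_error(repetition_stats(c(a = 1), 0, 3), class = "fm_config_error")
  single <- repetition_stats(c(a = 0), 8, 3)
  expect_equal(c(single$median, single$q1, single$q3), c(0, 0, 0))
})

test_that("quartiles agree with the position-formula oracle on random data", {
  set.seed(34)
  probs <- c(0.25, 0.5, 0.75)
  for (i in 1:50) {
    counts <- stats::setNames(sample(0:24, sample(3:12, 1), replace = TRUE),
                              NULL)
    rs <- repetition_stats(counts, participants = 8, max_attempts = 3)
    oracle <- hazen_quantile_oracle(rs$per_class$percent_of_max, probs)
    expect_equal(c(rs$q1, rs$median, rs$q3), oracle, tolerance = 1e-10)
  }
  # the spec's worked sample
  x <- c(0, 25, 29.17, 37.5, 37.5, 50, 66.67)
  expect_equal(unname(stats::quantile(x, probs, type = 5)),
               hazen_quantile_oracle(x, probs))
})

test_that("pca_map matches a brute-force eigendecomposition up to sign", {
  set.seed(35)
  for (i in 1:10) {
    n <- sample(5:12, 1); d <- sample(3:6, 1)
    X <- matrix(rnorm(n * d), n, d,
                dimnames = list(NULL, paste0("R_", 1:d)))
    map <- pca_map(as.data.frame(X), components = 2)
    Z <- scale(X)
    eig <- eigen(stats::cov(Z), symmetric = TRUE)
    oracle <- Z %*% eig$vectors[, 1:2]
    for (j in 1:2) {
      dev <- min(max(abs(map$scores[, j] - oracle[, j])),
                 max(abs(map$scores[, j] + oracle[, j])))
      expect_lt(dev, 1e-8)
    }
    shares <- eig$values / sum(eig$values)
    expect_equal(unname(map$explained), shares[1:2], tolerance = 1e-10)
    expect_true(all(diff(map$explained) <= 1e-12))
    expect_lte(sum(map$explained), 1 + 1e-12)
  }
})

test_that("collinear data load entirely on the first component", {
  t_ <- seq(0, 1, length.out = 20)
  X <- cbind(R_1 = 1 + 2 * t_, R_2 = 3 - t_, R_3 = 0.5 + 4 * t_)
  map <- pca_map(as.data.frame(X), components = 2)
  expect_equal(unname(map$explained[1]), 1, tolerance = 1e-10)
})

test_that("zero-variance features are dropped with a warning", {
  X <- data.frame(R_1 = rnorm(10), R_2 = rep(2, 10), R_3 = rnorm(10))
  expect_warning(map <- pca_map(X, components = 2), "R_2")
  expect_equal(ncol(map$rotation), 2)
  expect_equal(nrow(map$rotation), 2)
})

test_that("report writers emit readable CSV and JSON", {
  rs <- repetition_stats(table1_counts, 8, 3)
  js <- withr::local_tempfile(fileext = ".json")
  write_report(rs, js)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$median, rs$median, tolerance = 1e-12)
  expect_equal(nrow(back$per_class), 7)
  cs <- withr::local_tempfile(fileext = ".csv")
  write_report(rs, cs)
  expect_equal(nrow(utils::read.csv(cs)), 7)
})
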