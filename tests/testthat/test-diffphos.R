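test_that("quantile_normalize matches the sort-average-reassign oracle", {
  m <- matrix(c(1, 2, 3, 4), 2)           # columns [1,2] and [3,4]
  expect_equal(quantile_normalize(m), matrix(c(2, 3, 2, 3), 2))
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(rlnorm(7 * 4, 5, 1), 7, 4)   # continuous: no ties
    expect_equal(quantile_normalize(m), qn_oracle(m), tolerance = 1e-12)
  }
})

test_that("quantile_normalize handles ties by tied-block averaging", {
  # x = (2,1,1,5), y = (1,2,3,4); reference = rowMeans(sorted) = (1,1.5,2.5,4.5)
  # the tied 1s occupy ranks 1-2 -> (1+1.5)/2 = 1.25
  m <- cbind(x = c(2, 1, 1, 5), y = c(1, 2, 3, 4))
  got <- quantile_normalize(m)
  expect_equal(unname(got[, "x"]), c(2.5, 1.25, 1.25, 4.5))
  expect_equal(unname(got[, "y"]), c(1, 1.5, 2.5, 4.5))
  # a fully tied column gets the grand mean of the reference everywhere
  m2 <- cbind(c(3, 3, 3), c(1, 2, 6))
  expect_equal(unname(quantile_normalize(m2)[, 1]), rep(mean(c(2, 2.5, 4.5)), 3))
})

test_that("quantile_normalize equalizes distributions, idempotently", {
  set.seed(22)
  m <- matrix(rlnorm(60 * 6, 6, 1.2), 60, 6)
  q <- quantile_normalize(m)
  for (j in 2:6) expect_equal(sort(q[, j]), sort(q[, 1]))
  expect_equal(colMeans(q), rep(mean(q[, 1]), 6), ignore_attr = TRUE)
  expect_equal(quantile_normalize(q), q, tolerance = 1e-12)
  # identical columns are a fixed point
  same <- matrix(rep(rlnorm(30), 3), 30, 3)
  expect_equal(quantile_normalize(same), same, ignore_attr = TRUE)
  # single column unchanged
  one <- matrix(c(4, 1, 9), 3, 1)
  expect_equal(quantile_normalize(one), one, ignore_attr = TRUE)
  # column permutation equivariance
  perm <- c(3, 1, 2, 6, 5, 4)
  expect_equal(quantile_normalize(m[, perm]), q[, perm], ignore_attr = TRUE)
  expect_error(quantile_normalize(matrix(0, 0, 3)), "empty")
})

test_that("quantile_normalize agrees with limma on tie-free matrices", {
  skip_if_not_installed("limma")
  set.seed(23)
  m <- matrix(rlnorm(50 * 4, 5, 1), 50, 4)
  expect_equal(quantile_normalize(m), limma::normalizeQuantiles(m),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("differential_test reproduces the pooled t-test closed form", {
  r <- differential_test(c(2, 3, 4), c(1, 2, 3))
  # pooled s^2 = 1, t = 1/sqrt(2/3), df = 4
  expect_equal(r$p_value, 2 * pt(-sqrt(3 / 2), 4), tolerance = 1e-12)
  expect_equal(r$fold_change, 1.5)
  set.seed(24)
  for (i in 1:50) {
    x <- rnorm(sample(2:6, 1), 10, 2); y <- rnorm(sample(2:6, 1), 10, 2)
    expect_equal(differential_test(x, y)$p_value, ttest_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("differential_test direction, symmetry and degenerate cases", {
  r <- differential_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$fold_change, 1)
  expect_equal(r$direction, "ns")
  # swapping sides inverts FC and keeps p
  set.seed(25)
  for (i in 1:25) {
    x <- rlnorm(3, 2, 0.3); y <- rlnorm(3, 2.5, 0.3)
    a <- differential_test(x, y); b <- differential_test(y, x)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(a$fold_change, 1 / b$fold_change, tolerance = 1e-12)
  }
  # both sides constant
  expect_equal(differential_test(c(2, 2), c(2, 2))$p_value, 1)
  z <- differential_test(c(3, 3), c(2, 2))
  expect_equal(z$p_value, 0)
  expect_equal(z$direction, "up")
  # zero control mean flags the record
  f <- differential_test(c(1, 2), c(0, 0))
  expect_true(f$flagged)
  expect_true(is.na(f$fold_change))
  expect_error(differential_test(1, c(1, 2)), "replicates")
})

test_that("differential_analysis works on common SR spots end to end", {
  set.seed(26)
  n <- 100                                 # 5% down-regulated spots, so the
  base <- rlnorm(n, 6, 0.5)                # joint normalization stays honest
  mk <- function(eff) t(vapply(seq_len(n), function(i)
    base[i] * eff[i] * rlnorm(3, 0, 0.05), numeric(3)))
  eff <- rep(1, n); eff[1:5] <- 0.4        # strong down-effects on 5 spots
  ds <- tiny_dataset(list(test = mk(eff), control = mk(rep(1, n))))
  ds <- floor_negatives(ds)
  rec <- differential_analysis(ds, "test", "control", sr_level = 6)
  expect_s3_class(rec, "differential_records")
  # spot set is a subset of the SR-6 common list
  common <- attr(rec, "common_spots")
  expect_true(all(rec$spot_id %in% common))
  injected <- sprintf("SP%02d_1_13", 1:5)
  down <- rec$spot_id[rec$direction == "down"]
  expect_true(all(injected %in% down))
  expect_false(any(injected %in% rec$spot_id[rec$direction == "up"]))
  # annotation columns travel with the records
  expect_true(all(c("symbol", "uniprot_accession", "sequence") %in% names(rec)))
})

test_that("volcano_table partitions significant records into up/down", {
  rec <- data.frame(spot_id = c("a", "b", "c"),
                    p_value = c(0.01, 0.2, 0.03),
                    fold_change = c(2, 0.5, 0.25))
  v <- volcano_table(rec, alpha = 0.05)
  expect_equal(unname(v$counts), c(1, 1))
  expect_equal(v$table$log2_fc, c(1, -1, -2))
  expect_equal(v$table$direction, c("up", "ns", "down"))
  allns <- volcano_table(data.frame(spot_id = "a", p_value = 0.9,
                                    fold_change = 1.2))
  expect_equal(unname(allns$counts), c(0, 0))
})
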