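test_that("build_stack arranges pairs into 2x2 strata", {
  call <- tibble::tibble(pop = 1:4,
                         major_count = c(50L, 40L, 45L, 30L),
                         minor_count = c(10L, 20L, 15L, 30L))
  stack <- build_stack(call, pairs = list(c(1L, 3L), c(2L, 4L)))
  expect_equal(dim(stack), c(2L, 2L, 2L))
  expect_equal(stack[, , 1], rbind(c(50L, 10L), c(45L, 15L)),
               ignore_attr = TRUE)
  expect_equal(stack[, , 2], rbind(c(40L, 20L), c(30L, 30L)),
               ignore_attr = TRUE)

  single <- build_stack(call, pairs = list(c(1L, 2L)))
  expect_equal(dim(single)[3], 1L)

  expect_error(build_stack(call, pairs = list(c(1L, 5L))), "reference")
  expect_error(build_stack(call, pairs = list(c(1L, 3L), c(1L, 4L))),
               "disjoint")
})

test_that("identical allele proportions give a zero statistic and p = 1", {
  stack <- array(30L, dim = c(2, 2, 2))
  res <- cmh_test(stack, correction = FALSE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$degenerate)
})

test_that("the statistic matches an independent closed-form oracle and mantelhaen.test", {
  # the fixed worked example
  stack <- array(c(10, 15, 20, 5, 8, 9, 12, 11), dim = c(2, 2, 2))
  for (corr in c(TRUE, FALSE)) {
    mine <- cmh_test(stack, correction = corr)
    oracle <- cmh_oracle(stack, correction = corr)
    ref <- mantelhaen.test(stack, correct = corr)
    expect_equal(mine$statistic, oracle$statistic, tolerance = 1e-12)
    expect_equal(mine$p_value, oracle$p_value, tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  }

  # random stacks, both corrections
  withr::with_seed(2, {
    for (i in 1:50) {
      st <- array(sample(0:200, 8, replace = TRUE), dim = c(2, 2, 2))
      for (corr in c(TRUE, FALSE)) {
        mine <- cmh_test(st, correction = corr)
        oracle <- cmh_oracle(st, correction = corr)
        expect_equal(mine$statistic, oracle$statistic, tolerance = 1e-10)
        expect_equal(mine$p_value, oracle$p_value, tolerance = 1e-10)
      }
    }
  })
})

test_that("uninformative strata contribute nothing; fully degenerate SNPs get p = 1", {
  informative <- rbind(c(10, 20), c(15, 5))
  zero_row <- rbind(c(0, 0), c(5, 5))
  both <- array(c(zero_row, informative), dim = c(2, 2, 2))
  alone <- array(informative, dim = c(2, 2, 1))
  expect_equal(cmh_test(both)$statistic, cmh_test(alone)$statistic)
  expect_equal(cmh_test(both)$p_value, cmh_test(alone)$p_value)

  # zero column margin and n <= 1 are equally uninformative
  tiny <- array(c(1, 0, 0, 0, 0, 0, 0, 0), dim = c(2, 2, 2))
  res <- cmh_test(tiny)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_true(is.na(res$statistic))

  expect_error(cmh_test(array(c(-1, 2, 3, 4), dim = c(2, 2, 1))),
               "non-negative")
})

test_that("with one stratum the uncorrected CMH is the (n-1)/n-scaled Pearson chi-square", {
  withr::with_seed(4, {
    for (i in 1:20) {
      t2 <- matrix(sample(1:80, 4), 2, 2)
      n <- sum(t2)
      cmh <- cmh_test(array(t2, dim = c(2, 2, 1)), correction = FALSE)
      pearson <- suppressWarnings(chisq.test(t2, correct = FALSE))$statistic
      expect_equal(cmh$statistic, unname(pearson) * (n - 1) / n,
                   tolerance = 1e-12)
    }
  })
})

test_that("the statistic is invariant under pair-direction and allele relabeling", {
  withr::with_seed(6, {
    for (i in 1:20) {
      st <- array(sample(1:100, 8, replace = TRUE), dim = c(2, 2, 2))
      swapped_rows <- st[2:1, , , drop = FALSE]
      swapped_cols <- st[, 2:1, , drop = FALSE]
      base <- cmh_test(st)$statistic
      expect_equal(cmh_test(swapped_rows)$statistic, base, tolerance = 1e-12)
      expect_equal(cmh_test(swapped_cols)$statistic, base, tolerance = 1e-12)
    }
  })
})

test_that("cmh_test on a calls table matches per-SNP stack evaluation", {
  withr::with_seed(12, {
    maj <- matrix(rpois(200, 40), 50, 4)
    mnr <- matrix(rpois(200, 15), 50, 4)
    calls <- calls_from_matrices(maj, mnr)
    res <- cmh_test(calls, pairs = list(c(1L, 3L), c(2L, 4L)))
    expect_equal(nrow(res), 50L)
    for (i in c(1L, 17L, 50L)) {
      stack <- build_stack(calls[calls$pos == i, ],
                           pairs = list(c(1L, 3L), c(2L, 4L)))
      expect_equal(res$statistic[i], cmh_test(stack)$statistic,
                   tolerance = 1e-12)
    }
  })
})

test_that("null CMH p-values approach uniformity as coverage grows", {
  withr::with_seed(9, {
    ks <- vapply(c(60L, 200L, 1000L), function(cov) {
      n <- 5000L
      f <- runif(n, 0.1, 0.9)
      maj <- matrix(rbinom(4L * n, cov, rep(f, each = 4L)), n, 4L, byrow = TRUE)
      calls <- calls_from_matrices(maj, cov - maj)
      res <- cmh_test(calls, correction = FALSE)
      unname(suppressWarnings(ks.test(res$p_value, "punif"))$statistic)
    }, numeric(1))
    # discreteness-driven deviation shrinks with coverage
    expect_true(all(diff(ks) < 0))
    expect_lt(ks[3], 0.03)
  })
})

test_that("bh_adjust reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.4), 0.4)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.1)), "\\[0, 1\\]")

  withr::with_seed(13, {
    p <- runif(1000)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # monotone in p, q >= p, capped at 1
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  })
})

test_that("merge_dual_mappers keeps the intersection with maximal p", {
  a <- tibble::tibble(chrom = c("2L", "2L", "X"), pos = c(1L, 2L, 9L),
                      p_value = c(0.01, 0.5, 0.2))
  b <- tibble::tibble(chrom = c("2L", "X"), pos = c(1L, 9L),
                      p_value = c(0.05, 0.1))
  m <- merge_dual_mappers(a, b)
  expect_equal(nrow(m), 2L)
  expect_equal(m$p_value[m$pos == 1L], 0.05)   # max of 0.01, 0.05
  expect_equal(m$p_value[m$pos == 9L], 0.2)
  # the set never grows and no retained p-value decreases
  expect_true(all(m$p_value >= a$p_value[match(paste(m$chrom, m$pos),
                                               paste(a$chrom, a$pos))]))
  empty <- a[0, ]
  expect_equal(nrow(merge_dual_mappers(empty, empty)), 0L)
})

test_that("count_significant uses a strict q < alpha rule", {
  tbl <- tibble::tibble(q_value = c(1, 1, 1))
  expect_equal(count_significant(tbl)$n_significant, 0L)
  tbl2 <- tibble::tibble(q_value = c(0.005, 0.02))
  expect_equal(count_significant(tbl2, alpha = 0.01)$n_significant, 1L)
  expect_equal(count_significant(tibble::tibble(q_value = 0.01),
                                 alpha = 0.01)$n_significant, 0L)
})
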