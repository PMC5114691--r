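make_sync <- function(counts_by_pop, chrom = "2L", pos = NULL) {
  # counts_by_pop: list of site x 6 matrices (A,T,C,G,N,del), one per pop
  n_sites <- nrow(counts_by_pop[[1]])
  n_pops <- length(counts_by_pop)
  pos <- pos %||% seq_len(n_sites)
  rows <- lapply(seq_len(n_pops), function(p) {
    m <- counts_by_pop[[p]]
    tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = "A",
                   pop = p, A = m[, 1], T = m[, 2], C = m[, 3], G = m[, 4],
                   N = m[, 5], del = m[, 6])
  })
  dplyr::arrange(dplyr::bind_rows(rows), pos, pop)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("a site passing all filters yields a pooled-major/minor call", {
  sync <- make_sync(list(matrix(c(21, 0, 0, 9, 0, 0), 1),
                         matrix(c(25, 0, 0, 5, 0, 0), 1)))
  calls <- call_snps(sync, filter_config())
  expect_equal(nrow(calls), 2L)
  expect_equal(unique(calls$major), "A")
  expect_equal(unique(calls$minor), "G")  # pooled G = 14 >= 8
  expect_equal(calls$major_count, c(21L, 25L))
  expect_equal(calls$minor_count, c(9L, 5L))
})

test_that("the minimum allele count of eight is a pooled, inclusive boundary", {
  # pooled minor sum 7 -> dropped
  s7 <- make_sync(list(matrix(c(26, 0, 0, 4, 0, 0), 1),
                       matrix(c(27, 0, 0, 3, 0, 0), 1)))
  expect_equal(nrow(call_snps(s7, filter_config())), 0L)
  expect_equal(snp_filter_log(call_snps(s7, filter_config()))$n_sites[3], 1L)
  # pooled minor sum exactly 8 -> kept, even though each population is below 8
  s8 <- make_sync(list(matrix(c(26, 0, 0, 4, 0, 0), 1),
                       matrix(c(26, 0, 0, 4, 0, 0), 1)))
  expect_equal(nrow(call_snps(s8, filter_config())), 2L)
})

test_that("the coverage window applies to every population separately", {
  base <- c(40, 0, 0, 10, 0, 0)
  for (bad_cov in c(29, 501)) {
    bad <- c(bad_cov - 10, 0, 0, 10, 0, 0)
    sync <- make_sync(list(matrix(base, 1), matrix(bad, 1)))
    expect_equal(nrow(call_snps(sync, filter_config())), 0L)
  }
  # boundaries 30 and 500 are inclusive
  sync <- make_sync(list(matrix(c(20, 0, 0, 10, 0, 0), 1),
                         matrix(c(490, 0, 0, 10, 0, 0), 1)))
  expect_equal(nrow(call_snps(sync, filter_config())), 2L)
})

test_that("N and deletion counts are carried but never treated as alleles", {
  # A+T+C+G = 29 < 30 even though N/del push the raw depth to 60
  sync <- make_sync(list(matrix(c(20, 0, 0, 9, 30, 1), 1),
                         matrix(c(25, 0, 0, 10, 0, 0), 1)))
  expect_equal(nrow(call_snps(sync, filter_config())), 0L)
  # huge N never becomes major or minor
  sync2 <- make_sync(list(matrix(c(30, 0, 0, 10, 400, 0), 1),
                          matrix(c(30, 0, 0, 10, 0, 0), 1)))
  calls <- call_snps(sync2, filter_config())
  expect_equal(unique(calls$major), "A")
  expect_equal(unique(calls$minor), "G")
})

test_that("chromosome restriction and triallelic exclusion drop sites", {
  sync <- dplyr::bind_rows(
    make_sync(list(matrix(c(30, 0, 0, 10, 0, 0), 1)), chrom = "2L"),
    make_sync(list(matrix(c(30, 0, 0, 10, 0, 0), 1)), chrom = "U"))
  calls <- call_snps(sync, filter_config(chroms = c("X", "2L")))
  expect_equal(unique(calls$chrom), "2L")

  # third allele reaching min_count -> strictly biallelic pipeline drops it
  tri <- make_sync(list(matrix(c(30, 8, 0, 10, 0, 0), 1)))
  out <- call_snps(tri, filter_config())
  expect_equal(nrow(out), 0L)
  expect_equal(snp_filter_log(out)$n_sites[4], 1L)
  # third allele below min_count is tolerated
  tri2 <- make_sync(list(matrix(c(30, 7, 0, 10, 0, 0), 1)))
  expect_equal(nrow(call_snps(tri2, filter_config())), 1L)
})

test_that("major/minor ties break lexicographically A < C < G < T", {
  sync <- make_sync(list(matrix(c(30, 0, 0, 30, 0, 0), 1)))
  calls <- call_snps(sync, filter_config())
  expect_equal(calls$major, "A")
  expect_equal(calls$minor, "G")
  sync2 <- make_sync(list(matrix(c(0, 30, 30, 0, 0, 0), 1)))
  calls2 <- call_snps(sync2, filter_config())
  expect_equal(calls2$major, "C")
  expect_equal(calls2$minor, "T")
})

test_that("calling is independent of row order and filters are order-independent", {
  withr::with_seed(11, {
    sync <- random_sync(300, n_pops = 3L)
    cfg <- filter_config(min_coverage = 20L)
    a <- call_snps(sync, cfg)
    shuffled <- sync[sample.int(nrow(sync)), ]
    b <- call_snps(shuffled, cfg)
    key <- function(x) dplyr::arrange(x, chrom, pos, pop)
    expect_equal(key(a), key(b), ignore_attr = TRUE)

    # every emitted call still satisfies the filters when re-applied
    cov <- a$major_count + a$minor_count
    expect_true(all(tapply(a$minor_count, paste(a$chrom, a$pos), sum) >= 8))
  })
})

test_that("subsample_counts is an exact-total hypergeometric draw", {
  # drawing the whole pool is the identity
  expect_equal(subsample_counts(c(30, 30), 60, seed = 1), c(30L, 30L))
  # undrawable target errors
  expect_error(subsample_counts(c(5, 5), 60), "cannot subsample")
  expect_error(subsample_counts(c(-1, 5), 3), "non-negative")

  # componentwise bounds and exact total, any arity
  withr::with_seed(3, {
    for (i in 1:50) {
      counts <- rpois(6, 30)
      target <- sample.int(max(sum(counts) - 1L, 1L), 1L)
      out <- subsample_counts(counts, target)
      expect_equal(sum(out), target)
      expect_true(all(out <= counts) && all(out >= 0))
    }
  })

  # mean of the first component matches target * K / N within 3 SE
  draws <- withr::with_seed(5, {
    replicate(2e4, subsample_counts(c(100, 100), 60)[1])
  })
  v <- 60 * 0.5 * 0.5 * (200 - 60) / (200 - 1)  # hypergeometric variance
  expect_lt(abs(mean(draws) - 30), 3 * sqrt(v / 2e4))

  # exact distribution on a small case, against dhyper enumeration
  small <- withr::with_seed(8, replicate(2e4, subsample_counts(c(3, 2), 2)[1]))
  obs <- tabulate(small + 1L, nbins = 3L)
  expect_gt(chisq.test(obs, p = dhyper(0:2, 3, 2, 2))$p.value, 1e-3)
})

test_that("subsample_calls hits the target exactly, deterministically, order-free", {
  withr::with_seed(21, {
    maj <- matrix(rpois(400, 60), 100, 4)
    mnr <- matrix(rpois(400, 25), 100, 4)
    calls <- calls_from_matrices(maj, mnr)
    out <- subsample_calls(calls, 30L, seed = 99)
    expect_true(all(out$major_count + out$minor_count == 30L))
    expect_true(all(out$major_count <= calls$major_count))

    # determinism and row-order independence
    out2 <- subsample_calls(calls, 30L, seed = 99)
    expect_identical(out, out2)
    shuffled <- calls[sample.int(nrow(calls)), ]
    out3 <- subsample_calls(shuffled, 30L, seed = 99)
    expect_equal(dplyr::arrange(out3, pos, pop), dplyr::arrange(out, pos, pop),
                 ignore_attr = TRUE)

    # already at target -> identity
    at <- calls_from_matrices(matrix(20L, 5, 2), matrix(10L, 5, 2))
    expect_equal(subsample_calls(at, 30L, seed = 1), at, ignore_attr = TRUE)

    # sites with a population below target are dropped and counted
    low <- calls_from_matrices(rbind(c(10L, 40L), c(40L, 40L)),
                               rbind(c(10L, 10L), c(10L, 10L)))
    kept <- subsample_calls(low, 30L, seed = 1)
    expect_equal(unique(kept$pos), 2L)
    expect_equal(attr(kept, "n_below_target"), 1L)
  })
})

test_that("subsampling preserves expected allele frequency", {
  withr::with_seed(31, {
    n <- 10000L
    maj <- matrix(rbinom(n, 100, 0.7), n, 1)
    mnr <- 100L - maj
    calls <- calls_from_matrices(maj, mnr)
    out <- subsample_calls(calls, 30L, seed = 7)
    f_before <- mean(calls$minor_count / 100)
    f_after <- mean(out$minor_count / 30)
    # hypergeometric draws are unbiased; SE of the mean after-subsampling freq
    se <- sd(out$minor_count / 30) / sqrt(n)
    expect_lt(abs(f_after - f_before), 3 * se)
  })
})

test_that("filter_config validates its bounds", {
  expect_error(filter_config(min_coverage = 0), "min_coverage")
  expect_error(filter_config(min_coverage = 40, max_coverage = 30), "min_coverage")
  expect_error(filter_config(min_count = 0), "min_count")
  expect_error(filter_config(target_coverage = 40), "target_coverage")
  expect_silent(filter_config(target_coverage = 30))
})
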