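#' Build a stratified 2x2xK contingency stack for one SNP
#'
#' Arranges one SNP's per-population major/minor counts into K 2x2 strata,
#' one per (ancestral, evolved) population pair. Stratum k is
#' `rbind(c(major_anc, minor_anc), c(major_evo, minor_evo))` for pair k.
#' In a two-replicate AP/RAP design with population order AP1, AP2, RAP1,
#' RAP2 the pairs are `list(c(1, 3), c(2, 4))`.
#'
#' @param call One SNP's calls: a tibble with columns `pop`, `major_count`,
#'   `minor_count` (one row per population).
#' @param pairs List of length-2 integer vectors `(ancestral, evolved)`
#'   population indices; pairs must be disjoint.
#' @return A 2x2xK integer array (rows: populations; columns: major/minor).
#' @export
build_stack <- function(call, pairs = list(c(1L, 3L), c(2L, 4L))) {
  assert_columns(call, c("pop", "major_count", "minor_count"), "call")
  idx <- unlist(pairs)
  if (anyDuplicated(idx)) stop("pairs must be disjoint", call. = FALSE)
  if (!all(idx %in% call$pop)) {
    stop("pair indices must reference populations present in the call",
         call. = FALSE)
  }
  K <- length(pairs)
  stack <- array(0L, dim = c(2L, 2L, K),
                 dimnames = list(c("ancestral", "evolved"),
                                 c("major", "minor"), NULL))
  for (k in seq_len(K)) {
    a <- call[call$pop == pairs[[k]][1L], , drop = FALSE]
    b <- call[call$pop == pairs[[k]][2L], , drop = FALSE]
    stack[, , k] <- rbind(c(a$major_count, a$minor_count),
                          c(b$major_count, b$minor_count))
  }
  stack
}

# Vectorised CMH over sites: each argument is a site x K matrix of one cell
# of the 2x2 table (a = anc major, b = anc minor, c = evo major, d = evo minor).
# Returns statistic, p, and degeneracy flag per site.
cmh_core <- function(a, b, c, d, correction = TRUE) {
  # double arithmetic: margin products overflow 32-bit integers at high coverage
  storage.mode(a) <- storage.mode(b) <- "double"
  storage.mode(c) <- storage.mode(d) <- "double"
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d
  c1 <- a + c; c2 <- b + d
  informative <- n > 1L & r1 > 0L & r2 > 0L & c1 > 0L & c2 > 0L
  num <- a - r1 * c1 / n
  v <- r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  num[!informative] <- 0
  v[!informative] <- 0
  sum_num <- rowSums(num)
  sum_v <- rowSums(v)
  degenerate <- rowSums(informative) == 0L
  cc <- if (correction) 0.5 else 0
  base <- pmax(abs(sum_num) - cc, 0)
  stat <- ifelse(degenerate, NA_real_, base^2 / sum_v)
  p <- ifelse(degenerate, 1, stats::pchisq(stat, df = 1L, lower.tail = FALSE))
  list(statistic = stat, p_value = p, degenerate = degenerate)
}

#' Cochran-Mantel-Haenszel test per SNP across replicate population pairs
#'
#' For every SNP, tests the null of no consistent allele-frequency
#' difference between ancestral and evolved populations across K replicate
#' pairs (strata), using the 1-df CMH chi-square statistic
#' \deqn{X^2 = \frac{(|\sum_k (a_k - r_{1k} c_{1k}/n_k)| - cc)^2}
#'                  {\sum_k r_{1k} r_{2k} c_{1k} c_{2k} / (n_k^2 (n_k - 1))}}
#' where `a_k` is the top-left cell of stratum k, `r`/`c` its row/column
#' margins, `n_k` its total, and `cc = 1/2` with the continuity correction
#' (the default, matching `stats::mantelhaen.test`) or 0 without (the
#' numerator base is floored at 0). Strata with `n_k <= 1` or a zero margin
#' carry no information and are skipped; a SNP where every stratum is
#' uninformative is flagged `degenerate` and reported with p = 1 so SNP sets
#' stay comparable across analyses.
#'
#' @param x SNP calls ([call_snps()], typically after [subsample_calls()]),
#'   or a single 2x2xK array from [build_stack()].
#' @param pairs List of `(ancestral, evolved)` population index pairs
#'   defining the strata; default `list(c(1,3), c(2,4))` for the
#'   AP1/AP2/RAP1/RAP2 layout.
#' @param correction Apply the continuity correction (default `TRUE`).
#' @return A tibble with one row per SNP: `chrom`, `pos`, `statistic`,
#'   `p_value`, `degenerate`. For an array input, a one-row tibble without
#'   coordinates.
#' @examples
#' stack <- array(c(10, 15, 20, 5, 8, 9, 12, 11), dim = c(2, 2, 2))
#' cmh_test(stack)
#' @export
cmh_test <- function(x, pairs = list(c(1L, 3L), c(2L, 4L)), correction = TRUE) {
  if (is.array(x) && length(dim(x)) == 3L) {
    if (any(x < 0)) stop("table entries must be non-negative", call. = FALSE)
    K <- dim(x)[3L]
    res <- cmh_core(matrix(x[1L, 1L, ], 1L), matrix(x[1L, 2L, ], 1L),
                    matrix(x[2L, 1L, ], 1L), matrix(x[2L, 2L, ], 1L),
                    correction = correction)
    return(tibble::tibble(statistic = res$statistic, p_value = res$p_value,
                          degenerate = res$degenerate))
  }
  assert_columns(x, c("chrom", "pos", "pop", "major_count", "minor_count"), "x")
  idx <- unlist(pairs)
  if (anyDuplicated(idx)) stop("pairs must be disjoint", call. = FALSE)
  if (nrow(x) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          statistic = numeric(), p_value = numeric(),
                          degenerate = logical()))
  }
  n_pops <- length(unique(x$pop))
  if (!all(idx %in% seq_len(n_pops))) {
    stop("pair indices out of range for ", n_pops, " populations", call. = FALSE)
  }
  x <- dplyr::arrange(x, factor(.data$chrom, levels = unique(.data$chrom)),
                      .data$pos, .data$pop)
  n_sites <- nrow(x) / n_pops
  maj <- matrix(x$major_count, nrow = n_sites, ncol = n_pops, byrow = TRUE)
  mnr <- matrix(x$minor_count, nrow = n_sites, ncol = n_pops, byrow = TRUE)
  anc <- vapply(pairs, `[`, integer(1L), 1L)
  evo <- vapply(pairs, `[`, integer(1L), 2L)
  res <- cmh_core(maj[, anc, drop = FALSE], mnr[, anc, drop = FALSE],
                  maj[, evo, drop = FALSE], mnr[, evo, drop = FALSE],
                  correction = correction)
  first <- seq(1L, nrow(x), by = n_pops)
  tibble::tibble(chrom = x$chrom[first], pos = x$pos[first],
                 statistic = res$statistic, p_value = res$p_value,
                 degenerate = res$degenerate)
}

#' Intersect the SNP sets of two mapper-specific analyses
#'
#' Read mapping artifacts can produce spurious allele-frequency differences;
#' running the pipeline on alignments from two different mappers and keeping
#' only SNPs identified by both, each with its *larger* (more conservative)
#' p-value, suppresses them. Only `(chrom, pos)` keys present in both inputs
#' are retained.
#'
#' @param results_a,results_b Per-SNP result tibbles with columns `chrom`,
#'   `pos`, `p_value` (as from [cmh_test()]).
#' @return A tibble with columns `chrom`, `pos`, `p_value` where `p_value`
#'   is the maximum of the two analyses, ordered as in `results_a`.
#' @export
merge_dual_mappers <- function(results_a, results_b) {
  assert_columns(results_a, c("chrom", "pos", "p_value"), "results_a")
  assert_columns(results_b, c("chrom", "pos", "p_value"), "results_b")
  merged <- dplyr::inner_join(
    dplyr::select(results_a, "chrom", "pos", p_a = "p_value"),
    dplyr::select(results_b, "chrom", "pos", p_b = "p_value"),
    by = c("chrom", "pos"))
  tibble::tibble(chrom = merged$chrom, pos = merged$pos,
                 p_value = pmax(merged$p_a, merged$p_b))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with the p-values sorted ascending,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1 and mapped back to the
#' input order (the standard `stats::p.adjust(method = "BH")` computation,
#' with input validation).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return The adjusted q-values, in input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Add BH q-values to a per-SNP result table
#'
#' @param results A tibble with a `p_value` column.
#' @return `results` with a `q_value` column appended (or replaced).
#' @export
adjust_fdr <- function(results) {
  assert_columns(results, "p_value", "results")
  results$q_value <- bh_adjust(results$p_value)
  results
}

#' Count and extract SNPs significant at an FDR threshold
#'
#' @param results A tibble with a `q_value` column ([adjust_fdr()]).
#' @param alpha FDR threshold; significance is strict (`q_value < alpha`).
#' @return A list with elements `n_significant` (integer) and `snps` (the
#'   significant rows of `results`).
#' @export
count_significant <- function(results, alpha = 0.01) {
  assert_columns(results, "q_value", "results")
  snps <- results[results$q_value < alpha, , drop = FALSE]
  list(n_significant = nrow(snps), snps = snps)
}
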