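#' Draw parental allele frequencies from a truncated exponential spectrum
#'
#' Samples independent focal-allele frequencies from an exponential
#' allele-frequency spectrum truncated to `(0, upper_truncation]`, the
#' standard skew of a natural population's site-frequency spectrum where most
#' variants are rare. The default truncation at 0.5 makes the focal allele
#' the minor allele in the parental population. Sampling uses the
#' inverse-CDF transform, so draws are exact and fully determined by `seed`.
#'
#' @param n_snps Number of SNPs to draw.
#' @param rate Exponential rate parameter (larger = rarer alleles). The
#'   default 15 is calibrated so that a 202-line panel reproduces the
#'   characteristic neutral drift magnitude of isofemale-line maintenance
#'   (median |AFC| about 0.0074; see the package vignette).
#' @param upper_truncation Upper bound of the spectrum, in `(0, 1]`.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_snps` frequencies in `(0, upper_truncation]`.
#' @export
sample_parental_freqs <- function(n_snps, rate = 15, upper_truncation = 0.5,
                                  seed = NULL) {
  stopifnot(rate > 0, upper_truncation > 0, upper_truncation <= 1, n_snps >= 1)
  with_seed_if(seed, {
    u <- stats::runif(n_snps)
    -log(1 - u * (1 - exp(-rate * upper_truncation))) / rate
  })
}

#' Found a panel of isofemale lines from parental frequencies
#'
#' Each isofemale line descends from a cross between two individuals of a
#' parental population at Hardy-Weinberg equilibrium, so it carries four
#' founder chromosomes per locus. For each line and SNP, two genotypes are
#' drawn from the trinomial HWE distribution (probabilities `p^2`, `2pq`,
#' `q^2` for 2, 1, 0 copies of the focal allele) and summed, giving the
#' focal-allele copy number `k` in `{0, 1, 2, 3, 4}` among the four founder
#' chromosomes. (The sum of two such draws is Binomial(4, p); the
#' two-trinomial construction mirrors the line-founding process.)
#'
#' @param freqs Parental focal-allele frequencies, one per SNP (in \[0, 1\]).
#' @param n_lines Number of isofemale lines (e.g. 202 or 113).
#' @param seed Optional integer seed.
#' @return An integer matrix of copy numbers, `length(freqs)` rows (SNPs) by
#'   `n_lines` columns.
#' @export
found_lines <- function(freqs, n_lines, seed = NULL) {
  stopifnot(all(freqs >= 0 & freqs <= 1), n_lines >= 1)
  n_snps <- length(freqs)
  with_seed_if(seed, {
    p2 <- freqs^2
    het <- 2 * freqs * (1 - freqs)
    draw_genotype <- function() {
      u <- stats::runif(n_snps * n_lines)
      # per-SNP thresholds recycle down the column layout (SNPs vary fastest)
      2L * (u < p2) + 1L * (u >= p2 & u < p2 + het)
    }
    k <- draw_genotype() + draw_genotype()
    matrix(k, nrow = n_snps, ncol = n_lines)
  })
}

#' Drift alleles within lines to fixation
#'
#' Isofemale lines kept at small census size for tens of generations lose
#' their within-line polymorphism: each initially heterozygous line ends up
#' fixed for one or the other allele. Under neutrality the focal allele
#' fixes with probability equal to its current frequency, i.e. `k/4` for a
#' line carrying `k` copies among its 4 founder chromosomes (0.25, 0.5 or
#' 0.75 for `k` = 1, 2, 3). Lines already fixed (`k` = 0 or 4) are
#' unchanged. Fixation is resolved in a single step; no generation-by-
#' generation trajectory is simulated.
#'
#' @param panel Copy-number matrix from [found_lines()].
#' @param seed Optional integer seed.
#' @return A matrix of the same shape with every entry 0 or 4.
#' @export
simulate_fixation <- function(panel, seed = NULL) {
  stopifnot(all(panel %in% 0:4))
  with_seed_if(seed, {
    u <- stats::runif(length(panel))
    fixed <- ifelse(u < panel / 4, 4L, 0L)
    out <- matrix(as.integer(fixed), nrow = nrow(panel), ncol = ncol(panel))
    out
  })
}

#' Allele-frequency change between a founder panel and its fixed state
#'
#' Computes, per SNP, the panel-wide initial frequency (mean of `k/4` over
#' lines), the final frequency after fixation (fraction of lines fixed for
#' the focal allele), and their signed and absolute difference (AFC). A SNP
#' with no heterozygous line has AFC exactly 0. Purely deterministic.
#'
#' @param initial Founder copy-number matrix ([found_lines()]).
#' @param final Fixed matrix ([simulate_fixation()]); same shape, entries in
#'   `{0, 4}`.
#' @param p_parental Optional parental frequencies to carry through.
#' @return A tibble with one row per SNP: `p_parental` (if given),
#'   `f_initial`, `f_final`, `afc_signed`, `afc_abs`.
#' @export
compute_afc <- function(initial, final, p_parental = NULL) {
  if (!all(dim(initial) == dim(final))) {
    stop("initial and final panels must have the same shape", call. = FALSE)
  }
  if (!all(final %in% c(0L, 4L))) {
    stop("final panel must be fully fixed (entries 0 or 4)", call. = FALSE)
  }
  f_initial <- rowMeans(initial) / 4
  f_final <- rowMeans(final) / 4
  afc <- f_final - f_initial
  out <- tibble::tibble(f_initial = f_initial, f_final = f_final,
                        afc_signed = afc, afc_abs = abs(afc))
  if (!is.null(p_parental)) {
    stopifnot(length(p_parental) == nrow(initial))
    out <- dplyr::bind_cols(tibble::tibble(p_parental = p_parental), out)
  }
  out
}

#' Pool-Seq read sampling of allele frequencies
#'
#' Models pooled sequencing as one round of binomial sampling: for each SNP
#' a coverage `c` is drawn from `coverage` (an empirical distribution,
#' sampled with replacement, or a constant) and the focal-allele read count
#' is Binomial(`c`, `f`). The pool is treated as effectively infinite — read
#' sampling noise, not the finite number of pooled females, dominates.
#'
#' @param freqs True per-SNP frequencies in \[0, 1\].
#' @param coverage A [coverage_distribution()], a constant, or a numeric
#'   multiset of depths.
#' @param seed Optional integer seed.
#' @return A tibble with columns `coverage`, `count`, `f_obs` (= count /
#'   coverage), one row per SNP.
#' @export
poolseq_sample <- function(freqs, coverage, seed = NULL) {
  stopifnot(all(freqs >= 0 & freqs <= 1))
  with_seed_if(seed, {
    cov <- sample_coverage(coverage, length(freqs))
    count <- stats::rbinom(length(freqs), size = cov, prob = freqs)
    tibble::tibble(coverage = cov, count = count, f_obs = count / cov)
  })
}

#' Simulate neutral allele-frequency change in an isofemale-line panel
#'
#' End-to-end neutral simulation: parental frequencies from a truncated
#' exponential spectrum ([sample_parental_freqs()]), panel founding
#' ([found_lines()]), within-line fixation ([simulate_fixation()]), AFC
#' computation ([compute_afc()]) and, optionally, Pool-Seq binomial
#' resampling of both the initial and final frequencies at independently
#' drawn coverages ([poolseq_sample()]). SNPs are independent (no linkage),
#' so the computation is chunked over SNPs to bound memory; results are
#' deterministic given `seed` and `chunk_size`.
#'
#' @param n_snps Number of SNPs to simulate.
#' @param n_lines Number of isofemale lines in the panel (default 202).
#' @param rate,upper_truncation Spectrum parameters
#'   ([sample_parental_freqs()]).
#' @param coverage Optional Pool-Seq coverage source (constant, multiset or
#'   [coverage_distribution()]); when supplied, observed-frequency columns
#'   are added.
#' @param seed Optional integer seed.
#' @param chunk_size SNPs per chunk (memory/speed trade-off).
#' @return A tibble with one row per SNP: `p_parental`, `f_initial`,
#'   `f_final`, `afc_signed`, `afc_abs`, and with `coverage` also
#'   `f_initial_obs`, `f_final_obs`, `afc_obs`, `afc_obs_abs`.
#' @examples
#' sim <- simulate_drift(1000, n_lines = 202, seed = 1)
#' median(sim$afc_abs)
#' @export
simulate_drift <- function(n_snps, n_lines = 202L, rate = 15,
                           upper_truncation = 0.5, coverage = NULL,
                           seed = NULL, chunk_size = 50000L) {
  stopifnot(n_snps >= 1, n_lines >= 1)
  run <- function() {
    starts <- seq(1L, n_snps, by = chunk_size)
    pieces <- vector("list", length(starts))
    for (i in seq_along(starts)) {
      m <- min(chunk_size, n_snps - starts[i] + 1L)
      p <- sample_parental_freqs(m, rate = rate,
                                 upper_truncation = upper_truncation)
      panel0 <- found_lines(p, n_lines)
      panel1 <- simulate_fixation(panel0)
      afc <- compute_afc(panel0, panel1, p_parental = p)
      if (!is.null(coverage)) {
        obs0 <- poolseq_sample(afc$f_initial, coverage)
        obs1 <- poolseq_sample(afc$f_final, coverage)
        afc$f_initial_obs <- obs0$f_obs
        afc$f_final_obs <- obs1$f_obs
        afc$afc_obs <- obs1$f_obs - obs0$f_obs
        afc$afc_obs_abs <- abs(afc$afc_obs)
      }
      pieces[[i]] <- afc
    }
    dplyr::bind_rows(pieces)
  }
  with_seed_if(seed, run())
}

#' Summary statistics of allele-frequency change
#'
#' Median, mean and upper quantiles of the absolute AFC columns of a
#' simulation table — drift-only (`afc_abs`) and, when present, Pool-Seq-
#' observed (`afc_obs_abs`) — for comparing the drift and sequencing-noise
#' contributions to apparent frequency change.
#'
#' @param afc An AFC tibble from [simulate_drift()] or [compute_afc()].
#' @param columns Which absolute-AFC columns to summarize; defaults to all
#'   present among `afc_abs`, `afc_obs_abs`.
#' @return A tibble with one row per column: `source`, `n`, `mean`,
#'   `median`, `q75`, `q95`, `q99`, `max`.
#' @export
summarize_afc <- function(afc, columns = intersect(c("afc_abs", "afc_obs_abs"),
                                                   names(afc))) {
  if (nrow(afc) == 0L) stop("empty AFC table", call. = FALSE)
  if (length(columns) == 0L) stop("no AFC columns to summarize", call. = FALSE)
  purrr::map_dfr(columns, function(col) {
    x <- afc[[col]]
    q <- stats::quantile(x, c(0.75, 0.95, 0.99), names = FALSE)
    tibble::tibble(source = col, n = length(x), mean = mean(x),
                   median = stats::median(x), q75 = q[1L], q95 = q[2L],
                   q99 = q[3L], max = max(x))
  })
}

#' Paired quantiles of two AFC distributions for QQ comparison
#'
#' @param x,y Numeric vectors (e.g. drift-only and observed |AFC|, or a
#'   simulated and an empirical AFC set; lengths may differ).
#' @param n_quantiles Number of evenly spaced probability points.
#' @return A tibble with columns `prob`, `qx`, `qy` suitable for a QQ plot.
#' @export
qq_afc <- function(x, y, n_quantiles = 1000L) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  prob <- (seq_len(n_quantiles) - 0.5) / n_quantiles
  tibble::tibble(prob = prob,
                 qx = stats::quantile(x, prob, names = FALSE),
                 qy = stats::quantile(y, prob, names = FALSE))
}
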