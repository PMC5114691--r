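#' Configuration for a synthetic AP/RAP Pool-Seq experiment
#'
#' Describes a four-population experiment — two ancestral pools (AP1, AP2)
#' created from freshly founded isofemale lines and two reconstituted
#' ancestral pools (RAP1, RAP2) assembled from the same lines after
#' within-line fixation — to be generated by [generate_experiment()] under
#' the neutral model, optionally with a spiked selection signal for power
#' checks.
#'
#' @param n_snps Number of SNPs.
#' @param n_lines Number of isofemale lines (default 202).
#' @param rate,upper_truncation Parental spectrum parameters
#'   ([sample_parental_freqs()]).
#' @param coverage Per-population coverage sources in the order AP1, AP2,
#'   RAP1, RAP2: a length-4 numeric vector of constant coverages, or a list
#'   of 4 elements each acceptable to [sample_coverage()] (constants,
#'   multisets or [coverage_distribution()] objects). The default
#'   `c(150, 170, 40, 70)` mirrors typical high-coverage AP / lower-coverage
#'   RAP sequencing runs.
#' @param error_rate Per-read probability `e` of being mis-read as a
#'   uniformly chosen other base; must satisfy `0 <= e < 0.01`.
#' @param spike_fraction,spike_delta Fraction of SNPs whose RAP truth is
#'   shifted by `spike_delta` (clamped to \[0, 1\]) before sequencing —
#'   a synthetic selection signal; both default to 0 (pure null).
#' @param seed Master seed; all randomness in [generate_experiment()]
#'   derives from it.
#' @param chrom_lengths Named integer vector giving the synthetic chromosome
#'   layout; defaults to the six major Drosophila arms with realistic
#'   lengths.
#' @return An `experiment_config` object (validated list).
#' @export
experiment_config <- function(n_snps, n_lines = 202L, rate = 15,
                              upper_truncation = 0.5,
                              coverage = c(150L, 170L, 40L, 70L),
                              error_rate = 0, spike_fraction = 0,
                              spike_delta = 0, seed = NULL,
                              chrom_lengths = c(X = 23000000L, `2L` = 23500000L,
                                                `2R` = 25000000L, `3L` = 28000000L,
                                                `3R` = 32000000L, `4` = 1350000L)) {
  stopifnot(n_snps >= 1, n_lines >= 1, rate > 0,
            upper_truncation > 0, upper_truncation <= 1)
  if (!(is.list(coverage) && length(coverage) == 4L) &&
      !(is.numeric(coverage) && length(coverage) == 4L)) {
    stop("coverage must specify 4 populations (AP1, AP2, RAP1, RAP2)",
         call. = FALSE)
  }
  if (!is.list(coverage)) coverage <- as.list(coverage)
  if (!isTRUE(error_rate >= 0 && error_rate < 0.01)) {
    stop("error_rate must satisfy 0 <= error_rate < 0.01", call. = FALSE)
  }
  if (!isTRUE(spike_fraction >= 0 && spike_fraction <= 1)) {
    stop("spike_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!isTRUE(abs(spike_delta) <= 1)) {
    stop("spike_delta must lie in [-1, 1]", call. = FALSE)
  }
  if (is.null(names(chrom_lengths)) || any(chrom_lengths < 1)) {
    stop("chrom_lengths must be a named vector of positive lengths",
         call. = FALSE)
  }
  structure(list(n_snps = as.integer(n_snps), n_lines = as.integer(n_lines),
                 rate = rate, upper_truncation = upper_truncation,
                 coverage = coverage, error_rate = error_rate,
                 spike_fraction = spike_fraction, spike_delta = spike_delta,
                 seed = seed, chrom_lengths = chrom_lengths),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> %d SNPs, %d lines, spectrum Exp(%g) trunc %g, error rate %g%s\n",
    x$n_snps, x$n_lines, x$rate, x$upper_truncation, x$error_rate,
    if (x$spike_fraction > 0)
      sprintf(", spike %g%% by %+g", 100 * x$spike_fraction, x$spike_delta)
    else ""))
  invisible(x)
}

#' Spike a selection signal into a truth table
#'
#' Shifts `f_final` by `delta` (clamped to \[0, 1\]) for a seeded random
#' subset of `round(fraction * n)` SNPs and flags them, enabling power
#' analyses of the differentiation pipeline on otherwise-neutral data.
#'
#' @param truth A truth tibble with an `f_final` column
#'   ([generate_experiment()]).
#' @param fraction Fraction of SNPs to spike, in \[0, 1\].
#' @param delta Frequency shift in \[-1, 1\].
#' @param seed Optional integer seed.
#' @return The truth tibble with `f_final` shifted and `selected` set for
#'   the spiked rows.
#' @export
spike_selection <- function(truth, fraction, delta, seed = NULL) {
  assert_columns(truth, "f_final", "truth")
  stopifnot(fraction >= 0, fraction <= 1, abs(delta) <= 1)
  n <- nrow(truth)
  if (!("selected" %in% names(truth))) truth$selected <- FALSE
  n_spike <- round(fraction * n)
  if (n_spike == 0L) return(truth)
  idx <- with_seed_if(seed, sample.int(n, n_spike))
  truth$f_final[idx] <- pmin(pmax(truth$f_final[idx] + delta, 0), 1)
  truth$selected[idx] <- TRUE
  truth
}

# Distribute n_snps across chromosomes proportionally to length (largest
# remainders), then draw sorted distinct positions per chromosome.
synth_coordinates <- function(n_snps, chrom_lengths) {
  chrom_lengths <- as.numeric(chrom_lengths) |> stats::setNames(names(chrom_lengths))
  share <- n_snps * chrom_lengths / sum(chrom_lengths)
  n_per <- floor(share)
  rem <- n_snps - sum(n_per)
  if (rem > 0L) {
    top <- order(share - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[top] <- n_per[top] + 1L
  }
  if (any(n_per > chrom_lengths)) {
    stop("more SNPs than positions on a chromosome", call. = FALSE)
  }
  chrom <- rep(names(chrom_lengths), n_per)
  pos <- unlist(lapply(seq_along(chrom_lengths), function(i) {
    if (n_per[i] == 0L) return(integer(0))
    sort(sample.int(chrom_lengths[i], n_per[i]))
  }), use.names = FALSE)
  tibble::tibble(chrom = chrom, pos = as.integer(pos))
}

# Scatter sequencing errors: reads leave their true base with prob e and land
# uniformly on one of the 3 other bases. counts: site-level vector for one
# base; returns list(kept, to_other = matrix with 3 columns).
scatter_errors <- function(counts, error_rate) {
  err <- stats::rbinom(length(counts), counts, error_rate)
  e1 <- stats::rbinom(length(counts), err, 1 / 3)
  e2 <- stats::rbinom(length(counts), err - e1, 1 / 2)
  e3 <- err - e1 - e2
  list(kept = counts - err, to_other = cbind(e1, e2, e3))
}

#' Generate a synthetic four-population AP/RAP Pool-Seq experiment
#'
#' Simulates the full study design under the neutral model: one panel of
#' isofemale lines per SNP drives all four populations. AP1 and AP2 are
#' replicate pools of the same founder lines, so they share the true initial
#' frequency `f_initial`; RAP1 and RAP2 are both assembled from the same
#' lines after one fixation realization, so they share `f_final`. Only the
#' sequencing step — a coverage draw and binomial read sampling, plus
#' optional uniform base mis-reads at `error_rate` — is independent across
#' populations. Reference and alternate bases are assigned per SNP and
#' positions are laid out on a synthetic chromosome scaffold, strictly
#' increasing within each chromosome.
#'
#' @param cfg An [experiment_config()].
#' @return A list of class `rap_experiment` with elements
#'   \describe{
#'     \item{sync}{A four-population sync tibble (population order AP1, AP2,
#'       RAP1, RAP2 = pop 1..4), writable with [write_sync()].}
#'     \item{truth}{Per-SNP truth: `chrom`, `pos`, `ref`, `alt`,
#'       `p_parental`, `f_initial`, `f_final`, `selected`.}
#'     \item{config}{The configuration used.}
#'   }
#' @examples
#' exp <- generate_experiment(experiment_config(n_snps = 100, seed = 1))
#' head(exp$truth)
#' @export
generate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  with_seed_if(cfg$seed, {
    n <- cfg$n_snps
    coords <- synth_coordinates(n, cfg$chrom_lengths)
    p <- sample_parental_freqs(n, rate = cfg$rate,
                               upper_truncation = cfg$upper_truncation)
    # founder panel and fixation, chunked over SNPs to bound memory
    chunk <- 50000L
    f_initial <- f_final <- numeric(n)
    for (s in seq(1L, n, by = chunk)) {
      e <- min(s + chunk - 1L, n)
      panel0 <- found_lines(p[s:e], cfg$n_lines)
      panel1 <- simulate_fixation(panel0)
      f_initial[s:e] <- rowMeans(panel0) / 4
      f_final[s:e] <- rowMeans(panel1) / 4
    }
    ref_idx <- sample.int(4L, n, replace = TRUE)
    alt_idx <- ((ref_idx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
    truth <- tibble::tibble(chrom = coords$chrom, pos = coords$pos,
                            ref = BASES[ref_idx], alt = BASES[alt_idx],
                            p_parental = p, f_initial = f_initial,
                            f_final = f_final, selected = FALSE)
    if (cfg$spike_fraction > 0) {
      truth <- spike_selection(truth, cfg$spike_fraction, cfg$spike_delta)
    }
    pop_truth <- list(truth$f_initial, truth$f_initial,
                      truth$f_final, truth$f_final)
    sync_rows <- vector("list", 4L)
    for (pop in 1:4) {
      cov <- sample_coverage(cfg$coverage[[pop]], n)
      alt_reads <- stats::rbinom(n, cov, pop_truth[[pop]])
      ref_reads <- cov - alt_reads
      counts <- matrix(0L, n, 4L)  # columns A, T, C, G
      if (cfg$error_rate > 0) {
        sr <- scatter_errors(ref_reads, cfg$error_rate)
        sa <- scatter_errors(alt_reads, cfg$error_rate)
        counts[cbind(seq_len(n), match(truth$ref, BASES))] <- sr$kept
        counts[cbind(seq_len(n), match(truth$alt, BASES))] <-
          counts[cbind(seq_len(n), match(truth$alt, BASES))] + sa$kept
        # errors land uniformly on the three non-source bases
        for (b in 1:4) {
          from_ref <- truth$ref == BASES[b]
          from_alt <- truth$alt == BASES[b]
          others <- setdiff(1:4, b)
          for (j in 1:3) {
            counts[from_ref, others[j]] <-
              counts[from_ref, others[j]] + sr$to_other[from_ref, j]
            counts[from_alt, others[j]] <-
              counts[from_alt, others[j]] + sa$to_other[from_alt, j]
          }
        }
      } else {
        counts[cbind(seq_len(n), match(truth$ref, BASES))] <- ref_reads
        counts[cbind(seq_len(n), match(truth$alt, BASES))] <-
          counts[cbind(seq_len(n), match(truth$alt, BASES))] + alt_reads
      }
      sync_rows[[pop]] <- tibble::tibble(
        chrom = truth$chrom, pos = truth$pos, ref = truth$ref, pop = pop,
        A = counts[, 1L], T = counts[, 2L], C = counts[, 3L], G = counts[, 4L],
        N = 0L, del = 0L)
    }
    sync <- dplyr::bind_rows(sync_rows)
    sync <- dplyr::arrange(sync,
                           factor(.data$chrom, levels = names(cfg$chrom_lengths)),
                           .data$pos, .data$pop)
    structure(list(sync = sync, truth = truth, config = cfg),
              class = "rap_experiment")
  })
}

#' @export
print.rap_experiment <- function(x, ...) {
  cat(sprintf(
    "<rap_experiment> %d SNPs x 4 populations (AP1, AP2, RAP1, RAP2), %d lines%s\n",
    nrow(x$truth), x$config$n_lines,
    if (any(x$truth$selected))
      sprintf(", %d spiked", sum(x$truth$selected)) else ""))
  invisible(x)
}
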