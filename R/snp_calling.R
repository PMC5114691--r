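#' Site-filter configuration for SNP calling
#'
#' Bundles the coverage, allele-count and chromosome filters applied when
#' calling biallelic SNPs from pooled allele counts, together with the target
#' coverage for downsampling. Defaults follow common Pool-Seq practice for
#' Drosophila panels: per-population coverage between 30 and 500x, a minimum
#' minor-allele count of 8 summed across populations (guarding against
#' sequencing errors), and restriction to the major chromosome arms when
#' `chroms` is set.
#'
#' @param min_coverage,max_coverage Per-population bounds on the A+T+C+G
#'   coverage (inclusive).
#' @param min_count Minimum minor-allele count summed across all populations.
#' @param target_coverage Optional coverage to which counts are subsampled
#'   without replacement ([subsample_calls()]); must not exceed
#'   `min_coverage` so every retained site can be subsampled. Typical values
#'   are 60x (D. melanogaster) or 30x (D. simulans), matching the
#'   lowest-coverage population of a study.
#' @param chroms Optional character vector of chromosome names to keep
#'   (e.g. `c("X","2L","2R","3L","3R","4")`); `NULL` keeps all.
#' @return A `filter_config` object (a validated list).
#' @export
filter_config <- function(min_coverage = 30L, max_coverage = 500L,
                          min_count = 8L, target_coverage = NULL,
                          chroms = NULL) {
  min_coverage <- as.integer(min_coverage)
  max_coverage <- as.integer(max_coverage)
  min_count <- as.integer(min_count)
  if (!isTRUE(min_coverage > 0L) || !isTRUE(min_coverage <= max_coverage)) {
    stop("must have 0 < min_coverage <= max_coverage", call. = FALSE)
  }
  if (!isTRUE(min_count >= 1L)) stop("min_count must be >= 1", call. = FALSE)
  if (!is.null(target_coverage)) {
    target_coverage <- as.integer(target_coverage)
    if (!isTRUE(target_coverage >= 1L) || target_coverage > min_coverage) {
      stop("target_coverage must be a positive integer <= min_coverage",
           call. = FALSE)
    }
  }
  structure(list(min_coverage = min_coverage, max_coverage = max_coverage,
                 min_count = min_count, target_coverage = target_coverage,
                 chroms = chroms),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf(
    "<filter_config> coverage %d-%dx per population, min minor count %d%s%s\n",
    x$min_coverage, x$max_coverage, x$min_count,
    if (is.null(x$target_coverage)) "" else
      sprintf(", subsample to %dx", x$target_coverage),
    if (is.null(x$chroms)) "" else
      sprintf(", chroms {%s}", paste(x$chroms, collapse = ","))))
  invisible(x)
}

#' Call biallelic SNPs from a multi-population sync table
#'
#' Applies the site filters of `config` and reduces each passing site to a
#' biallelic major/minor call. A site is emitted iff
#' (a) its chromosome is in `config$chroms` (when set);
#' (b) every population's A+T+C+G coverage lies in
#'     `[min_coverage, max_coverage]` (N and deletion counts are not alleles
#'     and never count toward coverage);
#' (c) pooling A,T,C,G counts across all populations, the second most
#'     frequent allele (the minor allele) reaches `min_count`; and
#' (d) no third allele also reaches `min_count` (such near-triallelic sites
#'     are dropped and logged, keeping the pipeline strictly biallelic).
#' Major and minor alleles are identified from counts pooled across all
#' populations; ties break lexicographically (A < C < G < T), so calls are
#' deterministic and replicate-symmetric.
#'
#' @param sync A sync tibble ([read_sync()] or [generate_experiment()]).
#' @param config A [filter_config()].
#' @param verbose Emit a one-line summary of sites dropped per filter.
#' @return A tibble of SNP calls, long over populations, with columns
#'   `chrom`, `pos`, `major`, `minor`, `pop`, `major_count`, `minor_count`.
#'   The attribute `"filter_log"` holds a tibble of sites dropped per rule.
#' @seealso [subsample_calls()], [cmh_test()], [snp_filter_log()]
#' @export
call_snps <- function(sync, config = filter_config(), verbose = FALSE) {
  stopifnot(inherits(config, "filter_config"))
  n_pops <- validate_sync(sync)
  if (nrow(sync) == 0L) return(empty_calls())
  sync <- dplyr::arrange(sync, factor(.data$chrom, levels = unique(.data$chrom)),
                         .data$pos, .data$pop)
  n_sites <- nrow(sync) / n_pops
  # site x pop matrices for each base (rows = sites)
  base_mats <- lapply(c("A", "C", "G", "T"), function(b) {
    matrix(sync[[b]], nrow = n_sites, ncol = n_pops, byrow = TRUE)
  })
  names(base_mats) <- c("A", "C", "G", "T")
  cov_mat <- base_mats$A + base_mats$C + base_mats$G + base_mats$T
  site_chrom <- sync$chrom[seq(1L, nrow(sync), by = n_pops)]
  site_pos <- sync$pos[seq(1L, nrow(sync), by = n_pops)]

  pooled <- vapply(base_mats, rowSums, numeric(n_sites))
  if (n_sites == 1L) pooled <- matrix(pooled, nrow = 1L,
                                      dimnames = list(NULL, names(base_mats)))
  # ranked alleles; max.col with ties.method = "first" on A,C,G,T columns
  # implements the lexicographic tie-break
  first <- max.col(pooled, ties.method = "first")
  tmp <- pooled
  tmp[cbind(seq_len(n_sites), first)] <- -1
  second <- max.col(tmp, ties.method = "first")
  tmp[cbind(seq_len(n_sites), second)] <- -1
  third <- max.col(tmp, ties.method = "first")

  minor_sum <- pooled[cbind(seq_len(n_sites), second)]
  third_sum <- pooled[cbind(seq_len(n_sites), third)]

  pass_chrom <- if (is.null(config$chroms)) rep(TRUE, n_sites) else
    site_chrom %in% config$chroms
  pass_cov <- rowSums(cov_mat >= config$min_coverage &
                      cov_mat <= config$max_coverage) == n_pops
  pass_count <- minor_sum >= config$min_count
  pass_biallelic <- third_sum < config$min_count

  # sequential logging: each site is attributed to the first rule it fails
  drop_chrom <- !pass_chrom
  drop_cov <- pass_chrom & !pass_cov
  drop_count <- pass_chrom & pass_cov & !pass_count
  drop_tri <- pass_chrom & pass_cov & pass_count & !pass_biallelic
  keep <- pass_chrom & pass_cov & pass_count & pass_biallelic

  log <- tibble::tibble(
    rule = c("chromosome", "coverage", "min_count", "triallelic", "retained"),
    n_sites = c(sum(drop_chrom), sum(drop_cov), sum(drop_count),
                sum(drop_tri), sum(keep)))
  if (verbose) {
    message(sprintf(
      "call_snps: %d sites in; dropped %d (chromosome), %d (coverage), %d (min_count), %d (triallelic); %d SNPs out",
      n_sites, log$n_sites[1], log$n_sites[2], log$n_sites[3], log$n_sites[4],
      log$n_sites[5]))
  }

  idx <- which(keep)
  if (length(idx) == 0L) {
    out <- empty_calls()
    attr(out, "filter_log") <- log
    return(out)
  }
  base_names <- names(base_mats)
  major_base <- base_names[first[idx]]
  minor_base <- base_names[second[idx]]
  # per-population counts of the called alleles
  all_counts <- array(unlist(base_mats, use.names = FALSE),
                      dim = c(n_sites, n_pops, 4L))
  major_counts <- minor_counts <- matrix(0L, length(idx), n_pops)
  for (p in seq_len(n_pops)) {
    major_counts[, p] <- all_counts[cbind(idx, p, first[idx])]
    minor_counts[, p] <- all_counts[cbind(idx, p, second[idx])]
  }
  out <- tibble::tibble(
    chrom = rep(site_chrom[idx], each = n_pops),
    pos   = rep(site_pos[idx], each = n_pops),
    major = rep(major_base, each = n_pops),
    minor = rep(minor_base, each = n_pops),
    pop   = rep.int(seq_len(n_pops), length(idx)),
    major_count = as.integer(t(major_counts)),
    minor_count = as.integer(t(minor_counts)))
  attr(out, "filter_log") <- log
  out
}

empty_calls <- function() {
  tibble::tibble(chrom = character(), pos = integer(), major = character(),
                 minor = character(), pop = integer(),
                 major_count = integer(), minor_count = integer())
}

#' Retrieve the per-rule filter log of a SNP call set
#'
#' @param calls A tibble returned by [call_snps()].
#' @return A tibble with columns `rule` and `n_sites`.
#' @export
snp_filter_log <- function(calls) {
  attr(calls, "filter_log") %||%
    tibble::tibble(rule = character(), n_sites = integer())
}

#' Subsample one count vector without replacement
#'
#' Draws `target` reads without replacement from a pool whose composition is
#' given by `counts` (a multivariate hypergeometric draw). Works for any
#' count vector: a `(major, minor)` pair or a full `A,T,C,G,N,del` 6-tuple.
#'
#' @param counts Non-negative integer vector; `sum(counts)` must be at least
#'   `target`.
#' @param target Positive integer total after subsampling.
#' @param seed Optional integer seed; the draw is deterministic given a seed.
#' @return An integer vector of the same length (and names) as `counts`,
#'   summing exactly to `target`, with every component at most its input
#'   value.
#' @examples
#' subsample_counts(c(major = 100, minor = 100), 60, seed = 1)
#' @export
subsample_counts <- function(counts, target, seed = NULL) {
  counts <- as.integer(counts)
  target <- as.integer(target)
  if (any(counts < 0L)) stop("counts must be non-negative", call. = FALSE)
  if (!isTRUE(target >= 1L)) stop("target must be a positive integer", call. = FALSE)
  total <- sum(counts)
  if (total < target) {
    stop(sprintf("cannot subsample %d reads from a pool of %d", target, total),
         call. = FALSE)
  }
  with_seed_if(seed, {
    out <- integer(length(counts))
    remaining_pool <- total
    remaining_draw <- target
    for (i in seq_along(counts)) {
      if (remaining_draw == 0L) break
      other <- remaining_pool - counts[i]
      out[i] <- stats::rhyper(1L, m = counts[i], n = other, k = remaining_draw)
      remaining_draw <- remaining_draw - out[i]
      remaining_pool <- other
    }
    names(out) <- names(counts)
    out
  })
}

#' Subsample every population of every SNP call to a target coverage
#'
#' Applies an independent without-replacement (hypergeometric) draw to the
#' `(major_count, minor_count)` pair of each population at each site, so that
#' every population's major+minor total equals `target_coverage` exactly.
#' This equalizes the information content across populations before
#' association testing, at the cost of discarding reads above the target.
#'
#' Draws are made in a canonical site order (`chrom`, `pos`, `pop`) from a
#' single stream seeded by `seed`, so results are reproducible and
#' independent of the row order of `calls`; the input row order is restored
#' on return.
#'
#' @param calls SNP calls from [call_snps()].
#' @param config A [filter_config()] with `target_coverage` set, or a single
#'   positive integer target.
#' @param seed Optional integer seed.
#' @return The calls tibble with counts replaced by the subsampled counts.
#'   Sites where some population's major+minor total falls below the target
#'   (possible when a third allele absorbed part of the coverage) are dropped;
#'   their number is stored in the `"n_below_target"` attribute.
#' @export
subsample_calls <- function(calls, config, seed = NULL) {
  target <- if (inherits(config, "filter_config")) {
    if (is.null(config$target_coverage)) {
      stop("config$target_coverage is not set", call. = FALSE)
    }
    config$target_coverage
  } else {
    as.integer(config)
  }
  if (!isTRUE(target >= 1L)) stop("target must be a positive integer", call. = FALSE)
  assert_columns(calls, c("chrom", "pos", "pop", "major_count", "minor_count"),
                 "calls")
  if (nrow(calls) == 0L) return(calls)
  ord <- order(calls$chrom, calls$pos, calls$pop)
  sorted <- calls[ord, , drop = FALSE]
  tot <- sorted$major_count + sorted$minor_count
  site_key <- paste(sorted$chrom, sorted$pos)
  bad_sites <- unique(site_key[tot < target])
  drop <- site_key %in% bad_sites
  kept <- sorted[!drop, , drop = FALSE]
  tot <- tot[!drop]
  new_major <- with_seed_if(seed, {
    as.integer(stats::rhyper(nrow(kept), m = kept$major_count,
                             n = kept$minor_count, k = target))
  })
  kept$major_count <- new_major
  kept$minor_count <- as.integer(target) - new_major
  # restore input row order among retained rows
  orig_idx <- ord[!drop]
  out <- kept[order(orig_idx), , drop = FALSE]
  attr(out, "filter_log") <- attr(calls, "filter_log")
  attr(out, "n_below_target") <- length(bad_sites)
  out
}
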