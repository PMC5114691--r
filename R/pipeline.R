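#' Run the AP-vs-RAP differentiation pipeline end to end
#'
#' Composes the full analysis on one (or, for dual-mapper emulation, two)
#' multi-population sync inputs: optional masking ([apply_mask()]), SNP
#' calling under the site filters ([call_snps()]), without-replacement
#' subsampling to the target coverage ([subsample_calls()]), per-SNP CMH
#' tests across the replicate AP/RAP pairs ([cmh_test()]), optional
#' intersection of the two mapper-specific analyses keeping each SNP's
#' maximal p-value ([merge_dual_mappers()]), Benjamini-Hochberg adjustment
#' ([adjust_fdr()]) and significance counting ([count_significant()]).
#' The run is fully deterministic given `seed`; stage-wise record counts are
#' collected in a manifest.
#'
#' @param sync A sync tibble or path to a sync file (population order AP1,
#'   AP2, RAP1, RAP2 unless `pairs` says otherwise).
#' @param sync_b Optional second sync input (e.g. from a second mapper); when
#'   given, both are analysed identically and intersected.
#' @param mask Optional mask tibble or BED path ([read_bed()]).
#' @param filter A [filter_config()]; `target_coverage` must be set.
#' @param pairs Stratum definition passed to [cmh_test()].
#' @param correction Continuity correction for the CMH statistic.
#' @param alpha FDR significance threshold (strict `q < alpha`).
#' @param min_maf Optional pooled minor-allele-frequency floor applied before
#'   FDR adjustment ([maf_filter()]).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Optional directory: writes `results.tsv` (chrom, pos,
#'   p_value, q_value and, for single-input runs, statistic),
#'   `manhattan.tsv` (chrom, pos, neglog10_p) and `manifest.yaml`.
#' @return An object of class `rap_pipeline`: list with `results` (per-SNP
#'   tibble incl. `q_value`), `significant`, `n_significant`, `manifest`
#'   (stage/count tibble), `calls` (post-subsampling calls of the first
#'   input) and the run parameters. [generics::tidy()] returns the result
#'   table, [generics::glance()] a one-row run summary, and
#'   [ggplot2::autoplot()] a Manhattan plot.
#' @examples
#' exp <- generate_experiment(experiment_config(n_snps = 500, seed = 7))
#' fit <- run_pipeline(exp$sync,
#'                     filter = filter_config(target_coverage = 30),
#'                     seed = 7)
#' glance(fit)
#' @export
run_pipeline <- function(sync, sync_b = NULL, mask = NULL,
                         filter = filter_config(target_coverage = 30L),
                         pairs = list(c(1L, 3L), c(2L, 4L)),
                         correction = TRUE, alpha = 0.01, min_maf = NULL,
                         seed = NULL, out_dir = NULL) {
  stopifnot(inherits(filter, "filter_config"))
  if (is.null(filter$target_coverage)) {
    stop("pipeline requires filter$target_coverage (subsampling step)",
         call. = FALSE)
  }
  if (!is.null(min_maf) && !(min_maf >= 0 && min_maf <= 0.5)) {
    stop("min_maf must lie in [0, 0.5]", call. = FALSE)
  }
  if (is.character(sync)) sync <- read_sync(sync)
  if (is.character(sync_b)) sync_b <- read_sync(sync_b)
  if (is.character(mask)) mask <- read_bed(mask)

  manifest <- list()
  note_stage <- function(stage, n_in, n_out, input = "a") {
    manifest[[length(manifest) + 1L]] <<-
      tibble::tibble(input = input, stage = stage,
                     n_in = as.integer(n_in), n_out = as.integer(n_out))
  }

  analyse_one <- function(sync_x, sub_seed, label) {
    n_pops <- validate_sync(sync_x)
    n_sites <- nrow(sync_x) / max(n_pops, 1L)
    if (!is.null(mask)) {
      sync_x <- apply_mask(sync_x, mask)
      note_stage("mask", n_sites, nrow(sync_x) / max(n_pops, 1L), label)
      n_sites <- nrow(sync_x) / max(n_pops, 1L)
    }
    calls <- call_snps(sync_x, filter)
    n_called <- nrow(calls) / max(n_pops, 1L)
    note_stage("call_snps", n_sites, n_called, label)
    calls <- subsample_calls(calls, filter, seed = sub_seed)
    n_sub <- nrow(calls) / max(n_pops, 1L)
    note_stage("subsample", n_called, n_sub, label)
    res <- cmh_test(calls, pairs = pairs, correction = correction)
    note_stage("cmh_test", n_sub, nrow(res), label)
    list(results = res, calls = calls)
  }

  a <- analyse_one(sync, derive_seed(seed, 1L), "a")
  if (!is.null(sync_b)) {
    b <- analyse_one(sync_b, derive_seed(seed, 2L), "b")
    results <- merge_dual_mappers(a$results, b$results)
    note_stage("merge_dual_mappers",
               max(nrow(a$results), nrow(b$results)), nrow(results), "a+b")
  } else {
    results <- a$results
  }
  if (!is.null(min_maf) && min_maf > 0) {
    n_before <- nrow(results)
    results <- maf_filter(results, a$calls, min_maf, adjust = FALSE)
    note_stage("maf_filter", n_before, nrow(results), "a")
  }
  results <- adjust_fdr(results)
  sig <- count_significant(results, alpha)
  note_stage("count_significant", nrow(results), sig$n_significant, "a")

  out <- structure(list(
    results = results, significant = sig$snps,
    n_significant = sig$n_significant,
    manifest = dplyr::bind_rows(manifest),
    calls = a$calls, filter = filter, pairs = pairs,
    correction = correction, alpha = alpha, min_maf = min_maf,
    seed = seed), class = "rap_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(fit, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(fit$results, file.path(out_dir, "results.tsv"))
  manhattan <- dplyr::mutate(
    dplyr::select(fit$results, "chrom", "pos"),
    neglog10_p = -log10(pmax(fit$results$p_value, .Machine$double.xmin)))
  readr::write_tsv(manhattan, file.path(out_dir, "manhattan.tsv"))
  yaml::write_yaml(
    list(alpha = fit$alpha, seed = fit$seed,
         correction = fit$correction,
         min_maf = fit$min_maf,
         target_coverage = fit$filter$target_coverage,
         n_significant = fit$n_significant,
         manifest = lapply(seq_len(nrow(fit$manifest)), function(i)
           as.list(fit$manifest[i, ]))),
    file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Run the pipeline from a plain-text YAML configuration file
#'
#' A thin file-driven front end over [run_pipeline()]. Recognized keys:
#' `sync`, `sync_b`, `mask` (paths), `min_coverage`, `max_coverage`,
#' `min_count`, `target_coverage`, `chroms`, `pairs` (list of 2-vectors),
#' `correction`, `alpha`, `min_maf`, `seed`, `out_dir`. Unknown keys raise
#' an error naming the key; missing input files are reported before any
#' stage runs.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return The `rap_pipeline` object from [run_pipeline()].
#' @export
run_pipeline_file <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  known <- c("sync", "sync_b", "mask", "min_coverage", "max_coverage",
             "min_count", "target_coverage", "chroms", "pairs", "correction",
             "alpha", "min_maf", "seed", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$sync)) stop("config key 'sync' is required", call. = FALSE)
  for (key in c("sync", "sync_b", "mask")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop(sprintf("config key '%s': file not found: %s", key, cfg[[key]]),
           call. = FALSE)
    }
  }
  filter <- filter_config(
    min_coverage = cfg$min_coverage %||% 30L,
    max_coverage = cfg$max_coverage %||% 500L,
    min_count = cfg$min_count %||% 8L,
    target_coverage = cfg$target_coverage %||% 30L,
    chroms = cfg$chroms)
  pairs <- if (is.null(cfg$pairs)) list(c(1L, 3L), c(2L, 4L)) else
    lapply(cfg$pairs, as.integer)
  run_pipeline(sync = cfg$sync, sync_b = cfg$sync_b, mask = cfg$mask,
               filter = filter, pairs = pairs,
               correction = cfg$correction %||% TRUE,
               alpha = cfg$alpha %||% 0.01, min_maf = cfg$min_maf,
               seed = cfg$seed, out_dir = cfg$out_dir)
}

#' Re-test after filtering on pooled minor-allele frequency
#'
#' Keeps SNPs whose minor-allele frequency, pooled over all populations of
#' the post-subsampling calls, is at least `min_maf`, then (by default)
#' re-applies the Benjamini-Hochberg adjustment on the retained subset — a
#' common robustness check, since low-frequency SNPs carry little power and
#' inflate the multiple-testing burden.
#'
#' @param results Per-SNP result tibble with `chrom`, `pos`, `p_value`.
#' @param calls The post-subsampling calls the results came from.
#' @param min_maf Frequency floor in \[0, 0.5\].
#' @param adjust Re-run [adjust_fdr()] on the retained rows.
#' @return The filtered (and re-adjusted) result tibble.
#' @export
maf_filter <- function(results, calls, min_maf, adjust = TRUE) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  assert_columns(results, c("chrom", "pos", "p_value"), "results")
  assert_columns(calls, c("chrom", "pos", "major_count", "minor_count"),
                 "calls")
  pooled <- dplyr::summarise(
    dplyr::group_by(calls, .data$chrom, .data$pos),
    maf = sum(.data$minor_count) /
      sum(.data$major_count + .data$minor_count),
    .groups = "drop")
  keep <- dplyr::inner_join(results, pooled, by = c("chrom", "pos"))
  keep <- keep[keep$maf >= min_maf, setdiff(names(keep), "maf"), drop = FALSE]
  if (adjust) keep <- adjust_fdr(keep) else keep
}

#' @export
print.rap_pipeline <- function(x, ...) {
  cat(sprintf(
    "<rap_pipeline> %d SNPs tested, %d significant at FDR < %g%s\n",
    nrow(x$results), x$n_significant, x$alpha,
    if (is.null(x$seed)) "" else sprintf(" (seed %s)", x$seed)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-SNP results of a pipeline run
#'
#' @param x A `rap_pipeline` object.
#' @param ... Unused.
#' @return The per-SNP result tibble (`chrom`, `pos`, `p_value`, `q_value`,
#'   plus `statistic`/`degenerate` for single-input runs).
#' @export
tidy.rap_pipeline <- function(x, ...) x$results

#' One-row summary of a pipeline run
#'
#' @param x A `rap_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_tested`, `n_significant`, `alpha`,
#'   `target_coverage`, `min_p`, `min_q`.
#' @export
glance.rap_pipeline <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x$results),
    n_significant = x$n_significant,
    alpha = x$alpha,
    target_coverage = x$filter$target_coverage,
    min_p = if (nrow(x$results)) min(x$results$p_value) else NA_real_,
    min_q = if (nrow(x$results)) min(x$results$q_value) else NA_real_)
}

#' Manhattan plot of per-SNP CMH p-values
#'
#' Plots -log10(p) against genomic position per chromosome, with a dashed
#' line at the largest p-value that would be significant at `alpha` (drawn
#' only when at least one SNP crosses it, mirroring how a BH threshold is
#' data-dependent).
#'
#' @param object A `rap_pipeline` object.
#' @param alpha FDR threshold for the guide line (defaults to the run's).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rap_pipeline <- function(object, alpha = object$alpha, ...) {
  df <- object$results
  df$neglog10_p <- -log10(pmax(df$p_value, .Machine$double.xmin))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6,
                                         y = .data$neglog10_p)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
  sig <- df$p_value[df$q_value < alpha]
  if (length(sig) > 0L) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(max(sig)),
                                   linetype = "dashed")
  }
  gg
}

#' QQ plot of drift-only versus Pool-Seq-observed allele frequency change
#'
#' @param afc An AFC tibble from [simulate_drift()] containing both
#'   `afc_abs` and `afc_obs_abs`, or a tibble from [qq_afc()].
#' @param n_quantiles Number of quantile points when `afc` is a simulation
#'   table.
#' @return A ggplot object with the identity line for reference.
#' @export
plot_afc_qq <- function(afc, n_quantiles = 1000L) {
  qq <- if (all(c("qx", "qy") %in% names(afc))) afc else {
    assert_columns(afc, c("afc_abs", "afc_obs_abs"), "afc")
    qq_afc(afc$afc_abs, afc$afc_obs_abs, n_quantiles)
  }
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$qx, y = .data$qy)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::labs(x = "drift-only |AFC| quantiles",
                  y = "observed |AFC| quantiles") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
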