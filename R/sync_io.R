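#' Read a synchronized ("sync") allele-count file
#'
#' Parses a PoPoolation-style synchronized file into a tidy tibble with one
#' row per site and population. A sync file is tab-separated with columns
#' `chrom`, `pos` (1-based), `ref`, and then one colon-separated count field
#' per population in the fixed order `A:T:C:G:N:del`. Lines starting with
#' `#` are skipped as comments.
#'
#' @param path Path to a sync file.
#' @return A tibble with columns `chrom` (character), `pos` (integer, 1-based),
#'   `ref` (character), `pop` (integer population index, 1-based, in file
#'   column order) and integer count columns `A`, `T`, `C`, `G`, `N`, `del`.
#'   Rows are ordered as in the file, populations nested within site.
#' @details The number of populations is inferred from the first data line and
#'   enforced for every subsequent line; a malformed count field (wrong arity
#'   or a non-integer part) raises an error naming the offending line.
#' @seealso [write_sync()], [apply_mask()], [coverage_distribution()]
#' @examples
#' f <- tempfile(fileext = ".sync")
#' writeLines("2L\t5002\tA\t58:0:0:2:0:0\t30:0:0:30:0:0", f)
#' read_sync(f)
#' @export
read_sync <- function(path) {
  if (!file.exists(path)) stop("sync file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_sync())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 4L)) {
    bad <- line_no[which(n_fields < 4L)[1L]]
    stop(sprintf("sync parse error at line %d: fewer than 4 tab-separated fields", bad),
         call. = FALSE)
  }
  n_pops <- n_fields[1L] - 3L
  if (any(n_fields != n_fields[1L])) {
    bad <- line_no[which(n_fields != n_fields[1L])[1L]]
    stop(sprintf(
      "sync structural error at line %d: expected %d population field(s), found %d",
      bad, n_pops, n_fields[which(n_fields != n_fields[1L])[1L]] - 3L), call. = FALSE)
  }
  mat <- matrix(unlist(fields, use.names = FALSE), ncol = n_fields[1L], byrow = TRUE)
  pos <- suppressWarnings(as.integer(mat[, 2L]))
  if (anyNA(pos)) {
    bad <- line_no[which(is.na(pos))[1L]]
    stop(sprintf("sync parse error at line %d: non-integer position", bad), call. = FALSE)
  }
  count_fields <- t(mat[, -(1:3), drop = FALSE])  # pop-major within site
  parts <- strsplit(as.vector(count_fields), ":", fixed = TRUE)
  arity <- lengths(parts)
  if (any(arity != 6L)) {
    idx <- which(arity != 6L)[1L]
    bad <- line_no[ceiling(idx / n_pops)]
    stop(sprintf(
      "sync parse error at line %d: count field '%s' has %d part(s), expected 6 (A:T:C:G:N:del)",
      bad, as.vector(count_fields)[idx], arity[idx]), call. = FALSE)
  }
  counts <- suppressWarnings(matrix(as.integer(unlist(parts, use.names = FALSE)),
                                    ncol = 6L, byrow = TRUE))
  if (anyNA(counts)) {
    idx <- which(rowSums(is.na(counts)) > 0L)[1L]
    bad <- line_no[ceiling(idx / n_pops)]
    stop(sprintf("sync parse error at line %d: non-integer count in field '%s'",
                 bad, as.vector(count_fields)[idx]), call. = FALSE)
  }
  if (any(counts < 0L)) stop("sync parse error: negative count", call. = FALSE)
  n_sites <- length(lines)
  out <- tibble::tibble(
    chrom = rep(mat[, 1L], each = n_pops),
    pos   = rep(pos, each = n_pops),
    ref   = rep(mat[, 3L], each = n_pops),
    pop   = rep.int(seq_len(n_pops), n_sites),
    A = counts[, 1L], T = counts[, 2L], C = counts[, 3L],
    G = counts[, 4L], N = counts[, 5L], del = counts[, 6L]
  )
  out
}

empty_sync <- function() {
  tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                 pop = integer(), A = integer(), T = integer(), C = integer(),
                 G = integer(), N = integer(), del = integer())
}

validate_sync <- function(sync, what = "sync") {
  assert_columns(sync, c("chrom", "pos", "ref", "pop", SYNC_COUNT_COLS), what)
  n_pops <- length(unique(sync$pop))
  if (nrow(sync) %% max(n_pops, 1L) != 0L ||
      (nrow(sync) > 0L && !all(tabulate(sync$pop) == nrow(sync) / n_pops))) {
    stop(sprintf("`%s` must contain every population once per site", what),
         call. = FALSE)
  }
  invisible(n_pops)
}

#' Write a tidy sync table to a synchronized file
#'
#' Inverse of [read_sync()]: serializes one tab-separated line per site with
#' colon-separated `A:T:C:G:N:del` count fields, one per population.
#' `write_sync()` followed by [read_sync()] is the identity, and reading then
#' writing a canonical sync file reproduces it byte for byte.
#'
#' @param sync A sync tibble as returned by [read_sync()] (or
#'   [generate_experiment()]); every site must carry the same populations.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sync, path) {
  validate_sync(sync)
  if (nrow(sync) == 0L) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  # group populations within each site, keeping sites in appearance order
  site_key <- paste(sync$chrom, sync$pos, sep = "\r")
  sync <- dplyr::arrange(sync, factor(site_key, levels = unique(site_key)),
                         .data$pop)
  field <- paste(sync$A, sync$T, sync$C, sync$G, sync$N, sync$del, sep = ":")
  n_pops <- length(unique(sync$pop))
  site <- seq_len(nrow(sync) / n_pops)
  first <- (seq_len(nrow(sync)) - 1L) %% n_pops == 0L
  pops_by_site <- matrix(field, nrow = n_pops)
  body <- apply(pops_by_site, 2L, paste, collapse = "\t")
  lines <- paste(sync$chrom[first], sync$pos[first], sync$ref[first], body, sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a BED mask file
#'
#' @param path Path to a BED file (tab-separated `chrom`, `start`, `end`;
#'   0-based half-open intervals; further columns and `#` comments ignored).
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 3L) stop("BED file must have at least 3 columns", call. = FALSE)
  out <- tibble::tibble(chrom = as.character(df[[1L]]),
                        start = as.integer(df[[2L]]),
                        end = as.integer(df[[3L]]))
  if (any(out$start >= out$end)) {
    stop("BED intervals must satisfy start < end", call. = FALSE)
  }
  out
}

#' Remove masked sites from a sync table
#'
#' Drops every site whose position falls inside a mask interval. Sync
#' positions are 1-based (PoPoolation convention) while mask intervals are
#' BED-style 0-based half-open, so a site at 1-based position `p` is removed
#' iff some interval `(chrom, start, end)` has `start <= p - 1 < end`.
#' Masks of repeats, indels and their flanks are built upstream; this
#' function only applies them.
#'
#' @param sync A sync tibble ([read_sync()]).
#' @param mask A tibble of intervals with columns `chrom`, `start`, `end`
#'   (0-based half-open, as from [read_bed()]); intervals may overlap. An
#'   empty mask leaves the input untouched.
#' @return The sync tibble restricted to unmasked sites; row order and row
#'   contents are preserved.
#' @export
apply_mask <- function(sync, mask) {
  validate_sync(sync)
  assert_columns(mask, c("chrom", "start", "end"), "mask")
  if (nrow(mask) == 0L || nrow(sync) == 0L) return(sync)
  if (any(mask$start >= mask$end)) {
    stop("mask intervals must satisfy start < end", call. = FALSE)
  }
  masked <- rep(FALSE, nrow(sync))
  for (chr in unique(mask$chrom)) {
    iv <- mask[mask$chrom == chr, , drop = FALSE]
    # merge overlapping/adjacent intervals so findInterval gives a unique hit
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    merged_start <- iv$start[1L]; merged_end <- iv$end[1L]
    starts <- ends <- integer(0)
    for (i in seq_len(nrow(iv))[-1L]) {
      if (iv$start[i] <= merged_end) {
        merged_end <- max(merged_end, iv$end[i])
      } else {
        starts <- c(starts, merged_start); ends <- c(ends, merged_end)
        merged_start <- iv$start[i]; merged_end <- iv$end[i]
      }
    }
    starts <- c(starts, merged_start); ends <- c(ends, merged_end)
    on_chr <- sync$chrom == chr
    p0 <- sync$pos[on_chr] - 1L  # to 0-based
    j <- findInterval(p0, starts)
    hit <- j >= 1L & p0 < ends[pmax(j, 1L)]
    masked[on_chr] <- masked[on_chr] | hit
  }
  sync[!masked, , drop = FALSE]
}

#' Empirical per-site coverage distribution of one population
#'
#' Collects the multiset of per-site total read depths (sum of the six
#' `A,T,C,G,N,del` counts) for one population of a sync table, for use as an
#' empirical coverage distribution in Pool-Seq resampling
#' ([poolseq_sample()], [generate_experiment()]).
#'
#' @param x A sync tibble, or a numeric vector of depths (e.g. read from a
#'   one-column plain-text depth list).
#' @param population Population index (required when `x` is a sync tibble).
#' @param label Optional population label carried along for plots/summaries.
#' @return An object of class `coverage_distribution`: a list with elements
#'   `depths` (integer vector, the multiset) and `label`.
#' @examples
#' cd <- coverage_distribution(c(60, 60, 58), label = "sim_rap1")
#' sample_coverage(cd, 5, seed = 1)
#' @export
coverage_distribution <- function(x, population = NULL, label = NULL) {
  if (is.data.frame(x)) {
    validate_sync(x)
    if (is.null(population)) {
      stop("`population` is required when `x` is a sync table", call. = FALSE)
    }
    rows <- x[x$pop == population, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("no sites for population ", population, call. = FALSE)
    }
    depths <- rows$A + rows$T + rows$C + rows$G + rows$N + rows$del
    label <- label %||% paste0("pop", population)
  } else {
    depths <- as.integer(x)
    if (length(depths) == 0L) stop("empty coverage distribution", call. = FALSE)
    label <- label %||% "coverage"
  }
  if (anyNA(depths) || any(depths < 1L)) {
    stop("all depths must be positive integers", call. = FALSE)
  }
  structure(list(depths = depths, label = label), class = "coverage_distribution")
}

#' Read a one-column plain-text depth list as a coverage distribution
#'
#' @param path Path to a plain-text file with one positive integer depth per
#'   line.
#' @param label Optional label, defaults to the file name.
#' @return A `coverage_distribution` object.
#' @export
read_coverage <- function(path, label = NULL) {
  depths <- as.integer(readr::read_lines(path))
  coverage_distribution(depths, label = label %||% basename(path))
}

#' @export
print.coverage_distribution <- function(x, ...) {
  cat(sprintf("<coverage_distribution '%s'> %d sites, depth %d-%d (median %g)\n",
              x$label, length(x$depths), min(x$depths), max(x$depths),
              stats::median(x$depths)))
  invisible(x)
}

#' Draw per-site coverages
#'
#' Samples `n` depths with replacement from a coverage distribution, or
#' recycles a constant/vector coverage specification.
#'
#' @param coverage A `coverage_distribution`, a single number (constant
#'   coverage) or a numeric vector (sampled with replacement when longer
#'   than 1).
#' @param n Number of draws.
#' @param seed Optional integer seed for reproducibility.
#' @return An integer vector of length `n`.
#' @export
sample_coverage <- function(coverage, n, seed = NULL) {
  with_seed_if(seed, {
    if (inherits(coverage, "coverage_distribution")) {
      sample(coverage$depths, n, replace = TRUE)
    } else if (length(coverage) == 1L) {
      rep.int(as.integer(coverage), n)
    } else {
      sample(as.integer(coverage), n, replace = TRUE)
    }
  })
}
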