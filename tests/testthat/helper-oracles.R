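# Independent oracle implementations used to cross-check the package.
# These are deliberately written as plain scalar loops, separate from the
# vectorised code paths they validate.

# Closed-form CMH statistic, one stack at a time.
cmh_oracle <- function(stack, correction = TRUE) {
  K <- dim(stack)[3]
  sum_num <- 0; sum_var <- 0; informative <- 0L
  for (k in seq_len(K)) {
    t2 <- stack[, , k]
    storage.mode(t2) <- "double"  # margin products overflow 32-bit integers
    a <- t2[1, 1]; b <- t2[1, 2]; c <- t2[2, 1]; d <- t2[2, 2]
    n <- a + b + c + d
    r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
    if (n <= 1 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) next
    informative <- informative + 1L
    sum_num <- sum_num + (a - r1 * c1 / n)
    sum_var <- sum_var + r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  }
  if (informative == 0L) {
    return(list(statistic = NA_real_, p_value = 1, degenerate = TRUE))
  }
  cc <- if (correction) 0.5 else 0
  stat <- max(abs(sum_num) - cc, 0)^2 / sum_var
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

# Step-up BH adjustment, coded directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, m * p[ord[i]] / i)
    q_sorted[i] <- min(running_min, 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Random sync tibble for round-trip / masking property tests.
random_sync <- function(n_sites, n_pops = 2L, chroms = c("2L", "2R", "X"),
                        max_pos = 1000L) {
  coords <- unique(data.frame(
    chrom = sample(chroms, n_sites * 2L, replace = TRUE),
    pos = sample.int(max_pos, n_sites * 2L, replace = TRUE)))
  coords <- coords[seq_len(min(n_sites, nrow(coords))), ]
  n <- nrow(coords)
  tibble::tibble(
    chrom = rep(coords$chrom, each = n_pops),
    pos = rep(as.integer(coords$pos), each = n_pops),
    ref = rep(sample(c("A", "C", "G", "T"), n, replace = TRUE), each = n_pops),
    pop = rep.int(seq_len(n_pops), n),
    A = rpois(n * n_pops, 20), T = rpois(n * n_pops, 5),
    C = rpois(n * n_pops, 5), G = rpois(n * n_pops, 20),
    N = rpois(n * n_pops, 0.2), del = rpois(n * n_pops, 0.2))
}

# Long-format calls tibble from site x pop major/minor count matrices.
calls_from_matrices <- function(maj, mnr, chrom = "2L") {
  n_sites <- nrow(maj); n_pops <- ncol(maj)
  tibble::tibble(
    chrom = rep(chrom, n_sites * n_pops),
    pos = rep(seq_len(n_sites), each = n_pops),
    major = "A", minor = "C",
    pop = rep.int(seq_len(n_pops), n_sites),
    major_count = as.integer(t(maj)),
    minor_count = as.integer(t(mnr)))
}
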