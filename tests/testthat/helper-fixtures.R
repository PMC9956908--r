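# shared fixture builders: everything is generated in code, no stored data

# one alignment block with sensible defaults
make_block <- function(query_name = "q1", query_length = 1e6,
                       query_start = 0, query_end = 5000,
                       strand = "+",
                       target_name = "t1", target_length = 1e6,
                       target_start = 0, target_end = NULL,
                       matches = NULL, block_length = NULL, mapq = 60) {
  if (is.null(block_length)) block_length <- query_end - query_start
  if (is.null(target_end)) target_end <- target_start + block_length
  if (is.null(matches)) matches <- round(0.9 * block_length)
  tibble::tibble(
    query_name = query_name, query_length = query_length,
    query_start = query_start, query_end = query_end, strand = strand,
    target_name = target_name, target_length = target_length,
    target_start = target_start, target_end = target_end,
    matches = matches, block_length = block_length, mapq = mapq
  )
}

# a batch of random valid blocks for property tests
random_blocks <- function(n, n_chrom_q = 3, n_chrom_t = 3, seed = NULL) {
  gen <- function() {
    len <- floor(runif(n, 500, 30000))
    qs <- floor(runif(n, 0, 1e6 - len))
    ts <- floor(runif(n, 0, 1e6 - len))
    tibble::tibble(
      query_name = paste0("q", sample.int(n_chrom_q, n, replace = TRUE)),
      query_length = 1e6, query_start = qs, query_end = qs + len,
      strand = sample(c("+", "-"), n, replace = TRUE),
      target_name = paste0("t", sample.int(n_chrom_t, n, replace = TRUE)),
      target_length = 1e6, target_start = ts, target_end = ts + len,
      matches = floor(len * runif(n, 0.5, 1)),
      block_length = len,
      mapq = sample(0:255, n, replace = TRUE)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# a chain of single-pair blocks laid out left-to-right on the target, with a
# given strand sequence; block i occupies [i*step, i*step + size) on both axes
make_chain_blocks <- function(strands, size = 20000, step = 30000,
                              chrom_len = NULL) {
  n <- length(strands)
  if (is.null(chrom_len)) chrom_len <- n * step + size
  pos <- (seq_len(n) - 1) * step
  make_block(
    query_name = "qA", query_length = chrom_len,
    query_start = pos, query_end = pos + size,
    strand = strands,
    target_name = "tA", target_length = chrom_len,
    target_start = pos, target_end = pos + size
  )
}

# a small, fast simulation used across tests: 6 chromosomes incl. Z,
# one stem inversion, one fusion + one Z-autosome fusion + terminal Z
# inversion on the c branch
tiny_events <- function() {
  inv <- function(cc, pc) list(kind = "inversion", chrom_class = cc,
                               position_class = pc)
  list(
    stem = list(inv("autosome", "interstitial")),
    jurtina = list(),
    ligea = list(),
    aethiops = list(
      inv("Z", "terminal"),
      list(kind = "fusion", partners = "autosome-autosome"),
      list(kind = "fusion", partners = "Z-autosome")
    )
  )
}

tiny_config <- function(seed = 1, ...) {
  sim_config(seed = seed, ancestor_n = 6, events = tiny_events(), ...)
}

# the exhaustive minority-strand-run scanner: an independent oracle for
# call_inversions, written as a direct transcription of the definition
oracle_inversion_runs <- function(chain, min_blocks = 3, min_span = 5e4,
                                  max_gap = 1e6) {
  b <- chain$blocks
  runs <- list()
  current <- integer()
  flush_run <- function(runs, current) {
    if (length(current) > 0) runs[[length(runs) + 1]] <- current
    runs
  }
  for (i in seq_len(nrow(b))) {
    if (b$strand[i] == "-") {
      if (length(current) > 0 &&
          (b$target_start[i] - b$target_end[current[length(current)]]) > max_gap) {
        runs <- flush_run(runs, current)
        current <- integer()
      }
      current <- c(current, i)
    } else {
      runs <- flush_run(runs, current)
      current <- integer()
    }
  }
  runs <- flush_run(runs, current)
  out <- list()
  for (r in runs) {
    span <- max(b$target_end[r]) - min(b$target_start[r])
    if (length(r) >= min_blocks && span >= min_span) {
      out[[length(out) + 1]] <- c(t0 = min(b$target_start[r]),
                                  t1 = max(b$target_end[r]),
                                  n = length(r))
    }
  }
  out
}

# O(n^2) dynamic program for block-length-weighted longest chain strictly
# increasing in both coordinates; oracle for collinearity_report
oracle_weighted_lis <- function(blocks) {
  n <- nrow(blocks)
  if (n == 0) return(0)
  ord <- order(blocks$target_start, blocks$query_start)
  t <- blocks$target_start[ord]
  q <- blocks$query_start[ord]
  w <- blocks$block_length[ord]
  dp <- w
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (t[j] < t[i] && q[j] < q[i] && dp[j] + w[i] > dp[i]) {
        dp[i] <- dp[j] + w[i]
      }
    }
  }
  max(dp) / sum(blocks$block_length)
}
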