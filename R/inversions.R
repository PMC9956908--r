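#' Normalize the strand polarity of one chromosome pair
#'
#' Assembly strand is arbitrary, so "reverse orientation" is only defined
#' relative to the dominant polarity of a chromosome pair. If blocks on the
#' '-' strand carry the majority of aligned bp, the query coordinates are
#' mirrored (`x -> query_length - x`) and all strands toggled, so that after
#' normalization the majority of aligned bp is always '+'. An exact 50/50
#' tie resolves to no flip. Mirroring twice is the identity.
#'
#' @param blocks Alignment blocks, all sharing one (query, target)
#'   chromosome pair. Must be nonempty.
#' @return An `oriented_chain`: a list with `blocks` (sorted by
#'   `target_start`), `pair`, `dominant_strand` (the majority strand before
#'   normalization) and `flipped`.
#' @export
normalize_orientation <- function(blocks) {
  if (nrow(blocks) == 0L) abort("cannot orient an empty block set")
  pair <- unique(blocks[, c("query_name", "target_name")])
  if (nrow(pair) != 1L) {
    abort("all blocks must share a single (query, target) chromosome pair")
  }
  minus_bp <- sum(blocks$block_length[blocks$strand == "-"])
  plus_bp <- sum(blocks$block_length[blocks$strand == "+"])
  flipped <- minus_bp > plus_bp
  if (flipped) {
    qlen <- blocks$query_length
    new_start <- qlen - blocks$query_end
    new_end <- qlen - blocks$query_start
    blocks$query_start <- new_start
    blocks$query_end <- new_end
    blocks$strand <- ifelse(blocks$strand == "+", "-", "+")
  }
  blocks <- blocks[order(blocks$target_start, blocks$target_end), , drop = FALSE]
  structure(
    list(
      blocks = blocks,
      pair = c(query = pair$query_name, target = pair$target_name),
      dominant_strand = if (flipped) "-" else "+",
      flipped = flipped
    ),
    class = "oriented_chain"
  )
}

#' @export
print.oriented_chain <- function(x, ...) {
  cat(sprintf(
    "<oriented_chain> %s ~ %s: %d blocks, dominant strand '%s'%s\n",
    x$pair[["query"]], x$pair[["target"]], nrow(x$blocks),
    x$dominant_strand, if (x$flipped) " (query mirrored)" else ""
  ))
  invisible(x)
}

#' Call inversions as maximal reversed-orientation block runs
#'
#' Scans the normalized chain in target-coordinate order (reading a dot
#' plot left to right) and reports each maximal run of consecutive '-'
#' blocks as one inversion, provided the run has at least `min_blocks`
#' blocks and spans at least `min_span` bp on the target. Consecutive '-'
#' blocks separated by a target gap larger than `max_gap` start a new run.
#' Calls are non-overlapping on the target. Minority runs below the
#' thresholds are tallied as micro-rearrangements (attribute
#' `micro_runs`), not emitted as calls.
#'
#' Query coordinates of a call are reported in the original (un-mirrored)
#' query frame even when the chain was flipped.
#'
#' @param chain An `oriented_chain` from [normalize_orientation()].
#' @param min_blocks Minimum number of blocks in a reported run (default 3).
#' @param min_span Minimum target span in bp (default 5e4).
#' @param max_gap Maximum target gap joining consecutive '-' blocks into
#'   one run (default 1e6).
#' @return A tibble of inversion calls: `query_chrom`, `target_chrom`,
#'   `query_start`, `query_end`, `target_start`, `target_end`, `n_blocks`,
#'   `span_bp`, `query_length`, `target_length`.
#' @export
call_inversions <- function(chain, min_blocks = 3, min_span = 5e4, max_gap = 1e6) {
  stopifnot(inherits(chain, "oriented_chain"))
  b <- chain$blocks
  out <- empty_inversions()
  micro <- 0L
  m <- which(b$strand == "-")
  if (length(m) > 0L) {
    new_run <- c(TRUE, diff(m) > 1L |
                   (b$target_start[m[-1]] - b$target_end[m[-length(m)]]) > max_gap)
    runs <- split(m, cumsum(new_run))
    rows <- list()
    for (r in runs) {
      t0 <- min(b$target_start[r]); t1 <- max(b$target_end[r])
      q0 <- min(b$query_start[r]); q1 <- max(b$query_end[r])
      if (chain$flipped) {
        qlen <- b$query_length[r[1]]
        tmp <- qlen - q1
        q1 <- qlen - q0
        q0 <- tmp
      }
      span <- t1 - t0
      if (length(r) >= min_blocks && span >= min_span) {
        rows[[length(rows) + 1L]] <- tibble(
          query_chrom = chain$pair[["query"]],
          target_chrom = chain$pair[["target"]],
          query_start = q0, query_end = q1,
          target_start = t0, target_end = t1,
          n_blocks = length(r), span_bp = span,
          query_length = b$query_length[r[1]],
          target_length = b$target_length[r[1]]
        )
      } else {
        micro <- micro + 1L
      }
    }
    if (length(rows) > 0L) out <- bind_rows(rows)
  }
  attr(out, "micro_runs") <- micro
  out
}

empty_inversions <- function() {
  tibble(
    query_chrom = character(), target_chrom = character(),
    query_start = numeric(), query_end = numeric(),
    target_start = numeric(), target_end = numeric(),
    n_blocks = integer(), span_bp = numeric(),
    query_length = numeric(), target_length = numeric()
  )
}

#' Classify the chromosomal position of inversion calls
#'
#' Positions are classified by the distance of the call interval from the
#' nearer chromosome end, as a fraction of chromosome length: below
#' `terminal_frac` the call is `terminal`, below `subtelomeric_frac` it is
#' `subtelomeric`, otherwise `interstitial`. The three-way scheme
#' quantifies the qualitative terminal/subtelomeric/interstitial
#' distinction of classical cytogenetics; the cutoffs are tunable because
#' no standard quantitative definition exists.
#'
#' @param calls A tibble of inversion calls from [call_inversions()].
#' @param karyo Karyotype of the side being classified.
#' @param side Which coordinates to classify: `"query"` (default) or
#'   `"target"`.
#' @param terminal_frac,subtelomeric_frac Class cutoffs as fractions of
#'   chromosome length (defaults 0.02 and 0.15).
#' @return `calls` with a `position_class` column added.
#' @export
classify_position <- function(calls, karyo, side = c("query", "target"),
                              terminal_frac = 0.02, subtelomeric_frac = 0.15) {
  side <- match.arg(side)
  if (nrow(calls) == 0L) {
    calls$position_class <- character()
    return(calls)
  }
  chrom <- calls[[paste0(side, "_chrom")]]
  start <- calls[[paste0(side, "_start")]]
  end <- calls[[paste0(side, "_end")]]
  len <- karyo$length[match(chrom, karyo$chrom)]
  if (anyNA(len)) {
    abort(paste0("chromosome not in karyotype: ",
                 chrom[which(is.na(len))[1L]]))
  }
  if (any(start < 0 | end > len)) abort("call interval outside chromosome")
  frac <- pmin(start, len - end) / len
  calls$position_class <- ifelse(
    frac < terminal_frac, "terminal",
    ifelse(frac < subtelomeric_frac, "subtelomeric", "interstitial")
  )
  calls
}

# Fenwick tree over prefix maxima; used for the weighted
# longest-increasing-subsequence in collinearity_score
fenwick_new <- function(n) rep(-Inf, n)
fenwick_update <- function(tree, i, value) {
  n <- length(tree)
  while (i <= n) {
    if (tree[i] < value) tree[i] <- value
    i <- i + bitwAnd(i, -i)
  }
  tree
}
fenwick_prefix_max <- function(tree, i) {
  best <- 0
  while (i > 0) {
    if (tree[i] > best) best <- tree[i]
    i <- i - bitwAnd(i, -i)
  }
  best
}

#' Score the collinearity of a chromosome pair
#'
#' Collinearity is measured as the fraction of aligned bp lying on the
#' heaviest chain of blocks strictly increasing in both query and target
#' coordinates (a block-length-weighted longest increasing subsequence,
#' computed in O(n log n)). A perfectly collinear pair scores 1; each
#' inversion or shuffled segment removes its aligned bp from the best
#' chain. Because the chain is normalized first, a whole-chromosome
#' reversal also scores 1.
#'
#' @param chain An `oriented_chain` from [normalize_orientation()].
#' @param calls Optional inversion calls for the pair, used to report
#'   `n_inversions`.
#' @return A one-row tibble: `query_chrom`, `target_chrom`,
#'   `monotone_fraction`, `n_inversions`.
#' @export
collinearity_report <- function(chain, calls = NULL) {
  stopifnot(inherits(chain, "oriented_chain"))
  b <- chain$blocks
  total <- sum(b$block_length)
  ord <- order(b$target_start, b$query_start)
  t_s <- b$target_start[ord]
  q_s <- b$query_start[ord]
  w <- b$block_length[ord]
  ranks <- match(q_s, sort(unique(q_s)))
  tree <- fenwick_new(max(ranks))
  best <- 0
  i <- 1L
  n <- length(ord)
  while (i <= n) {
    # batch blocks with equal target_start so ties never chain together
    j <- i
    while (j < n && t_s[j + 1L] == t_s[i]) j <- j + 1L
    dp <- numeric(j - i + 1L)
    for (k in i:j) {
      dp[k - i + 1L] <- w[k] + fenwick_prefix_max(tree, ranks[k] - 1L)
    }
    for (k in i:j) {
      tree <- fenwick_update(tree, ranks[k], dp[k - i + 1L])
      if (dp[k - i + 1L] > best) best <- dp[k - i + 1L]
    }
    i <- j + 1L
  }
  tibble(
    query_chrom = chain$pair[["query"]],
    target_chrom = chain$pair[["target"]],
    monotone_fraction = if (total > 0) best / total else NA_real_,
    n_inversions = if (is.null(calls)) NA_integer_ else nrow(calls)
  )
}

#' Call inversions across all chromosome pairs of a filtered alignment
#'
#' Groups filtered blocks by homologous chromosome pair (restricted to the
#' pairs retained in `relations` when given), normalizes each pair's
#' orientation and calls inversions.
#'
#' @param blocks Filtered alignment blocks.
#' @param relations Optional relations tibble; when given, only
#'   (query, target) pairs belonging to a relation are scanned, which
#'   avoids calling inversions on noise pairs.
#' @inheritParams call_inversions
#' @return A tibble of inversion calls over all pairs, ordered by target
#'   chromosome and coordinate.
#' @export
call_inversions_all <- function(blocks, relations = NULL,
                                min_blocks = 3, min_span = 5e4, max_gap = 1e6) {
  if (nrow(blocks) == 0L) return(empty_inversions())
  if (!is.null(relations)) {
    pairs <- purrr::map2(relations$query_members, relations$target_members,
                         ~ tidyr::expand_grid(query_name = .x, target_name = .y))
    pairs <- bind_rows(pairs)
    blocks <- dplyr::semi_join(blocks, pairs, by = c("query_name", "target_name"))
  }
  groups <- split(blocks, paste(blocks$query_name, blocks$target_name, sep = "\r"))
  calls <- map(groups, function(g) {
    call_inversions(normalize_orientation(g),
                    min_blocks = min_blocks, min_span = min_span,
                    max_gap = max_gap)
  })
  out <- bind_rows(calls)
  if (nrow(out) > 0L) {
    out <- arrange(out, .data$target_chrom, .data$target_start)
  }
  attr(out, "micro_runs") <- sum(vapply(calls, function(x) attr(x, "micro_runs"),
                                        integer(1)))
  out
}
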