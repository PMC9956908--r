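#' Read alignment blocks from a PAF file
#'
#' Parses the 12 mandatory tab-separated PAF columns into a tibble of
#' alignment blocks, one row per record. Optional SAM-style tag columns
#' (column 13 onwards) are ignored. Coordinates are kept verbatim in the
#' PAF convention: 0-based, half-open.
#'
#' Records in which the query and target chromosome carry the same name are
#' rejected: the pipeline is strictly pairwise between two different
#' assemblies, and identical names on both sides indicate a self-alignment.
#'
#' @param path Path to a PAF file. An empty file yields a zero-row tibble.
#' @return A tibble of alignment blocks with columns `query_name`,
#'   `query_length`, `query_start`, `query_end`, `strand`, `target_name`,
#'   `target_length`, `target_start`, `target_end`, `matches`,
#'   `block_length`, `mapq`.
#' @examples
#' paf <- tempfile(fileext = ".paf")
#' writeLines("q1\t1000\t0\t500\t+\tt1\t2000\t100\t600\t480\t500\t60", paf)
#' read_paf(paf)
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("PAF file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_blocks())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1L]
    abort(sprintf(
      "malformed PAF line %d: expected >= 12 tab-separated columns, found %d",
      bad, nf[bad]
    ))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  num_col <- function(i, what) {
    raw <- col(i)
    x <- suppressWarnings(as.numeric(raw))
    if (anyNA(x)) {
      bad <- which(is.na(x))[1L]
      abort(sprintf(
        "malformed PAF line %d: non-numeric %s ('%s')", bad, what, raw[bad]
      ))
    }
    x
  }
  strand <- col(5)
  if (!all(strand %in% c("+", "-"))) {
    bad <- which(!strand %in% c("+", "-"))[1L]
    abort(sprintf(
      "malformed PAF line %d: strand must be '+' or '-', found '%s'",
      bad, strand[bad]
    ))
  }
  blocks <- tibble(
    query_name    = col(1),
    query_length  = num_col(2, "query length"),
    query_start   = num_col(3, "query start"),
    query_end     = num_col(4, "query end"),
    strand        = strand,
    target_name   = col(6),
    target_length = num_col(7, "target length"),
    target_start  = num_col(8, "target start"),
    target_end    = num_col(9, "target end"),
    matches       = num_col(10, "match count"),
    block_length  = num_col(11, "block length"),
    mapq          = num_col(12, "mapping quality")
  )
  validate_blocks(blocks)
  blocks
}

empty_blocks <- function() {
  tibble(
    query_name = character(), query_length = numeric(),
    query_start = numeric(), query_end = numeric(),
    strand = character(),
    target_name = character(), target_length = numeric(),
    target_start = numeric(), target_end = numeric(),
    matches = numeric(), block_length = numeric(), mapq = numeric()
  )
}

#' Validate a tibble of alignment blocks
#'
#' Checks the PAF record invariants: coordinate ordering within chromosome
#' bounds, `matches <= block_length`, mapq in \[0, 255\], and that no record
#' aligns a chromosome against itself.
#'
#' @param blocks A tibble as returned by [read_paf()].
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_blocks <- function(blocks) {
  req <- c(
    "query_name", "query_length", "query_start", "query_end", "strand",
    "target_name", "target_length", "target_start", "target_end",
    "matches", "block_length", "mapq"
  )
  missing <- setdiff(req, names(blocks))
  if (length(missing) > 0L) {
    abort(paste0("blocks tibble lacks columns: ", paste(missing, collapse = ", ")))
  }
  check <- function(cond, msg) {
    if (any(!cond)) {
      abort(sprintf("invalid alignment block (line %d): %s", which(!cond)[1L], msg))
    }
  }
  with(blocks, {
    check(query_start >= 0 & query_start < query_end & query_end <= query_length,
          "query interval must satisfy 0 <= start < end <= length")
    check(target_start >= 0 & target_start < target_end & target_end <= target_length,
          "target interval must satisfy 0 <= start < end <= length")
    check(matches <= block_length, "matches must not exceed block length")
    check(mapq >= 0 & mapq <= 255, "mapq must lie in [0, 255]")
    check(query_name != target_name,
          "query and target share a chromosome name (self-alignment)")
  })
  invisible(blocks)
}

#' Write alignment blocks to a PAF file
#'
#' Emits the 12 mandatory PAF columns, tab-separated. Reading a well-formed
#' PAF with [read_paf()] and writing it back round-trips the mandatory
#' columns byte-identically (tags are dropped).
#'
#' @param blocks A tibble of alignment blocks.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(blocks, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- paste(
    blocks$query_name, fmt(blocks$query_length), fmt(blocks$query_start),
    fmt(blocks$query_end), blocks$strand, blocks$target_name,
    fmt(blocks$target_length), fmt(blocks$target_start), fmt(blocks$target_end),
    fmt(blocks$matches), fmt(blocks$block_length), fmt(blocks$mapq),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Filter alignment blocks by mapping quality and length
#'
#' Discards blocks with mapping quality below `min_mapq` or block length
#' below `min_length`. The thresholds are strict-less for discarding, so
#' blocks exactly at the thresholds are retained. A mapq of 255 means
#' "unavailable" in the PAF/SAM convention and is treated as missing: such
#' blocks are discarded whenever `min_mapq > 0`.
#'
#' @param blocks A tibble of alignment blocks.
#' @param min_mapq Minimum mapping quality retained (default 60).
#' @param min_length Minimum alignment block length in bp retained
#'   (default 2000, i.e. 2 kb).
#' @return The retained blocks, in input order. Idempotent.
#' @export
filter_blocks <- function(blocks, min_mapq = 60, min_length = 2000) {
  stopifnot(min_mapq >= 0, min_length >= 0)
  keep <- blocks$mapq >= min_mapq & blocks$block_length >= min_length
  if (min_mapq > 0) {
    keep <- keep & blocks$mapq != 255
  }
  blocks[keep, , drop = FALSE]
}

#' Summarise block lengths
#'
#' Returns the maximum, sum and count of alignment block lengths, the three
#' columns of the standard per-pair alignment summary.
#'
#' @param blocks A tibble of alignment blocks (usually already filtered).
#' @return A one-row tibble with `max_block_length`, `sum_block_lengths`
#'   and `n_blocks`. An empty input yields zeros.
#' @export
summarize_blocks <- function(blocks) {
  n <- nrow(blocks)
  tibble(
    max_block_length = if (n == 0L) 0 else max(blocks$block_length),
    sum_block_lengths = if (n == 0L) 0 else sum(blocks$block_length),
    n_blocks = n
  )
}
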