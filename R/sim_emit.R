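#' Homologous segments between two simulated genomes
#'
#' Composes the two species' coordinate maps through their shared ancestor:
#' each maximal interval that descends to both genomes becomes one segment
#' with coordinates on both, and an orientation ('-' when the two lineages
#' inherited it in opposite reading directions).
#'
#' @param sim A `karyo_sim`.
#' @param query_species,target_species Species labels.
#' @return A tibble of segments: `query_chrom`, `query_start`, `query_end`,
#'   `target_chrom`, `target_start`, `target_end`, `strand`.
#' @export
homologous_segments <- function(sim, query_species, target_species) {
  mq <- sim$species[[query_species]]$map
  mt <- sim$species[[target_species]]$map
  seg <- dplyr::inner_join(mq, mt, by = "anc_chrom", suffix = c("_q", "_t"),
                           relationship = "many-to-many") %>%
    mutate(o1 = pmax(.data$anc_start_q, .data$anc_start_t),
           o2 = pmin(.data$anc_end_q, .data$anc_end_t)) %>%
    filter(.data$o2 > .data$o1)
  tibble(
    query_chrom = seg$chrom_q,
    query_start = ifelse(seg$strand_q == "+",
                         seg$start_q + (seg$o1 - seg$anc_start_q),
                         seg$start_q + (seg$anc_end_q - seg$o2)),
    target_chrom = seg$chrom_t,
    target_start = ifelse(seg$strand_t == "+",
                          seg$start_t + (seg$o1 - seg$anc_start_t),
                          seg$start_t + (seg$anc_end_t - seg$o2)),
    strand = ifelse(seg$strand_q == seg$strand_t, "+", "-"),
    length = seg$o2 - seg$o1
  ) %>%
    mutate(query_end = .data$query_start + .data$length,
           target_end = .data$target_start + .data$length) %>%
    select("query_chrom", "query_start", "query_end",
           "target_chrom", "target_start", "target_end", "strand") %>%
    arrange(.data$query_chrom, .data$query_start)
}

# tile one segment with block intervals along the query axis; returns a
# matrix-free list of (start, end) offsets relative to the segment
tile_offsets <- function(seg_len, min_len, max_len, gap_max) {
  starts <- numeric(); ends <- numeric()
  pos <- 0
  while (seg_len - pos >= min_len) {
    rem <- seg_len - pos
    len <- if (rem <= max_len) rem else floor(runif(1, min_len, max_len))
    starts <- c(starts, pos)
    ends <- c(ends, pos + len)
    pos <- pos + len + floor(runif(1, 0, gap_max))
  }
  list(starts = starts, ends = ends)
}

#' Emit a fragmented pairwise alignment between two simulated genomes
#'
#' Tiles every homologous segment with alignment blocks whose lengths are
#' drawn from the configured block-size range, separated by short unaligned
#' gaps (the fragmented-block structure of a real divergent whole-genome
#' alignment). True blocks get mapq 60; configured noise adds sub-threshold
#' blocks (mapq below 60, or shorter than 2 kb) and optionally spurious
#' well-mapped blocks joining random chromosome pairs.
#'
#' @param sim A `karyo_sim`.
#' @param query_species,target_species Species labels; the first is the
#'   PAF query.
#' @param noise Noise settings (defaults to the config's).
#' @param seed Seed for block tiling; derived deterministically from the
#'   config seed and the species pair when NULL.
#' @return A tibble of alignment blocks (valid PAF content).
#' @export
sim_paf <- function(sim, query_species, target_species,
                    noise = sim$config$noise, seed = NULL) {
  config <- sim$config
  if (is.null(seed)) {
    pair_hash <- sum(utf8ToInt(paste(query_species, target_species))) %% 9973
    seed <- (config$seed * 10007 + pair_hash) %% .Machine$integer.max
  }
  kq <- sim$species[[query_species]]$karyotype
  kt <- sim$species[[target_species]]$karyotype
  segs <- homologous_segments(sim, query_species, target_species)
  min_len <- config$block_size_range[1]
  max_len <- config$block_size_range[2]
  withr::with_seed(seed, {
    rows <- vector("list", nrow(segs))
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, ]
      off <- tile_offsets(s$query_end - s$query_start, min_len, max_len,
                          config$gap_max)
      if (length(off$starts) == 0L) next
      qa <- s$query_start + off$starts
      qb <- s$query_start + off$ends
      if (s$strand == "+") {
        ta <- s$target_start + off$starts
        tb <- s$target_start + off$ends
      } else {
        ta <- s$target_end - off$ends
        tb <- s$target_end - off$starts
      }
      len <- qb - qa
      rows[[i]] <- tibble(
        query_name = s$query_chrom, query_start = qa, query_end = qb,
        strand = s$strand,
        target_name = s$target_chrom, target_start = ta, target_end = tb,
        matches = floor(len * runif(length(len), config$identity_range[1],
                                    config$identity_range[2])),
        block_length = len, mapq = 60
      )
    }
    blocks <- bind_rows(rows)
    noise_rows <- emit_noise(noise, kq, kt, min_len, max_len)
    blocks <- bind_rows(blocks, noise_rows)
    if (nrow(blocks) == 0L) return(empty_blocks())
    blocks$query_length <- kq$length[match(blocks$query_name, kq$chrom)]
    blocks$target_length <- kt$length[match(blocks$target_name, kt$chrom)]
    blocks <- blocks[, names(empty_blocks())]
    validate_blocks(blocks)
    blocks
  })
}

random_placement <- function(n, karyo, len) {
  chrom_i <- sample.int(nrow(karyo), n, replace = TRUE,
                        prob = karyo$length / sum(karyo$length))
  chrom <- karyo$chrom[chrom_i]
  start <- floor(runif(n, 0, pmax(1, karyo$length[chrom_i] - len)))
  list(chrom = chrom, start = start)
}

emit_noise <- function(noise, kq, kt, min_len, max_len) {
  out <- NULL
  mk <- function(n, len, mapq) {
    q <- random_placement(n, kq, len)
    t <- random_placement(n, kt, len)
    tibble(
      query_name = q$chrom, query_start = q$start, query_end = q$start + len,
      strand = sample(c("+", "-"), n, replace = TRUE),
      target_name = t$chrom, target_start = t$start, target_end = t$start + len,
      matches = floor(len * 0.8), block_length = len, mapq = mapq
    )
  }
  n1 <- noise$n_low_mapq %||% 0L
  if (n1 > 0L) {
    out <- bind_rows(out, mk(n1, floor(runif(n1, min_len, max_len)),
                             sample(0:59, n1, replace = TRUE)))
  }
  n2 <- noise$n_short %||% 0L
  if (n2 > 0L) {
    out <- bind_rows(out, mk(n2, floor(runif(n2, 200, 1999)), 60))
  }
  n3 <- noise$n_offdiag %||% 0L
  if (n3 > 0L) {
    rng <- noise$offdiag_length_range %||% c(2000, 20000)
    out <- bind_rows(out, mk(n3, floor(runif(n3, rng[1], rng[2])), 60))
  }
  out
}

#' Ancestral and derived genome sequences for a simulation
#'
#' Sequence content is cosmetic for the pipeline (the callers only ever see
#' alignment coordinates), but emitting it lets the coordinate maps be
#' verified at base level: a derived chromosome is the concatenation of its
#' ancestral pieces, reverse-complemented where the map says so.
#'
#' @param sim A `karyo_sim`.
#' @param gc GC content of the random ancestral sequence.
#' @return For `sim_ancestor_seq`, a named character vector of ancestral
#'   chromosome sequences; for `sim_genome_seq`, the same for one extant
#'   species.
#' @export
sim_ancestor_seq <- function(sim, gc = 0.35) {
  k <- sim$ancestor$karyotype
  withr::with_seed(sim$config$seed + 777L, {
    seqs <- vapply(k$length, function(n) {
      paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                   prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
            collapse = "")
    }, character(1))
    setNames(seqs, k$chrom)
  })
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' @rdname sim_ancestor_seq
#' @param species Species label.
#' @param anc_seq Ancestral sequences from [sim_ancestor_seq()] (recomputed
#'   when NULL).
#' @export
sim_genome_seq <- function(sim, species, anc_seq = NULL, gc = 0.35) {
  if (is.null(anc_seq)) anc_seq <- sim_ancestor_seq(sim, gc)
  map <- sim$species[[species]]$map
  pieces <- substring(anc_seq[map$anc_chrom], map$anc_start + 1, map$anc_end)
  pieces[map$strand == "-"] <- revcomp(pieces[map$strand == "-"])
  vapply(split(pieces, map$chrom), paste, character(1), collapse = "")
}

#' Write simulation outputs to a directory
#'
#' Emits, per species, a FASTA-index-style chromosome table; per species
#' pair, a PAF alignment; plus the ground-truth event log as JSON and the
#' configuration as a YAML-style key-value file.
#'
#' @param sim A `karyo_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_outputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- unname(sim$config$species)
  for (s in sp) {
    write_fai(sim$species[[s]]$karyotype, file.path(dir, paste0(s, ".fai")))
  }
  pairs <- list(c(sp[1], sp[2]), c(sp[1], sp[3]), c(sp[2], sp[3]))
  for (p in pairs) {
    write_paf(sim_paf(sim, p[1], p[2]),
              file.path(dir, paste0(p[1], "_", p[2], ".paf")))
  }
  jsonlite::write_json(sim$log, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE)
  cfg <- sim$config
  scalar <- vapply(cfg, function(x) is.atomic(x) && !is.null(x), logical(1))
  lines <- unlist(lapply(names(cfg)[scalar], function(nm) {
    paste0(nm, ": ", paste(cfg[[nm]], collapse = ", "))
  }))
  writeLines(lines, file.path(dir, "config.yaml"))
  invisible(dir)
}
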