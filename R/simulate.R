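#' Configure a karyotype-evolution simulation
#'
#' The simulator evolves an ancestral holocentric karyotype (by default
#' n = 29 including one Z, the ancestral satyrine complement) along a
#' rooted three-taxon tree `((b, c), a)` by fusions, fissions and
#' inversions, tracks a base-exact coordinate map for every lineage, and
#' emits fragmented pairwise alignments so the whole calling pipeline can
#' be validated against known ground truth.
#'
#' The default genome is scaled down (0.7-1.4 Mb per chromosome, about
#' 1/16 of the real 402-506 Mb satyrine assemblies) so that simulations
#' run in well under a second; `full_scale = TRUE` switches to realistic
#' 8-25 Mb chromosomes. Alignment-block sizes default to the 2-52 kb range
#' observed in real filtered whole-genome alignments of these species.
#'
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @param species Named character vector `c(a=, b=, c=)` of species labels;
#'   the topology is `((b, c), a)`.
#' @param ancestor_n Ancestral haploid chromosome number incl. Z (default 29).
#' @param chrom_length_range Min/max ancestral chromosome length, bp.
#' @param block_size_range Min/max emitted alignment-block length, bp.
#' @param gap_max Maximum unaligned gap between consecutive blocks, bp.
#'   Gaps emulate lineage-specific micro-indel divergence.
#' @param identity_range Range of per-block match fraction.
#' @param inversion_span_range Min/max planted inversion span, bp.
#' @param events Per-branch event specifications, as produced by
#'   [satyrine_events()]. Branches are `stem` (internal branch to the
#'   (b, c) ancestor) and the three species names.
#' @param noise List: `n_low_mapq` (blocks with mapq < 60), `n_short`
#'   (blocks shorter than 2 kb), `n_offdiag` (spurious well-mapped blocks
#'   joining random chromosome pairs) and `offdiag_length_range`.
#' @param add_w Add a tiny unalignable W chromosome (1/12 of the Z) to
#'   each extant karyotype (default FALSE; male assemblies carry no W).
#' @param full_scale Use realistic chromosome sizes (default FALSE).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       species = c(a = "jurtina", b = "ligea", c = "aethiops"),
                       ancestor_n = 29L,
                       chrom_length_range = c(7e5, 1.4e6),
                       block_size_range = c(2000, 52000),
                       gap_max = 8000,
                       identity_range = c(0.85, 0.98),
                       inversion_span_range = c(1.5e5, 2.5e5),
                       events = satyrine_events(),
                       noise = list(n_low_mapq = 0L, n_short = 0L, n_offdiag = 0L,
                                    offdiag_length_range = c(2000, 20000)),
                       add_w = FALSE,
                       full_scale = FALSE) {
  if (full_scale) {
    chrom_length_range <- c(8e6, 2.5e7)
    inversion_span_range <- c(1.5e6, 3e6)
  }
  stopifnot(ancestor_n >= 2L, all(block_size_range >= 1),
            length(species) == 3L)
  structure(
    list(
      seed = as.integer(seed), species = species, ancestor_n = as.integer(ancestor_n),
      chrom_length_range = chrom_length_range,
      block_size_range = block_size_range, gap_max = gap_max,
      identity_range = identity_range,
      inversion_span_range = inversion_span_range,
      events = events, noise = noise, add_w = add_w, full_scale = full_scale
    ),
    class = "sim_config"
  )
}

#' The satyrine event preset
#'
#' Reproduces the rearrangement inventory separating *M. jurtina*,
#' *E. ligea* and *E. aethiops*: nine inversions (eight autosomal, one
#' interstitial Z; four subtelomeric, five interstitial overall) on the
#' internal path between the jurtina lineage and the ligea/aethiops
#' ancestor, and on the aethiops branch one terminal Z inversion, nine
#' simple autosomal fusions and one Z-autosome fusion producing a neo-Z.
#' With an ancestral n = 29 this yields extant n = 29, 29 and 19.
#'
#' The internal-path inversions are placed on the stem branch: without an
#' outgroup, pairwise comparisons cannot separate the jurtina terminal
#' branch from the stem, and placing them on the stem makes them shared by
#' ligea and aethiops, matching their observed absence from that
#' comparison.
#'
#' @return A named list of per-branch event specification lists.
#' @export
satyrine_events <- function() {
  inv <- function(chrom_class, position_class) {
    list(kind = "inversion", chrom_class = chrom_class,
         position_class = position_class)
  }
  fus <- function(partners) list(kind = "fusion", partners = partners)
  list(
    stem = c(
      rep(list(inv("autosome", "subtelomeric")), 4),
      rep(list(inv("autosome", "interstitial")), 4),
      list(inv("Z", "interstitial"))
    ),
    jurtina = list(),
    ligea = list(),
    aethiops = c(
      list(inv("Z", "terminal")),
      rep(list(fus("autosome-autosome")), 9),
      list(fus("Z-autosome"))
    )
  )
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

new_state <- function(karyo, map) list(karyotype = karyo, map = map)

#' Simulate the ancestral karyotype
#'
#' Draws `ancestor_n` chromosome lengths uniformly from the configured
#' range, labels the last chromosome Z, and initialises the identity
#' coordinate map. Uses the config seed, so repeated runs are identical.
#'
#' @param config A [sim_config()].
#' @return A state: list with `karyotype` and `map` (the piecewise map
#'   from ancestral to derived coordinates; the identity here).
#' @export
simulate_ancestor <- function(config) {
  withr::with_seed(config$seed, draw_ancestor(config))
}

draw_ancestor <- function(config) {
  n <- config$ancestor_n
  lens <- floor(runif(n, config$chrom_length_range[1], config$chrom_length_range[2]))
  # the lepidopteran Z is typically among the largest chromosomes; drawing it
  # at the top of the range also keeps reversed-orientation bp a strict
  # minority when several Z inversions accumulate on one lineage
  lens[n] <- config$chrom_length_range[2]
  names_ <- c(sprintf("anc_%02d", seq_len(n - 1L)), "anc_Z")
  karyo <- karyotype(names_, lens,
                     sex_class = c(rep("autosome", n - 1L), "Z"),
                     species = "ancestor")
  map <- tibble(
    chrom = names_, start = 0, end = lens,
    anc_chrom = names_, anc_start = 0, anc_end = lens,
    strand = "+"
  )
  new_state(karyo, map)
}

# introduce a piece boundary at pos on a derived chromosome
split_map_at <- function(map, chrom, pos) {
  i <- which(map$chrom == chrom & map$start < pos & map$end > pos)
  if (length(i) == 0L) return(map)
  p <- map[i, ]
  off <- pos - p$start
  left <- p; right <- p
  left$end <- pos
  right$start <- pos
  if (p$strand == "+") {
    left$anc_end <- p$anc_start + off
    right$anc_start <- p$anc_start + off
  } else {
    left$anc_start <- p$anc_end - off
    right$anc_end <- p$anc_end - off
  }
  arrange(bind_rows(map[-i, ], left, right), .data$chrom, .data$start)
}

#' Apply one rearrangement event to a karyotype state
#'
#' Events are concrete: an `inversion` carries `chrom`, `start`, `end`
#' (0-based half-open); a `fusion` carries `chrom`, `chrom2` and an
#' `orientation` (`"forward"` or `"reverse"`) for the second partner; a
#' `fission` carries `chrom` and `start` as the breakpoint. Fusions
#' concatenate end-to-end (holocentric chromosomes tolerate this: the
#' product is not dicentric), fissions split (fragments keep kinetic
#' activity), inversions reverse a map interval in place. All events are
#' length-preserving and keep the coordinate map invertible.
#'
#' @param state A state (list of `karyotype`, `map`).
#' @param event A named list describing one event (see Details).
#' @return The updated state, with attribute `log_row` describing the
#'   applied event (including the resulting chromosome name).
#' @export
apply_event <- function(state, event) {
  kind <- event$kind
  karyo <- state$karyotype
  map <- state$map
  log_row <- tibble(
    kind = kind, chrom = event$chrom %||% NA_character_,
    chrom2 = event$chrom2 %||% NA_character_,
    start = event$start %||% NA_real_, end = event$end %||% NA_real_,
    orientation = event$orientation %||% NA_character_,
    position_class = event$position_class %||% NA_character_,
    new_name = NA_character_
  )
  if (kind == "inversion") {
    chrom <- event$chrom
    s <- event$start; e <- event$end
    len <- karyo$length[karyo$chrom == chrom]
    if (length(len) == 0L) abort(paste0("unknown chromosome: ", chrom))
    if (e <= s) abort("zero-length inversion")
    if (s < 0 || e > len) abort("inversion interval outside chromosome")
    map <- split_map_at(map, chrom, s)
    map <- split_map_at(map, chrom, e)
    sel <- map$chrom == chrom & map$start >= s & map$end <= e
    sub <- map[sel, ][order(map$start[sel]), ]
    sub <- sub[rev(seq_len(nrow(sub))), ]
    piece_len <- sub$end - sub$start
    sub$start <- s + cumsum(c(0, head(piece_len, -1L)))
    sub$end <- sub$start + piece_len
    sub$strand <- flip_strand(sub$strand)
    map <- arrange(bind_rows(map[!sel, ], sub), .data$chrom, .data$start)
    log_row$new_name <- chrom
  } else if (kind == "fusion") {
    a <- event$chrom; b <- event$chrom2
    if (identical(a, b)) abort("cannot fuse a chromosome with itself")
    if (!all(c(a, b) %in% karyo$chrom)) abort("unknown fusion partner")
    orientation <- event$orientation %||% "forward"
    la <- karyo$length[karyo$chrom == a]
    lb <- karyo$length[karyo$chrom == b]
    new_name <- paste0("fus(", a, "+", b, ")")
    bsel <- map$chrom == b
    bsub <- map[bsel, ][order(map$start[bsel]), ]
    if (orientation == "reverse") {
      bsub <- bsub[rev(seq_len(nrow(bsub))), ]
      piece_len <- bsub$end - bsub$start
      bsub$start <- cumsum(c(0, head(piece_len, -1L)))
      bsub$end <- bsub$start + piece_len
      bsub$strand <- flip_strand(bsub$strand)
    }
    bsub$start <- bsub$start + la
    bsub$end <- bsub$end + la
    bsub$chrom <- new_name
    map$chrom[map$chrom == a] <- new_name
    map <- arrange(bind_rows(map[!bsel, ], bsub), .data$chrom, .data$start)
    sex <- if (any(karyo$sex_class[karyo$chrom %in% c(a, b)] == "Z")) "Z" else "autosome"
    karyo <- karyo[!karyo$chrom %in% c(a, b), ]
    karyo <- bind_rows(karyo, tibble(chrom = new_name, length = la + lb,
                                     sex_class = sex,
                                     species = karyo$species[1]))
    log_row$new_name <- new_name
  } else if (kind == "fission") {
    chrom <- event$chrom
    pos <- event$start
    len <- karyo$length[karyo$chrom == chrom]
    if (length(len) == 0L) abort(paste0("unknown chromosome: ", chrom))
    if (pos <= 0 || pos >= len) abort("fission breakpoint must be internal")
    map <- split_map_at(map, chrom, pos)
    n1 <- paste0(chrom, ".1"); n2 <- paste0(chrom, ".2")
    left <- map$chrom == chrom & map$end <= pos
    right <- map$chrom == chrom & map$start >= pos
    map$chrom[left] <- n1
    map$chrom[right] <- n2
    map$start[map$chrom == n2] <- map$start[map$chrom == n2] - pos
    map$end[map$chrom == n2] <- map$end[map$chrom == n2] - pos
    map <- arrange(map, .data$chrom, .data$start)
    sex <- karyo$sex_class[karyo$chrom == chrom]
    karyo <- karyo[karyo$chrom != chrom, ]
    karyo <- bind_rows(karyo, tibble(
      chrom = c(n1, n2), length = c(pos, len - pos),
      # a Z fission leaves the Z label on the larger fragment
      sex_class = if (sex == "Z") c("Z", "autosome")[order(c(pos, len - pos),
                                                          decreasing = TRUE)]
      else c(sex, sex),
      species = karyo$species[1]
    ))
    log_row$new_name <- n1
  } else {
    abort(paste0("unknown event kind: ", kind))
  }
  state <- new_state(karyo, map)
  attr(state, "log_row") <- log_row
  state
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# draw concrete parameters for one event spec on the current state
draw_event <- function(state, spec, config, used) {
  karyo <- state$karyotype
  if (spec$kind == "inversion") {
    pool <- if (identical(spec$chrom_class, "Z")) {
      karyo$chrom[karyo$sex_class == "Z"]
    } else {
      setdiff(karyo$chrom[karyo$sex_class == "autosome"], used)
    }
    chrom <- if (length(pool) == 1L) pool else sample(pool, 1L)
    len <- karyo$length[karyo$chrom == chrom]
    span <- floor(runif(1, config$inversion_span_range[1],
                        config$inversion_span_range[2]))
    span <- min(span, floor(0.45 * len))
    pc <- spec$position_class
    # class regions are kept disjoint on a chromosome: terminal events sit
    # flush at the right end, subtelomeric on the left flank, interstitial
    # in the middle but clear of the terminal region
    if (pc == "terminal") {
      s <- len - span
    } else if (pc == "subtelomeric") {
      s <- floor(runif(1, 0.03 * len, 0.10 * len))
    } else {
      hi <- len - span - max(0.18 * len, config$inversion_span_range[2] + 2e4)
      lo <- 0.18 * len
      s <- floor(runif(1, lo, max(lo + 1, hi)))
    }
    list(kind = "inversion", chrom = chrom, start = s, end = s + span,
         position_class = pc)
  } else if (spec$kind == "fusion") {
    if (identical(spec$partners, "Z-autosome")) {
      z <- karyo$chrom[karyo$sex_class == "Z"]
      pool <- setdiff(karyo$chrom[karyo$sex_class == "autosome"], used)
      a <- if (length(pool) == 1L) pool else sample(pool, 1L)
      list(kind = "fusion", chrom = a, chrom2 = z,
           orientation = sample(c("forward", "reverse"), 1L))
    } else {
      pool <- setdiff(karyo$chrom[karyo$sex_class == "autosome"], used)
      ab <- sample(pool, 2L)
      list(kind = "fusion", chrom = ab[1], chrom2 = ab[2],
           orientation = sample(c("forward", "reverse"), 1L))
    }
  } else if (spec$kind == "fission") {
    pool <- setdiff(karyo$chrom[karyo$sex_class == "autosome"], used)
    chrom <- if (length(pool) == 1L) pool else sample(pool, 1L)
    len <- karyo$length[karyo$chrom == chrom]
    list(kind = "fission", chrom = chrom,
         start = floor(runif(1, 0.2 * len, 0.8 * len)))
  } else {
    abort(paste0("unknown event kind: ", spec$kind))
  }
}

apply_branch <- function(state, specs, branch, config) {
  log <- NULL
  used <- character()
  for (i in seq_along(specs)) {
    ev <- draw_event(state, specs[[i]], config, used)
    state <- apply_event(state, ev)
    row <- attr(state, "log_row")
    # each chromosome (and each event product) takes part in at most one
    # event per branch, so fusions stay simple and inversions distinct
    used <- c(used, ev$chrom, ev$chrom2, row$new_name)
    row$branch <- branch
    row$step <- i
    log <- bind_rows(log, row)
  }
  list(state = state, log = log)
}

finalize_species <- function(state, species, add_w = FALSE) {
  karyo <- state$karyotype
  ord <- order(-karyo$length, karyo$chrom)
  karyo <- karyo[ord, ]
  is_auto <- karyo$sex_class == "autosome"
  new <- character(nrow(karyo))
  new[is_auto] <- sprintf("%s_%d", species, seq_len(sum(is_auto)))
  new[karyo$sex_class == "Z"] <- paste0(species, "_Z")
  name_map <- tibble(species = species, old = karyo$chrom, new = new)
  map <- state$map
  map$chrom <- name_map$new[match(map$chrom, name_map$old)]
  karyo$chrom <- new
  karyo$species <- species
  if (add_w) {
    zlen <- karyo$length[karyo$sex_class == "Z"]
    karyo <- bind_rows(karyo, tibble(
      chrom = paste0(species, "_W"),
      length = floor(if (length(zlen) == 1L) zlen / 12 else min(karyo$length) / 5),
      sex_class = "W", species = species
    ))
  }
  map <- arrange(map, .data$chrom, .data$start)
  st <- new_state(karyo, map)
  attr(st, "name_map") <- name_map
  st
}

#' Simulate karyotype evolution along the three-taxon tree
#'
#' Draws the ancestor, applies the configured events along the topology
#' `((b, c), a)` — stem events first, then each terminal branch — and
#' finalises extant karyotypes with assembly-style names (chromosomes
#' numbered by descending size, the Z labelled `<species>_Z`). All
#' randomness is governed by the config seed.
#'
#' @param config A [sim_config()].
#' @return A `karyo_sim` object: list with `config`, `ancestor` (state),
#'   `species` (named list of extant states), `log` (the ground-truth
#'   event log with concrete parameters) and `name_maps`.
#' @export
simulate_tree <- function(config) {
  withr::with_seed(config$seed, {
    root <- draw_ancestor(config)
    sp <- config$species
    ev <- config$events
    stem <- apply_branch(root, ev$stem %||% list(), "stem", config)
    res_a <- apply_branch(root, ev[[sp[["a"]]]] %||% list(), sp[["a"]], config)
    res_b <- apply_branch(stem$state, ev[[sp[["b"]]]] %||% list(), sp[["b"]], config)
    res_c <- apply_branch(stem$state, ev[[sp[["c"]]]] %||% list(), sp[["c"]], config)
    states <- list(
      finalize_species(res_a$state, sp[["a"]], config$add_w),
      finalize_species(res_b$state, sp[["b"]], config$add_w),
      finalize_species(res_c$state, sp[["c"]], config$add_w)
    )
    names(states) <- unname(sp)
    log <- bind_rows(stem$log, res_a$log, res_b$log, res_c$log)
    if (is.null(log) || ncol(log) == 0L) {
      log <- tibble(kind = character(), chrom = character(),
                    chrom2 = character(), start = numeric(), end = numeric(),
                    orientation = character(), position_class = character(),
                    new_name = character(), branch = character(),
                    step = integer())
    }
    structure(
      list(config = config, ancestor = root, species = states,
           log = select(log, "branch", "step", "kind", "chrom", "chrom2",
                        "start", "end", "orientation", "position_class",
                        "new_name"),
           name_maps = bind_rows(lapply(states, attr, "name_map"))),
      class = "karyo_sim"
    )
  })
}

#' Replay a ground-truth event log on the ancestor
#'
#' Re-applies the concrete logged events (no randomness involved) to the
#' simulation's ancestor and re-derives the extant coordinate maps. The
#' result must equal the simulation's own maps exactly; this is the
#' simulator's integrity check.
#'
#' @param sim A `karyo_sim` from [simulate_tree()].
#' @return A named list of extant states, finalized like the simulation's.
#' @export
replay_log <- function(sim) {
  sp <- sim$config$species
  replay_branch <- function(state, branch) {
    rows <- sim$log[sim$log$branch == branch, , drop = FALSE]
    if (nrow(rows) > 0L) {
      for (i in seq_len(nrow(rows))) {
        r <- as.list(rows[i, ])
        ev <- list(kind = r$kind, chrom = r$chrom, chrom2 = r$chrom2,
                   start = r$start, end = r$end, orientation = r$orientation,
                   position_class = r$position_class)
        state <- apply_event(state, ev)
      }
    }
    state
  }
  stem <- replay_branch(sim$ancestor, "stem")
  out <- list(
    finalize_species(replay_branch(sim$ancestor, sp[["a"]]), sp[["a"]],
                     sim$config$add_w),
    finalize_species(replay_branch(stem, sp[["b"]]), sp[["b"]],
                     sim$config$add_w),
    finalize_species(replay_branch(stem, sp[["c"]]), sp[["c"]],
                     sim$config$add_w)
  )
  names(out) <- unname(sp)
  out
}

#' @export
print.karyo_sim <- function(x, ...) {
  cat("<karyo_sim> seed", x$config$seed, "\n")
  cat("  ancestor: n =", nrow(x$ancestor$karyotype), "\n")
  for (s in names(x$species)) {
    cat(sprintf("  %s: n = %d, %d Mb\n", s, nrow(x$species[[s]]$karyotype),
                round(sum(x$species[[s]]$karyotype$length) / 1e6)))
  }
  cat("  events:", nrow(x$log), "\n")
  invisible(x)
}

#' Tidy a simulation into its ground-truth event log
#'
#' @param x A `karyo_sim`.
#' @param ... Unused.
#' @return The ground-truth log tibble.
#' @export
tidy.karyo_sim <- function(x, ...) x$log

#' One-row summary of a simulation
#'
#' @param x A `karyo_sim`.
#' @param ... Unused.
#' @export
glance.karyo_sim <- function(x, ...) {
  tibble(
    seed = x$config$seed,
    ancestor_n = nrow(x$ancestor$karyotype),
    n_events = nrow(x$log),
    n_inversions = sum(x$log$kind == "inversion"),
    n_fusions = sum(x$log$kind == "fusion"),
    n_fissions = sum(x$log$kind == "fission"),
    genome_bp = sum(x$ancestor$karyotype$length)
  )
}

#' Events separating two extant species
#'
#' Returns the logged ground-truth events lying on the tree path between
#' two species, i.e. the rearrangements a pairwise comparison of the two
#' genomes should reveal.
#'
#' @param sim A `karyo_sim`.
#' @param sp1,sp2 Two species labels.
#' @return The subset of the ground-truth log on the connecting path.
#' @export
true_events_for_pair <- function(sim, sp1, sp2) {
  sp <- sim$config$species
  branch_sets <- list()
  branch_sets[[sp[["a"]]]] <- c(sp[["a"]], "stem")
  branch_sets[[sp[["b"]]]] <- c(sp[["b"]])
  branch_sets[[sp[["c"]]]] <- c(sp[["c"]])
  # the path between a and either of b/c crosses the stem; between b and c
  # it does not
  path <- if (sp[["a"]] %in% c(sp1, sp2)) {
    other <- setdiff(c(sp1, sp2), sp[["a"]])
    c(sp[["a"]], "stem", other)
  } else {
    c(sp1, sp2)
  }
  sim$log[sim$log$branch %in% path, , drop = FALSE]
}
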