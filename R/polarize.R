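#' Collect rearrangement events from one pairwise comparison
#'
#' Bundles a pair's inversion calls and its fusion/fission relations into a
#' single event table used for cross-pair matching. Inversions carry
#' coordinates on both genomes; fusion and fission events carry chromosome
#' member sets (they are whole-chromosome events, so they are matched by
#' member-set identity, not coordinates).
#'
#' @param inversions Inversion calls for the pair (from
#'   [call_inversions_all()]).
#' @param relations Relations for the pair (from [classify_relations()]).
#' @param query_species,target_species Species labels of the pair.
#' @return An event tibble with attribute `species` recording the pair's
#'   (query, target) species.
#' @export
pair_events <- function(inversions, relations, query_species, target_species) {
  inv <- if (nrow(inversions) > 0L) {
    tibble(
      kind = "inversion",
      query_chrom = inversions$query_chrom,
      query_start = inversions$query_start,
      query_end = inversions$query_end,
      target_chrom = inversions$target_chrom,
      target_start = inversions$target_start,
      target_end = inversions$target_end,
      query_members = map(inversions$query_chrom, identity),
      target_members = map(inversions$target_chrom, identity)
    )
  } else NULL
  interchrom <- relations[relations$kind %in% c("fusion", "fission"), , drop = FALSE]
  ic <- if (nrow(interchrom) > 0L) {
    tibble(
      kind = interchrom$kind,
      query_chrom = NA_character_, query_start = NA_real_, query_end = NA_real_,
      target_chrom = NA_character_, target_start = NA_real_, target_end = NA_real_,
      query_members = interchrom$query_members,
      target_members = interchrom$target_members
    )
  } else NULL
  ev <- bind_rows(inv, ic)
  if (is.null(ev) || ncol(ev) == 0L) {
    ev <- tibble(
      kind = character(),
      query_chrom = character(), query_start = numeric(), query_end = numeric(),
      target_chrom = character(), target_start = numeric(), target_end = numeric(),
      query_members = list(), target_members = list()
    )
  }
  attr(ev, "species") <- c(query = query_species, target = target_species)
  ev
}

# project an event table onto one species' coordinates / member sets
project_events <- function(ev, species) {
  sp <- attr(ev, "species")
  side <- if (identical(unname(sp[["query"]]), species)) "query"
  else if (identical(unname(sp[["target"]]), species)) "target"
  else abort(paste0("species '", species, "' not part of this pair"))
  tibble(
    kind = ev$kind,
    chrom = ev[[paste0(side, "_chrom")]],
    start = ev[[paste0(side, "_start")]],
    end = ev[[paste0(side, "_end")]],
    members = ev[[paste0(side, "_members")]]
  )
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

#' Match rearrangement events across the three pairwise comparisons
#'
#' Events from different pairwise comparisons are identified as the same
#' rearrangement through the species the two comparisons share: inversions
#' must lie on the same chromosome of the shared species and overlap
#' reciprocally by at least `min_reciprocal_overlap`; fusions and fissions
#' must have identical chromosome member sets on the shared species.
#' Matching is transitive (connected components); a call that would join
#' two distinct events of the same comparison raises an ambiguity error.
#'
#' @param events_ab,events_ac,events_bc Event tables from [pair_events()]
#'   for the three pairwise comparisons of a species trio (A-B, A-C, B-C).
#' @param min_reciprocal_overlap Reciprocal-overlap threshold for matching
#'   inversions (default 0.5).
#' @return A presence table: one row per distinct event, with logical
#'   columns `in_ab`, `in_ac`, `in_bc`, the event `kind`, a human-readable
#'   `description`, and attribute `species` naming the trio
#'   `c(a =, b =, c =)`.
#' @export
match_events_across_pairs <- function(events_ab, events_ac, events_bc,
                                      min_reciprocal_overlap = 0.5) {
  sp_ab <- attr(events_ab, "species")
  sp_ac <- attr(events_ac, "species")
  sp_bc <- attr(events_bc, "species")
  a <- intersect(sp_ab, sp_ac)
  b <- intersect(sp_ab, sp_bc)
  c_ <- intersect(sp_ac, sp_bc)
  if (length(a) != 1L || length(b) != 1L || length(c_) != 1L) {
    abort("the three comparisons must pairwise share exactly one species")
  }
  evs <- list(ab = events_ab, ac = events_ac, bc = events_bc)
  shared <- list(c("ab", "ac", a), c("ab", "bc", b), c("ac", "bc", c_))
  sizes <- vapply(evs, nrow, integer(1))
  offset <- c(ab = 0L, ac = sizes[["ab"]], bc = sizes[["ab"]] + sizes[["ac"]])
  n_total <- sum(sizes)
  parent <- seq_len(max(n_total, 1L))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  for (s in shared) {
    p1 <- s[[1]]; p2 <- s[[2]]; spp <- s[[3]]
    if (sizes[[p1]] == 0L || sizes[[p2]] == 0L) next
    pr1 <- project_events(evs[[p1]], spp)
    pr2 <- project_events(evs[[p2]], spp)
    for (i in seq_len(nrow(pr1))) {
      for (j in seq_len(nrow(pr2))) {
        if (pr1$kind[i] != pr2$kind[j]) next
        hit <- if (pr1$kind[i] == "inversion") {
          identical(pr1$chrom[i], pr2$chrom[j]) &&
            reciprocal_overlap(pr1$start[i], pr1$end[i],
                               pr2$start[j], pr2$end[j]) >= min_reciprocal_overlap
        } else {
          identical(sort(pr1$members[[i]]), sort(pr2$members[[j]]))
        }
        if (hit) union_(offset[[p1]] + i, offset[[p2]] + j)
      }
    }
  }
  if (n_total == 0L) {
    out <- tibble(event_id = character(), kind = character(),
                  description = character(),
                  in_ab = logical(), in_ac = logical(), in_bc = logical())
    attr(out, "species") <- c(a = a, b = b, c = c_)
    return(out)
  }
  comp <- vapply(seq_len(n_total), find, integer(1))
  pair_of <- rep(c("ab", "ac", "bc"), sizes)
  # ambiguity: one comparison contributing two calls to one event means a
  # call overlapped two distinct events above threshold
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (anyDuplicated(pair_of[members])) {
      abort(paste0(
        "ambiguous event matching: comparison '",
        pair_of[members][duplicated(pair_of[members])][1L],
        "' contributes multiple calls to one matched event (rows ",
        paste(members, collapse = ", "), ")"
      ))
    }
  }
  all_ev <- bind_rows(
    evs$ab[, c("kind", "query_chrom", "query_members", "target_members")],
    evs$ac[, c("kind", "query_chrom", "query_members", "target_members")],
    evs$bc[, c("kind", "query_chrom", "query_members", "target_members")]
  )
  describe <- function(rows) {
    r <- rows[1L]
    if (all_ev$kind[r] == "inversion") {
      paste0("inversion@", all_ev$query_chrom[r])
    } else {
      paste0(all_ev$kind[r], ":",
             paste(sort(unique(unlist(all_ev$query_members[rows]))), collapse = "+"),
             "->",
             paste(sort(unique(unlist(all_ev$target_members[rows]))), collapse = "+"))
    }
  }
  comp_ids <- unique(comp)
  out <- tibble(
    kind = vapply(comp_ids, function(cc) all_ev$kind[which(comp == cc)[1L]],
                  character(1)),
    description = vapply(comp_ids, function(cc) describe(which(comp == cc)),
                         character(1)),
    in_ab = vapply(comp_ids, function(cc) any(pair_of[comp == cc] == "ab"),
                   logical(1)),
    in_ac = vapply(comp_ids, function(cc) any(pair_of[comp == cc] == "ac"),
                   logical(1)),
    in_bc = vapply(comp_ids, function(cc) any(pair_of[comp == cc] == "bc"),
                   logical(1))
  ) %>%
    arrange(.data$kind, .data$description) %>%
    mutate(event_id = sprintf("ev%02d", row_number())) %>%
    select("event_id", "kind", "description", "in_ab", "in_ac", "in_bc")
  attr(out, "species") <- c(a = a, b = b, c = c_)
  out
}

#' Polarize events onto the branches of a rooted three-taxon tree
#'
#' For a trio with topology `((B, C), A)` and pairwise comparisons A-B,
#' A-C and B-C, a single rearrangement fixed on one terminal branch is
#' visible in exactly the two comparisons involving that species:
#' presence pattern (A-B, A-C, B-C) = (0,1,1) places the event on the C
#' branch, (1,0,1) on the B branch, and (1,1,0) on the path between A and
#' the B/C ancestor. Without an outgroup the last pattern cannot separate
#' the A terminal branch from the internal stem, so it is reported as a
#' single `"<A>_or_stem"` branch. Any other pattern — including presence
#' in all three comparisons, which no single event on a three-taxon tree
#' can produce — is not explicable by one fixed event and is flagged
#' `inconsistent` (for example a polymorphic inversion lost in one
#' lineage, or a mismatched call).
#'
#' @param presence A presence table from [match_events_across_pairs()].
#' @return The presence table with `branch` and `status`
#'   (`fixed`/`inconsistent`) columns added.
#' @export
polarize_events <- function(presence) {
  sp <- attr(presence, "species")
  if (is.null(sp)) sp <- c(a = "A", b = "B", c = "C")
  pat <- paste0(as.integer(presence$in_ab), as.integer(presence$in_ac),
                as.integer(presence$in_bc))
  branch <- dplyr::case_when(
    pat == "011" ~ unname(sp[["c"]]),
    pat == "101" ~ unname(sp[["b"]]),
    pat == "110" ~ paste0(sp[["a"]], "_or_stem"),
    TRUE ~ "unresolved"
  )
  presence$branch <- branch
  presence$status <- ifelse(branch == "unresolved", "inconsistent", "fixed")
  attr(presence, "species") <- sp
  presence
}
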