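#' Compare two assemblies from a pairwise whole-genome alignment
#'
#' The full per-pair pipeline: filter alignment blocks (mapq >= 60,
#' length >= 2 kb by default), aggregate them into a chromosome
#' correspondence matrix, classify homology relations (synteny, fusion,
#' fission), detect neo-Z fusions, call inversions within each homologous
#' pair and classify their chromosomal positions, and score collinearity.
#'
#' @param blocks Alignment blocks (e.g. from [read_paf()] or [sim_paf()]).
#' @param query_karyotype,target_karyotype Karyotypes of the two
#'   assemblies, carrying species labels and sex classes.
#' @param min_mapq,min_length Block filter thresholds (see
#'   [filter_blocks()]).
#' @param min_partner_fraction,min_partner_bp Relation pruning thresholds
#'   (see [classify_relations()]).
#' @param min_blocks,min_span,max_gap Inversion-calling thresholds (see
#'   [call_inversions()]).
#' @param terminal_frac,subtelomeric_frac Position-class cutoffs (see
#'   [classify_position()]); positions are classified on the query side.
#' @param exclude_w Exclude W chromosomes from relation building.
#' @return A `synteny_comparison` object: list with the filtered `blocks`,
#'   `correspondence`, `relations`, `fusion_calls`, `inversions` (with
#'   `position_class`), `collinearity` (per chromosome pair), `stats`
#'   (block-length summary), the two karyotypes and the `species` pair.
#' @export
compare_pair <- function(blocks, query_karyotype, target_karyotype,
                         min_mapq = 60, min_length = 2000,
                         min_partner_fraction = 0.05, min_partner_bp = 1e5,
                         min_blocks = 3, min_span = 5e4, max_gap = 1e6,
                         terminal_frac = 0.02, subtelomeric_frac = 0.15,
                         exclude_w = TRUE) {
  filtered <- filter_blocks(blocks, min_mapq = min_mapq, min_length = min_length)
  corr <- build_correspondence(filtered)
  relations <- classify_relations(
    corr, min_partner_fraction = min_partner_fraction,
    min_partner_bp = min_partner_bp,
    query_karyotype = query_karyotype, target_karyotype = target_karyotype,
    exclude_w = exclude_w
  )
  fusion_calls <- detect_neo_sex(relations, query_karyotype, target_karyotype)
  inversions <- call_inversions_all(filtered, relations,
                                    min_blocks = min_blocks,
                                    min_span = min_span, max_gap = max_gap)
  inversions <- classify_position(inversions, query_karyotype, side = "query",
                                  terminal_frac = terminal_frac,
                                  subtelomeric_frac = subtelomeric_frac)
  pair_key <- paste(filtered$query_name, filtered$target_name, sep = "\r")
  retained <- unlist(purrr::map2(
    relations$query_members, relations$target_members,
    function(q, t) as.vector(outer(q, t, paste, sep = "\r"))
  ))
  groups <- split(filtered, pair_key)
  groups <- groups[names(groups) %in% retained]
  collinearity <- bind_rows(lapply(groups, function(g) {
    ch <- normalize_orientation(g)
    calls <- inversions[inversions$query_chrom == ch$pair[["query"]] &
                          inversions$target_chrom == ch$pair[["target"]], ,
                        drop = FALSE]
    collinearity_report(ch, calls)
  }))
  structure(
    list(
      blocks = filtered,
      correspondence = corr,
      relations = relations,
      fusion_calls = fusion_calls,
      inversions = inversions,
      collinearity = collinearity,
      stats = summarize_blocks(filtered),
      query_karyotype = query_karyotype,
      target_karyotype = target_karyotype,
      species = c(query = query_karyotype$species[1],
                  target = target_karyotype$species[1]),
      params = list(min_mapq = min_mapq, min_length = min_length,
                    min_blocks = min_blocks, min_span = min_span)
    ),
    class = "synteny_comparison"
  )
}

#' @export
print.synteny_comparison <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<synteny_comparison> %s ~ %s\n", x$species[["query"]],
              x$species[["target"]]))
  cat(sprintf("  %d blocks (%.1f Mb aligned)\n", g$n_blocks,
              g$aligned_bp / 1e6))
  cat(sprintf("  relations: %d one-to-one, %d fusion, %d fission, %d complex\n",
              g$n_one_to_one, g$n_fusion, g$n_fission, g$n_complex))
  cat(sprintf("  inversions: %d (%d neo-Z fusion%s)\n", g$n_inversions,
              g$n_neo_z, if (g$n_neo_z == 1) "" else "s"))
  invisible(x)
}

#' Tidy a pairwise comparison into its relations table
#'
#' @param x A `synteny_comparison`.
#' @param ... Unused.
#' @return The relations tibble with member sets flattened to
#'   `+`-separated strings.
#' @export
tidy.synteny_comparison <- function(x, ...) {
  rel <- x$relations
  tibble(
    query = map_chr(rel$query_members, paste, collapse = "+"),
    target = map_chr(rel$target_members, paste, collapse = "+"),
    kind = rel$kind,
    support_bp = rel$support_bp,
    support_fraction = rel$support_fraction
  )
}

#' One-row summary of a pairwise comparison
#'
#' @param x A `synteny_comparison`.
#' @param ... Unused.
#' @export
glance.synteny_comparison <- function(x, ...) {
  tibble(
    n_blocks = nrow(x$blocks),
    aligned_bp = sum(x$blocks$block_length),
    max_block_length = x$stats$max_block_length,
    n_one_to_one = sum(x$relations$kind == "one_to_one"),
    n_fusion = sum(x$relations$kind == "fusion"),
    n_fission = sum(x$relations$kind == "fission"),
    n_complex = sum(x$relations$kind == "complex"),
    n_inversions = nrow(x$inversions),
    n_neo_z = sum(x$fusion_calls$involves_Z),
    median_monotone_fraction = stats::median(x$collinearity$monotone_fraction)
  )
}

#' @export
autoplot.synteny_comparison <- function(object, ...) {
  plot_dotplot(object$blocks, object$query_karyotype, object$target_karyotype,
               highlight = object$inversions, ...)
}

comparison_events <- function(cmp) {
  pair_events(cmp$inversions, cmp$relations,
              cmp$species[["query"]], cmp$species[["target"]])
}

#' Polarize rearrangements from three pairwise comparisons
#'
#' Matches inversion, fusion and fission events across the comparisons
#' A-B, A-C and B-C of a species trio and assigns each to a branch of the
#' rooted topology `((B, C), A)` (see [polarize_events()] for the
#' presence-pattern logic).
#'
#' @param cmp_ab,cmp_ac,cmp_bc `synteny_comparison` objects for the three
#'   pairs, oriented consistently (A as query of the first two, B as query
#'   of the third).
#' @param min_reciprocal_overlap Inversion-matching threshold.
#' @return A placements tibble: `event_id`, `kind`, `description`,
#'   presence flags, `branch`, `status`.
#' @export
polarize_trio <- function(cmp_ab, cmp_ac, cmp_bc, min_reciprocal_overlap = 0.5) {
  presence <- match_events_across_pairs(
    comparison_events(cmp_ab),
    comparison_events(cmp_ac),
    comparison_events(cmp_bc),
    min_reciprocal_overlap = min_reciprocal_overlap
  )
  polarize_events(presence)
}

#' Run the full three-species pipeline on a simulation
#'
#' Emits the three pairwise alignments from a `karyo_sim`, runs
#' [compare_pair()] on each, and polarizes the combined events onto the
#' tree. Convenience wrapper used throughout validation.
#'
#' @param sim A `karyo_sim`.
#' @param ... Passed on to [compare_pair()].
#' @return A `trio_analysis`: list with `comparisons` (named `ab`, `ac`,
#'   `bc`), `placements` and `species`.
#' @export
analyze_trio <- function(sim, ...) {
  sp <- sim$config$species
  k <- lapply(sim$species, `[[`, "karyotype")
  cmp <- function(q, t) {
    compare_pair(sim_paf(sim, q, t), k[[q]], k[[t]], ...)
  }
  ab <- cmp(sp[["a"]], sp[["b"]])
  ac <- cmp(sp[["a"]], sp[["c"]])
  bc <- cmp(sp[["b"]], sp[["c"]])
  structure(
    list(comparisons = list(ab = ab, ac = ac, bc = bc),
         placements = polarize_trio(ab, ac, bc),
         species = sp),
    class = "trio_analysis"
  )
}

#' @export
print.trio_analysis <- function(x, ...) {
  cat("<trio_analysis>", paste(unname(x$species), collapse = " / "), "\n")
  pl <- x$placements
  for (br in unique(pl$branch)) {
    cat(sprintf("  %s: %s\n", br,
                paste(sprintf("%d %s", table(pl$kind[pl$branch == br]),
                              names(table(pl$kind[pl$branch == br]))),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
tidy.trio_analysis <- function(x, ...) x$placements

#' @export
glance.trio_analysis <- function(x, ...) {
  pl <- x$placements
  tibble(
    n_events = nrow(pl),
    n_fixed = sum(pl$status == "fixed"),
    n_inconsistent = sum(pl$status == "inconsistent"),
    n_inversions = sum(pl$kind == "inversion"),
    n_fusions = sum(pl$kind == "fusion"),
    n_fissions = sum(pl$kind == "fission")
  )
}
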