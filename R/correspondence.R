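#' Aggregate filtered blocks into a chromosome correspondence matrix
#'
#' Each alignment block contributes its block length to the cell indexed by
#' its (query chromosome, target chromosome) pair. The resulting long-format
#' matrix quantifies how much aligned sequence supports each candidate
#' chromosome homology.
#'
#' @param blocks A tibble of filtered alignment blocks.
#' @return A tibble with columns `query_chrom`, `target_chrom`,
#'   `aligned_bp`, sorted by descending `aligned_bp`.
#' @export
build_correspondence <- function(blocks) {
  if (nrow(blocks) == 0L) {
    return(tibble(query_chrom = character(), target_chrom = character(),
                  aligned_bp = numeric()))
  }
  blocks %>%
    group_by(query_chrom = .data$query_name, target_chrom = .data$target_name) %>%
    summarise(aligned_bp = sum(.data$block_length), .groups = "drop") %>%
    arrange(desc(.data$aligned_bp), .data$query_chrom, .data$target_chrom)
}

#' Marginal aligned-bp totals of a correspondence matrix
#'
#' @param corr A correspondence tibble from [build_correspondence()].
#' @return A list with named numeric vectors `query` and `target`.
#' @export
correspondence_totals <- function(corr) {
  q <- tapply(corr$aligned_bp, corr$query_chrom, sum)
  t <- tapply(corr$aligned_bp, corr$target_chrom, sum)
  list(query = setNames(as.numeric(q), names(q)),
       target = setNames(as.numeric(t), names(t)))
}

# connected components of a bipartite chromosome graph given edge endpoints;
# returns integer component id per edge
bipartite_components <- function(qnode, tnode) {
  nodes <- c(paste0("q|", unique(qnode)), paste0("t|", unique(tnode)))
  idx <- setNames(seq_along(nodes), nodes)
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  qi <- idx[paste0("q|", qnode)]
  ti <- idx[paste0("t|", tnode)]
  for (e in seq_along(qi)) {
    a <- find(qi[e]); b <- find(ti[e])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(qi, find, integer(1))
  match(roots, unique(roots))
}

#' Classify chromosome homology relations
#'
#' Prunes weak cells of the correspondence matrix as alignment noise, then
#' takes connected components of the remaining bipartite chromosome graph.
#' Component shape determines the relation kind: 1:1 is conserved synteny
#' (`one_to_one`), k:1 means k query chromosomes fused into one target
#' chromosome (`fusion`), 1:k is a `fission`, and anything spanning several
#' chromosomes on both sides is `complex` (a translocation candidate, never
#' silently split).
#'
#' A cell is retained if its aligned bp reaches `min_partner_bp` *or* its
#' fraction of the larger side's marginal total reaches
#' `min_partner_fraction`; cells below both thresholds are pruned.
#' W chromosomes are excluded from relation building by default: the W is
#' tiny and repeat-dominated, so its alignment signal is unreliable.
#'
#' @param corr A correspondence tibble from [build_correspondence()].
#' @param min_partner_fraction Fraction of the larger side's aligned bp a
#'   cell must explain to be retained (default 0.05).
#' @param min_partner_bp Absolute aligned bp sufficient to retain a cell
#'   (default 1e5).
#' @param query_karyotype,target_karyotype Optional karyotypes; needed for
#'   W exclusion and by [detect_neo_sex()].
#' @param exclude_w Drop cells involving a W chromosome before relation
#'   building (default TRUE).
#' @return A tibble of relations with list-columns `query_members` and
#'   `target_members`, plus `kind`, `support_bp`, `support_fraction` and
#'   `n_cells`, ordered by descending support. Attributes `pruned_bp`
#'   (total aligned bp discarded as noise) and `unassigned` (chromosomes
#'   whose every cell was pruned) carry the residuals.
#' @export
classify_relations <- function(corr,
                               min_partner_fraction = 0.05,
                               min_partner_bp = 1e5,
                               query_karyotype = NULL,
                               target_karyotype = NULL,
                               exclude_w = TRUE) {
  if (nrow(corr) == 0L) abort("correspondence matrix is empty")
  if (exclude_w) {
    w_q <- if (!is.null(query_karyotype)) {
      query_karyotype$chrom[query_karyotype$sex_class == "W"]
    } else character()
    w_t <- if (!is.null(target_karyotype)) {
      target_karyotype$chrom[target_karyotype$sex_class == "W"]
    } else character()
    corr <- corr[!(corr$query_chrom %in% w_q | corr$target_chrom %in% w_t), ,
                 drop = FALSE]
  }
  tot <- correspondence_totals(corr)
  larger <- pmax(tot$query[corr$query_chrom], tot$target[corr$target_chrom])
  keep <- corr$aligned_bp >= min_partner_bp |
    corr$aligned_bp / larger >= min_partner_fraction
  pruned_bp <- sum(corr$aligned_bp[!keep])
  kept <- corr[keep, , drop = FALSE]
  unassigned <- bind_rows(
    tibble(side = "query",
           chrom = setdiff(unique(corr$query_chrom), unique(kept$query_chrom))),
    tibble(side = "target",
           chrom = setdiff(unique(corr$target_chrom), unique(kept$target_chrom)))
  )
  if (nrow(kept) == 0L) {
    rel <- tibble(query_members = list(), target_members = list(),
                  kind = character(), support_bp = numeric(),
                  support_fraction = numeric(), n_cells = integer())
    attr(rel, "pruned_bp") <- pruned_bp
    attr(rel, "unassigned") <- unassigned
    return(rel)
  }
  comp <- bipartite_components(kept$query_chrom, kept$target_chrom)
  rel <- kept %>%
    mutate(component = comp) %>%
    group_by(.data$component) %>%
    summarise(
      query_members = list(sort(unique(.data$query_chrom))),
      target_members = list(sort(unique(.data$target_chrom))),
      support_bp = sum(.data$aligned_bp),
      n_cells = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(
      nq = lengths(.data$query_members),
      nt = lengths(.data$target_members),
      kind = dplyr::case_when(
        .data$nq == 1 & .data$nt == 1 ~ "one_to_one",
        .data$nq >= 2 & .data$nt == 1 ~ "fusion",
        .data$nq == 1 & .data$nt >= 2 ~ "fission",
        TRUE ~ "complex"
      ),
      support_fraction = .data$support_bp / pmax(
        map_dbl(.data$query_members, ~ sum(tot$query[.x])),
        map_dbl(.data$target_members, ~ sum(tot$target[.x]))
      )
    ) %>%
    arrange(desc(.data$support_bp), map_chr(.data$query_members, 1)) %>%
    select("query_members", "target_members", "kind",
           "support_bp", "support_fraction", "n_cells")
  if (any(rel$kind == "complex")) {
    warn(paste0(
      sum(rel$kind == "complex"),
      " complex relation(s) (translocation candidates) detected; ",
      "inter-chromosomal signal on both sides is unexpected in clean data"
    ))
  }
  attr(rel, "pruned_bp") <- pruned_bp
  attr(rel, "unassigned") <- unassigned
  rel
}

#' Detect neo-sex chromosomes among fusion relations
#'
#' Turns every fusion relation into a fusion call and flags fusions that
#' involve a Z chromosome: a Z-autosome fusion produces a neo-Z chromosome,
#' a hallmark of sex-chromosome turnover in Lepidoptera. Fusions touching a
#' W chromosome are flagged for manual review (W signal is excluded from
#' relation building by default, so such calls indicate a non-default run).
#'
#' @param relations A relations tibble from [classify_relations()].
#' @param query_karyotype,target_karyotype Karyotypes carrying sex-class
#'   labels for the two assemblies.
#' @return A tibble of fusion calls with `involves_Z`, `involves_W` and a
#'   `label` column (`"neo-Z"` for Z fusions). Empty if there are no
#'   fusion relations.
#' @export
detect_neo_sex <- function(relations, query_karyotype, target_karyotype) {
  fus <- relations[relations$kind == "fusion", , drop = FALSE]
  if (nrow(fus) == 0L) {
    return(tibble(query_members = list(), target_members = list(),
                  support_bp = numeric(), involves_Z = logical(),
                  involves_W = logical(), label = character()))
  }
  sex_of <- function(members, k) k$sex_class[match(members, k$chrom)]
  calls <- fus %>%
    mutate(
      involves_Z = map_lgl(.data$query_members, ~ any(sex_of(.x, query_karyotype) == "Z", na.rm = TRUE)) |
        map_lgl(.data$target_members, ~ any(sex_of(.x, target_karyotype) == "Z", na.rm = TRUE)),
      involves_W = map_lgl(.data$query_members, ~ any(sex_of(.x, query_karyotype) == "W", na.rm = TRUE)) |
        map_lgl(.data$target_members, ~ any(sex_of(.x, target_karyotype) == "W", na.rm = TRUE)),
      label = ifelse(.data$involves_Z, "neo-Z", "autosomal")
    ) %>%
    select("query_members", "target_members", "support_bp",
           "involves_Z", "involves_W", "label")
  if (any(calls$involves_W)) {
    warn("fusion involving a W chromosome: flagged for manual review")
  }
  calls
}
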