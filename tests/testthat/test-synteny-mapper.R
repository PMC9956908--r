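test_that("correspondence accumulates block lengths per chromosome pair", {
  b <- dplyr::bind_rows(
    make_block("qA", target_name = "tB", query_end = 7000),
    make_block("qA", target_name = "tB", query_start = 10000,
               query_end = 13000),
    make_block("qA", target_name = "tC", query_start = 20000,
               query_end = 23000)
  )
  corr <- build_correspondence(b)
  expect_equal(nrow(corr), 2L)
  expect_equal(corr$aligned_bp[corr$target_chrom == "tB"], 10000)
  expect_equal(corr$aligned_bp[corr$target_chrom == "tC"], 3000)

  # 70/30 split by length
  frac <- corr$aligned_bp / sum(corr$aligned_bp)
  expect_equal(sort(frac), c(3 / 13, 10 / 13))
})

test_that("correspondence equals naive dictionary accumulation on random input", {
  b <- random_blocks(1000, n_chrom_q = 6, n_chrom_t = 6, seed = 21)
  corr <- build_correspondence(b)
  oracle <- tapply(b$block_length, paste(b$query_name, b$target_name), sum)
  got <- stats::setNames(corr$aligned_bp,
                         paste(corr$query_chrom, corr$target_chrom))
  expect_equal(got[names(oracle)], stats::setNames(as.numeric(oracle),
                                                   names(oracle)))
  tot <- correspondence_totals(corr)
  expect_equal(sum(tot$query), sum(b$block_length))
  expect_equal(sum(tot$target), sum(b$block_length))
})

make_corr <- function(...) {
  cells <- list(...)
  tibble::tibble(
    query_chrom = vapply(cells, `[[`, character(1), 1),
    target_chrom = vapply(cells, `[[`, character(1), 2),
    aligned_bp = vapply(cells, function(x) as.numeric(x[[3]]), numeric(1))
  )
}

test_that("relation kinds follow component shape", {
  corr <- make_corr(
    list("lig_1", "jur_1", 5e6),                 # one-to-one
    list("lig_2", "aet_5", 3e6),                 # fusion: 2+24 -> 5
    list("lig_24", "aet_5", 2e6),
    list("big_1", "frag_1", 2e6),                # fission: 1 -> 2
    list("big_1", "frag_2", 1.5e6)
  )
  rel <- classify_relations(corr)
  expect_equal(sort(rel$kind), c("fission", "fusion", "one_to_one"))
  fus <- rel[rel$kind == "fusion", ]
  expect_equal(fus$query_members[[1]], c("lig_2", "lig_24"))
  expect_equal(fus$target_members[[1]], "aet_5")
  expect_true(all(rel$support_fraction > 0 & rel$support_fraction <= 1))
})

test_that("a cross-linked component is reported complex, never split", {
  corr <- make_corr(
    list("q1", "t1", 2e6), list("q1", "t2", 1e6), list("q2", "t2", 2e6)
  )
  expect_warning(rel <- classify_relations(corr), "complex")
  expect_equal(rel$kind, "complex")
  expect_equal(rel$query_members[[1]], c("q1", "q2"))
})

test_that("components match an exhaustive graph-traversal oracle", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      nq <- sample(3:8, 1); nt <- sample(3:8, 1)
      cells <- expand.grid(q = paste0("q", 1:nq), t = paste0("t", 1:nt),
                           stringsAsFactors = FALSE)
      cells <- cells[runif(nrow(cells)) < 0.25, ]
      if (nrow(cells) == 0) next
      corr <- tibble::tibble(query_chrom = cells$q, target_chrom = cells$t,
                             aligned_bp = 1e6)
      rel <- suppressWarnings(classify_relations(corr, min_partner_bp = 0,
                                                 min_partner_fraction = 0))
      # oracle: repeated set expansion from each seed edge
      oracle_groups <- list()
      seen <- rep(FALSE, nrow(corr))
      while (any(!seen)) {
        qs <- corr$query_chrom[which(!seen)[1]]
        ts <- character()
        repeat {
          ts2 <- unique(corr$target_chrom[corr$query_chrom %in% qs])
          qs2 <- unique(corr$query_chrom[corr$target_chrom %in% ts2])
          if (setequal(qs2, qs) && setequal(ts2, ts)) break
          qs <- qs2; ts <- ts2
        }
        idx <- corr$query_chrom %in% qs
        seen[idx] <- TRUE
        oracle_groups[[length(oracle_groups) + 1]] <-
          list(q = sort(qs), t = sort(ts))
      }
      got <- lapply(seq_len(nrow(rel)), function(i) {
        list(q = rel$query_members[[i]], t = rel$target_members[[i]])
      })
      key <- function(g) paste(paste(g$q, collapse = ","),
                               paste(g$t, collapse = ","), sep = "|")
      expect_setequal(vapply(got, key, character(1)),
                      vapply(oracle_groups, key, character(1)))
    }
  })
})

test_that("weak cells are pruned and reported, strong cells retained either way", {
  corr <- make_corr(
    list("q1", "t1", 5e6),
    list("q1", "t2", 5e4),   # below both thresholds: pruned
    list("q2", "t2", 4e6),
    list("q3", "t3", 9e4)    # below bp but 100% of its chromosomes: kept
  )
  rel <- classify_relations(corr)
  expect_equal(sort(vapply(rel$query_members, `[[`, character(1), 1)),
               c("q1", "q2", "q3"))
  expect_true(all(rel$kind == "one_to_one"))
  expect_equal(attr(rel, "pruned_bp"), 5e4)
  expect_equal(nrow(attr(rel, "unassigned")), 0L)

  # a chromosome whose only signal is pruned lands in the unassigned report
  corr2 <- make_corr(list("q1", "t1", 5e6), list("q9", "t1", 4e4))
  rel2 <- classify_relations(corr2)
  un <- attr(rel2, "unassigned")
  expect_equal(un$chrom, "q9")
})

test_that("aligned bp is conserved: relations support + pruned = total", {
  b <- random_blocks(500, n_chrom_q = 5, n_chrom_t = 5, seed = 41)
  corr <- build_correspondence(b)
  rel <- suppressWarnings(classify_relations(corr, min_partner_bp = 5e5,
                                             min_partner_fraction = 0.2))
  expect_equal(sum(rel$support_bp) + attr(rel, "pruned_bp"),
               sum(b$block_length))
})

test_that("swapping query and target mirrors fusion into fission", {
  corr <- make_corr(list("a1", "x1", 3e6), list("a2", "x1", 2e6))
  swapped <- tibble::tibble(query_chrom = corr$target_chrom,
                            target_chrom = corr$query_chrom,
                            aligned_bp = corr$aligned_bp)
  rel <- classify_relations(corr)
  rel_sw <- classify_relations(swapped)
  expect_equal(rel$kind, "fusion")
  expect_equal(rel_sw$kind, "fission")
  expect_equal(rel$query_members[[1]], rel_sw$target_members[[1]])
  expect_equal(rel$support_bp, rel_sw$support_bp)
})

test_that("Z-involving fusions are labelled neo-Z; W fusions are flagged", {
  kq <- karyotype(c("lig_12", "lig_Z", "lig_3", "lig_4"),
                  rep(1e6, 4), c("autosome", "Z", "autosome", "autosome"),
                  species = "ligea")
  kt <- karyotype(c("aet_neoZ", "aet_2"), c(2e6, 2e6), c("Z", "autosome"),
                  species = "aethiops")
  corr <- make_corr(
    list("lig_12", "aet_neoZ", 9e5), list("lig_Z", "aet_neoZ", 9e5),
    list("lig_3", "aet_2", 9e5), list("lig_4", "aet_2", 9e5)
  )
  rel <- classify_relations(corr, query_karyotype = kq, target_karyotype = kt)
  calls <- detect_neo_sex(rel, kq, kt)
  expect_equal(nrow(calls), 2L)
  z <- calls[calls$involves_Z, ]
  expect_equal(z$label, "neo-Z")
  expect_equal(z$query_members[[1]], c("lig_12", "lig_Z"))
  expect_false(any(calls$involves_W))
  expect_equal(calls$label[!calls$involves_Z], "autosomal")

  # no fusions at all -> empty call set
  rel1 <- classify_relations(make_corr(list("lig_3", "aet_2", 9e5)))
  expect_equal(nrow(detect_neo_sex(rel1, kq, kt)), 0L)
})

test_that("W chromosomes are excluded from relation building by default", {
  kq <- karyotype(c("a_1", "a_W"), c(1e6, 1e5), c("autosome", "W"), "sp1")
  kt <- karyotype(c("b_1", "b_2"), c(1e6, 1e6), "autosome", "sp2")
  corr <- make_corr(list("a_1", "b_1", 9e5), list("a_W", "b_2", 9e5))
  rel <- classify_relations(corr, query_karyotype = kq, target_karyotype = kt)
  expect_equal(nrow(rel), 1L)
  expect_equal(rel$query_members[[1]], "a_1")
  rel_w <- classify_relations(corr, query_karyotype = kq,
                              target_karyotype = kt, exclude_w = FALSE)
  expect_equal(nrow(rel_w), 2L)
})

test_that("simulated sub-threshold and spurious noise never creates fusion partners", {
  sim <- simulate_tree(tiny_config(seed = 9))
  noisy <- list(n_low_mapq = 40L, n_short = 40L, n_offdiag = 15L,
                offdiag_length_range = c(2000, 20000))
  blocks <- sim_paf(sim, "jurtina", "ligea", noise = noisy)
  cmp <- compare_pair(blocks, sim$species$jurtina$karyotype,
                      sim$species$ligea$karyotype)
  expect_equal(sort(unique(cmp$relations$kind)), "one_to_one")
  expect_equal(nrow(cmp$relations), 6L)
})
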