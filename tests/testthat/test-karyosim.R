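test_that("simulation is deterministic under the seed and sensitive to it", {
  s1 <- simulate_tree(tiny_config(seed = 5))
  s2 <- simulate_tree(tiny_config(seed = 5))
  expect_identical(s1$log, s2$log)
  expect_identical(s1$species$aethiops$map, s2$species$aethiops$map)
  expect_identical(sim_paf(s1, "ligea", "aethiops"),
                   sim_paf(s2, "ligea", "aethiops"))
  s3 <- simulate_tree(tiny_config(seed = 6))
  expect_false(identical(s1$ancestor$karyotype$length,
                         s3$ancestor$karyotype$length))
})

test_that("ancestral chromosomes respect the configured count and length range", {
  for (seed in 1:15) {
    cfg <- tiny_config(seed = seed)
    anc <- simulate_ancestor(cfg)
    expect_equal(nrow(anc$karyotype), 6L)
    expect_true(all(anc$karyotype$length >= cfg$chrom_length_range[1] &
                      anc$karyotype$length <= cfg$chrom_length_range[2]))
    expect_equal(sum(anc$karyotype$sex_class == "Z"), 1L)
  }
  tiny2 <- simulate_ancestor(sim_config(seed = 1, ancestor_n = 2))
  expect_equal(nrow(tiny2$karyotype), 2L)
})

test_that("events conserve genome length and maps stay a valid tiling", {
  sim <- simulate_tree(tiny_config(seed = 3))
  total_anc <- sum(sim$ancestor$karyotype$length)
  for (sp in names(sim$species)) {
    st <- sim$species[[sp]]
    expect_equal(sum(st$karyotype$length[st$karyotype$sex_class != "W"]),
                 total_anc)
    m <- dplyr::arrange(st$map, chrom, start)
    for (ch in unique(m$chrom)) {
      p <- m[m$chrom == ch, ]
      expect_equal(p$start[1], 0)
      expect_equal(p$end[nrow(p)],
                   st$karyotype$length[st$karyotype$chrom == ch])
      if (nrow(p) > 1) expect_equal(p$start[-1], p$end[-nrow(p)])
      expect_equal(p$end - p$start, p$anc_end - p$anc_start)
    }
  }
})

test_that("apply_event handles fusion, fission and inversion edge cases", {
  anc <- simulate_ancestor(tiny_config(seed = 1))
  a <- anc$karyotype$chrom[1]; b <- anc$karyotype$chrom[2]
  la <- anc$karyotype$length[1]; lb <- anc$karyotype$length[2]

  fused <- apply_event(anc, list(kind = "fusion", chrom = a, chrom2 = b,
                                 orientation = "reverse"))
  new <- attr(fused, "log_row")$new_name
  expect_equal(fused$karyotype$length[fused$karyotype$chrom == new], la + lb)
  expect_error(apply_event(anc, list(kind = "fusion", chrom = a, chrom2 = a)),
               "itself")

  expect_error(apply_event(anc, list(kind = "inversion", chrom = a,
                                     start = 100, end = 100)),
               "zero-length")
  expect_error(apply_event(anc, list(kind = "inversion", chrom = a,
                                     start = 0, end = la + 1)),
               "outside")

  inv1 <- apply_event(anc, list(kind = "inversion", chrom = a,
                                start = 1e5, end = 3e5))
  expect_false(identical(inv1$map, anc$map))
  inv2 <- apply_event(inv1, list(kind = "inversion", chrom = a,
                                 start = 1e5, end = 3e5))
  m1 <- dplyr::arrange(inv2$map, chrom, start)
  m0 <- dplyr::arrange(anc$map, chrom, start)
  # inverting twice restores the ancestral mapping (modulo piece boundaries)
  expect_true(all(m1$strand == "+"))
  expect_equal(sum(m1$end - m1$start), sum(m0$end - m0$start))

  fis <- apply_event(anc, list(kind = "fission", chrom = a, start = 2e5))
  expect_equal(sort(fis$karyotype$length[grepl(a, fis$karyotype$chrom,
                                               fixed = TRUE)]),
               sort(c(2e5, la - 2e5)))
  expect_error(apply_event(anc, list(kind = "fission", chrom = a, start = 0)),
               "internal")
})

test_that("replaying the ground-truth log reproduces the extant maps exactly", {
  for (seed in c(1, 7, 13)) {
    sim <- simulate_tree(tiny_config(seed = seed))
    re <- replay_log(sim)
    for (sp in names(sim$species)) {
      expect_identical(sim$species[[sp]]$map, re[[sp]]$map)
      expect_identical(sim$species[[sp]]$karyotype, re[[sp]]$karyotype)
    }
  }
})

test_that("logged event counts per branch equal the configuration", {
  sim <- simulate_tree(sim_config(seed = 4))
  ev <- satyrine_events()
  counts <- table(sim$log$branch)
  expect_equal(unname(counts[["stem"]]), length(ev$stem))
  expect_equal(unname(counts[["aethiops"]]), length(ev$aethiops))
  expect_false("ligea" %in% names(counts))
  # no events -> three identical karyotypes
  null_sim <- simulate_tree(sim_config(
    seed = 4, ancestor_n = 5,
    events = list(stem = list(), jurtina = list(), ligea = list(),
                  aethiops = list())
  ))
  expect_equal(null_sim$species$jurtina$karyotype$length,
               null_sim$species$aethiops$karyotype$length)
  expect_equal(nrow(null_sim$log), 0L)
})

test_that("emitted alignments are valid PAF content with configured block sizes", {
  sim <- simulate_tree(tiny_config(seed = 10))
  b <- sim_paf(sim, "jurtina", "aethiops")
  expect_silent(validate_blocks(b))
  rng <- sim$config$block_size_range
  expect_true(all(b$block_length >= rng[1] & b$block_length <= rng[2]))
  expect_true(all(b$mapq == 60))
  # round-trip through the PAF format
  tmp <- withr::local_tempfile(fileext = ".paf")
  write_paf(b, tmp)
  expect_equal(nrow(read_paf(tmp)), nrow(b))
})

test_that("a single planted inversion yields exactly one reversed run, zero noise", {
  ev <- list(stem = list(), jurtina = list(),
             ligea = list(list(kind = "inversion", chrom_class = "autosome",
                               position_class = "interstitial")),
             aethiops = list())
  sim <- simulate_tree(sim_config(seed = 12, ancestor_n = 4, events = ev))
  b <- sim_paf(sim, "jurtina", "ligea")
  chroms <- split(b, paste(b$query_name, b$target_name))
  calls <- dplyr::bind_rows(lapply(chroms, function(g) {
    call_inversions(normalize_orientation(g))
  }))
  expect_equal(nrow(calls), 1L)
  truth <- sim$log[sim$log$kind == "inversion", ]
  # recovered with high reciprocal overlap against the planted interval
  ov <- min(calls$target_end, truth$end) - max(calls$target_start, truth$start)
  expect_gte(ov / (truth$end - truth$start), 0.9)
  expect_gte(ov / (calls$target_end - calls$target_start), 0.9)
})

test_that("noise-only alignments vanish at the standard filter thresholds", {
  sim <- simulate_tree(tiny_config(seed = 14))
  noisy <- sim_paf(sim, "jurtina", "ligea",
                   noise = list(n_low_mapq = 30L, n_short = 30L,
                                n_offdiag = 0L))
  clean <- sim_paf(sim, "jurtina", "ligea",
                   noise = list(n_low_mapq = 0L, n_short = 0L, n_offdiag = 0L))
  expect_equal(nrow(noisy), nrow(clean) + 60L)
  f <- filter_blocks(noisy)
  expect_equal(nrow(f), nrow(clean))
  expect_true(all(f$mapq >= 60 & f$block_length >= 2000))
})

test_that("emitted genome sequences agree with emitted alignment coordinates", {
  sim <- simulate_tree(sim_config(
    seed = 20, ancestor_n = 3, chrom_length_range = c(4e4, 6e4),
    block_size_range = c(2000, 8000), gap_max = 2000,
    inversion_span_range = c(12000, 15000),
    events = list(stem = list(), jurtina = list(),
                  ligea = list(list(kind = "inversion",
                                    chrom_class = "autosome",
                                    position_class = "interstitial")),
                  aethiops = list())
  ))
  anc_seq <- sim_ancestor_seq(sim)
  qs <- sim_genome_seq(sim, "jurtina", anc_seq)
  ts <- sim_genome_seq(sim, "ligea", anc_seq)
  b <- sim_paf(sim, "jurtina", "ligea")
  expect_gt(nrow(b), 10)
  for (i in seq_len(nrow(b))) {
    q <- substring(qs[b$query_name[i]], b$query_start[i] + 1, b$query_end[i])
    t <- substring(ts[b$target_name[i]], b$target_start[i] + 1, b$target_end[i])
    if (b$strand[i] == "-") t <- synkaryo:::revcomp(t)
    expect_identical(unname(q), unname(t))
  }
})

test_that("true_events_for_pair returns the events on the connecting path", {
  sim <- simulate_tree(tiny_config(seed = 16))
  jl <- true_events_for_pair(sim, "jurtina", "ligea")
  expect_setequal(unique(jl$branch), "stem")
  bc <- true_events_for_pair(sim, "ligea", "aethiops")
  expect_setequal(unique(bc$branch), "aethiops")
  ja <- true_events_for_pair(sim, "jurtina", "aethiops")
  expect_setequal(unique(ja$branch), c("stem", "aethiops"))
})

test_that("simulation outputs write to standard text formats", {
  sim <- simulate_tree(tiny_config(seed = 18))
  dir <- withr::local_tempdir()
  write_sim_outputs(sim, dir)
  files <- list.files(dir)
  expect_true(all(c("jurtina.fai", "ligea_aethiops.paf", "ground_truth.json",
                    "config.yaml") %in% files))
  k <- load_karyotype(file.path(dir, "ligea.fai"),
                      sex_labels = c(ligea_Z = "Z"), species = "ligea")
  expect_identical(k$length, sim$species$ligea$karyotype$length)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(length(gt), nrow(sim$log))
})
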