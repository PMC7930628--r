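test_that("fragment count follows the closed form and depth is conserved", {
  ref <- synthetic_reference()
  fr <- sample_fragments(ref, coverage = 100, fragment_length = 110, seed = 1)
  expect_equal(nrow(fr), round(100 * 16569 / 110))  # 15063
  expect_equal(nrow(fr), 15063L)
  # mean fragment-level depth ~ coverage, by brute-force pileup
  d <- oracle_depth(fr$start, fr$length, ref$length)
  expect_lt(abs(mean(d) / 100 - 1), 0.02)
  # single-fragment limit
  toy <- make_toy_ref(16569)
  f1 <- sample_fragments(toy, coverage = 110 / 16569, fragment_length = 110,
                         seed = 2)
  expect_equal(nrow(f1), 1L)
  expect_error(sample_fragments(toy, coverage = 0), "positive")
  expect_error(sample_fragments(toy, 1, fragment_length = 10,
                                min_fragment = 30), "min_fragment")
})

test_that("fragments spanning the origin keep depth continuous at the wrap", {
  toy <- make_toy_ref(500, seed = 3)
  fr <- sample_fragments(toy, coverage = 200, fragment_length = 110, seed = 4)
  d <- oracle_depth(fr$start, fr$length, toy$length)
  # no discontinuity at the origin relative to overall variation
  edge <- mean(d[c(496:500, 1:5)])
  expect_lt(abs(edge / mean(d) - 1), 0.2)
  # fragments that start near the end do wrap
  expect_true(any(fr$start + fr$length - 1L > toy$length))
})

test_that("damage is a no-op at zero rate and saturates at rate one", {
  seqs <- c("CCCCCCCCCCCCCCCC", "GGGGGGGGGGGGGGGG", "ATATATATATATATAT")
  p0 <- damage_params(0, 0)
  expect_equal(apply_damage(seqs, p0, seed = 1)$seqs, seqs)
  p1 <- damage_params(1, 1, decay = 1, window = 12)
  out <- apply_damage(seqs, p1, seed = 1)
  # every C in the first 12 bases -> T; every G in the last 12 -> A
  expect_equal(substr(out$seqs[1], 1, 12), strrep("T", 12))
  expect_equal(substr(out$seqs[1], 13, 16), "CCCC")
  expect_equal(substr(out$seqs[2], 5, 16), strrep("A", 12))
  expect_equal(substr(out$seqs[2], 1, 4), "GGGG")
  expect_equal(out$seqs[3], seqs[3])  # no eligible bases
})

test_that("damage rates match the geometric model by binomial counting", {
  n <- 10000
  seqs <- rep(strrep("C", 30), n)
  out <- apply_damage(seqs, damage_params(0.3, 0, decay = 0.5), seed = 9)
  m <- out$events
  r0 <- sum(m$offset == 0L) / n
  r3 <- sum(m$offset == 3L) / n
  se0 <- sqrt(0.30 * 0.70 / n)
  se3 <- sqrt(0.0375 * (1 - 0.0375) / n)
  expect_lt(abs(r0 - 0.30), 3 * se0)
  expect_lt(abs(r3 - 0.0375), 3 * se3)
})

test_that("only C>T (5') and G>A (3') damage events ever occur", {
  ref <- make_toy_ref(2000, seed = 5)
  hap <- apply_variants(ref, random_snp_set(ref, 10, seed = 6))
  cfg <- simulation_config(ref, endogenous_haplotype = hap, coverage = 30,
                           contamination_rate = 0.1, error_rate = 0, seed = 7)
  sim <- simulate_dataset(cfg)
  ev <- sim$damage_events
  expect_true(all(ev$original %in% c("C", "G")))
  expect_true(all(paste0(ev$original, ">", ev$observed) %in% c("C>T", "G>A")))
  expect_true(all(ev$end[ev$original == "C"] == "5p"))
  expect_true(all(ev$end[ev$original == "G"] == "3p"))
})

test_that("NumtS decoys hit the requested divergence and degenerate cases", {
  ref <- synthetic_reference()
  d0 <- generate_numts_decoys(ref, 1, mean_divergence = 0, seed = 1)
  expect_equal(d0$n_edits, 0L)
  expect_equal(d0$sequence, circular_substr_test(ref, d0$source_start, d0$length))

  d <- generate_numts_decoys(ref, 5, mean_divergence = 0.03,
                             length_range = c(500, 2000), seed = 2)
  expect_equal(nrow(d), 5L)
  for (i in 1:5) {
    obs <- d$n_edits[i] / d$length[i]
    se <- sqrt(0.03 * 0.97 / d$length[i])
    expect_lt(abs(obs - 0.03), 3 * se)
  }
  expect_equal(nrow(generate_numts_decoys(ref, 0)), 0L)
  expect_error(generate_numts_decoys(ref, 1, mean_divergence = 0.5), "0.2")
})

test_that("truth allele fractions follow the design composition", {
  ref <- make_toy_ref(3000, seed = 11)
  v <- random_snp_set(ref, 12, seed = 12)
  hap <- apply_variants(ref, v)
  # homoplasmic with 2% contamination -> expected AF ~ 0.98
  s1 <- simulate_dataset(simulation_config(ref, endogenous_haplotype = hap,
                                           coverage = 50,
                                           contamination_rate = 0.02,
                                           seed = 13))
  expect_equal(nrow(s1$truth$variants), 12L)
  expect_equal(unique(s1$truth$variants$expected_af), 0.98, tolerance = 0.01)
  # 30:70 mixture with 2% contamination -> expected AF ~ 0.294
  s2 <- simulate_dataset(simulation_config(
    ref, mixture = list(haplotype = hap, fraction = 0.30),
    coverage = 50, contamination_rate = 0.02, seed = 14))
  expect_equal(unique(s2$truth$variants$expected_af), 0.294, tolerance = 0.01)
})

test_that("identical config and seed give byte-identical FASTQ", {
  ref <- make_toy_ref(2000, seed = 21)
  cfg <- simulation_config(ref, coverage = 10, contamination_rate = 0.05,
                           seed = 99)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fastq"); f2 <- file.path(d, "b.fastq")
  write_fastq(simulate_dataset(cfg), f1)
  write_fastq(simulate_dataset(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and FASTQ round trip preserves the reads
  rt <- read_fastq(f1)
  sim <- simulate_dataset(cfg)
  expect_equal(rt$sequence, sim$reads$sequence)
  expect_equal(rt$qualities, sim$reads$qualities)
})

test_that("contaminant alleles appear at about the contamination rate", {
  ref <- make_toy_ref(3000, seed = 31)
  cont <- apply_variants(ref, random_snp_set(ref, 8, seed = 32))
  cfg <- simulation_config(ref, contaminant_haplotype = cont, coverage = 60,
                           contamination_rate = 0.10, damage = NULL,
                           error_rate = 0, seed = 33)
  sim <- simulate_dataset(cfg)
  al <- map_reads(sim$reads, ref)
  al$retained <- al$mapped
  pu <- build_pileup(al, sim$reads, ref)
  v <- cont$variants
  for (i in seq_len(nrow(v))) {
    p <- v$position[i]
    af <- pu$counts[p, v$alt_allele[i]] / pu$depth[p]
    se <- sqrt(0.1 * 0.9 / pu$depth[p])
    expect_lt(abs(af - 0.10), 3 * se + 1e-9)
  }
})
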