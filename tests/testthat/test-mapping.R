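test_that("exact reads map uniquely with MQ 37; origin-spanners stay whole", {
  ref <- make_toy_ref(2000, seed = 1)
  r1 <- substr(ref$sequence, 1, 101)
  # read spanning the origin (start near the end of the circle)
  r2 <- circular_substr_test(ref, 1950L, 101L)
  reads <- toy_reads_tbl(c(r1, r2))
  al <- map_reads(reads, ref)
  expect_equal(al$start, c(1L, 1950L))
  expect_equal(al$mismatches, c(0L, 0L))
  expect_equal(al$mapq, c(37L, 37L))
  expect_equal(al$n_best, c(1L, 1L))
  expect_equal(al$strand, c("+", "+"))
})

test_that("admission contract rejects short, low-quality and degenerate reads", {
  ref <- make_toy_ref(2000, seed = 1)
  good <- substr(ref$sequence, 10, 110)
  reads <- tibble::tibble(
    id = c("short", "lowq", "alln", "ok"),
    sequence = c(substr(good, 1, 20), good, strrep("N", 101), good),
    qualities = c(strrep("I", 20), strrep("5", 101),  # '5' = Q20
                  strrep("I", 101), strrep("I", 101)))
  al <- map_reads(reads, ref)
  expect_equal(al$reject_reason[1:3], c("too_short", "low_quality", "degenerate"))
  expect_true(al$mapped[4])
})

test_that("a read from a zero-divergence decoy ties and gets MQ 0", {
  ref <- make_toy_ref(2000, seed = 2)
  dec <- generate_numts_decoys(ref, 1, mean_divergence = 0, seed = 3)
  rd <- substr(dec$sequence[1], 1, 101)
  al <- map_reads(toy_reads_tbl(rd), ref, decoys = dec)
  expect_gte(al$n_best[1], 2L)
  expect_equal(al$mapq[1], 0L)
})

test_that("the mapper equals the brute-force minimum-mismatch oracle", {
  withr::with_seed(77, {
    ref <- make_toy_ref(1200, seed = 78, name = "MT")
    dec <- generate_numts_decoys(ref, 2, mean_divergence = 0.05,
                                 length_range = c(200, 400), seed = 79)
    targets <- c(list(list(name = "MT", sequence = ref$sequence)),
                 lapply(seq_len(nrow(dec)), function(i) {
                   list(name = dec$name[i], sequence = dec$sequence[i])
                 }))
    circ <- c(TRUE, FALSE, FALSE)
    reads <- character(40)
    for (i in 1:40) {
      src <- sample(3, 1)
      len <- sample(c(40, 60, 101), 1)
      maxs <- if (circ[src]) nchar(targets[[src]]$sequence)
              else nchar(targets[[src]]$sequence) - len + 1
      s <- sample(maxs, 1)
      rd <- if (circ[src]) {
        circular_substr_test(list(sequence = targets[[src]]$sequence), s, len)
      } else {
        substr(targets[[src]]$sequence, s, s + len - 1)
      }
      v <- strsplit(rd, "")[[1]]
      k <- sample(0:5, 1)
      if (k > 0) {
        at <- sample(len, k)
        v[at] <- sample(c("A", "C", "G", "T"), k, TRUE)
      }
      rd <- paste(v, collapse = "")
      if (runif(1) < 0.5) rd <- rc1(rd)
      reads[i] <- rd
    }
    al <- map_reads(toy_reads_tbl(reads), ref, decoys = dec,
                    min_length = 30, min_mean_bq = 30)
    for (i in 1:40) {
      o <- oracle_map(reads[i], targets, circ)
      expect_identical(al$mismatches[i], o$mismatches, label = paste("mm read", i))
      if (!is.na(o$mismatches)) {
        expect_identical(al$n_best[i], o$n_best, label = paste("n_best read", i))
        expect_identical(al$second_best_mismatches[i], o$second,
                         label = paste("second read", i))
        if (o$n_best == 1L) {
          expect_identical(al$start[i], o$best$start, label = paste("start", i))
          expect_identical(al$target[i], o$best$target)
          expect_identical(al$strand[i], o$best$strand)
        }
      }
    }
  })
})

test_that("deduplication keeps one representative per placement", {
  ref <- make_toy_ref(1000, seed = 5)
  s <- substr(ref$sequence, 100, 200)
  reads <- tibble::tibble(
    id = c("b", "a", "c", "d"),
    sequence = c(s, s, s, substr(ref$sequence, 100, 190)),
    qualities = c(strrep("I", 101), strrep("I", 101), strrep("H", 101),
                  strrep("I", 91)))
  al <- deduplicate(map_reads(reads, ref), reads)
  # same (start,end,strand): a and b tie on quality -> "a" wins; c lower
  expect_equal(sort(al$read_id[!al$duplicate]), c("a", "d"))
  # same start, different end -> both kept
  expect_false(al$duplicate[al$read_id == "d"])
})

test_that("deduplication matches a hash-grouping oracle on random input", {
  ref <- make_toy_ref(300, seed = 6)
  withr::with_seed(7, {
    n <- 30
    starts <- sample(10, n, TRUE)  # force collisions
    strands <- sample(c("+", "-"), n, TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      s <- circular_substr_test(ref, starts[i], 60L)
      if (strands[i] == "-") rc1(s) else s
    }, character(1))
    reads <- toy_reads_tbl(seqs)
    al <- deduplicate(map_reads(reads, ref, min_length = 30), reads)
    groups <- paste(al$target, al$start, al$strand)
    expect_equal(sum(!al$duplicate[al$mapped]),
                 length(unique(groups[al$mapped])))
  })
})

test_that("ambiguity filtering removes decoy-best, ties and close seconds", {
  ref <- make_toy_ref(2000, seed = 8)
  al <- tibble::tibble(
    read_id = c("uniq", "tie", "dec", "close", "lowq"),
    mapped = TRUE, reject_reason = NA_character_,
    target = c("toy", "toy", "numt_01", "toy", "toy"),
    start = 1:5, strand = "+",
    mismatches = c(0L, 0L, 0L, 1L, 0L),
    mapq = c(37L, 0L, 37L, 37L, 20L),
    n_best = c(1L, 2L, 1L, 1L, 1L),
    second_best_mismatches = c(NA, 0L, NA, 1L, NA))
  out <- filter_ambiguous(al, mt_name = "toy")
  expect_equal(out$retained, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$removed_reason[2:5],
               c("tie", "decoy-best", "suboptimal-close", "low-mapq"))
  # monotone in delta: decreasing delta never removes more reads
  r0 <- sum(filter_ambiguous(al, delta = 0, mt_name = "toy")$retained)
  r1 <- sum(filter_ambiguous(al, delta = 1, mt_name = "toy")$retained)
  expect_gte(r0, r1)
})

test_that("no NumtS read survives the unique-mapping filter in simulation", {
  ref <- make_toy_ref(4000, seed = 9)
  cfg <- simulation_config(
    ref, coverage = 15,
    numts = list(count = 2, divergence = 0.03, length_range = c(400, 800),
                 coverage = 5),
    seed = 10)
  sim <- simulate_dataset(cfg)
  expect_gt(sum(sim$reads$true_source == "numts"), 0)
  al <- map_reads(sim$reads, ref, decoys = sim$decoys)
  al <- deduplicate(al, sim$reads)
  al <- filter_ambiguous(al, mt_name = ref$name)
  src <- sim$reads$true_source[match(al$read_id, sim$reads$id)]
  expect_true(all(src[al$retained] != "numts"))
  # and on a NumtS-free simulation nothing is lost to ambiguity
  cfg2 <- simulation_config(ref, coverage = 10, seed = 11)
  sim2 <- simulate_dataset(cfg2)
  al2 <- filter_ambiguous(deduplicate(map_reads(sim2$reads, ref), sim2$reads),
                          mt_name = ref$name)
  expect_equal(sum(al2$removed_reason %in%
                     c("tie", "decoy-best", "suboptimal-close")), 0L)
})

test_that("damage-profile estimation recovers the configured rates", {
  ref <- make_toy_ref(4000, seed = 12)
  cfg <- simulation_config(ref, coverage = 100,
                           damage = damage_params(0.3, 0.3, decay = 0.5),
                           seed = 13)
  sim <- simulate_dataset(cfg)
  al <- filter_ambiguous(deduplicate(map_reads(sim$reads, ref), sim$reads),
                         mt_name = ref$name)
  prof <- estimate_damage_profile(al, sim$reads, ref)
  se <- sqrt(0.3 * 0.7 / prof$n5_C[1])
  expect_lt(abs(prof$rate5_CT[1] - 0.3), 3 * se + 0.01)
  # strand symmetry: forward-only and reverse-only profiles agree
  pf <- estimate_damage_profile(al[al$strand %in% "+" | !al$retained, ],
                                sim$reads, ref)
  pr <- estimate_damage_profile(al[al$strand %in% "-" | !al$retained, ],
                                sim$reads, ref)
  expect_lt(abs(pf$rate5_CT[1] - pr$rate5_CT[1]),
            4 * sqrt(0.3 * 0.7 * (1 / pf$n5_C[1] + 1 / pr$n5_C[1])))
  # undamaged simulation: null profile at about error_rate / 3
  cfg0 <- simulation_config(ref, coverage = 60, damage = NULL, seed = 14)
  sim0 <- simulate_dataset(cfg0)
  al0 <- filter_ambiguous(deduplicate(map_reads(sim0$reads, ref), sim0$reads),
                          mt_name = ref$name)
  p0 <- estimate_damage_profile(al0, sim0$reads, ref)
  expect_lt(max(p0$rate5_CT, na.rm = TRUE), 0.01)
})

test_that("quality rescaling follows the closed form and never raises quality", {
  ref <- mt_reference(paste0("C", strrep("A", 99)), name = "m")
  # read with T over reference C at offset 0, Q30 everywhere
  rd <- paste0("T", strrep("A", 49))
  reads <- toy_reads_tbl(rd, q = 30L)
  al <- tibble::tibble(read_id = "r001", mapped = TRUE,
                       reject_reason = NA_character_, target = "m",
                       start = 1L, strand = "+", mismatches = 1L,
                       mapq = 37L, n_best = 1L,
                       second_best_mismatches = NA_integer_, retained = TRUE)
  prof <- tibble::tibble(offset = 0:11, rate5_CT = c(0.3, rep(0, 11)),
                         n5_C = 100L, rate3_GA = 0, n3_G = 100L)
  out <- rescale_qualities(reads, al, prof, ref)
  q <- utf8ToInt(out$qualities) - 33L
  # -10*log10(0.3 + 10^-3) = 5.21... -> floor 5
  expect_equal(q[1], 5L)
  expect_equal(q[-1], rep(30L, 49))  # non-mismatching bases untouched
  # d = 0 leaves qualities unchanged
  prof0 <- prof; prof0$rate5_CT <- 0
  expect_equal(rescale_qualities(reads, al, prof0, ref)$qualities,
               reads$qualities)
  # rescaling never raises any quality on simulated data
  toy <- make_toy_ref(2000, seed = 15)
  cfg <- simulation_config(toy, coverage = 20, seed = 16)
  sim <- simulate_dataset(cfg)
  alm <- filter_ambiguous(deduplicate(map_reads(sim$reads, toy), sim$reads),
                          mt_name = toy$name)
  pr <- estimate_damage_profile(alm, sim$reads, toy)
  rs <- rescale_qualities(sim$reads, alm, pr, toy)
  before <- unlist(lapply(sim$reads$qualities, utf8ToInt))
  after <- unlist(lapply(rs$qualities, utf8ToInt))
  expect_true(all(after <= before))
})

test_that("SAM text round-trips the alignment and read fields", {
  ref <- make_toy_ref(1000, seed = 17)
  cfg <- simulation_config(ref, coverage = 5, seed = 18)
  sim <- simulate_dataset(cfg)
  al <- deduplicate(map_reads(sim$reads, ref), sim$reads)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(al, sim$reads, ref, f)
  back <- read_sam(f)
  m <- al[al$mapped, ]
  expect_equal(back$alignments$read_id, m$read_id)
  expect_equal(back$alignments$start, m$start)
  expect_equal(back$alignments$strand, m$strand)
  expect_equal(back$alignments$mismatches, m$mismatches)
  expect_equal(back$alignments$duplicate, m$duplicate)
  expect_equal(back$reads$sequence,
               sim$reads$sequence[match(m$read_id, sim$reads$id)])
})
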