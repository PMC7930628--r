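mini_ref <- function() mt_reference(strrep("ACGT", 25), name = "m")

# alignments tibble for hand-built reads, all plus strand, retained
mini_al <- function(n, start = 1L) {
  tibble::tibble(read_id = sprintf("r%03d", seq_len(n)), mapped = TRUE,
                 reject_reason = NA_character_, target = "m",
                 start = rep(start, n), strand = "+", mismatches = 0L,
                 mapq = 37L, n_best = 1L,
                 second_best_mismatches = NA_integer_, retained = TRUE)
}

test_that("pileup counts respect depth, wrap and the base-quality floor", {
  ref <- mini_ref()
  # 3 reads covering position 1..20, all reference
  rd <- substr(ref$sequence, 1, 20)
  reads <- toy_reads_tbl(rep(rd, 3), q = 30L)
  pu <- build_pileup(mini_al(3), reads, ref)
  expect_equal(pu$depth[1:20], rep(3L, 20))
  expect_equal(unname(pu$counts[1, "A"]), 3L)
  expect_equal(sum(pu$counts[1, ]), pu$depth[1])
  st <- tibble::as_tibble(pu)
  expect_equal(nrow(st[st$position == 1, ]), 1L)  # one allele only

  # a base below min_bq is excluded from DP
  reads2 <- toy_reads_tbl(rd, q = 30L)
  q <- reads2$qualities
  substr(q, 5, 5) <- intToUtf8(19 + 33)  # Q19 < 20
  reads2$qualities <- q
  pu2 <- build_pileup(mini_al(1), reads2, ref)
  expect_equal(pu2$depth[5], 0L)
  expect_equal(pu2$depth[4], 1L)

  # circular wrap: a read over the origin contributes to both ends
  rdw <- circular_substr_test(ref, 95L, 10L)
  puw <- build_pileup(mini_al(1, start = 95L), toy_reads_tbl(rdw, q = 30L), ref)
  expect_equal(puw$depth[c(95, 100, 1, 4)], rep(1L, 4))

  # empty alignment set -> empty pileup, not an error
  pu0 <- build_pileup(mini_al(0), toy_reads_tbl(character(0)), ref)
  expect_equal(sum(pu0$depth), 0L)
})

test_that("candidate calling emits strong signals and suppresses null sites", {
  ref <- mini_ref()
  # 100 reads over 1..20; 50 carry C at position 1 (ref A)
  rd_ref <- substr(ref$sequence, 1, 20)
  rd_alt <- paste0("C", substr(ref$sequence, 2, 20))
  reads <- toy_reads_tbl(c(rep(rd_ref, 50), rep(rd_alt, 50)), q = 30L)
  pu <- build_pileup(mini_al(100), reads, ref)
  calls <- call_variants(pu)
  hit <- calls[calls$position == 1, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$AF, 0.5)
  expect_equal(hit$AD, 50L)
  expect_equal(hit$RD, 50L)
  expect_gt(hit$lod, 10)
  # 0 alt reads -> no candidate at other positions
  expect_equal(nrow(calls[calls$position == 2, ]), 0L)
})

test_that("lod agrees with a direct two-hypothesis likelihood to 1e-9", {
  ref <- mini_ref()
  withr::with_seed(5, {
    for (rep in 1:5) {
      n_alt <- sample(1:10, 1)
      n_ref <- 20 - n_alt
      quals <- sample(20:38, 20, TRUE)
      rd <- substr(ref$sequence, 1, 10)
      alt <- paste0("T", substr(rd, 2, 10))  # ref at pos 1 is A
      reads <- tibble::tibble(
        id = sprintf("r%03d", 1:20),
        sequence = c(rep(alt, n_alt), rep(rd, n_ref)),
        qualities = vapply(quals, function(q) {
          paste(rep(intToUtf8(q + 33), 10), collapse = "")
        }, character(1)))
      pu <- build_pileup(mini_al(20), reads, ref, min_bq = 0)
      calls <- call_variants(pu)
      got <- calls[calls$position == 1 & calls$alt_allele == "T", ]
      # independent oracle: direct likelihood evaluation over the 20 bases
      e <- 10^(-quals / 10)
      af <- n_alt / 20
      isalt <- c(rep(TRUE, n_alt), rep(FALSE, n_ref))
      p_alt <- ifelse(isalt, 1 - e, e / 3)
      p_ref <- ifelse(isalt, e / 3, 1 - e)
      lod <- sum(log10((af * p_alt + (1 - af) * p_ref) / p_ref))
      if (lod >= 0) {
        expect_equal(got$lod, lod, tolerance = 1e-9)
      } else {
        expect_equal(nrow(got), 0L)
      }
    }
  })
})

test_that("call filters tag low AF, contamination, position and strand bias", {
  base <- tibble::tibble(
    position = 1:5, ref_allele = "A", alt_allele = "G",
    AD = c(4L, 8L, 40L, 60L, 30L), RD = c(96L, 392L, 60L, 40L, 70L),
    DP = c(100L, 400L, 100L, 100L, 100L),
    AF = c(0.04, 0.02, 0.4, 0.6, 0.3), lod = c(5, 5, 50, 80, -1),
    alt_fwd = c(2L, 4L, 40L, 30L, 15L), alt_rev = c(2L, 4L, 0L, 30L, 15L),
    ref_fwd = c(48L, 196L, 0L, 20L, 35L), ref_rev = c(48L, 196L, 60L, 20L, 35L),
    median_end_distance = c(30, 30, 2, 30, 30), vclass = "SNP")
  out <- apply_call_filters(base, cr = 0.02)
  expect_match(out$filters[1], "low_af")
  expect_match(out$filters[2], "contamination")  # AF 0.02 at cr 0.02, DP 400
  expect_match(out$filters[3], "position_bias")
  expect_match(out$filters[3], "strand_bias")    # one-strand alt, extreme table
  expect_equal(out$filters[4], "PASS")
  expect_match(out$filters[5], "weak_evidence")
  # majority allele never tagged as contamination even at high cr
  out2 <- apply_call_filters(base[4, ], cr = 0.7)
  expect_false(grepl("contamination", out2$filters))
  # tags never flip to PASS when more filters engage
  out3 <- apply_call_filters(base, cr = 0.3)
  was_tagged <- out$filters != "PASS"
  expect_true(all(out3$filters[was_tagged] != "PASS"))
})

test_that("variant normalization is idempotent, left-aligning and splitting", {
  ref <- mt_reference("TTAACCCGGT", name = "m")
  snp <- tibble::tibble(position = 2L, ref_allele = "T", alt_allele = "G")
  expect_equal(normalize_variants(snp, ref), snp)
  # insertion in the CCC homopolymer (positions 5-7): any representation
  # left-aligns to position 4
  ins <- tibble::tibble(position = 7L, ref_allele = "C", alt_allele = "CC")
  out <- normalize_variants(ins, ref)
  expect_equal(out$position, 4L)
  expect_equal(out$ref_allele, "A")
  expect_equal(out$alt_allele, "AC")
  # exhaustive-shift oracle: all placements of the same insertion normalize
  # to the same record
  for (p in 5:7) {
    o <- normalize_variants(
      tibble::tibble(position = p, ref_allele = "C", alt_allele = "CC"), ref)
    expect_equal(o, out)
  }
  # trailing-base representation reduces to a minimal SNP
  mnp <- tibble::tibble(position = 2L, ref_allele = "TA", alt_allele = "GA")
  expect_equal(normalize_variants(mnp, ref)$ref_allele, "T")
  # biallelic record splits into two records sharing DP
  bi <- tibble::tibble(position = 2L, ref_allele = "T", alt_allele = "G,C",
                       DP = 50L)
  sp <- normalize_variants(bi, ref)
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$DP, c(50L, 50L))
  expect_setequal(sp$alt_allele, c("G", "C"))
  # inconsistent reference allele is an error
  expect_error(
    normalize_variants(tibble::tibble(position = 2L, ref_allele = "A",
                                      alt_allele = "G"), ref),
    "inconsistent")
})

test_that("VCF writing and reading round-trip the call fields", {
  skip_if_not_installed("vcfR")
  ref <- mini_ref()
  calls <- tibble::tibble(
    position = c(10L, 20L, 30L), ref_allele = c("C", "A", "G"),
    alt_allele = c("T", "G", "A"), AD = c(40L, 12L, 5L),
    RD = c(60L, 80L, 90L), DP = c(100L, 95L, 99L),
    AF = c(0.4, 0.126316, 0.050505),
    filters = c("PASS", "contamination", "low_af;strand_bias"))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, "s1", f, ref = ref)
  back <- read_vcf(f)
  expect_equal(back$position, calls$position)
  expect_equal(back$ref_allele, calls$ref_allele)
  expect_equal(back$alt_allele, calls$alt_allele)
  expect_equal(back$AD, calls$AD)
  expect_equal(back$RD, calls$RD)
  expect_equal(back$DP, calls$DP)
  expect_equal(back$AF, calls$AF, tolerance = 1e-6)
  expect_equal(back$filters, calls$filters)
  # zero calls -> valid header-only VCF
  f0 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls[0, ], "s1", f0, ref = ref)
  expect_equal(nrow(read_vcf(f0)), 0L)
})

test_that("an externally produced minimal VCF is ingested for filtering", {
  skip_if_not_installed("vcfR")
  back <- read_vcf(test_path("external_minimal.vcf"))
  expect_equal(nrow(back), 3L)
  expect_equal(back$position, c(152L, 3107L, 8860L))
  expect_equal(back$AD, c(95L, 2L, 48L))
  expect_equal(back$DP, c(100L, 50L, 100L))
  tagged <- apply_call_filters(
    dplyr::mutate(back, lod = 10, alt_fwd = 1L, alt_rev = 1L,
                  ref_fwd = 1L, ref_rev = 1L, median_end_distance = 30),
    cr = 0)
  expect_match(tagged$filters[2], "low_af")
})
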