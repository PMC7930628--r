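# Shared fixtures and independent oracles, built in code.

# small random circular reference
make_toy_ref <- function(n = 2000, seed = 42, name = "toy") {
  withr::with_seed(seed, {
    mt_reference(paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
                 name = name)
  })
}

toy_reads_tbl <- function(seqs, q = 35L) {
  tibble::tibble(
    id = sprintf("r%03d", seq_along(seqs)),
    sequence = seqs,
    qualities = vapply(nchar(seqs),
                       function(n) paste(rep(intToUtf8(q + 33L), n),
                                         collapse = ""),
                       character(1)))
}

rc1 <- function(s) paleomt::revcomp(s)

# brute-force minimum-mismatch mapping oracle over all placements on both
# strands of all targets (circular targets scanned over the doubled copy)
oracle_map <- function(read, targets, circular, max_mismatch = 4L) {
  best <- max_mismatch + 1L; second <- max_mismatch + 1L; nbest <- 0L
  b <- list(target = NA_character_, start = NA_integer_, strand = NA_character_)
  for (t in seq_along(targets)) {
    seqt <- targets[[t]]$sequence
    L <- nchar(seqt)
    scan <- if (circular[t]) paste0(seqt, seqt) else seqt
    rl <- nchar(read)
    nst <- if (circular[t]) L else L - rl + 1L
    if (nst < 1) next
    for (strand in c("+", "-")) {
      rd <- if (strand == "+") read else rc1(read)
      rv <- strsplit(rd, "")[[1]]
      for (s in seq_len(nst)) {
        tv <- strsplit(substring(scan, s, s + rl - 1L), "")[[1]]
        mm <- sum(tv != rv | rv == "N")
        if (mm > max_mismatch) next
        if (mm < best) {
          second <- best; best <- mm; nbest <- 1L
          b <- list(target = targets[[t]]$name, start = s, strand = strand)
        } else if (mm == best) {
          nbest <- nbest + 1L; second <- mm
        } else if (mm < second) {
          second <- mm
        }
      }
    }
  }
  list(mismatches = if (best > max_mismatch) NA_integer_ else best,
       n_best = nbest,
       second = if (second > max_mismatch) NA_integer_ else second,
       best = b)
}

# brute-force pileup depth by counting fragment coverage on the circle
oracle_depth <- function(starts, lens, L) {
  d <- integer(L)
  for (i in seq_along(starts)) {
    p <- ((starts[i] - 1L + seq_len(lens[i]) - 1L) %% L) + 1L
    d[p] <- d[p] + 1L
  }
  d
}

# brute-force per-site confusion classification
oracle_confusion <- function(test, refs, L, excl = integer(0)) {
  test <- test[!test$position %in% excl, ]
  refs <- refs[!refs$position %in% excl, ]
  tp <- fp <- fn <- 0L
  for (p in seq_len(L)) {
    tv <- test$alt_allele[test$position == p]
    rv <- refs$alt_allele[refs$position == p]
    if (length(tv) && length(rv)) {
      if (tv == rv) tp <- tp + 1L else fp <- fp + 1L
    } else if (length(tv)) {
      fp <- fp + 1L
    } else if (length(rv)) {
      fn <- fn + 1L
    }
  }
  c(TP = tp, TN = L - tp - fp - fn, FP = fp, FN = fn)
}

# independent circular substring (avoids the package's own helper)
circular_substr_test <- function(ref, start, len) {
  dbl <- paste0(ref$sequence, ref$sequence)
  substring(dbl, start, start + len - 1L)
}

empty_calls_tbl <- function() {
  tibble::tibble(position = integer(0), ref_allele = character(0),
                 alt_allele = character(0), vclass = character(0))
}

metric_cols_test <- function() {
  c("PPV", "SN", "SPC", "FNR", "FPR", "NPV", "FDR", "FOR", "ACC")
}

# synthetic tagged call set spanning the AD/AF/DP grid (for pattern tests)
acc_homo_calls_fixture <- function() {
  withr::with_seed(202, {
    n <- 60
    dp <- sample(c(2:6, 9:12, 19:25, 80:120), n, TRUE)
    ad <- pmin(pmax(1L, as.integer(round(dp * runif(n, 0.02, 1)))), dp)
    tibble::tibble(
      position = sort(sample(16569L, n)),
      ref_allele = sample(c("A", "C", "G", "T"), n, TRUE),
      alt_allele = NA_character_, AD = ad, RD = dp - ad, DP = dp,
      AF = ad / dp, lod = runif(n, 1, 40), alt_fwd = ad, alt_rev = 0L,
      ref_fwd = 0L, ref_rev = dp - ad, median_end_distance = 30,
      filters = sample(c("PASS", "PASS", "PASS", "low_af"), n, TRUE),
      vclass = "SNP") |>
      dplyr::rowwise() |>
      dplyr::mutate(alt_allele = sample(setdiff(c("A", "C", "G", "T"),
                                                .data$ref_allele), 1)) |>
      dplyr::ungroup()
  })
}
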