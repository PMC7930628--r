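# Ancient-DNA read simulator with ground truth.
#
# Emulates single-end sequencing of short aDNA fragments: fixed-length
# fragments drawn uniformly from the circular genome, terminal cytosine
# deamination (C>T at the 5' end, G>A at the 3' end of the molecule as
# sequenced, double-stranded library semantics), undamaged present-day
# contaminant reads mixed in at a configured rate, an optional second
# endogenous haplotype for heteroplasmy designs, and NumtS-like nuclear
# decoy reads. Reads are emitted adapter-free and pre-trimmed.

#' Deamination damage parameters
#'
#' Damage probability at offset `i` (0-based) from the relevant read end is
#' `delta_max * decay^i` for `i < window`, else 0. Alternatively a
#' per-position rate table (`rate5`, `rate3` vectors of length `window`)
#' can be supplied to mimic an empirical misincorporation profile.
#'
#' @param delta5_max probability of C>T at the first 5' base.
#' @param delta3_max probability of G>A at the last 3' base.
#' @param decay per-base geometric decay factor in (0, 1].
#' @param window bases considered deaminated at each end (default 12).
#' @param rate5,rate3 optional explicit per-offset rate vectors overriding
#'   the geometric model.
#' @return an object of class `damage_params`.
#' @export
damage_params <- function(delta5_max = 0.3, delta3_max = 0.3, decay = 0.5,
                          window = 12L, rate5 = NULL, rate3 = NULL) {
  stopifnot(delta5_max >= 0, delta5_max <= 1, delta3_max >= 0,
            delta3_max <= 1, decay > 0, decay <= 1, window >= 0)
  window <- as.integer(window)
  r5 <- rate5 %||% (delta5_max * decay^(seq_len(window) - 1))
  r3 <- rate3 %||% (delta3_max * decay^(seq_len(window) - 1))
  stopifnot(length(r5) == window, length(r3) == window,
            all(r5 >= 0 & r5 <= 1), all(r3 >= 0 & r3 <= 1))
  structure(list(delta5_max = delta5_max, delta3_max = delta3_max,
                 decay = decay, window = window, rate5 = r5, rate3 = r3,
                 library = "double-stranded"),
            class = "damage_params")
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions this package benchmarks:
#' single-end 101 bp reads from fixed 110 bp fragments at 100-fold
#' endogenous coverage, 12 bp deamination windows, and a present-day
#' (undamaged) contaminant drawn from the reference haplotype.
#'
#' @param reference an [mt_reference()].
#' @param endogenous_haplotype an `mt_haplotype` (from [apply_variants()]); defaults to the plain
#'   reference.
#' @param contaminant_haplotype an `mt_haplotype` (from [apply_variants()]); defaults to the plain
#'   reference (present-day human contaminant).
#' @param mixture optional `list(haplotype =, fraction =)` second endogenous
#'   haplotype for heteroplasmy designs (e.g. fraction 0.30 for a 30:70
#'   mixture).
#' @param coverage endogenous fold coverage in fragments (default 100).
#' @param fragment_length fixed fragment length in bp (default 110).
#' @param min_fragment minimum admissible fragment length (default 30).
#' @param read_length machine read length (default 101).
#' @param contamination_rate fraction of fragments from the contaminant, in
#'   `[0, 1)`.
#' @param numts optional `list(count =, divergence =, length_range =,
#'   coverage =)` NumtS-like decoy configuration.
#' @param damage a [damage_params()] object, or `NULL` for no damage.
#' @param error_rate per-base sequencing substitution probability
#'   (default 1e-3, Phred 30).
#' @param seed integer seed; every stochastic stage derives from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(reference,
                              endogenous_haplotype = NULL,
                              contaminant_haplotype = NULL,
                              mixture = NULL,
                              coverage = 100,
                              fragment_length = 110L,
                              min_fragment = 30L,
                              read_length = 101L,
                              contamination_rate = 0,
                              numts = NULL,
                              damage = damage_params(),
                              error_rate = 1e-3,
                              seed = 1L) {
  stopifnot(coverage > 0, contamination_rate >= 0, contamination_rate < 1,
            read_length >= 1, fragment_length >= min_fragment)
  if (!is.null(mixture)) {
    stopifnot(is.list(mixture), inherits(mixture$haplotype, "mt_haplotype"),
              mixture$fraction > 0, mixture$fraction < 1)
  }
  structure(
    list(reference = reference,
         endogenous_haplotype =
           endogenous_haplotype %||% apply_variants(reference, mt_variants(integer(0), character(0), character(0))),
         contaminant_haplotype =
           contaminant_haplotype %||% apply_variants(reference, mt_variants(integer(0), character(0), character(0))),
         mixture = mixture, coverage = coverage,
         fragment_length = as.integer(fragment_length),
         min_fragment = as.integer(min_fragment),
         read_length = as.integer(read_length),
         contamination_rate = contamination_rate,
         numts = numts, damage = damage, error_rate = error_rate,
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Sample fragments from a (circular) haplotype
#'
#' Fragment count is `round(coverage * genome_length / fragment_length)`;
#' start positions are uniform on the circle and strands uniform. With a
#' fixed-length model shorter-than-minimum fragments cannot arise; the
#' check guards degenerate configurations.
#'
#' @param haplotype an `mt_haplotype` (from [apply_variants()]) (or `mt_reference`).
#' @param coverage fold coverage (fragment-based).
#' @param fragment_length fixed fragment length.
#' @param min_fragment minimum admissible length.
#' @param seed integer seed.
#' @return tibble with `start` (1-based on the source sequence), `length`,
#'   `strand`.
#' @export
sample_fragments <- function(haplotype, coverage, fragment_length = 110L,
                             min_fragment = 30L, seed = 1L) {
  if (coverage <= 0) abort("coverage must be positive")
  if (fragment_length < min_fragment) {
    abort("fragment model produces only fragments below min_fragment")
  }
  glen <- if (inherits(haplotype, "mt_reference")) haplotype$length
          else nchar(haplotype$sequence)
  n <- round(coverage * glen / fragment_length)
  withr::with_seed(seed, {
    tibble(start = sample.int(glen, n, replace = TRUE),
           length = rep(as.integer(fragment_length), n),
           strand = sample(c("+", "-"), n, replace = TRUE))
  })
}

# fragment sequences in molecule (as-sequenced) orientation
fragment_seqs <- function(sequence, fragments) {
  dbl <- paste0(sequence, sequence)
  s <- substring(dbl, fragments$start, fragments$start + fragments$length - 1L)
  neg <- fragments$strand == "-"
  s[neg] <- revcomp(s[neg])
  s
}

#' Apply terminal deamination damage to fragments
#'
#' Fragments are given in as-sequenced orientation. Only cytosines within
#' the 5' window can become T and only guanines within the 3' window can
#' become A; nothing else ever changes, so depurination-type G>T artifacts
#' are structurally impossible.
#'
#' @param seqs character vector of equal-length fragment sequences.
#' @param params a [damage_params()] object.
#' @param seed integer seed.
#' @return list with `seqs` (damaged sequences) and `events` tibble
#'   (`fragment`, `offset` 0-based from the relevant end, `end`,
#'   `original`, `observed`).
#' @export
apply_damage <- function(seqs, params, seed = 1L) {
  n <- length(seqs)
  if (n == 0 || is.null(params)) {
    return(list(seqs = seqs, events = damage_events_empty()))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    out <- seqs
    evl <- vector("list", 0)
    for (L in unique(lens)) {
      i <- which(lens == L)
      r <- apply_damage(seqs[i], params, derive_seed(seed, L))
      out[i] <- r$seqs
      ev <- r$events; ev$fragment <- i[ev$fragment]
      evl[[length(evl) + 1]] <- ev
    }
    return(list(seqs = out,
                events = if (length(evl)) dplyr::bind_rows(evl)
                         else damage_events_empty()))
  }
  L <- lens[1]
  w <- min(params$window, L)
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = n, ncol = L, byrow = TRUE)
  ev <- vector("list", 2 * w)
  withr::with_seed(seed, {
    for (j in seq_len(w)) {
      hit <- m[, j] == "C" & runif(n) < params$rate5[j]
      if (any(hit)) {
        m[hit, j] <- "T"
        ev[[j]] <- tibble(fragment = which(hit), offset = j - 1L,
                          end = "5p", original = "C", observed = "T")
      }
    }
    for (j in seq_len(w)) {
      col <- L - j + 1L
      hit <- m[, col] == "G" & runif(n) < params$rate3[j]
      if (any(hit)) {
        m[hit, col] <- "A"
        ev[[w + j]] <- tibble(fragment = which(hit), offset = j - 1L,
                              end = "3p", original = "G", observed = "A")
      }
    }
  })
  ev <- ev[!vapply(ev, is.null, logical(1))]
  list(seqs = collapse_rows(m),
       events = if (length(ev)) dplyr::bind_rows(ev) else damage_events_empty())
}

damage_events_empty <- function() {
  tibble(fragment = integer(0), offset = integer(0), end = character(0),
         original = character(0), observed = character(0))
}

#' Generate NumtS-like nuclear decoy sequences
#'
#' Each decoy is a contiguous segment of the mitochondrial reference with
#' random substitutions at the stated divergence, mimicking a nuclear copy
#' of mitochondrial origin.
#'
#' @param ref an [mt_reference()].
#' @param count number of decoys.
#' @param mean_divergence per-base substitution probability in (0, 0.2)
#'   (0 allowed for the maximally confounding identical decoy).
#' @param length_range integer length range, e.g. `c(500, 2000)`.
#' @param seed integer seed.
#' @return tibble with `name`, `source_start`, `length`, `n_edits`,
#'   `edits` (list of positions within the decoy), `sequence`.
#' @export
generate_numts_decoys <- function(ref, count, mean_divergence = 0.03,
                                  length_range = c(500L, 2000L), seed = 1L) {
  if (count == 0) {
    return(tibble(name = character(0), source_start = integer(0),
                  length = integer(0), n_edits = integer(0),
                  edits = list(), sequence = character(0)))
  }
  if (mean_divergence < 0 || mean_divergence >= 0.2) {
    abort("mean_divergence must be in [0, 0.2)")
  }
  withr::with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], count, replace = TRUE)
    starts <- sample.int(ref$length, count, replace = TRUE)
    seqs <- character(count)
    nedit <- integer(count)
    edits <- vector("list", count)
    for (i in seq_len(count)) {
      chars <- seq_chars(circular_substr(ref, starts[i], lens[i]))
      k <- rbinom(1, lens[i], mean_divergence)
      p <- sample(which(chars != "N"), min(k, sum(chars != "N")))
      for (j in p) chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1)
      seqs[i] <- paste(chars, collapse = "")
      nedit[i] <- length(p)
      edits[[i]] <- sort(p)
    }
    tibble(name = sprintf("numt_%02d", seq_len(count)),
           source_start = starts, length = lens, n_edits = nedit,
           edits = edits, sequence = seqs)
  })
}

#' Simulate an aDNA sequencing dataset with full ground truth
#'
#' Draws fragments from the endogenous haplotype(s), the contaminant and
#' any NumtS decoys; applies deamination damage to ancient molecules
#' (endogenous, mixture and decoy reads -- the present-day contaminant is
#' left undamaged); truncates fragments to the read length; applies uniform
#' per-base sequencing errors; and emits Phred+33 qualities (Q30 perturbed
#' by up to 2). Fully reproducible from the config seed.
#'
#' @param config a [simulation_config()].
#' @return an object of class `mt_simulation`: a list with `reads` (tibble:
#'   `id`, `sequence`, `qualities`, `true_source`, `true_frag_start`,
#'   `true_map_start`, `true_strand`), `truth` (list with `variants` tibble
#'   carrying `expected_af`, and `placements`), `decoys`, `damage_events`,
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ref <- config$reference
  rl <- config$read_length
  fl <- config$fragment_length
  n_total <- round(config$coverage * ref$length / fl)
  n_cont <- round(n_total * config$contamination_rate)
  n_endo <- n_total - n_cont
  n_mix <- if (is.null(config$mixture)) 0L else round(n_endo * config$mixture$fraction)
  n_endoA <- n_endo - n_mix

  sources <- list(
    list(name = "endogenous", hap = config$endogenous_haplotype,
         n = n_endoA, damaged = TRUE),
    list(name = "mixture", hap = config$mixture$haplotype, n = n_mix,
         damaged = TRUE),
    list(name = "contaminant", hap = config$contaminant_haplotype,
         n = n_cont, damaged = FALSE))

  reads_l <- list()
  events_l <- list()
  stage <- 0L
  for (src in sources) {
    stage <- stage + 1L
    if (is.null(src$hap) || src$n == 0) next
    glen <- nchar(src$hap$sequence)
    frags <- withr::with_seed(derive_seed(config$seed, stage), {
      tibble(start = sample.int(glen, src$n, replace = TRUE),
             length = rep(fl, src$n),
             strand = sample(c("+", "-"), src$n, replace = TRUE))
    })
    seqs <- fragment_seqs(src$hap$sequence, frags)
    if (src$damaged && !is.null(config$damage)) {
      d <- apply_damage(seqs, config$damage, derive_seed(config$seed, 10L + stage))
      seqs <- d$seqs
      if (nrow(d$events)) {
        d$events$source <- src$name
        events_l[[length(events_l) + 1]] <- d$events
      }
    }
    rlen <- min(rl, fl)
    seqs <- substr(seqs, 1L, rlen)
    # leftmost genome coordinate of the sequenced window
    map_start <- ifelse(frags$strand == "+", frags$start,
                        frags$start + frags$length - rlen)
    map_start <- ((map_start - 1L) %% glen) + 1L
    reads_l[[length(reads_l) + 1]] <- tibble(
      sequence = seqs, true_source = src$name,
      true_frag_start = frags$start, true_map_start = as.integer(map_start),
      true_strand = frags$strand)
  }

  decoys <- if (!is.null(config$numts) && (config$numts$count %||% 0) > 0) {
    generate_numts_decoys(ref, config$numts$count,
                          config$numts$divergence %||% 0.03,
                          config$numts$length_range %||% c(500L, 2000L),
                          derive_seed(config$seed, 20L))
  } else {
    generate_numts_decoys(ref, 0)
  }
  if (nrow(decoys)) {
    ncov <- config$numts$coverage %||% 5
    n_dec <- round(ncov * sum(decoys$length) / fl)
    dfr <- withr::with_seed(derive_seed(config$seed, 21L), {
      di <- sample.int(nrow(decoys), n_dec, replace = TRUE,
                       prob = decoys$length)
      st <- vapply(di, function(i) {
        sample.int(max(decoys$length[i] - fl + 1L, 1L), 1L)
      }, integer(1))
      tibble(decoy = di, start = st,
             strand = sample(c("+", "-"), n_dec, replace = TRUE))
    })
    seqs <- substring(decoys$sequence[dfr$decoy], dfr$start,
                      dfr$start + fl - 1L)
    neg <- dfr$strand == "-"
    seqs[neg] <- revcomp(seqs[neg])
    d <- apply_damage(seqs, config$damage, derive_seed(config$seed, 22L))
    seqs <- substr(d$seqs, 1L, min(rl, fl))
    reads_l[[length(reads_l) + 1]] <- tibble(
      sequence = seqs, true_source = "numts",
      true_frag_start = dfr$start, true_map_start = NA_integer_,
      true_strand = dfr$strand)
  }

  reads <- dplyr::bind_rows(reads_l)
  n <- nrow(reads)
  reads$id <- sprintf("rd%06d", seq_len(n))

  # sequencing errors: uniform substitution to one of the 3 alternatives
  rlen <- min(rl, fl)
  withr::with_seed(derive_seed(config$seed, 30L), {
    m <- matrix(unlist(strsplit(reads$sequence, "", fixed = TRUE),
                       use.names = FALSE), nrow = n, ncol = rlen, byrow = TRUE)
    err <- matrix(runif(n * rlen) < config$error_rate, n, rlen) & m != "N"
    if (any(err)) {
      shift <- sample.int(3L, sum(err), replace = TRUE)
      bases <- c("A", "C", "G", "T")
      cur <- match(m[err], bases)
      m[err] <- bases[((cur - 1L + shift) %% 4L) + 1L]
    }
    reads$sequence <- collapse_rows(m)
    q0 <- as.integer(round(-10 * log10(max(config$error_rate, 1e-4))))
    qm <- matrix(q0 + sample(-2:2, n * rlen, replace = TRUE), n, rlen)
    reads$qualities <- collapse_rows(
      matrix(intToUtf8(t(qm) + 33L, multiple = TRUE), n, rlen, byrow = TRUE))
  })

  truth_variants <- truth_variant_table(config, n_endoA, n_mix, n_cont, n_total)
  reads <- reads[, c("id", "sequence", "qualities", "true_source",
                     "true_frag_start", "true_map_start", "true_strand")]
  structure(
    list(reads = reads,
         truth = list(variants = truth_variants,
                      placements = reads[, c("id", "true_source",
                                             "true_map_start", "true_strand")]),
         decoys = decoys,
         damage_events = if (length(events_l)) dplyr::bind_rows(events_l)
                         else damage_events_empty(),
         config = config),
    class = "mt_simulation")
}

# expected AF per truth site from the fragment composition
truth_variant_table <- function(config, n_endoA, n_mix, n_cont, n_total) {
  haps <- list(list(h = config$endogenous_haplotype, f = n_endoA / n_total),
               list(h = config$mixture$haplotype, f = n_mix / n_total),
               list(h = config$contaminant_haplotype, f = n_cont / n_total))
  rows <- list()
  for (x in haps) {
    if (is.null(x$h) || x$f == 0 || nrow(x$h$variants) == 0) next
    v <- x$h$variants
    v$fraction <- x$f
    rows[[length(rows) + 1]] <- v
  }
  if (!length(rows)) {
    return(tibble(position = integer(0), ref_allele = character(0),
                  alt_allele = character(0), vclass = character(0),
                  expected_af = numeric(0)))
  }
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$position, .data$ref_allele, .data$alt_allele,
                    .data$vclass) |>
    dplyr::summarise(expected_af = sum(.data$fraction), .groups = "drop") |>
    dplyr::arrange(.data$position)
}

#' @export
print.mt_simulation <- function(x, ...) {
  cat(sprintf("<mt_simulation> %d reads (%s), %d truth variant(s)\n",
              nrow(x$reads),
              paste(sprintf("%s: %d", names(table(x$reads$true_source)),
                            table(x$reads$true_source)), collapse = ", "),
              nrow(x$truth$variants)))
  invisible(x)
}

#' Write simulated reads as FASTQ (Phred+33)
#'
#' @param sim an `mt_simulation` (or a reads tibble with `id`, `sequence`,
#'   `qualities`).
#' @param path output FASTQ path.
#' @export
write_fastq <- function(sim, path) {
  reads <- if (inherits(sim, "mt_simulation")) sim$reads else sim
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n",
                    reads$qualities), con)
  invisible(path)
}

#' Read a FASTQ file into a reads tibble
#'
#' @param path FASTQ path (plain text).
#' @return tibble with `id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  x <- readLines(path)
  if (length(x) %% 4 != 0) abort("truncated FASTQ file")
  i <- seq(1, length(x), by = 4)
  tibble(id = sub("^@", "", sub("\\s.*$", "", x[i])),
         sequence = x[i + 1], qualities = x[i + 3])
}

#' Write the ground-truth tables of a simulation
#'
#' Tab-separated: a variant table (`pos`, `ref`, `alt`, `expected_AF`) and a
#' read-placement table.
#'
#' @param sim an `mt_simulation`.
#' @param dir output directory.
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- sim$truth$variants
  write.table(
    data.frame(pos = v$position, ref = v$ref_allele, alt = v$alt_allele,
               expected_AF = v$expected_af),
    file.path(dir, "truth_variants.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(sim$truth$placements),
              file.path(dir, "truth_placements.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
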