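# End-to-end orchestration: simulate -> map -> call -> filter/consensus ->
# heteroplasmy -> evaluate, as one reproducible run.

#' Pipeline run configuration
#'
#' Bundles the per-stage parameters of a full run. The seed propagates to
#' every stochastic stage; identical config + seed gives identical
#' outputs.
#'
#' @param reference an [mt_reference()].
#' @param simulation a [simulation_config()], or `NULL` to start from
#'   `fastq` input.
#' @param fastq path to an input FASTQ when not simulating.
#' @param output_dir run directory for artifacts (`NULL` = no artifacts).
#' @param mapping list: `max_mismatch`, `min_length`, `min_mean_bq`,
#'   `delta`, `min_mapq`.
#' @param calling list: `min_bq`, `min_mq`, `min_af`, `min_median_end`,
#'   `sb_p`.
#' @param pattern a [filter_pattern()] for consensus-level filtering.
#' @param cr_mean,cr_high contamination-rate scalars (external estimates);
#'   `cr_tested` is what the call filters receive.
#' @param cr_tested contamination rate passed to [apply_call_filters()].
#' @param exclusions an [exclusion_lists()].
#' @param sample sample name used in reports.
#' @param seed integer master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(reference,
                            simulation = NULL,
                            fastq = NULL,
                            output_dir = NULL,
                            mapping = list(),
                            calling = list(),
                            pattern = filter_pattern("none", 10, 50, NA),
                            cr_mean = 0, cr_high = 0, cr_tested = cr_high,
                            exclusions = exclusion_lists(),
                            sample = "sample",
                            seed = 1L) {
  if (is.null(simulation) && is.null(fastq)) {
    abort("either a simulation config or a fastq path is required")
  }
  if (!is.null(fastq) && !file.exists(fastq)) {
    abort(sprintf("fastq input not found: %s", fastq))
  }
  mapping <- utils::modifyList(
    list(max_mismatch = 4L, min_length = 30L, min_mean_bq = 30L,
         delta = 0L, min_mapq = 30L), mapping)
  calling <- utils::modifyList(
    list(min_bq = 20L, min_mq = 30L, min_af = 0.05, min_median_end = 3,
         sb_p = 1e-3), calling)
  structure(list(reference = reference, simulation = simulation,
                 fastq = fastq, output_dir = output_dir, mapping = mapping,
                 calling = calling, pattern = pattern, cr_mean = cr_mean,
                 cr_high = cr_high, cr_tested = cr_tested,
                 exclusions = exclusions, sample = sample,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages: simulate (or read FASTQ), map to the circular reference plus
#' any decoys, deduplicate, exclude ambiguous/NumtS placements, estimate
#' the damage profile and rescale base qualities, pileup, call and tag
#' variants, apply the filter pattern, resolve multiallelic sites, build
#' the consensus, profile heteroplasmy, and (in simulation mode) score
#' the retained calls against the truth set. Each stage is logged; a
#' stage failure halts with the stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return object of class `mt_run` with all intermediate and final
#'   results.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    say("stage %s", name)
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  ref <- config$reference
  out <- list(config = config)

  if (!is.null(config$simulation)) {
    out$simulation <- stage("simulate", simulate_dataset(config$simulation))
    reads <- out$simulation$reads
    decoys <- out$simulation$decoys
    say("simulated %d reads", nrow(reads))
  } else {
    reads <- stage("read-fastq", read_fastq(config$fastq))
    decoys <- NULL
  }

  mp <- config$mapping
  al <- stage("map", map_reads(reads, ref, decoys,
                               max_mismatch = mp$max_mismatch,
                               min_length = mp$min_length,
                               min_mean_bq = mp$min_mean_bq))
  al <- stage("deduplicate", deduplicate(al, reads))
  al <- stage("filter-ambiguous",
              filter_ambiguous(al, delta = mp$delta,
                               min_mapq = mp$min_mapq, mt_name = ref$name))
  say("mapped %d / retained %d", sum(al$mapped), sum(al$retained))
  out$alignments <- al

  out$damage_profile <- stage("damage-profile",
                              estimate_damage_profile(al, reads, ref))
  reads <- stage("rescale", rescale_qualities(reads, al, out$damage_profile,
                                              ref))
  out$reads <- reads

  cl <- config$calling
  out$pileup <- stage("pileup", build_pileup(al, reads, ref,
                                             min_bq = cl$min_bq,
                                             min_mq = cl$min_mq))
  calls <- stage("call", call_variants(out$pileup))
  calls <- stage("filter-calls",
                 apply_call_filters(calls, cr = config$cr_tested,
                                    min_af = cl$min_af,
                                    min_median_end = cl$min_median_end,
                                    sb_p = cl$sb_p))
  out$calls <- calls
  say("%d candidate calls, %d PASS", nrow(calls),
      sum(calls$filters == "PASS"))

  retained <- stage("pattern", apply_pattern(calls, config$pattern,
                                             cr_mean = config$cr_mean,
                                             cr_high = config$cr_high))
  retained <- stage("resolve", resolve_multiallelic(retained))
  out$retained <- retained
  out$consensus <- stage("consensus",
                         build_consensus(ref, retained, out$pileup$depth))

  het <- stage("heteroplasmy", {
    sel <- select_heteroplasmy_sites(calls)
    sel <- sel[sel$AF >= 0.05, ]
    af_bin_profile(sel, sample = config$sample)
  })
  out$heteroplasmy <- het
  out$base_changes <- base_change_composition(calls[calls$filters == "PASS", ])
  out$titv <- titv_ratio(calls[calls$filters == "PASS", ])

  if (!is.null(config$simulation)) {
    truth <- out$simulation$truth$variants
    out$confusion <- stage("evaluate",
                           classify_calls(retained, truth,
                                          exclusions = config$exclusions,
                                          genome_length = ref$length))
    out$metrics <- compute_metrics(out$confusion)
  }

  say("done in %.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out$log <- log_lines
  class(out) <- "mt_run"
  if (!is.null(config$output_dir)) write_run_artifacts(out)
  out
}

# persist the artifacts of a run (FASTQ/SAM/VCF/FASTA/TSV/JSON + log)
write_run_artifacts <- function(run) {
  dir <- run$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- run$config$reference
  if (!is.null(run$simulation)) {
    write_fastq(run$simulation, file.path(dir, "reads.fastq"))
    write_truth(run$simulation, dir)
  }
  write_sam(run$alignments, run$reads, ref, file.path(dir, "alignments.sam"),
            decoys = if (!is.null(run$simulation)) run$simulation$decoys)
  write_vcf(run$calls, run$config$sample, file.path(dir, "calls.vcf"),
            ref = ref)
  write_consensus(run$consensus, file.path(dir, "consensus.fasta"),
                  name = paste0(run$config$sample, "_consensus"))
  write.table(as.data.frame(run$heteroplasmy),
              file.path(dir, "heteroplasmy_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(sample = run$config$sample, seed = run$config$seed,
                 coverage_pct = run$consensus$coverage_pct,
                 mean_depth = run$consensus$mean_depth,
                 n_calls = nrow(run$calls),
                 n_retained = nrow(run$retained),
                 titv = run$titv)
  if (!is.null(run$confusion)) {
    report$confusion <- run$confusion[c("TP", "TN", "FP", "FN")]
    report$metrics <- as.list(run$metrics[1, metric_cols])
  }
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.mt_run <- function(x, ...) {
  cat(sprintf("<mt_run> %s: %d calls, %d retained, %.2f%% consensus coverage\n",
              x$config$sample, nrow(x$calls), nrow(x$retained),
              x$consensus$coverage_pct))
  if (!is.null(x$confusion)) print(x$confusion)
  invisible(x)
}

#' One benchmark simulation replicate
#'
#' Convenience wrapper reproducing the benchmark design: a 36-SNP
#' endogenous haplotype (four of the SNPs placed on the excluded
#' rare-polymorphism positions) at 100X with a present-day contaminant,
#' run through the full pipeline and scored against truth. In the
#' `"mixture"` design the mutant haplotype is simulated at 30 percent of
#' the endogenous fraction over a plain-reference background (the 30:70
#' heteroplasmy design) and the consensus-level allele-fraction floor
#' drops to 5 percent.
#'
#' @param ref an [mt_reference()].
#' @param haplotype an `mt_haplotype` (from [apply_variants()]) carrying the truth SNPs.
#' @param seed integer replicate seed.
#' @param contamination_rate simulated contaminant fraction.
#' @param tested_cr contamination rate given to the filters (an external
#'   estimate; may deliberately differ from the simulated rate).
#' @param design `"homoplasmic"` or `"mixture"`.
#' @param pattern consensus filter pattern; default AD10/AF50 for the
#'   homoplasmic design and AD10/AF5 for the mixture design.
#' @param exclusions an [exclusion_lists()].
#' @param coverage total fold coverage (default 100).
#' @return the `mt_run`, with `$true_site_af` (calls at truth sites) added.
#' @export
benchmark_run <- function(ref, haplotype, seed,
                          contamination_rate = 0.02,
                          tested_cr = contamination_rate,
                          design = c("homoplasmic", "mixture"),
                          pattern = NULL,
                          exclusions = exclusion_lists(),
                          coverage = 100) {
  design <- match.arg(design)
  pattern <- pattern %||%
    filter_pattern("none", 10, if (design == "homoplasmic") 50 else 5, NA)
  sim <- if (design == "homoplasmic") {
    simulation_config(ref, endogenous_haplotype = haplotype,
                      contamination_rate = contamination_rate,
                      coverage = coverage, seed = seed)
  } else {
    simulation_config(ref,
                      mixture = list(haplotype = haplotype, fraction = 0.30),
                      contamination_rate = contamination_rate,
                      coverage = coverage, seed = seed)
  }
  cfg <- pipeline_config(ref, simulation = sim, pattern = pattern,
                         cr_mean = tested_cr, cr_high = tested_cr,
                         cr_tested = tested_cr, exclusions = exclusions,
                         sample = sprintf("sim_seed%d", seed), seed = seed)
  run <- run_pipeline(cfg)
  truth <- run$simulation$truth$variants
  hits <- dplyr::inner_join(
    run$calls[run$calls$filters == "PASS", ],
    truth[, c("position", "alt_allele")],
    by = c("position", "alt_allele"))
  run$true_site_af <- hits$AF
  run
}

#' Replicate the benchmark over a contamination grid
#'
#' Runs `n_replicates` independent simulations per contamination rate and
#' summarises the confusion counts and statistics per condition, one row
#' per replicate (layout mirrors the simulation benchmark table:
#' simulated and tested rates, allele-fraction design, counts, metrics).
#'
#' @param ref an [mt_reference()].
#' @param haplotype truth haplotype (see [benchmark_run()]).
#' @param cr_grid numeric vector of simulated contamination rates.
#' @param n_replicates replicates per rate.
#' @param design `"homoplasmic"` or `"mixture"`.
#' @param tested_cr tested rate; default = the simulated rate ("correct
#'   CR"); a scalar forces one tested value for the whole grid.
#' @param base_seed seed; replicate r of rate i runs at
#'   `base_seed + 1000*i + r`.
#' @param exclusions an [exclusion_lists()].
#' @return tibble with one row per (rate, replicate), plus
#'   `mean_true_af`.
#' @export
replicate_contamination_grid <- function(ref, haplotype,
                                         cr_grid = c(0.02, 0.1, 0.2, 0.3, 0.4),
                                         n_replicates = 1L,
                                         design = "homoplasmic",
                                         tested_cr = NULL,
                                         base_seed = 1L,
                                         exclusions = exclusion_lists()) {
  stopifnot(n_replicates >= 1)
  rows <- list()
  for (i in seq_along(cr_grid)) {
    for (r in seq_len(n_replicates)) {
      tc <- if (is.null(tested_cr)) cr_grid[i] else tested_cr
      run <- benchmark_run(ref, haplotype,
                           seed = base_seed + 1000L * i + r,
                           contamination_rate = cr_grid[i], tested_cr = tc,
                           design = design, exclusions = exclusions)
      m <- run$metrics
      m$simulated_cr <- cr_grid[i]
      m$tested_cr <- tc
      m$af_design <- if (design == "homoplasmic") 100 else 30
      m$replicate <- r
      m$mean_true_af <- mean(run$true_site_af)
      rows[[length(rows) + 1]] <- m
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::relocate("simulated_cr", "tested_cr", "af_design", "replicate")
}
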