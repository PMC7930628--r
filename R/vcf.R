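# VCF v4.2 input/output for per-site calls.
#
# Written with a small dedicated writer so the FORMAT fields (AD, DP, AF)
# and FILTER tags round-trip exactly; read through the vcfR parser.

vcf_filter_ids <- c("low_af", "position_bias", "strand_bias",
                    "contamination", "weak_evidence")

#' Write calls as VCF v4.2
#'
#' FORMAT fields `AD` (ref,alt depths), `DP`, `AF`; the FILTER column
#' carries the filter tags. Lossless round trip with [read_vcf()] for
#' those fields.
#'
#' @param calls calls tibble (from [call_variants()] +
#'   [apply_call_filters()], or compatible).
#' @param sample sample name for the genotype column.
#' @param path output path.
#' @param ref optional [mt_reference()] for the contig header line.
#' @export
write_vcf <- function(calls, sample, path, ref = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=paleomt-%s", as.character(utils::packageVersion("paleomt"))),
    if (!is.null(ref)) sprintf("##contig=<ID=%s,length=%d>", ref$name, ref$length),
    sprintf("##FILTER=<ID=%s,Description=\"%s\">", vcf_filter_ids,
            c("allele fraction below threshold",
              "variant too close to read ends",
              "strand bias by exact conditional test",
              "allele fraction within contamination band",
              "negative log-likelihood ratio")),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  chrom <- if (!is.null(ref)) ref$name else "MT"
  if (nrow(calls)) {
    filt <- if ("filters" %in% names(calls)) calls$filters else "."
    gt <- sprintf("%d,%d:%d:%.6g", calls$RD, calls$AD, calls$DP, calls$AF)
    rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tAD:DP:AF\t%s",
                   chrom, calls$position, calls$ref_allele,
                   calls$alt_allele, filt, gt)
  } else {
    rec <- character(0)
  }
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a VCF into a calls tibble
#'
#' Accepts any VCF v4.x carrying AD/DP/AF FORMAT fields (externally
#' produced files are ingested for downstream filtering). Parse failures
#' report the offending line.
#'
#' @param path VCF path.
#' @return calls tibble with `position`, `ref_allele`, `alt_allele`, `AD`,
#'   `RD`, `DP`, `AF`, `filters`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_vcf requires the vcfR package")
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- empty_calls()
    out$filters <- character(0)
    return(out[, c("position", "ref_allele", "alt_allele", "AD", "RD",
                   "DP", "AF", "filters")])
  }
  bad <- which(is.na(suppressWarnings(as.integer(fix$POS))))
  if (length(bad)) {
    abort(sprintf("malformed VCF record at data line %d of %s", bad[1], path))
  }
  ad <- unname(vcfR::extract.gt(v, "AD")[, 1])
  dp <- unname(suppressWarnings(as.integer(vcfR::extract.gt(v, "DP")[, 1])))
  af <- unname(suppressWarnings(as.numeric(vcfR::extract.gt(v, "AF")[, 1])))
  adm <- do.call(rbind, lapply(strsplit(ad, ",", fixed = TRUE), function(x) {
    as.integer(x[1:2])
  }))
  tibble(position = as.integer(fix$POS),
         ref_allele = fix$REF, alt_allele = fix$ALT,
         AD = adm[, 2], RD = adm[, 1], DP = dp, AF = af,
         filters = ifelse(is.na(fix$FILTER) | fix$FILTER == ".",
                          "PASS", fix$FILTER))
}
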