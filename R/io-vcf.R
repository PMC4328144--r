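#' Read genotype posteriors or hard calls from a VCF
#'
#' Reads a VCF 4.x file (via \pkg{vcfR}) and builds the same internal
#' representation as [read_gen()]. Per-sample `GP` fields (genotype
#' posterior probabilities, ordered AA, AB, BB on the alternate allele)
#' are used when present; otherwise `GT` hard calls are converted to
#' degenerate one-hot posteriors. `./.` (or absent GP and GT) becomes a
#' missing genotype.
#'
#' The VCF carries no phenotype, so case/control status and the
#' stratification region must be supplied in `samples`; if omitted, a
#' placeholder table (all controls, one region) is returned and must be
#' replaced before any association analysis.
#'
#' @param vcf_path Path to a VCF file (plain text or bgzipped).
#' @param samples Optional tibble with `sample_id`, `status`, `region`
#'   (and optionally `array`), matched to the VCF sample columns by id.
#' @return A [dosage_data()] object.
#' @export
read_vcf_dosage <- function(vcf_path, samples = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) {
    stop("multi-allelic record(s) at ",
         paste(utils::head(fix[grepl(",", alt), "POS"], 5), collapse = ", "),
         "; split them upstream (e.g. bcftools norm -m-)")
  }
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  m <- nrow(fix)

  sample_ids <- colnames(vcf@gt)[-1]
  n <- length(sample_ids)
  p_aa <- matrix(NA_real_, m, n)
  p_ab <- matrix(NA_real_, m, n)
  p_bb <- matrix(NA_real_, m, n)

  fmt_has <- function(el) {
    any(vapply(strsplit(vcf@gt[, "FORMAT"], ":"), function(f) el %in% f, logical(1)))
  }
  if (fmt_has("GP")) {
    gp <- vcfR::extract.gt(vcf, element = "GP")
    ok <- !is.na(gp) & gp != "."
    if (any(ok)) {
      parts <- strsplit(gp[ok], ",")
      if (any(lengths(parts) != 3)) stop("GP fields must have 3 comma-separated values")
      vals <- matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE)
      p_aa[ok] <- vals[, 1]; p_ab[ok] <- vals[, 2]; p_bb[ok] <- vals[, 3]
    }
  }
  if (fmt_has("GT")) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    need <- is.na(p_aa) & !is.na(gt) & !gt %in% c("./.", ".|.", ".")
    if (any(need)) {
      nalt <- vapply(strsplit(gt[need], "[/|]"),
                     function(a) sum(a == "1"), numeric(1))
      p_aa[need] <- as.numeric(nalt == 0)
      p_ab[need] <- as.numeric(nalt == 1)
      p_bb[need] <- as.numeric(nalt == 2)
    }
  }

  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = sample_ids, status = "control",
                              region = "all")
  } else {
    samples <- tibble::as_tibble(samples)
    mi <- match(sample_ids, samples$sample_id)
    if (anyNA(mi)) stop("samples table is missing VCF sample id(s): ",
                        paste(utils::head(sample_ids[is.na(mi)], 5), collapse = ", "))
    samples <- samples[mi, ]
  }

  variants <- tibble::tibble(
    id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    a0 = fix[, "REF"], a1 = alt
  )
  ord <- order(variants$pos, variants$id)
  dosage_data(variants[ord, ],
              p_aa = p_aa[ord, , drop = FALSE],
              p_ab = p_ab[ord, , drop = FALSE],
              p_bb = p_bb[ord, , drop = FALSE],
              samples = samples)
}
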