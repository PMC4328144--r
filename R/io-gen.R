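#' Read an Oxford GEN + SAMPLE file pair
#'
#' Parses the space-delimited Oxford GEN format (one row per variant:
#' `chrom id pos a0 a1` followed by three genotype posterior
#' probabilities per sample) together with its SAMPLE file (two header
#' lines: column names, then Oxford type codes). Dosages count the
#' alternate allele, i.e. the second GEN allele (`a1`).
#'
#' Posterior triplets whose sum deviates from 1 by more than `sum_tol`
#' are flagged missing; they are mean-imputed with `2 * alt_freq` when a
#' design matrix is built (see [dosages()]). Malformed rows are reported
#' with their line number.
#'
#' @param gen_path Path to the GEN file.
#' @param sample_path Path to the SAMPLE file. Must contain a binary
#'   `status` column (1 = case, 0 = control) and a discrete `region`
#'   column; an optional `array` column assigns samples to genotyping
#'   arrays.
#' @param sum_tol Posterior-sum tolerance; see [dosage_data()].
#' @return A [dosage_data()] object.
#' @export
read_gen <- function(gen_path, sample_path, sum_tol = 0.02) {
  samples <- read_sample_file(sample_path)
  n <- nrow(samples)

  lines <- readLines(gen_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GEN file: ", gen_path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  bad <- which(len != 5 + 3 * n)
  if (length(bad) > 0) {
    stop("GEN file ", gen_path, ": line(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " have ", paste(unique(len[bad]), collapse = "/"),
         " fields, expected ", 5 + 3 * n,
         " for ", n, " samples (triplet count mismatch)")
  }
  m <- length(toks)
  meta <- t(vapply(toks, function(x) x[1:5], character(5)))
  probs <- matrix(
    suppressWarnings(as.numeric(t(vapply(toks, function(x) x[-(1:5)],
                                         character(3 * n))))),
    nrow = m, byrow = FALSE
  )
  if (anyNA(probs)) {
    bad_row <- which(apply(is.na(probs), 1, any))
    stop("GEN file ", gen_path, ": non-numeric probability on line(s) ",
         paste(utils::head(bad_row, 5), collapse = ", "))
  }
  idx <- 3 * (seq_len(n) - 1)
  variants <- tibble::tibble(
    id = meta[, 2], chrom = meta[, 1],
    pos = as.integer(meta[, 3]), a0 = meta[, 4], a1 = meta[, 5]
  )
  ord <- order(variants$pos, variants$id)
  variants <- variants[ord, ]
  probs <- probs[ord, , drop = FALSE]
  dosage_data(variants,
              p_aa = probs[, idx + 1, drop = FALSE],
              p_ab = probs[, idx + 2, drop = FALSE],
              p_bb = probs[, idx + 3, drop = FALSE],
              samples = samples, sum_tol = sum_tol)
}

read_sample_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("SAMPLE file needs the two Oxford header lines")
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  types <- strsplit(trimws(lines[2]), "[ \t]+")[[1]]
  if (length(types) != length(header)) {
    stop("SAMPLE file: type line does not match header")
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  toks <- strsplit(trimws(body), "[ \t]+")
  if (any(lengths(toks) != length(header))) {
    stop("SAMPLE file: field count mismatch on line(s) ",
         paste(which(lengths(toks) != length(header)) + 2, collapse = ", "))
  }
  df <- as.data.frame(do.call(rbind, toks), stringsAsFactors = FALSE)
  names(df) <- header
  need <- c("status", "region")
  if (!all(need %in% names(df))) {
    stop("SAMPLE file must have 'status' and 'region' columns")
  }
  status_num <- suppressWarnings(as.integer(df$status))
  if (anyNA(status_num) || !all(status_num %in% 0:1)) {
    stop("SAMPLE 'status' must be binary 0/1 (1 = case)")
  }
  out <- tibble::tibble(
    sample_id = df[[1]],
    status = ifelse(status_num == 1, "case", "control"),
    region = df$region
  )
  out$array <- if ("array" %in% names(df)) df$array else "array1"
  out
}

#' Write a dosage dataset as Oxford GEN + SAMPLE files
#'
#' Inverse of [read_gen()]. Probabilities are printed with enough digits
#' that a write/read round trip reproduces the dosage matrix exactly to
#' printed precision.
#'
#' @param x A [dosage_data()] object.
#' @param gen_path,sample_path Output paths.
#' @param digits Significant digits for probabilities (default 6).
#' @return Invisibly, the two paths.
#' @export
write_gen <- function(x, gen_path, sample_path, digits = 6) {
  stopifnot(inherits(x, "dosage_data"))
  n <- nrow(x$samples)
  m <- nrow(x$variants)
  probs <- matrix(NA_real_, m, 3 * n)
  idx <- 3 * (seq_len(n) - 1)
  probs[, idx + 1] <- x$p_aa
  probs[, idx + 2] <- x$p_ab
  probs[, idx + 3] <- x$p_bb
  # Oxford convention: missing genotype written as "0 0 0"
  probs[is.na(probs)] <- 0
  ptxt <- matrix(formatC(probs, digits = digits, format = "g"), m, 3 * n)
  rows <- paste(x$variants$chrom, x$variants$id, x$variants$pos,
                x$variants$a0, x$variants$a1,
                apply(ptxt, 1, paste, collapse = " "))
  writeLines(rows, gen_path)

  hdr <- c("ID_1 ID_2 missing status region array",
           "0 0 0 B D D")
  body <- paste(x$samples$sample_id, x$samples$sample_id, 0,
                as.integer(x$samples$status == "case"),
                x$samples$region, x$samples$array)
  writeLines(c(hdr, body), sample_path)
  invisible(c(gen = gen_path, sample = sample_path))
}
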