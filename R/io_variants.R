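#' Construct and validate a variant table
#'
#' The in-memory representation of variant calls is one data frame row per
#' site, with per-sample read depths for the reference and (first) alternate
#' allele of each of the four cross roles. Multiallelic sites keep their
#' extra alternate alleles as a comma-separated `alt` string and are flagged
#' by [is_multiallelic()]; indels are flagged by [is_indel()]. Both are kept
#' in the table so the quality filter can reject them explicitly.
#'
#' @param df data frame with columns `contig`, `pos` (1-based), `ref`, `alt`
#'   (comma-separated for multiallelic sites), `mq` (site-level mapping
#'   quality) and, for each role in `wt_parent`, `mut_parent`, `wt_pool`,
#'   `mut_pool`, integer columns `<role>_ref` and `<role>_alt`.
#' @return the validated data frame with class `variant_table`.
#' @export
variant_table <- function(df) {
  need <- c("contig", "pos", "ref", "alt", "mq", .depth_cols())
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("variant table lacks columns: %s",
                           paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$pos <- as.integer(df$pos)
  df$mq <- as.numeric(df$mq)
  for (col in .depth_cols()) df[[col]] <- as.integer(df[[col]])
  if (nrow(df)) {
    if (anyNA(df$pos) || any(df$pos < 1L)) .stopf("pos must be integer >= 1")
    if (anyNA(df$mq) || any(df$mq < 0)) .stopf("mq must be non-negative")
    d <- as.matrix(df[, .depth_cols()])
    if (anyNA(d) || any(d < 0L)) .stopf("allele depths must be >= 0")
    bad <- mapply(function(r, a) r %in% strsplit(a, ",", fixed = TRUE)[[1]],
                  df$ref, df$alt, USE.NAMES = FALSE)
    if (any(bad)) .stopf("ref allele equals an alt allele at row %d",
                         which(bad)[1])
  }
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' @rdname variant_table
#' @param vt a `variant_table`.
#' @export
is_multiallelic <- function(vt) grepl(",", vt$alt, fixed = TRUE)

#' @rdname variant_table
#' @export
is_indel <- function(vt) {
  alt1 <- vapply(strsplit(vt$alt, ",", fixed = TRUE),
                 function(a) max(nchar(a), 0L), integer(1))
  nchar(vt$ref) > 1L | alt1 > 1L
}

#' Per-sample site coverage
#'
#' Coverage of a sample at a site is the sum of its reference and alternate
#' read depths, the quantity the coverage window filter applies per sample.
#'
#' @param vt a `variant_table`.
#' @return integer matrix, one column per role.
#' @export
site_coverage <- function(vt) {
  m <- sapply(SAMPLE_ROLES, function(r) {
    vt[[paste0(r, "_ref")]] + vt[[paste0(r, "_alt")]]
  })
  if (nrow(vt) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, SAMPLE_ROLES))
  if (nrow(vt) == 0L) m <- matrix(integer(0), ncol = 4,
                                  dimnames = list(NULL, SAMPLE_ROLES))
  m
}

#' Read a variant-call table
#'
#' Reads either a minimal VCF 4.2 (CHROM, POS, REF, ALT, `INFO/MQ`,
#' per-sample `AD`) whose sample columns are named after the four cross
#' roles, or the package's flat TSV dialect with explicit depth columns.
#' Multiallelic and indel records are preserved (and flagged) so the quality
#' filter can count and reject them; they are not dropped at parse time.
#'
#' @param path path to the file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @return a [variant_table()].
#' @export
read_variant_table <- function(path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("no such file: %s", path)
  if (dialect == "tsv") {
    df <- read.delim(path, colClasses = list(contig = "character",
                                             ref = "character",
                                             alt = "character"))
    return(variant_table(df))
  }
  .read_vcf_variants(path)
}

.read_vcf_variants <- function(path) {
  lines <- readLines(path, n = 500L)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    .stopf("malformed VCF header at line 1: expected '##fileformat=VCF...'")
  chrom_line <- grep("^#CHROM\t", lines)
  if (!length(chrom_line))
    .stopf("malformed VCF header: no '#CHROM' column line within first %d lines",
           length(lines))
  hdr <- strsplit(lines[chrom_line[1]], "\t", fixed = TRUE)[[1]]
  samples <- hdr[-(1:9)]
  miss <- setdiff(SAMPLE_ROLES, samples)
  if (length(miss))
    .stopf("VCF is missing role sample(s): %s", paste(miss, collapse = ", "))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n <- nrow(fix)
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  if (n && anyNA(mq)) .stopf("INFO/MQ missing or non-numeric at record %d",
                             which(is.na(mq))[1])
  ad <- if (n) vcfR::extract.gt(v, element = "AD") else
    matrix(character(0), ncol = length(samples), dimnames = list(NULL, samples))
  dep <- lapply(SAMPLE_ROLES, function(role) {
    parts <- strsplit(ifelse(is.na(ad[, role]), "0,0", ad[, role]), ",",
                      fixed = TRUE)
    list(ref = vapply(parts, function(p) as.integer(p[1]), integer(1)),
         alt = vapply(parts, function(p)
           if (length(p) >= 2) as.integer(p[2]) else 0L, integer(1)))
  })
  names(dep) <- SAMPLE_ROLES
  df <- data.frame(contig = as.character(fix[, "CHROM"]),
                   pos = as.integer(fix[, "POS"]),
                   ref = as.character(fix[, "REF"]),
                   alt = as.character(fix[, "ALT"]),
                   mq = mq, stringsAsFactors = FALSE)
  for (role in SAMPLE_ROLES) {
    df[[paste0(role, "_ref")]] <- dep[[role]]$ref
    df[[paste0(role, "_alt")]] <- dep[[role]]$alt
  }
  variant_table(df)
}

#' Write a variant table
#'
#' The VCF dialect writes a fixed VCF 4.2 subset: site `MQ` in INFO, and
#' `AD:DP` per sample (no genotype calls are emitted -- pools of many
#' individuals have no single genotype, and parents are re-classified from
#' depths downstream anyway). Extra alternate alleles of multiallelic sites
#' are padded with zero depths.
#'
#' @inheritParams read_variant_table
#' @param vt a [variant_table()].
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(vt, path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  vt <- variant_table(vt)
  if (dialect == "tsv") {
    write.table(vt, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Site mapping quality\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", SAMPLE_ROLES), collapse = "\t"))
  n_alt <- vapply(strsplit(vt$alt, ",", fixed = TRUE), length, integer(1))
  body <- character(nrow(vt))
  if (nrow(vt)) {
    sample_fields <- sapply(SAMPLE_ROLES, function(role) {
      dr <- vt[[paste0(role, "_ref")]]
      da <- vt[[paste0(role, "_alt")]]
      pad <- vapply(pmax(n_alt - 1L, 0L), function(k)
        paste(rep("0", k), collapse = ","), character(1))
      ad <- ifelse(pad == "", paste(dr, da, sep = ","),
                   paste(dr, da, pad, sep = ","))
      paste0(ad, ":", dr + da)
    })
    if (nrow(vt) == 1L) sample_fields <- matrix(sample_fields, nrow = 1)
    body <- paste(vt$contig, vt$pos, ".", vt$ref, vt$alt, ".", ".",
                  paste0("MQ=", format(vt$mq, trim = TRUE, scientific = FALSE)),
                  "AD:DP",
                  sample_fields[, 1], sample_fields[, 2],
                  sample_fields[, 3], sample_fields[, 4], sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
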