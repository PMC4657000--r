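#' Read and write FASTA sequence files
#'
#' Thin wrappers around Biostrings IO returning plain named character
#' vectors, order-preserving, with strict alphabet validation: sequences
#' must be over `{A,C,G,T,N}` (case-insensitive; stored uppercase).
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences (empty for an
#'   empty file); `write_fasta()`: `path`, invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    .stopf("non-IUPAC character '%s' in record '%s' at position %d",
           substr(seqs[i], bad[i], bad[i]), names(seqs)[i], bad[i])
  }
  seqs
}

#' @rdname read_fasta
#' @param records named character vector of `{A,C,G,T,N}` sequences.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.character(records), !is.null(names(records)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(records), path,
                              width = 70L)
  invisible(path)
}

#' Read a per-individual genotype table
#'
#' TSV with columns `individual`, `family`, `phenotype` (`WT` or `mutant`)
#' followed by one column per marker. Recognized genotype strings are
#' `het`, `hom_amel` and `hom_wt`; anything else (including `NA` and empty
#' cells) is mapped to `missing`.
#'
#' @param path file path.
#' @return data frame, one row per individual.
#' @export
read_genotype_table <- function(path) {
  df <- read.delim(path, colClasses = "character", na.strings = NULL)
  need <- c("individual", "family", "phenotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("genotype table lacks columns: %s",
                           paste(miss, collapse = ", "))
  if (anyDuplicated(df$individual))
    .stopf("duplicated individual_id: %s",
           df$individual[duplicated(df$individual)][1])
  bad_ph <- !df$phenotype %in% c("WT", "mutant")
  if (any(bad_ph)) .stopf("unknown phenotype '%s' for individual %s",
                          df$phenotype[bad_ph][1], df$individual[bad_ph][1])
  for (m in setdiff(names(df), need)) {
    g <- df[[m]]
    g[!g %in% c("het", "hom_amel", "hom_wt")] <- "missing"
    df[[m]] <- g
  }
  df
}

#' @rdname read_genotype_table
#' @param df genotype data frame as returned by [read_genotype_table()].
#' @export
write_genotype_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a contig-to-reference hit table
#'
#' TSV with columns `contig`, `chrom`, `start_mbp`, `end_mbp`, `score`,
#' abstracting translated-alignment placements of contigs on a reference
#' karyotype. Coordinates are in Mbp; `score` is an alignment significance
#' where larger is better.
#'
#' @param path file path.
#' @return data frame of hits.
#' @export
read_hit_table <- function(path) {
  df <- read.delim(path, colClasses = list(contig = "character",
                                           chrom = "character"))
  need <- c("contig", "chrom", "start_mbp", "end_mbp", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("hit table lacks columns: %s",
                           paste(miss, collapse = ", "))
  if (nrow(df) && any(df$start_mbp > df$end_mbp))
    .stopf("hit with start_mbp > end_mbp")
  df[, need]
}

#' @rdname read_hit_table
#' @param hits hit data frame.
#' @export
write_hit_table <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with columns `gene`, `chrom`, `start_mbp`, `end_mbp`, `biotype`.
#' Malformed rows (non-numeric coordinates) are dropped with a warning
#' naming the row.
#'
#' @param path file path.
#' @return data frame of gene records.
#' @export
read_annotation_table <- function(path) {
  df <- read.delim(path, colClasses = "character")
  need <- c("gene", "chrom", "start_mbp", "end_mbp", "biotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("annotation lacks columns: %s",
                           paste(miss, collapse = ", "))
  start <- suppressWarnings(as.numeric(df$start_mbp))
  end <- suppressWarnings(as.numeric(df$end_mbp))
  bad <- is.na(start) | is.na(end)
  for (i in which(bad)) warning("annotation row ", i, " malformed; dropped",
                                call. = FALSE)
  df <- df[!bad, , drop = FALSE]
  df$start_mbp <- start[!bad]
  df$end_mbp <- end[!bad]
  df
}

#' Chromosome intervals in Mbp
#'
#' A half-closed convention is not used here: intervals are plain Mbp
#' coordinate pairs as reported in comparative-mapping narratives, displayed
#' rounded to 3 decimals. A zero-width interval is permitted (degenerate
#' cluster of co-located hits) but `start_mbp > end_mbp` is not.
#'
#' @param chrom chromosome name.
#' @param start_mbp,end_mbp boundaries in Mbp, `start_mbp <= end_mbp`.
#' @return object of class `genomic_interval` with a `width_mbp` field.
#' @export
genomic_interval <- function(chrom, start_mbp, end_mbp) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start_mbp <- as.numeric(start_mbp); end_mbp <- as.numeric(end_mbp)
  if (is.na(start_mbp) || is.na(end_mbp) || start_mbp > end_mbp)
    .stopf("invalid interval: [%s, %s]", start_mbp, end_mbp)
  structure(list(chrom = chrom, start_mbp = start_mbp, end_mbp = end_mbp,
                 width_mbp = end_mbp - start_mbp),
            class = "genomic_interval")
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%.3f-%.3f Mbp (width %.3f)", x$chrom, x$start_mbp, x$end_mbp,
          x$width_mbp)
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Export an interval as BED3
#'
#' Converts Mbp boundaries to 0-based half-open bp coordinates, the BED
#' convention.
#'
#' @param interval a [genomic_interval()].
#' @param path file path.
#' @export
write_bed <- function(interval, path) {
  stopifnot(inherits(interval, "genomic_interval"))
  line <- sprintf("%s\t%d\t%d", interval$chrom,
                  as.integer(round(interval$start_mbp * 1e6)),
                  as.integer(round(interval$end_mbp * 1e6)))
  writeLines(line, path)
  invisible(path)
}

#' Coordinate convention converters
#'
#' On-disk formats in this package are 1-based inclusive (VCF `POS`);
#' in-memory sequence offsets are 0-based half-open. These two helpers are
#' each other's inverses.
#'
#' @param pos1 1-based inclusive position(s).
#' @param off0 0-based offset(s).
#' @return converted integer position(s).
#' @export
pos1_to_off0 <- function(pos1) as.integer(pos1) - 1L

#' @rdname pos1_to_off0
#' @export
off0_to_pos1 <- function(off0) as.integer(off0) + 1L
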