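#' Keep the best reference placement per contig
#'
#' Retains, for each contig, the hit with maximal score; ties are broken
#' first by chromosome name (lexicographic) and then by leftmost start, so
#' the result is deterministic and permutation-invariant.
#'
#' @param hits hit data frame (`contig`, `chrom`, `start_mbp`, `end_mbp`,
#'   `score`).
#' @return hit data frame with exactly one row per distinct contig.
#' @export
best_hit_per_contig <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$contig, -hits$score, hits$chrom, hits$start_mbp)
  h <- hits[o, , drop = FALSE]
  h <- h[!duplicated(h$contig), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# maximal-cardinality run of sorted midpoints with consecutive gaps
# <= max_gap; ties resolved toward the widest then leftmost run.
# Returns integer indices into the sorted vector.
.best_run <- function(mid_sorted, max_gap) {
  n <- length(mid_sorted)
  breaks <- which(diff(mid_sorted) > max_gap)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  size <- ends - starts + 1L
  width <- mid_sorted[ends] - mid_sorted[starts]
  o <- order(-size, -width, mid_sorted[starts])
  seq.int(starts[o[1]], ends[o[1]])
}

#' Delineate the candidate interval from synteny hits
#'
#' Two-step rule mirroring a chromosome-first narrative: (1) the candidate
#' chromosome is the one with the plurality of best-hits (ties go to the
#' chromosome holding the larger gap-bounded cluster, then lexicographic);
#' (2) on that chromosome, hit midpoints are sorted and the
#' maximal-cardinality run whose consecutive gaps are at most
#' `max_gap_mbp` is taken as the cluster (ties: widest, then leftmost).
#' The reported interval spans the minimum start to the maximum end of the
#' clustered hits; remaining hits on the chromosome are counted as
#' excluded singletons.
#'
#' @param hits best-hit data frame (see [best_hit_per_contig()]).
#' @param max_gap_mbp largest tolerated gap between consecutive hit
#'   midpoints within the cluster, in Mbp.
#' @return list with `chrom`, `interval` (a [genomic_interval()]),
#'   `n_hits_chrom`, `n_hits_cluster`, `singletons_excluded`,
#'   `cluster_contigs`, and `degenerate` (TRUE for a width-0 interval).
#' @export
cluster_hits <- function(hits, max_gap_mbp = 10) {
  if (!nrow(hits)) .stopf("empty hit list")
  mid <- (hits$start_mbp + hits$end_mbp) / 2
  counts <- table(hits$chrom)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    cl_size <- vapply(top, function(ch) {
      length(.best_run(sort(mid[hits$chrom == ch]), max_gap_mbp))
    }, integer(1))
    top <- sort(top[cl_size == max(cl_size)])[1]
  }
  chrom <- top
  on_ch <- which(hits$chrom == chrom)
  o <- on_ch[order(mid[on_ch])]
  run <- o[.best_run(mid[o], max_gap_mbp)]
  interval <- genomic_interval(chrom, min(hits$start_mbp[run]),
                               max(hits$end_mbp[run]))
  list(chrom = chrom,
       interval = interval,
       n_hits_chrom = length(on_ch),
       n_hits_cluster = length(run),
       singletons_excluded = length(on_ch) - length(run),
       cluster_contigs = hits$contig[run],
       degenerate = interval$width_mbp == 0)
}

#' Genes overlapping an interval
#'
#' Closed-interval intersection on Mbp coordinates: a gene abutting the
#' interval boundary exactly is included.
#'
#' @param interval a [genomic_interval()].
#' @param annotation gene table (`gene`, `chrom`, `start_mbp`, `end_mbp`,
#'   `biotype`), e.g. from [read_annotation_table()].
#' @param biotype if non-`NULL`, restrict to this biotype (e.g.
#'   `"protein_coding"`).
#' @return the intersecting annotation rows.
#' @export
genes_in_interval <- function(interval, annotation, biotype = NULL) {
  stopifnot(inherits(interval, "genomic_interval"))
  keep <- annotation$chrom == interval$chrom &
    annotation$end_mbp >= interval$start_mbp &
    annotation$start_mbp <= interval$end_mbp
  if (!is.null(biotype)) keep <- keep & annotation$biotype == biotype
  out <- annotation[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
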