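#' Haldane map function
#'
#' Converts a physical distance in Mbp into a recombination fraction under
#' the Haldane (no-interference) map, at a configurable recombination rate.
#'
#' @param d_mbp physical distance in Mbp (vectorized).
#' @param cm_per_mbp recombination rate, centiMorgan per Mbp (default 1).
#' @return recombination fraction in `[0, 0.5)`.
#' @export
haldane_theta <- function(d_mbp, cm_per_mbp = 1) {
  d_morgan <- abs(d_mbp) * cm_per_mbp / 100
  (1 - exp(-2 * d_morgan)) / 2
}

#' Count recombinants between a marker and the trait locus
#'
#' For offspring of amel/amel x amel/+ crosses every meiosis of the
#' heterozygous parent is informative: the trait genotype is read directly
#' from the phenotype (WT implies amel/+, mutant implies amel/amel, full
#' penetrance) and a fully linked marker must be `het` in WT and
#' `hom_amel` in mutant offspring. A recombinant is an offspring whose
#' marker genotype is discordant with its phenotype. Missing marker
#' genotypes reduce the informative count rather than being imputed.
#'
#' @param records genotype data frame (see [read_genotype_table()]).
#' @param marker marker column name.
#' @return list with `r` (recombinants), `n` (informative meioses),
#'   `recombinant_ids` (individual ids), and `uninformative` (TRUE when
#'   `n == 0`).
#' @export
count_recombinants <- function(records, marker) {
  if (!marker %in% names(records))
    .stopf("marker '%s' absent from genotype table", marker)
  g <- records[[marker]]
  informative <- g %in% c("het", "hom_amel", "hom_wt")
  rec <- informative &
    ((records$phenotype == "WT" & g == "hom_amel") |
       (records$phenotype == "mutant" & g == "het") |
       (g == "hom_wt"))  # impossible from this cross without recombination
  list(r = sum(rec), n = sum(informative),
       recombinant_ids = records$individual[rec],
       uninformative = sum(informative) == 0L)
}

#' Two-point LOD score
#'
#' Closed form for a fully informative backcross-type design:
#' `LOD(theta) = log10( theta^r (1-theta)^(n-r) / 0.5^n )`. At complete
#' linkage (`theta = 0`) the value is defined as the limit, which is
#' `n * log10(2)` when `r = 0` and `-Inf` otherwise.
#'
#' @param n informative meioses.
#' @param r recombinant count, `0 <= r <= n`.
#' @param theta recombination fraction(s) in `[0, 0.5]`.
#' @return LOD value(s).
#' @export
lod_score <- function(n, r, theta) {
  if (r > n || r < 0) .stopf("need 0 <= r <= n")
  if (any(theta < 0 | theta > 0.5)) .stopf("theta must be in [0, 0.5]")
  out <- r * log10(theta) + (n - r) * log10(1 - theta) + n * log10(2)
  out[theta == 0] <- if (r == 0) n * log10(2) else -Inf
  out
}

#' @rdname lod_score
#' @details `lod_max()` evaluates the LOD at the maximum-likelihood
#'   recombination fraction `theta_hat = r / n` (clamped to 0.5; the
#'   `theta -> 0` limit is used when `r = 0`).
#' @export
lod_max <- function(n, r) {
  lod_score(n, r, min(max(r / n, 0), 0.5))
}

#' Bundle a marker's linkage evidence
#'
#' @param name marker name.
#' @param chrom chromosome.
#' @param start_mbp,end_mbp marker (gene) span in Mbp.
#' @param r,n recombinant count and informative meioses.
#' @param recombinant_ids optional recombinant individual ids.
#' @return object of class `linkage_result`: marker metadata, `theta_hat`,
#'   `lod_max`, and `lod_at(theta)`.
#' @export
linkage_result <- function(name, chrom, start_mbp, end_mbp, r, n,
                           recombinant_ids = character(0)) {
  stopifnot(r >= 0, r <= n)
  structure(list(marker = name, chrom = chrom,
                 span = genomic_interval(chrom, start_mbp, end_mbp),
                 r = as.integer(r), n = as.integer(n),
                 theta_hat = if (n > 0) r / n else NA_real_,
                 lod_max = if (n > 0) lod_max(n, r) else NA_real_,
                 lod_at = function(theta) lod_score(n, r, theta),
                 recombinant_ids = recombinant_ids),
            class = "linkage_result")
}

#' Two-point linkage across a marker panel
#'
#' Runs [count_recombinants()] for every marker in `markers` and returns
#' both the per-marker [linkage_result()] objects and a flat report table.
#'
#' @param records genotype data frame.
#' @param markers marker table (`marker`, `chrom`, `start_mbp`, `end_mbp`),
#'   e.g. [default_marker_table()].
#' @return list with `results` (named list of `linkage_result`) and
#'   `report` (data frame ordered by position).
#' @export
linkage_analysis <- function(records, markers) {
  markers <- markers[order(markers$start_mbp), , drop = FALSE]
  results <- lapply(seq_len(nrow(markers)), function(i) {
    cr <- count_recombinants(records, markers$marker[i])
    linkage_result(markers$marker[i], markers$chrom[i], markers$start_mbp[i],
                   markers$end_mbp[i], cr$r, cr$n, cr$recombinant_ids)
  })
  names(results) <- markers$marker
  report <- data.frame(
    marker = markers$marker, chrom = markers$chrom,
    start_mbp = markers$start_mbp, end_mbp = markers$end_mbp,
    n = vapply(results, `[[`, integer(1), "n"),
    r = vapply(results, `[[`, integer(1), "r"),
    theta_hat = vapply(results, `[[`, numeric(1), "theta_hat"),
    lod_max = vapply(results, `[[`, numeric(1), "lod_max"),
    recombinant_ids = vapply(results, function(x)
      paste(x$recombinant_ids, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(results = results, report = report)
}

#' Refine the candidate interval from flanking recombinant markers
#'
#' The zero-recombinant markers delimit where the locus must lie; the
#' interval is bounded by the nearest recombinant markers on each side:
#' left flank = the `r > 0` marker with the largest position below all
#' `r = 0` markers, right flank = the `r > 0` marker with the smallest
#' position above them. Boundaries are the *outer* gene-span edges of the
#' flanks (left flank's span start, right flank's span end). If no marker
#' has `r = 0` (possible in simulation with very tight markers), the
#' marker(s) with the minimal recombinant count stand in for the zero
#' block and the result is flagged. A missing flank on one side yields an
#' open boundary at the chromosome end with a warning.
#'
#' @param results list of [linkage_result()] objects on one chromosome.
#' @param chrom_start_mbp,chrom_end_mbp chromosome bounds used for open
#'   intervals.
#' @return list with `interval` (a [genomic_interval()]), `report` (markers
#'   ordered by position with `r`, `n`), `zero_markers`, and flags
#'   `open_left`, `open_right`, `no_zero_marker`.
#' @export
refine_interval <- function(results, chrom_start_mbp = 0,
                            chrom_end_mbp = Inf) {
  stopifnot(length(results) >= 1)
  chrom <- unique(vapply(results, `[[`, character(1), "chrom"))
  if (length(chrom) != 1L) .stopf("markers must lie on one chromosome")
  pos <- vapply(results, function(x) (x$span$start_mbp + x$span$end_mbp) / 2,
                numeric(1))
  r <- vapply(results, `[[`, integer(1), "r")
  o <- order(pos)
  results <- results[o]; pos <- pos[o]; r <- r[o]
  no_zero <- !any(r == 0L)
  zero <- if (no_zero) which(r == min(r)) else which(r == 0L)
  lo <- min(pos[zero]); hi <- max(pos[zero])
  left_cand <- which(r > min(r[zero]) & pos < lo)
  right_cand <- which(r > min(r[zero]) & pos > hi)
  open_left <- length(left_cand) == 0L
  open_right <- length(right_cand) == 0L
  if (open_left) warning("no recombinant marker left of the zero block; ",
                         "interval open at chromosome start", call. = FALSE)
  if (open_right) warning("no recombinant marker right of the zero block; ",
                          "interval open at chromosome end", call. = FALSE)
  start <- if (open_left) chrom_start_mbp else
    results[[max(left_cand)]]$span$start_mbp
  end <- if (open_right) chrom_end_mbp else
    results[[min(right_cand)]]$span$end_mbp
  interval <- genomic_interval(chrom, start,
                               if (is.finite(end)) end else
                                 max(vapply(results, function(x)
                                   x$span$end_mbp, numeric(1))))
  # every zero-recombinant marker span must fall inside the interval
  for (i in zero) {
    sp <- results[[i]]$span
    if (sp$start_mbp < interval$start_mbp || sp$end_mbp > interval$end_mbp)
      .stopf("zero-recombinant marker %s lies outside the refined interval",
             results[[i]]$marker)
  }
  report <- data.frame(
    marker = vapply(results, `[[`, character(1), "marker"),
    pos_mbp = pos,
    r = r,
    n = vapply(results, `[[`, integer(1), "n"),
    stringsAsFactors = FALSE)
  list(interval = interval, report = report,
       zero_markers = report$marker[zero],
       open_left = open_left, open_right = open_right,
       no_zero_marker = no_zero,
       width_display_mbp = round(interval$width_mbp, 1))
}

#' Default seven-marker panel on the candidate chromosome
#'
#' The two outer markers (*RAP2A*, *ARHGAP6*) and the recombinant-defined
#' inner flanks (*UXS1*, *AKAP17A*) carry their published anole-lizard
#' chromosome 3 coordinates. *UNC50*, *HERC2* and *NIPA2* have no published
#' coordinates; their spans here are synthetic placements inside the
#' refined interval that preserve the published marker order (HERC2 is
#' centred on the default simulated causal position, reflecting the
#' physical adjacency of HERC2 and OCA2 in amniote genomes).
#'
#' @return marker data frame (`marker`, `chrom`, `start_mbp`, `end_mbp`).
#' @export
default_marker_table <- function() {
  data.frame(
    marker = c("RAP2A", "UXS1", "UNC50", "HERC2", "NIPA2", "AKAP17A",
               "ARHGAP6"),
    chrom = "chr3",
    start_mbp = c(86.073, 108.455, 109.600, 110.400, 111.200, 112.976,
                  119.453),
    end_mbp = c(86.099, 108.515, 109.660, 110.600, 111.260, 113.359,
                119.496),
    stringsAsFactors = FALSE)
}
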