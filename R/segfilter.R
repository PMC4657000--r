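#' Filter thresholds for the variant cascade
#'
#' Defaults reproduce the published cascade: sites with mapping quality
#' below 100 are excluded, per-sample coverage must lie inside the closed
#' window \[18, 50\] (the printed exclusions are strict: coverage < 18 or
#' > 50), and a sample is treated as fixed when its minor allele is
#' supported by at most one read (`tolerance_reads`).
#'
#' @param mq_min minimum site mapping quality (sites with `mq < mq_min`
#'   fail).
#' @param depth_min,depth_max closed per-sample coverage window in reads.
#' @param tolerance_reads minor-allele reads tolerated in a "fixed" call.
#' @param fixed_allele which homozygous states satisfy the "fixed"
#'   requirement for the mutant parent and pool. The default `"either"`
#'   accepts both `FIXED_REF` and `FIXED_ALT`: when the alignment reference
#'   is assembled from the mutant parent's own reads, the causally linked
#'   allele is the *reference* allele, so demanding `FIXED_ALT` would throw
#'   away the true signal.
#' @param pool_maf_min minimum minor-allele fraction for a pool to be called
#'   heterozygous, on top of the read-count tolerance. Default 0 (pure
#'   tolerance rule, the same classifier as for individuals).
#' @return object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(mq_min = 100, depth_min = 18L, depth_max = 50L,
                              tolerance_reads = 1L,
                              fixed_allele = c("either", "ref", "alt"),
                              pool_maf_min = 0) {
  fixed_allele <- match.arg(fixed_allele)
  if (depth_min > depth_max) .stopf("depth_min must be <= depth_max")
  if (tolerance_reads < 0) .stopf("tolerance_reads must be >= 0")
  structure(list(mq_min = mq_min, depth_min = as.integer(depth_min),
                 depth_max = as.integer(depth_max),
                 tolerance_reads = as.integer(tolerance_reads),
                 fixed_allele = fixed_allele,
                 pool_maf_min = pool_maf_min),
            class = "filter_thresholds")
}

#' Classify a sample's allelic state from its allele depths
#'
#' Implements the one-read-tolerance rule: a sample is `FIXED_REF`
#' (`FIXED_ALT`) when its alternate (reference) depth is at most
#' `tolerance_reads`; it is `HET` when both alleles exceed the tolerance.
#' With both depths at or below the tolerance no call is possible and
#' `AMBIGUOUS` is returned (unreachable for depths inside the coverage
#' window whenever `depth_min > 2 * tolerance_reads`).
#'
#' @param depth_ref,depth_alt integer read depths (vectorized).
#' @param t a [filter_thresholds()].
#' @param pool apply the pool minor-allele-fraction requirement on top of
#'   the tolerance rule.
#' @return character vector of states in
#'   `{HET, FIXED_REF, FIXED_ALT, AMBIGUOUS}`.
#' @export
classify_state <- function(depth_ref, depth_alt, t = filter_thresholds(),
                           pool = FALSE) {
  tol <- t$tolerance_reads
  state <- rep("AMBIGUOUS", length(depth_ref))
  state[depth_ref > tol & depth_alt > tol] <- "HET"
  state[depth_alt <= tol & depth_ref > tol] <- "FIXED_REF"
  state[depth_ref <= tol & depth_alt > tol] <- "FIXED_ALT"
  if (pool && t$pool_maf_min > 0) {
    total <- depth_ref + depth_alt
    maf <- pmin(depth_ref, depth_alt) / pmax(total, 1L)
    demote <- state == "HET" & maf < t$pool_maf_min
    state[demote] <- ifelse(depth_ref[demote] >= depth_alt[demote],
                            "FIXED_REF", "FIXED_ALT")
  }
  state
}

.fixed_states <- function(t) {
  switch(t$fixed_allele,
         either = c("FIXED_REF", "FIXED_ALT"),
         ref = "FIXED_REF",
         alt = "FIXED_ALT")
}

#' Quality filter: indels, multiallelic sites, mapping quality, coverage
#'
#' Applies the pre-segregation exclusions, reporting for each site the
#' first failing reason in the fixed order `indel`, `multiallelic`,
#' `low_mq`, `coverage_out_of_range(<role>)`. The coverage window is tested
#' per sample on `depth_ref + depth_alt`.
#'
#' @param vt a [variant_table()]; all four role observations must be
#'   present (enforced by the table constructor).
#' @param t a [filter_thresholds()].
#' @return character vector, `NA` for passing sites, otherwise the reason.
#' @export
quality_filter <- function(vt, t = filter_thresholds()) {
  vt <- variant_table(vt)
  reason <- rep(NA_character_, nrow(vt))
  cov <- site_coverage(vt)
  out <- cov < t$depth_min | cov > t$depth_max
  first_bad <- apply(out, 1, function(x) if (any(x)) which(x)[1] else NA_integer_)
  cov_reason <- ifelse(is.na(first_bad), NA_character_,
                       paste0("coverage_out_of_range(",
                              SAMPLE_ROLES[first_bad], ")"))
  reason[!is.na(cov_reason)] <- cov_reason[!is.na(cov_reason)]
  reason[vt$mq < t$mq_min] <- "low_mq"
  reason[is_multiallelic(vt)] <- "multiallelic"
  reason[is_indel(vt)] <- "indel"
  reason
}

.state_matrix <- function(vt, t) {
  m <- sapply(SAMPLE_ROLES, function(role) {
    classify_state(vt[[paste0(role, "_ref")]], vt[[paste0(role, "_alt")]],
                   t, pool = grepl("_pool$", role))
  })
  if (nrow(vt) <= 1L) m <- matrix(m, nrow = nrow(vt),
                                  dimnames = list(NULL, SAMPLE_ROLES))
  m
}

# the expected segregation pattern for a recessive locus in an
# amel/amel x amel/+ cross: het in WT parent and WT pool, fixed in the
# mutant parent and mutant pool
.matches_pattern <- function(states, t) {
  fixed <- .fixed_states(t)
  states[, "wt_parent"] == "HET" & states[, "mut_parent"] %in% fixed &
    states[, "wt_pool"] == "HET" & states[, "mut_pool"] %in% fixed
}

#' Segregation-pattern filter cascade
#'
#' Runs the full cascade in the published stage order: quality exclusions
#' first, then the parental conditions (heterozygous WT parent, fixed
#' mutant parent), then the pool conditions (heterozygous WT offspring
#' pool, fixed mutant offspring pool). A site survives iff it passes every
#' stage; the audit trail attributes each rejected site to the *first*
#' stage that rejected it, so stage-wise counts can be reported in the
#' same shape as the published narrative. The surviving set itself is a
#' pure conjunction and therefore independent of stage order.
#'
#' @param vt a [variant_table()].
#' @param t a [filter_thresholds()].
#' @return list with `survivors` (a `variant_table`) and `audit` (data
#'   frame: `contig`, `pos`, `stage_rejected` in
#'   `{quality, parents, pools, none}`, `reason`, and the four classified
#'   states).
#' @export
segregation_filter <- function(vt, t = filter_thresholds()) {
  vt <- variant_table(vt)
  qreason <- quality_filter(vt, t)
  states <- .state_matrix(vt, t)
  fixed <- .fixed_states(t)
  parents_ok <- states[, "wt_parent"] == "HET" &
    states[, "mut_parent"] %in% fixed
  pools_ok <- states[, "wt_pool"] == "HET" & states[, "mut_pool"] %in% fixed
  stage <- rep("none", nrow(vt))
  stage[!pools_ok] <- "pools"
  stage[!parents_ok] <- "parents"
  stage[!is.na(qreason)] <- "quality"
  audit <- data.frame(contig = vt$contig, pos = vt$pos,
                      stage_rejected = stage,
                      reason = ifelse(stage == "quality", qreason,
                                      ifelse(stage == "none", NA_character_,
                                             stage)),
                      stringsAsFactors = FALSE)
  audit <- cbind(audit, as.data.frame(states, stringsAsFactors = FALSE))
  list(survivors = vt[stage == "none", , drop = FALSE], audit = audit)
}

#' Contig-level co-segregation verdicts
#'
#' A contig is `CONSISTENT` when it carries at least one surviving SNP and
#' *every* quality-passing SNP on it matches the expected segregation
#' pattern; a single quality-passing discordant SNP makes it
#' `CONTRADICTED` (the contig is then treated as a false positive);
#' contigs with no surviving SNP are `NO_PASSING_SNP`. Only quality-passing
#' SNPs can contradict: quality-failing records carry no reliable allelic
#' state.
#'
#' @param vt a [variant_table()] of all candidate sites (the function
#'   re-runs the quality filter and state classification internally so the
#'   verdicts are self-contained).
#' @param t a [filter_thresholds()].
#' @return data frame: `contig`, `n_snps_total`, `n_snps_passing`
#'   (surviving the full cascade), `verdict`.
#' @export
cosegregation_verdicts <- function(vt, t = filter_thresholds()) {
  vt <- variant_table(vt)
  res <- segregation_filter(vt, t)
  qpass <- res$audit$stage_rejected != "quality"
  surv <- res$audit$stage_rejected == "none"
  states <- as.matrix(res$audit[, SAMPLE_ROLES])
  match_ok <- .matches_pattern(states, t)
  contigs <- unique(vt$contig)
  per <- lapply(contigs, function(cg) {
    i <- vt$contig == cg
    n_surv <- sum(surv & i)
    contradicts <- any(qpass & i & !match_ok)
    verdict <- if (n_surv == 0L) "NO_PASSING_SNP"
    else if (contradicts) "CONTRADICTED"
    else "CONSISTENT"
    data.frame(contig = cg, n_snps_total = sum(i), n_snps_passing = n_surv,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, per)
}
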