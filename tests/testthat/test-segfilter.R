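test_that("quality filter applies the published exclusions with strict bounds", {
  t <- filter_thresholds()
  expect_equal(quality_filter(one_site(mq = 99,
                                       wt_parent = c(15L, 15L),
                                       mut_parent = c(30L, 0L),
                                       wt_pool = c(15L, 15L),
                                       mut_pool = c(30L, 0L)), t), "low_mq")
  expect_equal(quality_filter(one_site(mq = 100, wt_parent = c(10L, 7L)), t),
               "coverage_out_of_range(wt_parent)")
  # boundary inclusion: 18 and 50 are inside the window
  vt <- one_site(mq = 100, wt_parent = c(9L, 9L), mut_parent = c(50L, 0L),
                 wt_pool = c(25L, 25L), mut_pool = c(0L, 18L))
  expect_true(is.na(quality_filter(vt, t)))
  expect_equal(quality_filter(one_site(alt = "TA"), t), "indel")
  expect_equal(quality_filter(one_site(alt = "T,G"), t), "multiallelic")
})

test_that("allelic-state classification follows the one-read-tolerance rule", {
  t <- filter_thresholds()
  expect_equal(classify_state(25L, 1L, t), "FIXED_REF")
  expect_equal(classify_state(0L, 20L, t), "FIXED_ALT")
  expect_equal(classify_state(12L, 10L, t), "HET")
  expect_equal(classify_state(c(25L, 0L, 12L), c(1L, 20L, 10L), t),
               c("FIXED_REF", "FIXED_ALT", "HET"))
  expect_equal(classify_state(1L, 1L, t), "AMBIGUOUS")
  # tolerance 0 makes one stray read heterozygous
  expect_equal(classify_state(25L, 1L, filter_thresholds(tolerance_reads = 0)),
               "HET")
})

test_that("segregation filter keeps the expected pattern and attributes rejections in stage order", {
  # hand-enumerated survivor: het/fixed/het/fixed across the four roles
  res <- segregation_filter(one_site())
  expect_equal(nrow(res$survivors), 1L)
  expect_equal(res$audit$stage_rejected, "none")
  expect_equal(unlist(res$audit[1, c("wt_parent", "mut_parent", "wt_pool",
                                     "mut_pool")], use.names = FALSE),
               c("HET", "FIXED_REF", "HET", "FIXED_ALT"))
  # homozygous WT parent fails at the parent stage
  res <- segregation_filter(one_site(wt_parent = c(20L, 0L)))
  expect_equal(res$audit$stage_rejected, "parents")
  # heterozygous mutant pool fails at the pool stage
  res <- segregation_filter(one_site(mut_pool = c(15L, 16L)))
  expect_equal(res$audit$stage_rejected, "pools")
  # quality failures mask later stages in the audit
  res <- segregation_filter(one_site(mq = 10, wt_parent = c(20L, 0L)))
  expect_equal(res$audit$stage_rejected, "quality")
})

test_that("the survivor set is monotone along the cascade and order-robust", {
  vt <- rand_variant_table(10000, seed = 42)
  t <- filter_thresholds()
  res <- segregation_filter(vt, t)
  qpass <- which(is.na(quality_filter(vt, t)))
  surv <- which(res$audit$stage_rejected == "none")
  parents_pass <- which(res$audit$stage_rejected %in% c("none", "pools"))
  # monotone shrinkage: each later stage filters a subset of the previous
  expect_true(all(parents_pass %in% qpass))
  expect_true(all(surv %in% parents_pass))
  # order robustness: the final set equals the conjunction of the three
  # independent predicates, whatever order they are applied in
  st <- list(
    quality = is.na(quality_filter(vt, t)),
    parents = classify_state(vt$wt_parent_ref, vt$wt_parent_alt, t) == "HET" &
      classify_state(vt$mut_parent_ref, vt$mut_parent_alt, t) %in%
        c("FIXED_REF", "FIXED_ALT"),
    pools = classify_state(vt$wt_pool_ref, vt$wt_pool_alt, t) == "HET" &
      classify_state(vt$mut_pool_ref, vt$mut_pool_alt, t) %in%
        c("FIXED_REF", "FIXED_ALT"))
  for (ord in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))) {
    keep <- seq_len(nrow(vt))
    for (k in ord) keep <- keep[st[[k]][keep]]
    expect_identical(sort(keep), surv)
  }
})

test_that("contig verdicts separate consistent, contradicted and empty contigs", {
  mk_site <- function(contig, pos, wt_parent) {
    v <- one_site(wt_parent = wt_parent)
    v$contig <- contig; v$pos <- pos
    v
  }
  vt <- variant_table(rbind(
    mk_site("cA", 1L, c(12L, 10L)), mk_site("cA", 2L, c(15L, 14L)),
    mk_site("cA", 3L, c(10L, 20L)),                     # all surviving
    mk_site("cB", 1L, c(12L, 10L)), mk_site("cB", 2L, c(30L, 0L)),  # discordant
    mk_site("cC", 1L, c(40L, 0L))))                     # nothing survives
  v <- cosegregation_verdicts(vt)
  expect_equal(v$verdict[v$contig == "cA"], "CONSISTENT")
  expect_equal(v$n_snps_passing[v$contig == "cA"], 3L)
  expect_equal(v$verdict[v$contig == "cB"], "CONTRADICTED")
  expect_equal(v$verdict[v$contig == "cC"], "NO_PASSING_SNP")
})

test_that("on error-free simulations every in-window linked SNP survives", {
  cfg <- sim_config(seed = 31, n_contigs = 1500, sequencing_error = 0,
                    prop_low_mq = 0, prop_indel = 0, prop_multiallelic = 0)
  ped <- simulate_pedigree(cfg)
  vc <- suppressWarnings(simulate_variant_calls(cfg, ped))
  res <- segregation_filter(vc$variants)
  cov <- site_coverage(vc$variants)
  in_window <- rowSums(cov >= 18 & cov <= 50) == 4L
  linked <- vc$site_truth$linked
  expect_true(all(res$audit$stage_rejected[linked & in_window] == "none"))
  # and every truth-linked contig with an in-window SNP is CONSISTENT
  v <- cosegregation_verdicts(vc$variants)
  linked_ok <- unique(vc$variants$contig[linked & in_window])
  expect_true(all(v$verdict[v$contig %in% linked_ok] == "CONSISTENT"))
})

test_that("chance survival of unlinked SNPs matches the state-enumeration oracle", {
  cfg <- sim_config(seed = 77, n_contigs = 6000, fraction_linked = 0,
                    sequencing_error = 0, prop_low_mq = 0, prop_indel = 0,
                    prop_multiallelic = 0)
  vc <- suppressWarnings(simulate_variant_calls(cfg, simulate_pedigree(cfg)))
  res <- segregation_filter(vc$variants)
  qpass <- res$audit$stage_rejected != "quality"
  p_obs <- mean(res$audit$stage_rejected[qpass] == "none")
  p <- pattern_match_prob()
  expect_equal(p, 4 / 81)
  se <- sqrt(p * (1 - p) / sum(qpass))
  expect_lt(abs(p_obs - p), 3 * se)
})
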