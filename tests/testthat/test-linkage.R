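test_that("recombinants are offspring discordant between marker and phenotype", {
  g <- data.frame(individual = paste0("i", 1:4), family = "fam1",
                  phenotype = c("WT", "mutant", "WT", "mutant"),
                  m1 = c("het", "hom_amel", "hom_amel", "hom_amel"),
                  stringsAsFactors = FALSE)
  cr <- count_recombinants(g, "m1")
  expect_equal(cr$r, 1L)
  expect_equal(cr$n, 4L)
  expect_equal(cr$recombinant_ids, "i3")
  # a fully linked marker shows no recombinants
  g$m2 <- ifelse(g$phenotype == "WT", "het", "hom_amel")
  expect_equal(count_recombinants(g, "m2")$r, 0L)
  # missing genotypes reduce n instead of being imputed
  g$m3 <- "missing"
  cr3 <- count_recombinants(g, "m3")
  expect_equal(c(cr3$r, cr3$n), c(0L, 0L))
  expect_true(cr3$uninformative)
  expect_error(count_recombinants(g, "nope"), "absent")
})

test_that("the two-point LOD matches its closed form and brute-force product", {
  # complete linkage over 256 meioses: limit value n * log10(2)
  expect_equal(lod_score(256, 0, 0), 256 * log10(2))
  expect_gt(lod_score(256, 0, 0), 74.2)
  # null identity at free recombination
  expect_equal(lod_score(10, 5, 0.5), 0)
  expect_equal(lod_score(256, 0, 0.5), 0)
  # closed form vs one-term-per-meiosis brute force
  for (case in list(c(256, 7), c(100, 23), c(40, 2))) {
    th <- case[2] / case[1]
    expect_equal(lod_score(case[1], case[2], th),
                 lod_brute(case[1], case[2], th), tolerance = 1e-10)
  }
  expect_equal(lod_score(256, 7, 7 / 256), 63.12, tolerance = 0.01)
  expect_equal(lod_score(256, 0, 0), lod_max(256, 0))
  expect_error(lod_score(5, 6, 0.1), "r <= n")
})

test_that("LOD is maximized at theta-hat and grows with non-recombinant meioses", {
  grid <- seq(0.001, 0.5, by = 0.001)
  for (case in list(c(50, 5), c(256, 7), c(30, 0))) {
    n <- case[1]; r <- case[2]
    expect_true(all(lod_max(n, r) >= lod_score(n, r, grid) - 1e-9))
  }
  # adding a non-recombinant informative meiosis never lowers the LOD
  th <- c(0.01, 0.1, 0.3, 0.49)
  expect_true(all(lod_score(101, 5, th) >= lod_score(100, 5, th)))
})

test_that("flanking recombinant markers refine the interval as published", {
  res <- published_linkage_results()
  out <- refine_interval(res)
  expect_equal(out$interval$start_mbp, 108.455)  # UXS1 span start
  expect_equal(out$interval$end_mbp, 113.359)    # AKAP17A span end
  expect_equal(out$width_display_mbp, 4.9)
  expect_equal(sort(out$zero_markers), c("HERC2", "NIPA2", "UNC50"))
  expect_false(out$no_zero_marker)
  # permutation invariance of the input order
  out2 <- refine_interval(res[sample(length(res))])
  expect_equal(out2$interval, out$interval)
  # every zero-recombinant marker span is inside the interval
  for (m in out$zero_markers) {
    i <- which(vapply(res, `[[`, character(1), "marker") == m)
    expect_gte(res[[i]]$span$start_mbp, out$interval$start_mbp)
    expect_lte(res[[i]]$span$end_mbp, out$interval$end_mbp)
  }
})

test_that("degenerate refinement cases behave as documented", {
  mk <- function(name, lo, hi, r) linkage_result(name, "chr1", lo, hi, r, 100L)
  # single zero marker with immediately adjacent flanks
  out <- refine_interval(list(mk("L", 10, 11, 3), mk("Z", 20, 21, 0),
                              mk("R", 30, 31, 2)))
  expect_equal(out$interval$start_mbp, 10)
  expect_equal(out$interval$end_mbp, 31)
  # missing right flank opens the interval to the chromosome end
  expect_warning(
    out2 <- refine_interval(list(mk("L", 10, 11, 3), mk("Z", 20, 21, 0)),
                            chrom_end_mbp = 150),
    "open")
  expect_equal(out2$interval$end_mbp, 150)
  expect_true(out2$open_right)
  # no zero-recombinant marker: the least-recombinant marker stands in
  out3 <- refine_interval(list(mk("A", 10, 11, 5), mk("B", 20, 21, 1),
                               mk("C", 30, 31, 4)))
  expect_true(out3$no_zero_marker)
  expect_equal(out3$zero_markers, "B")
  expect_equal(out3$interval$start_mbp, 10)
  expect_equal(out3$interval$end_mbp, 31)
})

test_that("linkage_analysis reports per-marker counts over the panel", {
  cfg <- sim_config(seed = 61)
  ped <- simulate_pedigree(cfg)
  la <- linkage_analysis(ped$genotypes, cfg$marker_positions)
  expect_equal(nrow(la$report), 7L)
  expect_true(all(la$report$n == 256L))
  # markers are reported in positional order
  expect_equal(la$report$marker[1], "RAP2A")
  expect_equal(la$report$marker[7], "ARHGAP6")
  # recombinant counts grow with distance from the causal locus (ends vs middle)
  expect_gt(la$report$r[la$report$marker == "RAP2A"],
            la$report$r[la$report$marker == "UXS1"])
  expect_equal(la$report$r[la$report$marker == "HERC2"], 0L)
})
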