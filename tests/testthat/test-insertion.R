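test_that("insertion detection is exact and left-normalized", {
  ev <- detect_insertion("ACGCACGT", "ACGCTTTTACGT")
  expect_equal(ev$position, 4L)
  expect_equal(ev$inserted_seq, "TTTT")
  expect_equal(ev$length, 4L)
  # a junction sharing a base with the insertion shifts to the left
  ev1 <- detect_insertion("ACGTACGT", "ACGTTTTTACGT")
  expect_equal(ev1$position, 3L)
  expect_identical(apply_insertion("ACGTACGT", ev1$position,
                                   ev1$inserted_seq), "ACGTTTTTACGT")
  # ambiguous homopolymer resolves to the leftmost position
  ev2 <- detect_insertion("AAAA", "AAAAA")
  expect_equal(ev2$position, 0L)
  expect_equal(ev2$inserted_seq, "A")
  # a substitution alongside the size change is not a simple insertion
  expect_error(detect_insertion("AAAATTTT", "AAAACGGGG"), "single contiguous")
  expect_error(detect_insertion("ACGT", "ACG"), "longer")
})

test_that("detect_insertion inverts apply_insertion on random sequences", {
  set.seed(17)
  for (i in 1:200) {
    wt <- paste(sample(c("A", "C", "G", "T"), sample(30:120, 1), TRUE),
                collapse = "")
    ins <- paste(sample(c("A", "C", "G", "T"), sample(1:40, 1), TRUE),
                 collapse = "")
    pos <- sample(0:nchar(wt), 1)
    mut <- apply_insertion(wt, pos, ins)
    ev <- detect_insertion(wt, mut)
    # compare left-normalized reconstructions, not raw coordinates
    expect_identical(apply_insertion(wt, ev$position, ev$inserted_seq), mut)
    expect_equal(ev$length, nchar(ins))
  }
})

test_that("splice reconstruction matches brute-force chain enumeration", {
  context <- paste0("ATGCA", "GTGGAG", "TTTTT", "GTGGAG", "CCCCC")
  cdna <- "ATGCATTTTTCCCCC"
  sp <- reconstruct_splice(context, cdna, min_fragment = 5)
  expect_equal(sp$n_fragments, 3L)
  expect_equal(sp$fragments$g_start, c(0L, 11L, 22L))
  expect_equal(sp$fragments$g_end, c(5L, 16L, 27L))
  expect_true(all(sp$donor_ok))
  expect_true(all(sp$acceptor_ok))
  # independent oracle: exhaustive enumeration of all valid chains
  chains <- enumerate_chains(context, cdna, 5)
  sizes <- lengths(chains)
  expect_equal(min(sizes), 3L)
  minimal <- chains[sizes == 3L]
  expect_equal(length(minimal), 1L)
  expect_false(sp$ambiguous)
  expect_equal(do.call(rbind, minimal[[1]])[, 1], sp$fragments$g_start)
  # fragments concatenate byte-exactly to the cDNA insertion
  expect_identical(paste(splice_fragment_seqs(sp, context), collapse = ""),
                   cdna)
})

test_that("a cDNA identical to the genomic insertion is one unspliced fragment", {
  s <- "ATGCATTTTT"
  sp <- reconstruct_splice(s, s)
  expect_equal(sp$n_fragments, 1L)
  expect_equal(sp$fragments$g_start, 0L)
  expect_equal(sp$fragments$g_end, nchar(s))
  expect_length(sp$donor_ok, 0L)
  expect_error(reconstruct_splice("ACGTACGT", "GGGGGGGG"), "not splicable")
})

test_that("reconstruction recovers generator truth on random gene models", {
  for (seed in 1:60) {
    m <- random_gene_model(seed)
    s <- simulate_gene_with_insertion(m)
    gi <- detect_insertion(s[["wt_gdna"]], s[["mut_gdna"]])
    ci <- detect_insertion(s[["wt_cdna"]], s[["mut_cdna"]])
    sp <- reconstruct_splice(gi$inserted_seq, ci$inserted_seq)
    expect_equal(sp$fragments$g_start, m$retained_fragments$g_start)
    expect_equal(sp$fragments$g_end, m$retained_fragments$g_end)
    expect_true(all(sp$donor_ok) && all(sp$acceptor_ok))
    expect_false(sp$ambiguous)
  }
})

test_that("corrupting one donor site flips exactly one canonical-splice flag", {
  m <- random_gene_model(99)
  gap_start <- m$retained_fragments$g_end[1] + 1L  # 1-based first gap base
  ins <- m$insertion_seq
  substr(ins, gap_start, gap_start) <- "C"  # GT -> CT
  fr <- m$retained_fragments
  cdna_ins <- paste0(substring(ins, fr$g_start + 1L, fr$g_end),
                     collapse = "")
  sp <- reconstruct_splice(ins, cdna_ins)
  expect_false(sp$donor_ok[1])
  expect_true(all(sp$donor_ok[-1]))
  expect_true(all(sp$acceptor_ok))
})

test_that("ORF finding translates with the standard code and both policies", {
  orf <- find_orf("ATGAAATAA")
  expect_true(orf$found)
  expect_equal(orf$protein, "MK")
  expect_equal(orf$protein_len_aa, 2L)
  expect_equal(orf$orf_len_nt, 9L)
  # protein_len * 3 + 3 = orf_len for every stop-terminated ORF
  set.seed(3)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    o <- find_orf(s)
    if (o$found) expect_equal(o$protein_len_aa * 3L + 3L, o$orf_len_nt)
  }
  expect_false(find_orf("CCCCCCCC")$found)
  # longest vs first-ATG policy on a nested-ORF construct
  s <- paste0("ATGTAA", "ATGAAAAAAAAATAA")
  expect_equal(find_orf(s, "longest")$protein_len_aa, 4L)
  expect_equal(find_orf(s, "first_atg")$protein_len_aa, 1L)
})

test_that("truncation reporting compares proteins from the shared start codon", {
  # identical transcripts: equal lengths, no flag
  wt <- paste0("CCCC", "ATG", "AAACCCGGG", "TAA", "CC")
  tr <- truncation_report(wt, wt)
  expect_equal(tr$wt_protein_len_aa, tr$mut_protein_len_aa)
  expect_false(tr$loss_of_function_likely)
  expect_false(tr$premature_stop)
  # in-frame stop-free insertion lengthens the protein, no flag
  mut <- apply_insertion(wt, 10L, "AAAGGGCCC")
  tr2 <- truncation_report(wt, mut)
  expect_equal(tr2$mut_protein_len_aa, tr2$wt_protein_len_aa + 3L)
  expect_false(tr2$premature_stop)
  expect_false(tr2$loss_of_function_likely)
  expect_equal(tr2$n_novel_stops_in_insert, 0L)
  # frameshifting insertion with an internal stop truncates
  mut3 <- apply_insertion(wt, 10L, "TAAC")
  tr3 <- truncation_report(wt, mut3)
  expect_true(tr3$premature_stop)
  expect_equal(tr3$n_novel_stops_in_insert, 1L)
  expect_equal(tr3$first_novel_stop_offset_in_insert, 0L)
})

test_that("the default gene model reproduces the full analysis arithmetic", {
  m <- gene_model(seed = 1)
  s <- simulate_gene_with_insertion(m)
  gi <- detect_insertion(s[["wt_gdna"]], s[["mut_gdna"]])
  expect_equal(gi$length, 5832L)
  wt_intron <- m$exons$start[m$insertion_intron + 1L] -
    m$exons$end[m$insertion_intron]
  expect_equal(wt_intron, 2011L)
  expect_equal(wt_intron + gi$length, 7843L)
  ci <- detect_insertion(s[["wt_cdna"]], s[["mut_cdna"]])
  expect_equal(ci$length, 397L)
  orf <- find_orf(s[["wt_cdna"]])
  expect_equal(orf$orf_len_nt, 2532L)
  expect_equal(orf$protein_len_aa, 843L)
  tr <- truncation_report(s[["wt_cdna"]], s[["mut_cdna"]])
  expect_equal(tr$mut_protein_len_aa, 402L)
  expect_lt(tr$mut_protein_len_aa, tr$wt_protein_len_aa)
  expect_equal(tr$n_novel_stops_in_insert, 2L)
  expect_true(tr$loss_of_function_likely)
  # a model with no retained fragments leaves the transcript untouched
  m0 <- gene_model(seed = 2, retained_starts = integer(0),
                   retained_lengths = integer(0),
                   stop_codon_offsets = NULL)
  s0 <- simulate_gene_with_insertion(m0)
  expect_identical(s0[["wt_cdna"]], s0[["mut_cdna"]])
})
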