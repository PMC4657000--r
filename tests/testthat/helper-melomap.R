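# shared fixtures and independent oracles, all built in code

# a variant table of random sites: depths, MQ and allele structure drawn
# broadly enough to exercise every filter branch
rand_variant_table <- function(n, seed, contigs = max(1L, n %/% 5L)) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1),
                USE.NAMES = FALSE)
  u <- runif(n)
  alt[u < 0.05] <- paste0(alt[u < 0.05], "A")              # indels
  mult <- u >= 0.05 & u < 0.10                             # triallelic
  alt[mult] <- vapply(which(mult), function(i)
    paste(c(alt[i], sample(setdiff(bases, c(ref[i], alt[i])), 1)),
          collapse = ","), character(1))
  df <- data.frame(contig = sprintf("c%04d", sample(contigs, n, TRUE)),
                   pos = sample.int(1e6, n), ref = ref, alt = alt,
                   mq = round(runif(n, 0, 250), 1),
                   stringsAsFactors = FALSE)
  for (col in c("wt_parent_ref", "wt_parent_alt", "mut_parent_ref",
                "mut_parent_alt", "wt_pool_ref", "wt_pool_alt",
                "mut_pool_ref", "mut_pool_alt"))
    df[[col]] <- sample(0:60, n, replace = TRUE)
  variant_table(df)
}

# one-site variant table with explicit depths; defaults form a surviving site
one_site <- function(wt_parent = c(12L, 10L), mut_parent = c(22L, 0L),
                     wt_pool = c(20L, 18L), mut_pool = c(1L, 40L),
                     mq = 150, ref = "A", alt = "T") {
  variant_table(data.frame(
    contig = "c1", pos = 100L, ref = ref, alt = alt, mq = mq,
    wt_parent_ref = wt_parent[1], wt_parent_alt = wt_parent[2],
    mut_parent_ref = mut_parent[1], mut_parent_alt = mut_parent[2],
    wt_pool_ref = wt_pool[1], wt_pool_alt = wt_pool[2],
    mut_pool_ref = mut_pool[1], mut_pool_alt = mut_pool[2]))
}

# exhaustive enumeration of all splice chains (independent oracle for
# reconstruct_splice on tiny instances)
enumerate_chains <- function(context, cdna, min_fragment) {
  m <- nchar(cdna); L <- nchar(context)
  gc <- strsplit(context, "")[[1]]; cc <- strsplit(cdna, "")[[1]]
  rec <- function(i, j) {
    if (i == m) return(list(list()))
    out <- list()
    for (s in j:(L - 1)) {
      if (s >= L) break
      maxl <- 0L
      while (s + maxl < L && i + maxl < m &&
             gc[s + maxl + 1] == cc[i + maxl + 1]) maxl <- maxl + 1L
      if (maxl == 0L) next
      for (len in seq_len(maxl)) {
        if (len < min_fragment && i + len != m) next
        for (rest in rec(i + len, s + len))
          out[[length(out) + 1L]] <- c(list(c(s, len)), rest)
      }
    }
    out
  }
  rec(0L, 0L)
}

# log-space brute-force two-point likelihood ratio: one term per meiosis
lod_brute <- function(n, r, theta) {
  terms <- c(rep(log10(theta), r), rep(log10(1 - theta), n - r))
  sum(terms) - sum(rep(log10(0.5), n))
}

# enumeration of independent per-sample allelic states (uniform over
# hom-ref, het, hom-alt): probability the four-sample pattern matches the
# recessive-cross expectation by chance
pattern_match_prob <- function() {
  st <- expand.grid(wt_parent = 0:2, mut_parent = 0:2,
                    wt_pool = 0:2, mut_pool = 0:2)
  ok <- st$wt_parent == 1 & st$mut_parent != 1 &
    st$wt_pool == 1 & st$mut_pool != 1
  mean(ok)
}

# linkage results for the published seven-marker worked example
published_linkage_results <- function() {
  mk <- default_marker_table()
  r <- c(RAP2A = 7L, UXS1 = 4L, UNC50 = 0L, HERC2 = 0L, NIPA2 = 0L,
         AKAP17A = 1L, ARHGAP6 = 2L)
  lapply(seq_len(nrow(mk)), function(i)
    linkage_result(mk$marker[i], mk$chrom[i], mk$start_mbp[i],
                   mk$end_mbp[i], r[[mk$marker[i]]], 256L))
}
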