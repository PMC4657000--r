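#' Build a gene model carrying an intronic insertion with cryptic exons
#'
#' Constructs, deterministically from `seed`, a synthetic gene whose
#' mutant allele carries a large insertion inside one intron, of which an
#' ordered set of internal fragments ("cryptic exons") is retained in the
#' mature mutant transcript. The default geometry reproduces the
#' OCA2-like case the package's analysis stage targets: a 2,776-bp
#' transcript with a 2,532-bp ORF (843-aa protein), a 2,011-bp intron
#' between exons 11 and 12 receiving a 5,832-bp insertion, three retained
#' fragments totalling 397 bp, and two in-frame stop codons near the 5'
#' end of the first fragment so the mutant protein truncates at 402 aa.
#'
#' All inter-fragment gaps begin `GT` and end `AG`, and an acceptor
#' (donor) is placed immediately before the first (after the last)
#' fragment, so splicing is canonical. A few identifiability constraints
#' are imposed so that detection and reconstruction are exactly
#' invertible: retained-fragment boundaries avoid `G` next to the `GT`/
#' `AG` signals (which would make the minimal splice chain ambiguous),
#' and the last inserted base differs from the base preceding the
#' junction (which would make the left-normalized insertion position
#' ambiguous).
#'
#' @param seed integer seed.
#' @param utr5_len,utr3_len untranslated region lengths (the 5' UTR is
#'   generated ATG-free so the annotated start is the 5'-most ATG).
#' @param n_cds_codons CDS length in codons including start and stop.
#' @param exon_lengths exon lengths summing to the transcript length.
#' @param default_intron_len length of ordinary introns.
#' @param insertion_intron index of the intron receiving the insertion.
#' @param wt_intron_len WT length of that intron.
#' @param insertion_offset_in_intron 0-based insertion offset within it
#'   (at least 2 from either intron end, preserving its own GT/AG).
#' @param insertion_len insertion length in bp.
#' @param retained_starts 0-based starts of the retained fragments within
#'   the insertion (first at least 2, internal gaps at least 4, at least
#'   3 bp after the last fragment).
#' @param retained_lengths fragment lengths; use `integer(0)` for a model
#'   whose insertion is fully spliced out.
#' @param stop_codon_offsets in-frame stop codon offsets within the
#'   retained sequence (0-based, multiples of 3; requires the junction to
#'   fall on a codon boundary), or `NULL` for unconstrained content.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(seed = 1L,
                       utr5_len = 100L, n_cds_codons = 844L, utr3_len = 144L,
                       exon_lengths = c(160L, rep(114L, 10L), rep(113L, 12L),
                                        120L),
                       default_intron_len = 300L,
                       insertion_intron = 11L,
                       wt_intron_len = 2011L,
                       insertion_offset_in_intron = 500L,
                       insertion_len = 5832L,
                       retained_starts = c(800L, 2600L, 4700L),
                       retained_lengths = c(132L, 132L, 133L),
                       stop_codon_offsets = c(6L, 12L)) {
  set.seed(.stage_seed(seed, "gene"))
  k <- length(retained_lengths)
  if (length(retained_starts) != k)
    .stopf("retained_starts and retained_lengths differ in length")

  cdna <- paste0(.random_dna_no_atg(utr5_len),
                 paste(c("ATG", sample(.sense_codons, n_cds_codons - 2L,
                                       replace = TRUE), "TAA"),
                       collapse = ""),
                 .random_dna(utr3_len))
  if (sum(exon_lengths) != nchar(cdna))
    .stopf("exon lengths sum to %d but transcript is %d bp",
           sum(exon_lengths), nchar(cdna))
  n_exons <- length(exon_lengths)
  if (insertion_intron < 1L || insertion_intron > n_exons - 1L)
    .stopf("insertion_intron out of range")
  ce <- cumsum(exon_lengths)
  cdna_junction <- ce[insertion_intron]  # 0-based cDNA offset of insertion
  prev_base <- substr(cdna, cdna_junction, cdna_junction)

  retained <- if (k > 0L)
    .build_retained(retained_lengths, stop_codon_offsets,
                    cdna_junction - utr5_len, prev_base) else ""

  intron_lengths <- rep(default_intron_len, n_exons - 1L)
  intron_lengths[insertion_intron] <- wt_intron_len
  if (any(intron_lengths < 4L)) .stopf("introns must be at least 4 bp")
  introns <- vapply(intron_lengths, function(l)
    paste0("GT", .random_dna(l - 4L), "AG"), character(1))

  exon_seqs <- substring(cdna, c(1L, ce[-n_exons] + 1L), ce)
  wt_gdna <- paste0(paste0(exon_seqs, c(introns, "")), collapse = "")
  g_exon_start <- cumsum(c(0L, exon_lengths[-n_exons] +
                             intron_lengths))  # 0-based
  exons <- data.frame(start = g_exon_start,
                      end = g_exon_start + exon_lengths)

  insertion_seq <- if (k > 0L)
    .build_insertion(insertion_len, retained, retained_starts,
                     retained_lengths) else .random_dna(insertion_len)
  if (insertion_offset_in_intron < 2L ||
      insertion_offset_in_intron > wt_intron_len - 2L)
    .stopf("insertion offset must keep the host intron's GT/AG intact")
  insertion_offset <- exons$end[insertion_intron] + insertion_offset_in_intron
  # block left-shift ambiguity of the genomic insertion
  gprev <- substr(wt_gdna, insertion_offset, insertion_offset)
  if (substr(insertion_seq, insertion_len, insertion_len) == gprev) {
    repl <- sample(setdiff(.bases, gprev), 1)
    substr(insertion_seq, insertion_len, insertion_len) <- repl
  }

  model <- structure(list(
    exons = exons, wt_gdna = wt_gdna, cdna = cdna,
    cdna_junction = cdna_junction,
    insertion_intron = insertion_intron,
    insertion_offset = insertion_offset,
    insertion_seq = insertion_seq,
    retained_fragments = data.frame(g_start = as.integer(retained_starts),
                                    g_end = as.integer(retained_starts +
                                                         retained_lengths)),
    orf_start = utr5_len,
    seed = seed), class = "gene_model")
  validate_gene_model(model)
  model
}

# content of the retained (cryptic-exon) sequence, honoring stop-codon
# placement and the boundary identifiability constraints
.build_retained <- function(lens, stop_offsets, cds_offset, prev_base) {
  R <- sum(lens)
  splits <- cumsum(lens)[-length(lens)]
  if (is.null(stop_offsets)) {
    v <- sample(.bases, R, replace = TRUE)
    for (b in splits) {
      if (v[b] == "G") v[b] <- sample(c("A", "C", "T"), 1)
      if (v[b + 1L] == "G") v[b + 1L] <- sample(c("A", "C", "T"), 1)
    }
    if (v[R] == prev_base)
      v[R] <- sample(setdiff(.bases, prev_base), 1)
    return(paste(v, collapse = ""))
  }
  if (cds_offset < 0L || cds_offset %% 3L != 0L)
    .stopf("stop placement requires the junction on a codon boundary")
  if (any(stop_offsets %% 3L != 0L) || any(stop_offsets + 3L > R))
    .stopf("stop_codon_offsets must be in-frame and inside the retained seq")
  ncod <- R %/% 3L
  cods <- sample(.sense_codons, ncod, replace = TRUE)
  stop_idx <- stop_offsets %/% 3L + 1L
  cods[stop_idx] <- rep(c("TAG", "TGA", "TAA"),
                        length.out = length(stop_idx))
  no_end_g <- .sense_codons[substr(.sense_codons, 3, 3) != "G"]
  no_start_g <- .sense_codons[substr(.sense_codons, 1, 1) != "G"]
  for (b in splits) {
    if (b %% 3L != 0L)
      .stopf("with stop placement, fragment boundaries must be in-frame")
    i1 <- b %/% 3L; i2 <- i1 + 1L
    if (any(c(i1, i2) %in% stop_idx))
      .stopf("stop codon at a fragment boundary is unsupported")
    if (substr(cods[i1], 3, 3) == "G") cods[i1] <- sample(no_end_g, 1)
    if (substr(cods[i2], 1, 1) == "G") cods[i2] <- sample(no_start_g, 1)
  }
  leftover <- R %% 3L
  tail_nt <- if (leftover > 0L)
    paste(sample(.bases, leftover, replace = TRUE), collapse = "") else ""
  s <- paste0(paste(cods, collapse = ""), tail_nt)
  if (substr(s, R, R) == prev_base) {
    if (leftover > 0L) {
      substr(s, R, R) <- sample(setdiff(.bases, prev_base), 1)
    } else {
      ok <- no_end_g[substr(no_end_g, 3, 3) != prev_base]
      if (ncod %in% stop_idx) .stopf("stop codon at retained end unsupported")
      cods[ncod] <- sample(ok, 1)
      s <- paste(cods, collapse = "")
    }
  }
  s
}

# the genomic insertion: random backbone, retained fragments written in,
# canonical GT/AG at every splice junction
.build_insertion <- function(L, retained, starts, lens) {
  k <- length(lens)
  ends <- starts + lens
  if (is.unsorted(starts, strictly = TRUE) || any(starts[-1] - ends[-k] < 4L))
    .stopf("retained fragments must be ordered with gaps of at least 4 bp")
  if (starts[1] < 2L || ends[k] > L - 3L)
    .stopf("retained fragments leave no room for flanking splice signals")
  v <- sample(.bases, L, replace = TRUE)
  cb <- cumsum(lens)
  frag_seq <- substring(retained, c(1L, cb[-k] + 1L), cb)
  for (i in seq_len(k)) {
    v[(starts[i] + 1L):ends[i]] <- strsplit(frag_seq[i], "")[[1]]
    v[c(starts[i] - 1L, starts[i])] <- c("A", "G")      # acceptor before
    v[c(ends[i] + 1L, ends[i] + 2L)] <- c("G", "T")     # donor after
  }
  paste(v, collapse = "")
}

#' Validate a gene model's structural invariants
#'
#' Checks fragment ordering and non-overlap, canonical `GT`/`AG` at every
#' internal gap of the insertion, and that the concatenated exons
#' reproduce the stored transcript.
#'
#' @param model a [gene_model()].
#' @return `model`, invisibly; errors on violation.
#' @export
validate_gene_model <- function(model) {
  fr <- model$retained_fragments
  k <- nrow(fr)
  if (k > 1L) {
    if (is.unsorted(fr$g_start, strictly = TRUE) ||
        any(fr$g_start[-1] < fr$g_end[-k]))
      .stopf("retained fragments must be ordered and non-overlapping")
    gaps <- substring(model$insertion_seq, fr$g_end[-k] + 1L, fr$g_start[-1])
    if (!all(substr(gaps, 1, 2) == "GT" &
               substring(gaps, nchar(gaps) - 1L) == "AG"))
      .stopf("internal insertion gap lacking GT/AG splice signals")
  }
  ex <- paste0(substring(model$wt_gdna, model$exons$start + 1L,
                         model$exons$end), collapse = "")
  if (!identical(ex, model$cdna))
    .stopf("exons do not concatenate to the stored transcript")
  invisible(model)
}

#' Assemble the four sequences implied by a gene model
#'
#' @param model a [gene_model()].
#' @return named character vector with `wt_gdna`, `mut_gdna` (WT gDNA with
#'   the insertion applied), `wt_cdna` (concatenated exons) and `mut_cdna`
#'   (WT cDNA with the concatenated retained fragments inserted at the
#'   exon junction); writable with [write_fasta()].
#' @export
simulate_gene_with_insertion <- function(model) {
  validate_gene_model(model)
  fr <- model$retained_fragments
  retained <- if (nrow(fr)) paste0(substring(model$insertion_seq,
                                             fr$g_start + 1L, fr$g_end),
                                   collapse = "") else ""
  c(wt_gdna = model$wt_gdna,
    mut_gdna = apply_insertion(model$wt_gdna, model$insertion_offset,
                               model$insertion_seq),
    wt_cdna = model$cdna,
    mut_cdna = apply_insertion(model$cdna, model$cdna_junction, retained))
}

#' Draw a small random gene model
#'
#' Random valid geometry at reduced scale (insertion 500-800 bp, 2-4
#' retained fragments of 25-60 bp, 4-7 exons), used for property testing
#' of the insertion and splice-reconstruction stages.
#'
#' @param seed integer seed.
#' @return a [gene_model()].
#' @export
random_gene_model <- function(seed = 1L) {
  set.seed(.stage_seed(seed, "model"))
  n_exons <- sample(4:7, 1)
  n_codons <- sample(100:160, 1)
  cdna_len <- 30L + 3L * n_codons + 40L
  w <- as.vector(stats::rmultinom(1, cdna_len - 20L * n_exons,
                                  rep(1, n_exons)))
  exon_lengths <- 20L + w
  k <- sample(2:4, 1)
  lens <- sample(25:60, k, replace = TRUE)
  L <- sample(500:800, 1)
  slack <- L - sum(lens) - 2L - 3L - 4L * (k - 1L)
  g <- as.vector(stats::rmultinom(1, slack, rep(1, k + 1L)))
  starts <- 2L + g[1] + c(0L, cumsum(lens[-k] + 4L + g[2:k]))
  intron_i <- sample(seq_len(n_exons - 1L), 1)
  wt_intron <- sample(150:400, 1)
  gene_model(seed = seed,
             utr5_len = 30L, n_cds_codons = n_codons, utr3_len = 40L,
             exon_lengths = exon_lengths,
             default_intron_len = 80L,
             insertion_intron = intron_i,
             wt_intron_len = wt_intron,
             insertion_offset_in_intron = sample(2:(wt_intron - 2L), 1),
             insertion_len = L,
             retained_starts = starts,
             retained_lengths = lens,
             stop_codon_offsets = NULL)
}
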