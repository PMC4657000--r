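#' Detect a single contiguous insertion between two sequences
#'
#' Locates the insertion that turns `wt` into `mut`, left-normalized: when
#' the insertion point is ambiguous (repeated sequence at the junction) the
#' smallest position yielding an identical reconstruction is reported, the
#' same convention as variant left-alignment.
#'
#' @param wt,mut sequences (character scalars); `nchar(mut) > nchar(wt)`
#'   and the two must differ by exactly one contiguous insertion.
#' @return object of class `insertion_event`: `position` (0-based offset in
#'   `wt` before which the insertion sits), `inserted_seq`, `length`.
#' @export
detect_insertion <- function(wt, mut) {
  nw <- nchar(wt); nm <- nchar(mut)
  d <- nm - nw
  if (d <= 0) .stopf("mut must be longer than wt (got %d vs %d)", nm, nw)
  wr <- charToRaw(wt); mr <- charToRaw(mut)
  # longest common prefix / suffix of wt against mut
  p0 <- if (nw == 0) 0L else {
    neq <- which(wr != mr[seq_len(nw)])
    if (length(neq)) neq[1] - 1L else nw
  }
  s0 <- if (nw == 0) 0L else {
    neq <- which(rev(wr) != rev(mr)[seq_len(nw)])
    if (length(neq)) neq[1] - 1L else nw
  }
  pos <- max(0L, nw - s0)  # leftmost valid insertion point
  if (pos > p0)
    .stopf("sequences do not differ by a single contiguous insertion")
  structure(list(position = pos,
                 inserted_seq = substr(mut, pos + 1L, pos + d),
                 length = d),
            class = "insertion_event")
}

#' @rdname detect_insertion
#' @param position 0-based offset in `wt`.
#' @param seq sequence to insert.
#' @return `apply_insertion()`: the mutant sequence.
#' @export
apply_insertion <- function(wt, position, seq) {
  stopifnot(position >= 0, position <= nchar(wt))
  paste0(substr(wt, 1, position), seq, substring(wt, position + 1))
}

#' Reconstruct cryptic-exon splicing of an insertion
#'
#' Given the genomic insertion sequence (optionally with flanking context)
#' and the extra sequence observed in the mature cDNA, finds the
#' minimum-cardinality chain of exact, non-overlapping, order-preserving
#' matches of cDNA substrings within the genomic sequence that concatenate
#' to exactly the cDNA insertion -- the retained "cryptic exons". Each
#' match must be at least `min_fragment` long (the final fragment is
#' exempt when the remaining cDNA is shorter), which suppresses spurious
#' micro-chains. Matching is exact: the method is intended for
#' same-allele sequence comparisons. Every inter-fragment gap is then
#' checked for the canonical 5' `GT` donor and 3' `AG` acceptor.
#'
#' The search is a dynamic programme over states (cDNA offset, minimum
#' usable genomic offset) with memoized minimum fragment counts; among
#' minimal chains the leftmost (lexicographically smallest genomic starts)
#' is returned and the existence of an alternative minimal chain is
#' flagged.
#'
#' @param context genomic sequence containing the retained fragments
#'   (coordinates in the result are relative to it).
#' @param cdna_insertion the inserted sequence observed in the cDNA.
#' @param min_fragment minimum retained-fragment length in bp.
#' @return object of class `splice_model`: `fragments` (data frame
#'   `g_start`, `g_end` 0-based half-open, `order_index`), `donor_ok` /
#'   `acceptor_ok` (per inter-fragment junction), `gaps` (the excised
#'   sequences), `n_fragments`, `cdna_insertion_len`, `ambiguous`.
#' @export
reconstruct_splice <- function(context, cdna_insertion, min_fragment = 20L) {
  m <- nchar(cdna_insertion)
  if (m == 0) .stopf("cdna_insertion is empty")
  min_fragment <- max(1L, as.integer(min_fragment))
  L <- nchar(context)
  gr <- charToRaw(context); cr <- charToRaw(cdna_insertion)

  K <- min(4L, min_fragment, m)
  idx <- NULL
  if (L >= K) {
    keys <- substring(context, seq_len(L - K + 1L), K:L)
    idx <- split(0:(L - K), keys)
  }
  lce <- function(s, i, cap) {
    if (cap <= 0L) return(0L)
    neq <- which(gr[(s + 1L):(s + cap)] != cr[(i + 1L):(i + cap)])
    if (length(neq)) neq[1] - 1L else cap
  }
  cand_starts <- function(i, j) {
    rem <- m - i
    if (rem >= K) {
      ss <- idx[[substr(cdna_insertion, i + 1L, i + K)]]
      if (is.null(ss)) integer(0) else ss[ss >= j]
    } else {
      if (L - rem < j) return(integer(0))
      ss <- j:(L - rem)
      ss <- ss[gr[ss + 1L] == cr[i + 1L]]
      ss[vapply(ss, function(s) lce(s, i, rem) == rem, logical(1))]
    }
  }
  valid_lens <- function(i, l) {
    rem <- m - i
    hi <- min(l, rem)
    lens <- if (hi >= min_fragment) min_fragment:hi else integer(0)
    if (rem <= l && rem < min_fragment) lens <- c(lens, rem)  # short last frag
    lens
  }

  memo <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv()); state$max_i <- 0L
  minfrags <- function(i, j) {
    if (i == m) return(0)
    key <- paste0(i, "_", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- Inf
    for (s in cand_starts(i, j)) {
      l <- lce(s, i, min(m - i, L - s))
      if (l < 1L) next
      if (i + l > state$max_i) state$max_i <- i + l
      for (len in valid_lens(i, l)) {
        sub <- minfrags(i + len, s + len)
        if (sub + 1 < best) best <- sub + 1
      }
    }
    memo[[key]] <- best
    best
  }
  kmin <- minfrags(0L, 0L)
  if (!is.finite(kmin))
    .stopf(paste0("cDNA insertion is not splicable from the genomic context ",
                  "(longest matched cDNA prefix: %d of %d bp)"),
           state$max_i, m)

  build_chain <- function(i, j, k) {
    if (i == m) return(NULL)
    for (s in cand_starts(i, j)) {
      l <- lce(s, i, min(m - i, L - s))
      if (l < 1L) next
      for (len in valid_lens(i, l)) {
        if (minfrags(i + len, s + len) == k - 1)
          return(rbind(c(s, len), build_chain(i + len, s + len, k - 1)))
      }
    }
    .stopf("internal error: chain reconstruction failed")
  }
  count_chains <- function(i, j, k, cap = 2L) {
    if (i == m) return(1L)
    total <- 0L
    for (s in cand_starts(i, j)) {
      l <- lce(s, i, min(m - i, L - s))
      if (l < 1L) next
      for (len in valid_lens(i, l)) {
        if (minfrags(i + len, s + len) == k - 1) {
          total <- total + count_chains(i + len, s + len, k - 1, cap)
          if (total >= cap) return(cap)
        }
      }
    }
    total
  }
  chain <- build_chain(0L, 0L, kmin)
  ambiguous <- count_chains(0L, 0L, kmin) > 1L

  g_start <- chain[, 1]; g_end <- chain[, 1] + chain[, 2]
  nf <- nrow(chain)
  donor_ok <- acceptor_ok <- logical(0)
  gaps <- character(0)
  if (nf > 1L) {
    gaps <- substring(context, g_end[-nf] + 1L, g_start[-1])
    donor_ok <- substr(gaps, 1L, 2L) == "GT"
    acceptor_ok <- nchar(gaps) >= 2L &
      substring(gaps, pmax(nchar(gaps) - 1L, 1L)) == "AG"
  }
  structure(list(fragments = data.frame(g_start = g_start, g_end = g_end,
                                        order_index = seq_len(nf)),
                 donor_ok = donor_ok, acceptor_ok = acceptor_ok,
                 gaps = gaps,
                 n_fragments = nf,
                 cdna_insertion_len = m,
                 min_fragment = min_fragment,
                 ambiguous = ambiguous),
            class = "splice_model")
}

#' Splice-model fragment sequences
#'
#' @param model a `splice_model` from [reconstruct_splice()].
#' @param context the genomic sequence the model was built against.
#' @return character vector of retained fragment sequences; their
#'   concatenation equals the cDNA insertion byte-exactly.
#' @export
splice_fragment_seqs <- function(model, context) {
  substring(context, model$fragments$g_start + 1L, model$fragments$g_end)
}

#' Find and translate the open reading frame of a transcript
#'
#' Default policy: the longest ATG-initiated reading frame terminated by an
#' in-frame stop (TAA/TAG/TGA), searched over the three forward frames,
#' translated with the standard nuclear code. The alternative
#' `"first_atg"` policy takes the 5'-most ATG and reads to its first
#' in-frame stop. A transcript without any stop-terminated ATG frame gives
#' a no-ORF result (`found = FALSE`), not an error.
#'
#' @param cdna transcript sequence over `{A,C,G,T}`.
#' @param policy `"longest"` or `"first_atg"`.
#' @return list: `found`, `orf_start` / `orf_end` (0-based half-open cDNA
#'   coordinates, stop codon included), `orf_len_nt`, `protein` (residues,
#'   stop excluded), `protein_len_aa`.
#' @export
find_orf <- function(cdna, policy = c("longest", "first_atg")) {
  policy <- match.arg(policy)
  n <- nchar(cdna)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (f in 0:2) {
    starts_at <- seq.int(f + 1L, by = 3L,
                         length.out = max((n - f) %/% 3L, 0L))
    if (!length(starts_at)) next
    codons <- substring(cdna, starts_at, starts_at + 2L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% stops
    prev_stop <- 0L
    for (t in which(is_stop)) {
      atg <- which(is_atg[(prev_stop + 1L):t])
      if (length(atg)) {
        a <- prev_stop + atg[1]
        cand <- list(orf_start = starts_at[a] - 1L,
                     orf_end = starts_at[t] + 2L,
                     atg_pos = starts_at[a] - 1L)
        len <- cand$orf_end - cand$orf_start
        if (is.null(best) || policy == "longest" && len > best$len ||
            policy == "first_atg" && cand$atg_pos < best$orf_start)
          best <- c(cand, len = len)
      }
      prev_stop <- t
    }
  }
  if (is.null(best))
    return(list(found = FALSE, orf_start = NA_integer_, orf_end = NA_integer_,
                orf_len_nt = NA_integer_, protein = NA_character_,
                protein_len_aa = NA_integer_))
  orf_seq <- substr(cdna, best$orf_start + 1L, best$orf_end)
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(orf_seq)))
  prot <- sub("\\*$", "", prot)
  list(found = TRUE, orf_start = best$orf_start, orf_end = best$orf_end,
       orf_len_nt = best$len, protein = prot, protein_len_aa = nchar(prot))
}

# translate from a fixed start position to the first in-frame stop;
# returns protein length and stop codon start (NA if no stop before end)
.translate_from <- function(cdna, start0) {
  n <- nchar(cdna)
  starts_at <- seq.int(start0 + 1L, by = 3L,
                       length.out = max((n - start0) %/% 3L, 0L))
  codons <- substring(cdna, starts_at, starts_at + 2L)
  st <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(st)) {
    list(protein_len_aa = st[1] - 1L, stop_start0 = starts_at[st[1]] - 1L,
         terminated = TRUE)
  } else {
    list(protein_len_aa = length(codons), stop_start0 = NA_integer_,
         terminated = FALSE)
  }
}

#' Compare WT and mutant transcripts for ORF truncation
#'
#' The WT ORF is located with [find_orf()]; the mutant transcript is then
#' translated **from the same start codon** (its position is upstream of
#' the insertion and therefore unchanged), which reflects how the ribosome
#' reads the mutant mRNA. A longest-ORF policy applied to the mutant can
#' instead latch onto an internal ATG downstream of a frameshifting
#' insertion and hide the truncation, which is why it is not used here.
#' In-frame stop codons whose codon lies inside the inserted sequence are
#' reported as novel stops, with the first one's position relative to the
#' insertion start.
#'
#' @param wt_cdna,mut_cdna transcript sequences. Identical sequences are
#'   reported as equal-length with the flag `FALSE`.
#' @param loss_threshold flag `loss_of_function_likely` when the mutant
#'   protein is shorter than this fraction of the WT protein.
#' @return list with `wt_protein_len_aa`, `mut_protein_len_aa`,
#'   `premature_stop`, `n_novel_stops_in_insert`,
#'   `first_novel_stop_offset_in_insert` (0-based, codon start relative to
#'   the insertion; `NA` when none), `insertion` (the detected
#'   [detect_insertion()] event or `NULL`), `loss_of_function_likely`.
#' @export
truncation_report <- function(wt_cdna, mut_cdna, loss_threshold = 0.5) {
  wt_orf <- find_orf(wt_cdna)
  if (!wt_orf$found) .stopf("WT transcript has no ORF")
  ins <- if (nchar(mut_cdna) > nchar(wt_cdna))
    detect_insertion(wt_cdna, mut_cdna) else NULL
  if (is.null(ins) && !identical(wt_cdna, mut_cdna))
    .stopf("mut_cdna is neither identical to wt_cdna nor longer by an insertion")
  if (is.null(ins)) {
    return(list(wt_protein_len_aa = wt_orf$protein_len_aa,
                mut_protein_len_aa = wt_orf$protein_len_aa,
                premature_stop = FALSE, n_novel_stops_in_insert = 0L,
                first_novel_stop_offset_in_insert = NA_integer_,
                insertion = NULL, loss_of_function_likely = FALSE))
  }
  if (ins$position <= wt_orf$orf_start)
    .stopf("insertion upstream of the start codon; no coding comparison")
  tr <- .translate_from(mut_cdna, wt_orf$orf_start)
  # novel in-frame stops with their codon start inside the inserted region
  n <- nchar(mut_cdna)
  starts_at <- seq.int(wt_orf$orf_start + 1L, by = 3L,
                       length.out = max((n - wt_orf$orf_start) %/% 3L, 0L))
  codons <- substring(mut_cdna, starts_at, starts_at + 2L)
  stop0 <- starts_at[codons %in% c("TAA", "TAG", "TGA")] - 1L
  in_insert <- stop0 >= ins$position & stop0 < ins$position + ins$length
  novel <- stop0[in_insert]
  mut_len <- tr$protein_len_aa
  list(wt_protein_len_aa = wt_orf$protein_len_aa,
       mut_protein_len_aa = mut_len,
       premature_stop = mut_len < wt_orf$protein_len_aa,
       n_novel_stops_in_insert = length(novel),
       first_novel_stop_offset_in_insert =
         if (length(novel)) novel[1] - ins$position else NA_integer_,
       insertion = ins,
       loss_of_function_likely = mut_len < loss_threshold *
         wt_orf$protein_len_aa)
}
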