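#' Simulation configuration for the pooled-cross mapping design
#'
#' The defaults emulate the study design the pipeline assumes: seven
#' families of amel/amel x amel/+ crosses totalling 256 offspring, four
#' sequenced DNA samples (the two parents of one family plus two
#' phenotype-sorted offspring pools of 20), per-sample read depths around
#' 30x so that most sites fall inside the \[18, 50\] coverage window, a
#' causal locus at 110.5 Mbp of a 200-Mbp chromosome, and a seven-marker
#' panel around it. One global `seed` drives derived per-stage substreams,
#' so any stage is reproducible in isolation; the same seed gives
#' bit-identical outputs.
#'
#' @param seed integer seed for all randomness.
#' @param n_families number of crosses.
#' @param offspring_per_family integer vector, one count per family.
#' @param karyotype named numeric vector of chromosome lengths in Mbp.
#' @param causal_chrom,causal_pos_mbp location of the causal locus.
#' @param n_contigs number of exome contigs carrying candidate SNPs.
#' @param fraction_linked proportion of contigs fully linked to the causal
#'   locus.
#' @param snps_per_contig_mean mean SNPs per contig (zero-truncated
#'   Poisson).
#' @param coverage_mean mean per-sample read depth (Poisson).
#' @param sequencing_error per-read probability of reporting the other
#'   allele.
#' @param pool_size offspring per phenotype pool.
#' @param pool_family family index feeding the pools; `NULL` picks the
#'   family with the most balanced phenotype counts.
#' @param marker_positions marker table (`marker`, `chrom`, `start_mbp`,
#'   `end_mbp`); default [default_marker_table()].
#' @param cm_per_mbp recombination rate for the Haldane map.
#' @param prop_low_mq,prop_indel,prop_multiallelic fractions of simulated
#'   records that carry a sub-threshold mapping quality, are indels, or
#'   are triallelic (exercising the quality filter).
#' @param hit_rate probability that a contig receives a reference
#'   placement (default 0.36, the observed placed fraction the generator
#'   emulates).
#' @param linked_window_mbp half-width of the placement window around the
#'   causal position for linked contigs.
#' @param mislocate_fraction fraction of linked contigs placed uniformly
#'   at random instead (noisy synteny).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 7L,
                       offspring_per_family = c(40L, 40L, 40L, 36L, 36L,
                                                32L, 32L),
                       karyotype = c(chr1 = 200, chr2 = 180, chr3 = 200,
                                     chr4 = 150, chr5 = 140, chr6 = 120),
                       causal_chrom = "chr3",
                       causal_pos_mbp = 110.5,
                       n_contigs = 2000L,
                       fraction_linked = 0.1,
                       snps_per_contig_mean = 1.5,
                       coverage_mean = 30,
                       sequencing_error = 0.002,
                       pool_size = 20L,
                       pool_family = NULL,
                       marker_positions = default_marker_table(),
                       cm_per_mbp = 1,
                       prop_low_mq = 0.05,
                       prop_indel = 0.05,
                       prop_multiallelic = 0.03,
                       hit_rate = 0.36,
                       linked_window_mbp = 10,
                       mislocate_fraction = 0.05) {
  if (length(offspring_per_family) != n_families)
    .stopf("offspring_per_family must have length n_families (%d)", n_families)
  if (fraction_linked < 0 || fraction_linked > 1)
    .stopf("fraction_linked must be in [0, 1]")
  if (coverage_mean <= 0) .stopf("coverage_mean must be > 0")
  if (!causal_chrom %in% names(karyotype))
    .stopf("causal_chrom '%s' not in karyotype", causal_chrom)
  if (causal_pos_mbp <= 0 || causal_pos_mbp >= karyotype[[causal_chrom]])
    .stopf("causal position outside its chromosome")
  structure(as.list(environment()), class = "sim_config")
}

.bases <- c("A", "C", "G", "T")
.stop_codons <- c("TAA", "TAG", "TGA")
.all_codons <- as.vector(outer(outer(.bases, .bases, paste0), .bases, paste0))
.sense_codons <- setdiff(.all_codons, .stop_codons)

.random_dna <- function(n) paste(sample(.bases, n, replace = TRUE),
                                 collapse = "")

# random sequence guaranteed to contain no ATG (for 5' UTRs, so the
# annotated start codon is the 5'-most ATG)
.random_dna_no_atg <- function(n) {
  s <- .random_dna(n)
  while (grepl("ATG", s, fixed = TRUE)) s <- sub("ATG", "ACG", s, fixed = TRUE)
  s
}

#' Simulate the pedigree of the pooled crosses
#'
#' Every offspring of an amel/amel x amel/+ cross receives one amel allele
#' from the homozygous parent; the heterozygous parent's gamete determines
#' both phenotype (mutant iff it carries amel at the causal locus) and the
#' marker genotypes: the marker allele co-transmits with the causal allele
#' except with probability given by the Haldane map of the marker-to-locus
#' distance. Marker genotypes are therefore `het` or `hom_amel` only.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (the per-individual genotype table) and
#'   `truth` (long data frame: `individual`, `marker`, `recombinant`,
#'   plus the transmitted causal allele per individual as attribute
#'   columns on `genotypes`).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config$seed, "pedigree"))
  fam_sizes <- config$offspring_per_family
  fam <- rep(seq_along(fam_sizes), fam_sizes)
  n <- sum(fam_sizes)
  id <- sprintf("F%d_%03d", fam, sequence(fam_sizes))
  causal_amel <- rbinom(n, 1L, 0.5) == 1L
  geno <- data.frame(individual = id,
                     family = paste0("fam", fam),
                     phenotype = ifelse(causal_amel, "mutant", "WT"),
                     stringsAsFactors = FALSE)
  mk <- config$marker_positions
  truth <- vector("list", nrow(mk))
  for (i in seq_len(nrow(mk))) {
    mid <- (mk$start_mbp[i] + mk$end_mbp[i]) / 2
    theta <- haldane_theta(abs(mid - config$causal_pos_mbp),
                           config$cm_per_mbp)
    rec <- rbinom(n, 1L, theta) == 1L
    allele_amel <- xor(causal_amel, rec)
    geno[[mk$marker[i]]] <- ifelse(allele_amel, "hom_amel", "het")
    truth[[i]] <- data.frame(individual = id, marker = mk$marker[i],
                             recombinant = rec, stringsAsFactors = FALSE)
  }
  attr(geno, "causal_amel") <- causal_amel
  list(genotypes = geno, truth = do.call(rbind, truth))
}

# pick the pool family: most balanced phenotype split
.choose_pool_family <- function(config, genotypes) {
  if (!is.null(config$pool_family)) return(as.integer(config$pool_family))
  fams <- paste0("fam", seq_len(config$n_families))
  balance <- vapply(fams, function(f) {
    ph <- genotypes$phenotype[genotypes$family == f]
    min(sum(ph == "WT"), sum(ph == "mutant"))
  }, numeric(1))
  which.max(balance)
}

#' Simulate pooled variant calls at linked and unlinked contigs
#'
#' Linked contigs carry the segregation pattern of the causal region (the
#' alignment reference is the mutant parent's own assembly, so the
#' causally linked allele is the *reference* allele: alternate-allele
#' dosages are 0.5 in the WT parent and WT pool and 0 in the mutant parent
#' and mutant pool). At unlinked contigs each of the four samples draws
#' its true allelic state independently and uniformly from hom-ref, het,
#' hom-alt. Per-sample depths are Poisson around `coverage_mean`; allele
#' reads are binomial around the true dosage with a per-read error flip.
#' A configurable fraction of records are indels, triallelic, or
#' low-mapping-quality, so the quality filter has work to do.
#'
#' @param config a [sim_config()].
#' @param pedigree result of [simulate_pedigree()] (used to select and
#'   validate the pooled family).
#' @return list with `variants` (a [variant_table()]), `truth` (data
#'   frame `contig`, `linked`), `site_truth` (per-site true alternate
#'   dosages per role) and `pools` (pooled family and realized pool
#'   sizes).
#' @export
simulate_variant_calls <- function(config, pedigree) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config$seed, "variants"))
  geno <- pedigree$genotypes
  pf <- .choose_pool_family(config, geno)
  ph <- geno$phenotype[geno$family == paste0("fam", pf)]
  n_wt <- min(config$pool_size, sum(ph == "WT"))
  n_mut <- min(config$pool_size, sum(ph == "mutant"))
  if (n_wt < config$pool_size || n_mut < config$pool_size)
    warning(sprintf("family %d has fewer than %d offspring of a phenotype; ",
                    pf, config$pool_size),
            "pooling all available individuals", call. = FALSE)

  nc <- config$n_contigs
  contig <- sprintf("contig%05d", seq_len(nc))
  linked <- rbinom(nc, 1L, config$fraction_linked) == 1L
  k <- 1L + rpois(nc, max(config$snps_per_contig_mean - 1, 0))
  row_contig <- rep(contig, k)
  row_linked <- rep(linked, k)
  ns <- length(row_contig)
  pos <- as.integer(unlist(lapply(k, function(m)
    cumsum(50L + rpois(m, 300)))))

  ref <- sample(.bases, ns, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(.bases, b), 1), character(1),
                USE.NAMES = FALSE)
  u <- runif(ns)
  indel <- u < config$prop_indel
  multi <- !indel & u < config$prop_indel + config$prop_multiallelic
  alt[indel] <- paste0(alt[indel],
                       sample(.bases, sum(indel), replace = TRUE))
  if (any(multi)) {
    alt2 <- mapply(function(b, a) sample(setdiff(.bases, c(b, a)), 1),
                   ref[multi], alt[multi], USE.NAMES = FALSE)
    alt[multi] <- paste(alt[multi], alt2, sep = ",")
  }
  low_mq <- runif(ns) < config$prop_low_mq
  mq <- ifelse(low_mq, round(runif(ns, 0, 99), 1),
               round(runif(ns, 100, 250), 1))

  # true alternate-allele dosage per role
  dosage <- matrix(NA_real_, ns, 4, dimnames = list(NULL, SAMPLE_ROLES))
  dosage[row_linked, ] <- rep(c(0.5, 0, 0.5, 0), each = sum(row_linked))
  n_unl <- sum(!row_linked)
  dosage[!row_linked, ] <- sample(c(0, 0.5, 1), n_unl * 4L, replace = TRUE)

  e <- config$sequencing_error
  df <- data.frame(contig = row_contig, pos = pos, ref = ref, alt = alt,
                   mq = mq, stringsAsFactors = FALSE)
  for (j in seq_along(SAMPLE_ROLES)) {
    depth <- rpois(ns, config$coverage_mean)
    p_alt <- dosage[, j] * (1 - e) + (1 - dosage[, j]) * e
    da <- rbinom(ns, depth, p_alt)
    df[[paste0(SAMPLE_ROLES[j], "_ref")]] <- depth - da
    df[[paste0(SAMPLE_ROLES[j], "_alt")]] <- da
  }
  list(variants = variant_table(df),
       truth = data.frame(contig = contig, linked = linked,
                          stringsAsFactors = FALSE),
       site_truth = cbind(data.frame(contig = row_contig, pos = pos,
                                     linked = row_linked,
                                     stringsAsFactors = FALSE),
                          as.data.frame(dosage)),
       pools = list(family = pf, n_wt = n_wt, n_mut = n_mut))
}

#' Simulate contig placements on the reference karyotype
#'
#' Each contig receives a placement with probability `hit_rate`. Linked
#' contigs place inside a window around the causal position (except a
#' `mislocate_fraction` placed uniformly, emulating noisy synteny);
#' unlinked contigs place uniformly across the karyotype with probability
#' proportional to chromosome length. Hit spans are exon-scale (0.5-5 kb).
#'
#' @param config a [sim_config()].
#' @param truth data frame with columns `contig` and `linked` (e.g. from
#'   [simulate_variant_calls()], possibly subset to surviving contigs).
#' @return hit data frame (`contig`, `chrom`, `start_mbp`, `end_mbp`,
#'   `score`).
#' @export
simulate_hit_table <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"),
            all(c("contig", "linked") %in% names(truth)))
  set.seed(.stage_seed(config$seed, "hits"))
  n <- nrow(truth)
  placed <- rbinom(n, 1L, config$hit_rate) == 1L
  t2 <- truth[placed, , drop = FALSE]
  m <- nrow(t2)
  if (m == 0L)
    return(data.frame(contig = character(0), chrom = character(0),
                      start_mbp = numeric(0), end_mbp = numeric(0),
                      score = numeric(0)))
  kar <- config$karyotype
  in_window <- t2$linked & runif(m) >= config$mislocate_fraction
  chrom <- character(m)
  mid <- numeric(m)
  chrom[in_window] <- config$causal_chrom
  lo <- max(config$causal_pos_mbp - config$linked_window_mbp, 0.5)
  hi <- min(config$causal_pos_mbp + config$linked_window_mbp,
            kar[[config$causal_chrom]] - 0.5)
  mid[in_window] <- runif(sum(in_window), lo, hi)
  n_out <- sum(!in_window)
  if (n_out) {
    ch <- sample(names(kar), n_out, replace = TRUE, prob = kar / sum(kar))
    chrom[!in_window] <- ch
    mid[!in_window] <- runif(n_out, 0.5, kar[ch] - 0.5)
  }
  span <- runif(m, 0.0005, 0.005)
  data.frame(contig = t2$contig, chrom = chrom,
             start_mbp = mid - span / 2, end_mbp = mid + span / 2,
             score = round(runif(m, 50, 500), 1),
             stringsAsFactors = FALSE)
}
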