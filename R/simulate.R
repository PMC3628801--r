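#' Simulation configuration
#'
#' Defines the synthetic study: a small case/control cohort genotyped at
#' dense biallelic markers on one chromosome, with an identical-by-descent
#' homozygous segment planted in all cases, plus a variant table over that
#' segment carrying one causal single-base coding deletion and one linked
#' nonsense passenger in perfect LD. Defaults mirror the mapped study
#' design: 7 cases, 7 controls, a ~3.5 Mb planted segment, a 12-genome
#' panel; the marker count is 5,000 on one 80 Mb chromosome, preserving the
#' original marker density (roughly 40 markers inside the segment).
#'
#' @param seed RNG seed (mandatory; the whole simulation is a deterministic
#'   function of the config).
#' @param n_cases,n_controls cohort sizes.
#' @param n_markers markers on the simulated chromosome.
#' @param chrom chromosome name.
#' @param chrom_length_bp chromosome length.
#' @param ibd_start,ibd_end planted shared-homozygosity segment (bp).
#' @param maf_shape Beta shape parameters; marker MAFs are
#'   `0.05 + 0.45 * Beta(shape1, shape2)`, spanning the post-QC range.
#' @param missing_rate per-genotype missingness.
#' @param genotype_error_rate per-genotype error rate.
#' @param n_panel panel genomes for the absence step.
#' @param n_interval_variants variants planted inside the segment.
#' @param n_background_variants variants outside the segment.
#' @param fail_fraction fraction of variants built to fail each hard
#'   filter.
#' @param carrier_het_freq heterozygote frequency of the causal allele
#'   among breed controls in the validation cohort.
#' @param n_breed_controls,n_other_breeds validation cohort group sizes.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_cases = 7L, n_controls = 7L,
                       n_markers = 5000L,
                       chrom = "chr2",
                       chrom_length_bp = 80e6,
                       ibd_start = 40e6, ibd_end = 43.5e6,
                       maf_shape = c(1.5, 1.5),
                       missing_rate = 0.02,
                       genotype_error_rate = 0.001,
                       n_panel = 12L,
                       n_interval_variants = 60L,
                       n_background_variants = 200L,
                       fail_fraction = 0.10,
                       carrier_het_freq = 0.062,
                       n_breed_controls = 200L,
                       n_other_breeds = 357L) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  if (cfg$ibd_start < 1 || cfg$ibd_end > cfg$chrom_length_bp ||
      cfg$ibd_start >= cfg$ibd_end)
    stop("planted segment must lie within the chromosome", call. = FALSE)
  rates <- c(cfg$missing_rate, cfg$genotype_error_rate, cfg$fail_fraction,
             cfg$carrier_het_freq)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0,1]", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the SNP-array cohort with a planted IBD segment
#'
#' Marker positions are placed uniformly at random and sorted; control
#' genotypes are drawn under Hardy-Weinberg equilibrium at each marker's
#' MAF; case genotypes likewise, except inside the planted segment where
#' every case is homozygous for one fixed founder haplotype (the
#' identical-by-descent state of an inbred recessive cohort). Genotype
#' error then missingness are applied last.
#'
#' @param cfg a [sim_config()].
#' @return list with `dataset` (a [genotype_dataset()]) and `truth`
#'   (`planted_interval`, `founder_allele` per in-segment marker,
#'   `segment_marker_ids`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$n_markers
  n <- cfg$n_cases + cfg$n_controls
  pos <- sort(sample.int(cfg$chrom_length_bp, m))
  maf <- 0.05 + 0.45 * stats::rbeta(m, cfg$maf_shape[1], cfg$maf_shape[2])

  in_seg <- pos >= cfg$ibd_start & pos <= cfg$ibd_end
  if (sum(in_seg) < 10L)
    stop("planted segment contains fewer than 10 markers at this density",
         call. = FALSE)

  geno <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  founder <- stats::rbinom(sum(in_seg), 1L, maf[in_seg])
  ci <- seq_len(cfg$n_cases)
  geno[ci, in_seg] <- matrix(rep(2L * founder, each = cfg$n_cases),
                             cfg$n_cases, sum(in_seg))

  if (cfg$genotype_error_rate > 0) {
    err <- stats::runif(n * m) < cfg$genotype_error_rate
    geno[err] <- sample(0:2, sum(err), replace = TRUE)
  }
  if (cfg$missing_rate > 0)
    geno[stats::runif(n * m) < cfg$missing_rate] <- NA_integer_

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  map <- data.frame(marker_id = sprintf("m%05d", seq_len(m)),
                    chromosome = cfg$chrom, position_bp = pos,
                    ref_allele = ref, alt_allele = unname(alt),
                    stringsAsFactors = FALSE)
  samples <- c(sprintf("case%02d", seq_len(cfg$n_cases)),
               sprintf("ctrl%02d", seq_len(cfg$n_controls)))
  phenotype <- c(rep("case", cfg$n_cases), rep("control", cfg$n_controls))
  ds <- genotype_dataset(map, samples, phenotype, geno)

  list(dataset = ds,
       truth = list(planted_interval = c(start_bp = cfg$ibd_start,
                                         end_bp = cfg$ibd_end),
                    founder_allele = founder,
                    segment_marker_ids = map$marker_id[in_seg]))
}

## a random CDS of n_codons with no internal stop, ATG start, TAA end
random_cds <- function(n_codons) {
  codons <- c("GCT", "TGT", "GAT", "GAA", "TTT", "GGT", "CAT", "ATT",
              "AAA", "CTG", "ATG", "AAT", "CCT", "CAG", "CGT", "TCT",
              "ACT", "GTT", "TGG", "TAT")
  paste0("ATG",
         paste(sample(codons, n_codons - 2L, replace = TRUE), collapse = ""),
         "TAA")
}

## place `context` into the CDS starting at 1-based position `at`
with_context <- function(cds, at, context) {
  paste0(substr(cds, 1L, at - 1L), context,
         substr(cds, at + nchar(context), nchar(cds)))
}

#' Simulate the proband variant calls, panel and transcripts
#'
#' Plants `n_interval_variants` variants inside the shared segment and
#' background variants outside it. QC annotations are drawn so that a
#' configured fraction fails each hard-filter expression; the panel carries
#' the alternate allele of every variant except the causal deletion and the
#' passenger nonsense SNV, which are panel-absent and homozygous in the
#' proband. Synthetic transcripts are constructed so the causal single-base
#' deletion is a frameshift with the new stop at frameshifted position 3,
#' and the passenger is a nonsense SNV.
#'
#' @param cfg a [sim_config()].
#' @param truth the `truth` element from [simulate_cohort()].
#' @return list with `variants` ([variant_table()]), `panel`
#'   ([panel_genotypes()]), `transcripts`, `coding_variants`,
#'   `consequences` (named list keyed by variant id), and `truth` extended
#'   with `causal_variant_id` / `passenger_variant_id`.
#' @export
simulate_variants <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  iv_start <- truth$planted_interval[["start_bp"]]
  iv_end <- truth$planted_interval[["end_bp"]]

  n_iv <- cfg$n_interval_variants
  n_bg <- cfg$n_background_variants
  # a coarse grid keeps variants >= 20 bp apart: no accidental SNV clusters
  grid_iv <- seq(iv_start + 50, iv_end - 50, by = 20)
  grid_bg <- setdiff(seq(1000, cfg$chrom_length_bp - 1000, by = 5000),
                     seq(iv_start - 1000, iv_end + 1000, by = 5000))
  pos <- c(sort(sample(grid_iv, n_iv)), sort(sample(grid_bg, n_bg)))
  n <- n_iv + n_bg
  in_iv <- c(rep(TRUE, n_iv), rep(FALSE, n_bg))

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")

  # proband genotype: the affected genome is homozygous through the
  # segment, so in-interval variants are mostly hom_alt
  genotype <- ifelse(in_iv,
                     sample(c("hom_alt", "hom_ref"), n, TRUE, c(0.8, 0.2)),
                     sample(c("hom_alt", "het", "hom_ref"), n, TRUE,
                            c(0.3, 0.4, 0.3)))

  # QC annotations: passing draws, then planted failures per expression
  qual <- stats::runif(n, 50, 3000)
  qd <- stats::runif(n, 6, 30)
  dp <- pmax(1L, round(stats::rlnorm(n, log(20), 0.35)))
  mq0 <- stats::rbinom(n, 1L, 0.3)
  hrun <- pmin(stats::rpois(n, 0.4), 5L)
  sb <- stats::runif(n, -3000, -0.01)

  fail_lowq <- stats::runif(n) < cfg$fail_fraction
  clause <- sample(4L, n, replace = TRUE)
  qual[fail_lowq & clause == 1L] <- stats::runif(sum(fail_lowq & clause == 1L), 1, 29.9)
  qd[fail_lowq & clause == 2L] <- stats::runif(sum(fail_lowq & clause == 2L), 0.1, 4.9)
  hrun[fail_lowq & clause == 3L] <- sample(6:12, sum(fail_lowq & clause == 3L), TRUE)
  sb[fail_lowq & clause == 4L] <- stats::runif(sum(fail_lowq & clause == 4L), 0.01, 50)
  fail_hard <- stats::runif(n) < cfg$fail_fraction
  mq0[fail_hard] <- sample(4:12, sum(fail_hard), TRUE)
  dp[fail_hard] <- pmax(1L, floor(mq0[fail_hard] * stats::runif(sum(fail_hard), 2, 9)))

  vt <- data.frame(chrom = cfg$chrom, pos = pos, ref = ref,
                   alt = unname(alt), genotype = genotype, qual = qual,
                   qd = qd, mq0 = mq0, dp = dp, hrun = hrun, sb = sb,
                   stringsAsFactors = FALSE)

  # the causal 1-bp deletion and the linked passenger nonsense SNV: both
  # homozygous in the proband, clean QC, inside the segment
  mid <- floor((iv_start + iv_end) / 2)
  causal <- data.frame(chrom = cfg$chrom, pos = mid + 7, ref = "TC",
                       alt = "T", genotype = "hom_alt", qual = 2000,
                       qd = 25, mq0 = 0L, dp = 30L, hrun = 1L, sb = -1200,
                       stringsAsFactors = FALSE)
  passenger <- data.frame(chrom = cfg$chrom, pos = mid - 100003, ref = "G",
                          alt = "A", genotype = "hom_alt", qual = 1800,
                          qd = 22, mq0 = 0L, dp = 28L, hrun = 0L, sb = -900,
                          stringsAsFactors = FALSE)
  vt <- vt[!(vt$pos %in% c(causal$pos, passenger$pos)), ]
  vt <- variant_table(rbind(vt, causal, passenger))
  causal_id <- sprintf("%s:%d:TC>T", cfg$chrom, causal$pos)
  passenger_id <- sprintf("%s:%d:G>A", cfg$chrom, passenger$pos)

  # panel: every variant except causal/passenger is carried by >= 1 genome
  codes <- c("hom_ref", "het", "hom_alt", "missing")
  pg <- matrix(sample(codes, nrow(vt) * cfg$n_panel, TRUE,
                      prob = c(0.55, 0.28, 0.12, 0.05)),
               nrow(vt), cfg$n_panel, dimnames = list(vt$id, NULL))
  carries <- rowSums(pg == "het" | pg == "hom_alt") > 0
  pg[!carries, 1L] <- "het"
  pg[causal_id, ] <- sample(c("hom_ref", "missing"), cfg$n_panel, TRUE,
                            prob = c(0.92, 0.08))
  pg[passenger_id, ] <- sample(c("hom_ref", "missing"), cfg$n_panel, TRUE,
                               prob = c(0.92, 0.08))
  panel <- panel_genotypes(pg)

  # transcripts: causal deletion context CAGAGCTTGA at codon 20 -> fs*3;
  # passenger context CGA at codon 15 -> R15* under C>T
  cds_c <- with_context(random_cds(40L), (20L - 1L) * 3L + 1L, "CAGAGCTTGA")
  tm_causal <- transcript_model("TX_CAUSAL_SYNTH", cds_c, "CUBN-like")
  cv_causal <- coding_variant("TX_CAUSAL_SYNTH", (20L - 1L) * 3L + 1L,
                              "C", "")
  cds_p <- with_context(random_cds(30L), (15L - 1L) * 3L + 1L, "CGA")
  tm_pass <- transcript_model("TX_PASSENGER_SYNTH", cds_p, "MRC1-like")
  cv_pass <- coding_variant("TX_PASSENGER_SYNTH", (15L - 1L) * 3L + 1L,
                            "C", "T")

  consequences <- stats::setNames(
    as.list(sample(c("synonymous", "missense", "other"), nrow(vt), TRUE,
                   prob = c(0.45, 0.25, 0.30))), vt$id)
  consequences[[causal_id]] <- annotate_coding_variant(tm_causal, cv_causal)
  consequences[[passenger_id]] <- annotate_coding_variant(tm_pass, cv_pass)

  truth$causal_variant_id <- causal_id
  truth$passenger_variant_id <- passenger_id
  list(variants = vt, panel = panel,
       transcripts = list(causal = tm_causal, passenger = tm_pass),
       coding_variants = list(causal = cv_causal, passenger = cv_pass),
       consequences = consequences, truth = truth)
}

#' Simulate the validation cohort for candidate variants
#'
#' Draws the genotyping-cohort counts used by the segregation module: all
#' cases homozygous-alt, breed controls carrying the allele only as
#' heterozygotes at the configured carrier frequency, other breeds free of
#' the allele. The causal and passenger variants receive identical carrier
#' vectors (perfect LD), so their genotype r-squared is 1.
#'
#' @param cfg a [sim_config()].
#' @param truth extended truth from [simulate_variants()].
#' @return list with `tables` (named [genotype_table()]s for causal and
#'   passenger), `dosages` (named 0/1/2 vectors over the pooled cohort) and
#'   `planted_het_fraction` (realized heterozygote fraction among breed
#'   controls).
#' @export
simulate_validation_cohort <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n_het <- stats::rbinom(1L, cfg$n_breed_controls, cfg$carrier_het_freq)
  counts <- rbind(cases = c(0, 0, cfg$n_cases),
                  breed_controls = c(cfg$n_breed_controls - n_het, n_het, 0),
                  other_breeds = c(cfg$n_other_breeds, 0, 0))
  tabs <- list(
    causal = genotype_table(truth$causal_variant_id, counts),
    passenger = genotype_table(truth$passenger_variant_id, counts))
  dose <- c(rep(2L, cfg$n_cases),
            sample(c(rep(1L, n_het),
                     rep(0L, cfg$n_breed_controls - n_het))),
            rep(0L, cfg$n_other_breeds))
  list(tables = tabs,
       dosages = list(causal = dose, passenger = dose),
       planted_het_fraction = n_het / cfg$n_breed_controls)
}
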