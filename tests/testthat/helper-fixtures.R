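# Shared fixtures and independent oracles for the test suite.

## Full-enumeration oracle for the exact Hardy-Weinberg test: probabilities
## of every heterozygote count via log-factorials, p = sum of those <= the
## observed configuration's probability.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (rare == 0 || rare == 2 * n) return(1.0)
  h_vals <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  logp <- vapply(h_vals, function(h) {
    hr <- (rare - h) / 2
    hc <- n - hr - h
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) - (lfactorial(2 * n) - lfactorial(rare) -
                    lfactorial(2 * n - rare))
  }, 0)
  p <- exp(logp)
  p <- p / sum(p)
  p_obs <- p[match(n_het, h_vals)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

## Brute-force shared-run scanner: checks every contiguous marker window
## against the sharing criterion directly.
shared_runs_bruteforce <- function(ds, min_markers = 1L) {
  g <- ds$geno[ds$phenotype == "case", , drop = FALSE]
  m <- ncol(g)
  ok_marker <- function(j) {
    x <- g[, j]
    x <- x[!is.na(x)]
    length(x) > 0 && !any(x == 1) && length(unique(x)) == 1
  }
  compat <- vapply(seq_len(m), ok_marker, TRUE)
  same_chr <- function(i1, i2)
    length(unique(ds$map$chromosome[i1:i2])) == 1
  window_ok <- function(i1, i2)
    all(compat[i1:i2]) && same_chr(i1, i2)
  runs <- list()
  for (i1 in seq_len(m)) for (i2 in i1:m) {
    if (!window_ok(i1, i2)) next
    maximal <- (i1 == 1 || !window_ok(i1 - 1, i2)) &&
               (i2 == m || !window_ok(i1, i2 + 1))
    if (maximal && i2 - i1 + 1 >= min_markers)
      runs[[length(runs) + 1]] <- c(i1, i2)
  }
  runs
}

## Small dataset builder: genotype rows supplied per sample.
toy_dataset <- function(geno_rows, phenotype,
                        positions = NULL, chrom = "chr1") {
  geno <- do.call(rbind, geno_rows)
  m <- ncol(geno)
  if (is.null(positions)) positions <- seq_len(m) * 1000L
  map <- data.frame(marker_id = sprintf("m%03d", seq_len(m)),
                    chromosome = chrom, position_bp = positions,
                    ref_allele = "A", alt_allele = "G",
                    stringsAsFactors = FALSE)
  genotype_dataset(map, sprintf("s%02d", seq_along(geno_rows)),
                   phenotype, geno)
}

## Random CDS with no internal stop (codon pool avoids stop-prefix issues).
random_orf <- function(n_codons) {
  pool <- c("GCT", "TGT", "GAT", "GAA", "TTT", "GGT", "CAT", "ATT",
            "AAA", "CTG", "ATG", "AAT", "CCT", "CAG", "CGT", "TCT",
            "ACT", "GTT", "TGG", "TAT")
  paste0("ATG", paste(sample(pool, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

## Mutate-and-translate oracle: apply a variant to a CDS string directly.
apply_cds_variant <- function(cds, pos, ref, alt) {
  paste0(substr(cds, 1, pos - 1), alt, substr(cds, pos + nchar(ref),
                                              nchar(cds)))
}
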