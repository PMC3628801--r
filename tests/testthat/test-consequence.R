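test_that("CDS translation follows the standard code and stop rules", {
  expect_identical(translate_cds("ATGTGA"), "M")
  expect_identical(translate_cds("ATGCGATAA"), "MR")
  expect_identical(translate_cds("ATGAAACG"), "MK")   # trailing 2-mer dropped
  expect_identical(translate_cds("ATGTAACGA"), "M")   # stops at first stop
  expect_error(translate_cds("ATGNNN"), "A/C/G/T")
  expect_error(translate_cds("AT"), "one codon")
})

test_that("transcript models are validated as single-ORF coding sequences", {
  expect_s3_class(transcript_model("tx", "ATGAAATGA"), "transcript_model")
  expect_error(transcript_model("tx", "ATGAAA"), "stop")
  expect_error(transcript_model("tx", "AAATGA"), "ATG")
  expect_error(transcript_model("tx", "ATGTAATGA"), "exactly one stop")
  expect_error(transcript_model("tx", "ATGAATG"), "divisible")
})

## builds a CDS of n codons with `context` placed at codon `at`
cds_with <- function(n, at, context) {
  set.seed(101)
  cds <- random_orf(n)
  paste0(substr(cds, 1, (at - 1) * 3), context,
         substr(cds, (at - 1) * 3 + nchar(context) + 1, nchar(cds)))
}

test_that("nonsense SNV: CGA codon 715 + c.2143C>T gives p.R715*", {
  cds <- cds_with(1457, 715, "CGA")
  tm <- transcript_model("TX_MRC1_SYNTH", cds)
  call <- annotate_coding_variant(tm, coding_variant("TX_MRC1_SYNTH",
                                                     2143, "C", "T"))
  expect_identical(call$hgvs_c, "c.2143C>T")
  expect_identical(call$hgvs_p, "p.R715*")
  expect_identical(call$effect, "nonsense")
  expect_equal(call$wt_orf_codons, 1456L)
  expect_equal(call$mut_orf_codons, 714L)
  # truncates more than half of the 1,456-residue protein
  ts <- truncation_summary(call)
  expect_equal(ts$fraction_lost, (1456 - 714) / 1456)
  expect_gt(ts$fraction_lost, 0.5)
})

test_that("frameshift deletion: CAGAGCTTGA context gives p.Q2798Rfs*3", {
  cds <- cds_with(2900, 2798, "CAGAGCTTGA")
  tm <- transcript_model("TX_CUBN_SYNTH", cds)
  call <- annotate_coding_variant(tm, coding_variant("TX_CUBN_SYNTH",
                                                     8392, "C", ""))
  expect_identical(call$hgvs_c, "c.8392delC")
  expect_identical(call$hgvs_p, "p.Q2798Rfs*3")
  expect_identical(call$effect, "frameshift")
  expect_equal(call$mut_orf_codons, 2799L)
})

test_that("missense SNV: AGC codon 3072 + c.9215G>C gives p.S3072T", {
  cds <- cds_with(3100, 3072, "AGC")
  tm <- transcript_model("TX_CUBN_SYNTH", cds)
  call <- annotate_coding_variant(tm, coding_variant("TX_CUBN_SYNTH",
                                                     9215, "G", "C"))
  expect_identical(call$hgvs_c, "c.9215G>C")
  expect_identical(call$hgvs_p, "p.S3072T")
  expect_identical(call$effect, "missense")
  expect_equal(call$mut_orf_codons, call$wt_orf_codons)
})

test_that("identity and out-of-range variants behave as defined", {
  tm <- transcript_model("tx", "ATGCGAAAATGA")
  same <- annotate_coding_variant(tm, coding_variant("tx", 4, "C", "C"))
  expect_identical(same$effect, "synonymous")
  expect_equal(same$mut_orf_codons, same$wt_orf_codons)

  expect_error(annotate_coding_variant(tm, coding_variant("tx", 13, "A", "G")),
               "out of CDS")
  expect_error(annotate_coding_variant(tm, coding_variant("tx", 4, "G", "T")),
               "does not match")
})

test_that("truncation summary rejects non-truncating calls", {
  tm <- transcript_model("tx", "ATGCGAAAATGA")
  mis <- annotate_coding_variant(tm, coding_variant("tx", 5, "G", "T"))
  expect_identical(mis$effect, "missense")
  expect_error(truncation_summary(mis), "truncating")
})

test_that("frameshift fs*n is internally consistent: mut ORF = pos + n - 2", {
  set.seed(202)
  for (rep in 1:60) {
    n_codons <- sample(20:80, 1)
    cds <- random_orf(n_codons)
    tm <- transcript_model("tx", cds)
    pos <- sample(4:(3 * (n_codons - 2)), 1)
    width <- sample(c(1, 2, 4), 1)   # non-multiple-of-3 deletions
    if (pos + width - 1 > 3 * (n_codons - 1)) next
    ref <- substr(cds, pos, pos + width - 1)
    call <- annotate_coding_variant(tm, coding_variant("tx", pos, ref, ""))
    m <- regmatches(call$hgvs_p,
                    regexec("^p\\.([A-Z*])(\\d+)([A-Z])fs\\*(\\d+)$",
                            call$hgvs_p))[[1]]
    if (length(m) == 0) next   # immediate stop or no-stop edge forms
    p1 <- as.integer(m[3]); nn <- as.integer(m[5])
    expect_equal(call$mut_orf_codons, p1 + nn - 2L)
  }
})

test_that("HGVS protein strings agree with a mutate-and-translate oracle", {
  set.seed(303)
  for (rep in 1:80) {
    n_codons <- sample(15:60, 1)
    cds <- random_orf(n_codons)
    tm <- transcript_model("tx", cds)
    pos <- sample(2:(nchar(cds) - 4), 1)
    type <- sample(c("snv", "del1", "del2", "ins1"), 1)
    cv <- switch(type,
      snv = {
        ref <- substr(cds, pos, pos)
        coding_variant("tx", pos, ref, sample(setdiff(c("A", "C", "G", "T"),
                                                      ref), 1))
      },
      del1 = coding_variant("tx", pos, substr(cds, pos, pos), ""),
      del2 = coding_variant("tx", pos, substr(cds, pos, pos + 1), ""),
      ins1 = coding_variant("tx", pos, "", sample(c("A", "C", "G", "T"), 1)))
    call <- annotate_coding_variant(tm, cv)

    # oracle: apply the variant to the CDS directly and translate
    mut <- apply_cds_variant(cds, cv$c_position, cv$ref, cv$alt)
    prot <- if (nchar(mut) >= 3) translate_cds(mut) else ""
    expect_equal(call$mut_orf_codons, nchar(prot), info = call$hgvs_c)

    if (grepl("fs\\*\\d+$", call$hgvs_p)) {
      m <- regmatches(call$hgvs_p,
                      regexec("^p\\.([A-Z*])(\\d+)([A-Z])fs\\*(\\d+)$",
                              call$hgvs_p))[[1]]
      p1 <- as.integer(m[3]); aa_new <- m[4]
      expect_identical(substr(prot, p1, p1), aa_new, info = call$hgvs_p)
      # wildtype prefix is preserved up to the first changed residue
      expect_identical(substr(prot, 1, p1 - 1),
                       substr(translate_cds(cds), 1, p1 - 1))
    }
  }
})

test_that("deletions are 3'-normalized within repeats before naming", {
  # homopolymer AAAA at c.4-7: any single-A deletion names the 3'-most copy
  cds <- paste0("ATG", "AAA", "ACG", "TTG", "TCA", "TGA")
  tm <- transcript_model("tx", cds)
  for (p in 4:7) {   # c.4..7 all delete an A from the AAAA run
    call <- annotate_coding_variant(tm, coding_variant("tx", p, "A", ""))
    expect_identical(call$hgvs_c, "c.7delA", info = p)
  }

  # property: naive left name + shift oracle over random homopolymers
  set.seed(404)
  for (rep in 1:40) {
    cds <- random_orf(sample(12:30, 1))
    # find any homopolymer run of length >= 2 strictly inside the ORF
    runs <- gregexpr("([ACGT])\\1+", cds)[[1]]
    if (runs[1] == -1) next
    len <- attr(runs, "match.length")
    keep <- runs > 1 & (runs + len - 1) < nchar(cds)
    if (!any(keep)) next
    i <- which(keep)[1]
    start <- runs[i]; end <- runs[i] + len[i] - 1
    base <- substr(cds, start, start)
    tm <- transcript_model("tx", cds)
    calls <- vapply(start:end, function(p)
      annotate_coding_variant(tm, coding_variant("tx", p, base, ""))$hgvs_c,
      "")
    expect_true(all(calls == sprintf("c.%ddel%s", end, base)),
                info = cds)
  }
})
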