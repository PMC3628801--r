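base_variant <- function(...) {
  defaults <- list(chrom = "chr2", pos = 1000L, ref = "A", alt = "G",
                   genotype = "hom_alt", qual = 100, qd = 10, mq0 = 0L,
                   dp = 30L, hrun = 0L, sb = -10)
  args <- utils::modifyList(defaults, list(...))
  variant_table(as.data.frame(args, stringsAsFactors = FALSE))
}

test_that("hard filters reproduce the printed expressions", {
  # clean record passes every clause
  expect_identical(hard_filter_label(base_variant())[[1]], character(0))

  # MQ0 >= 4 and MQ0/DP > 0.1
  v <- base_variant(mq0 = 4L, dp = 30L)   # 4/30 = 0.133 > 0.1
  expect_identical(hard_filter_label(v)[[1]], "HardToValidate")
  v <- base_variant(mq0 = 4L, dp = 41L)   # 4/41 < 0.1: ratio clause fails
  expect_identical(hard_filter_label(v)[[1]], character(0))
  v <- base_variant(mq0 = 3L, dp = 10L)   # MQ0 < 4
  expect_identical(hard_filter_label(v)[[1]], character(0))
  # division guard: DP = 0 with MQ0 present fails
  v <- base_variant(mq0 = 5L, dp = 0L)
  expect_identical(hard_filter_label(v)[[1]], "HardToValidate")

  # each LowQual clause, at and just past its threshold
  expect_identical(hard_filter_label(base_variant(qd = 4.9))[[1]], "LowQual")
  expect_identical(hard_filter_label(base_variant(qd = 5.0))[[1]],
                   character(0))
  expect_identical(hard_filter_label(base_variant(qual = 29.9))[[1]],
                   "LowQual")
  expect_identical(hard_filter_label(base_variant(hrun = 6L))[[1]],
                   "LowQual")
  expect_identical(hard_filter_label(base_variant(hrun = 5L))[[1]],
                   character(0))
  # SB is strict: exactly 0.00 passes
  expect_identical(hard_filter_label(base_variant(sb = 0.0))[[1]],
                   character(0))
  expect_identical(hard_filter_label(base_variant(sb = 0.01))[[1]],
                   "LowQual")
})

cluster_fixture <- function(positions, classes = NULL) {
  n <- length(positions)
  ref <- rep("A", n); alt <- rep("G", n)
  if (!is.null(classes)) {
    ref[classes == "del"] <- "AT"
    alt[classes == "del"] <- "A"
  }
  variant_table(data.frame(chrom = "chr1", pos = positions, ref = ref,
                           alt = alt, genotype = "hom_alt",
                           stringsAsFactors = FALSE))
}

test_that("SNV cluster flagging follows the window definition", {
  expect_identical(flag_snp_clusters(cluster_fixture(c(100, 105, 109))),
                   rep(TRUE, 3))                     # span 9 <= 10
  expect_identical(flag_snp_clusters(cluster_fixture(c(100, 105, 120))),
                   rep(FALSE, 3))
  expect_identical(flag_snp_clusters(cluster_fixture(c(100, 101))),
                   rep(FALSE, 2))                    # below cluster_size
  # indels neither count nor get flagged
  vt <- cluster_fixture(c(100, 104, 105, 109),
                        classes = c("snv", "del", "snv", "snv"))
  expect_identical(flag_snp_clusters(vt), c(TRUE, FALSE, TRUE, TRUE))
  vt2 <- cluster_fixture(c(100, 104, 109), classes = c("snv", "del", "snv"))
  expect_identical(flag_snp_clusters(vt2), rep(FALSE, 3))

  bad <- cluster_fixture(c(100, 105, 109))
  bad$pos <- c(109L, 100L, 105L)
  expect_error(flag_snp_clusters(bad), "sorted")
})

cascade_fixture <- function() {
  # 50 variants engineered so the funnel counts are [20, 10, 4, 2]
  # (after the pass pre-step): 30 fail filters or are not hom_alt such
  # that 20 survive pass+hom_alt, 10 of those in the interval, 4 of those
  # panel-absent, 2 of those non-synonymous
  pos <- seq(1000L, by = 1000L, length.out = 50L)
  gt <- rep("hom_alt", 50)
  qd <- rep(10, 50)
  # 25 hom_alt PASS in play; make 5 of them het and 20 remain:
  gt[1:20] <- "het"          # drop at hom_alt step (still PASS)
  qd[21:30] <- 1             # fail LowQual
  # interval will cover positions 31000..40000 -> variants 31..40
  in_iv <- 31:40
  vt <- variant_table(data.frame(
    chrom = "chr9", pos = pos, ref = "A", alt = "G", genotype = gt,
    qual = 100, qd = qd, mq0 = 0L, dp = 30L, hrun = 0L, sb = -5,
    stringsAsFactors = FALSE))
  iv <- critical_interval("chr9", 31000, 40000)

  ids <- vt$id[order(vt$pos)]
  pg <- matrix("hom_ref", 50, 3, dimnames = list(vt$id, NULL))
  carried <- vt$id[vt$pos %in% (c(31:36) * 1000)][1:6]
  pg[carried, 2] <- "het"    # 6 of the 10 in-interval are panel-carried
  panel <- panel_genotypes(pg)

  absent <- setdiff(vt$id[vt$pos %in% (in_iv * 1000)], carried)
  cons <- stats::setNames(as.list(rep("synonymous", 50)), vt$id)
  cons[[absent[1]]] <- "frameshift"
  cons[[absent[2]]] <- "nonsense"
  list(vt = vt, iv = iv, panel = panel, cons = cons,
       expect_final = c(absent[1], absent[2]))
}

test_that("the cascade reproduces engineered funnel counts", {
  fx <- cascade_fixture()
  rep <- run_cascade(fx$vt, fx$iv, fx$panel, fx$cons)
  counts <- rep$steps$n_variants[match(
    c("total_homozygous", "in_interval", "absent_from_panel",
      "nonsynonymous"), rep$steps$step)]
  expect_equal(counts, c(20L, 10L, 4L, 2L))
  expect_setequal(rep$surviving, fx$expect_final)
  # counts never increase along the funnel
  expect_false(is.unsorted(rev(rep$steps$n_variants)))
})

test_that("cascade steps are order-invariant intersections", {
  fx <- cascade_fixture()
  rep <- run_cascade(fx$vt, fx$iv, fx$panel, fx$cons)
  s <- rep$survivors_by_step
  # the final set equals the intersection of all per-step predicates
  final_direct <- Reduce(intersect, s)
  expect_setequal(final_direct, rep$surviving)
})

test_that("cascade edge cases: empty input, chromosome mismatch, missing panel", {
  empty <- variant_table(data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character(),
                                    genotype = character()))
  iv <- critical_interval("chr9", 1000, 2000)
  pg <- panel_genotypes(matrix("hom_ref", 1, 2,
                               dimnames = list("x", NULL)))
  rep <- run_cascade(empty, iv, pg)
  expect_true(all(rep$steps$n_variants == 0L))

  v <- base_variant(chrom = "chrX")
  expect_error(run_cascade(v, iv, pg), "chromosome name")

  # missing panel genotypes do not exclude, but are audited
  v <- base_variant(chrom = "chr9", pos = 1500L)
  pg2 <- panel_genotypes(matrix(c("missing", "hom_ref"), 1, 2,
                                dimnames = list(v$id, NULL)))
  rep2 <- run_cascade(v, iv, pg2, stats::setNames(list("missense"), v$id))
  expect_identical(rep2$surviving, v$id)
  expect_equal(unname(rep2$n_panel_missing[v$id]), 1)
})
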