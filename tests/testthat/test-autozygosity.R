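test_that("shared runs split at heterozygous or discordant markers", {
  # marker 4 has a het (case1) and discordant homs (case2 vs others)
  ds <- toy_dataset(list(c(2L, 2L, 2L, 1L, 2L, 2L, 2L),
                         c(2L, 2L, 2L, 0L, 2L, 2L, 2L),
                         c(2L, 2L, 2L, 2L, 2L, 2L, 2L)),
                    rep("case", 3))
  runs <- find_shared_runs(ds)
  expect_length(runs, 2L)
  expect_equal(runs[[1]]$first_marker_index, 1L)
  expect_equal(runs[[1]]$last_marker_index, 3L)
  expect_equal(runs[[2]]$first_marker_index, 5L)
  expect_equal(runs[[2]]$last_marker_index, 7L)
  expect_identical(runs[[1]]$shared_allele_per_marker, rep("alt", 3))
})

test_that("degenerate sharing patterns behave as defined", {
  # all cases identical and homozygous: one full-length run
  ds <- toy_dataset(list(rep(2L, 10), rep(2L, 10)), rep("case", 2))
  runs <- find_shared_runs(ds)
  expect_length(runs, 1L)
  expect_equal(runs[[1]]$n_markers, 10L)

  # one case heterozygous at every second marker: length-1 runs only
  ds <- toy_dataset(list(c(2L, 1L, 2L, 1L, 2L), rep(2L, 5)),
                    rep("case", 2))
  expect_true(all(vapply(find_shared_runs(ds), `[[`, 0L, "n_markers") == 1L))
  expect_length(find_shared_runs(ds, min_markers = 2), 0L)

  expect_error(find_shared_runs(toy_dataset(list(rep(0L, 3)), "control")),
               "case")
})

test_that("missing genotypes neither break nor carry a run", {
  # middle marker: one case missing, others agree -> run continues
  ds <- toy_dataset(list(c(2L, NA, 2L), c(2L, 2L, 2L)), rep("case", 2))
  expect_equal(find_shared_runs(ds)[[1]]$n_markers, 3L)
  # middle marker: all cases missing -> run breaks
  ds <- toy_dataset(list(c(2L, NA, 2L), c(2L, NA, 2L)), rep("case", 2))
  expect_length(find_shared_runs(ds), 2L)
})

test_that("run finding equals the brute-force window scanner", {
  set.seed(17)
  for (rep in 1:40) {
    n_case <- sample(2:5, 1)
    m <- sample(5:50, 1)
    geno <- matrix(sample(c(0:2, NA), n_case * m, replace = TRUE,
                          prob = c(0.25, 0.2, 0.5, 0.05)), n_case, m)
    chrom <- sort(sample(c("chr1", "chr2"), m, replace = TRUE))
    map <- data.frame(marker_id = sprintf("m%03d", 1:m), chromosome = chrom,
                      position_bp = as.integer(1:m * 100 + 1),
                      stringsAsFactors = FALSE)
    ds <- genotype_dataset(map, sprintf("s%d", 1:n_case),
                           rep("case", n_case), geno)
    got <- lapply(find_shared_runs(ds), function(r)
      c(r$first_marker_index, r$last_marker_index))
    want <- shared_runs_bruteforce(ds)
    expect_equal(got, want, info = paste("replicate", rep))
  }
})

test_that("interval delineation uses flanking discordant markers", {
  ds <- toy_dataset(list(c(2L, 2L, 2L, 1L, 2L, 2L, 2L),
                         c(2L, 2L, 2L, 0L, 2L, 2L, 2L),
                         c(2L, 2L, 2L, 2L, 2L, 2L, 2L)),
                    rep("case", 3))
  runs <- find_shared_runs(ds)
  iv <- delineate_interval(runs[[2]], ds)   # markers 5-7
  expect_equal(iv$start_bp, 4000)           # the discordant marker
  expect_equal(iv$end_bp, 7000)             # chromosome end -> truncated
  expect_false(iv$truncated_left)
  expect_true(iv$truncated_right)

  # run spanning the whole chromosome: both ends truncated
  ds2 <- toy_dataset(list(rep(2L, 4), rep(2L, 4)), rep("case", 2))
  iv2 <- delineate_interval(find_shared_runs(ds2)[[1]], ds2)
  expect_true(iv2$truncated_left && iv2$truncated_right)
  expect_equal(c(iv2$start_bp, iv2$end_bp), c(1000, 4000))
})

test_that("adding a case can only shrink or split runs", {
  set.seed(23)
  for (rep in 1:20) {
    m <- 30L
    g1 <- matrix(sample(c(0L, 2L), 3 * m, TRUE), 3, m)
    extra <- sample(c(0:2, NA), m, TRUE)
    ds3 <- toy_dataset(asplit(g1, 1), rep("case", 3))
    ds4 <- toy_dataset(c(asplit(g1, 1), list(extra)), rep("case", 4))
    in_runs <- function(ds) {
      covered <- logical(m)
      for (r in find_shared_runs(ds))
        covered[r$first_marker_index:r$last_marker_index] <- TRUE
      covered
    }
    expect_true(all(in_runs(ds4) <= in_runs(ds3)), info = rep)
  }
})

test_that("interval report formats sizes in Mb, half-up at two decimals", {
  rep1 <- interval_report(list(critical_interval("chr2", 17283880, 20818258)))
  expect_identical(rep1$size_mb, "3.53 Mb")
  rep2 <- interval_report(list(critical_interval("chr1", 1, 1000001)))
  expect_identical(rep2$size_mb, "1.00 Mb")
  empty <- interval_report(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("chromosome", "size_mb") %in% names(empty)))
})

test_that("pipeline mapping bridges isolated discordant markers only", {
  # a clean 30-marker shared block with one erroneous het in its middle,
  # flanked by dense discordance outside
  set.seed(9)
  m <- 50L
  founder <- sample(c(0L, 2L), m, TRUE)
  rows <- lapply(1:4, function(i) founder)
  for (i in 1:4) {      # outside the block (markers 1-10, 41-50): random
    rows[[i]][c(1:10, 41:50)] <- sample(0:2, 20, TRUE)
  }
  rows[[2]][25] <- 1L   # genotyping error inside the block
  ds <- toy_dataset(rows, rep("case", 4))

  strict <- find_shared_runs(ds, min_markers = 5)
  expect_true(all(vapply(strict, `[[`, 0L, "n_markers") < 30L))

  mp <- map_critical_interval(ds, min_markers = 5)
  expect_gte(mp$run$first_marker_index, 10L)
  expect_lte(mp$run$first_marker_index, 11L)
  expect_gte(mp$run$last_marker_index, 40L)
  expect_true("m025" %in% attr(mp$run, "bridged"))

  # strict mode reproduces find_shared_runs behaviour
  mp0 <- map_critical_interval(ds, min_markers = 5, max_bridge = 0)
  expect_lt(mp0$run$n_markers, 30L)
})

test_that("parameter recovery: planted segment bounds within one spacing", {
  n_rep <- 30
  ok <- logical(n_rep)
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(seed = 5000 + s, n_markers = 2000)
    sim <- simulate_cohort(cfg)
    ds <- qc_filter(sim$dataset)$dataset
    mp <- map_critical_interval(ds, min_markers = 10)
    if (is.null(mp)) next
    pb <- sim$truth$planted_interval
    pos <- ds$map$position_bp
    # "within one marker spacing": at most one retained marker may lie
    # between each interval bound and the corresponding planted boundary
    between <- function(a, b) sum(pos > min(a, b) & pos < max(a, b))
    ok[s] <- between(mp$interval$start_bp, pb[["start_bp"]]) <= 1 &&
             between(mp$interval$end_bp, pb[["end_bp"]]) <= 1
  }
  expect_gte(mean(ok), 0.95)
})
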