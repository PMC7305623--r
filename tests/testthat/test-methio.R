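test_that("read QC enforces strict quality and length thresholds", {
  reads <- tibble::tibble(
    read_name = c("short", "good", "boundary_q", "low_q"),
    sequence = c(strrep("A", 150), strrep("A", 300), strrep("A", 300),
                 strrep("A", 300)),
    qualities = list(rep(30L, 150), rep(20L, 300), rep(8L, 300),
                     rep(5L, 300)))
  res <- qc_filter_reads(reads, qc_params())
  expect_equal(res$reads$read_name, "good")
  expect_equal(res$n_input, 4)
  expect_equal(res$n_passed, 1)
  expect_equal(res$n_failed, 3)
  # mean quality of uniform-Q reads is exactly Q; Phred 8 fails "> 8"
  expect_equal(res$mean_q[3], 8)
  expect_false(res$pass[3])

  # error-probability averaging: one terrible base drags harder than
  # an arithmetic mean of Q would
  mixed <- tibble::tibble(read_name = "m", sequence = strrep("A", 201),
                          qualities = list(c(rep(30L, 200), 0L)))
  expect_lt(qc_filter_reads(mixed)$mean_q, 30)

  bad <- tibble::tibble(read_name = "b", sequence = "ACGT",
                        qualities = list(rep(10L, 3)))
  expect_error(qc_filter_reads(bad), "record 1")
})

test_that("FASTQ round-trips through the QC entry point", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", strrep("ACGT", 80), "+", strrep("I", 320),
               "@r2", strrep("AC", 50), "+", strrep("I", 100)), fq)
  reads <- read_fastq(fq)
  res <- qc_filter_reads(reads)
  expect_equal(names(res$reads), "r1")  # r2 fails the length gate
  expect_equal(res$n_passed, 1)
})

test_that("CpG enumeration scans the forward strand case-insensitively", {
  sites <- enumerate_cpgs("ACGTCG")
  expect_equal(sites$start, c(1L, 4L))
  expect_equal(sites$panel_index, c(1L, 2L))

  expect_equal(nrow(enumerate_cpgs("ATTTTA")), 0)
  expect_equal(enumerate_cpgs("acgt")$start, 1L)
  expect_equal(nrow(enumerate_cpgs("ACNGT")), 0)

  std <- generate_standard(standard_spec(897, 52, 1, seed = 7))
  expect_equal(nrow(enumerate_cpgs(std$sequence)), 52)

  # captured interval restricts and renumbers from its 5' end
  windowed <- enumerate_cpgs("CGAACGAACG", interval = c(2L, 10L))
  expect_equal(windowed$start, c(4L, 8L))
  expect_equal(windowed$panel_index, c(1L, 2L))
})

test_that("site aggregation applies the LLR-magnitude and read-depth filters", {
  full <- aggregate_site_frequency(calls_from_llrs(list(rep(5, 10))))
  expect_equal(nrow(full), 1)
  expect_equal(full$called_sites, 10)
  expect_equal(full$methylated_frequency, 1)

  # 9 qualifying calls: below the 10-read gate
  expect_equal(nrow(aggregate_site_frequency(calls_from_llrs(list(rep(5, 9))))), 0)

  # ambiguous |llr| < 2.5 calls are excluded from both counts
  mixed <- aggregate_site_frequency(
    calls_from_llrs(list(c(rep(3, 8), rep(-3, 8), rep(1, 4)))))
  expect_equal(mixed$called_sites, 16)
  expect_equal(mixed$methylated_frequency, 0.5)

  # a CpG-group call contributes its state once per motif, but the depth
  # gate counts reads
  grp <- aggregate_site_frequency(calls_from_llrs(list(rep(4, 10)),
                                                  num_motifs = 3L))
  expect_equal(grp$called_sites, 30)
  expect_equal(grp$called_sites_methylated, 30)
  expect_equal(
    nrow(aggregate_site_frequency(calls_from_llrs(list(rep(4, 5)),
                                                  num_motifs = 3L))), 0)

  expect_equal(nrow(aggregate_site_frequency(empty <- calls_from_llrs(list())[0, ])), 0)
})

test_that("aggregation matches a brute-force oracle on random tables", {
  for (seed in 1:25) {
    calls <- random_calls(seed)
    got <- aggregate_site_frequency(calls)
    want <- brute_force_frequency(calls)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$chromosome, want$chromosome)
      expect_equal(got$start, want$start)
      expect_equal(got$called_sites, want$called_sites)
      expect_equal(got$methylated_frequency, want$methylated_frequency)
    }
    expect_true(all(got$methylated_frequency >= 0 &
                      got$methylated_frequency <= 1))
  }
})

test_that("raising the LLR cutoff never gains qualifying reads", {
  for (seed in 1:10) {
    calls <- random_calls(seed, n_sites = 4L)
    prev <- Inf
    for (cutoff in c(0.5, 1.5, 2.5, 4)) {
      agg <- aggregate_site_frequency(calls,
                                      meth_filter_params(cutoff, min_reads = 1L))
      total <- sum(agg$called_sites)
      expect_lte(total, prev)
      prev <- total
    }
  }
})

test_that("region means use panel indices and signal empty windows", {
  sites <- tibble::tibble(chrom = "MGMT", start = seq(0, 999, by = 10),
                          panel_index = 1:100,
                          subregion = "promoter_exon1")
  freq <- tibble::tibble(chromosome = "MGMT",
                         start = sites$start[70:81], end = sites$start[70:81],
                         num_motifs_in_group = 1L, called_sites = 20L,
                         called_sites_methylated = 8L,
                         methylated_frequency = rep(c(0.2, 0.6), each = 6),
                         group_sequence = "CG")
  dmr2 <- region_window("DMR2", 70, 81)
  expect_equal(dmr2$hi - dmr2$lo + 1L, 12L)
  res <- region_mean(freq, sites, dmr2)
  expect_equal(res$mean, 0.4)
  expect_equal(res$n_sites_used, 12)

  flat <- freq
  flat$methylated_frequency <- 0.4
  expect_equal(region_mean(flat, sites, dmr2)$mean, 0.4)

  none <- region_mean(freq, sites, region_window("empty", 90, 95))
  expect_true(is.na(none$mean))
  expect_equal(none$n_sites_used, 0)
})

test_that("clinical binning is a total order-preserving step function", {
  x <- c(0, 0.05, 0.0999, 0.10, 0.2, 0.30, 0.3001, 0.38, 1)
  got <- classify_methylation_level(x)
  expect_equal(as.character(got),
               c("not_detected", "not_detected", "not_detected", "low",
                 "low", "low", "detected", "detected", "detected"))
  expect_true(is.ordered(got))
  # order preservation on a random grid
  grid <- sort(stats::runif(50))
  expect_true(!is.unsorted(classify_methylation_level(grid)))
  expect_error(classify_methylation_level(1.2), "\\[0, 1\\]")
  expect_error(classify_methylation_level(-0.1), "\\[0, 1\\]")
})

test_that("call and frequency TSV dialects round-trip; bad lines are named", {
  calls <- simulate_meth_calls(c(3L, 40L), c(1, 0), 12, seed = 5,
                               chrom = "rt")
  f <- tempfile(fileext = ".tsv")
  write_meth_calls(calls, f)
  back <- read_meth_calls(f)
  expect_equal(as.data.frame(back), as.data.frame(calls), tolerance = 1e-12)

  freq <- aggregate_site_frequency(calls)
  f2 <- tempfile(fileext = ".tsv")
  write_meth_freq(freq, f2)
  expect_equal(as.data.frame(read_meth_freq(f2)), as.data.frame(freq),
               tolerance = 1e-12)

  # corrupt two body lines
  lines <- readLines(f2)
  lines[2] <- paste(lines[2], "extra_field", sep = "\t")
  corrupt <- c(lines, "short\tline")
  f3 <- tempfile(fileext = ".tsv")
  writeLines(corrupt, f3)
  expect_error(read_meth_freq(f3), "line 2")
  expect_message(perm <- read_meth_freq(f3, strict = FALSE), "2 malformed")
  expect_equal(nrow(perm), nrow(freq) - 1)

  f4 <- tempfile(fileext = ".tsv")
  writeLines("wrong\theader", f4)
  expect_error(read_meth_calls(f4), "bad header")
})
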