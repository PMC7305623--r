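# Independent oracle: exhaustive 3-genotype binomial likelihood with the
# candidate gates applied by hand.
oracle_genotype <- function(counts, ref, params) {
  depth <- sum(counts)
  if (depth < params$min_candidate_depth) return("no_call")
  cand <- counts[setdiff(names(counts), ref)]
  alt <- names(cand)[order(-cand, names(cand))][1]
  if (counts[[alt]] / depth < params$min_candidate_frequency) return("ref/ref")
  e <- params$error_rate / 3
  ll <- vapply(c(e, 0.5, 1 - e), function(p) {
    lchoose(depth, counts[[alt]]) + counts[[alt]] * log(p) +
      (depth - counts[[alt]]) * log1p(-p)
  }, numeric(1))
  c("ref/ref", "ref/alt", "alt/alt")[which.max(ll)]
}

test_that("candidate gates are enforced exactly", {
  expect_equal(call_genotype(pile_row("A", a = 5, g = 4))$genotype, "no_call")
  expect_equal(call_genotype(pile_row("A", a = 5, g = 4))$no_call_reason,
               "insufficient_depth")
  # 5% alt at depth 100: below the 0.15 candidate-frequency gate
  low <- call_genotype(pile_row("C", c = 95, t = 5))
  expect_equal(low$genotype, "ref/ref")
  expect_equal(low$allele_frequency, 0.05)
  # balanced het
  het <- call_genotype(pile_row("C", c = 50, g = 50))
  expect_equal(het$genotype, "ref/alt")
  expect_equal(het$alt_base, "G")
  expect_equal(het$allele_frequency, 0.5)
  expect_gt(het$quality, 0)
  hom <- call_genotype(pile_row("C", c = 2, g = 98))
  expect_equal(hom$genotype, "alt/alt")

  expect_error(call_genotype(pile_row("A", a = -1, g = 10)), "invalid base")
})

test_that("calls match exhaustive likelihood enumeration on random columns", {
  params <- variant_params()
  set.seed(99)
  for (i in 1:200) {
    depth <- sample(0:150, 1)
    counts <- as.vector(stats::rmultinom(1, depth, c(0.55, 0.25, 0.15, 0.05)))
    names(counts) <- sample(c("A", "C", "G", "T"))
    ref <- sample(c("A", "C", "G", "T"), 1)
    col <- pile_row(ref, a = counts[["A"]], c = counts[["C"]],
                    g = counts[["G"]], t = counts[["T"]])
    expect_equal(call_genotype(col, params)$genotype,
                 oracle_genotype(counts, ref, params),
                 info = sprintf("iteration %d", i))
  }
})

test_that("planted genotypes are recovered from simulated pileups", {
  clean <- error_profile(sub_rate = 0.08, ins_rate = 0, del_rate = 0.02,
                         homopolymer_sub_multiplier = 1)
  region <- strrep("ACTG", 10)
  n_ok <- 0L
  trials <- 200L
  for (i in seq_len(trials)) {
    af <- if (i %% 2 == 0) 0.5 else 1
    plan <- data.frame(offset = 13L, ref_base = "C", alt_base = "T",
                       allele_fraction = af)
    pile <- simulate_pileup(region, plan, depth = 60, clean, seed = 5000 + i)
    call <- call_genotype(pile[14, ])
    want <- if (af == 0.5) "ref/alt" else "alt/alt"
    n_ok <- n_ok + (call$genotype == want && call$alt_base == "T")
  }
  expect_gte(n_ok / trials, 0.99)
})

test_that("error-only regions produce no variant calls at depth 500", {
  region <- strrep("GATC", 50)
  noisy <- error_profile(sub_rate = 0.05, ins_rate = 0.03, del_rate = 0.03)
  pile <- simulate_pileup(region, NULL, depth = 500, noisy, seed = 17)
  vars <- call_region(pile, region)
  expect_equal(nrow(vars), 0)
})

test_that("region scans emit planted variants with hotspot metadata", {
  panel <- generate_panel(panel_spec(seed = 21))
  for (rg in c("IDH1", "IDH2")) {
    ref <- panel$references[[rg]]
    plan <- panel$variant_plan[panel$variant_plan$region == rg, ]
    pile <- simulate_pileup(ref, plan, depth = 400, error_profile(),
                            seed = 22 + match(rg, c("IDH1", "IDH2")),
                            chrom = rg)
    vars <- call_region(pile, ref,
                        cpg_sites = panel$cpg_sites$start[
                          panel$cpg_sites$chrom == rg])
    expect_equal(nrow(vars), 1)
    expect_equal(vars$pos, plan$offset)
    expect_equal(vars$alt_base, plan$alt_base)
    expect_equal(vars$genotype, "ref/alt")
    expect_equal(vars$allele_frequency, 0.5, tolerance = 0.15)
  }
  expect_error(call_region(pile_row("A", a = 20), "ACGT"), "columns")
})

test_that("raising the candidate frequency never adds variants", {
  region <- strrep("TCGA", 30)
  plan <- data.frame(offset = c(10L, 49L), ref_base = c("G", "C"),
                     alt_base = c("A", "T"), allele_fraction = c(0.5, 0.2))
  pile <- simulate_pileup(region, plan, depth = 200, error_profile(),
                          seed = 31)
  prev <- Inf
  for (f in c(0.05, 0.15, 0.3, 0.6)) {
    n <- nrow(call_region(pile, region,
                          variant_params(min_candidate_frequency = f)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("homopolymer flagging covers runs and their flanks", {
  seq1 <- "AAGGGGGGTT"
  for (pos in 2:7) expect_true(flag_homopolymer(seq1, pos))
  expect_true(flag_homopolymer(seq1, 1))   # immediately adjacent
  expect_true(flag_homopolymer(seq1, 8))
  expect_false(flag_homopolymer(seq1, 9))

  for (pos in 0:7) expect_false(flag_homopolymer("ACGTACGT", pos))

  run5 <- "TTCCCCCTT"
  expect_true(flag_homopolymer(run5, 4, min_run = 5))
  expect_false(flag_homopolymer(run5, 4, min_run = 6))

  # a het inside the planted 6-G run is emitted but flagged
  region <- paste0(strrep("ACTG", 10), "TGGGGGGT", strrep("ACTG", 10))
  plan <- data.frame(offset = 43L, ref_base = "G", alt_base = "A",
                     allele_fraction = 0.5)
  pile <- simulate_pileup(region, plan, depth = 300,
                          error_profile(homopolymer_sub_multiplier = 1),
                          seed = 41)
  vars <- call_region(pile, region)
  expect_equal(nrow(vars), 1)
  expect_true(vars$homopolymer_flag)
})

test_that("somatic status follows the tumor/normal contract", {
  het <- call_genotype(pile_row("C", c = 50, g = 50))
  ref <- call_genotype(pile_row("C", c = 98, g = 2))
  nocall <- call_genotype(pile_row("C", c = 4))
  expect_equal(classify_somatic(het, ref)$status, "somatic")
  expect_equal(classify_somatic(het, het)$status, "germline")
  expect_equal(classify_somatic(ref, het)$status, "absent")
  expect_equal(classify_somatic(nocall, ref)$status, "inconsistent")
  expect_equal(classify_somatic(het, nocall)$status, "inconsistent")
  other <- call_genotype(pile_row("C", c = 50, g = 50, pos = 5L))
  expect_error(classify_somatic(het, other), "different loci")
})

test_that("platform allele-frequency comparison is a plain Pearson chi-squared", {
  same <- compare_allele_frequencies(c(50, 50), c(50, 50))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$delta_af, 0)

  # hand-computed: 2x2 table (60,40)/(40,60), expected 50 everywhere
  flip <- compare_allele_frequencies(c(60, 40), c(40, 60))
  expect_equal(flip$statistic, 8)
  expect_equal(flip$p_value, stats::pchisq(8, 1, lower.tail = FALSE))
  expect_equal(flip$delta_af, 0.2)

  expect_error(compare_allele_frequencies(c(0, 0), c(10, 10)), "margin")
})

test_that("VCF output round-trips through the module's own reader", {
  region <- paste0(strrep("ACTG", 10), "TGGGGGGT", strrep("ACTG", 10))
  plan <- data.frame(offset = c(13L, 43L), ref_base = c("C", "G"),
                     alt_base = c("T", "A"), allele_fraction = c(0.5, 1))
  pile <- simulate_pileup(region, plan, depth = 300,
                          error_profile(homopolymer_sub_multiplier = 1),
                          seed = 51)
  vars <- call_region(pile, region)
  expect_equal(nrow(vars), 2)
  f <- tempfile(fileext = ".vcf")
  write_vcf(vars, f)
  back <- read_vcf(f)
  expect_equal(back$chrom, vars$chrom)
  expect_equal(back$pos, vars$pos)
  expect_equal(back$ref_base, vars$ref_base)
  expect_equal(back$alt_base, vars$alt_base)
  expect_equal(back$genotype, vars$genotype)
  expect_equal(back$homopolymer_flag, vars$homopolymer_flag)
  expect_equal(back$allele_frequency, vars$allele_frequency,
               tolerance = 1e-4)
  expect_equal(back$depth, vars$depth)
  expect_equal(back$quality, vars$quality, tolerance = 0.01)

  expect_error(read_vcf(textConnectionPath <- {
    p <- tempfile(); writeLines("not a vcf", p); p
  }), "VCFv4.2")
})
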