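# Small in-code fixtures shared across test files.

# A compact methylation standard plus fully methylated / unmethylated call
# pools, deep enough for mixture subsampling.
make_test_pools <- function(n_cpg = 10L, length_bp = 300L, pool_depth = 80L,
                            model = llr_model(), seed = 1L) {
  std <- generate_standard(standard_spec(length_bp, n_cpg, 1, seed = seed))
  p100 <- simulate_meth_calls(std$cpg_starts, 1, pool_depth, model,
                              seed = seed + 1L, chrom = "std")
  p0 <- simulate_meth_calls(std$cpg_starts, 0, pool_depth, model,
                            seed = seed + 2L, chrom = "std")
  # distinguishable read names so tests can trace a call to its pool
  p100$read_name <- sub("^std", "met", p100$read_name)
  p0$read_name <- sub("^std", "unmet", p0$read_name)
  list(standard = std, pool100 = p100, pool0 = p0)
}

# Hand-built call table: one site per element of `llrs` lists.
calls_from_llrs <- function(llrs, start = 0L, chrom = "chr", num_motifs = 1L) {
  rows <- lapply(seq_along(llrs), function(i) {
    x <- llrs[[i]]
    tibble::tibble(chromosome = chrom, strand = "+",
                   start = start + (i - 1L) * 10L,
                   end = start + (i - 1L) * 10L,
                   read_name = sprintf("r%03d", seq_along(x)),
                   log_lik_ratio = x, log_lik_methylated = x / 2,
                   log_lik_unmethylated = -x / 2, num_calling_strands = 1L,
                   num_motifs = num_motifs, sequence = "CG")
  })
  do.call(rbind, rows)
}

# Independent brute-force aggregation oracle: plain loops, no shared code
# with aggregate_site_frequency().
brute_force_frequency <- function(calls, llr_cutoff = 2.5, min_reads = 10L) {
  keys <- unique(paste(calls$chromosome, calls$start, calls$end, sep = "|"))
  out <- list()
  for (k in keys) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    sel <- calls$chromosome == parts[1] &
      calls$start == as.integer(parts[2]) & calls$end == as.integer(parts[3])
    n_qual <- 0L; called <- 0L; meth <- 0L
    for (i in which(sel)) {
      llr <- calls$log_lik_ratio[i]
      if (abs(llr) >= llr_cutoff) {
        n_qual <- n_qual + 1L
        called <- called + calls$num_motifs[i]
        if (llr > 0) meth <- meth + calls$num_motifs[i]
      }
    }
    if (n_qual >= min_reads) {
      out[[k]] <- data.frame(chromosome = parts[1],
                             start = as.integer(parts[2]),
                             called_sites = called,
                             called_sites_methylated = meth,
                             methylated_frequency = meth / called)
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$chromosome, res$start), , drop = FALSE]
}

# One pileup column with named base counts.
pile_row <- function(ref, a = 0, c = 0, g = 0, t = 0, pos = 0L) {
  tibble::tibble(chrom = "locus", pos = pos, ref_base = ref,
                 A = a, C = c, G = g, T = t)
}

# Random call table generator for property tests.
random_calls <- function(seed, n_sites = 6L, max_depth = 25L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_sites), function(i) {
    d <- sample.int(max_depth, 1L)
    tibble::tibble(chromosome = sample(c("chrA", "chrB"), 1L),
                   strand = "+", start = i * 5L, end = i * 5L,
                   read_name = sprintf("r%02d", seq_len(d)),
                   log_lik_ratio = round(stats::rnorm(d, 0, 4), 3),
                   log_lik_methylated = 0, log_lik_unmethylated = 0,
                   num_calling_strands = 1L,
                   num_motifs = sample(1:3, 1L), sequence = "CG")
  }))
}
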