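#' Specification for a synthetic methylation standard
#'
#' Describes a linear double-stranded DNA control molecule of the kind used to
#' calibrate nanopore methylation calling: a sequence of `length_bp` bases
#' carrying exactly `n_cpg` CpG dinucleotides, all at a common true
#' methylation level. The shipped defaults mirror the commercial CpG
#' standard set (897 bp, 52 CpGs, fully methylated or fully unmethylated).
#'
#' @param length_bp Positive integer, molecule length in bases.
#' @param n_cpg Non-negative integer, number of CG dinucleotides on the
#'   forward strand. Must satisfy `n_cpg <= floor(length_bp / 2)` since CpG
#'   sites are disjoint 2-mers.
#' @param true_meth_level Fraction in \[0, 1\]: the common true methylation
#'   level of every CpG on the molecule.
#' @param seed Integer seed controlling CpG placement and base fill.
#' @return A list of class `standard_spec`.
#' @export
standard_spec <- function(length_bp = 897L, n_cpg = 52L,
                          true_meth_level = 1, seed = 1L) {
  length_bp <- as.integer(length_bp)
  n_cpg <- as.integer(n_cpg)
  stopifnot(length_bp >= 1L, n_cpg >= 0L)
  stopifnot_scalar_fraction(true_meth_level, "true_meth_level")
  structure(list(length_bp = length_bp, n_cpg = n_cpg,
                 true_meth_level = true_meth_level, seed = as.integer(seed)),
            class = "standard_spec")
}

#' Per-read log-likelihood-ratio model for simulated 5mC calls
#'
#' Models the per-read, per-CpG output of a signal-level methylation caller as
#' a signed Gaussian: a truly methylated call draws magnitude
#' `|N(mu_meth, sigma)|` with positive sign, an unmethylated call
#' `|N(mu_unmeth, sigma)|` with negative sign, and the sign is flipped with
#' probability `miscall_rate`. Positive LLR is evidence for 5mC. The defaults
#' place typical magnitudes well above the 2.5 filtering cutoff so that most
#' calls qualify, while leaving a realistic minority of ambiguous and
#' miscalled reads.
#'
#' @param mu_meth,mu_unmeth Positive expected LLR magnitudes for truly
#'   methylated / unmethylated calls.
#' @param sigma Positive LLR spread.
#' @param miscall_rate Probability in \[0, 0.5) that a call's sign is flipped.
#' @return A list of class `llr_model`.
#' @export
llr_model <- function(mu_meth = 4, mu_unmeth = 4, sigma = 1.5,
                      miscall_rate = 0.03) {
  stopifnot(mu_meth > 0, mu_unmeth > 0, sigma > 0,
            miscall_rate >= 0, miscall_rate < 0.5)
  structure(list(mu_meth = mu_meth, mu_unmeth = mu_unmeth, sigma = sigma,
                 miscall_rate = miscall_rate), class = "llr_model")
}

#' Nanopore-like base-level error profile
#'
#' @param sub_rate,ins_rate,del_rate Per-base substitution / insertion /
#'   deletion rates; their sum must be below 1.
#' @param homopolymer_sub_multiplier Multiplier (>= 1) applied to `sub_rate`
#'   inside single-base runs of length >= `homopolymer_min_run`, reflecting
#'   that homopolymer-rich regions are the dominant error source on current
#'   pores.
#' @param homopolymer_min_run Run length at which inflation starts.
#' @return A list of class `error_profile`.
#' @export
error_profile <- function(sub_rate = 0.05, ins_rate = 0.04, del_rate = 0.04,
                          homopolymer_sub_multiplier = 3,
                          homopolymer_min_run = 5L) {
  for (nm in c("sub_rate", "ins_rate", "del_rate")) {
    stopifnot_scalar_fraction(get(nm), nm)
  }
  stopifnot(sub_rate + ins_rate + del_rate < 1,
            homopolymer_sub_multiplier >= 1)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate,
                 homopolymer_sub_multiplier = homopolymer_sub_multiplier,
                 homopolymer_min_run = as.integer(homopolymer_min_run)),
            class = "error_profile")
}

# ---------------------------------------------------------------------------
# Sequence construction

# Sample `n_cpg` disjoint CG start positions (0-based) in a sequence of
# `length_bp` bases, uniformly among feasible arrangements, avoiding
# `blocked` intervals (0-based half-open, e.g. planted motifs). Uses the
# stars-and-bars bijection for disjoint 2-mers plus rejection against blocks.
sample_cpg_starts <- function(length_bp, n_cpg, blocked = NULL) {
  if (n_cpg == 0L) return(integer(0))
  if (n_cpg > length_bp %/% 2L) {
    stop(sprintf(
      "infeasible CpG count: %d disjoint CG sites cannot fit in %d bases (max %d)",
      n_cpg, length_bp, length_bp %/% 2L), call. = FALSE)
  }
  for (attempt in seq_len(10000L)) {
    x <- sort(sample.int(length_bp - n_cpg, n_cpg))
    starts <- x + seq_len(n_cpg) - 1L - 1L  # 0-based
    if (is.null(blocked) || nrow(blocked) == 0L) return(starts)
    clash <- FALSE
    for (b in seq_len(nrow(blocked))) {
      if (any(starts < blocked$end[b] & starts + 2L > blocked$start[b])) {
        clash <- TRUE
        break
      }
    }
    if (!clash) return(starts)
  }
  stop("could not place CpG sites around planted motifs after 10000 attempts",
       call. = FALSE)
}

# Fill unfixed positions of a base vector so that no CG dinucleotide is
# created beyond the fixed ones: a free base never takes 'G' after a 'C' and
# never takes 'C' right before a fixed 'G'.
fill_free_bases <- function(bases) {
  free <- which(is.na(bases))
  n <- length(bases)
  for (i in free) {
    allowed <- BASES
    if (i > 1L && !is.na(bases[i - 1L]) && bases[i - 1L] == "C") {
      allowed <- setdiff(allowed, "G")
    }
    if (i < n && !is.na(bases[i + 1L]) && bases[i + 1L] == "G") {
      allowed <- setdiff(allowed, "C")
    }
    bases[i] <- sample(allowed, 1L)
  }
  bases
}

# Build one sequence with exactly the requested CpG placement and optional
# planted motifs (list of list(offset, seq); offsets 0-based). CGs inside a
# motif are the caller's responsibility to count.
build_sequence <- function(length_bp, cpg_starts, motifs = list()) {
  bases <- rep(NA_character_, length_bp)
  for (m in motifs) {
    chars <- strsplit(toupper(m$seq), "")[[1]]
    idx <- m$offset + seq_along(chars)
    stopifnot(all(idx >= 1L), all(idx <= length_bp))
    bases[idx] <- chars
  }
  for (s in cpg_starts) {
    bases[s + 1L] <- "C"
    bases[s + 2L] <- "G"
  }
  paste(fill_free_bases(bases), collapse = "")
}

#' Generate a synthetic methylation standard
#'
#' Produces a random sequence honouring the spec exactly: `length_bp` bases
#' containing exactly `n_cpg` forward-strand CG dinucleotides at seeded,
#' uniformly sampled disjoint positions, together with the per-CpG true
#' methylation vector (constant at `true_meth_level`).
#'
#' @param spec A [standard_spec()].
#' @return A list with elements `sequence` (character scalar), `cpg_starts`
#'   (0-based integer positions of the C of each CG, sorted), `truth`
#'   (numeric vector, one entry per CpG), and `spec`.
#' @examples
#' std <- generate_standard(standard_spec(897, 52, 1, seed = 7))
#' length(std$cpg_starts)  # 52
#' @export
generate_standard <- function(spec) {
  stopifnot(inherits(spec, "standard_spec"))
  with_seed(spec$seed, {
    starts <- sample_cpg_starts(spec$length_bp, spec$n_cpg)
    seq <- build_sequence(spec$length_bp, starts)
    list(sequence = seq,
         cpg_starts = starts,
         truth = rep(spec$true_meth_level, spec$n_cpg),
         spec = spec)
  })
}

# ---------------------------------------------------------------------------
# Per-read methylation calls

meth_call_columns <- c("chromosome", "strand", "start", "end", "read_name",
                       "log_lik_ratio", "log_lik_methylated",
                       "log_lik_unmethylated", "num_calling_strands",
                       "num_motifs", "sequence")

empty_meth_calls <- function() {
  tibble::tibble(chromosome = character(), strand = character(),
                 start = integer(), end = integer(), read_name = character(),
                 log_lik_ratio = numeric(), log_lik_methylated = numeric(),
                 log_lik_unmethylated = numeric(),
                 num_calling_strands = integer(), num_motifs = integer(),
                 sequence = character())
}

#' Simulate a per-read methylation-call table
#'
#' Emulates the per-read, per-CpG output of a nanopore methylation caller.
#' Each site receives `depth` reads; each read's true state is Bernoulli in
#' the site's true methylation fraction; the LLR magnitude is drawn from the
#' signed Gaussian [llr_model()] and the sign flipped with the model's
#' miscall rate. Reads are simulated per molecule: read *j* carries one call
#' at every site, linked by `read_name`.
#'
#' @param sites Integer vector of 0-based CpG start coordinates (the C of
#'   each CG). May be empty, giving an empty table.
#' @param truth Per-site true methylation fraction in \[0, 1\]; recycled to
#'   `length(sites)` if scalar.
#' @param depth Integer >= 1: reads per site.
#' @param model An [llr_model()].
#' @param seed Optional integer seed.
#' @param chrom Chromosome / region name written in the table.
#' @param reference Optional reference sequence used to fill the call-context
#'   `sequence` column; `"CG"` is written when absent.
#' @return A tibble in the methylation-call TSV dialect (columns
#'   `chromosome, strand, start, end, read_name, log_lik_ratio,
#'   log_lik_methylated, log_lik_unmethylated, num_calling_strands,
#'   num_motifs, sequence`).
#' @export
simulate_meth_calls <- function(sites, truth, depth, model = llr_model(),
                                seed = NULL, chrom = "region",
                                reference = NULL) {
  sites <- as.integer(sites)
  if (length(sites) == 0L) return(empty_meth_calls())
  stopifnot(depth >= 1L)
  truth <- rep_len(as.numeric(truth), length(sites))
  stopifnot(all(truth >= 0 & truth <= 1))
  with_seed(seed, {
    n_sites <- length(sites)
    n <- n_sites * depth
    site_idx <- rep(seq_len(n_sites), each = depth)
    read_idx <- rep(seq_len(depth), times = n_sites)
    state <- stats::rbinom(n, 1L, truth[site_idx])
    mu <- ifelse(state == 1L, model$mu_meth, model$mu_unmeth)
    mag <- abs(stats::rnorm(n, mean = mu, sd = model$sigma))
    flip <- stats::rbinom(n, 1L, model$miscall_rate)
    sign <- ifelse(xor(state == 1L, flip == 1L), 1, -1)
    llr <- sign * mag
    ctx <- if (is.null(reference)) {
      rep("CG", n_sites)
    } else {
      vapply(sites, function(s) {
        substr(reference, max(1L, s - 4L), min(nchar(reference), s + 7L))
      }, character(1))
    }
    tibble::tibble(
      chromosome = chrom,
      strand = "+",
      start = sites[site_idx],
      end = sites[site_idx],
      read_name = sprintf("%s_read_%05d", chrom, read_idx),
      log_lik_ratio = llr,
      log_lik_methylated = llr / 2,
      log_lik_unmethylated = -llr / 2,
      num_calling_strands = 1L,
      num_motifs = 1L,
      sequence = ctx[site_idx]
    )
  })
}

# ---------------------------------------------------------------------------
# Pileups

#' Simulate per-position base-count pileups over a region
#'
#' Draws `depth` reads per reference position and corrupts them with the
#' [error_profile()]: a read is dropped from a column with the deletion rate,
#' substituted uniformly into one of the three other bases with the (possibly
#' homopolymer-inflated) substitution rate; insertions do not alter column
#' counts. Variant positions carry the alternate base in a fraction
#' `allele_fraction` of reads before errors are applied.
#'
#' @param region Character scalar: the reference sequence of the region.
#' @param variant_plan Optional data frame with columns `offset` (0-based),
#'   `ref_base`, `alt_base`, `allele_fraction`. A `ref_base` that disagrees
#'   with the reference is a consistency error.
#' @param depth Integer >= 1: reads attempted per column.
#' @param profile An [error_profile()].
#' @param seed Optional integer seed.
#' @param chrom Region name for the output.
#' @return A tibble with one row per position: `chrom, pos` (0-based),
#'   `ref_base`, counts `A, C, G, T`, and `depth` (= sum of the counts).
#' @export
simulate_pileup <- function(region, variant_plan = NULL, depth,
                            profile = error_profile(), seed = NULL,
                            chrom = "region") {
  stopifnot(is.character(region), length(region) == 1L, depth >= 1L)
  region <- toupper(region)
  n <- nchar(region)
  ref <- strsplit(region, "")[[1]]
  alt <- rep(NA_character_, n)
  af <- rep(0, n)
  if (!is.null(variant_plan) && nrow(variant_plan) > 0L) {
    for (i in seq_len(nrow(variant_plan))) {
      off <- as.integer(variant_plan$offset[i])
      stopifnot(off >= 0L, off < n)
      if (ref[off + 1L] != toupper(variant_plan$ref_base[i])) {
        stop(sprintf(
          "variant plan inconsistent with reference at offset %d: plan ref '%s', reference '%s'",
          off, variant_plan$ref_base[i], ref[off + 1L]), call. = FALSE)
      }
      alt[off + 1L] <- toupper(variant_plan$alt_base[i])
      af[off + 1L] <- variant_plan$allele_fraction[i]
      stopifnot_scalar_fraction(af[off + 1L], "allele_fraction")
    }
  }
  in_homopolymer <- homopolymer_positions(region, profile$homopolymer_min_run)
  sub <- pmin(1, profile$sub_rate *
                ifelse(in_homopolymer, profile$homopolymer_sub_multiplier, 1))
  with_seed(seed, {
    counts <- matrix(0L, nrow = n, ncol = 4L,
                     dimnames = list(NULL, BASES))
    for (i in seq_len(n)) {
      nread <- stats::rbinom(1L, depth, 1 - profile$del_rate)
      if (nread == 0L) next
      n_alt <- if (af[i] > 0) stats::rbinom(1L, nread, af[i]) else 0L
      for (grp in list(list(base = ref[i], n = nread - n_alt),
                       list(base = alt[i], n = n_alt))) {
        if (grp$n == 0L) next
        n_err <- stats::rbinom(1L, grp$n, sub[i])
        counts[i, grp$base] <- counts[i, grp$base] + grp$n - n_err
        if (n_err > 0L) {
          others <- setdiff(BASES, grp$base)
          err <- stats::rmultinom(1L, n_err, rep(1 / 3, 3))[, 1L]
          counts[i, others] <- counts[i, others] + err
        }
      }
    }
    tibble::tibble(chrom = chrom, pos = seq_len(n) - 1L, ref_base = ref,
                   A = counts[, "A"], C = counts[, "C"],
                   G = counts[, "G"], T = counts[, "T"],
                   depth = as.integer(rowSums(counts)))
  })
}

# Logical vector: does each position lie inside a single-base run of
# length >= min_run?
homopolymer_positions <- function(sequence, min_run = 5L) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  r <- rle(chars)
  rep(r$lengths >= min_run, r$lengths)
}

# ---------------------------------------------------------------------------
# Target panel

#' Specification for the synthetic three-locus target panel
#'
#' Defines the regions a Cas9-targeted panel captures. The default mirrors
#' the glioma panel this package models: one MGMT region whose
#' promoter/exon-1 portion carries exactly 98 CpGs and whose 5' intron-1
#' portion carries exactly 121 CpGs, plus IDH1 and IDH2 exon-4 amplicons
#' carrying the codon-132 (CGT) and codon-172 (AGG) hotspot contexts. A 6-G
#' homopolymer is planted inside the MGMT region as a known error hotspot.
#'
#' @param regions List of regions; each is a list with `name` and
#'   `subregions`, a list of `list(label, length_bp, n_cpg)` laid out 5' to
#'   3'. Labels come from `{promoter_exon1, intron1, idh1, idh2}`.
#' @param motifs List of `list(region, offset, seq)` sequences forced into
#'   the reference (0-based offsets); CGs inside a motif count towards its
#'   subregion's CpG total.
#' @param variant_plan Data frame with columns `region, offset, ref_base,
#'   alt_base, allele_fraction` describing variants available for pileup
#'   simulation.
#' @param seed Integer seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(regions = NULL, motifs = NULL, variant_plan = NULL,
                       seed = 1L) {
  if (is.null(regions)) {
    regions <- list(
      list(name = "MGMT",
           subregions = list(
             list(label = "promoter_exon1", length_bp = 1500L, n_cpg = 98L),
             list(label = "intron1", length_bp = 2000L, n_cpg = 121L))),
      list(name = "IDH1",
           subregions = list(
             list(label = "idh1", length_bp = 300L, n_cpg = 3L))),
      list(name = "IDH2",
           subregions = list(
             list(label = "idh2", length_bp = 300L, n_cpg = 2L))))
  }
  if (is.null(motifs)) {
    motifs <- list(
      list(region = "IDH1", offset = 150L, seq = "CGT"),    # codon 132
      list(region = "IDH2", offset = 150L, seq = "AGG"),    # codon 172
      list(region = "MGMT", offset = 2600L, seq = "TGGGGGGT"))
  }
  if (is.null(variant_plan)) {
    variant_plan <- tibble::tibble(
      region = c("IDH1", "IDH2"),
      offset = c(150L, 151L),
      ref_base = c("C", "G"),
      alt_base = c("G", "A"),
      allele_fraction = c(0.5, 0.5))
  }
  structure(list(regions = regions, motifs = motifs,
                 variant_plan = variant_plan, seed = as.integer(seed)),
            class = "panel_spec")
}

count_cg <- function(x) {
  lengths(regmatches(x, gregexpr("CG", toupper(x), fixed = TRUE))) *
    (nchar(x) > 0)
}

#' Generate the synthetic target-panel reference
#'
#' Builds one random reference sequence per region honouring the
#' per-subregion CpG counts exactly (planted motifs included in the count of
#' the subregion containing them), enumerates and numbers the panel CpGs, and
#' validates the variant plan against the generated references.
#'
#' @param spec A [panel_spec()].
#' @return A list with `references` (named character vector),
#'   `subregions` (tibble: region, subregion, start, end; 0-based half-open),
#'   `cpg_sites` (tibble: chrom, start, panel_index, subregion — indices run
#'   1..N in genomic order within each region), and `variant_plan`.
#' @export
generate_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    refs <- character(0)
    sub_rows <- list()
    for (rg in spec$regions) {
      motifs <- Filter(function(m) m$region == rg$name, spec$motifs)
      offset <- 0L
      all_starts <- integer(0)
      region_len <- sum(vapply(rg$subregions, function(s) as.integer(s$length_bp),
                               integer(1)))
      blocked_all <- if (length(motifs)) {
        data.frame(start = vapply(motifs, function(m) as.integer(m$offset), integer(1)),
                   end = vapply(motifs, function(m) as.integer(m$offset) + nchar(m$seq),
                                integer(1)))
      } else {
        data.frame(start = integer(0), end = integer(0))
      }
      for (sr in rg$subregions) {
        len <- as.integer(sr$length_bp)
        # motifs falling inside this subregion, in subregion coordinates
        in_sub <- blocked_all[blocked_all$start >= offset &
                                blocked_all$end <= offset + len, , drop = FALSE]
        motif_cg <- 0L
        if (nrow(in_sub)) {
          for (m in motifs) {
            if (m$offset >= offset && m$offset + nchar(m$seq) <= offset + len) {
              motif_cg <- motif_cg + count_cg(m$seq)
            }
          }
        }
        n_random <- as.integer(sr$n_cpg) - motif_cg
        if (n_random < 0L) {
          stop("planted motifs carry more CpGs than the subregion allows",
               call. = FALSE)
        }
        local_blocked <- in_sub
        local_blocked$start <- local_blocked$start - offset
        local_blocked$end <- local_blocked$end - offset
        starts <- sample_cpg_starts(len, n_random, local_blocked)
        all_starts <- c(all_starts, starts + offset)
        sub_rows[[length(sub_rows) + 1L]] <- tibble::tibble(
          region = rg$name, subregion = sr$label,
          start = offset, end = offset + len)
        offset <- offset + len
      }
      region_motifs <- lapply(motifs, function(m) {
        list(offset = as.integer(m$offset), seq = m$seq)
      })
      refs[rg$name] <- build_sequence(region_len, sort(all_starts),
                                      region_motifs)
    }
    subregions <- do.call(rbind, sub_rows)
    cpg_sites <- do.call(rbind, lapply(names(refs), function(nm) {
      subs <- subregions[subregions$region == nm, , drop = FALSE]
      enumerate_cpgs(refs[[nm]], chrom = nm,
                     subregions = subs[, c("subregion", "start", "end")])
    }))
    # generator invariant: per-subregion CpG counts honoured exactly
    for (rg in spec$regions) {
      subs <- subregions[subregions$region == rg$name, , drop = FALSE]
      for (i in seq_along(rg$subregions)) {
        sr <- rg$subregions[[i]]
        got <- sum(cpg_sites$chrom == rg$name &
                     cpg_sites$subregion == sr$label)
        if (got != sr$n_cpg) {
          stop(sprintf("internal error: subregion %s/%s has %d CpGs, expected %d",
                       rg$name, sr$label, got, sr$n_cpg), call. = FALSE)
        }
      }
    }
    vp <- spec$variant_plan
    if (!is.null(vp) && nrow(vp) > 0L) {
      for (i in seq_len(nrow(vp))) {
        ref_char <- substr(refs[[vp$region[i]]], vp$offset[i] + 1L,
                           vp$offset[i] + 1L)
        if (ref_char != toupper(vp$ref_base[i])) {
          stop(sprintf("variant plan ref_base '%s' does not match reference '%s' at %s:%d",
                       vp$ref_base[i], ref_char, vp$region[i], vp$offset[i]),
               call. = FALSE)
        }
      }
    }
    list(references = refs, subregions = tibble::as_tibble(subregions),
         cpg_sites = tibble::as_tibble(cpg_sites), variant_plan = vp,
         spec = spec)
  })
}

# ---------------------------------------------------------------------------
# Cohort

#' Specification for a synthetic methylation-expression cohort
#'
#' Plants the regulatory structure the MGMT locus shows across glioma
#' samples: per sample, exon-1 CpG methylation values scatter around a
#' sample-level exon mean and intron-1 CpGs around an intron mean, and log2
#' relative expression is a linear function of the two means — negative
#' coupling to exon-1 methylation, positive coupling to intron-1 methylation
#' — plus Gaussian noise. Truth is recorded so recovery can be tested.
#'
#' @param n_samples Integer >= 4.
#' @param exon_effect Slope of exon-mean methylation on log2 expression
#'   (expected negative).
#' @param intron_effect Slope of intron-mean methylation (expected positive).
#' @param noise_sd Positive residual SD of log2 expression.
#' @param n_exon_cpgs,n_intron_cpgs CpGs simulated per compartment.
#' @param cpg_sd Per-CpG scatter around the sample-level mean.
#' @param intercept Intercept of log2 expression.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 50L, exon_effect = -3, intron_effect = 3,
                        noise_sd = 0.75, n_exon_cpgs = 12L,
                        n_intron_cpgs = 34L, cpg_sd = 0.05, intercept = 2,
                        seed = 1L) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 4L) {
    stop("a cohort needs at least 4 samples for correlation to be meaningful",
         call. = FALSE)
  }
  stopifnot(noise_sd >= 0, cpg_sd >= 0, n_exon_cpgs >= 1L, n_intron_cpgs >= 1L)
  structure(list(n_samples = n_samples, exon_effect = exon_effect,
                 intron_effect = intron_effect, noise_sd = noise_sd,
                 n_exon_cpgs = as.integer(n_exon_cpgs),
                 n_intron_cpgs = as.integer(n_intron_cpgs),
                 cpg_sd = cpg_sd, intercept = intercept,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic methylation-expression cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list with `methylation` (samples x CpGs matrix of fractions,
#'   columns `exon_##` then `intron_##`), `expression` (positive relative
#'   expression per sample, `2^log2expr`), `samples` (tibble of sample
#'   metadata), `subregion` (named vector mapping each CpG column to
#'   `promoter_exon1` / `intron1`), and `truth` (sample-level means and the
#'   planted effects).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    exon_mean <- stats::runif(n, 0.05, 0.95)
    intron_mean <- stats::runif(n, 0.05, 0.95)
    clamp01 <- function(x) {
      x[x < 0] <- 0
      x[x > 1] <- 1
      x
    }
    meth_exon <- clamp01(matrix(stats::rnorm(n * spec$n_exon_cpgs,
                                             mean = exon_mean,
                                             sd = spec$cpg_sd),
                                nrow = n))
    meth_intron <- clamp01(matrix(stats::rnorm(n * spec$n_intron_cpgs,
                                               mean = intron_mean,
                                               sd = spec$cpg_sd),
                                  nrow = n))
    meth <- cbind(meth_exon, meth_intron)
    colnames(meth) <- c(sprintf("exon_%02d", seq_len(spec$n_exon_cpgs)),
                        sprintf("intron_%02d", seq_len(spec$n_intron_cpgs)))
    rownames(meth) <- sprintf("S%02d", seq_len(n))
    log2expr <- spec$intercept + spec$exon_effect * exon_mean +
      spec$intron_effect * intron_mean + stats::rnorm(n, 0, spec$noise_sd)
    subregion <- stats::setNames(
      rep(c("promoter_exon1", "intron1"),
          c(spec$n_exon_cpgs, spec$n_intron_cpgs)),
      colnames(meth))
    samples <- tibble::tibble(
      sample_id = rownames(meth),
      sample_type = rep_len(c("cell_line", "tumor"), n),
      relative_expression = 2 ^ log2expr)
    list(methylation = meth, expression = samples$relative_expression,
         samples = samples, subregion = subregion,
         truth = list(exon_mean = exon_mean, intron_mean = intron_mean,
                      log2_expression = log2expr,
                      exon_effect = spec$exon_effect,
                      intron_effect = spec$intron_effect),
         spec = spec)
  })
}
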