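#' Diploid variant-calling parameters
#'
#' The candidate gates used when calling SNVs from long-read pileups: a
#' column is considered only at `min_candidate_depth` reads, the most
#' frequent non-reference base becomes a candidate only at
#' `min_candidate_frequency`, and the diploid genotype is the maximum of a
#' binomial likelihood over `{0/0, 0/1, 1/1}` with expected alt fractions
#' `{e, 1/2, 1 - e}` where `e = error_rate / 3` is the per-base error
#' directed at the candidate alt.
#'
#' @param min_candidate_frequency Minimum alt-allele fraction (default 0.15).
#' @param min_candidate_depth Minimum column depth (default 10).
#' @param ploidy Only 2 is supported.
#' @param error_rate Per-base substitution error rate (default 0.05).
#' @return A list of class `variant_params`.
#' @export
variant_params <- function(min_candidate_frequency = 0.15,
                           min_candidate_depth = 10L, ploidy = 2L,
                           error_rate = 0.05) {
  stopifnot(min_candidate_frequency > 0, min_candidate_depth >= 1L,
            error_rate > 0, error_rate < 1)
  if (ploidy != 2L) stop("only ploidy 2 is supported", call. = FALSE)
  structure(list(min_candidate_frequency = min_candidate_frequency,
                 min_candidate_depth = as.integer(min_candidate_depth),
                 ploidy = 2L, error_rate = error_rate),
            class = "variant_params")
}

genotype_call_row <- function(chrom, pos, ref_base, alt_base, genotype,
                              allele_frequency, depth, quality,
                              homopolymer_flag = FALSE,
                              no_call_reason = NA_character_) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref_base = ref_base,
                 alt_base = alt_base, genotype = genotype,
                 allele_frequency = allele_frequency,
                 depth = as.integer(depth), quality = quality,
                 homopolymer_flag = homopolymer_flag,
                 no_call_reason = no_call_reason)
}

#' Call a diploid genotype from one pileup column
#'
#' Applies the candidate gates and the 3-genotype binomial likelihood of
#' [variant_params()]. Quality is the natural-log likelihood margin between
#' the best and second-best genotype.
#'
#' @param col A one-row data frame (or list) with `chrom`, `pos`, `ref_base`
#'   and base counts `A`, `C`, `G`, `T` (see [simulate_pileup()]).
#' @param params A [variant_params()].
#' @param exclude_alt Optional bases never considered as candidate alts at
#'   this column (used for CpG-aware C>T / G>A artifact masking).
#' @return A one-row genotype tibble with `genotype` in
#'   `{"ref/ref", "ref/alt", "alt/alt", "no_call"}`, the alt base, allele
#'   frequency (alt count / depth), depth, quality, and a `no_call_reason`.
#' @export
call_genotype <- function(col, params = variant_params(),
                          exclude_alt = NULL) {
  counts <- c(A = as.integer(col$A), C = as.integer(col$C),
              G = as.integer(col$G), T = as.integer(col$T))
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("invalid base counts in pileup column", call. = FALSE)
  }
  ref <- toupper(col$ref_base)
  stopifnot(ref %in% BASES)
  depth <- sum(counts)
  if (depth < params$min_candidate_depth) {
    return(genotype_call_row(col$chrom, col$pos, ref, NA_character_,
                             "no_call", NA_real_, depth, NA_real_,
                             no_call_reason = "insufficient_depth"))
  }
  cand <- counts[setdiff(BASES, c(ref, exclude_alt))]
  alt <- names(cand)[which.max(cand)]  # which.max tie-breaks by base order
  af <- counts[[alt]] / depth
  if (af < params$min_candidate_frequency) {
    return(genotype_call_row(col$chrom, col$pos, ref, NA_character_,
                             "ref/ref", af, depth, NA_real_))
  }
  e <- params$error_rate / 3
  p_alt <- c("ref/ref" = e, "ref/alt" = 0.5, "alt/alt" = 1 - e)
  ll <- stats::dbinom(counts[[alt]], depth, p_alt, log = TRUE)
  ord <- order(ll, decreasing = TRUE)
  genotype_call_row(col$chrom, col$pos, ref, alt, names(p_alt)[ord[1]],
                    af, depth, unname(ll[ord[1]] - ll[ord[2]]))
}

#' Scan a region's pileup and emit variant calls
#'
#' Calls every column with [call_genotype()] and returns the non-reference
#' calls, each flagged for homopolymer context with [flag_homopolymer()]
#' (advisory metadata: the flag never suppresses a call). When `cpg_sites`
#' is given the caller is methylation-aware: at a known CpG the C>T (and
#' reverse-strand G>A) artifact bases are excluded as candidate alts.
#'
#' @param pileups A pileup tibble sorted by position, one row per reference
#'   position ([simulate_pileup()]).
#' @param reference The region's reference sequence; its length must match
#'   the pileup.
#' @param params A [variant_params()].
#' @param cpg_sites Optional integer vector of 0-based CpG C positions in
#'   this region.
#' @param min_run Homopolymer run length used for flagging (default 5).
#' @return A genotype tibble containing only rows with genotype `ref/alt` or
#'   `alt/alt`.
#' @export
call_region <- function(pileups, reference, params = variant_params(),
                        cpg_sites = NULL, min_run = 5L) {
  reference <- toupper(reference)
  if (nrow(pileups) != nchar(reference)) {
    stop(sprintf("pileup has %d columns but reference has %d bases",
                 nrow(pileups), nchar(reference)), call. = FALSE)
  }
  ref_chars <- strsplit(reference, "")[[1]]
  if (!all(toupper(pileups$ref_base) == ref_chars)) {
    stop("pileup ref_base column disagrees with the reference sequence",
         call. = FALSE)
  }
  exclude_at <- vector("list", nrow(pileups))
  if (!is.null(cpg_sites)) {
    for (s in cpg_sites) {
      if (s + 1L <= nrow(pileups)) exclude_at[[s + 1L]] <- "T"   # CpG C>T
      if (s + 2L <= nrow(pileups)) exclude_at[[s + 2L]] <- "A"   # CpG G>A
    }
  }
  out <- list()
  for (i in seq_len(nrow(pileups))) {
    call <- call_genotype(pileups[i, ], params, exclude_alt = exclude_at[[i]])
    if (call$genotype %in% c("ref/alt", "alt/alt")) {
      call$homopolymer_flag <- flag_homopolymer(reference, call$pos, min_run)
      out[[length(out) + 1L]] <- call
    }
  }
  if (!length(out)) {
    return(genotype_call_row(character(0), integer(0), character(0),
                             character(0), character(0), numeric(0),
                             integer(0), numeric(0), logical(0),
                             character(0)))
  }
  do.call(rbind, out)
}

#' Is a position in (or immediately adjacent to) a homopolymer run?
#'
#' Nanopore base calls inside long single-base runs are a known error
#' hotspot (the MGMT panel carries a 6-G run at one assayed locus), so calls
#' in or next to a run of `min_run` identical bases are flagged as
#' low-confidence.
#'
#' @param reference Region sequence.
#' @param pos 0-based position.
#' @param min_run Minimum run length (default 5).
#' @return `TRUE` iff `pos` lies within, or is immediately adjacent to, a
#'   run of at least `min_run` identical bases.
#' @export
flag_homopolymer <- function(reference, pos, min_run = 5L) {
  n <- nchar(reference)
  pos <- as.integer(pos)
  stopifnot(pos >= 0L, pos < n)
  inside <- homopolymer_positions(reference, min_run)
  any(inside[pmax(1L, pos):pmin(n, pos + 2L)])
}

#' Classify a tumor variant against a matched normal
#'
#' @param tumor,normal One-row genotype tibbles at the same locus
#'   ([call_genotype()]); the normal is typically saliva-derived germline
#'   DNA.
#' @return A one-row tibble with `chrom`, `pos` and `status`: `somatic`
#'   (variant in tumor, reference in normal), `germline` (variant in both),
#'   `absent` (tumor is reference), or `inconsistent` (either call is a
#'   no-call).
#' @export
classify_somatic <- function(tumor, normal) {
  if (!identical(tumor$chrom, normal$chrom) ||
      !identical(as.integer(tumor$pos), as.integer(normal$pos))) {
    stop("tumor and normal calls are at different loci", call. = FALSE)
  }
  is_var <- function(g) g %in% c("ref/alt", "alt/alt")
  status <- if (tumor$genotype == "no_call" || normal$genotype == "no_call") {
    "inconsistent"
  } else if (!is_var(tumor$genotype)) {
    "absent"
  } else if (is_var(normal$genotype)) {
    "germline"
  } else {
    "somatic"
  }
  tibble::tibble(chrom = tumor$chrom, pos = as.integer(tumor$pos),
                 status = status)
}

#' Compare allele frequencies from two platforms
#'
#' Pearson chi-squared test (no continuity correction) on the 2x2 table of
#' reference/alternate read counts from two assays of the same locus, plus
#' the absolute allele-frequency difference.
#'
#' @param counts_a,counts_b Length-2 numeric vectors `(ref, alt)`.
#' @return A list with `statistic`, `p_value` and `delta_af`.
#' @export
compare_allele_frequencies <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 2L, length(counts_b) == 2L,
            all(counts_a >= 0), all(counts_b >= 0))
  tab <- rbind(a = counts_a, b = counts_b)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared test undefined: a table margin is zero", call. = FALSE)
  }
  af_a <- counts_a[2] / sum(counts_a)
  af_b <- counts_b[2] / sum(counts_b)
  if (identical(as.numeric(counts_a), as.numeric(counts_b)) ||
      af_a == af_b) {
    # chisq.test warns on some degenerate equal tables; statistic is exactly 0
    return(list(statistic = 0, p_value = 1, delta_af = 0))
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       delta_af = abs(af_a - af_b))
}

# ---------------------------------------------------------------------------
# Minimal VCF 4.2

#' Write / read genotype calls as minimal VCF 4.2
#'
#' A deliberately small dialect carrying what the panel readout needs:
#' `CHROM, POS` (1-based), `REF, ALT, QUAL, FILTER` (`PASS` or
#' `homopolymer`), `INFO` (`AF`, `DP`) and a single sample's `GT`.
#' `read_vcf(write_vcf(x))` reproduces the calls.
#'
#' @param calls A genotype tibble of variant rows ([call_region()]).
#' @param path Output path.
#' @return `write_vcf` returns `path` invisibly; `read_vcf` a genotype
#'   tibble.
#' @export
write_vcf <- function(calls, path) {
  gt_code <- c("ref/ref" = "0/0", "ref/alt" = "0/1", "alt/alt" = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ncatsr",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt allele frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FILTER=<ID=homopolymer,Description=\"Within or adjacent to a homopolymer run\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
  rows <- character(0)
  if (nrow(calls)) {
    rows <- sprintf(
      "%s\t%d\t.\t%s\t%s\t%s\t%s\tAF=%s;DP=%d\tGT\t%s",
      calls$chrom, calls$pos + 1L, calls$ref_base, calls$alt_base,
      ifelse(is.na(calls$quality), ".", format(round(calls$quality, 2))),
      ifelse(calls$homopolymer_flag, "homopolymer", "PASS"),
      format(calls$allele_frequency, digits = 6), calls$depth,
      gt_code[calls$genotype])
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "##fileformat=VCFv4.2") {
    stop(sprintf("'%s' is not a VCFv4.2 file", path), call. = FALSE)
  }
  body <- lines[!startsWith(lines, "#")]
  gt_decode <- c("0/0" = "ref/ref", "0/1" = "ref/alt", "1/1" = "alt/alt")
  if (!length(body)) {
    return(genotype_call_row(character(0), integer(0), character(0),
                             character(0), character(0), numeric(0),
                             integer(0), numeric(0), logical(0),
                             character(0)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- lengths(f) != 10L
  if (any(bad)) {
    stop(sprintf("'%s': malformed VCF record at data line %d", path,
                 which(bad)[1]), call. = FALSE)
  }
  m <- do.call(rbind, f)
  info <- strsplit(m[, 8], ";", fixed = TRUE)
  get_info <- function(x, key) {
    hit <- x[startsWith(x, paste0(key, "="))]
    if (!length(hit)) return(NA_character_)
    sub(paste0(key, "="), "", hit[1])
  }
  tibble::tibble(
    chrom = m[, 1],
    pos = as.integer(m[, 2]) - 1L,
    ref_base = m[, 4],
    alt_base = m[, 5],
    genotype = unname(gt_decode[vapply(strsplit(m[, 10], ":"), `[`, "", 1)]),
    allele_frequency = as.numeric(vapply(info, get_info, "", key = "AF")),
    depth = as.integer(vapply(info, get_info, "", key = "DP")),
    quality = suppressWarnings(as.numeric(m[, 6])),
    homopolymer_flag = m[, 7] == "homopolymer",
    no_call_reason = NA_character_)
}
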