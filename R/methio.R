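#' Methylation-call filtering parameters
#'
#' The two per-sample filters applied before any site-level frequency is
#' reported: a call is used only when its LLR magnitude reaches `llr_cutoff`
#' (ambiguous calls are excluded from numerator and denominator alike), and a
#' site is reported only when at least `min_reads` qualifying calls remain.
#'
#' @param llr_cutoff Positive LLR magnitude cutoff (default 2.5).
#' @param min_reads Minimum qualifying reads per reported site (default 10).
#' @return A list of class `meth_filter_params`.
#' @export
meth_filter_params <- function(llr_cutoff = 2.5, min_reads = 10L) {
  stopifnot(llr_cutoff > 0, min_reads >= 1L)
  structure(list(llr_cutoff = llr_cutoff, min_reads = as.integer(min_reads)),
            class = "meth_filter_params")
}

#' Read-level quality-control parameters
#'
#' @param min_mean_q Mean Phred quality a read must exceed (strict `>`,
#'   default 8). Mean quality is computed on the error-probability scale:
#'   `-10 * log10(mean(10^(-Q/10)))`.
#' @param min_length Read length a read must exceed (strict `>`, default 200).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_mean_q = 8, min_length = 200L) {
  stopifnot(min_mean_q >= 0, min_length >= 0L)
  structure(list(min_mean_q = min_mean_q, min_length = as.integer(min_length)),
            class = "qc_params")
}

#' A named panel-index window
#'
#' @param name Window name (e.g. `"DMR2"`).
#' @param lo,hi Inclusive 1-based panel CpG indices, `lo <= hi`.
#' @return A list of class `region_window`.
#' @examples
#' dmr2 <- region_window("DMR2", 70, 81)  # the 12 clinically relevant CpGs
#' @export
region_window <- function(name, lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(lo >= 1L, lo <= hi)
  structure(list(name = name, lo = lo, hi = hi), class = "region_window")
}

# ---------------------------------------------------------------------------
# FASTQ QC

#' Read a FASTQ file
#'
#' Thin wrapper over [Biostrings::readQualityScaledDNAStringSet()].
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return A `QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(path) {
  tryCatch(
    # the reader warns that FASTQ metadata columns are dropped; they carry
    # nothing this pipeline uses
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) {
      stop(sprintf("malformed FASTQ '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
}

#' Quality-filter reads
#'
#' A read passes iff its mean quality is strictly above `min_mean_q` and its
#' length strictly above `min_length`. Mean quality is the Phred-scaled mean
#' per-base error probability, `-10 log10(mean(10^(-Q/10)))` — the convention
#' of standard long-read QC tools, which down-weights a few very bad bases
#' less than an arithmetic mean of Q would.
#'
#' @param reads A `QualityScaledDNAStringSet` (see [read_fastq()]), or a data
#'   frame with columns `read_name`, `sequence` and `qualities` (list column
#'   of integer Phred scores).
#' @param params A [qc_params()].
#' @return A list with `reads` (the passing subset, same class as the input),
#'   `n_input`, `n_passed`, `n_failed`, and `mean_q` (per input read).
#' @export
qc_filter_reads <- function(reads, params = qc_params()) {
  if (methods::is(reads, "QualityScaledDNAStringSet")) {
    qlist <- suppressWarnings(as(Biostrings::quality(reads), "IntegerList"))
    quals <- as.list(qlist)
    lens <- Biostrings::width(reads)
  } else {
    stopifnot(is.data.frame(reads),
              all(c("read_name", "sequence", "qualities") %in% names(reads)))
    quals <- reads$qualities
    lens <- nchar(reads$sequence)
    bad <- lens != lengths(quals)
    if (any(bad)) {
      stop(sprintf("record %d: sequence and quality lengths differ",
                   which(bad)[1]), call. = FALSE)
    }
  }
  mean_q <- vapply(quals, function(q) {
    -10 * log10(mean(10 ^ (-q / 10)))
  }, numeric(1))
  pass <- mean_q > params$min_mean_q & lens > params$min_length
  kept <- if (is.data.frame(reads)) {
    reads[pass, , drop = FALSE]
  } else {
    # subsetting QualityScaledDNAStringSet warns about dropped mcols
    suppressWarnings(reads[pass])
  }
  list(reads = kept, n_input = length(pass),
       n_passed = sum(pass), n_failed = sum(!pass), mean_q = mean_q,
       pass = pass)
}

# ---------------------------------------------------------------------------
# CpG enumeration

#' Enumerate and number the CpG sites of a captured interval
#'
#' Scans the forward strand for CG dinucleotides (case-insensitive; `N` never
#' matches) inside a captured interval and numbers them consecutively from
#' the 5' end. The two strands of a CpG are one site, reported at the
#' position of the plus-strand C. Panel numbering therefore reproduces the
#' literature's CpG indices once the captured interval is configured to start
#' at literature CpG #1.
#'
#' @param sequence Reference sequence (character scalar).
#' @param interval 0-based half-open captured interval, default the whole
#'   sequence.
#' @param chrom Name written in the `chrom` column.
#' @param subregions Optional data frame with columns `subregion`, `start`,
#'   `end` (0-based half-open) used to label each site.
#' @return A tibble with columns `chrom`, `start` (0-based C position),
#'   `panel_index` (1..N) and `subregion`.
#' @export
enumerate_cpgs <- function(sequence, interval = NULL, chrom = "region",
                           subregions = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (is.null(interval)) interval <- c(0L, n)
  stopifnot(interval[1] >= 0L, interval[2] <= n, interval[1] <= interval[2])
  sub <- toupper(substr(sequence, interval[1] + 1L, interval[2]))
  m <- gregexpr("CG", sub, fixed = TRUE)[[1]]
  starts <- if (m[1] == -1L) integer(0) else as.integer(m) - 1L + interval[1]
  label <- rep(NA_character_, length(starts))
  if (!is.null(subregions) && length(starts)) {
    for (i in seq_len(nrow(subregions))) {
      inside <- starts >= subregions$start[i] & starts < subregions$end[i]
      label[inside] <- subregions$subregion[i]
    }
  }
  tibble::tibble(chrom = chrom, start = starts,
                 panel_index = seq_along(starts), subregion = label)
}

# ---------------------------------------------------------------------------
# Aggregation

#' Aggregate per-read calls into per-site methylation frequencies
#'
#' Implements the per-sample filtering used throughout this package: a call
#' QUALIFIES iff `|llr| >= llr_cutoff` (ambiguous calls are discarded
#' entirely), it is methylated iff its LLR is positive among qualifiers, and
#' a site is reported iff at least `min_reads` qualifying calls remain.
#' Calls covering a CpG group (`num_motifs > 1`) contribute the same state to
#' every motif of the group, so `called_sites` accumulates
#' `num_motifs` per qualifying read while the read-depth gate counts reads.
#'
#' @param calls A methylation-call tibble (see [simulate_meth_calls()] /
#'   [read_meth_calls()]).
#' @param params A [meth_filter_params()].
#' @return A tibble in the methylation-frequency dialect: `chromosome`,
#'   `start`, `end`, `num_motifs_in_group`, `called_sites`,
#'   `called_sites_methylated`, `methylated_frequency`, `group_sequence`,
#'   sorted by chromosome then start. Sites failing the read gate are absent.
#' @export
aggregate_site_frequency <- function(calls, params = meth_filter_params()) {
  empty <- tibble::tibble(chromosome = character(), start = integer(),
                          end = integer(), num_motifs_in_group = integer(),
                          called_sites = integer(),
                          called_sites_methylated = integer(),
                          methylated_frequency = numeric(),
                          group_sequence = character())
  if (is.null(calls) || nrow(calls) == 0L) return(empty)
  qual <- calls[abs(calls$log_lik_ratio) >= params$llr_cutoff, , drop = FALSE]
  if (nrow(qual) == 0L) return(empty)
  key <- paste(qual$chromosome, qual$start, qual$end, sep = "\r")
  grp <- split(seq_len(nrow(qual)), key)
  rows <- lapply(grp, function(idx) {
    n_reads <- length(idx)
    if (n_reads < params$min_reads) return(NULL)
    motifs <- qual$num_motifs[idx]
    meth <- qual$log_lik_ratio[idx] > 0
    data.frame(chromosome = qual$chromosome[idx[1]],
               start = qual$start[idx[1]],
               end = qual$end[idx[1]],
               num_motifs_in_group = motifs[1],
               called_sites = sum(motifs),
               called_sites_methylated = sum(motifs[meth]),
               methylated_frequency = sum(motifs[meth]) / sum(motifs),
               group_sequence = qual$sequence[idx[1]],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Mean methylation over a panel-index window
#'
#' Unweighted mean of reported site frequencies whose panel index falls in
#' the window. Sites dropped by the read filter simply do not contribute; a
#' window with no reported site yields an undefined mean (`NA`), which is
#' distinct from 0.
#'
#' @param freq A frequency tibble from [aggregate_site_frequency()].
#' @param sites The CpG site table ([enumerate_cpgs()]) giving each site its
#'   panel index; joined on `chrom`/`chromosome` and `start`.
#' @param window A [region_window()].
#' @return A list with `mean` (fraction or `NA`), `n_sites_used` and
#'   `window`.
#' @export
region_mean <- function(freq, sites, window) {
  stopifnot(inherits(window, "region_window"))
  key_freq <- paste(freq$chromosome, freq$start)
  key_site <- paste(sites$chrom, sites$start)
  idx <- match(key_freq, key_site)
  panel_index <- sites$panel_index[idx]
  use <- !is.na(panel_index) & panel_index >= window$lo &
    panel_index <= window$hi
  n <- sum(use)
  list(mean = if (n > 0) mean(freq$methylated_frequency[use]) else NA_real_,
       n_sites_used = n, window = window)
}

#' Bin a methylation frequency into the clinical three-category readout
#'
#' The semiquantitative categories used clinically for MGMT: below 10%
#' "not detected", 10-30% inclusive "low", above 30% "detected".
#'
#' @param freq Numeric vector of fractions in \[0, 1\].
#' @param boundaries Length-2 numeric, the lower and upper band edges
#'   (default `c(0.10, 0.30)`); both edges belong to the "low" band.
#' @return An ordered factor with levels
#'   `not_detected < low < detected`.
#' @export
classify_methylation_level <- function(freq, boundaries = c(0.10, 0.30)) {
  if (any(is.na(freq)) || any(freq < 0 | freq > 1)) {
    stop("methylation frequencies must lie in [0, 1]", call. = FALSE)
  }
  out <- ifelse(freq < boundaries[1], "not_detected",
                ifelse(freq <= boundaries[2], "low", "detected"))
  factor(out, levels = c("not_detected", "low", "detected"), ordered = TRUE)
}

# ---------------------------------------------------------------------------
# TSV dialects

read_tsv_dialect <- function(path, columns, types, strict = TRUE) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    stop(sprintf("'%s': empty file, expected a header line", path),
         call. = FALSE)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, columns)) {
    stop(sprintf("'%s': bad header; expected columns %s", path,
                 paste(columns, collapse = ", ")), call. = FALSE)
  }
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ok <- lengths(fields) == length(columns)
  if (any(!ok)) {
    first_bad <- which(!ok)[1]
    if (strict) {
      stop(sprintf("'%s': line %d has %d fields, expected %d", path,
                   first_bad + 1L, lengths(fields)[first_bad],
                   length(columns)), call. = FALSE)
    }
    message(sprintf("'%s': skipped %d malformed line(s)", path, sum(!ok)))
    fields <- fields[ok]
  }
  if (!length(fields)) {
    mat <- matrix(character(0), ncol = length(columns))
  } else {
    mat <- do.call(rbind, fields)
  }
  out <- lapply(seq_along(columns), function(j) {
    v <- mat[, j]
    switch(types[j], integer = as.integer(v), numeric = as.numeric(v), v)
  })
  names(out) <- columns
  tibble::as_tibble(out)
}

write_tsv_dialect <- function(x, path, columns) {
  stopifnot(all(columns %in% names(x)))
  utils::write.table(as.data.frame(x)[, columns, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

meth_call_types <- c("character", "character", "integer", "integer",
                     "character", "numeric", "numeric", "numeric",
                     "integer", "integer", "character")

#' Read / write the per-read methylation-call TSV dialect
#'
#' The tab-separated dialect emitted by signal-level methylation callers:
#' columns `chromosome, strand, start, end, read_name, log_lik_ratio,
#' log_lik_methylated, log_lik_unmethylated, num_calling_strands,
#' num_motifs, sequence`. `read_meth_calls` validates the header and each
#' row's field count; in strict mode it stops at the first malformed line
#' (naming it), otherwise malformed lines are skipped with a message.
#' Write-then-read is an identity on valid tables.
#'
#' @param path File path.
#' @param strict Stop on the first malformed line (default) or skip them.
#' @return `read_meth_calls`: a methylation-call tibble.
#' @export
read_meth_calls <- function(path, strict = TRUE) {
  read_tsv_dialect(path, meth_call_columns, meth_call_types, strict)
}

#' @rdname read_meth_calls
#' @param calls A methylation-call tibble.
#' @export
write_meth_calls <- function(calls, path) {
  write_tsv_dialect(calls, path, meth_call_columns)
}

meth_freq_columns <- c("chromosome", "start", "end", "num_motifs_in_group",
                       "called_sites", "called_sites_methylated",
                       "methylated_frequency", "group_sequence")
meth_freq_types <- c("character", "integer", "integer", "integer",
                     "integer", "integer", "numeric", "character")

#' Read / write the methylation-frequency TSV dialect
#'
#' Columns `chromosome, start, end, num_motifs_in_group, called_sites,
#' called_sites_methylated, methylated_frequency, group_sequence`; same
#' strict/permissive contract as [read_meth_calls()].
#'
#' @param path File path.
#' @param strict Stop on the first malformed line (default) or skip them.
#' @return `read_meth_freq`: a frequency tibble.
#' @export
read_meth_freq <- function(path, strict = TRUE) {
  read_tsv_dialect(path, meth_freq_columns, meth_freq_types, strict)
}

#' @rdname read_meth_freq
#' @param freq A frequency tibble ([aggregate_site_frequency()]).
#' @export
write_meth_freq <- function(freq, path) {
  write_tsv_dialect(freq, path, meth_freq_columns)
}
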