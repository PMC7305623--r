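#' Default end-to-end pipeline configuration
#'
#' One nested list holds every tunable of the pipeline; where the modelled
#' assay states a value it is the default (LLR cutoff 2.5, minimum 10 reads
#' per site, Phred > 8 / length > 200 read QC, candidate gates 0.15 / 10 at
#' ploidy 2, selection threshold 0.7, DMR2 = panel CpGs 70-81, 897-bp /
#' 52-CpG standards). The configuration is plain YAML-serializable data and
#' round-trips through [write_pipeline_config()] / [read_pipeline_config()]
#' unchanged.
#'
#' @param seed Master seed; all stage and sample streams derive from it.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    standard = list(length_bp = 897L, n_cpg = 52L, depth = 200L,
                    meth_level_high = 1.0, meth_level_low = 0.0),
    llr_model = list(mu_meth = 4, mu_unmeth = 4, sigma = 1.5,
                     miscall_rate = 0.03),
    filters = list(llr_cutoff = 2.5, min_reads = 10L),
    qc = list(min_mean_q = 8, min_length = 200L),
    variant = list(min_candidate_frequency = 0.15,
                   min_candidate_depth = 10L, ploidy = 2L,
                   error_rate = 0.05),
    error_profile = list(sub_rate = 0.05, ins_rate = 0.04, del_rate = 0.04,
                         homopolymer_sub_multiplier = 3,
                         homopolymer_min_run = 5L),
    windows = list(dmr2 = list(lo = 70L, hi = 81L)),
    association = list(threshold = 0.7, log2_expression = TRUE),
    lod = list(enabled = FALSE,
               levels = c(0, 0.10, 0.25, 0.50, 0.75, 1),
               depths = c(5L, 10L, 15L, 20L, 25L, 50L),
               n_replicates = 100L, alpha = 0.05),
    samples = list(
      list(name = "demo_methylated_tumor", depth = 40L,
           promoter_meth = 0.45, intron_meth = 0.35,
           variants = list(list(region = "IDH1", offset = 150L,
                                ref_base = "C", alt_base = "G",
                                allele_fraction = 0.5)),
           germline_variants = list()),
      list(name = "demo_unmethylated_line", depth = 40L,
           promoter_meth = 0.05, intron_meth = 0.70,
           variants = list(),
           germline_variants = list()))),
    class = "pipeline_config")
}

config_template_keys <- function() {
  c("seed", "standard", "llr_model", "filters", "qc", "variant",
    "error_profile", "windows", "association", "lod", "samples")
}

#' Validate a pipeline configuration
#'
#' Fails fast naming the offending key path for unknown or missing top-level
#' keys and for out-of-range parameter values (delegated to the per-module
#' constructors).
#'
#' @param config A list as produced by [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config) {
  known <- config_template_keys()
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    stop(sprintf("unknown config key: $%s", extra[1]), call. = FALSE)
  }
  missing <- setdiff(known, names(config))
  if (length(missing)) {
    stop(sprintf("missing config key: $%s", missing[1]), call. = FALSE)
  }
  # constructors enforce their own invariants
  do.call(llr_model, config$llr_model)
  do.call(meth_filter_params, config$filters)
  do.call(qc_params, config$qc)
  do.call(variant_params, config$variant)
  do.call(error_profile, config$error_profile)
  region_window("DMR2", config$windows$dmr2$lo, config$windows$dmr2$hi)
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    for (f in c("name", "depth", "promoter_meth", "intron_meth")) {
      if (is.null(s[[f]])) {
        stop(sprintf("missing config key: $samples[[%d]]$%s", i, f),
             call. = FALSE)
      }
    }
  }
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config`: a validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  config <- yaml::read_yaml(path)
  validate_config(config)
  structure(config, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @param config A pipeline configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

variant_list_to_plan <- function(vlist) {
  if (!length(vlist)) {
    return(tibble::tibble(region = character(), offset = integer(),
                          ref_base = character(), alt_base = character(),
                          allele_fraction = numeric()))
  }
  tibble::tibble(
    region = vapply(vlist, `[[`, "", "region"),
    offset = vapply(vlist, function(v) as.integer(v$offset), integer(1)),
    ref_base = vapply(vlist, `[[`, "", "ref_base"),
    alt_base = vapply(vlist, `[[`, "", "alt_base"),
    allele_fraction = vapply(vlist, function(v) as.numeric(v$allele_fraction),
                             numeric(1)))
}

log_record <- function(log, stage, sample, n_in, n_out) {
  rbind(log, data.frame(stage = stage, sample = sample,
                        n_in = n_in, n_out = n_out,
                        n_filtered = n_in - n_out))
}

#' Run the full pipeline from one configuration
#'
#' Orchestrates simulate -> aggregate -> genotype -> report for every
#' configured sample, plus the standards (and optionally the
#' limit-of-detection titration), writing all intermediate tables, per-sample
#' JSON and text reports, a structured stage log, and a run manifest
#' recording every effective parameter and derived seed. Re-running with the
#' same configuration and seed reproduces byte-identical outputs. Failure of
#' one sample is logged and reported without aborting the others.
#'
#' @param config A validated [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `reports` (per-sample lists), `panel`,
#'   `log` (stage-count tibble) and the output directory.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 3L + 2L * length(config$samples))
  model <- do.call(llr_model, config$llr_model)
  filters <- do.call(meth_filter_params, config$filters)
  vparams <- do.call(variant_params, config$variant)
  eprofile <- do.call(error_profile, config$error_profile)
  dmr2 <- region_window("DMR2", config$windows$dmr2$lo,
                        config$windows$dmr2$hi)
  log <- data.frame(stage = character(), sample = character(),
                    n_in = integer(), n_out = integer(),
                    n_filtered = integer())

  # --- panel ---------------------------------------------------------------
  panel <- generate_panel(panel_spec(seed = seeds[1]))
  refs <- Biostrings::DNAStringSet(panel$references)
  Biostrings::writeXStringSet(refs, file.path(out_dir, "panel.fasta"))
  bed <- sprintf("%s\t%d\t%d\tCpG_%d\t0\t+", panel$cpg_sites$chrom,
                 panel$cpg_sites$start, panel$cpg_sites$start + 2L,
                 panel$cpg_sites$panel_index)
  writeLines(bed, file.path(out_dir, "panel_cpgs.bed"))

  # --- standards -----------------------------------------------------------
  standards <- list()
  for (which_std in c("high", "low")) {
    level <- config$standard[[paste0("meth_level_", which_std)]]
    std <- generate_standard(standard_spec(
      config$standard$length_bp, config$standard$n_cpg, level,
      seed = seeds[2]))
    calls <- simulate_meth_calls(std$cpg_starts, std$truth,
                                 config$standard$depth, model,
                                 seed = seeds[3] + match(which_std, c("high", "low")),
                                 chrom = paste0("standard_", which_std),
                                 reference = std$sequence)
    freq <- aggregate_site_frequency(calls, filters)
    write_meth_calls(calls, file.path(out_dir,
                                      sprintf("standard_%s_calls.tsv", which_std)))
    write_meth_freq(freq, file.path(out_dir,
                                    sprintf("standard_%s_freq.tsv", which_std)))
    log <- log_record(log, "standard_aggregate", which_std,
                      length(std$cpg_starts), nrow(freq))
    standards[[which_std]] <- list(standard = std, calls = calls, freq = freq)
  }

  # --- optional LOD titration ---------------------------------------------
  lod_result <- NULL
  if (isTRUE(config$lod$enabled)) {
    scenario <- mixture_scenario(config$lod$levels, config$lod$depths,
                                 config$lod$n_replicates, config$lod$alpha,
                                 seed = seeds[2] + 1L)
    lod_result <- titrate(scenario, standards$low$calls,
                          standards$high$calls, filters)
    write_tsv_dialect(lod_result$summary, file.path(out_dir, "lod_summary.tsv"),
                      names(lod_result$summary))
    write_tsv_dialect(lod_result$tests, file.path(out_dir, "lod_tests.tsv"),
                      names(lod_result$tests))
    jsonlite::write_json(list(lod_depth = lod_result$lod_depth),
                         file.path(out_dir, "lod.json"), auto_unbox = TRUE)
  }

  # --- samples -------------------------------------------------------------
  mgmt_sites <- panel$cpg_sites[panel$cpg_sites$chrom == "MGMT", ]
  reports <- list()
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    sample_seed <- seeds[3L + 2L * i - 1L]
    pile_seed <- seeds[3L + 2L * i]
    report <- tryCatch({
      truth <- ifelse(mgmt_sites$subregion == "promoter_exon1",
                      s$promoter_meth, s$intron_meth)
      calls <- simulate_meth_calls(mgmt_sites$start, truth, s$depth, model,
                                   seed = sample_seed, chrom = "MGMT",
                                   reference = panel$references[["MGMT"]])
      freq <- aggregate_site_frequency(calls, filters)
      write_meth_freq(freq, file.path(out_dir,
                                      sprintf("%s_mgmt_freq.tsv", s$name)))
      log <- log_record(log, "methylation_aggregate", s$name,
                         nrow(mgmt_sites), nrow(freq))
      prom_idx <- mgmt_sites$panel_index[mgmt_sites$subregion == "promoter_exon1"]
      intr_idx <- mgmt_sites$panel_index[mgmt_sites$subregion == "intron1"]
      prom <- region_mean(freq, mgmt_sites,
                          region_window("promoter_exon1", min(prom_idx),
                                        max(prom_idx)))
      intr <- region_mean(freq, mgmt_sites,
                          region_window("intron1", min(intr_idx),
                                        max(intr_idx)))
      dmr2_mean <- region_mean(freq, mgmt_sites, dmr2)
      meth_block <- list(
        promoter_exon1_mean = prom$mean,
        promoter_exon1_category = if (is.na(prom$mean)) "unusable" else
          as.character(classify_methylation_level(prom$mean)),
        intron1_mean = intr$mean,
        dmr2_mean = dmr2_mean$mean,
        dmr2_category = if (is.na(dmr2_mean$mean)) "unusable" else
          as.character(classify_methylation_level(dmr2_mean$mean)),
        n_sites_reported = nrow(freq),
        n_sites_filtered = nrow(mgmt_sites) - nrow(freq))

      tumor_plan <- variant_list_to_plan(s$variants)
      germ_plan <- variant_list_to_plan(s$germline_variants)
      geno_block <- list()
      all_variants <- list()
      for (rg in c("IDH1", "IDH2")) {
        ref <- panel$references[[rg]]
        plan_t <- rbind(tumor_plan[tumor_plan$region == rg, ],
                        germ_plan[germ_plan$region == rg, ])
        plan_n <- germ_plan[germ_plan$region == rg, ]
        rg_cpgs <- panel$cpg_sites$start[panel$cpg_sites$chrom == rg]
        pile_t <- simulate_pileup(ref, plan_t, s$depth, eprofile,
                                  seed = pile_seed + match(rg, c("IDH1", "IDH2")),
                                  chrom = rg)
        pile_n <- simulate_pileup(ref, plan_n, s$depth, eprofile,
                                  seed = pile_seed + 10L + match(rg, c("IDH1", "IDH2")),
                                  chrom = rg)
        vars <- call_region(pile_t, ref, vparams, cpg_sites = rg_cpgs,
                            min_run = config$error_profile$homopolymer_min_run)
        log <- log_record(log, paste0("genotype_", rg), s$name,
                           nrow(pile_t), nrow(vars))
        locus <- list(region = rg, genotype = "ref/ref",
                      alt_base = NA, allele_frequency = NA,
                      somatic_status = "absent", homopolymer_flag = FALSE)
        if (nrow(vars) > 0L) {
          v <- vars[1, ]
          ncall <- call_genotype(pile_n[v$pos + 1L, ], vparams)
          somatic <- classify_somatic(v, ncall)$status
          locus <- list(region = rg, genotype = v$genotype,
                        alt_base = v$alt_base,
                        allele_frequency = v$allele_frequency,
                        somatic_status = somatic,
                        homopolymer_flag = v$homopolymer_flag)
          all_variants[[length(all_variants) + 1L]] <- v
        }
        geno_block[[rg]] <- locus
      }
      if (length(all_variants)) {
        write_vcf(do.call(rbind, all_variants),
                  file.path(out_dir, sprintf("%s_variants.vcf", s$name)))
      }
      list(sample_id = s$name, genotypes = geno_block,
           methylation = meth_block,
           qc = list(depth = s$depth), error = NULL)
    }, error = function(e) {
      list(sample_id = s$name, error = conditionMessage(e))
    })
    reports[[s$name]] <- report
    jsonlite::write_json(report,
                         file.path(out_dir, sprintf("%s_report.json", s$name)),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
    writeLines(render_report(report),
               file.path(out_dir, sprintf("%s_report.txt", s$name)))
  }

  utils::write.table(log, file.path(out_dir, "pipeline_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(package = "ncatsr",
                   version = as.character(utils::packageVersion("ncatsr")),
                   config = unclass(config),
                   derived_seeds = as.integer(seeds))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(reports = reports, panel = panel, standards = standards,
                 lod = lod_result, log = tibble::as_tibble(log),
                 out_dir = out_dir))
}

# Human-readable one-sample summary mirroring the clinical readout:
# IDH genotype + allele fraction + somatic status, MGMT methylation + category.
render_report <- function(report) {
  if (!is.null(report$error)) {
    return(c(sprintf("Sample: %s", report$sample_id),
             sprintf("  FAILED: %s", report$error)))
  }
  fmt_pct <- function(x) if (is.na(x)) "unusable" else sprintf("%.1f%%", 100 * x)
  lines <- c(sprintf("Sample: %s", report$sample_id), "Genotypes:")
  for (g in report$genotypes) {
    lines <- c(lines, sprintf(
      "  %s: %s%s  AF=%s  status=%s%s", g$region, g$genotype,
      if (!is.null(g$alt_base) && !is.na(g$alt_base))
        sprintf(" (alt %s)", g$alt_base) else "",
      if (is.null(g$allele_frequency) || is.na(g$allele_frequency)) "NA" else
        sprintf("%.2f", g$allele_frequency),
      g$somatic_status,
      if (isTRUE(g$homopolymer_flag)) "  [homopolymer context]" else ""))
  }
  m <- report$methylation
  c(lines, "MGMT methylation:",
    sprintf("  promoter/exon1 mean: %s (%s)", fmt_pct(m$promoter_exon1_mean),
            m$promoter_exon1_category),
    sprintf("  DMR2 (CpGs 70-81) mean: %s (%s)", fmt_pct(m$dmr2_mean),
            m$dmr2_category),
    sprintf("  intron1 mean: %s", fmt_pct(m$intron1_mean)),
    sprintf("  sites reported/filtered: %d/%d", m$n_sites_reported,
            m$n_sites_filtered))
}
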