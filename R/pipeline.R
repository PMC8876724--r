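# Pipeline orchestration: configuration, per-sample execution, artifact
# writing and detection-threshold comparison reporting.

#' Default pipeline configuration
#'
#' Single nested list mirroring the module structure; every pipeline
#' constant (100X depth, 5%/2%/10% thresholds, quality radius 5 bp / Q30,
#' 0.5/0.8 and 0.95/0.95 mapping fractions, the <10%/<=1500X secondary
#' review gate, the <=4 below-threshold boundary) surfaces as a named key.
#' Round-trips through YAML via [write_pipeline_config()].
#'
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "mitohap_out") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    thresholds_report = c(0.02, 0.05, 0.10),
    mapping = list(
      default = list(length_fraction = 0.5, similarity_fraction = 0.8),
      strict = list(length_fraction = 0.95, similarity_fraction = 0.95)
    ),
    calling = list(
      min_depth = 100L, quality_radius = 5L, min_quality = 30L,
      detect_freq = 0.05, review_freq = 0.02,
      nearly_complete_max_below = 4L,
      confirm_min_depth = 20L, confirm_major_freq = 0.90
    ),
    classify = list(
      secondary_max_freq = 0.10, secondary_max_depth = 1500,
      cluster_window = 500L, recurrence_min = 3L, votes_required = 2L,
      phase_min_pairs = 5L, phase_min_concordance = 0.9,
      strand_min_share = 0.10, ignore_16093 = FALSE
    ),
    qc = list(
      nearly_complete_max_below = 4L, max_php = 4L,
      kinship_cutoff = 0.0884
    ),
    simulate = list(
      target_depth = 1000, read_length = 150L,
      insert_mean = 350, insert_sd = 50,
      error_rate = 0.001, base_quality = 35L,
      post_homopolymer_boost = 20
    )
  )
}

#' Write / read a pipeline configuration as YAML
#' @param config list from [pipeline_config()].
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- pipeline_config()
  merge_cfg <- function(base, upd) {
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]])) {
        merge_cfg(base[[k]], upd[[k]])
      } else upd[[k]]
    }
    base
  }
  merge_cfg(base, cfg)
}

config_thresholds <- function(config, detect_freq = NULL) {
  cl <- config$calling
  call_thresholds(
    min_depth = cl$min_depth, quality_radius = cl$quality_radius,
    min_quality = cl$min_quality,
    detect_freq = detect_freq %||% cl$detect_freq,
    nearly_complete_max_below = cl$nearly_complete_max_below,
    confirm_min_depth = cl$confirm_min_depth,
    confirm_major_freq = cl$confirm_major_freq)
}

config_criteria <- function(config) {
  cc <- config$classify
  review_criteria(
    secondary_max_freq = cc$secondary_max_freq,
    secondary_max_depth = cc$secondary_max_depth,
    cluster_window = cc$cluster_window,
    recurrence_min = cc$recurrence_min,
    votes_required = cc$votes_required,
    phase_min_pairs = cc$phase_min_pairs,
    phase_min_concordance = cc$phase_min_concordance,
    strand_min_share = cc$strand_min_share,
    ignore_16093 = cc$ignore_16093)
}

#' Process one sample: consensus mapping and variant calling
#'
#' Maps the reads through the three-stage consensus workflow, calls the
#' haplotype at the review (2%) threshold and derives the reporting
#' thresholds by filtering, so threshold call sets nest exactly.
#'
#' @param reads data.frame read set.
#' @param reference a [mito_reference()].
#' @param config pipeline configuration.
#' @param sample_id label.
#' @return Sample list consumed by [classify_dataset()] (plus `hap`,
#'   `workflow`, `metrics`).
#' @export
process_sample <- function(reads, reference, config = pipeline_config(),
                           sample_id = "sample") {
  md <- config$mapping$default
  ms <- config$mapping$strict
  wf <- consensus_workflow(
    reads, reference,
    mapping_params(md$length_fraction, md$similarity_fraction),
    mapping_params(ms$length_fraction, ms$similarity_fraction))
  thr2 <- config_thresholds(config, config$calling$review_freq)
  hap <- call_sample(wf$final, reference, thr2, sample_id)
  hap$detect_freq <- config$calling$detect_freq  # reporting threshold
  metrics <- compute_metrics(wf, hap$profiles, hap)
  list(id = sample_id, mixed = hap$mixed, mapping = wf$final,
       profiles = hap$profiles, avg_depth = metrics$avg_depth,
       hap = hap, workflow = wf, metrics = metrics)
}

#' Run the full pipeline over a cohort
#'
#' Inputs are either truth specs (simulated cohort) or paths to paired
#' FASTQ / SAM files.  Every stage is deterministic given the
#' configuration seed; rerunning with the same inputs reproduces all
#' artifacts bit-identically.
#'
#' @param config pipeline configuration list.
#' @param inputs named list: each element either a [truth_spec()], a
#'   `list(r1 =, r2 =)` of FASTQ paths, or a `list(sam =)` path.
#' @param reference a [mito_reference()].
#' @param kinship optional kinship data.frame (or TSV path).
#' @param write_artifacts write SAM/TSV/haplotype outputs to
#'   `config$out_dir`.
#' @return List: `samples`, `records` (classification), `qc`, `report`
#'   (threshold comparison), `haplotypes` (strings).
#' @export
run_pipeline <- function(config, inputs, reference = mito_reference(),
                         kinship = NULL, write_artifacts = TRUE) {
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    stop("configuration error: inputs must be a named list of samples")
  }
  for (nm in names(inputs)) {
    inp <- inputs[[nm]]
    if (!inherits(inp, "truth_spec")) {
      paths <- unlist(inp)
      if (!all(file.exists(paths))) {
        stop("configuration error: missing input file(s) for sample ", nm,
             ": ", paste(paths[!file.exists(paths)], collapse = ", "))
      }
    }
  }
  if (is.character(kinship)) kinship <- read_kinship(kinship)

  out_dir <- config$out_dir
  if (write_artifacts) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  log_lines <- character(0)
  logf <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, paste0(...))
    log_lines <<- c(log_lines, msg)
  }
  logf("config", sprintf("seed=%d detect_freq=%s hash=%s", config$seed,
                         config$calling$detect_freq,
                         substr(digest_config(config), 1, 12)))

  samples <- list()
  for (i in seq_along(inputs)) {
    nm <- names(inputs)[i]
    inp <- inputs[[nm]]
    reads <- if (inherits(inp, "truth_spec")) {
      inp$seed <- as.integer((config$seed * 1000L + i) %% .Machine$integer.max)
      simulate_sample(inp, reference)$reads
    } else if (!is.null(inp$sam)) {
      read_sam(inp$sam)
    } else {
      read_fastq(inp$r1, inp$r2)
    }
    s <- tryCatch(
      process_sample(reads, reference, config, nm),
      error = function(e) stop("stage 'map/call' failed for sample ", nm,
                               ": ", conditionMessage(e)))
    logf("map", sprintf("%s: %d reads, %d in final mapping, %.0fX", nm,
                        nrow(reads), nrow(s$mapping$alignments),
                        s$avg_depth))
    samples[[nm]] <- s
  }

  criteria <- config_criteria(config)
  records <- classify_dataset(samples, criteria, numt_catalog(),
                              php_hotspots(),
                              detect_freq = config$calling$detect_freq)
  logf("classify", sprintf("%d universe positions, %d NUMT, %d PHP",
                           nrow(records), sum(records$label == "NUMT"),
                           sum(records$label == "PHP")))

  # propagate classification labels into each haplotype so NUMT variants
  # and artifacts are pruned from the reported haplotype strings
  for (nm in names(samples)) {
    hap <- samples[[nm]]$hap
    r <- records[records$sample == nm, , drop = FALSE]
    idx <- match(hap$mixed$pos, r$pos)
    lab <- r$label[idx]
    hap$mixed$classification[!is.na(idx)] <- lab[!is.na(idx)]
    samples[[nm]]$hap <- hap
  }
  haps <- lapply(samples, `[[`, "hap")
  metrics <- do.call(rbind, lapply(samples, `[[`, "metrics"))
  metrics <- cbind(sample = names(samples), metrics)
  qc <- qc_dataset(haps, metrics, records, kinship,
                   config$qc$nearly_complete_max_below,
                   config$qc$max_php, config$qc$kinship_cutoff)
  report <- threshold_report(records, config$thresholds_report,
                             n_samples = length(samples))
  hap_strings <- vapply(haps, haplotype_string, character(1))

  if (write_artifacts) {
    for (nm in names(samples)) {
      write_sam(samples[[nm]]$mapping,
                file.path(out_dir, paste0(nm, ".sam")))
      write.table(variant_table(haps[[nm]]),
                  file.path(out_dir, paste0(nm, ".variants.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(c(sprintf("# sample %s, range 1-%d", nm, reference$length),
                   hap_strings[[nm]]),
                 file.path(out_dir, paste0(nm, ".haplotype.txt")))
    }
    write.table(records, file.path(out_dir, "classification.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(qc, file.path(out_dir, "qc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(metrics, file.path(out_dir, "metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(report, file.path(out_dir, "threshold_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  list(samples = samples, records = records, qc = qc, report = report,
       haplotypes = hap_strings, metrics = metrics, log = log_lines)
}

digest_config <- function(config) {
  # stable parameter fingerprint for the run log
  s <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)))
}

#' Threshold comparison report
#'
#' Re-derives the call set at each detection threshold by filtering minor
#' frequency over the classified universe (no recomputation drift:
#' thresholds nest exactly) and summarises NUMT/PHP counts, the share of
#' samples carrying at least one PHP, the maximum PHPs per sample, and the
#' control-region vs coding-region breakdown of distinct PHP positions
#' (percentages of the 1122-bp CR and 15,447-bp codR, one decimal).
#'
#' @param records classification records from [classify_dataset()].
#' @param thresholds numeric detection thresholds (fractions).
#' @param n_samples cohort size (for percentage of samples with PHPs).
#' @return data.frame, one row per threshold.
#' @export
threshold_report <- function(records, thresholds = c(0.02, 0.05, 0.10),
                             n_samples = length(unique(records$sample))) {
  regs <- mito_regions()
  rows <- lapply(thresholds, function(th) {
    r <- records[records$minor_freq >= th & records$label != "artifact", ,
                 drop = FALSE]
    php <- r[r$label == "PHP", , drop = FALSE]
    per_sample <- if (nrow(php)) table(php$sample) else integer(0)
    cr_pos <- unique(php$pos[region_contains(regs$CR, php$pos)])
    codr_pos <- unique(php$pos[region_contains(regs$codR, php$pos)])
    data.frame(
      threshold = th,
      numt_variants = sum(r$label == "NUMT"),
      php = nrow(php),
      samples_with_php = length(per_sample),
      pct_samples_with_php = if (n_samples > 0) {
        round(100 * length(per_sample) / n_samples, 1)
      } else 0,
      max_php_per_sample = if (length(per_sample)) max(per_sample) else 0L,
      cr_php_positions = length(cr_pos),
      pct_cr_positions = region_php_percentage(length(cr_pos), regs$CR),
      codr_php_positions = length(codr_pos),
      pct_codr_positions = region_php_percentage(length(codr_pos),
                                                 regs$codR),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percentage of a region's positions harbouring PHPs
#'
#' Uses the circular region length as denominator, e.g. 64 distinct CR
#' positions give 64/1122 x 100 = 5.7%.
#'
#' @param n_positions distinct PHP positions in the region.
#' @param region a `mito_region`.
#' @param digits decimals (reports use one).
#' @export
region_php_percentage <- function(n_positions, region, digits = 1L) {
  round(100 * n_positions / region_length(region), digits)
}
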