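# Sample-level metrics, QC categorisation (passing / incomplete / mixed /
# related), shared-haplotype detection and relatedness exclusion.

#' Sample-level metrics
#'
#' Average read depth is the mean qualified depth over all reference
#' positions.  The percentage of mapped reads that are mtDNA can only be
#' computed when the nuclear mapping total is supplied as metadata
#' (shotgun WGS pipelines report it upstream); it is `NA` otherwise.
#'
#' @param workflow a `consensus_result` (or final `mito_mapping`).
#' @param profiles a [pileup_profiles()] of the final mapping.
#' @param hap the sample's `mito_haplotype` (for below-threshold counts).
#' @param total_reads,mapped_reads optional WGS-level metadata.
#' @return One-row data.frame of metrics.
#' @export
compute_metrics <- function(workflow, profiles, hap = NULL,
                            total_reads = NA_real_,
                            mapped_reads = NA_real_) {
  final <- if (inherits(workflow, "consensus_result")) workflow$final
           else workflow
  n_mt <- unname(final$stats[["accepted"]])
  data.frame(
    total_reads = total_reads,
    pct_mapped = if (!is.na(total_reads) && !is.na(mapped_reads)) {
      100 * mapped_reads / total_reads
    } else NA_real_,
    pct_mtdna = if (!is.na(mapped_reads)) 100 * n_mt / mapped_reads
                else NA_real_,
    mtdna_reads = n_mt,
    avg_depth = mean(profiles$depth),
    min_depth = min(profiles$depth),
    below_100x = if (!is.null(hap)) length(hap$below_threshold)
                 else sum(profiles$depth < 100L),
    stringsAsFactors = FALSE)
}

#' Mixture flag from residual heteroplasmy load
#'
#' With NUMT-labeled positions removed, a single-source mitogenome is
#' expected to carry few PHPs; a residual count of five or more, or any
#' multi-allelic position, flags the sample as a possible mixture (a
#' passing single-source sample may legitimately carry four).
#'
#' @param residual_php_count PHP-labeled mixed positions in the sample.
#' @param multiallelic_count positions with three alleles above threshold.
#' @param max_php largest residual PHP count not flagged.
#' @export
mixture_flag <- function(residual_php_count, multiallelic_count = 0L,
                         max_php = 4L) {
  residual_php_count > max_php | multiallelic_count > 0L
}

#' Categorise a sample
#'
#' Coverage: 0 positions below the depth threshold is complete, 1-4 nearly
#' complete, 5 or more incomplete.  A mixture flag overrides to `mixed`;
#' relatedness (`related = TRUE`, resolved at dataset level by
#' [exclude_related()]) overrides everything.
#'
#' @param below_count positions below the 100X threshold.
#' @param mixture logical from [mixture_flag()].
#' @param related logical.
#' @param nearly_complete_max_below boundary (default 4).
#' @return One of `passing_complete`, `passing_nearly_complete`,
#'   `incomplete`, `mixed`, `related`.
#' @export
categorize <- function(below_count, mixture = FALSE, related = FALSE,
                       nearly_complete_max_below = 4L) {
  if (related) return("related")
  if (mixture) return("mixed")
  if (below_count == 0L) "passing_complete"
  else if (below_count <= nearly_complete_max_below) {
    "passing_nearly_complete"
  } else "incomplete"
}

haplotype_comparison_sets <- function(haps) {
  lapply(haps, function(h) {
    subs <- h$calls[h$calls$kind == "sub", , drop = FALSE]
    list(subs = paste0(subs$ref, subs$pos, subs$alt),
         sub_pos = subs$pos, mixed_pos = h$mixed$pos)
  })
}

#' Find shared haplotypes (ignoring indels and heteroplasmy)
#'
#' Two haplotypes match when their substitution-only call sets are
#' identical after removing, on both sides, every position that is mixed
#' (IUPAC-coded) in either haplotype.  Matching is symmetric and
#' reflexive.
#'
#' @param haps named list of `mito_haplotype` objects.
#' @return data.frame of matching pairs (`sample_a`, `sample_b`).
#' @export
shared_haplotypes <- function(haps) {
  ids <- names(haps) %||% vapply(haps, `[[`, character(1), "sample_id")
  sets <- haplotype_comparison_sets(haps)
  out <- data.frame(sample_a = character(), sample_b = character(),
                    stringsAsFactors = FALSE)
  n <- length(haps)
  if (n < 2L) return(out)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      excl <- union(sets[[i]]$mixed_pos, sets[[j]]$mixed_pos)
      a <- sets[[i]]$subs[!sets[[i]]$sub_pos %in% excl]
      b <- sets[[j]]$subs[!sets[[j]]$sub_pos %in% excl]
      if (setequal(a, b)) {
        out <- rbind(out, data.frame(sample_a = ids[i], sample_b = ids[j],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Read a kinship table
#' @param path TSV with columns `sample_a`, `sample_b`, `kinship`.
#' @export
read_kinship <- function(path) {
  k <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_a", "sample_b", "kinship") %in% names(k))) {
    stop("kinship TSV needs columns sample_a, sample_b, kinship")
  }
  if (any(k$kinship < 0 | k$kinship > 0.5)) {
    stop("kinship coefficients must lie in [0, 0.5]")
  }
  k
}

#' Exclude maternal relatives among shared-haplotype pairs
#'
#' For each matching pair with a kinship coefficient above `cutoff`
#' (default 0.0884, the conventional second-degree lower bound), the
#' member with the lower average read depth is dropped and tagged
#' `related`.  Pairs without kinship data are retained and reported for
#' manual follow-up.
#'
#' @param matches data.frame from [shared_haplotypes()].
#' @param kinship data.frame (`sample_a`, `sample_b`, `kinship`).
#' @param avg_depth named numeric vector of sample average depths.
#' @param cutoff kinship cutoff.
#' @return List: `excluded` (sample ids tagged related), `unresolved`
#'   (matching pairs lacking kinship data).
#' @export
exclude_related <- function(matches, kinship, avg_depth,
                            cutoff = 0.0884) {
  excluded <- character(0)
  unresolved <- matches[0, , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  kin <- setNames(kinship$kinship, key(kinship$sample_a,
                                       kinship$sample_b))
  for (i in seq_len(nrow(matches))) {
    a <- matches$sample_a[i]; b <- matches$sample_b[i]
    kc <- kin[key(a, b)]
    if (is.na(kc)) {
      unresolved <- rbind(unresolved, matches[i, , drop = FALSE])
    } else if (kc > cutoff) {
      drop <- if ((avg_depth[a] %||% 0) < (avg_depth[b] %||% 0)) a else b
      excluded <- union(excluded, drop)
    }
  }
  list(excluded = excluded, unresolved = unresolved)
}

#' Full QC categorisation of a dataset
#'
#' @param haps named list of `mito_haplotype`s.
#' @param metrics data.frame, one row per sample (same order), from
#'   [compute_metrics()].
#' @param records classification records from [classify_dataset()].
#' @param kinship optional kinship data.frame.
#' @param nearly_complete_max_below,max_php,kinship_cutoff rule knobs.
#' @return data.frame: sample, below_100x, residual_php, numt_variants,
#'   mixture, category.
#' @export
qc_dataset <- function(haps, metrics, records, kinship = NULL,
                       nearly_complete_max_below = 4L, max_php = 4L,
                       kinship_cutoff = 0.0884) {
  ids <- names(haps)
  php_count <- vapply(ids, function(s) {
    sum(records$sample == s & records$label == "PHP" & records$detected)
  }, integer(1))
  numt_count <- vapply(ids, function(s) {
    sum(records$sample == s & records$label == "NUMT" & records$detected)
  }, integer(1))
  # multi-allelic positions only count against a sample when the third
  # allele reaches the reporting threshold
  multi <- vapply(haps, function(h) {
    sum(h$multiallelic$third_freq >= h$detect_freq)
  }, integer(1))
  below <- vapply(haps, function(h) length(h$below_threshold), integer(1))
  mix <- mixture_flag(php_count, multi, max_php)

  related <- character(0)
  if (!is.null(kinship)) {
    matches <- shared_haplotypes(haps)
    depth <- setNames(metrics$avg_depth, ids)
    related <- exclude_related(matches, kinship, depth,
                               kinship_cutoff)$excluded
  }
  category <- vapply(seq_along(ids), function(i) {
    categorize(below[i], mix[i], ids[i] %in% related,
               nearly_complete_max_below)
  }, character(1))
  data.frame(sample = ids, below_100x = below, residual_php = php_count,
             numt_variants = numt_count, multiallelic = multi,
             mixture = mix, category = category,
             row.names = NULL, stringsAsFactors = FALSE)
}
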