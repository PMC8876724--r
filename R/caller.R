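# Per-position profiling, quality-filtered low-frequency variant detection,
# homopolymer indel handling and forensic-nomenclature haplotype emission.

#' Variant calling thresholds
#'
#' Defaults follow the low-frequency detection settings shown to produce
#' reliable mitogenome data: minimum 100X qualified depth, neighbourhood
#' quality filtering (radius 5 bp, minimum central and window-mean quality
#' 30), and a 5% minor nucleotide frequency for heteroplasmy detection
#' (2% and 10% are the companion review/elevated thresholds).
#'
#' @param min_depth minimum qualified read depth (X) for a call.
#' @param quality_radius neighbourhood radius (bp) of the quality filter.
#' @param min_quality minimum central and window-mean base quality.
#' @param detect_freq minor nucleotide frequency threshold (fraction).
#' @param nearly_complete_max_below max positions below `min_depth` for a
#'   sample to count as nearly complete.
#' @param confirm_min_depth,confirm_major_freq auto-confirmation rule for
#'   the 1-4 below-threshold positions of nearly complete samples.
#' @param php_expected_max biological expectation for PHPs per mitogenome.
#' @export
call_thresholds <- function(min_depth = 100L, quality_radius = 5L,
                            min_quality = 30L, detect_freq = 0.05,
                            nearly_complete_max_below = 4L,
                            confirm_min_depth = 20L,
                            confirm_major_freq = 0.90,
                            php_expected_max = 3L) {
  stopifnot(detect_freq > 0, detect_freq < 0.5, min_depth > 0)
  structure(list(min_depth = as.integer(min_depth),
                 quality_radius = as.integer(quality_radius),
                 min_quality = as.integer(min_quality),
                 detect_freq = detect_freq,
                 nearly_complete_max_below =
                   as.integer(nearly_complete_max_below),
                 confirm_min_depth = as.integer(confirm_min_depth),
                 confirm_major_freq = confirm_major_freq,
                 php_expected_max = as.integer(php_expected_max)),
            class = "call_thresholds")
}

#' Quality-filtered per-position profiles from a mapping
#'
#' Each aligned base is counted at exactly one reference position, and only
#' when its own quality and the mean quality of the +/- `quality_radius` bp
#' window on the read both reach `min_quality` (windows truncate at read
#' ends).  Deletions are tallied at the deleted positions and included in
#' the qualified depth; insertions are tallied at their anchor position.
#'
#' @param mapping an rCRS-anchored `mito_mapping`.
#' @param thresholds a [call_thresholds()].
#' @return `position_profiles`: list with `counts` (L x 5 matrix: A, C, G,
#'   T, del), `fwd` (forward-strand counts), `meanq` (mean quality per
#'   base), `ins` (insertion table), `depth` (qualified depth vector).
#' @export
pileup_profiles <- function(mapping, thresholds = call_thresholds()) {
  a <- mapping$alignments
  L <- mapping$L
  if (nrow(a) == 0L) {
    counts <- matrix(0L, L, 5,
                     dimnames = list(NULL, c("A", "C", "G", "T", "del")))
    return(structure(list(counts = counts, fwd = counts,
                          meanq = matrix(NA_real_, L, 4),
                          ins = data.frame(pos = integer(),
                                           inserted = character(),
                                           count = integer(),
                                           fwd = integer()),
                          depth = rep(0L, L), L = L),
                     class = "position_profiles"))
  }
  p <- cpp_pileup(a$pos, a$strand, a$cigar, a$seq, a$qual, L,
                  radius = thresholds$quality_radius,
                  minq = thresholds$min_quality)
  colnames(p$counts) <- colnames(p$fwd) <- c("A", "C", "G", "T", "del")
  meanq <- p$qualsum / pmax(p$counts[, 1:4], 1L)
  meanq[p$counts[, 1:4] == 0L] <- NA_real_
  structure(list(counts = p$counts, fwd = p$fwd, meanq = meanq,
                 ins = p$ins, depth = as.integer(rowSums(p$counts)),
                 L = L),
            class = "position_profiles")
}

#' @export
print.position_profiles <- function(x, ...) {
  cat(sprintf("<position_profiles> %d positions, mean depth %.1fX\n",
              x$L, mean(x$depth)))
  invisible(x)
}

#' Detect homoplasmic variants and mixed positions
#'
#' At every position with qualified depth >= `min_depth` the major base is
#' called; a second base at frequency >= `detect_freq` yields a mixed
#' position with its IUPAC code.  Positions below `min_depth` are flagged,
#' not called; positions with three bases above threshold are routed to QC
#' as multi-allelic rather than force-coded.  Frequencies use the
#' qualified depth (deletions included) as denominator.
#'
#' @param profiles a [pileup_profiles()] result.
#' @param reference the [mito_reference()].
#' @param thresholds a [call_thresholds()].
#' @return List: `mixed` (data.frame of mixed positions), `homoplasmic`
#'   (variant rows incl. indels), `below_threshold`, `multiallelic`.
#' @export
detect_variants <- function(profiles, reference,
                            thresholds = call_thresholds()) {
  L <- profiles$L
  counts <- profiles$counts
  depth <- profiles$depth
  refch <- strsplit(reference$seq, "")[[1]]
  callable <- depth >= thresholds$min_depth
  below <- which(!callable)

  bases <- c("A", "C", "G", "T")
  nuc <- counts[, 1:4, drop = FALSE]
  ord1 <- max.col(nuc, ties.method = "first")
  top1 <- nuc[cbind(1:L, ord1)]
  nuc2 <- nuc; nuc2[cbind(1:L, ord1)] <- -1L
  ord2 <- max.col(nuc2, ties.method = "first")
  top2 <- nuc[cbind(1:L, ord2)]
  nuc3 <- nuc2; nuc3[cbind(1:L, ord2)] <- -1L
  top3 <- nuc[cbind(1:L, max.col(nuc3, ties.method = "first"))]

  freq2 <- ifelse(depth > 0, top2 / depth, 0)
  freq3 <- ifelse(depth > 0, top3 / depth, 0)
  # exact 50/50 tie: keep the reference base as major when it is involved
  tie <- callable & top1 == top2 & top2 > 0
  swap <- tie & bases[ord2] == refch
  tmp <- ord1[swap]; ord1[swap] <- ord2[swap]; ord2[swap] <- tmp

  multi <- which(callable & freq3 >= thresholds$detect_freq)
  is_mixed <- callable & freq2 >= thresholds$detect_freq &
    !(seq_len(L) %in% multi)
  w <- which(is_mixed)
  mixed <- data.frame(
    pos = w, ref = refch[w], major = bases[ord1[w]], minor = bases[ord2[w]],
    minor_freq = freq2[w], depth = depth[w],
    iupac = if (length(w)) iupac_code(bases[ord1[w]], bases[ord2[w]])
            else character(0),
    classification = rep("unassigned", length(w)),
    stringsAsFactors = FALSE)

  # homoplasmic substitutions: callable, major differs from reference, not
  # mixed at this position
  subs <- which(callable & bases[ord1] != refch & !is_mixed &
                  !(seq_len(L) %in% multi))
  homop <- data.frame(pos = subs, kind = rep("sub", length(subs)),
                      ref = refch[subs], alt = bases[ord1[subs]],
                      ins_index = rep(NA_integer_, length(subs)),
                      stringsAsFactors = FALSE)
  # majority deletions
  dels <- which(callable & counts[, "del"] / pmax(depth, 1L) > 0.5)
  if (length(dels)) {
    homop <- rbind(homop, data.frame(
      pos = dels, kind = "del", ref = "", alt = "",
      ins_index = NA_integer_, stringsAsFactors = FALSE))
  }
  # majority insertions (count relative to the anchor's qualified depth)
  ins <- profiles$ins
  if (nrow(ins)) {
    keep <- ins$count / pmax(depth[ins$pos], 1L) > 0.5 & callable[ins$pos]
    ins <- ins[keep, , drop = FALSE]
    for (i in seq_len(nrow(ins))) {
      ib <- strsplit(ins$inserted[i], "")[[1]]
      homop <- rbind(homop, data.frame(
        pos = ins$pos[i], kind = "ins", ref = "", alt = ib,
        ins_index = seq_along(ib), stringsAsFactors = FALSE))
    }
  }
  homop <- homop[order(homop$pos, homop$ins_index), , drop = FALSE]
  rownames(homop) <- NULL
  list(mixed = mixed, homoplasmic = homop,
       below_threshold = below,
       multiallelic = data.frame(pos = multi, third_freq = freq3[multi]))
}

#' Shift indel calls 3' within homopolymer runs
#'
#' Every indel inside a homopolymer run is reported at the 3'-most
#' equivalent position: deletions at the run's last position, insertions
#' with decimal suffixes after it (forensic nomenclature).  Indels outside
#' runs (run length < 2) are unchanged.
#'
#' @param calls variant data.frame (as from [detect_variants()]).
#' @param reference the [mito_reference()].
#' @export
shift_indels_3prime <- function(calls, reference) {
  if (nrow(calls) == 0L) return(calls)
  for (i in which(calls$kind == "del")) {
    run <- homopolymer_run(reference, calls$pos[i])
    if (region_length(run) >= 2L) calls$pos[i] <- run$end
  }
  insrows <- which(calls$kind == "ins")
  for (i in insrows) {
    p <- calls$pos[i]
    b <- calls$alt[i]
    # find the run of the inserted base adjacent to the anchor
    anchor_run <- NULL
    if (base_at(reference, p) == b) {
      anchor_run <- homopolymer_run(reference, p)
    } else {
      nxt <- p %% reference$length + 1L
      if (base_at(reference, nxt) == b) {
        anchor_run <- homopolymer_run(reference, nxt)
      }
    }
    if (!is.null(anchor_run) && region_length(anchor_run) >= 2L) {
      calls$pos[i] <- anchor_run$end
    }
  }
  # renumber insertion suffixes per anchor
  if (length(insrows)) {
    for (p in unique(calls$pos[insrows])) {
      at <- which(calls$kind == "ins" & calls$pos == p)
      calls$ins_index[at] <- seq_along(at)
    }
  }
  calls <- calls[order(calls$pos, calls$ins_index), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Resolve length heteroplasmy in configured homopolymer regions
#'
#' Within each configured C-stretch region, reads fully spanning the region
#' vote on the molecule length; only the most frequent length variant is
#' reported (minor length variants are dropped; a 50/50 tie reports the
#' shorter molecule).  Point substitutions inside the run are unaffected.
#'
#' @param mapping the final `mito_mapping`.
#' @param reference the [mito_reference()].
#' @param regions list of `mito_region` C-stretch regions.
#' @return data.frame of indel variant rows describing the major molecule
#'   (empty when the major length equals the reference), with attribute
#'   `lhp` summarising the per-region length tables.
#' @export
resolve_length_heteroplasmy <- function(mapping, reference,
                                        regions = mito_regions()[
                                          c("HVS2_cstretch",
                                            "HVS1_cstretch")]) {
  a <- mapping$alignments
  out <- data.frame(pos = integer(), kind = character(), ref = character(),
                    alt = character(), ins_index = integer(),
                    stringsAsFactors = FALSE)
  lhp <- list()
  for (nm in names(regions)) {
    r <- regions[[nm]]
    reflen <- region_length(r)
    lens <- cpp_region_read_lengths(a$pos, a$cigar, r$start, r$end,
                                    mapping$L)
    lens <- lens[!is.na(lens)]
    if (length(lens) == 0L) {
      warning("no reads span homopolymer region ", nm,
              "; region reported from alignment consensus")
      next
    }
    tab <- table(lens)
    best <- max(tab)
    major <- min(as.integer(names(tab)[tab == best]))  # tie -> shorter
    lhp[[nm]] <- list(table = tab, major_length = major,
                      ref_length = reflen)
    delta <- major - reflen
    if (delta > 0) {
      b <- base_at(reference, r$end)
      out <- rbind(out, data.frame(
        pos = r$end, kind = "ins", ref = "", alt = rep(b, delta),
        ins_index = seq_len(delta), stringsAsFactors = FALSE))
    } else if (delta < 0) {
      out <- rbind(out, data.frame(
        pos = seq(r$end, by = -1L, length.out = -delta), kind = "del",
        ref = "", alt = "", ins_index = NA_integer_,
        stringsAsFactors = FALSE))
    }
  }
  attr(out, "lhp") <- lhp
  out
}

#' Remove A-stretch artifact heteroplasmies
#'
#' Low-level heteroplasmy in the polyadenine stretches immediately 5' of
#' the HVS1/HVS2 C-stretches (nps 16,180-16,183 and 300-302) is a
#' recurrent post-homopolymer sequencing artifact; mixed positions there
#' are removed from the haplotype and tagged `artifact`.
#'
#' @param mixed mixed-position data.frame.
#' @param zones list of `mito_region` artifact zones.
#' @return List: `kept` and `artifacts`.
#' @export
filter_astretch_artifacts <- function(mixed,
                                      zones = mito_regions()[
                                        c("HVS2_astretch",
                                          "HVS1_astretch")]) {
  if (nrow(mixed) == 0L) return(list(kept = mixed, artifacts = mixed))
  hit <- Reduce(`|`, lapply(zones, region_contains, pos = mixed$pos))
  artifacts <- mixed[hit, , drop = FALSE]
  if (nrow(artifacts)) artifacts$classification <- "artifact"
  list(kept = mixed[!hit, , drop = FALSE], artifacts = artifacts)
}

#' Forward/reverse strand share of a minor allele
#'
#' @param profiles a [pileup_profiles()] result.
#' @param pos position; `base` the minor base.
#' @return Share of the minor observations on the rarer strand (NaN when
#'   the minor allele was never counted).
#' @export
strand_minor_share <- function(profiles, pos, base) {
  tot <- profiles$counts[pos, base]
  fw <- profiles$fwd[pos, base]
  pmin(fw, tot - fw) / tot
}

#' Call a sample haplotype from its final mapping
#'
#' Runs the profile/detection/filter chain: pileup with quality filtering,
#' variant and mixed-position detection, A-stretch artifact removal, length
#' heteroplasmy resolution in the configured C-stretch regions, 3' indel
#' shifting, and assembly into a forensic-nomenclature haplotype.  Below-
#' threshold positions are excluded from the reported range unless the
#' sample is nearly complete (<= `nearly_complete_max_below` positions
#' below), in which case positions with depth >= `confirm_min_depth` and
#' major frequency >= `confirm_major_freq` are auto-confirmed.
#'
#' @param mapping rCRS-anchored final `mito_mapping`.
#' @param reference the [mito_reference()].
#' @param thresholds a [call_thresholds()].
#' @param sample_id sample label.
#' @param lhp_regions configured homopolymer (C-stretch) regions.
#' @return A `mito_haplotype` object.
#' @export
call_sample <- function(mapping, reference,
                        thresholds = call_thresholds(),
                        sample_id = "sample",
                        lhp_regions = mito_regions()[c("HVS2_cstretch",
                                                       "HVS1_cstretch")]) {
  profiles <- pileup_profiles(mapping, thresholds)
  det <- detect_variants(profiles, reference, thresholds)
  ast <- filter_astretch_artifacts(det$mixed)
  mixed <- ast$kept

  lhp_calls <- resolve_length_heteroplasmy(mapping, reference, lhp_regions)
  # indels inside configured LHP regions are owned by the LHP resolution
  in_lhp <- function(pos) {
    if (length(pos) == 0L) return(logical(0))
    nxt <- pos %% reference$length + 1L  # insertion anchors may sit 1 bp 5'
    hit <- lapply(lhp_regions, function(r) {
      region_contains(r, pos) | region_contains(r, nxt)
    })
    Reduce(`|`, hit)
  }
  homo <- det$homoplasmic
  drop <- homo$kind != "sub" & in_lhp(homo$pos)
  homo <- homo[!drop, , drop = FALSE]
  calls <- rbind(homo, lhp_calls)
  calls <- shift_indels_3prime(calls, reference)

  # below-threshold handling
  below <- det$below_threshold
  confirmed <- integer(0)
  if (length(below) > 0 &&
      length(below) <= thresholds$nearly_complete_max_below) {
    dep <- profiles$depth[below]
    nuc <- profiles$counts[below, 1:4, drop = FALSE]
    majfreq <- apply(nuc, 1, max) / pmax(dep, 1L)
    confirmed <- below[dep >= thresholds$confirm_min_depth &
                         majfreq >= thresholds$confirm_major_freq]
  }

  structure(list(sample_id = sample_id, calls = calls, mixed = mixed,
                 artifacts = ast$artifacts,
                 multiallelic = det$multiallelic,
                 below_threshold = below, confirmed = confirmed,
                 profiles = profiles,
                 detect_freq = thresholds$detect_freq,
                 lhp = attr(lhp_calls, "lhp")),
            class = "mito_haplotype")
}

#' Mixed positions of a haplotype at a given threshold
#' @param hap a `mito_haplotype` (called at its base threshold).
#' @param detect_freq reporting threshold; must be >= the call threshold.
#' @export
mixed_at_threshold <- function(hap, detect_freq) {
  hap$mixed[hap$mixed$minor_freq >= detect_freq, , drop = FALSE]
}

#' Variant token of a mixed position's minor allele
#'
#' `A13062G` when the minor differs from the reference; the bare reference
#' form (`A263`) when the minor equals the reference base.
#' @param ref,pos,minor reference base, position, minor base.
#' @export
mixed_variant_name <- function(ref, pos, minor) {
  ifelse(minor == ref, paste0(ref, pos), paste0(ref, pos, minor))
}

#' Render a haplotype as ordered forensic-nomenclature tokens
#'
#' Space-separated variants relative to the reference, ordered by position:
#' substitutions as `A263G`, insertions as `315.1C`, deletions as `315del`,
#' mixed positions with IUPAC codes (`T16093Y`).
#'
#' Mixed positions classified as NUMT variants or artifacts are pruned:
#' only probable PHPs (and still-unclassified positions) are maintained in
#' the reported haplotype.
#'
#' @param hap a `mito_haplotype`.
#' @param detect_freq threshold at which mixed positions are included
#'   (defaults to the haplotype's call threshold).
#' @return Single space-separated string (empty when rCRS-identical).
#' @export
haplotype_string <- function(hap, detect_freq = hap$detect_freq) {
  calls <- hap$calls
  mix <- mixed_at_threshold(hap, detect_freq)
  mix <- mix[!mix$classification %in% c("NUMT", "artifact"), ,
             drop = FALSE]
  tok <- data.frame(pos = numeric(0), token = character(0))
  if (nrow(calls)) {
    tok <- data.frame(
      pos = calls$pos + ifelse(is.na(calls$ins_index), 0,
                               calls$ins_index / 100),
      token = format_variants(calls), stringsAsFactors = FALSE)
  }
  if (nrow(mix)) {
    tok <- rbind(tok, data.frame(
      pos = mix$pos, token = paste0(mix$ref, mix$pos, mix$iupac),
      stringsAsFactors = FALSE))
  }
  tok <- tok[order(tok$pos), , drop = FALSE]
  paste(tok$token, collapse = " ")
}

#' @export
print.mito_haplotype <- function(x, ...) {
  cat(sprintf("<mito_haplotype> %s: %s\n", x$sample_id,
              haplotype_string(x)))
  if (length(x$below_threshold)) {
    cat(sprintf("  %d position(s) below depth threshold (%d confirmed)\n",
                length(x$below_threshold), length(x$confirmed)))
  }
  invisible(x)
}

#' Export a variant table for a haplotype
#' @param hap a `mito_haplotype`.
#' @return data.frame: position, ref, major, minor, minor_freq, depth,
#'   call, classification.
#' @export
variant_table <- function(hap) {
  mix <- hap$mixed
  h <- hap$calls
  rbind(
    if (nrow(h)) data.frame(
      pos = h$pos, ref = h$ref, major = h$alt, minor = "",
      minor_freq = NA_real_,
      depth = hap$profiles$depth[h$pos],
      call = format_variants(h), classification = "homoplasmic",
      stringsAsFactors = FALSE),
    if (nrow(mix)) data.frame(
      pos = mix$pos, ref = mix$ref, major = mix$major, minor = mix$minor,
      minor_freq = mix$minor_freq, depth = mix$depth,
      call = paste0(mix$ref, mix$pos, mix$iupac),
      classification = mix$classification, stringsAsFactors = FALSE)
  )
}
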