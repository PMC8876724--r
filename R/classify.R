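# Deterministic two-stage review classifying mixed positions as NUMT
# variants or probable point heteroplasmies (PHPs).  The initial review
# uses clustering, the NUMT variant catalog and read-level phasing; the
# secondary review applies the frequency/depth entry gate (<10% minor
# frequency and <=1500X average depth) and a configurable vote over the
# remaining evidence, with known PHP hotspots acting as a veto.

#' Known-NUMT variant catalog
#'
#' Built-in entries are the variants repeatedly documented as NUMT-derived
#' in shotgun WGS mitogenome data (the two signature clusters around nps
#' 12,612-13,105 and 16,390-16,527 plus recurrent singletons).  A
#' user-supplied TSV (columns `pos`, `alt`, optional `source`) such as a
#' large published NUMT-variant catalog replaces or extends the built-ins.
#'
#' @param path optional TSV path; `NULL` for the built-ins only.
#' @param include_builtin prepend the built-in entries.
#' @return data.frame with `pos`, `alt`, `source`.
#' @export
numt_catalog <- function(path = NULL, include_builtin = TRUE) {
  builtin_tokens <- c("A13062G", "G12684A", "T13095C", "C12705T",
                      "A13105G", "C16444T", "C16527T", "G16496A",
                      "G16390A", "A16399G", "G16129A", "T16519C")
  v <- parse_variants(builtin_tokens)
  builtin <- data.frame(pos = v$pos, alt = v$alt, source = "builtin",
                        stringsAsFactors = FALSE)
  out <- if (include_builtin) builtin else builtin[0, ]
  if (!is.null(path)) {
    u <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("pos", "alt") %in% names(u))) {
      stop("catalog TSV needs columns pos, alt")
    }
    if (is.null(u$source)) u$source <- "user"
    out <- rbind(out, u[, c("pos", "alt", "source")])
  }
  if (any(out$pos < 1L | out$pos > MT_LENGTH)) {
    stop("catalog positions must lie in 1..", MT_LENGTH)
  }
  out[!duplicated(out[c("pos", "alt")]), , drop = FALSE]
}

#' Known point-heteroplasmy hotspots
#'
#' Default: the recurrently heteroplasmic positions nps 146, 152, 204,
#' 16,093 and 16,192.  A TSV with column `pos` replaces the default.
#'
#' @param path optional TSV path.
#' @export
php_hotspots <- function(path = NULL) {
  if (is.null(path)) return(c(146L, 152L, 204L, 16093L, 16192L))
  u <- read.delim(path, stringsAsFactors = FALSE)
  as.integer(u$pos)
}

#' Review criteria for NUMT classification
#'
#' @param secondary_max_freq entry gate: only mixed positions with minor
#'   frequency below this enter the secondary review (others default PHP).
#' @param secondary_max_depth entry gate on the sample average read depth.
#' @param hotspot_region_1,hotspot_region_2 documented NUMT signature
#'   regions.
#' @param low_band frequency band of sub-threshold supporting variants.
#' @param cluster_window bp window for clustering mixed positions.
#' @param recurrence_min NUMT labels in this many other samples make a
#'   variant "recurrent".
#' @param votes_required NUMT votes needed in the secondary review.
#' @param phase_min_pairs minimum fragments covering both positions for a
#'   phasing call; `phase_min_concordance` the in-phase fraction required.
#' @param strand_min_share minimum share of minor observations on the rarer
#'   strand; below it the position is tagged a strand-bias artifact.
#' @param ignore_16093 treat np 16,093 as uninterpretable (drop it from
#'   classification output entirely).
#' @export
review_criteria <- function(secondary_max_freq = 0.10,
                            secondary_max_depth = 1500,
                            hotspot_region_1 = mito_region(12612L, 13105L),
                            hotspot_region_2 = mito_region(16390L, 16527L),
                            low_band = c(0.02, 0.05),
                            cluster_window = 500L,
                            recurrence_min = 3L,
                            votes_required = 2L,
                            phase_min_pairs = 5L,
                            phase_min_concordance = 0.9,
                            strand_min_share = 0.10,
                            ignore_16093 = FALSE) {
  structure(list(secondary_max_freq = secondary_max_freq,
                 secondary_max_depth = secondary_max_depth,
                 hotspot_regions = list(hotspot_region_1,
                                        hotspot_region_2),
                 low_band = low_band,
                 cluster_window = as.integer(cluster_window),
                 recurrence_min = as.integer(recurrence_min),
                 votes_required = as.integer(votes_required),
                 phase_min_pairs = as.integer(phase_min_pairs),
                 phase_min_concordance = phase_min_concordance,
                 strand_min_share = strand_min_share,
                 ignore_16093 = isTRUE(ignore_16093)),
            class = "review_criteria")
}

#' Cluster mixed positions along the circular genome
#'
#' Maximal groups in which consecutive members (in circular order) are at
#' most `window` bp apart; the gap across the origin counts.  Invariant to
#' input order.
#'
#' @param positions integer positions.
#' @param window bp.
#' @param L genome length.
#' @return List of integer vectors (ascending within each cluster).
#' @export
detect_clusters <- function(positions, window = 500L, L = MT_LENGTH) {
  positions <- sort(unique(as.integer(positions)))
  n <- length(positions)
  if (n == 0L) return(list())
  if (n == 1L) return(list(positions))
  gaps <- diff(positions)
  wrap_gap <- positions[1] + L - positions[n]
  breaks <- which(gaps > window)
  if (length(breaks) == 0L) return(list(positions))
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  clusters <- Map(function(s, e) positions[s:e], starts, ends)
  if (wrap_gap <= window && length(clusters) > 1L) {
    # last cluster wraps onto the first
    clusters[[1]] <- c(clusters[[length(clusters)]], clusters[[1]])
    clusters[[length(clusters)]] <- NULL
  }
  unname(clusters)
}

#' Per-fragment bases at a set of positions
#'
#' Combines the two mates of each read pair into one observation per
#' fragment; `""` when the fragment does not cover the position.
#'
#' @param mapping a `mito_mapping`.
#' @param positions integer positions.
#' @return Character matrix, fragments x positions.
#' @export
fragment_bases <- function(mapping, positions) {
  a <- mapping$alignments
  positions <- as.integer(positions)
  if (nrow(a) == 0L || length(positions) == 0L) {
    return(matrix(character(0), 0, length(positions)))
  }
  bm <- cpp_bases_at(a$pos, a$cigar, a$seq, positions, mapping$L)
  uid <- unique(a$id)
  idx <- match(a$id, uid)
  out <- matrix("", length(uid), length(positions))
  for (j in seq_along(positions)) {
    has <- which(bm[, j] != "")
    first <- has[!duplicated(idx[has])]   # mate 1 observation wins
    out[idx[first], j] <- bm[first, j]
  }
  rownames(out) <- uid
  out
}

phase_from_bases <- function(fb, i, j, minorA, minorB, criteria) {
  both <- fb[, i] != "" & fb[, j] != ""
  if (sum(both) < criteria$phase_min_pairs) return("unassessable")
  mA <- fb[both, i] == minorA
  mB <- fb[both, j] == minorB
  minor_bearing <- sum(mA | mB)
  if (minor_bearing == 0L) return("unassessable")
  conc <- sum(mA & mB) / minor_bearing
  if (conc >= criteria$phase_min_concordance) "in_phase" else "discordant"
}

#' Phase two mixed positions from the read mapping
#'
#' Over fragments (read pairs) covering both positions: `in_phase` when at
#' least `phase_min_concordance` of the minor-bearing fragments carry both
#' minor alleles; `unassessable` with fewer than `phase_min_pairs` covering
#' fragments (or none carrying a minor allele); otherwise `discordant`.
#'
#' @param mapping the final `mito_mapping`.
#' @param posA,posB positions; `minorA`, `minorB` their minor bases.
#' @param criteria a [review_criteria()].
#' @export
phase_check <- function(mapping, posA, posB, minorA, minorB,
                        criteria = review_criteria()) {
  fb <- fragment_bases(mapping, c(posA, posB))
  if (nrow(fb) == 0L) return("unassessable")
  phase_from_bases(fb, 1L, 2L, minorA, minorB, criteria)
}

in_any_region <- function(regions, pos) {
  if (length(pos) == 0L) return(logical(0))
  Reduce(`|`, lapply(regions, region_contains, pos = pos))
}

#' Initial review of a sample's mixed positions
#'
#' Works on the sample's 2%-threshold call universe (the >= 5% reported
#' set plus the 2-5% supporting band).  A position is provisionally NUMT
#' when (a) it lies in a documented NUMT signature region and is in-phase
#' with another universe member of that region, (b) it is in-phase with a
#' catalog entry, or (c) it belongs to a cluster (>= 2 members) where at
#' least half the members are catalog entries or signature-region members.
#' Minor alleles with extreme strand imbalance are tagged `artifact` first.
#'
#' The cluster rule only labels members that are themselves signature-
#' region or catalog members, and never a known PHP hotspot position --
#' hotspots require direct phase evidence (rules a/b) to be called NUMT.
#'
#' @param sample list with `id`, `mixed` (2%-universe mixed data.frame),
#'   `mapping` (final mapping), `profiles`, `avg_depth`.
#' @param criteria a [review_criteria()].
#' @param catalog a [numt_catalog()].
#' @param hotspots integer vector from [php_hotspots()].
#' @return The mixed data.frame with `label` (`NUMT` / `artifact` /
#'   `unassigned`) and `rules` columns.
#' @export
initial_review <- function(sample, criteria = review_criteria(),
                           catalog = numt_catalog(),
                           hotspots = php_hotspots()) {
  univ <- sample$mixed
  univ$label <- rep("unassigned", nrow(univ))
  univ$rules <- rep("", nrow(univ))
  if (nrow(univ) == 0L) return(univ)

  # strand balance artifact tagging
  if (!is.null(sample$profiles)) {
    share <- mapply(strand_minor_share, pos = univ$pos, base = univ$minor,
                    MoreArgs = list(profiles = sample$profiles))
    bad <- !is.na(share) & share < criteria$strand_min_share
    univ$label[bad] <- "artifact"
    univ$rules[bad] <- "strand_bias"
  }

  in_cat <- paste(univ$pos, univ$minor) %in%
    paste(catalog$pos, catalog$alt)
  # region id per position (the two signature regions are disjoint)
  reg_id <- rep(NA_integer_, nrow(univ))
  for (k in seq_along(criteria$hotspot_regions)) {
    reg_id[region_contains(criteria$hotspot_regions[[k]], univ$pos)] <- k
  }
  in_hs <- !is.na(reg_id)
  clusters <- detect_clusters(univ$pos, criteria$cluster_window)
  fb <- fragment_bases(sample$mapping, univ$pos)

  for (i in seq_len(nrow(univ))) {
    if (univ$label[i] != "unassigned") next
    fired <- character(0)
    # (a) signature-region membership + in-phase partner in the region
    if (in_hs[i]) {
      same_region <- which(seq_len(nrow(univ)) != i & reg_id == reg_id[i])
      for (j in same_region) {
        if (phase_from_bases(fb, i, j, univ$minor[i], univ$minor[j],
                             criteria) == "in_phase") {
          fired <- c(fired, "region_phase")
          break
        }
      }
    }
    # (b) in-phase with a catalog entry
    cat_partners <- which(seq_len(nrow(univ)) != i & in_cat)
    for (j in cat_partners) {
      if (phase_from_bases(fb, i, j, univ$minor[i], univ$minor[j],
                           criteria) == "in_phase") {
        fired <- c(fired, "catalog_phase")
        break
      }
    }
    # (c) cluster with >= half catalog/signature-region members; only
    # labels members with their own catalog/region support, and never a
    # PHP hotspot position
    if ((in_cat[i] || in_hs[i]) && !univ$pos[i] %in% hotspots) {
      cl <- clusters[vapply(clusters, function(c) univ$pos[i] %in% c,
                            logical(1))][[1]]
      if (length(cl) >= 2L) {
        members <- match(cl, univ$pos)
        supp <- in_cat[members] | in_hs[members]
        if (sum(supp) >= length(cl) / 2) fired <- c(fired, "cluster")
      }
    }
    if (length(fired)) {
      univ$label[i] <- "NUMT"
      univ$rules[i] <- paste(fired, collapse = ",")
    }
  }
  univ
}

#' Secondary review of positions left unlabeled by the initial review
#'
#' Entry gate: only positions with minor frequency below
#' `secondary_max_freq` in samples with average depth at most
#' `secondary_max_depth` are reviewed; positions failing the gate default
#' to PHP.  Known PHP hotspots are vetoed to PHP.  Within the review a
#' position is NUMT when at least `votes_required` of these concur:
#' catalog membership; the same variant NUMT-labeled in >=
#' `recurrence_min` other samples; an in-phase 2-5%-band partner; not a
#' PHP hotspot.
#'
#' @param sample as in [initial_review()]; `mixed` must carry the initial
#'   `label`/`rules` columns.
#' @param recurrence named integer vector: NUMT-label counts per variant
#'   token across the other samples of the dataset.
#' @param criteria a [review_criteria()].
#' @param catalog a [numt_catalog()].
#' @param hotspots integer vector from [php_hotspots()].
#' @export
secondary_review <- function(sample, recurrence = integer(0),
                             criteria = review_criteria(),
                             catalog = numt_catalog(),
                             hotspots = php_hotspots()) {
  univ <- sample$mixed
  if (nrow(univ) == 0L) return(univ)
  fb <- fragment_bases(sample$mapping, univ$pos)
  in_cat <- paste(univ$pos, univ$minor) %in%
    paste(catalog$pos, catalog$alt)
  low_band <- univ$minor_freq >= criteria$low_band[1] &
    univ$minor_freq < criteria$low_band[2]
  vn <- mixed_variant_name(univ$ref, univ$pos, univ$minor)

  for (i in which(univ$label == "unassigned")) {
    gate <- univ$minor_freq[i] < criteria$secondary_max_freq &&
      sample$avg_depth <= criteria$secondary_max_depth
    if (!gate) {
      univ$label[i] <- "PHP"
      univ$rules[i] <- "gate_fail"
      next
    }
    if (univ$pos[i] %in% hotspots) {
      univ$label[i] <- "PHP"
      univ$rules[i] <- "php_hotspot"
      next
    }
    votes <- character(0)
    if (in_cat[i]) votes <- c(votes, "catalog")
    if ((recurrence[vn[i]] %||% 0L) >= criteria$recurrence_min) {
      votes <- c(votes, "recurrent")
    }
    partners <- which(seq_len(nrow(univ)) != i & low_band)
    for (j in partners) {
      if (phase_from_bases(fb, i, j, univ$minor[i], univ$minor[j],
                           criteria) == "in_phase") {
        votes <- c(votes, "low_band_phase")
        break
      }
    }
    votes <- c(votes, "not_hotspot")  # hotspots were vetoed above
    if (length(votes) >= criteria$votes_required) {
      univ$label[i] <- "NUMT"
      univ$rules[i] <- paste(votes, collapse = ",")
    } else {
      univ$label[i] <- "PHP"
      univ$rules[i] <- "default"
    }
  }
  univ
}

#' Classify every mixed position of a dataset
#'
#' Runs the initial review per sample, compiles dataset-wide recurrence of
#' provisional NUMT labels, then the secondary review.  The classification
#' universe is each sample's 2%-threshold call set; per-threshold views are
#' obtained by filtering minor frequency (thresholds nest by
#' construction).
#'
#' @param samples list of sample lists (`id`, `mixed`, `mapping`,
#'   `profiles`, `avg_depth`).
#' @param criteria a [review_criteria()].
#' @param catalog a [numt_catalog()].
#' @param hotspots integer vector from [php_hotspots()].
#' @param detect_freq reporting threshold defining which universe members
#'   are reported mixed positions.
#' @return data.frame of `classification_record`s: sample, pos, ref,
#'   major, minor, minor_freq, depth, variant, label, rules,
#'   detected (logical, >= `detect_freq`).
#' @export
classify_dataset <- function(samples, criteria = review_criteria(),
                             catalog = numt_catalog(),
                             hotspots = php_hotspots(),
                             detect_freq = 0.05) {
  reviewed <- lapply(samples, function(s) {
    s$mixed <- initial_review(s, criteria, catalog, hotspots)
    s
  })
  # recurrence of provisional NUMT variants across samples
  all_init <- do.call(rbind, lapply(reviewed, function(s) {
    m <- s$mixed
    if (nrow(m) == 0L) return(NULL)
    data.frame(sample = s$id,
               variant = mixed_variant_name(m$ref, m$pos, m$minor),
               label = m$label, stringsAsFactors = FALSE)
  }))
  recurrence <- if (!is.null(all_init)) {
    tab <- table(all_init$variant[all_init$label == "NUMT"])
    setNames(as.integer(tab), names(tab))
  } else integer(0)

  out <- lapply(reviewed, function(s) {
    rec <- recurrence
    if (nrow(s$mixed) > 0L) {
      own <- mixed_variant_name(s$mixed$ref, s$mixed$pos, s$mixed$minor)
      own_numt <- own[s$mixed$label == "NUMT"]
      for (v in own_numt) rec[v] <- max(0L, (rec[v] %||% 0L) - 1L)
    }
    m <- secondary_review(s, rec, criteria, catalog, hotspots)
    if (nrow(m) == 0L) return(NULL)
    data.frame(sample = s$id, pos = m$pos, ref = m$ref, major = m$major,
               minor = m$minor, minor_freq = m$minor_freq,
               depth = m$depth,
               variant = mixed_variant_name(m$ref, m$pos, m$minor),
               label = m$label, rules = m$rules,
               detected = m$minor_freq >= detect_freq,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, out)
  if (is.null(records)) {
    records <- data.frame(sample = character(), pos = integer(),
                          ref = character(), major = character(),
                          minor = character(), minor_freq = numeric(),
                          depth = integer(), variant = character(),
                          label = character(), rules = character(),
                          detected = logical(), stringsAsFactors = FALSE)
  }
  if (criteria$ignore_16093) {
    records <- records[records$pos != 16093L, , drop = FALSE]
  }
  rownames(records) <- NULL
  records
}
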