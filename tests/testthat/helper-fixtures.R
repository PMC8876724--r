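# Shared fixtures, memoised so expensive simulations run once per suite.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fx_ref <- function() fixture("ref", function() mito_reference())

# clean single-source sample: no donors, no PHPs, no sequencing error
fx_clean <- function() {
  fixture("clean", function() {
    ref <- fx_ref()
    spec <- truth_spec(
      base_haplotype = c("A73G", "T152C", "A263G", "C295T"),
      target_depth = 200, error_rate = 0, post_homopolymer_boost = 1,
      seed = 11L)
    sim <- simulate_sample(spec, ref)
    wf <- consensus_workflow(sim$reads, ref)
    hap <- call_sample(wf$final, ref, call_thresholds(detect_freq = 0.02),
                       "clean")
    list(spec = spec, sim = sim, wf = wf, hap = hap)
  })
}

# sample carrying both documented NUMT signature donors at 8% plus a 20%
# PHP at the 16093 hotspot
fx_donor <- function() {
  fixture("donor", function() {
    ref <- fx_ref()
    spec <- truth_spec(
      base_haplotype = "A263G",
      phps = data.frame(pos = 16093L, minor = "C", fraction = 0.20,
                        stringsAsFactors = FALSE),
      donors = list(build_numt_donor("ND5_sig", 0.08),
                    build_numt_donor("HVS1_sig", 0.08)),
      target_depth = 300, seed = 42L)
    sim <- simulate_sample(spec, ref)
    wf <- consensus_workflow(sim$reads, ref)
    hap <- call_sample(wf$final, ref, call_thresholds(detect_freq = 0.02),
                       "donor")
    smp <- list(id = "donor", mixed = hap$mixed, mapping = wf$final,
                profiles = hap$profiles,
                avg_depth = mean(hap$profiles$depth))
    list(spec = spec, sim = sim, wf = wf, hap = hap, sample = smp,
         records = classify_dataset(list(donor = smp)))
  })
}

# fabricate a mapping from explicit alignment rows (ungapped, forward)
make_mapping <- function(rows, L = 16569L, ref_name = "rCRS_synthetic") {
  if (is.null(rows) || nrow(rows) == 0L) {
    rows <- data.frame(id = character(), mate = integer(), pos = integer(),
                       strand = character(), cigar = character(),
                       seq = character(), qual = character(),
                       stringsAsFactors = FALSE)
  }
  structure(list(ref_name = ref_name, L = L, alignments = rows,
                 stats = c(input = nrow(rows), accepted = nrow(rows),
                           rejected = 0L, ambiguous = 0L, unmapped = 0L)),
            class = "mito_mapping")
}

make_aln <- function(id, pos, seq, qual = strrep("I", nchar(seq)),
                     strand = "+", mate = 1L) {
  data.frame(id = id, mate = mate, pos = pos, strand = strand,
             cigar = paste0(nchar(seq), "M"), seq = seq, qual = qual,
             score = nchar(seq), length_fraction = 1,
             similarity_fraction = 1, accepted = TRUE,
             status = "accepted", stringsAsFactors = FALSE)
}

# fabricate position profiles with given base counts at given positions
make_profiles <- function(pos, counts_list, L = 16569L) {
  counts <- matrix(0L, L, 5,
                   dimnames = list(NULL, c("A", "C", "G", "T", "del")))
  for (i in seq_along(pos)) {
    counts[pos[i], names(counts_list[[i]])] <-
      as.integer(counts_list[[i]])
  }
  fwd <- counts
  fwd[] <- as.integer(ceiling(counts / 2))
  structure(list(counts = counts, fwd = fwd,
                 meanq = matrix(35, L, 4),
                 ins = data.frame(pos = integer(), inserted = character(),
                                  count = integer(), fwd = integer(),
                                  stringsAsFactors = FALSE),
                 depth = as.integer(rowSums(counts)), L = L),
            class = "position_profiles")
}

# fabricate a minimal haplotype object for QC-level tests
make_hap <- function(sample_id, subs = character(), indels = NULL,
                     mixed_pos = integer(), below = integer(),
                     multiallelic = data.frame(pos = integer(),
                                               third_freq = numeric())) {
  calls <- parse_variants(subs)
  if (!is.null(indels)) calls <- rbind(calls, parse_variants(indels))
  mixed <- data.frame(pos = mixed_pos,
                      ref = rep("T", length(mixed_pos)),
                      major = rep("T", length(mixed_pos)),
                      minor = rep("C", length(mixed_pos)),
                      minor_freq = rep(0.2, length(mixed_pos)),
                      depth = rep(1000L, length(mixed_pos)),
                      iupac = rep("Y", length(mixed_pos)),
                      classification = rep("unassigned",
                                           length(mixed_pos)),
                      stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, calls = calls, mixed = mixed,
                 artifacts = mixed[0, ], multiallelic = multiallelic,
                 below_threshold = below, confirmed = integer(0),
                 profiles = NULL, detect_freq = 0.05, lhp = list()),
            class = "mito_haplotype")
}

# independent column-walk over a cigar string, recomputing the alignment
# statistics from scratch (oracle for the aligner's reported fractions)
walk_cigar <- function(pos, cigar, seq, refseq, L) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDS]", cigar))[[1]]
  rp <- pos - 1L; ri <- 0L
  matches <- 0L; aln_cols <- 0L; read_aligned <- 0L
  refch <- strsplit(refseq, "")[[1]]
  rdch <- strsplit(seq, "")[[1]]
  for (op in ops) {
    len <- as.integer(sub("[MIDS]", "", op))
    type <- sub("[0-9]+", "", op)
    if (type == "S") ri <- ri + len
    else if (type == "M") {
      for (k in seq_len(len)) {
        if (rdch[ri + 1L] == refch[rp %% L + 1L]) matches <- matches + 1L
        aln_cols <- aln_cols + 1L; read_aligned <- read_aligned + 1L
        ri <- ri + 1L; rp <- rp + 1L
      }
    } else if (type == "D") {
      aln_cols <- aln_cols + len; rp <- rp + len
    } else if (type == "I") {
      read_aligned <- read_aligned + len; ri <- ri + len
    }
  }
  list(matches = matches, aln_cols = aln_cols, read_aligned = read_aligned,
       length_fraction = read_aligned / nchar(seq),
       similarity_fraction = matches / aln_cols)
}

ref_substr_circular <- function(ref, start, len) {
  s2 <- paste0(ref$seq, ref$seq)
  substr(s2, start, start + len - 1L)
}
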