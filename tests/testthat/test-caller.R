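# Quality-filtered pileup, low-frequency variant detection, homopolymer
# indel handling and haplotype emission.

test_that("neighbourhood quality filter gates counted bases", {
  ref <- fx_ref()
  read <- substr(ref$seq, 1000, 1149)
  q35 <- strrep(intToUtf8(33 + 35), 150)
  # central base below Q30 at offset 75 (position 1074)
  q_central <- q35
  substr(q_central, 75, 75) <- intToUtf8(33 + 29)
  # a Q10 block drags the window mean below 30 around offsets 40-50
  q_window <- q35
  substr(q_window, 40, 50) <- strrep(intToUtf8(33 + 10), 11)
  m <- make_mapping(rbind(
    make_aln("uniform", 1000L, read, q35),
    make_aln("lowcentral", 1000L, read, q_central),
    make_aln("lowwindow", 1000L, read, q_window)))
  prof <- pileup_profiles(m, call_thresholds())
  # uniform Q35 read contributes everywhere; the Q29 base is dropped once
  expect_equal(prof$depth[1000], 3L)
  expect_equal(prof$depth[1074], 2L)
  # window-mean failures strike the Q10 block and its 5-bp surroundings
  expect_equal(prof$depth[1044], 2L)  # read offset 45, mid-block
  expect_true(all(prof$depth[1120:1149] == 3L))
})

test_that("pileup conserves aligned bases and matches truth depth", {
  clean <- fx_clean()
  prof <- pileup_profiles(clean$wf$final, call_thresholds())
  # noiseless uniform-quality simulation: every base of every alignment is
  # counted exactly once
  total_aligned <- sum(vapply(clean$wf$final$alignments$cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+M", cg))[[1]]
    sum(as.integer(sub("M", "", ops)))
  }, numeric(1)))
  expect_equal(sum(as.numeric(prof$counts[, 1:4])), total_aligned)
  expect_lt(abs(mean(prof$depth) - 200) / 200, 0.1)
  # empty mapping gives all-zero depth
  empty <- make_mapping(NULL)
  expect_true(all(pileup_profiles(empty, call_thresholds())$depth == 0L))
})

test_that("minor frequencies decide mixed calls at each threshold", {
  ref <- fx_ref()
  prof <- make_profiles(
    pos = c(1000L, 2000L, 3000L),
    counts_list = list(c(A = 920L, G = 80L),      # 8% minor
                       c(A = 990L, G = 10L),      # 1% minor
                       c(C = 900L, T = 100L)))    # 10% minor
  det5 <- detect_variants(prof, ref, call_thresholds(detect_freq = 0.05))
  expect_true(1000L %in% det5$mixed$pos)
  expect_false(2000L %in% det5$mixed$pos)
  det10 <- detect_variants(prof, ref, call_thresholds(detect_freq = 0.10))
  expect_false(1000L %in% det10$mixed$pos)
  expect_true(3000L %in% det10$mixed$pos)
  det2 <- detect_variants(prof, ref, call_thresholds(detect_freq = 0.02))
  expect_false(2000L %in% det2$mixed$pos)
  # IUPAC codes reflect the base pair
  r1000 <- det5$mixed[det5$mixed$pos == 1000L, ]
  expect_equal(r1000$iupac, "R")
  r3000 <- det5$mixed[det5$mixed$pos == 3000L, ]
  expect_equal(r3000$iupac, "Y")
  expect_equal(r1000$minor_freq, 80 / 1000)
})

test_that("low-depth and multi-allelic positions are flagged, not called", {
  ref <- fx_ref()
  prof <- make_profiles(
    pos = c(500L, 600L),
    counts_list = list(c(A = 50L, G = 30L),                  # depth 80
                       c(A = 700L, G = 200L, T = 100L)))     # 3 alleles
  det <- detect_variants(prof, ref, call_thresholds(detect_freq = 0.05))
  expect_true(500L %in% det$below_threshold)
  expect_false(500L %in% det$mixed$pos)
  expect_true(600L %in% det$multiallelic$pos)
  expect_equal(det$multiallelic$third_freq, 0.1)
  expect_false(600L %in% det$mixed$pos)
})

test_that("indels shift 3' within homopolymer runs", {
  ref <- fx_ref()
  # C insertion aligned at the start of the 311-315 C run -> 315.1C
  ins <- data.frame(pos = 311L, kind = "ins", ref = "", alt = "C",
                    ins_index = 1L, stringsAsFactors = FALSE)
  shifted <- shift_indels_3prime(ins, ref)
  expect_equal(format_variants(shifted), "315.1C")
  # deletion of one C in the same run -> 315del
  del <- data.frame(pos = 312L, kind = "del", ref = "", alt = "",
                    ins_index = NA_integer_, stringsAsFactors = FALSE)
  expect_equal(format_variants(shift_indels_3prime(del, ref)), "315del")
  # rightmost-placement oracle: every run position shifts to the run end
  run <- homopolymer_run(ref, 313)
  for (p in region_positions(run)) {
    d <- data.frame(pos = p, kind = "del", ref = "", alt = "",
                    ins_index = NA_integer_, stringsAsFactors = FALSE)
    expect_equal(shift_indels_3prime(d, ref)$pos, run$end)
  }
  # an indel outside any run >= 2 is unchanged
  p_iso <- 310L  # the interrupting T, run length 1
  d <- data.frame(pos = p_iso, kind = "del", ref = "", alt = "",
                  ins_index = NA_integer_, stringsAsFactors = FALSE)
  expect_equal(shift_indels_3prime(d, ref)$pos, p_iso)
})

test_that("length heteroplasmy reports the major molecule", {
  ref <- fx_ref()
  with_ins <- apply_variants(ref, "315.1C")
  seg_ins <- substr(with_ins, 250, 400)   # spans the C-stretch, 151 bp
  seg_ref <- substr(ref$seq, 250, 399)
  rows <- do.call(rbind, c(
    lapply(1:12, function(i) make_aln(paste0("i", i), 250L, seg_ins)),
    lapply(1:8, function(i) make_aln(paste0("r", i), 250L, seg_ref))))
  # recompute CIGARs via the aligner so insertion reads carry an I op
  reads <- data.frame(id = rows$id, mate = 1L, seq = rows$seq,
                      qual = rows$qual, stringsAsFactors = FALSE)
  m <- map_reads(reads, ref)
  hvs2 <- mito_regions()["HVS2_cstretch"]
  lhp <- resolve_length_heteroplasmy(m, ref, regions = hvs2)
  expect_equal(format_variants(lhp), "315.1C")
  # 50/50 tie -> shorter molecule (no insertion reported)
  reads_tie <- reads[c(1:8, 13:20), ]
  m_tie <- map_reads(reads_tie, ref)
  lhp_tie <- resolve_length_heteroplasmy(m_tie, ref, regions = hvs2)
  expect_equal(nrow(lhp_tie), 0L)
  # no spanning reads -> warning
  short <- data.frame(id = "s", mate = 1L,
                      seq = substr(ref$seq, 5000, 5149),
                      qual = strrep("I", 150), stringsAsFactors = FALSE)
  expect_warning(
    resolve_length_heteroplasmy(map_reads(short, ref), ref,
                                regions = mito_regions()["HVS2_cstretch"]),
    "span")
})

test_that("point substitutions in C-stretches survive LHP filtering", {
  ref <- fx_ref()
  spec <- truth_spec(base_haplotype = c("T16189C", "A263G"),
                     target_depth = 150, error_rate = 0,
                     post_homopolymer_boost = 1, seed = 23L)
  sim <- simulate_sample(spec, ref)
  wf <- consensus_workflow(sim$reads, ref)
  hap <- call_sample(wf$final, ref, call_thresholds(), "s")
  expect_true("T16189C" %in% strsplit(haplotype_string(hap), " ")[[1]])
})

test_that("A-stretch heteroplasmies are tagged artifacts and removed", {
  mixed <- data.frame(
    pos = c(302L, 16183L, 16093L),
    ref = c("A", "A", "T"), major = c("A", "A", "T"),
    minor = c("C", "C", "C"), minor_freq = c(0.06, 0.05, 0.2),
    depth = c(1000L, 1000L, 1000L), iupac = c("M", "M", "Y"),
    classification = "unassigned", stringsAsFactors = FALSE)
  f <- filter_astretch_artifacts(mixed)
  expect_equal(f$kept$pos, 16093L)
  expect_setequal(f$artifacts$pos, c(302L, 16183L))
  expect_true(all(f$artifacts$classification == "artifact"))
})

test_that("post-homopolymer errors surface as A-stretch artifacts end-to-end", {
  ref <- fx_ref()
  spec <- truth_spec(target_depth = 250, error_rate = 0.004,
                     post_homopolymer_boost = 40, seed = 31L)
  sim <- simulate_sample(spec, ref)
  wf <- consensus_workflow(sim$reads, ref)
  hap <- call_sample(wf$final, ref, call_thresholds(detect_freq = 0.02),
                     "s")
  # the A302M-type artifact: mixed call inside 300-302, removed from the
  # haplotype by the A-stretch filter
  expect_true(any(hap$artifacts$pos %in% 300:302))
  expect_false(any(hap$mixed$pos %in% 300:302))
})

test_that("haplotype strings follow forensic nomenclature", {
  clean <- fx_clean()
  expect_equal(haplotype_string(clean$hap),
               "A73G T152C A263G C295T")
  donor <- fx_donor()
  tokens <- strsplit(haplotype_string(donor$hap, detect_freq = 0.05),
                     " ")[[1]]
  expect_true("A263G" %in% tokens)
  expect_true("T16093Y" %in% tokens)
  # mixed-position minor naming: variant form vs rCRS-consistent form
  expect_equal(mixed_variant_name("A", 13062L, "G"), "A13062G")
  expect_equal(mixed_variant_name("A", 263L, "A"), "A263")
  # empty call set renders an empty haplotype
  empty <- make_hap("e")
  expect_equal(haplotype_string(empty), "")
})

test_that("haplotype emission is idempotent under re-parsing", {
  clean <- fx_clean()
  s <- haplotype_string(clean$hap)
  v <- parse_variants(strsplit(s, " ")[[1]])
  expect_equal(paste(format_variants(v), collapse = " "), s)
})

test_that("planted minors above threshold + 3 SD are always recovered", {
  ref <- fx_ref()
  thr <- 0.05
  depth <- 300
  sd3 <- 3 * sqrt(thr * (1 - thr) / depth)
  hi <- 0.05 + sd3 + 0.045   # comfortably detectable
  lo <- 0.05 - sd3 - 0.012   # designed false negative
  for (seed in c(1L, 2L)) {
    set.seed(seed + 500)
    pos <- sample(setdiff(2000:9000, 955:961), 3)
    minor <- vapply(base_at(ref, pos), function(b) {
      setdiff(c("A", "C", "G", "T"), b)[1]
    }, character(1))
    spec <- truth_spec(
      phps = data.frame(pos = pos, minor = minor,
                        fraction = c(hi, hi, lo)),
      target_depth = depth, seed = seed)
    sim <- simulate_sample(spec, ref)
    wf <- consensus_workflow(sim$reads, ref)
    hap <- call_sample(wf$final, ref, call_thresholds(detect_freq = 0.05),
                       "s")
    expect_true(all(pos[1:2] %in% hap$mixed$pos),
                label = sprintf("seed %d high-fraction recovery", seed))
    expect_false(pos[3] %in% hap$mixed$pos,
                 label = sprintf("seed %d low-fraction exclusion", seed))
  }
})

test_that("noiseless clean samples reproduce their haplotype exactly", {
  clean <- fx_clean()
  expect_equal(haplotype_string(clean$hap),
               paste(clean$spec$base_haplotype, collapse = " "))
  expect_equal(nrow(clean$hap$mixed), 0L)
  expect_length(clean$hap$below_threshold, 0L)
})
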