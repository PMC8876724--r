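# Rule engine: clustering, phasing, the two-stage review and dataset-wide
# classification of mixed positions as NUMT variants or probable PHPs.

mixed_row <- function(pos, ref, minor, freq, depth = 1000L,
                      major = NULL) {
  if (is.null(major)) major <- ref
  data.frame(pos = pos, ref = ref, major = major, minor = minor,
             minor_freq = freq, depth = depth,
             iupac = iupac_code(major, minor),
             classification = "unassigned", stringsAsFactors = FALSE)
}

test_that("clusters group nearby positions and ignore input order", {
  cl <- detect_clusters(c(13062, 13095, 13105), 500)
  expect_length(cl, 1L)
  expect_equal(cl[[1]], c(13062L, 13095L, 13105L))
  cl2 <- detect_clusters(c(263, 13062), 500)
  expect_length(cl2, 2L)
  expect_identical(detect_clusters(c(13105, 13062, 13095), 500), cl)
  # the gap across the origin counts
  cl3 <- detect_clusters(c(16560, 10), 100)
  expect_length(cl3, 1L)
  expect_length(detect_clusters(integer(0)), 0L)
})

test_that("phasing separates shared-molecule from independent minors", {
  donor <- fx_donor()
  # HVS1 signature variants 52 bp apart ride the same donor molecules
  expect_equal(phase_check(donor$wf$final, 16444L, 16496L, "T", "A"),
               "in_phase")
  ref <- fx_ref()
  # two PHPs on distinct molecule subsets are discordant
  p1 <- 5000L; p2 <- 5040L
  m1 <- setdiff(c("A", "C", "G", "T"), base_at(ref, p1))[1]
  m2 <- setdiff(c("A", "C", "G", "T"), base_at(ref, p2))[1]
  spec <- truth_spec(
    phps = data.frame(pos = c(p1, p2), minor = c(m1, m2),
                      fraction = c(0.3, 0.3)),
    target_depth = 150, error_rate = 0, post_homopolymer_boost = 1,
    seed = 77L)
  sim <- simulate_sample(spec, ref)
  m <- map_reads(sim$reads, ref)
  expect_equal(phase_check(m, p1, p2, m1, m2), "discordant")
  # positions farther apart than any fragment cannot be assessed
  expect_equal(phase_check(m, 2000L, 3500L, "A", "A"), "unassessable")
})

test_that("initial review labels in-phase donor signatures as NUMT", {
  donor <- fx_donor()
  rev <- initial_review(donor$sample)
  nd5 <- rev[rev$pos %in% c(13062, 13095, 13105), ]
  expect_true(all(nd5$label == "NUMT"))
  hvs1 <- rev[rev$pos %in% c(16390, 16399, 16444, 16496, 16519, 16527), ]
  expect_true(all(hvs1$label == "NUMT"))
  # the 20% heteroplasmy at the 16093 hotspot is untouched by the initial
  # review (it falls through to the secondary gate)
  expect_equal(rev$label[rev$pos == 16093], "unassigned")
})

test_that("an isolated high-frequency heteroplasmy is not labeled initially", {
  s <- list(id = "iso",
            mixed = mixed_row(16093L, "T", "C", 0.20),
            mapping = make_mapping(NULL), profiles = NULL,
            avg_depth = 2000)
  rev <- initial_review(s)
  expect_equal(rev$label, "unassigned")
})

test_that("strand-imbalanced minors are tagged artifacts", {
  prof <- make_profiles(1000L, list(c(A = 900L, G = 60L)))
  prof$fwd[1000L, "G"] <- 60L  # every minor observation on one strand
  s <- list(id = "sb", mixed = mixed_row(1000L, "A", "G", 60 / 960),
            mapping = make_mapping(NULL), profiles = prof,
            avg_depth = 900)
  rev <- initial_review(s)
  expect_equal(rev$label, "artifact")
  expect_equal(rev$rules, "strand_bias")
})

test_that("secondary review gate retains high-frequency/high-depth PHPs", {
  # the A13105R worked case: minor G at 15.3%, 3287X average depth --
  # despite A13105G being a catalog NUMT variant, the gate keeps it a PHP
  s <- list(id = "SWE658-like",
            mixed = cbind(mixed_row(13105L, "A", "G", 0.153, 3287L),
                          label = "unassigned", rules = ""),
            mapping = make_mapping(NULL), profiles = NULL,
            avg_depth = 3287)
  out <- secondary_review(s)
  expect_equal(out$label, "PHP")
  expect_equal(out$rules, "gate_fail")
})

test_that("secondary review votes label low-level catalog variants NUMT", {
  # G16129A at 5.4% in a low-depth sample with an in-phase low-band
  # partner: catalog + phase votes concur
  ref <- fx_ref()
  p2 <- 16150L
  minor2 <- setdiff(c("A", "C", "G", "T"), base_at(ref, p2))[1]
  seg <- substr(ref$seq, 16100, 16249)
  seg_minor <- seg
  substr(seg_minor, 30, 30) <- "A"        # 16129
  substr(seg_minor, 51, 51) <- minor2     # 16150
  rows <- do.call(rbind, c(
    lapply(1:95, function(i) make_aln(paste0("r", i), 16100L, seg)),
    lapply(1:5, function(i) make_aln(paste0("m", i), 16100L, seg_minor))))
  mx <- rbind(cbind(mixed_row(16129L, "G", "A", 0.054, 650L),
                    label = "unassigned", rules = ""),
              cbind(mixed_row(p2, base_at(ref, p2), minor2, 0.03, 650L),
                    label = "unassigned", rules = ""))
  s <- list(id = "SWE866-like", mixed = mx,
            mapping = make_mapping(rows), profiles = NULL,
            avg_depth = 650)
  out <- secondary_review(s)
  r <- out[out$pos == 16129L, ]
  expect_equal(r$label, "NUMT")
  expect_true(grepl("catalog", r$rules))
  expect_true(grepl("low_band_phase", r$rules))
})

test_that("PHP hotspots are vetoed to PHP in the secondary review", {
  # T146Y at 12%: fails the gate regardless of catalog membership
  s1 <- list(id = "a",
             mixed = cbind(mixed_row(146L, "T", "C", 0.12), label =
                             "unassigned", rules = ""),
             mapping = make_mapping(NULL), profiles = NULL,
             avg_depth = 800)
  expect_equal(secondary_review(s1)$label, "PHP")
  # T146Y at 8% in a low-depth sample: hotspot veto applies inside the gate
  s2 <- list(id = "b",
             mixed = cbind(mixed_row(146L, "T", "C", 0.08), label =
                             "unassigned", rules = ""),
             mapping = make_mapping(NULL), profiles = NULL,
             avg_depth = 800)
  out <- secondary_review(s2)
  expect_equal(out$label, "PHP")
  expect_equal(out$rules, "php_hotspot")
})

test_that("dataset classification is exhaustive, exclusive and deterministic", {
  donor <- fx_donor()
  rec <- donor$records
  expect_true(all(rec$label %in% c("NUMT", "PHP", "artifact")))
  expect_false(any(duplicated(rec[c("sample", "pos")])))
  rec2 <- classify_dataset(list(donor = donor$sample))
  expect_identical(rec, rec2)
  # signature positions NUMT; the hotspot heteroplasmy PHP
  expect_true(all(rec$label[rec$pos %in% c(13062, 13095, 13105)] ==
                    "NUMT"))
  expect_equal(rec$label[rec$pos == 16093], "PHP")
})

test_that("clean cohorts produce zero NUMT labels", {
  clean <- fx_clean()
  s <- list(id = "clean", mixed = clean$hap$mixed,
            mapping = clean$wf$final, profiles = clean$hap$profiles,
            avg_depth = mean(clean$hap$profiles$depth))
  rec <- classify_dataset(list(clean = s))
  expect_equal(sum(rec$label == "NUMT"), 0L)
})

test_that("threshold call sets nest: 10% within 5% within 2%", {
  donor <- fx_donor()
  rec <- donor$records
  s2 <- rec[rec$minor_freq >= 0.02, ]
  s5 <- rec[rec$minor_freq >= 0.05, ]
  s10 <- rec[rec$minor_freq >= 0.10, ]
  expect_true(all(paste(s10$sample, s10$pos) %in%
                    paste(s5$sample, s5$pos)))
  expect_true(all(paste(s5$sample, s5$pos) %in%
                    paste(s2$sample, s2$pos)))
  expect_identical(s5[s5$minor_freq >= 0.10, ], s10)
})

test_that("donor signatures survive classification without the catalog", {
  donor <- fx_donor()
  rec <- classify_dataset(list(donor = donor$sample),
                          catalog = numt_catalog(include_builtin = FALSE))
  sig <- rec[rec$pos %in% c(13062, 13095, 13105, 16390, 16399, 16444,
                            16496, 16519, 16527), ]
  expect_true(all(sig$label == "NUMT"))
  expect_true(all(grepl("region_phase|cluster", sig$rules)))
})

test_that("np 16,093 can be ignored in all interpretations", {
  donor <- fx_donor()
  rec <- classify_dataset(list(donor = donor$sample),
                          criteria = review_criteria(ignore_16093 = TRUE))
  expect_false(16093L %in% rec$pos)
})
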