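# Synthetic shotgun mtDNA read generation with truth labels.
#
# The generator emulates the statistical structure of mtDNA reads drawn from
# whole-genome sequencing: paired-end reads sampled uniformly from the
# circular mitogenome (fragments may span the origin), point heteroplasmies
# realised per-molecule at a stated minor fraction, NUMT donor reads drawn
# from a nuclear insertion haplotype over its mtDNA-homology span, optional
# exogenous contaminant molecules, and per-base miscalls with an elevated
# rate immediately 3' of homopolymer runs (the post-homopolymer artifact of
# HiSeq-type chemistry).

#' NUMT donor definition
#'
#' A named nuclear insertion haplotype described by its variant set against
#' the mitochondrial reference and the mtDNA region it is homologous to.
#' `copy_fraction` is the target minor read fraction at the donor's own
#' region, i.e. donor depth / (donor + mtDNA depth) there; a donor at 0.08
#' therefore surfaces as mixed positions with ~8% minor frequency.
#'
#' @param name donor name.
#' @param source_region `mito_region` of mtDNA homology.
#' @param variants character vector of variant tokens (diffs vs the
#'   reference), all inside `source_region`.
#' @param copy_fraction numeric in `[0, 1)`.
#' @export
numt_donor <- function(name, source_region, variants, copy_fraction = 0.08) {
  stopifnot(copy_fraction >= 0, copy_fraction < 1)
  v <- parse_variants(variants)
  if (!all(region_contains(source_region, v$pos))) {
    stop("donor variants must lie inside the source region")
  }
  structure(list(name = name, source_region = source_region,
                 variants = v, copy_fraction = copy_fraction),
            class = "numt_donor")
}

#' Built-in NUMT donors documented in population WGS data
#'
#' Two signature clusters repeatedly observed as in-phase low-frequency
#' variant sets in shotgun WGS mitogenome alignments:
#' * `"ND5_sig"`: three in-phase variants A13062G, T13095C, A13105G over the
#'   51-bp span nps 13,060-13,110 (consistent with a polymorphic NUMT).
#' * `"HVS1_sig"`: six in-phase variants G16390A, A16399G, C16444T, G16496A,
#'   T16519C, C16527T over the 156-bp span nps 16,380-16,535.
#'
#' @param name one of `"HVS1_sig"`, `"ND5_sig"`.
#' @param copy_fraction target minor read fraction at the donor region.
#' @return A [numt_donor()].
#' @export
build_numt_donor <- function(name, copy_fraction = 0.08) {
  registry <- list(
    HVS1_sig = list(region = mito_region(16380L, 16535L),
                    variants = c("G16390A", "A16399G", "C16444T",
                                 "G16496A", "T16519C", "C16527T")),
    ND5_sig = list(region = mito_region(13060L, 13110L),
                   variants = c("A13062G", "T13095C", "A13105G"))
  )
  if (!name %in% names(registry)) {
    stop("unknown built-in NUMT donor: ", name,
         " (available: ", paste(names(registry), collapse = ", "), ")")
  }
  e <- registry[[name]]
  numt_donor(name, e$region, e$variants, copy_fraction)
}

#' Truth specification for a simulated sample
#'
#' Defaults follow 150+150 paired-end chemistry at desk scale: insert
#' 350 +/- 50 bp, constant Q35 base quality, per-base miscall rate 0.001,
#' and a 20x miscall boost within 3 bp 3' of homopolymer runs >= 4 bp
#' (biased toward the run's base).
#'
#' @param base_haplotype character vector of variant tokens defining the
#'   sample's true mtDNA haplotype (diffs vs the reference).
#' @param phps data.frame with columns `pos`, `minor`, `fraction`: point
#'   heteroplasmies realised per molecule; `fraction` is the minor fraction
#'   of reads covering the position.
#' @param donors list of [numt_donor()] objects.
#' @param contaminant optional `list(haplotype = <tokens>, fraction = f)`
#'   exogenous mtDNA mixture (fraction of total reads).
#' @param target_depth mean read depth (X) of the authentic mtDNA molecule.
#' @param read_length,insert_mean,insert_sd read model (bp).
#' @param error_rate per-base miscall probability.
#' @param base_quality constant Phred base quality emitted.
#' @param post_homopolymer_boost miscall-rate multiplier 3' of runs >= 4 bp.
#' @param seed integer seed; all stochastic choices derive from it.
#' @export
truth_spec <- function(base_haplotype = character(),
                       phps = NULL, donors = list(), contaminant = NULL,
                       target_depth = 1000, read_length = 150L,
                       insert_mean = 350, insert_sd = 50,
                       error_rate = 0.001, base_quality = 35L,
                       post_homopolymer_boost = 20, seed = 1L) {
  if (is.null(phps)) {
    phps <- data.frame(pos = integer(), minor = character(),
                       fraction = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(phps$fraction > 0), all(phps$fraction < 1),
            target_depth > 0, read_length > 0,
            insert_mean >= read_length)
  if (length(donors) > 0) {
    cf <- vapply(donors, function(d) d$copy_fraction, numeric(1))
    if (sum(cf) >= 1) stop("donor copy fractions must sum to < 1")
  }
  if (!is.null(contaminant)) {
    stopifnot(contaminant$fraction > 0, contaminant$fraction < 1)
  }
  structure(list(base_haplotype = base_haplotype, phps = phps,
                 donors = donors, contaminant = contaminant,
                 target_depth = target_depth,
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate,
                 base_quality = as.integer(base_quality),
                 post_homopolymer_boost = post_homopolymer_boost,
                 seed = as.integer(seed)),
            class = "truth_spec")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# fragments drawn from a circular molecule: uniform start, gaussian insert
circular_fragments <- function(molseq, n, read_length, insert_mean,
                               insert_sd) {
  Lm <- nchar(molseq)
  fl <- pmin(pmax(round(rnorm(n, insert_mean, insert_sd)), read_length), Lm)
  st <- sample.int(Lm, n, replace = TRUE)
  m2 <- paste0(molseq, molseq)
  list(start = st, len = as.integer(fl),
       seq = substring(m2, st, st + fl - 1L))
}

#' Simulate a paired-end mtDNA sample with truth labels
#'
#' Reads are sampled uniformly from the circular mtDNA molecule (fragments
#' may span the origin) and, for each NUMT donor, from the donor haplotype
#' over its homology span extended by one insert length of reference-
#' identical flank on each side (real nuclear insertions carry homologous
#' flanking sequence, so donor reads overlap the signature from both sides).
#' Deterministic given `spec$seed`.
#'
#' @param spec a [truth_spec()].
#' @param reference a [mito_reference()].
#' @return List of class `sim_sample`: `reads` (data.frame: one row per
#'   read with `id`, `mate`, `seq`, `qual`) and `truth` (one row per pair:
#'   `id`, `origin`, `start`).
#' @export
simulate_sample <- function(spec, reference = mito_reference()) {
  stopifnot(inherits(spec, "truth_spec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(spec$seed)

  L <- reference$length
  rl <- spec$read_length
  mol <- apply_variants(reference, spec$base_haplotype)
  Lm <- nchar(mol)
  n_mt <- max(1L, round(spec$target_depth * Lm / (2 * rl)))

  frag_tabs <- list()

  # authentic mtDNA fragments
  mt <- circular_fragments(mol, n_mt, rl, spec$insert_mean, spec$insert_sd)
  # realise point heteroplasmies per molecule (independently per PHP, so
  # distinct PHPs live on distinct molecule subsets)
  if (nrow(spec$phps) > 0) {
    for (i in seq_len(nrow(spec$phps))) {
      p <- spec$phps$pos[i]
      off <- (p - mt$start) %% Lm          # 0-based offset within fragment
      covered <- which(off < mt$len)
      if (length(covered) == 0) next
      carrier <- covered[runif(length(covered)) < spec$phps$fraction[i]]
      if (length(carrier) > 0) {
        o1 <- off[carrier] + 1L
        substr(mt$seq[carrier], o1, o1) <- spec$phps$minor[i]
      }
    }
  }
  frag_tabs[["mtDNA"]] <- data.frame(origin = "mtDNA", start = mt$start,
                                     len = mt$len, seq = mt$seq,
                                     stringsAsFactors = FALSE)

  # NUMT donor fragments: donor haplotype over extended homology span
  for (d in spec$donors) {
    if (d$copy_fraction <= 0) next
    donor_full <- apply_variants(reference, format_variants(d$variants))
    ext <- as.integer(round(spec$insert_mean))
    s <- ((d$source_region$start - 1L - ext) %% L) + 1L
    e <- ((d$source_region$end - 1L + ext) %% L) + 1L
    reg <- mito_region(s, e, L)
    pos <- region_positions(reg)
    dseq <- paste(strsplit(donor_full, "")[[1]][pos], collapse = "")
    span <- nchar(dseq)
    n_starts <- max(1L, span - as.integer(round(spec$insert_mean)) + 1L)
    nd <- max(1L, round(d$copy_fraction / (1 - d$copy_fraction) *
                          spec$target_depth * n_starts / (2 * rl)))
    fl <- pmin(pmax(round(rnorm(nd, spec$insert_mean, spec$insert_sd)), rl),
               span)
    st <- vapply(span - fl + 1L, function(k) sample.int(k, 1L), integer(1))
    frag_tabs[[d$name]] <- data.frame(
      origin = d$name,
      start = ((s - 1L + st - 1L) %% L) + 1L,
      len = as.integer(fl),
      seq = substring(dseq, st, st + fl - 1L),
      stringsAsFactors = FALSE)
  }

  # exogenous contaminant molecules
  if (!is.null(spec$contaminant)) {
    cmol <- apply_variants(reference, spec$contaminant$haplotype)
    f <- spec$contaminant$fraction
    nc <- max(1L, round(n_mt * f / (1 - f)))
    cf <- circular_fragments(cmol, nc, rl, spec$insert_mean, spec$insert_sd)
    frag_tabs[["contaminant"]] <- data.frame(
      origin = "contaminant", start = cf$start, len = cf$len, seq = cf$seq,
      stringsAsFactors = FALSE)
  }

  frags <- do.call(rbind, frag_tabs)
  rownames(frags) <- NULL
  n <- nrow(frags)
  ids <- sprintf("sim_%07d", seq_len(n))

  r1 <- substr(frags$seq, 1L, rl)
  r2 <- revcomp_chr(substring(frags$seq, frags$len - rl + 1L, frags$len))
  r1 <- cpp_add_errors(r1, spec$error_rate, spec$post_homopolymer_boost,
                       3L, 4L)
  r2 <- cpp_add_errors(r2, spec$error_rate, spec$post_homopolymer_boost,
                       3L, 4L)
  qual <- strrep(intToUtf8(33L + spec$base_quality), rl)

  reads <- data.frame(
    id = rep(ids, 2L),
    mate = rep(c(1L, 2L), each = n),
    seq = c(r1, r2),
    qual = rep(qual, 2L * n),
    stringsAsFactors = FALSE)
  ord <- order(reads$id, reads$mate)
  reads <- reads[ord, , drop = FALSE]
  rownames(reads) <- NULL
  truth <- data.frame(id = ids, origin = frags$origin, start = frags$start,
                      stringsAsFactors = FALSE)
  structure(list(reads = reads, truth = truth, spec = spec),
            class = "sim_sample")
}

#' @export
print.sim_sample <- function(x, ...) {
  cat(sprintf("<sim_sample> %d read pairs (%s)\n", nrow(x$truth),
              paste(sprintf("%s: %d", names(table(x$truth$origin)),
                            as.integer(table(x$truth$origin))),
                    collapse = ", ")))
  invisible(x)
}

# ---- FASTQ / truth I/O ---------------------------------------------------

#' Write paired reads to two FASTQ files
#' @param reads data.frame with `id`, `mate`, `seq`, `qual`.
#' @param r1_path,r2_path output FASTQ paths (mate 1 / mate 2).
#' @export
write_fastq <- function(reads, r1_path, r2_path) {
  if (nrow(reads) == 0L) stop("empty read set")
  for (m in 1:2) {
    sub <- reads[reads$mate == m, , drop = FALSE]
    sub <- sub[order(sub$id), , drop = FALSE]
    lines <- as.vector(rbind(paste0("@", sub$id, "/", m),
                             sub$seq, "+", sub$qual))
    writeLines(lines, if (m == 1) r1_path else r2_path)
  }
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a read set
#' @param r1_path,r2_path FASTQ paths.
#' @export
read_fastq <- function(r1_path, r2_path = NULL) {
  parse1 <- function(path, mate) {
    x <- readLines(path)
    if (length(x) %% 4L != 0L) stop("malformed FASTQ: ", path)
    i <- seq(1L, length(x), by = 4L)
    data.frame(id = sub("/[12]$", "", sub("^@", "", sub("\\s.*", "", x[i]))),
               mate = mate, seq = x[i + 1L], qual = x[i + 3L],
               stringsAsFactors = FALSE)
  }
  out <- parse1(r1_path, 1L)
  if (!is.null(r2_path)) out <- rbind(out, parse1(r2_path, 2L))
  out[order(out$id, out$mate), , drop = FALSE]
}

#' Write / read the truth table (read id, origin, source start)
#' @param truth data.frame from [simulate_sample()].
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a truth spec as YAML
#' @param spec a [truth_spec()].
#' @param path YAML path.
#' @export
write_truth_spec <- function(spec, path) {
  x <- unclass(spec)
  x$phps <- if (nrow(spec$phps)) as.list(spec$phps) else NULL
  x$donors <- lapply(spec$donors, function(d) {
    list(name = d$name,
         region = paste0(d$source_region$start, "-", d$source_region$end),
         variants = format_variants(d$variants),
         copy_fraction = d$copy_fraction)
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_truth_spec
#' @export
read_truth_spec <- function(path) {
  x <- yaml::read_yaml(path)
  donors <- lapply(x$donors, function(d) {
    numt_donor(d$name, parse_region(d$region), d$variants, d$copy_fraction)
  })
  phps <- if (!is.null(x$phps)) {
    data.frame(pos = as.integer(x$phps$pos), minor = x$phps$minor,
               fraction = x$phps$fraction, stringsAsFactors = FALSE)
  } else NULL
  truth_spec(base_haplotype = unlist(x$base_haplotype) %||% character(),
             phps = phps, donors = donors, contaminant = x$contaminant,
             target_depth = x$target_depth, read_length = x$read_length,
             insert_mean = x$insert_mean, insert_sd = x$insert_sd,
             error_rate = x$error_rate, base_quality = x$base_quality,
             post_homopolymer_boost = x$post_homopolymer_boost,
             seed = x$seed)
}
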