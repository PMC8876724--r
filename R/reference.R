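#' @useDynLib mitohap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

MT_LENGTH <- 16569L

# NULL / empty / NA coalescing helper used across modules
`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b
  else a
}

#' Load a circular mitochondrial reference genome
#'
#' Reads a single-sequence FASTA and returns a `mito_reference` object.  The
#' default is the bundled *synthetic* rCRS-like reference: a 16,569-bp
#' sequence with human-mtDNA base composition whose control-region landmarks
#' (HVS1/HVS2 C-stretches, the preceding A-stretches, hotspot and NUMT
#' signature reference bases) sit at their canonical rCRS coordinates.  It is
#' not the NC_012920.1 sequence; for real data supply the genuine rCRS.
#'
#' @param path FASTA file with exactly one sequence; `NULL` for the bundled
#'   synthetic reference.
#' @param circular logical; mitogenomes are circular.
#' @return A `mito_reference`: list with `name`, `seq` (upper-case ACGT
#'   string), `length`, `circular`.
#' @export
mito_reference <- function(path = NULL, circular = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "rCRS_synthetic.fa", package = "mitohap")
  }
  if (!file.exists(path)) {
    stop("reference FASTA not found: ", path)
  }
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) {
    stop("reference FASTA must contain exactly one sequence, found ",
         length(ss))
  }
  seq <- toupper(as.character(ss[[1]]))
  if (grepl("[^ACGT]", seq)) {
    stop("reference alphabet restricted to A/C/G/T")
  }
  structure(
    list(name = sub("\\s.*", "", names(ss)[1]), seq = seq,
         length = nchar(seq), circular = isTRUE(circular)),
    class = "mito_reference"
  )
}

#' @export
print.mito_reference <- function(x, ...) {
  cat(sprintf("<mito_reference> %s: %d bp, %s\n", x$name, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Circular 1-based inclusive region on the mitogenome
#'
#' Both ends are inclusive and 1-based, matching forensic mtDNA convention.
#' A region with `start > end` wraps the origin (position L is followed by
#' position 1), e.g. the control region nps 16,024-576.
#'
#' @param start,end 1-based positions.
#' @param L genome length (defines the wrap point).
#' @return A `mito_region` object.
#' @export
mito_region <- function(start, end, L = MT_LENGTH) {
  start <- as.integer(start); end <- as.integer(end); L <- as.integer(L)
  if (is.na(start) || is.na(end) || start < 1L || end < 1L ||
      start > L || end > L) {
    stop("region positions must lie in 1..", L)
  }
  structure(list(start = start, end = end, L = L, wraps = start > end),
            class = "mito_region")
}

#' @export
print.mito_region <- function(x, ...) {
  cat(sprintf("<mito_region> %d-%d%s (%d bp of %d)\n", x$start, x$end,
              if (x$wraps) " (wraps origin)" else "",
              region_length(x), x$L))
  invisible(x)
}

#' Parse a "start-end" region string
#' @param s string like `"16024-576"`.
#' @param L genome length.
#' @export
parse_region <- function(s, L = MT_LENGTH) {
  m <- regmatches(s, regexec("^([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 3L) stop("cannot parse region string: ", s)
  mito_region(as.integer(m[2]), as.integer(m[3]), L)
}

#' Number of positions in a circular region
#'
#' Non-wrapping regions span `end - start + 1` positions; wrapping regions
#' span `(L - start + 1) + end`.  The control region (16,024-576) is 1122 bp
#' and the coding region (577-16,023) 15,447 bp; together they partition the
#' 16,569-bp circle.
#'
#' @param region a `mito_region`.
#' @param L genome length (defaults to the region's own).
#' @export
region_length <- function(region, L = region$L) {
  if (region$wraps) (L - region$start + 1L) + region$end
  else region$end - region$start + 1L
}

#' Ordered positions of a circular region
#'
#' Traversal order wraps `L -> 1` for origin-spanning regions.
#' @inheritParams region_length
#' @export
region_positions <- function(region, L = region$L) {
  if (region$wraps) c(region$start:L, 1L:region$end)
  else region$start:region$end
}

#' Complement of a circular region
#' @inheritParams region_length
#' @export
region_complement <- function(region, L = region$L) {
  if (region_length(region, L) >= L) stop("region covers the whole genome")
  s <- region$end %% L + 1L
  e <- (region$start - 2L) %% L + 1L
  mito_region(s, e, L)
}

#' Is a position inside a circular region?
#' @param pos integer vector of positions.
#' @inheritParams region_length
#' @export
region_contains <- function(region, pos) {
  if (region$wraps) pos >= region$start | pos <= region$end
  else pos >= region$start & pos <= region$end
}

#' Named mitogenome regions used throughout the pipeline
#'
#' Control region (CR) and coding region (codR) per forensic convention;
#' HVS1/HVS2 C-stretch and preceding A-stretch artifact zones; the two
#' documented NUMT signature hotspot regions.
#' @return Named list of `mito_region` objects.
#' @export
mito_regions <- function() {
  list(
    CR             = mito_region(16024L, 576L),
    codR           = mito_region(577L, 16023L),
    HVS2_cstretch  = mito_region(303L, 315L),
    HVS1_cstretch  = mito_region(16184L, 16193L),
    HVS2_astretch  = mito_region(300L, 302L),
    HVS1_astretch  = mito_region(16180L, 16183L),
    numt_hotspot_1 = mito_region(12612L, 13105L),
    numt_hotspot_2 = mito_region(16390L, 16527L)
  )
}

# ---- variant specs -------------------------------------------------------

#' Parse forensic-nomenclature variant tokens
#'
#' Accepted forms: substitutions `"A263G"` (rCRS base, position, variant
#' base), insertions `"315.1C"` (decimal suffix after the anchor position),
#' deletions `"315del"`.
#'
#' @param tokens character vector of variant tokens.
#' @return data.frame with columns `pos`, `kind` (`sub`/`ins`/`del`), `ref`,
#'   `alt`, `ins_index`.
#' @export
parse_variants <- function(tokens) {
  tokens <- tokens[nzchar(tokens)]
  n <- length(tokens)
  out <- data.frame(pos = integer(n), kind = character(n),
                    ref = character(n), alt = character(n),
                    ins_index = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    t <- tokens[i]
    if (grepl("^[ACGT][0-9]+[ACGTRYSWKM]$", t)) {
      out$pos[i] <- as.integer(gsub("[^0-9]", "", t))
      out$kind[i] <- "sub"
      out$ref[i] <- substr(t, 1, 1)
      out$alt[i] <- substr(t, nchar(t), nchar(t))
    } else if (grepl("^[0-9]+\\.[0-9]+[ACGT]$", t)) {
      m <- regmatches(t, regexec("^([0-9]+)\\.([0-9]+)([ACGT])$", t))[[1]]
      out$pos[i] <- as.integer(m[2]); out$kind[i] <- "ins"
      out$ref[i] <- ""; out$alt[i] <- m[4]
      out$ins_index[i] <- as.integer(m[3])
    } else if (grepl("^[0-9]+del$", t, ignore.case = TRUE)) {
      out$pos[i] <- as.integer(gsub("[^0-9]", "", t))
      out$kind[i] <- "del"; out$ref[i] <- ""; out$alt[i] <- ""
    } else {
      stop("cannot parse variant token: ", t)
    }
  }
  out
}

#' Render variant rows back to nomenclature tokens
#' @param v data.frame as produced by [parse_variants()].
#' @export
format_variants <- function(v) {
  if (nrow(v) == 0L) return(character(0))
  vapply(seq_len(nrow(v)), function(i) {
    switch(v$kind[i],
      sub = paste0(v$ref[i], v$pos[i], v$alt[i]),
      ins = paste0(v$pos[i], ".", v$ins_index[i], v$alt[i]),
      del = paste0(v$pos[i], "del"),
      stop("unknown variant kind: ", v$kind[i]))
  }, character(1))
}

#' Apply variants to a reference sequence
#'
#' Substitutions replace the reference base (which must match the stated
#' rCRS base), deletions remove it, insertions add bases after the anchor
#' position ordered by their decimal suffix.  Conflicting variants at one
#' position are an error.
#'
#' @param reference a `mito_reference` or plain base string.
#' @param variants data.frame from [parse_variants()], or a character vector
#'   of tokens.
#' @return The mutated linear sequence (character scalar).
#' @export
apply_variants <- function(reference, variants) {
  seq <- if (inherits(reference, "mito_reference")) reference$seq
         else as.character(reference)
  if (is.character(variants)) variants <- parse_variants(variants)
  ch <- strsplit(seq, "")[[1]]
  if (nrow(variants) > 0L &&
      (any(variants$pos < 1L) || any(variants$pos > length(ch)))) {
    stop("variant position outside reference")
  }
  pointlike <- variants[variants$kind != "ins", , drop = FALSE]
  if (anyDuplicated(pointlike$pos)) {
    stop("conflicting variants at position(s): ",
         paste(unique(pointlike$pos[duplicated(pointlike$pos)]),
               collapse = ", "))
  }
  ins <- variants[variants$kind == "ins", , drop = FALSE]
  if (anyDuplicated(ins[c("pos", "ins_index")])) {
    stop("conflicting insertions at the same anchor/suffix")
  }
  keep <- rep(TRUE, length(ch))
  for (i in seq_len(nrow(pointlike))) {
    p <- pointlike$pos[i]
    if (pointlike$kind[i] == "sub") {
      if (ch[p] != pointlike$ref[i]) {
        stop(sprintf("reference mismatch at %d: expected %s, found %s",
                     p, pointlike$ref[i], ch[p]))
      }
      if (pointlike$alt[i] == pointlike$ref[i]) {
        stop("substitution with ref == alt at ", p)
      }
      ch[p] <- pointlike$alt[i]
    } else {
      keep[p] <- FALSE
    }
  }
  inserts <- rep("", length(ch))
  if (nrow(ins) > 0L) {
    ins <- ins[order(ins$pos, ins$ins_index), , drop = FALSE]
    for (p in unique(ins$pos)) {
      inserts[p] <- paste(ins$alt[ins$pos == p], collapse = "")
    }
  }
  paste0(paste0(ifelse(keep, ch, ""), inserts), collapse = "")
}

#' Substitution-only diff of two equal-length sequences
#'
#' Position-wise comparison; inverse of [apply_variants()] for
#' substitution-only variant sets.
#' @param ref,alt base strings of equal length.
#' @export
diff_sequences <- function(ref, alt) {
  if (inherits(ref, "mito_reference")) ref <- ref$seq
  if (nchar(ref) != nchar(alt)) {
    stop("diff_sequences requires equal-length sequences")
  }
  a <- strsplit(ref, "")[[1]]; b <- strsplit(alt, "")[[1]]
  w <- which(a != b)
  data.frame(pos = w, kind = rep("sub", length(w)), ref = a[w], alt = b[w],
             ins_index = rep(NA_integer_, length(w)),
             stringsAsFactors = FALSE)
}

#' Maximal homopolymer run containing a position
#'
#' Scans left and right (circularly) from `position` over identical bases.
#' @param reference `mito_reference` or base string.
#' @param position 1-based position.
#' @param L genome length; circular scan wraps when the input is circular.
#' @export
homopolymer_run <- function(reference, position, L = NULL) {
  circular <- TRUE
  if (inherits(reference, "mito_reference")) {
    circular <- reference$circular
    seq <- reference$seq
  } else seq <- as.character(reference)
  n <- nchar(seq)
  if (is.null(L)) L <- n
  if (position < 1L || position > n) stop("position outside reference")
  ch <- strsplit(seq, "")[[1]]
  b <- ch[position]
  s <- position; e <- position
  repeat {
    p <- if (s == 1L) { if (circular) n else break } else s - 1L
    if (ch[p] != b || p == e) break
    s <- p
  }
  repeat {
    p <- if (e == n) { if (circular) 1L else break } else e + 1L
    if (ch[p] != b || p == s) break
    e <- p
  }
  mito_region(s, e, n)
}

# ---- IUPAC ---------------------------------------------------------------

IUPAC_PAIRS <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")

#' IUPAC two-base ambiguity code
#' @param a,b the two bases (order-free).
#' @export
iupac_code <- function(a, b) {
  key <- paste0(pmin(a, b), pmax(a, b))
  code <- unname(IUPAC_PAIRS[key])
  if (any(is.na(code))) stop("not a two-base combination: ", key[is.na(code)])
  code
}

#' Bases encoded by a two-base IUPAC code
#' @param code single IUPAC ambiguity character.
#' @export
iupac_bases <- function(code) {
  i <- match(code, IUPAC_PAIRS)
  if (is.na(i)) stop("unknown IUPAC pair code: ", code)
  strsplit(names(IUPAC_PAIRS)[i], "")[[1]]
}

#' Base at a reference position
#' @param reference `mito_reference` or base string.
#' @param pos integer positions.
#' @export
base_at <- function(reference, pos) {
  seq <- if (inherits(reference, "mito_reference")) reference$seq
         else as.character(reference)
  substring(seq, pos, pos)
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
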