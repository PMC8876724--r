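# Consensus mapping workflow: permissive map to the circular reference,
# majority consensus, stringent remap to the consensus, realignment to
# reference coordinates.  Circularity is handled by aligning against a
# doubled reference and reducing start coordinates modulo the genome
# length; alignments that span the origin carry on across it.

#' Mapping acceptance parameters
#'
#' An alignment is accepted when both its length fraction (aligned read
#' bases / read length) and its similarity fraction (matching columns /
#' aligned columns, read-insert columns excluded) reach the thresholds.
#' Defaults mirror permissive first-pass mapping (0.5/0.8); the stringent
#' consensus remap uses 0.95/0.95.
#'
#' @param length_fraction,similarity_fraction numeric in (0, 1].
#' @export
mapping_params <- function(length_fraction = 0.5,
                           similarity_fraction = 0.8) {
  stopifnot(length_fraction > 0, length_fraction <= 1,
            similarity_fraction > 0, similarity_fraction <= 1)
  structure(list(length_fraction = length_fraction,
                 similarity_fraction = similarity_fraction),
            class = "mapping_params")
}

#' Align a single read against a circular reference
#'
#' Seed-and-extend banded local alignment against the doubled reference;
#' start coordinates are reduced modulo the genome length so reads spanning
#' the origin map without splitting.  Rejection (fractions below `params`)
#' is a value, not an error.
#'
#' @param seq read sequence; `qual` optional quality string.
#' @param reference a [mito_reference()].
#' @param params a [mapping_params()].
#' @return One-row data.frame: `pos`, `strand`, `cigar`, `score`,
#'   `length_fraction`, `similarity_fraction`, `accepted`, `status`
#'   (`accepted`/`rejected`/`ambiguous`/`unmapped`).
#' @export
align_read <- function(seq, reference, params = mapping_params(),
                       qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  m <- map_reads(data.frame(id = "r", mate = 1L, seq = seq, qual = qual,
                            stringsAsFactors = FALSE),
                 reference, params, keep_all = TRUE)
  m$alignments[, c("pos", "strand", "cigar", "score", "length_fraction",
                   "similarity_fraction", "accepted", "status")]
}

#' Map a read set against a circular reference
#'
#' @param reads data.frame with columns `id`, `mate`, `seq`, `qual`.
#' @param reference a [mito_reference()].
#' @param params a [mapping_params()].
#' @param keep_all keep rejected/ambiguous/unmapped rows (flagged) instead
#'   of dropping them.
#' @return A `mito_mapping`: list with `ref_name`, `L`, `alignments`
#'   (accepted alignments in reference coordinates) and `stats`.
#'   Multi-mapping reads (equal best score at two circular loci) are
#'   discarded as ambiguous.
#' @export
map_reads <- function(reads, reference, params = mapping_params(),
                      keep_all = FALSE) {
  stopifnot(inherits(reference, "mito_reference"))
  if (nrow(reads) == 0L) {
    warning("empty read set: empty mapping returned")
    aln <- data.frame(id = character(), mate = integer(), pos = integer(),
                      strand = character(), cigar = character(),
                      seq = character(), qual = character(),
                      score = integer(), length_fraction = numeric(),
                      similarity_fraction = numeric(),
                      accepted = logical(), status = character(),
                      stringsAsFactors = FALSE)
    return(structure(list(ref_name = reference$name, L = reference$length,
                          alignments = aln,
                          stats = c(input = 0L, accepted = 0L,
                                    rejected = 0L, ambiguous = 0L,
                                    unmapped = 0L)),
                     class = "mito_mapping"))
  }
  res <- cpp_map_reads(reads$seq, reads$qual, reference$seq,
                       reference$circular,
                       params$length_fraction, params$similarity_fraction)
  status <- c("accepted", "rejected", "ambiguous",
              "unmapped")[res$status + 1L]
  aln <- data.frame(id = reads$id, mate = reads$mate, pos = res$pos,
                    strand = res$strand, cigar = res$cigar,
                    seq = res$seq, qual = res$qual, score = res$score,
                    length_fraction = res$length_fraction,
                    similarity_fraction = res$similarity_fraction,
                    accepted = res$status == 0L, status = status,
                    stringsAsFactors = FALSE)
  stats <- c(input = nrow(reads),
             accepted = sum(res$status == 0L),
             rejected = sum(res$status == 1L),
             ambiguous = sum(res$status == 2L),
             unmapped = sum(res$status == 3L))
  if (!keep_all) aln <- aln[aln$accepted, , drop = FALSE]
  rownames(aln) <- NULL
  structure(list(ref_name = reference$name, L = reference$length,
                 alignments = aln, stats = stats),
            class = "mito_mapping")
}

#' @export
print.mito_mapping <- function(x, ...) {
  cat(sprintf("<mito_mapping> vs %s (%d bp): %d/%d reads accepted\n",
              x$ref_name, x$L, x$stats[["accepted"]], x$stats[["input"]]))
  invisible(x)
}

#' Majority consensus sequence from a mapping
#'
#' Per-position majority base over all aligned bases (no quality
#' filtering); positions with zero coverage fall back to the reference
#' base, as do exact ties (deterministic, reference-stable).  The consensus
#' is substitution-only: indels are not incorporated, so consensus
#' coordinates stay aligned with the reference.
#'
#' @param mapping a `mito_mapping`.
#' @param reference the [mito_reference()] the mapping is anchored to.
#' @return Base string of length `reference$length`.
#' @export
build_consensus <- function(mapping, reference) {
  if (nrow(mapping$alignments) == 0L) stop("cannot build consensus from an empty mapping")
  a <- mapping$alignments
  p <- cpp_pileup(a$pos, a$strand, a$cigar, a$seq, a$qual, mapping$L,
                  radius = 0L, minq = 0L)
  counts <- p$counts[, 1:4, drop = FALSE]
  refch <- strsplit(reference$seq, "")[[1]]
  refidx <- match(refch, c("A", "C", "G", "T"))
  best <- max.col(counts, ties.method = "first")
  mx <- counts[cbind(seq_len(nrow(counts)), best)]
  refcnt <- counts[cbind(seq_len(nrow(counts)), refidx)]
  # zero coverage or reference base ties the maximum -> reference base
  usedref <- mx == 0L | refcnt == mx
  out <- ifelse(usedref, refch, c("A", "C", "G", "T")[best])
  paste(out, collapse = "")
}

#' Consensus mapping workflow
#'
#' Three stages: (1) permissive map of all reads to the circular reference;
#' (2) majority consensus and stringent remap of all reads to that
#' consensus -- reads dissimilar to the sample haplotype (e.g. NUMT reads)
#' fail here; (3) realignment of the surviving reads to the reference for
#' variant calling.  Output alignments are in reference coordinates.
#'
#' @param reads data.frame read set.
#' @param reference a [mito_reference()].
#' @param params_default permissive parameters (first pass and realign).
#' @param params_strict stringent parameters (consensus remap).
#' @return List of class `consensus_result`: `first_pass` mapping,
#'   `consensus` sequence, `final` mapping (rCRS-anchored), `stats`.
#' @export
consensus_workflow <- function(reads, reference,
                               params_default = mapping_params(0.5, 0.8),
                               params_strict = mapping_params(0.95, 0.95)) {
  first <- map_reads(reads, reference, params_default)
  if (nrow(first$alignments) == 0L) {
    stop("consensus build failure: first-pass mapping is empty")
  }
  cons <- build_consensus(first, reference)
  cons_ref <- structure(list(name = "consensus", seq = cons,
                             length = nchar(cons),
                             circular = reference$circular),
                        class = "mito_reference")
  strict <- map_reads(reads, cons_ref, params_strict)
  keep <- paste(strict$alignments$id, strict$alignments$mate)
  surviving <- reads[paste(reads$id, reads$mate) %in% keep, , drop = FALSE]
  final <- map_reads(surviving, reference, params_default)
  structure(list(first_pass = first, consensus = cons, final = final,
                 stats = list(first = first$stats, strict = strict$stats,
                              final = final$stats)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result> first pass %d accepted; strict remap %d; final %d\n",
    x$first_pass$stats[["accepted"]], x$stats$strict[["accepted"]],
    x$final$stats[["accepted"]]))
  invisible(x)
}

# ---- SAM I/O -------------------------------------------------------------

#' Write a mapping as SAM
#'
#' Minimal single-reference SAM export.  Alignments that wrap the circular
#' origin keep their full CIGAR and a `ZC:i:1` tag (their reference span
#' extends past `L` and re-enters at position 1).
#'
#' @param mapping a `mito_mapping`.
#' @param path output SAM path.
#' @export
write_sam <- function(mapping, path) {
  a <- mapping$alignments
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", mapping$ref_name, mapping$L)),
             con)
  if (nrow(a) > 0L) {
    reflen <- vapply(a$cigar, function(cg) {
      ops <- regmatches(cg, gregexpr("[0-9]+[MIDS]", cg))[[1]]
      sum(as.integer(sub("[MIDS]", "", ops[grepl("[MD]", ops)])))
    }, numeric(1), USE.NAMES = FALSE)
    wraps <- a$pos + reflen - 1L > mapping$L
    flag <- ifelse(a$strand == "-", 16L, 0L) +
      ifelse(a$mate == 2L, 128L + 1L, ifelse(a$mate == 1L, 64L + 1L, 0L))
    lines <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s%s",
                     a$id, flag, mapping$ref_name, a$pos, a$cigar,
                     a$seq, a$qual, ifelse(wraps, "\tZC:i:1", ""))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read reads from a SAM file
#'
#' Extracts read sequences/qualities (re-orienting reverse-strand records)
#' so pre-aligned mtDNA reads can enter the pipeline as a read set.
#'
#' @param path SAM path.
#' @return data.frame read set (`id`, `mate`, `seq`, `qual`).
#' @export
read_sam <- function(path) {
  x <- readLines(path)
  x <- x[!startsWith(x, "@")]
  f <- strsplit(x, "\t")
  id <- vapply(f, `[[`, character(1), 1L)
  flag <- as.integer(vapply(f, `[[`, character(1), 2L))
  seq <- vapply(f, `[[`, character(1), 10L)
  qual <- vapply(f, `[[`, character(1), 11L)
  rev <- bitwAnd(flag, 16L) > 0L
  seq[rev] <- revcomp_chr(seq[rev])
  qual[rev] <- vapply(strsplit(qual[rev], ""), function(q) {
    paste(rev(q), collapse = "")
  }, character(1))
  mate <- ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)
  out <- data.frame(id = id, mate = mate, seq = toupper(seq), qual = qual,
                    stringsAsFactors = FALSE)
  out[qual != "*" | TRUE, , drop = FALSE]
}
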