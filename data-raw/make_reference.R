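# Builds the bundled synthetic rCRS-like mitochondrial reference.
#
# The packaged reference is SYNTHETIC: a 16,569-bp circular sequence with
# human-mtDNA base composition and the canonical control-region /
# signature-region landmark motifs placed at their true rCRS coordinates,
# so that every coordinate-anchored rule in the package (homopolymer
# stretches, artifact zones, hotspot and signature positions) behaves as it
# would on the real reference.  It is NOT the NC_012920.1 sequence; users
# analysing real data should supply the genuine rCRS FASTA instead.
#
# Run from the package root:  Rscript data-raw/make_reference.R

L <- 16569L
set.seed(16569)
# human mtDNA heavy-strand base composition
bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c(0.309, 0.313, 0.131, 0.247))

put <- function(pos, s) {
  s <- strsplit(s, "")[[1]]
  bases[pos + seq_along(s) - 1L] <<- s
}

# HVS2: A-stretch 300-302 then C-stretch 303-315 interrupted by T310
put(295, "C")
put(296, "C")
put(299, "C")            # bounds the A-run on the 5' side
put(300, "AAA")          # A-stretch preceding the HVS2 C-stretch
put(303, "CCCCCCC")      # nps 303-309
put(310, "T")
put(311, "CCCCC")        # nps 311-315
put(316, "G")

# HVS1: A-stretch 16180-16183 then C-stretch 16184-16193 with T16189
put(16179, "C")
put(16180, "AAAA")
put(16184, "CCCCC")
put(16189, "T")
put(16190, "CCCC")
put(16194, "A")

# small coding-region C-stretch noted at nps 956-960
put(955, "A")
put(956, "CCCCC")
put(961, "T")

# hotspot / worked-example reference bases
landmarks <- c(
  "73" = "A", "146" = "T", "150" = "C", "152" = "T", "195" = "T",
  "204" = "T", "263" = "A", "2887" = "C", "4155" = "C", "4917" = "A",
  "5054" = "G", "5147" = "G", "11386" = "T", "12285" = "T", "14905" = "G",
  "16093" = "T", "16129" = "G", "16192" = "C", "16311" = "T", "16354" = "C",
  # NUMT signature reference bases (ND5 and HVS1 clusters)
  "12612" = "C", "12684" = "G", "12705" = "C",
  "13062" = "A", "13095" = "T", "13105" = "A",
  "16390" = "G", "16399" = "A", "16444" = "C",
  "16496" = "G", "16519" = "T", "16527" = "C"
)
for (p in names(landmarks)) put(as.integer(p), landmarks[[p]])

seq <- paste(bases, collapse = "")
stopifnot(nchar(seq) == L)

out <- file.path("inst", "extdata", "rCRS_synthetic.fa")
lines <- c(
  ">rCRS_synthetic synthetic 16569-bp circular mitochondrial reference (rCRS-like landmark coordinates; not NC_012920.1)",
  substring(seq, seq(1, L, 70), pmin(seq(1, L, 70) + 69, L))
)
writeLines(lines, out)
cat("wrote", out, "\n")
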