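# Generates inst/extdata/cytoBand_hg19_synthetic.txt, the bundled band table.
#
# Chromosome lengths are the exact GRCh37/hg19 reference lengths.
# The band-level layout is a generated schematic, NOT the UCSC database dump
# (hence "synthetic" in the filename): centromeres (acen pairs) sit at the
# approximate reference centromere positions; the large heterochromatin
# blocks (1q12, 9q12, 16q11.2, distal Yq) are gvar; the acrocentric p-arms
# (13, 14, 15, 21, 22) carry gvar heterochromatin with a light-blue-rendered
# ribosomal stalk band; all other arm territory alternates gneg with a cycle
# of gpos intensities in roughly ISCN-sized blocks.
#
# Run from the package root:  Rscript data-raw/make_builtin_cytoband.R

lengths_hg19 <- c(
  `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
  `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
  `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
  `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
  `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
  `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566
)

# acen spans (start of p-side acen band, end of q-side acen band), ~hg19
centromeres <- list(
  `1` = c(121500000, 128900000), `2` = c(90500000, 96800000),
  `3` = c(87900000, 93900000), `4` = c(48200000, 52700000),
  `5` = c(46100000, 50700000), `6` = c(58700000, 63300000),
  `7` = c(58000000, 61700000), `8` = c(43100000, 48100000),
  `9` = c(47300000, 50700000), `10` = c(38000000, 42300000),
  `11` = c(51600000, 55700000), `12` = c(33300000, 38200000),
  `13` = c(16300000, 19500000), `14` = c(16100000, 19100000),
  `15` = c(15800000, 20700000), `16` = c(34600000, 38600000),
  `17` = c(22200000, 25800000), `18` = c(15400000, 19000000),
  `19` = c(24400000, 28600000), `20` = c(25600000, 29400000),
  `21` = c(10900000, 14300000), `22` = c(12200000, 17900000),
  X = c(58100000, 63000000), Y = c(11600000, 13400000)
)

acrocentric <- c("13", "14", "15", "21", "22")
# gvar heterochromatin blocks adjoining the centromere / distal Yq
het_q <- list(`1` = 18e6, `9` = 18e6, `16` = 10e6)

gpos_cycle <- c("gpos25", "gpos100", "gpos50", "gpos75")

giemsa_arm <- function(chrom, lo, hi, arm, offset = 0L) {
  span <- hi - lo
  n <- max(1L, round(span / 12e6))
  cuts <- round(seq(lo, hi, length.out = n + 1L))
  cuts <- unique(cuts)
  k <- length(cuts) - 1L
  if (k < 1L) return(NULL)
  stains <- character(k)
  io <- seq(1L, k, by = 2L)
  stains[io] <- "gneg"
  ig <- setdiff(seq_len(k), io)
  if (length(ig)) stains[ig] <- gpos_cycle[((seq_along(ig) - 1L) %% 4L) + 1L]
  data.frame(chrom = chrom, start = cuts[-length(cuts)], end = cuts[-1],
             name = paste0(arm, seq_len(k) + offset), stain = stains,
             stringsAsFactors = FALSE)
}

rows <- list()
for (ch in names(lengths_hg19)) {
  L <- lengths_hg19[[ch]]
  cen <- centromeres[[ch]]
  mid <- round(mean(cen))
  if (ch %in% acrocentric) {
    stalk_lo <- round(cen[1] * 0.35)
    stalk_hi <- round(cen[1] * 0.60)
    p <- data.frame(
      chrom = ch,
      start = c(0, stalk_lo, stalk_hi),
      end = c(stalk_lo, stalk_hi, cen[1]),
      name = c("p13", "p12", "p11.2"),
      stain = c("gvar", "stalk", "gvar"),
      stringsAsFactors = FALSE
    )
  } else {
    p <- giemsa_arm(ch, 0, cen[1], "p")
  }
  acen <- data.frame(chrom = ch, start = c(cen[1], mid), end = c(mid, cen[2]),
                     name = c("p11.1", "q11.1"), stain = "acen",
                     stringsAsFactors = FALSE)
  q_lo <- cen[2]
  extra <- NULL
  if (ch %in% names(het_q)) {
    extra <- data.frame(chrom = ch, start = q_lo, end = q_lo + het_q[[ch]],
                        name = "q12", stain = "gvar", stringsAsFactors = FALSE)
    q_lo <- q_lo + het_q[[ch]]
  }
  if (ch == "Y") {
    yq_het <- round(L - 30e6)
    q <- rbind(giemsa_arm(ch, q_lo, yq_het, "q", offset = 10L),
               data.frame(chrom = ch, start = yq_het, end = L, name = "q12",
                          stain = "gvar", stringsAsFactors = FALSE))
  } else {
    q <- giemsa_arm(ch, q_lo, L, "q", offset = 10L)
  }
  rows[[ch]] <- rbind(p, acen, extra, q)
}

tab <- do.call(rbind, rows)
lines <- sprintf("chr%s\t%d\t%d\t%s\t%s",
                 tab$chrom, as.integer(tab$start), as.integer(tab$end),
                 tab$name, tab$stain)
writeLines(lines, file.path("inst", "extdata", "cytoBand_hg19_synthetic.txt"))
cat(sprintf("wrote %d bands\n", length(lines)))
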