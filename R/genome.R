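# Genome coordinate model: chromosomes, centromeres, cytogenetic bands.
#
# Internal convention is the UCSC one: band intervals are 0-based, half-open.
# User-facing positions (the annotation file) are 1-based inclusive and are
# converted on ingest by the input parser.

#' Canonical human chromosome labels, in karyotype order
#'
#' The 22 autosomes followed by X and Y, without any "chr" prefix.
#'
#' @format Character vector of length 24.
#' @export
CHROMOSOMES <- c(as.character(1:22), "X", "Y")

#' Recognized Giemsa stain classes
#'
#' The gieStain vocabulary of UCSC cytoBand files: negative (R-band),
#' four positive intensities (G-bands), centromere, variable-region
#' heterochromatin, and ribosomal-RNA stalk.
#'
#' @format Character vector of length 8.
#' @export
STAINS <- c("gneg", "gpos25", "gpos50", "gpos75", "gpos100",
            "acen", "gvar", "stalk")

new_cytobands <- function(chrom, start_bp, end_bp, band_name, stain) {
  df <- data.frame(
    chrom = as.character(chrom),
    start_bp = as.numeric(start_bp),
    end_bp = as.numeric(end_bp),
    band_name = as.character(band_name),
    stain = as.character(stain),
    stringsAsFactors = FALSE
  )
  class(df) <- c("cytobands", "data.frame")
  df
}

chrom_rank <- function(chrom) match(chrom, CHROMOSOMES)

#' Parse cytogenetic bands in UCSC cytoBand format
#'
#' Reads the five-column UCSC cytoBand dialect (`chrom`, `chromStart`,
#' `chromEnd`, `name`, `gieStain`, tab-separated, "chr"-prefixed chromosome
#' names). Bands on chromosomes other than 1-22, X, Y (mitochondrion, random
#' and alternate contigs) are silently skipped, as real UCSC dumps contain
#' them. Coordinates are kept 0-based, half-open.
#'
#' @param lines Character vector, one cytoBand line per element.
#' @return A `cytobands` data frame with columns `chrom`, `start_bp`,
#'   `end_bp`, `band_name`, `stain`, sorted by chromosome then start.
#' @seealso [read_cytoband()] to read from a (possibly gzipped) file,
#'   [build_genome()] to assemble a genome from the result.
#' @export
#' @examples
#' parse_cytoband("chr1\t0\t2300000\tp36.33\tgneg")
parse_cytoband <- function(lines) {
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- fields[[i]]
    if (length(f) != 5L) {
      parse_error("cytoband line %d: expected 5 tab-separated fields, got %d",
                  i, length(f))
    }
    chrom <- sub("^chr", "", f[1])
    if (!chrom %in% CHROMOSOMES) next   # chrM, *_random, alt contigs
    start_bp <- suppressWarnings(as.numeric(f[2]))
    end_bp <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start_bp) || is.na(end_bp) ||
        start_bp != floor(start_bp) || end_bp != floor(end_bp)) {
      parse_error("cytoband line %d: non-integer coordinates '%s', '%s'",
                  i, f[2], f[3])
    }
    if (start_bp < 0 || end_bp <= start_bp) {
      parse_error("cytoband line %d: invalid interval [%s, %s)", i, f[2], f[3])
    }
    if (!f[5] %in% STAINS) {
      parse_error("cytoband line %d: unknown stain '%s'", i, f[5])
    }
    out[[i]] <- list(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                     band_name = f[4], stain = f[5])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(new_cytobands(character(), numeric(), numeric(),
                         character(), character()))
  }
  df <- new_cytobands(
    vapply(out, `[[`, "", "chrom"),
    vapply(out, `[[`, 0, "start_bp"),
    vapply(out, `[[`, 0, "end_bp"),
    vapply(out, `[[`, "", "band_name"),
    vapply(out, `[[`, "", "stain")
  )
  df <- df[order(chrom_rank(df$chrom), df$start_bp), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cytobands", "data.frame")
  df
}

#' Read a UCSC cytoBand file
#'
#' @param path Path to a cytoBand file, optionally gzip-compressed.
#' @return A `cytobands` data frame; see [parse_cytoband()].
#' @export
read_cytoband <- function(path) {
  if (!file.exists(path)) config_error("cytoband file not found: %s", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  parse_cytoband(readLines(con, warn = FALSE))
}

#' Serialize cytogenetic bands back to UCSC cytoBand lines
#'
#' Inverse of [parse_cytoband()]: `parse_cytoband(serialize_cytoband(x))` is
#' the identity for any valid band table.
#'
#' @param bands A `cytobands` data frame.
#' @return Character vector of tab-separated, "chr"-prefixed lines.
#' @export
serialize_cytoband <- function(bands) {
  sprintf("chr%s\t%d\t%d\t%s\t%s",
          bands$chrom, as.integer(bands$start_bp), as.integer(bands$end_bp),
          bands$band_name, bands$stain)
}

#' Assemble a genome from cytogenetic bands
#'
#' Chromosome length is the end of its last band; the centromere span is the
#' union of its `acen` bands. Every chromosome with bands must carry at least
#' one `acen` band.
#'
#' @param bands A non-empty `cytobands` data frame (see [parse_cytoband()]).
#' @return A `genome_assembly`: list with `chromosomes` (data frame `name`,
#'   `length_bp`, `centromere_start_bp`, `centromere_end_bp`, in karyotype
#'   order) and `bands` (the input, sorted).
#' @export
build_genome <- function(bands) {
  if (!inherits(bands, "data.frame") || nrow(bands) == 0L) {
    data_error("cannot build a genome from an empty band list")
  }
  bands <- bands[order(chrom_rank(bands$chrom), bands$start_bp), , drop = FALSE]
  rownames(bands) <- NULL
  present <- CHROMOSOMES[CHROMOSOMES %in% unique(bands$chrom)]
  chroms <- lapply(present, function(ch) {
    b <- bands[bands$chrom == ch, , drop = FALSE]
    if (any(b$end_bp[-nrow(b)] > b$start_bp[-1])) {
      data_error("chromosome %s: overlapping cytogenetic bands", ch)
    }
    acen <- b[b$stain == "acen", , drop = FALSE]
    if (nrow(acen) == 0L) {
      data_error("chromosome %s has bands but no acen (centromere) band", ch)
    }
    data.frame(name = ch, length_bp = max(b$end_bp),
               centromere_start_bp = min(acen$start_bp),
               centromere_end_bp = max(acen$end_bp),
               stringsAsFactors = FALSE)
  })
  genome <- list(chromosomes = do.call(rbind, chroms), bands = bands)
  class(genome) <- "genome_assembly"
  genome
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %d chromosomes, %d cytogenetic bands\n",
              nrow(x$chromosomes), nrow(x$bands)))
  invisible(x)
}

chromosome_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  genome$chromosomes$length_bp[i]
}

builtin_cache <- new.env(parent = emptyenv())

#' The bundled human (hg19-style) genome
#'
#' Returns a 24-chromosome human genome assembly built from the band table
#' shipped with the package. Chromosome lengths are the GRCh37/hg19 reference
#' lengths. The band-level layout is a synthetic schematic (the file is
#' generated, not the UCSC database dump): centromeres sit at the reference
#' centromere positions, pericentric and Yq heterochromatin and the
#' ribosomal-RNA stalks of the acrocentric p-arms (13, 14, 15, 21, 22) are in
#' place, and arms carry alternating R-band/G-band patterns.
#'
#' @return A `genome_assembly` with 24 chromosomes.
#' @export
builtin_genome <- function() {
  if (!is.null(builtin_cache$genome)) return(builtin_cache$genome)
  path <- system.file("extdata", "cytoBand_hg19_synthetic.txt",
                      package = "chromoglyph")
  if (!nzchar(path)) {
    config_error("bundled cytoband file is missing from the installation")
  }
  genome <- build_genome(read_cytoband(path))
  if (nrow(genome$chromosomes) != 24L) {
    config_error("bundled cytoband file is corrupt: %d chromosomes, expected 24",
                 nrow(genome$chromosomes))
  }
  builtin_cache$genome <- genome
  genome
}

#' Generate a small synthetic genome for tests and examples
#'
#' Builds `n_chrom` chromosomes of identical length, each with a centromere
#' near the middle and a seeded alternating gneg/gpos band pattern.
#' Deterministic for a fixed seed.
#'
#' @param n_chrom Number of chromosomes (at most 24; named "1", "2", ...).
#' @param length_bp Length of every chromosome, in base pairs.
#' @param seed Integer seed controlling band boundaries.
#' @return A `genome_assembly`.
#' @export
synthetic_genome <- function(n_chrom, length_bp, seed = 7L) {
  stopifnot(n_chrom >= 1, length_bp >= 20)
  if (n_chrom > 24) data_error("synthetic_genome supports at most 24 chromosomes")
  with_rng_seed(seed, {
    per_chrom <- lapply(CHROMOSOMES[seq_len(n_chrom)], function(ch) {
      cen_mid <- round(length_bp * stats::runif(1, 0.40, 0.60))
      cen_half <- max(1, round(length_bp * 0.02))
      cen <- c(max(1, cen_mid - cen_half), min(length_bp - 1, cen_mid + cen_half))
      arm_bands <- function(lo, hi, arm) {
        n_b <- max(1L, round((hi - lo) / length_bp * 8))
        cuts <- unique(round(seq(lo, hi, length.out = n_b + 1L)))
        k <- length(cuts) - 1L
        data.frame(chrom = ch, start_bp = cuts[-length(cuts)], end_bp = cuts[-1],
                   band_name = paste0(arm, seq_len(k)),
                   stain = rep(c("gneg", sample(c("gpos25", "gpos50",
                                                  "gpos75", "gpos100"), 1)),
                               length.out = k),
                   stringsAsFactors = FALSE)
      }
      rbind(
        arm_bands(0, cen[1], "p"),
        data.frame(chrom = ch, start_bp = c(cen[1], cen_mid),
                   end_bp = c(cen_mid, cen[2]),
                   band_name = c("p11", "q11"), stain = "acen",
                   stringsAsFactors = FALSE),
        arm_bands(cen[2], length_bp, "q")
      )
    })
    df <- do.call(rbind, per_chrom)
    class(df) <- c("cytobands", "data.frame")
    build_genome(df)
  })
}
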