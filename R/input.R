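# Annotation-file ingestion.
#
# The input is a single tab-delimited file whose first line is a header.
# Recognized columns (case-insensitive): CHR and POS (required), END,
# PHENOTYPE, NOTE (synonym ANNOTATION), ETHNICITY (synonym ANCESTRY), GROUP,
# POSCOLOR. Unrecognized columns are ignored with a warning. Invalid rows are
# fatal — silently dropping rows from a plotting tool misleads — and every
# error names the offending line.

COLUMN_SYNONYMS <- c(
  CHR = "CHR", POS = "POS", END = "END", PHENOTYPE = "PHENOTYPE",
  NOTE = "NOTE", ANNOTATION = "NOTE",
  ETHNICITY = "ETHNICITY", ANCESTRY = "ETHNICITY",
  GROUP = "GROUP", POSCOLOR = "POSCOLOR"
)

#' Maximum length of a NOTE annotation, in characters
#' @export
NOTE_MAX_CHARS <- 10L

normalize_chrom <- function(x) {
  x <- sub("^chr", "", trimws(x), ignore.case = TRUE)
  toupper(x)
}

parse_count <- function(x, what, line_no) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || v != floor(v)) {
    data_error("line %d: %s must be an integer, got '%s'", line_no, what, x)
  }
  v
}

#' Truncate an annotation note to the 10-character limit
#'
#' Notes longer than [NOTE_MAX_CHARS] characters are cut to the first 10
#' characters (counting characters, not bytes) with a warning.
#'
#' @param text Character vector of notes.
#' @return The truncated notes.
#' @export
#' @examples
#' truncate_note("MHC")
truncate_note <- function(text) {
  too_long <- !is.na(text) & nchar(text, type = "chars") > NOTE_MAX_CHARS
  if (any(too_long)) {
    warning(sprintf("%d note(s) longer than %d characters were truncated",
                    sum(too_long), NOTE_MAX_CHARS), call. = FALSE)
    text[too_long] <- substr(text[too_long], 1L, NOTE_MAX_CHARS)
  }
  text
}

#' Parse a tab-delimited annotation file
#'
#' @param lines Character vector of file lines; the first is the header.
#' @return A `parsed_input` list: `records` (data frame with columns `chrom`,
#'   `pos_bp`, `end_bp`, `phenotype`, `note`, `ancestry`, `group`, `poscolor`,
#'   `line_no`; optional cells are `NA`), `present_columns` (canonical names
#'   of the recognized columns found), and `warnings` (character).
#' @details Positions are 1-based inclusive; chromosome labels accept an
#'   optional "chr" prefix and are normalized to bare `1`-`22`, `X`, `Y`.
#'   A missing CHR or POS column, a malformed coordinate, `END < POS`, a
#'   POSCOLOR outside 0-7, or an unknown chromosome label is a fatal error
#'   naming the line.
#' @export
parse_input <- function(lines) {
  if (length(lines) == 0L || !nzchar(trimws(lines[1]))) {
    data_error("input is empty: expected a tab-separated header line")
  }
  warnings <- character()
  header <- toupper(trimws(strsplit(lines[1], "\t", fixed = TRUE)[[1]]))
  canonical <- unname(COLUMN_SYNONYMS[header])
  unknown <- header[is.na(canonical)]
  if (length(unknown)) {
    warnings <- c(warnings, sprintf("ignoring unrecognized column '%s'", unknown))
  }
  if (anyDuplicated(canonical[!is.na(canonical)])) {
    data_error("duplicate input column: %s",
               paste(canonical[duplicated(canonical)], collapse = ", "))
  }
  for (req in c("CHR", "POS")) {
    if (!req %in% canonical) data_error("missing required column %s", req)
  }
  col_of <- function(name) match(name, canonical)

  body <- which(seq_along(lines) > 1L & nzchar(trimws(lines)))
  n <- length(body)
  rec <- data.frame(
    chrom = character(n), pos_bp = numeric(n), end_bp = rep(NA_real_, n),
    phenotype = rep(NA_character_, n), note = rep(NA_character_, n),
    ancestry = rep(NA_character_, n), group = rep(NA_character_, n),
    poscolor = rep(NA_integer_, n), line_no = integer(n),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(n)) {
    line_no <- body[k]
    f <- strsplit(lines[line_no], "\t", fixed = TRUE)[[1]]
    cell <- function(name) {
      i <- col_of(name)
      if (is.na(i) || i > length(f)) return(NA_character_)
      v <- trimws(f[i])
      if (nzchar(v)) v else NA_character_
    }
    chrom <- cell("CHR")
    if (is.na(chrom)) data_error("line %d: empty CHR cell", line_no)
    chrom <- normalize_chrom(chrom)
    if (!chrom %in% CHROMOSOMES) {
      data_error("line %d: unknown chromosome label '%s'", line_no, chrom)
    }
    pos_cell <- cell("POS")
    if (is.na(pos_cell)) data_error("line %d: empty POS cell", line_no)
    pos <- parse_count(pos_cell, "POS", line_no)
    if (pos < 1) data_error("line %d: POS must be >= 1", line_no)
    end_cell <- cell("END")
    end <- NA_real_
    if (!is.na(end_cell)) {
      end <- parse_count(end_cell, "END", line_no)
      if (end < pos) data_error("line %d: END (%s) < POS (%s)",
                                line_no, end_cell, pos_cell)
    }
    pc_cell <- cell("POSCOLOR")
    pc <- NA_integer_
    if (!is.na(pc_cell)) {
      pc <- parse_count(pc_cell, "POSCOLOR", line_no)
      if (pc < 0 || pc > 7) {
        data_error("line %d: POSCOLOR must be an integer 0-7, got %s",
                   line_no, pc_cell)
      }
      pc <- as.integer(pc)
    }
    note <- cell("NOTE")
    if (!is.na(note) && nchar(note, type = "chars") > NOTE_MAX_CHARS) {
      warnings <- c(warnings,
                    sprintf("line %d: note truncated to %d characters",
                            line_no, NOTE_MAX_CHARS))
      note <- substr(note, 1L, NOTE_MAX_CHARS)
    }
    rec$chrom[k] <- chrom
    rec$pos_bp[k] <- pos
    rec$end_bp[k] <- end
    rec$phenotype[k] <- cell("PHENOTYPE")
    rec$note[k] <- note
    rec$ancestry[k] <- cell("ETHNICITY")
    rec$group[k] <- cell("GROUP")
    rec$poscolor[k] <- pc
    rec$line_no[k] <- line_no
  }
  out <- list(
    records = rec,
    present_columns = sort(unique(canonical[!is.na(canonical)])),
    warnings = warnings
  )
  class(out) <- "parsed_input"
  out
}

#' Read and parse an annotation file from disk
#'
#' @param path Path to the tab-delimited annotation file (UTF-8).
#' @return A `parsed_input`; see [parse_input()].
#' @export
read_input <- function(path) {
  if (!file.exists(path)) data_error("input file not found: %s", path)
  parse_input(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' @export
print.parsed_input <- function(x, ...) {
  cat(sprintf("<parsed_input> %d records, columns: %s\n",
              nrow(x$records), paste(x$present_columns, collapse = ", ")))
  if (length(x$warnings)) cat(" warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Check parsed records against a genome assembly
#'
#' Every record must name a chromosome present in the genome, with `pos_bp`
#' (and `end_bp`, when present) within the chromosome length. Passing records
#' are returned unchanged; any violation is a fatal error naming the line and
#' the chromosome length.
#'
#' @param records Data frame of records from [parse_input()].
#' @param genome A `genome_assembly`.
#' @return `records`, unchanged.
#' @export
validate_against_genome <- function(records, genome) {
  for (k in seq_len(nrow(records))) {
    ch <- records$chrom[k]
    len <- chromosome_length(genome, ch)
    if (is.na(len)) {
      data_error("line %d: chromosome %s is not in the genome",
                 records$line_no[k], ch)
    }
    if (records$pos_bp[k] > len) {
      data_error("line %d: POS %.0f exceeds chromosome %s length (%.0f bp)",
                 records$line_no[k], records$pos_bp[k], ch, len)
    }
    if (!is.na(records$end_bp[k]) && records$end_bp[k] > len) {
      data_error("line %d: END %.0f exceeds chromosome %s length (%.0f bp)",
                 records$line_no[k], records$end_bp[k], ch, len)
    }
  }
  records
}
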