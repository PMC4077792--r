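IUPAC_NT <- c("A", "C", "G", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Construct a table of sequence records
#'
#' A sequence record is one ungapped nucleotide sequence with an identifier,
#' an optional taxon, and a class label. Record tables are plain data frames
#' with columns `id`, `taxon`, `region` and `residues` so that they compose
#' with ordinary data-manipulation code.
#'
#' @param id character vector of unique identifiers.
#' @param residues character vector of sequences over the RNA alphabet
#'   (`T` is mapped to `U`, case is folded to upper).
#' @param taxon optional character vector of taxon names.
#' @param region class label per sequence: one of `"ITS1"`, `"ITS2"`,
#'   `"RANDOM"`, `"SYNTH"`, or `NA`.
#' @return data frame with one row per record.
#' @export
sequence_records <- function(id, residues, taxon = NA_character_,
                             region = NA_character_) {
  residues <- normalize_residues(residues, degap = FALSE)
  if (any(!nzchar(residues)))
    stop("empty residues for record(s): ",
         paste(id[!nzchar(residues)], collapse = ", "))
  bad <- vapply(strsplit(residues, ""), function(ch) any(!ch %in% IUPAC_NT),
                logical(1))
  if (any(bad))
    stop("non-IUPAC residues in record(s): ", paste(id[bad], collapse = ", "))
  region <- rep_len(as.character(region), length(id))
  ok <- is.na(region) | region %in% c("ITS1", "ITS2", "RANDOM", "SYNTH")
  if (any(!ok)) stop("invalid region label: ", paste(unique(region[!ok]), collapse = ", "))
  data.frame(id = as.character(id),
             taxon = rep_len(as.character(taxon), length(id)),
             region = region,
             residues = residues,
             stringsAsFactors = FALSE)
}

#' @rdname sequence_records
#' @param x character vector of raw sequences.
#' @param degap drop alignment gap characters (`-`, `.`)?
#' @export
normalize_residues <- function(x, degap = TRUE) {
  x <- toupper(x)
  if (degap) x <- gsub("[-.]", "", x)
  gsub("T", "U", x, fixed = TRUE)
}

# accept either a record row or a bare string wherever one sequence is needed
as_seq_record <- function(seq, id = "seq") {
  if (is.character(seq) && length(seq) == 1)
    return(sequence_records(id, seq))
  if (is.data.frame(seq) && all(c("id", "residues") %in% names(seq))) {
    if (nrow(seq) != 1) stop("expected a single sequence record")
    return(seq)
  }
  stop("expected a sequence string or a one-row record table")
}

#' Read and write FASTA sequence files
#'
#' `read_fasta()` reads records, optionally removing alignment gaps, mapping
#' `T` to `U` and folding case; any residue outside the IUPAC nucleotide
#' alphabet is rejected with the offending record named. The taxon field is
#' taken from the FASTA description after the first whitespace, when present.
#'
#' @param path FASTA file.
#' @param degap remove `-` and `.` characters (alignment input)?
#' @param region optional region label applied to all records.
#' @return `read_fasta()`: a record table (see [sequence_records()]).
#' @export
read_fasta <- function(path, degap = TRUE, region = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0)
    return(sequence_records(character(0), character(0)))
  nm <- names(ss)
  id <- sub("\\s.*$", "", nm)
  taxon <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), NA_character_)
  res <- normalize_residues(as.character(ss), degap = degap)
  sequence_records(id, res, taxon = taxon, region = region)
}

#' @rdname read_fasta
#' @param records a record table.
#' @param width line width for wrapped sequence lines.
#' @return `write_fasta()`: the path, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    hdr <- records$id[k]
    if (!is.na(records$taxon[k])) hdr <- paste(hdr, records$taxon[k])
    writeLines(paste0(">", hdr), con)
    res <- records$residues[k]
    starts <- seq(1, nchar(res), by = width)
    writeLines(substring(res, starts, pmin(starts + width - 1, nchar(res))), con)
  }
  invisible(path)
}

#' Secondary structure objects
#'
#' A secondary structure is a pseudoknot-free set of base pairs on one
#' sequence plus its free energy (kcal/mol). Pairs are stored as a two-column
#' integer matrix of 1-based positions with `i < j`; validity (involution,
#' minimum hairpin loop of 3 unpaired bases, no crossing pairs) is enforced
#' at construction.
#'
#' @param pairs two-column integer matrix of paired positions (may have zero
#'   rows for the open chain).
#' @param length sequence length (nt).
#' @param seq_id identifier of the folded sequence.
#' @param energy free energy in kcal/mol (`NA` when not scored).
#' @return an object of class `secondary_structure`.
#' @export
secondary_structure <- function(pairs, length, seq_id = "seq",
                                energy = NA_real_) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  validate_pairs(pairs, length)
  if (nrow(pairs) > 1) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(seq_id = seq_id, length = as.integer(length),
                 pairs = pairs, energy = energy),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("secondary structure of %s (%d nt): %d pairs, energy %s\n",
              x$seq_id, x$length, nrow(x$pairs),
              ifelse(is.na(x$energy), "NA", sprintf("%.1f kcal/mol", x$energy))))
  invisible(x)
}

#' @rdname secondary_structure
#' @param min_hairpin minimum unpaired bases enclosed by a pair.
#' @export
validate_pairs <- function(pairs, length, min_hairpin = 3) {
  if (nrow(pairs) == 0) return(invisible(TRUE))
  if (any(is.na(pairs)) || any(pairs < 1) || any(pairs > length))
    stop("pair index out of range")
  if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy i < j")
  idx <- c(pairs[, 1], pairs[, 2])
  if (anyDuplicated(idx)) stop("a position occurs in more than one pair")
  if (any(pairs[, 2] - pairs[, 1] - 1 < min_hairpin))
    stop("hairpin loop shorter than ", min_hairpin, " unpaired bases")
  # crossing check: i < i' < j < j' forbidden
  if (nrow(pairs) > 1) {
    o <- order(pairs[, 1])
    pi <- pairs[o, 1]; pj <- pairs[o, 2]
    open <- integer(0)
    pos <- sort(unique(c(pi, pj)))
    stack <- integer(0)
    for (p in pos) {
      if (p %in% pi) stack <- c(stack, pj[match(p, pi)])
      else {
        if (length(stack) == 0 || stack[length(stack)] != p)
          stop("crossing pairs (pseudoknot) not allowed")
        stack <- stack[-length(stack)]
      }
    }
  }
  invisible(TRUE)
}

# full-length pairing partner table; 0 = unpaired
pair_table <- function(pairs, length) {
  pt <- integer(length)
  if (nrow(pairs)) {
    pt[pairs[, 1]] <- pairs[, 2]
    pt[pairs[, 2]] <- pairs[, 1]
  }
  pt
}

#' Dot-bracket (Vienna) structure notation
#'
#' Matched parentheses denote base pairs, dots unpaired positions. Crossing
#' pairs cannot be serialized and are rejected by validation.
#'
#' @param pairs two-column matrix of 1-based pairs.
#' @param length sequence length.
#' @return `pairs_to_dotbracket()`: a string; `dotbracket_to_pairs()`: a
#'   two-column integer matrix.
#' @export
pairs_to_dotbracket <- function(pairs, length) {
  validate_pairs(pairs, length)
  db <- rep(".", length)
  db[pairs[, 1]] <- "("
  db[pairs[, 2]] <- ")"
  paste(db, collapse = "")
}

#' @rdname pairs_to_dotbracket
#' @param db dot-bracket string.
#' @export
dotbracket_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (any(!ch %in% c("(", ")", "."))) stop("invalid dot-bracket character")
  stack <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") stack <- c(stack, k)
    else if (ch[k] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket")
      pairs <- rbind(pairs, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket")
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Write and read structures as annotated dot-bracket files
#'
#' The on-disk form is three lines: a `>` header, the sequence, and the
#' dot-bracket string followed by the energy in parentheses.
#'
#' @param structure a [secondary_structure()].
#' @param record the matching one-row sequence record (or a string).
#' @param path output file.
#' @export
write_dotbracket <- function(structure, record, path) {
  rec <- as_seq_record(record, id = structure$seq_id)
  if (nchar(rec$residues) != structure$length)
    stop("sequence length does not match structure")
  db <- pairs_to_dotbracket(structure$pairs, structure$length)
  en <- if (is.na(structure$energy)) "" else sprintf(" (%.1f)", structure$energy)
  writeLines(c(paste0(">", structure$seq_id), rec$residues, paste0(db, en)),
             path)
  invisible(path)
}

#' @rdname write_dotbracket
#' @return `read_dotbracket()`: list with elements `record` and `structure`.
#' @export
read_dotbracket <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  if (length(ln) < 3 || !startsWith(ln[1], ">"))
    stop("malformed dot-bracket file: ", path)
  id <- sub("\\s.*$", "", substring(ln[1], 2))
  res <- normalize_residues(ln[2], degap = FALSE)
  m <- regmatches(ln[3], regexec("^([().]+)(?:\\s*\\((-?[0-9.]+)\\))?\\s*$", ln[3]))[[1]]
  if (length(m) == 0) stop("malformed structure line in ", path)
  db <- m[2]
  energy <- if (nchar(m[3])) as.numeric(m[3]) else NA_real_
  if (nchar(db) != nchar(res)) stop("structure and sequence length differ in ", path)
  list(record = sequence_records(id, res),
       structure = secondary_structure(dotbracket_to_pairs(db), nchar(res),
                                       seq_id = id, energy = energy))
}

#' Write and read structures in connectivity-table (CT) format
#'
#' CT is the exchange format used for cross-checks against external folding
#' programs: one row per base with 5'/3' neighbors and the pairing partner
#' (0 when unpaired).
#'
#' @inheritParams write_dotbracket
#' @export
write_ct <- function(structure, record, path) {
  rec <- as_seq_record(record, id = structure$seq_id)
  n <- structure$length
  if (nchar(rec$residues) != n) stop("sequence length does not match structure")
  pt <- pair_table(structure$pairs, n)
  en <- if (is.na(structure$energy)) "" else sprintf("  ENERGY = %.1f", structure$energy)
  hdr <- sprintf("%5d%s  %s", n, en, structure$seq_id)
  ch <- strsplit(rec$residues, "")[[1]]
  rows <- sprintf("%5d %s %7d %5d %5d %5d", seq_len(n), ch, seq_len(n) - 1L,
                  c(seq_len(n - 1) + 1L, 0L)[seq_len(n)], pt, seq_len(n))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ct
#' @return `read_ct()`: list with elements `record` and `structure`.
#' @export
read_ct <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  n <- as.integer(hdr[1])
  energy <- if (length(hdr) >= 4 && hdr[2] == "ENERGY") as.numeric(hdr[4]) else NA_real_
  id <- hdr[length(hdr)]
  body <- do.call(rbind, strsplit(trimws(ln[1 + seq_len(n)]), "\\s+"))
  res <- paste(body[, 2], collapse = "")
  part <- as.integer(body[, 5])
  keep <- part > seq_len(n)
  pairs <- cbind(seq_len(n)[keep], part[keep])
  list(record = sequence_records(id, res),
       structure = secondary_structure(pairs, n, seq_id = id, energy = energy))
}
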