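#' Sequence-plus-structure record
#'
#' A validated pairing of an \code{\link{rna_sequence}} with a set of
#' 1-based base pairs (i < j). Validation enforces index range, i != j, and
#' the one-partner-per-base rule.
#'
#' @param seq an \code{\link{rna_sequence}}
#' @param pairs two-column matrix (i, j), 1-based; zero rows allowed
#' @param id identifier; defaults to the sequence id
#' @return object of class \code{structure_record}
#' @export
structure_record <- function(seq, pairs, id = seq$id) {
  L <- length(seq)
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (nrow(pairs) > 0L) {
    if (any(pairs < 1L) || any(pairs > L)) stop("pair index outside [1, L]")
    if (any(pairs[, 1] == pairs[, 2])) stop("base paired with itself")
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, c(2, 1)]
    touched <- c(pairs)
    if (anyDuplicated(touched)) stop("a base appears in more than one pair")
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  structure(list(id = id, seq = seq, pairs = pairs),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("<structure_record> %s (L=%d, %d pairs)\n",
              x$id, length(x$seq), nrow(x$pairs)))
  invisible(x)
}

#' Contact map of a structure record
#'
#' @param record a \code{\link{structure_record}}
#' @return binary symmetric L x L matrix
#' @export
record_contact_map <- function(record) {
  pairs_to_contact(record$pairs, length(record$seq))
}

#' Read RNA sequences from a FASTA file
#'
#' Multi-record, uppercase-normalizing. With \code{dna_to_rna} (default),
#' T is rewritten to U before validation, so DNA-alphabet FASTA files are
#' accepted. Strict mode rejects records containing other non-ACGU
#' characters, naming the offending record.
#'
#' @param path FASTA file
#' @param dna_to_rna rewrite T to U
#' @param lenient tolerate IUPAC ambiguity codes (kept as N)
#' @return list of \code{\link{rna_sequence}} objects in file order
#' @export
read_fasta <- function(path, dna_to_rna = TRUE, lenient = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no FASTA records in '%s'", path))
  out <- vector("list", length(set))
  ids <- sub("\\s.*$", "", names(set))
  for (k in seq_along(set)) {
    s <- toupper(as.character(set[[k]]))
    if (dna_to_rna) s <- gsub("T", "U", s, fixed = TRUE)
    out[[k]] <- rna_sequence(s, id = ids[k], lenient = lenient)
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs list of \code{\link{rna_sequence}} (or a single one)
#' @param path output file
#' @return invisibly, the path
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s)
    c(paste0(">", s$id), paste(s$bases, collapse = ""))))
  writeLines(lines, path)
  invisible(path)
}

.read_structure_table <- function(path, ncol_body, skip_header) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= skip_header) stop(sprintf("'%s' has no body lines", path))
  header <- if (skip_header > 0L) lines[1L] else NULL
  body <- lines[(skip_header + 1L):length(lines)]
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < ncol_body))
    stop(sprintf("'%s': line with %d fields, expected %d",
                 path, min(nf), ncol_body))
  list(header = header, fields = fields)
}

.pairs_from_partner <- function(partner, path) {
  L <- length(partner)
  if (any(partner < 0L | partner > L)) stop(sprintf("'%s': pair index out of range", path))
  for (i in seq_len(L)) {
    j <- partner[i]
    if (j > 0L && partner[j] != i)
      stop(sprintf("'%s': asymmetric pairing (%d says %d but %d says %d)",
                   path, i, j, j, partner[j]))
    if (j == i) stop(sprintf("'%s': base %d paired with itself", path, i))
  }
  idx <- which(partner > seq_len(L))
  cbind(i = idx, j = partner[idx])
}

#' Read a CT-format structure file
#'
#' Standard 6-column CT body (index, base, previous, next, pair, index) under
#' a header line starting with the length; tolerant of energy annotations in
#' the header. Pair column 0 means unpaired. Validates contiguous indices
#' and symmetric pairing.
#'
#' @param path CT file
#' @param lenient passed to \code{\link{rna_sequence}}
#' @return a \code{\link{structure_record}}
#' @export
read_ct <- function(path, lenient = FALSE) {
  tab <- .read_structure_table(path, 6L, 1L)
  hdr <- strsplit(trimws(tab$header), "\\s+")[[1]]
  L <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(L)) stop(sprintf("'%s': CT header must start with the length", path))
  id <- if (length(hdr) > 1L) paste(hdr[-1], collapse = " ") else "ct_record"
  id <- sub("^ENERGY\\s*=\\s*\\S+\\s*", "", id)
  f <- tab$fields
  if (length(f) != L) stop(sprintf("'%s': header says %d bases, body has %d",
                                   path, L, length(f)))
  idxs <- as.integer(vapply(f, `[[`, "", 1L))
  if (!identical(idxs, seq_len(L))) stop(sprintf("'%s': index gaps in CT body", path))
  bases <- vapply(f, `[[`, "", 2L)
  partner <- as.integer(vapply(f, `[[`, "", 5L))
  seq <- rna_sequence(bases, id = id, lenient = lenient)
  structure_record(seq, .pairs_from_partner(partner, path), id = id)
}

#' Write a CT-format structure file
#'
#' @param record a \code{\link{structure_record}}
#' @param path output file
#' @return invisibly, the path
#' @export
write_ct <- function(record, path) {
  L <- length(record$seq)
  partner <- .partner_vector(record_contact_map(record))
  i <- seq_len(L)
  lines <- c(sprintf("%d %s", L, record$id),
             sprintf("%d %s %d %d %d %d",
                     i, record$seq$bases, i - 1L, ifelse(i == L, 0L, i + 1L),
                     partner, i))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BPSEQ-format structure file
#'
#' Three-column dialect (index, base, pair), no header; same validation as
#' \code{\link{read_ct}}.
#'
#' @param path BPSEQ file
#' @param id record identifier (BPSEQ has no header field for it)
#' @param lenient passed to \code{\link{rna_sequence}}
#' @return a \code{\link{structure_record}}
#' @export
read_bpseq <- function(path, id = NULL, lenient = FALSE) {
  tab <- .read_structure_table(path, 3L, 0L)
  f <- tab$fields
  L <- length(f)
  idxs <- as.integer(vapply(f, `[[`, "", 1L))
  if (!identical(idxs, seq_len(L))) stop(sprintf("'%s': index gaps in BPSEQ body", path))
  bases <- vapply(f, `[[`, "", 2L)
  partner <- as.integer(vapply(f, `[[`, "", 3L))
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  seq <- rna_sequence(bases, id = id, lenient = lenient)
  structure_record(seq, .pairs_from_partner(partner, path), id = id)
}

#' Write a BPSEQ-format structure file
#'
#' @param record a \code{\link{structure_record}}
#' @param path output file
#' @return invisibly, the path
#' @export
write_bpseq <- function(record, path) {
  L <- length(record$seq)
  partner <- .partner_vector(record_contact_map(record))
  writeLines(sprintf("%d %s %d", seq_len(L), record$seq$bases, partner), path)
  invisible(path)
}

.BRACKET_OPEN <- c("(", "[", "{", "<")
.BRACKET_CLOSE <- c(")", "]", "}", ">")

# TRUE iff pairs a=(i,j), b=(k,l) cross: i<k<j<l or k<i<l<j
.pairs_cross <- function(a, b) {
  (a[1] < b[1] && b[1] < a[2] && a[2] < b[2]) ||
  (b[1] < a[1] && a[1] < b[2] && b[2] < a[2])
}

#' Dot-bracket string of a structure
#'
#' Nested pairs use (); crossing (pseudoknotted) pairs are assigned
#' additional bracket tiers [ ], \{ \}, < > by greedy coloring of the
#' crossing graph: pairs are processed in ascending i and each takes the
#' lowest tier in which it crosses no already-placed pair. Warns if more
#' than 4 tiers are needed (overflow pairs are dropped from the string).
#'
#' @param record a \code{\link{structure_record}}
#' @param path optional output file; when NULL the string is returned only
#' @return the dot-bracket string, invisibly when writing to a file
#' @export
write_dotbracket <- function(record, path = NULL) {
  L <- length(record$seq)
  pairs <- record$pairs
  chars <- rep(".", L)
  if (nrow(pairs) > 0L) {
    tier_pairs <- vector("list", length(.BRACKET_OPEN))
    for (k in order(pairs[, 1])) {
      p <- pairs[k, ]
      placed <- FALSE
      for (t in seq_along(tier_pairs)) {
        conflict <- any(vapply(tier_pairs[[t]], .pairs_cross, TRUE, b = p))
        if (!conflict) {
          tier_pairs[[t]] <- c(tier_pairs[[t]], list(p))
          chars[p[1]] <- .BRACKET_OPEN[t]
          chars[p[2]] <- .BRACKET_CLOSE[t]
          placed <- TRUE
          break
        }
      }
      if (!placed)
        warning("structure needs more than 4 bracket tiers; pair dropped from string")
    }
  }
  db <- paste(chars, collapse = "")
  if (is.null(path)) return(db)
  writeLines(c(paste0(">", record$id),
               paste(record$seq$bases, collapse = ""), db), path)
  invisible(db)
}

#' Parse a dot-bracket string into a pair set
#'
#' Inverse of \code{\link{write_dotbracket}} for structures needing at most
#' 4 tiers.
#'
#' @param db dot-bracket string
#' @return two-column matrix of 1-based (i, j) pairs
#' @export
read_dotbracket <- function(db) {
  chars <- strsplit(db, "")[[1]]
  pairs <- list()
  for (t in seq_along(.BRACKET_OPEN)) {
    stack <- integer(0)
    for (pos in seq_along(chars)) {
      if (chars[pos] == .BRACKET_OPEN[t]) {
        stack <- c(stack, pos)
      } else if (chars[pos] == .BRACKET_CLOSE[t]) {
        if (length(stack) == 0L) stop("unbalanced brackets in dot-bracket string")
        pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], pos)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0L) stop("unbalanced brackets in dot-bracket string")
  }
  if (length(pairs) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  out <- do.call(rbind, pairs)
  colnames(out) <- c("i", "j")
  out[order(out[, 1]), , drop = FALSE]
}

#' Write per-sequence and aggregate evaluation reports
#'
#' @param ids record identifiers
#' @param counts list of per-record \code{confusion_counts}
#' @param path TSV output path; an "overall" row is appended
#' @return invisibly, the aggregate \code{metrics_report}
#' @export
write_eval_report <- function(ids, counts, path) {
  rows <- lapply(seq_along(ids), function(k) {
    m <- compute_metrics(counts[[k]])
    data.frame(id = ids[k], TP = m$counts$TP, TN = m$counts$TN,
               FP = m$counts$FP, FN = m$counts$FN, acc = m$acc,
               sen = m$sen, ppv = m$ppv, fscore = m$fscore)
  })
  overall <- compute_metrics(sum_counts(counts))
  rows[[length(rows) + 1L]] <- data.frame(
    id = "overall", TP = overall$counts$TP, TN = overall$counts$TN,
    FP = overall$counts$FP, FN = overall$counts$FN, acc = overall$acc,
    sen = overall$sen, ppv = overall$ppv, fscore = overall$fscore)
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(overall)
}
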