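RNA_BASES <- c("A", "C", "G", "U")

# 4x4 lookup: unordered base-pair class id for (base_i, base_j), classes
# ordered lexicographically over the sorted pair:
# AA AC AG AU CC CG CU GG GU UU
.pair_class4 <- local({
  m <- matrix(0L, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  k <- 0L
  for (i in 1:4) for (j in i:4) {
    k <- k + 1L
    m[i, j] <- k
    m[j, i] <- k
  }
  m
})

# all 16 ordered dimers, lexicographic (AA, AC, ..., UU)
.dimers16 <- local({
  g <- expand.grid(second = RNA_BASES, first = RNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$first, g$second)
})

# 16x16 lookup: unordered dimer-pair class id, 136 classes ordered
# lexicographically over the sorted dimer pair
.pair_class16 <- local({
  m <- matrix(0L, 16, 16, dimnames = list(.dimers16, .dimers16))
  k <- 0L
  for (i in 1:16) for (j in i:16) {
    k <- k + 1L
    m[i, j] <- k
    m[j, i] <- k
  }
  m
})

#' Validated RNA sequence
#'
#' Constructs a validated RNA sequence over the alphabet \{A, C, G, U\}.
#' In strict mode (the default) any other character is an error, mirroring
#' the exclusion of sequences with unknown bases from training corpora. With
#' \code{lenient = TRUE}, \code{T} is mapped to \code{U} and any remaining
#' IUPAC ambiguity code is retained as \code{N}; positions holding \code{N}
#' receive no feature channel when encoded.
#'
#' @param bases single string, or character vector of single bases
#' @param id record identifier (free text)
#' @param lenient map T to U and tolerate ambiguity codes instead of erroring
#' @return an object of class \code{rna_sequence} with fields \code{id},
#'   \code{bases} (character vector of length L) and length accessible via
#'   \code{length()}
#' @export
rna_sequence <- function(bases, id = "seq", lenient = FALSE) {
  if (length(bases) == 1L && nchar(bases) > 1L)
    bases <- strsplit(bases, "")[[1]]
  bases <- toupper(as.character(bases))
  if (length(bases) < 1L)
    stop("RNA sequence must have length >= 1")
  if (lenient) {
    bases[bases == "T"] <- "U"
    bases[!(bases %in% RNA_BASES)] <- "N"
  } else {
    bad <- setdiff(unique(bases), RNA_BASES)
    if (length(bad) > 0L)
      stop(sprintf("sequence '%s' contains non-ACGU characters: %s",
                   id, paste(bad, collapse = ", ")))
  }
  if (length(bases) == 1L)
    warning("length-1 sequence: tetranucleotide encoding degenerates to the wrap dimer")
  structure(list(id = id, bases = bases), class = "rna_sequence")
}

#' @export
length.rna_sequence <- function(x) length(x$bases)

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (L=%d)\n%s\n", x$id, length(x),
              paste(x$bases, collapse = "")))
  invisible(x)
}

#' Names of the 10 unordered dinucleotide classes
#'
#' Lexicographic over the sorted pair: AA, AC, AG, AU, CC, CG, CU, GG, GU, UU.
#' @return character vector of length 10
#' @export
dinucleotide_classes <- function() {
  out <- character(10)
  k <- 0L
  for (i in 1:4) for (j in i:4) {
    k <- k + 1L
    out[k] <- paste0(RNA_BASES[i], RNA_BASES[j])
  }
  out
}

#' Names of the 136 unordered tetranucleotide (dimer-pair) classes
#'
#' Lexicographic over the sorted dimer pair, dimers in 16-way lexicographic
#' order; class "AC|GU" covers both orders of the two dimers.
#' @return character vector of length 136
#' @export
tetranucleotide_classes <- function() {
  out <- character(136)
  k <- 0L
  for (i in 1:16) for (j in i:16) {
    k <- k + 1L
    out[k] <- paste0(.dimers16[i], "|", .dimers16[j])
  }
  out
}

#' Unordered dinucleotide class of a base pair
#'
#' Order-insensitive: \code{pair_class_of("A","U")} equals
#' \code{pair_class_of("U","A")}. Class ids are 1-based (1..10), ordered as
#' \code{\link{dinucleotide_classes}}.
#'
#' @param a,b single bases in \{A,C,G,U\}
#' @return integer class id in 1..10
#' @export
pair_class_of <- function(a, b) {
  ia <- match(a, RNA_BASES)
  ib <- match(b, RNA_BASES)
  if (anyNA(ia) || anyNA(ib))
    stop("invalid base: bases must be in {A, C, G, U}")
  .pair_class4[cbind(ia, ib)]
}

.base_index <- function(seq) {
  match(seq$bases, RNA_BASES)  # NA for lenient-mode N
}

#' Ordered dimer starting at a position
#'
#' Returns \code{(b_i, b_(i+1))} for \code{i < L}; at the terminal position
#' \code{i = L} returns the wrap dimer \code{(b_L, b_1)}, which makes the
#' tetranucleotide channels well-defined on the last row/column and keeps the
#' encoding applicable to circular RNAs.
#'
#' @param seq an \code{\link{rna_sequence}}
#' @param i 1-based position, 1 <= i <= L
#' @return character vector of the two bases
#' @export
dimer_at <- function(seq, i) {
  L <- length(seq)
  if (i < 1L || i > L) stop(sprintf("dimer index %d out of range [1, %d]", i, L))
  if (i < L) c(seq$bases[i], seq$bases[i + 1L]) else c(seq$bases[L], seq$bases[1L])
}

# integer dimer ids (1..16) for positions 1..L, wrap at L; NA where a base is N
.dimer_index <- function(seq) {
  v <- .base_index(seq)
  nxt <- c(v[-1L], v[1L])
  (v - 1L) * 4L + nxt
}

#' Dinucleotide contact-matrix encoding
#'
#' Encodes a sequence as 10 binary L x L contact matrices, one per unordered
#' base-pair class: channel c has a 1 at (i, j) iff \{b_i, b_j\} falls in
#' class c. Channels are symmetric and, over any fixed cell, exactly one
#' channel is hot, so they sum to the all-ones matrix.
#'
#' @param seq an \code{\link{rna_sequence}}
#' @return numeric array of dim c(L, L, 10) with channel dimnames
#' @export
encode_dinucleotide <- function(seq) {
  L <- length(seq)
  v <- .base_index(seq)
  arr <- array(0, c(L, L, 10L), dimnames = list(NULL, NULL, dinucleotide_classes()))
  cls <- matrix(.pair_class4[cbind(rep(v, times = L), rep(v, each = L))], L, L)
  ok <- which(!is.na(cls))
  arr[ok + (as.vector(cls)[ok] - 1L) * L * L] <- 1
  arr
}

#' Tetranucleotide contact-matrix encoding
#'
#' Encodes a sequence as 136 binary L x L contact matrices over unordered
#' pairs of consecutive dimers: channel c has a 1 at (i, j) iff the dimer
#' pair \{b_i b_(i+1), b_j b_(j+1)\} falls in class c, using the wrap dimer
#' \code{(b_L, b_1)} at position L. Same symmetry and partition properties as
#' \code{\link{encode_dinucleotide}}.
#'
#' @param seq an \code{\link{rna_sequence}}
#' @return numeric array of dim c(L, L, 136) with channel dimnames
#' @export
encode_tetranucleotide <- function(seq) {
  L <- length(seq)
  d <- .dimer_index(seq)
  arr <- array(0, c(L, L, 136L), dimnames = list(NULL, NULL, tetranucleotide_classes()))
  cls <- matrix(.pair_class16[cbind(rep(d, times = L), rep(d, each = L))], L, L)
  ok <- which(!is.na(cls))
  arr[ok + (as.vector(cls)[ok] - 1L) * L * L] <- 1
  arr
}

#' Full 146-channel input conformation
#'
#' Stacks the 10 dinucleotide channels (first) and the 136 tetranucleotide
#' channels (after) into the L x L x 146 binary input tensor consumed by the
#' scoring network.
#'
#' @param seq an \code{\link{rna_sequence}}
#' @return numeric array of dim c(L, L, 146); channels named
#' @export
build_input_conformation <- function(seq) {
  a <- encode_dinucleotide(seq)
  b <- encode_tetranucleotide(seq)
  L <- length(seq)
  out <- array(c(a, b), c(L, L, 146L),
               dimnames = list(NULL, NULL, c(dimnames(a)[[3]], dimnames(b)[[3]])))
  out
}

#' Dump an encoded tensor as plain text
#'
#' Debug export: one whitespace-separated L x L block per channel, preceded
#' by a "# <channel name>" line. Intended for inspection and for feeding
#' third-party tools, not for speed.
#'
#' @param tensor array as returned by the encoders
#' @param path output file
#' @return invisibly, the path
#' @export
export_tensor_text <- function(tensor, path) {
  ch <- dimnames(tensor)[[3]]
  if (is.null(ch)) ch <- paste0("channel_", seq_len(dim(tensor)[3]))
  con <- file(path, "w")
  on.exit(close(con))
  for (c in seq_len(dim(tensor)[3])) {
    writeLines(paste0("# ", ch[c]), con)
    utils::write.table(tensor[, , c], con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
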