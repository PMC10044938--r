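#' Configuration for the synthetic structure generator
#'
#' The generator builds feasible-by-construction corpora: every emitted pair
#' is canonical or wobble, satisfies |i - j| >= 4 (at least 3 unpaired bases
#' in every hairpin loop), and no base has two partners. These are code-path
#' fixtures, not thermodynamic samples.
#'
#' @param n_sequences corpus size
#' @param length_min,length_max sequence length bounds; at least 20 when
#'   pseudoknots are enabled (room for two crossing stems)
#' @param stem_min,stem_max stem length range, in base pairs
#' @param pseudoknot_probability probability a structure receives one
#'   crossing (H-type) stem pair
#' @param gu_fraction fraction of paired positions drawn as wobble G-U
#' @param seed integer seed; corpora are byte-reproducible
#' @return list of class \code{fixture_config}
#' @export
fixture_config <- function(n_sequences = 40L, length_min = 40L,
                           length_max = 100L, stem_min = 3L, stem_max = 6L,
                           pseudoknot_probability = 0.3, gu_fraction = 0.1,
                           seed = 1L) {
  stopifnot(length_min >= 5L, length_max >= length_min,
            stem_min >= 1L, stem_max >= stem_min,
            pseudoknot_probability >= 0, pseudoknot_probability <= 1,
            gu_fraction >= 0, gu_fraction <= 1)
  if (pseudoknot_probability > 0 && length_min < 20L)
    stop("length_min must be >= 20 when pseudoknots are enabled")
  structure(list(n_sequences = as.integer(n_sequences),
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 stem_min = as.integer(stem_min),
                 stem_max = as.integer(stem_max),
                 pseudoknot_probability = pseudoknot_probability,
                 gu_fraction = gu_fraction, seed = as.integer(seed)),
            class = "fixture_config")
}

# sample one element of v (safe for length-1 vectors)
.sample1 <- function(v) v[sample.int(length(v), 1L)]

# place nested stems recursively inside [lo, hi]
.place_nested <- function(lo, hi, cfg) {
  pairs <- NULL
  width <- hi - lo + 1L
  # a stem of s pairs anchored at (a, b) needs b - a >= 2s + 2 so the
  # innermost pair has separation >= 4
  s_fit <- ((width - 3L) %/% 2L) - 1L
  if (width < 2L * cfg$stem_min + 4L || s_fit < cfg$stem_min) return(NULL)
  s <- .sample1(cfg$stem_min:min(cfg$stem_max, s_fit))
  max_off <- width - (2L * s + 4L)
  a <- lo + sample.int(max_off + 1L, 1L) - 1L
  b_min <- a + 2L * s + 2L
  b <- b_min + sample.int(hi - b_min + 1L, 1L) - 1L
  k <- 0:(s - 1L)
  pairs <- cbind(a + k, b - k)
  # recurse into the enclosed loop and the tail after the stem
  inner <- .place_nested(a + s, b - s, cfg)
  after <- if (b + 1L + 2L * cfg$stem_min + 3L <= hi)
    .place_nested(b + 1L, hi, cfg) else NULL
  rbind(pairs, inner, after)
}

# one H-type pseudoknot core: stem1 pairs block [a, a+s-1] with
# [c, c+s-1], stem2 pairs [b, b+s-1] with [d, d+s-1], a < b < c < d,
# so stem1 and stem2 cross
.place_pseudoknot <- function(L, cfg) {
  s <- max(2L, cfg$stem_min)
  # minimal footprint: a..a+s-1, gap1>=1, b..b+s-1, sep, c..c+s-1, sep, d..
  while (4L * s + 10L > L && s > 2L) s <- s - 1L
  if (4L * s + 10L > L) return(NULL)
  slack <- L - (4L * s + 10L)
  offs <- sort(sample.int(slack + 1L, 4L, replace = TRUE) - 1L)
  a <- 1L + offs[1]
  b <- a + s + 1L + (offs[2] - offs[1])
  c <- b + s + 4L + (offs[3] - offs[2])
  d <- c + s + 4L + (offs[4] - offs[3])
  if (d + s - 1L > L) return(NULL)
  k <- 0:(s - 1L)
  stem1 <- cbind(a + k, c + s - 1L - k)
  stem2 <- cbind(b + k, d + s - 1L - k)
  if (min(stem1[, 2] - stem1[, 1]) < 4L || min(stem2[, 2] - stem2[, 1]) < 4L)
    return(NULL)
  rbind(stem1, stem2)
}

#' Sample a feasible secondary structure
#'
#' Recursively places non-overlapping nested stems with hairpin loops of at
#' least 3 unpaired bases; with probability \code{pseudoknot_probability}
#' the structure is instead built around one H-type crossing stem pair, with
#' nested stems filled into the remaining unpaired gaps. Every emitted pair
#' satisfies |i - j| >= 4 and the one-partner rule by construction.
#'
#' @param L sequence length
#' @param cfg a \code{\link{fixture_config}}
#' @return two-column matrix of 1-based (i, j) pairs, i < j
#' @export
sample_structure <- function(L, cfg = fixture_config()) {
  if (L < 2L * cfg$stem_min + 4L)
    stop(sprintf("L=%d cannot host a stem of %d pairs with loop >= 3",
                 L, cfg$stem_min))
  pairs <- NULL
  if (stats::runif(1) < cfg$pseudoknot_probability) {
    pairs <- .place_pseudoknot(L, cfg)
    if (is.null(pairs) && cfg$pseudoknot_probability >= 1)
      stop(sprintf("L=%d too short for a pseudoknot with stem_min=%d",
                   L, cfg$stem_min))
  }
  if (is.null(pairs)) {
    pairs <- .place_nested(1L, L, cfg)
  } else {
    # fill unpaired gaps around the knot with nested stems
    used <- logical(L)
    used[c(pairs)] <- TRUE
    runs <- rle(used)
    pos <- cumsum(c(1L, runs$lengths))
    for (r in seq_along(runs$values)) {
      if (!runs$values[r] && runs$lengths[r] >= 2L * cfg$stem_min + 4L) {
        extra <- .place_nested(pos[r], pos[r] + runs$lengths[r] - 1L, cfg)
        pairs <- rbind(pairs, extra)
      }
    }
  }
  if (is.null(pairs))
    pairs <- matrix(integer(0), ncol = 2)
  colnames(pairs) <- c("i", "j")
  stopifnot(all(pairs[, 2] - pairs[, 1] >= 4L), !anyDuplicated(c(pairs)))
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Sample a sequence compatible with a pair set
#'
#' Paired positions are drawn from \{AU, UA, CG, GC, GU, UG\}: wobble G-U
#' with probability \code{gu_fraction}, otherwise A-U or C-G equally, with
#' random orientation. Unpaired positions are uniform over \{A,C,G,U\}.
#'
#' @param pairs two-column pair matrix
#' @param L sequence length
#' @param cfg a \code{\link{fixture_config}}
#' @param id identifier for the returned sequence
#' @return an \code{\link{rna_sequence}}
#' @export
sample_sequence <- function(pairs, L, cfg = fixture_config(), id = "synthetic") {
  bases <- sample(RNA_BASES, L, replace = TRUE)
  if (nrow(pairs) > 0L) {
    for (k in seq_len(nrow(pairs))) {
      u <- stats::runif(1)
      duo <- if (u < cfg$gu_fraction) c("G", "U")
             else if (u < cfg$gu_fraction + (1 - cfg$gu_fraction) / 2) c("A", "U")
             else c("C", "G")
      if (stats::runif(1) < 0.5) duo <- rev(duo)
      bases[pairs[k, 1]] <- duo[1]
      bases[pairs[k, 2]] <- duo[2]
    }
  }
  rna_sequence(bases, id = id)
}

# TRUE iff the pair set contains at least one crossing pair
has_crossing_pairs <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2L) return(FALSE)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (.pairs_cross(pairs[a, ], pairs[b, ])) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic corpus of structure records
#'
#' @param cfg a \code{\link{fixture_config}}
#' @return list of \code{\link{structure_record}}s, with a
#'   \code{pseudoknotted} logical attribute per record
#' @export
simulate_corpus <- function(cfg = fixture_config()) {
  .with_local_seed(cfg$seed, {
    lapply(seq_len(cfg$n_sequences), function(k) {
      L <- .sample1(cfg$length_min:cfg$length_max)
      pairs <- sample_structure(L, cfg)
      seq <- sample_sequence(pairs, L, cfg, id = sprintf("synth_%04d", k))
      rec <- structure_record(seq, pairs)
      attr(rec, "pseudoknotted") <- has_crossing_pairs(pairs)
      rec
    })
  })
}

#' Write a synthetic corpus to disk
#'
#' Emits one FASTA file per record, one CT file per record, and a manifest
#' TSV (id, length, n_pairs, pseudoknot flag, files).
#'
#' @param cfg a \code{\link{fixture_config}}
#' @param out_dir writable output directory (created if missing)
#' @return invisibly, the manifest data.frame
#' @export
emit_corpus <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- simulate_corpus(cfg)
  rows <- lapply(records, function(rec) {
    fa <- file.path(out_dir, paste0(rec$id, ".fasta"))
    ct <- file.path(out_dir, paste0(rec$id, ".ct"))
    write_fasta(rec$seq, fa)
    write_ct(rec, ct)
    data.frame(id = rec$id, length = length(rec$seq),
               n_pairs = nrow(rec$pairs),
               pseudoknot = isTRUE(attr(rec, "pseudoknotted")),
               fasta = basename(fa), ct = basename(ct))
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
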