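# partner vector: partner[i] = j if base i paired with j, else 0
.partner_vector <- function(P) {
  L <- nrow(P)
  partner <- integer(L)
  idx <- contact_pairs(P)
  if (nrow(idx) > 0L) {
    partner[idx[, "i"]] <- idx[, "j"]
    partner[idx[, "j"]] <- idx[, "i"]
  }
  partner
}

#' Per-base confusion counts between two structures
#'
#' Counts over the L bases of the sequence (not over cells): a base is a
#' true positive when it is paired in both structures with the SAME partner;
#' a true negative when unpaired in both; a false positive when unpaired in
#' the reference but paired in the prediction; and a false negative when
#' paired in the reference but unpaired or wrongly partnered in the
#' prediction. Note the asymmetry: a wrongly partnered reference base counts
#' as FN only, never additionally as FP — conventions differ between tools,
#' so this is stated explicitly.
#'
#' @param reference binary symmetric contact map (or pair matrix + L)
#' @param predicted binary symmetric contact map of the same size
#' @return list of class \code{confusion_counts} with TP, TN, FP, FN
#' @export
confusion_per_base <- function(reference, predicted) {
  if (!all(dim(reference) == dim(predicted)))
    stop("reference and prediction lengths disagree")
  pr <- .partner_vector(reference)
  pp <- .partner_vector(predicted)
  tp <- sum(pr > 0L & pp == pr)
  tn <- sum(pr == 0L & pp == 0L)
  fp <- sum(pr == 0L & pp > 0L)
  fn <- sum(pr > 0L & (pp == 0L | pp != pr))
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")
}

#' Sum confusion counts (micro-aggregation)
#'
#' @param ... \code{confusion_counts} objects, or a list of them
#' @return a \code{confusion_counts}
#' @export
sum_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "confusion_counts")) xs <- xs[[1]]
  structure(list(TP = sum(vapply(xs, `[[`, 0, "TP")),
                 TN = sum(vapply(xs, `[[`, 0, "TN")),
                 FP = sum(vapply(xs, `[[`, 0, "FP")),
                 FN = sum(vapply(xs, `[[`, 0, "FN"))),
            class = "confusion_counts")
}

#' Accuracy metrics from confusion counts
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN), SEN = TP/(TP+FN), PPV = TP/(TP+FP),
#' F-score = 2 / (1/SEN + 1/PPV). When a ratio is undefined (zero
#' denominator) it is reported as 0 and the corresponding \code{*_defined}
#' flag is set to FALSE.
#'
#' @param counts a \code{confusion_counts}
#' @return list of class \code{metrics_report}: acc, sen, ppv, fscore,
#'   definedness flags, and the counts
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion counts are zero")
  sen_def <- (tp + fn) > 0
  ppv_def <- (tp + fp) > 0
  sen <- if (sen_def) tp / (tp + fn) else 0
  ppv <- if (ppv_def) tp / (tp + fp) else 0
  f_def <- sen_def && ppv_def && sen > 0 && ppv > 0
  fscore <- if (f_def) 2 / (1 / sen + 1 / ppv) else 0
  structure(list(acc = (tp + tn) / total, sen = sen, ppv = ppv,
                 fscore = fscore, sen_defined = sen_def,
                 ppv_defined = ppv_def, fscore_defined = f_def,
                 counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC=%.3f SEN=%.3f PPV=%.3f F=%.3f  (TP=%d TN=%d FP=%d FN=%d)\n",
              x$acc, x$sen, x$ppv, x$fscore,
              x$counts$TP, x$counts$TN, x$counts$FP, x$counts$FN))
  invisible(x)
}

#' Evaluate predictions against references
#'
#' Micro-averaged by default (counts are summed over sequences before the
#' ratios are taken); \code{macro = TRUE} instead averages the per-sequence
#' metric values.
#'
#' @param references,predictions lists of contact maps, matched by position
#' @param macro average per-sequence metrics instead of pooling counts
#' @return a \code{metrics_report}; with \code{macro} the counts field holds
#'   the pooled counts but acc/sen/ppv/fscore are macro averages
#' @export
evaluate_structures <- function(references, predictions, macro = FALSE) {
  stopifnot(length(references) == length(predictions))
  counts <- mapply(confusion_per_base, references, predictions,
                   SIMPLIFY = FALSE)
  pooled <- sum_counts(counts)
  if (!macro) return(compute_metrics(pooled))
  per <- lapply(counts, compute_metrics)
  out <- compute_metrics(pooled)
  out$acc <- mean(vapply(per, `[[`, 0, "acc"))
  out$sen <- mean(vapply(per, `[[`, 0, "sen"))
  out$ppv <- mean(vapply(per, `[[`, 0, "ppv"))
  out$fscore <- mean(vapply(per, `[[`, 0, "fscore"))
  out
}

#' Deterministic k-fold split
#'
#' Randomly partitions record indices into k folds of sizes differing by at
#' most one; the permutation is a deterministic function of the seed and
#' does not disturb the caller's RNG state.
#'
#' @param n number of records (or a list of records, whose length is used)
#' @param k number of folds, 2 <= k <= n
#' @param seed integer seed
#' @return list of k integer vectors of indices
#' @export
crossval_split <- function(n, k = 4L, seed = 1L) {
  if (is.list(n)) n <- length(n)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("more folds than records")
  ord <- .with_local_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(k), length.out = n)
  out <- split(ord, fold_of)
  names(out) <- NULL
  out
}

# evaluate expr under set.seed(seed), restoring the caller's RNG state
.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Write fold assignments as TSV
#'
#' @param ids record identifiers
#' @param folds list of index vectors from \code{\link{crossval_split}}
#' @param path output file
#' @return invisibly, the path
#' @export
write_fold_assignments <- function(ids, folds, path) {
  fold_of <- integer(length(ids))
  for (f in seq_along(folds)) fold_of[folds[[f]]] <- f
  utils::write.table(data.frame(id = ids, fold = fold_of),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
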