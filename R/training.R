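#' Training configuration
#'
#' @param epochs maximum optimization epochs
#' @param batch_size records per optimizer step (gradients are averaged;
#'   records are processed one map at a time, so variable lengths batch
#'   freely)
#' @param learning_rate Adam step size
#' @param positive_weight up-weighting of paired cells in the loss; NULL
#'   recomputes it per record as valid-cell count over positive-cell count,
#'   capped at \code{positive_weight_cap}
#' @param positive_weight_cap cap on the automatic positive weight
#' @param max_length records longer than this are skipped with a warning
#' @param seed seed for initialization and data order
#' @param checkpoint_dir when set, the best model (by monitored F-score) is
#'   written there as \code{best.rds} along with \code{training_log.tsv}
#' @param eval_every epochs between F-score evaluations
#' @param target_fscore optional early stop once the monitored F-score
#'   reaches this value
#' @return list of class \code{train_config}
#' @export
train_config <- function(epochs = 50L, batch_size = 4L, learning_rate = 1e-3,
                         positive_weight = NULL, positive_weight_cap = 300,
                         max_length = 720L, seed = 1L, checkpoint_dir = NULL,
                         eval_every = 10L, target_fscore = NULL) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            max_length >= 1L, eval_every >= 1L)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 positive_weight = positive_weight,
                 positive_weight_cap = positive_weight_cap,
                 max_length = as.integer(max_length),
                 seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir,
                 eval_every = as.integer(eval_every),
                 target_fscore = target_fscore),
            class = "train_config")
}

#' Read / write a training configuration file
#'
#' YAML file whose keys mirror \code{\link{train_config}} fields exactly.
#'
#' @param path YAML file
#' @return a \code{train_config}
#' @export
read_train_config <- function(path) {
  do.call(train_config, yaml::read_yaml(path))
}

#' @rdname read_train_config
#' @param cfg a \code{train_config}
#' @export
write_train_config <- function(cfg, path) {
  vals <- unclass(cfg)
  yaml::write_yaml(vals[!vapply(vals, is.null, TRUE)], path)
  invisible(path)
}

#' Training target from a structure record
#'
#' @param record a \code{\link{structure_record}}
#' @return binary symmetric L x L matrix with zero diagonal
#' @export
target_from_record <- function(record) {
  record_contact_map(record)
}

# valid loss support: upper triangle at separation >= 4 (cells the decoder
# could ever select)
.valid_cells <- function(L) {
  which(upper.tri(matrix(0, L, L)) & (col(matrix(0, L, L)) - row(matrix(0, L, L))) >= 4L)
}

#' Class-weighted cross-entropy between a score map and a target structure
#'
#' Binary cross-entropy of the sigmoid-transformed scores against the target
#' contact map, restricted to upper-triangle cells with separation >= 4;
#' paired cells are up-weighted by \code{positive_weight} (paired cells are
#' rare, about one in L/2 valid cells). Returns the scalar loss with the
#' gradient with respect to the score map attached.
#'
#' @param S L x L score map
#' @param target binary L x L matrix
#' @param positive_weight positive-class weight; NULL picks
#'   valid-count / positive-count, capped
#' @param cap cap for the automatic weight
#' @return list: \code{loss} (scalar), \code{grad} (L x L matrix),
#'   \code{positive_weight} (the weight used)
#' @export
pair_loss <- function(S, target, positive_weight = NULL, cap = 300) {
  if (!all(dim(S) == dim(target))) stop("score map and target shapes disagree")
  L <- nrow(S)
  idx <- .valid_cells(L)
  s <- S[idx]
  t <- target[idx]
  n <- length(idx)
  if (is.null(positive_weight)) {
    npos <- sum(t)
    positive_weight <- if (npos > 0) min(cap, n / npos) else 1
  }
  w <- ifelse(t > 0, positive_weight, 1)
  # numerically stable BCE-with-logits: max(s,0) - s*t + log(1 + exp(-|s|))
  bce <- pmax(s, 0) - s * t + log1p(exp(-abs(s)))
  loss <- sum(w * bce) / n
  p <- 1 / (1 + exp(-s))
  grad <- matrix(0, L, L)
  grad[idx] <- w * (p - t) / n
  list(loss = loss, grad = grad, positive_weight = positive_weight)
}

# ---- Adam over nested parameter trees -------------------------------------

# recursion is driven by the gradient tree, so non-optimized leaves of the
# parameter tree (batch-norm running statistics) are left untouched
.adam_step <- function(p, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  if (is.list(g)) {
    if (is.null(state)) state <- vector("list", length(g))
    for (nm in names(g)) {
      r <- .adam_step(p[[nm]], g[[nm]], state[[nm]], lr, t, beta1, beta2, eps)
      p[[nm]] <- r$p
      state[[nm]] <- r$state
    }
    return(list(p = p, state = state))
  }
  if (is.null(state)) state <- list(m = g * 0, v = g * 0)
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), state = state)
}

.tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(b)) {
    for (nm in names(b)) a[[nm]] <- .tree_add(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

.tree_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, .tree_scale, s = s))
  a * s
}

# micro F-score of decoded predictions over records (inference mode)
.eval_fscore <- function(model, records, solver_cfg) {
  counts <- lapply(records, function(rec) {
    pred <- predict_structure(rec$seq, predict_scores(model, rec$seq),
                              solver_cfg)
    confusion_per_base(record_contact_map(rec), pred)
  })
  compute_metrics(sum_counts(counts))$fscore
}

#' Train the scoring network
#'
#' Seeded mini-batch Adam on the weighted cross-entropy of
#' \code{\link{pair_loss}}. Records longer than the configured maximum are
#' skipped with a warning. Every \code{eval_every} epochs the model is
#' evaluated (decode + micro F-score) on \code{val_records} — or on the
#' training records when no validation set is given — and the best-scoring
#' weights are kept and optionally checkpointed.
#'
#' @param records list of \code{\link{structure_record}}s
#' @param net_cfg a \code{\link{network_config}}
#' @param train_cfg a \code{\link{train_config}}
#' @param val_records optional held-out records for model selection
#' @param solver_cfg decoder settings used for the F-score evaluations
#' @param verbose print per-epoch progress
#' @return list: \code{model} (best weights), \code{history} (data.frame of
#'   epoch, loss, fscore), \code{fscore} (best monitored F-score)
#' @export
train_network <- function(records, net_cfg = network_config(),
                          train_cfg = train_config(), val_records = NULL,
                          solver_cfg = solver_config(), verbose = FALSE) {
  if (length(records) == 0L) stop("empty training set")
  keep <- vapply(records, function(r) length(r$seq) <= train_cfg$max_length, TRUE)
  if (!all(keep)) {
    warning(sprintf("%d record(s) exceed max_length %d and were excluded",
                    sum(!keep), train_cfg$max_length))
    records <- records[keep]
  }
  if (length(records) == 0L) stop("no records within the length limit")
  monitor <- if (is.null(val_records)) records else val_records
  .with_local_seed(train_cfg$seed, {
    model <- init_network(net_cfg, seed = train_cfg$seed)
    confs <- lapply(records, function(r) build_input_conformation(r$seq))
    targets <- lapply(records, target_from_record)
    n <- length(records)
    state <- NULL
    step <- 0L
    best <- list(fscore = -Inf, params = model$params)
    history <- data.frame(epoch = integer(), loss = numeric(),
                          fscore = numeric())
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      chunks <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
      for (chunk in chunks) {
        gacc <- NULL
        for (r in chunk) {
          fw <- .net_apply(model, confs[[r]], training = TRUE, keep = TRUE)
          model <- fw$model
          lo <- pair_loss(fw$S, targets[[r]], train_cfg$positive_weight,
                          train_cfg$positive_weight_cap)
          epoch_loss <- epoch_loss + lo$loss
          gacc <- .tree_add(gacc, .net_backward(model, fw, lo$grad))
        }
        gacc <- .tree_scale(gacc, 1 / length(chunk))
        step <- step + 1L
        r2 <- .adam_step(model$params, gacc, state, train_cfg$learning_rate,
                         step)
        model$params <- r2$p
        state <- r2$state
      }
      epoch_loss <- epoch_loss / n
      fscore <- NA_real_
      if (epoch %% train_cfg$eval_every == 0L || epoch == train_cfg$epochs) {
        fscore <- .eval_fscore(model, monitor, solver_cfg)
        if (fscore > best$fscore)
          best <- list(fscore = fscore, params = model$params)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = epoch_loss,
                                  fscore = fscore))
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f  fscore %s", epoch, epoch_loss,
                        ifelse(is.na(fscore), "-", sprintf("%.3f", fscore))))
      if (!is.null(train_cfg$target_fscore) && !is.na(fscore) &&
          fscore >= train_cfg$target_fscore) break
    }
    model$params <- best$params
    if (!is.null(train_cfg$checkpoint_dir)) {
      dir.create(train_cfg$checkpoint_dir, recursive = TRUE,
                 showWarnings = FALSE)
      save_checkpoint(model, file.path(train_cfg$checkpoint_dir, "best.rds"))
      utils::write.table(history,
                         file.path(train_cfg$checkpoint_dir, "training_log.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(model = model, history = history, fscore = best$fscore)
  })
}

#' k-fold cross-validation of the full pipeline
#'
#' Splits the records with \code{\link{crossval_split}}, trains on each
#' complement, decodes the held-out fold, and reports micro-averaged
#' per-fold and pooled metrics.
#'
#' @param records list of \code{\link{structure_record}}s
#' @param k number of folds
#' @param net_cfg,train_cfg,solver_cfg configurations passed through
#' @param seed seed for the fold split
#' @return list: \code{folds} (index vectors), \code{reports} (per-fold
#'   \code{metrics_report}s), \code{overall} (pooled report)
#' @export
run_crossval <- function(records, k = 4L, net_cfg = network_config(),
                         train_cfg = train_config(),
                         solver_cfg = solver_config(), seed = 1L) {
  folds <- crossval_split(length(records), k = k, seed = seed)
  reports <- vector("list", k)
  all_counts <- list()
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    fit <- train_network(records[-test_idx], net_cfg, train_cfg,
                         solver_cfg = solver_cfg)
    counts <- lapply(records[test_idx], function(rec) {
      pred <- predict_structure(rec$seq,
                                predict_scores(fit$model, rec$seq),
                                solver_cfg)
      confusion_per_base(record_contact_map(rec), pred)
    })
    reports[[f]] <- compute_metrics(sum_counts(counts))
    all_counts <- c(all_counts, counts)
  }
  list(folds = folds, reports = reports,
       overall = compute_metrics(sum_counts(all_counts)))
}
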