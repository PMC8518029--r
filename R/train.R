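#' Binary cross-entropy loss
#'
#' Mean over the batch of `-y log(p) - (1 - y) log(1 - p)`. Probabilities at
#' exactly 0 or 1 are clamped at `1e-7` (with a warning) so the loss stays
#' finite.
#'
#' @param probabilities predicted probabilities in `(0, 1)`.
#' @param labels binary vector of the same length.
#' @return A nonnegative number.
#' @export
bce_loss <- function(probabilities, labels) {
  if (length(probabilities) != length(labels)) stop("lengths differ")
  if (any(probabilities <= 0 | probabilities >= 1)) {
    warning("probabilities at the boundary clamped to [1e-7, 1 - 1e-7]")
    probabilities <- pmin(pmax(probabilities, 1e-7), 1 - 1e-7)
  }
  -mean(labels * log(probabilities) + (1 - labels) * log(1 - probabilities))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train a higher-order GCN on a fixed edge split
#'
#' Full-graph encoding per step with minibatch binary cross-entropy over
#' balanced positive/negative training pairs, Adam updates, and early
#' stopping on validation AUPRC with best-checkpoint restore. Negative pools
#' are sampled once per split (excluding all positives of every split, so no
#' leakage) and frozen across epochs; optionally the training negatives are
#' resampled each epoch.
#'
#' One master `seed` derives every stream: the negative-sampling seeds
#' (`seed + 1`, `seed + 2`), the parameter-initialization seed (`seed + 3`)
#' and the epoch shuffle/dropout stream (`seed + 4`), so two runs with the
#' same inputs are bitwise identical.
#'
#' @param graph an `interaction_graph`.
#' @param split an [split_edges()] result.
#' @param config an [hogcn_config()].
#' @param epochs maximum number of epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param patience epochs without validation improvement before stopping.
#' @param seed master seed.
#' @param features optional explicit node features (default one-hot).
#' @param resample_train_negatives redraw the training negative pool each
#'   epoch (validation negatives stay frozen).
#' @param verbose print per-epoch progress.
#' @return List with `params` (best-epoch parameters), `history` data frame
#'   (`epoch`, `loss`, `val_auprc`, `val_auroc`), `best_epoch`, `config`.
#' @export
train_hogcn <- function(graph, split, config = hogcn_config(),
                        epochs = 50L, batch_size = 256L,
                        learning_rate = 5e-4, patience = 10L, seed = 1L,
                        features = NULL,
                        resample_train_negatives = FALSE,
                        verbose = FALSE) {
  if (nrow(split$train) < 1L || nrow(split$validation) < 1L) {
    stop("train and validation splits must be nonempty")
  }
  patience <- min(as.integer(patience), as.integer(epochs))
  if (patience < 1L) stop("patience must be >= 1")
  # Message passing sees training edges only: held-out edges are masked from
  # the adjacency, exactly as they are masked from the loss.
  adj <- normalized_adjacency(training_graph(graph, split))
  X <- features %||% graph$features
  bip <- !is.null(graph$node_type)
  seed <- as.integer(seed)

  train_set <- balanced_labeled_set(graph, split$train, seed + 1L, bip)
  val_set <- balanced_labeled_set(graph, split$validation, seed + 2L, bip)
  params <- init_hogcn_params(config, n_nodes(graph),
                              if (is.null(X)) NULL else ncol(X),
                              seed = seed + 3L)
  state <- adam_init(params)

  n_tr <- length(train_set$labels)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_auprc = numeric(), val_auroc = numeric())
  best <- list(auprc = -Inf, params = params, epoch = 0L)
  stall <- 0L

  with_seed(seed + 4L, {
    for (epoch in seq_len(as.integer(epochs))) {
      if (resample_train_negatives && epoch > 1L) {
        train_set <- balanced_labeled_set(graph, split$train,
                                          seed + 100L + epoch, bip)
      }
      ord <- sample.int(n_tr)
      losses <- numeric()
      for (start in seq(1L, n_tr, by = batch_size)) {
        ix <- ord[start:min(start + batch_size - 1L, n_tr)]
        out <- hogcn_loss_grads(adj, X, train_set$pairs[ix, , drop = FALSE],
                                train_set$labels[ix], params, config,
                                train = TRUE)
        if (!is.finite(out$loss)) {
          stop("non-finite training loss at epoch ", epoch,
               "; try a lower learning rate")
        }
        upd <- adam_step(params, out$grads, state, learning_rate)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, out$loss)
      }
      val_p <- predict_pairs_prob(adj, X, val_set$pairs, params, config)
      v_auprc <- auprc(val_p, val_set$labels)
      v_auroc <- auroc(val_p, val_set$labels)
      history[epoch, ] <- list(epoch, mean(losses), v_auprc, v_auroc)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val AUPRC %.4f  AUROC %.4f",
                        epoch, mean(losses), v_auprc, v_auroc))
      }
      if (v_auprc > best$auprc) {
        best <- list(auprc = v_auprc, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  })
  list(params = best$params, history = history, best_epoch = best$epoch,
       config = config)
}

#' Fit a higher-order graph convolutional link predictor
#'
#' The main entry point: takes an interaction network, splits its edges,
#' samples leakage-safe negatives, trains the higher-order GCN encoder with
#' bilinear decoder, and evaluates ranking (AUPRC/AUROC) and calibration
#' (Brier score, reliability curve) on the held-out test edges.
#'
#' The encoder stacks `n_layers` higher-order graph convolution layers, each
#' concatenating `sigma(A_hat^j H W_j)` over the adjacency powers
#' `j in powers`; the decoder fuses two node embeddings with a learnable
#' bilinear tensor and a two-layer feed-forward head into an interaction
#' probability. `powers = 1` recovers a plain GCN, `powers = c(1, 2)` the
#' direct-plus-skip aggregation of skip-similarity models.
#'
#' @param graph an `interaction_graph` (see [read_edge_list()],
#'   [generate_sbm()], [generate_bipartite()]).
#' @param powers adjacency powers mixed per layer (default `0:3`).
#' @param d per-power embedding width.
#' @param n_layers encoder depth.
#' @param d_e bilinear edge-feature dimension.
#' @param h prediction-head hidden width.
#' @param dropout dropout rate.
#' @param activation encoder nonlinearity.
#' @param ratios train/validation/test proportions.
#' @param split optional precomputed [split_edges()] result (overrides
#'   `ratios`).
#' @param epochs,batch_size,learning_rate,patience optimizer settings; the
#'   defaults are the reference protocol (Adam, at most 50 epochs, batches of
#'   256, learning rate `5e-4`, patience 10).
#' @param seed master seed controlling split, negatives, initialization and
#'   shuffling.
#' @param features optional node feature matrix (default one-hot).
#' @param evaluate_test score the held-out test edges after training.
#' @param verbose print training progress.
#' @return An object of class `hogcn` with components `config`, `params`,
#'   `split`, `history`, `best_epoch`, `test` (pairs, labels, probabilities
#'   and an `eval_report`), `graph`, `seed` and `call`.
#' @seealso [predict.hogcn()], [eval_report()], [run_sweep()]
#' @examples
#' g <- generate_sbm(60, p_in = 0.4, p_out = 0.05, seed = 1)
#' fit <- hogcn(g, d = 8, d_e = 8, h = 8, epochs = 3, seed = 1)
#' fit
#' head(predict(fit))
#' @export
hogcn <- function(graph, powers = 0:3, d = 32L, n_layers = 2L, d_e = 64L,
                  h = 32L, dropout = 0.1, activation = "elu",
                  ratios = c(0.7, 0.1, 0.2), split = NULL,
                  epochs = 50L, batch_size = 256L, learning_rate = 5e-4,
                  patience = 10L, seed = 1L, features = NULL,
                  evaluate_test = TRUE, verbose = FALSE) {
  cl <- match.call()
  config <- hogcn_config(powers = powers, d = d, n_layers = n_layers,
                         d_e = d_e, h = h, dropout = dropout,
                         activation = activation)
  seed <- as.integer(seed)
  split <- split %||% split_edges(graph, ratios, seed = seed)
  fitted <- train_hogcn(graph, split, config, epochs = epochs,
                        batch_size = batch_size,
                        learning_rate = learning_rate, patience = patience,
                        seed = seed, features = features, verbose = verbose)
  obj <- structure(
    list(config = config, params = fitted$params, split = split,
         history = fitted$history, best_epoch = fitted$best_epoch,
         graph = graph, features = features, seed = seed, test = NULL,
         call = cl),
    class = "hogcn"
  )
  if (evaluate_test && nrow(split$test) > 0L) {
    bip <- !is.null(graph$node_type)
    test_set <- balanced_labeled_set(graph, split$test, seed + 5L, bip)
    p <- predict(obj, pairs = test_set$pairs)
    obj$test <- list(pairs = test_set$pairs, labels = test_set$labels,
                     probabilities = p,
                     report = eval_report(p, test_set$labels))
  }
  obj
}

#' @export
print.hogcn <- function(x, ...) {
  cat("Higher-order GCN link predictor\n")
  print(x$config)
  cat(sprintf("  graph: %d nodes, %d edges; split %d/%d/%d (seed %d)\n",
              n_nodes(x$graph), n_edges(x$graph), nrow(x$split$train),
              nrow(x$split$validation), nrow(x$split$test), x$seed))
  cat(sprintf("  trained %d epoch(s); best validation AUPRC %.4f at epoch %d\n",
              nrow(x$history), max(x$history$val_auprc), x$best_epoch))
  if (!is.null(x$test)) {
    r <- x$test$report
    cat(sprintf("  test: AUPRC %.4f  AUROC %.4f  Brier %.4f\n",
                r$auprc, r$auroc, r$brier))
  }
  invisible(x)
}

#' @export
summary.hogcn <- function(object, ...) {
  structure(list(fit = object), class = "summary.hogcn")
}

#' @export
print.summary.hogcn <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$test)) {
    cat("\nTest-set reliability (10 equal-width bins):\n")
    print(x$fit$test$report$reliability, row.names = FALSE, digits = 3)
  }
  cat("\nTraining history (last epochs):\n")
  print(utils::tail(x$fit$history, 5L), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict interaction probabilities for node pairs
#'
#' @param object a fitted [hogcn()] model.
#' @param pairs two-column matrix of node identifiers or indices; defaults to
#'   the held-out test pairs.
#' @param ... unused.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
predict.hogcn <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) {
    if (is.null(object$test)) stop("no test pairs stored; supply pairs")
    pairs <- object$test$pairs
  }
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2L)
  idx <- resolve_pairs(object$graph, pairs)
  adj <- normalized_adjacency(training_graph(object$graph, object$split))
  X <- object$features %||% object$graph$features
  predict_pairs_prob(adj, X, idx, object$params, object$config)
}

#' @export
coef.hogcn <- function(object, ...) object$params

#' Plot training history or test-set reliability of a fitted model
#'
#' @param x a fitted [hogcn()] model.
#' @param which `"history"` (loss and validation AUPRC per epoch) or
#'   `"reliability"` (test-set reliability diagram; the diagonal is perfect
#'   calibration).
#' @param ... passed to the underlying plot call.
#' @export
plot.hogcn <- function(x, which = c("history", "reliability"), ...) {
  which <- match.arg(which)
  if (which == "history") {
    h <- x$history
    graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(mfrow = c(1, 1)))
    graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                   ylab = "training loss", ...)
    graphics::plot(h$epoch, h$val_auprc, type = "b", xlab = "epoch",
                   ylab = "validation AUPRC", ...)
  } else {
    if (is.null(x$test)) stop("no test evaluation stored")
    rel <- x$test$report$reliability
    graphics::plot(rel$mean_predicted, rel$fraction_positive,
                   xlim = c(0, 1), ylim = c(0, 1), type = "b",
                   xlab = "mean predicted probability",
                   ylab = "fraction of positives", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Residuals of a fitted link predictor
#'
#' Response residuals `label - probability` on the held-out test pairs.
#'
#' @param object a fitted [hogcn()] model.
#' @param ... unused.
#' @export
residuals.hogcn <- function(object, ...) {
  if (is.null(object$test)) stop("no test evaluation stored")
  object$test$labels - object$test$probabilities
}
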