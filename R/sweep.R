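#' Sweep neighborhood order and training-edge fraction
#'
#' Trains one model per `(k, fraction, seed)` cell with power set
#' `P = {0, ..., k}` and reports held-out AUPRC/AUROC/Brier per cell. For a
#' training fraction `f`, one tenth of the held-out edges serve as the
#' validation set and the rest as test, mirroring the sparsity-robustness
#' protocol for interaction networks. With `out_dir` set, each finished cell
#' is written to its own TSV and completed cells are skipped on re-run, so
#' long sweeps are resumable. A failing cell is recorded with `NA` metrics
#' and the sweep continues.
#'
#' @param graph an `interaction_graph`.
#' @param k_values maximum neighborhood orders to try (power set `0:k`).
#' @param fractions training-edge fractions in `(0, 1)`.
#' @param seeds master seeds (one model per seed per cell).
#' @param d,n_layers,d_e,h,dropout,activation architecture settings, as in
#'   [hogcn()].
#' @param epochs,batch_size,learning_rate,patience optimizer settings.
#' @param out_dir optional directory for per-cell TSVs (enables resuming).
#' @param verbose print per-cell progress.
#' @return Data frame with one row per cell: `k`, `fraction`, `seed`,
#'   `auprc`, `auroc`, `brier`, `epochs_trained`, `error`.
#' @export
run_sweep <- function(graph, k_values = 0:3, fractions = 0.7, seeds = 1L,
                      d = 32L, n_layers = 2L, d_e = 64L, h = 32L,
                      dropout = 0.1, activation = "elu",
                      epochs = 50L, batch_size = 256L, learning_rate = 5e-4,
                      patience = 10L, out_dir = NULL, verbose = FALSE) {
  if (!length(k_values) || !length(fractions) || !length(seeds)) {
    stop("k_values, fractions and seeds must be nonempty")
  }
  if (any(fractions <= 0 | fractions >= 1)) stop("fractions must be in (0, 1)")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  cells <- expand.grid(k = as.integer(k_values), fraction = fractions,
                       seed = as.integer(seeds), KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    k <- cells$k[i]; f <- cells$fraction[i]; s <- cells$seed[i]
    tag <- sprintf("k%d_f%g_s%d", k, f, s)
    cell_file <- if (!is.null(out_dir)) file.path(out_dir,
                                                  paste0(tag, ".tsv"))
    if (!is.null(cell_file) && file.exists(cell_file)) {
      rows[[i]] <- utils::read.delim(cell_file)
      next
    }
    rows[[i]] <- tryCatch({
      ratios <- c(f, 0.1 * (1 - f), 0.9 * (1 - f))
      fit <- hogcn(graph, powers = 0:k, d = d, n_layers = n_layers,
                   d_e = d_e, h = h, dropout = dropout,
                   activation = activation, ratios = ratios,
                   epochs = epochs, batch_size = batch_size,
                   learning_rate = learning_rate, patience = patience,
                   seed = s)
      r <- fit$test$report
      out <- data.frame(k = k, fraction = f, seed = s, auprc = r$auprc,
                        auroc = r$auroc, brier = r$brier,
                        epochs_trained = nrow(fit$history),
                        error = NA_character_)
      if (verbose) message(sprintf("%s: AUROC %.3f AUPRC %.3f", tag,
                                   r$auroc, r$auprc))
      out
    }, error = function(e) {
      data.frame(k = k, fraction = f, seed = s, auprc = NA_real_,
                 auroc = NA_real_, brier = NA_real_,
                 epochs_trained = NA_integer_,
                 error = conditionMessage(e))
    })
    if (!is.null(cell_file)) {
      utils::write.table(rows[[i]], cell_file, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  do.call(rbind, rows)
}
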