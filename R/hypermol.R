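# Model fitting: scaffold split, seeded multi-run training with Adam on the
# masked binary cross-entropy, best-validation-epoch model selection, and
# across-run aggregation of test ROC-AUC.

#' ROC-AUC (Mann-Whitney formulation)
#'
#' Fraction of (positive, negative) pairs in which the positive is scored
#' higher, ties counted 0.5; computed via the rank-sum identity, which is
#' exactly the all-pairs count.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 vector of the same length (NAs dropped pairwise).
#' @return the AUC in [0, 1], or `NA_real_` when only one class is present
#'   (the undefined-metric signal; callers skip such tasks).
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(labels) & !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# per-task AUC of a score matrix against a label matrix
.auc_by_task <- function(scores, labels, task_names) {
  auc <- vapply(seq_len(ncol(labels)), function(k) {
    roc_auc(scores[, k], labels[, k])
  }, numeric(1))
  names(auc) <- task_names
  auc
}

#' Evaluate a fitted model on a dataset slice
#'
#' Per-task ROC-AUC over non-missing labels; tasks whose ground truth in the
#' slice contains a single class are excluded from the mean and reported in
#' `excluded_tasks`.
#'
#' @param object a `hypermol` fit.
#' @param dataset an `hm_dataset` to score.
#' @return list with `per_task_auc`, `mean_auc` and `excluded_tasks`.
#' @export
evaluate_model <- function(object, dataset) {
  stopifnot(inherits(object, "hypermol"), inherits(dataset, "hm_dataset"))
  scores <- predict(object, dataset)
  auc <- .auc_by_task(scores, dataset$labels, dataset$task_names)
  if (all(is.na(auc))) stop("no evaluable task in this slice")
  list(per_task_auc = auc,
       mean_auc = mean(auc, na.rm = TRUE),
       excluded_tasks = dataset$task_names[is.na(auc)])
}

# one seeded training run; pres = precomputed hypergraphs for all molecules
.hm_train_run <- function(pres, labels, split, cfg, seed, task_names,
                          verbose = FALSE) {
  set.seed(seed)
  params <- .hm_init_params(cfg$backbone, cfg$fp_length, cfg$hidden_dim,
                            cfg$n_layers, ncol(labels))
  state <- .adam_init(params)
  train_idx <- split$train_idx
  n_batches <- ceiling(length(train_idx) / cfg$batch_size)
  best <- list(valid_auc = -Inf, params = params, epoch = 0L)
  curve <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      valid_mean_auc = numeric(0))

  if (cfg$epochs > 0) {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample(train_idx)
      losses <- numeric(n_batches)
      for (b in seq_len(n_batches)) {
        take <- perm[((b - 1) * cfg$batch_size + 1):
                     min(b * cfg$batch_size, length(perm))]
        batch <- .hm_batch(pres[take])
        fw <- .hm_forward(params, batch)
        bw <- .hm_backward(params, batch, fw,
                           labels[take, , drop = FALSE])
        if (!is.finite(bw$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               ", seed ", seed)
        }
        losses[b] <- bw$loss
        st <- .adam_step(params, bw$grads, state, lr = cfg$learning_rate)
        params <- st$params; state <- st$state
      }
      vsc <- .hm_scores(params, pres, split$valid_idx)
      vauc <- .auc_by_task(vsc, labels[split$valid_idx, , drop = FALSE],
                           task_names)
      vmean <- if (all(is.na(vauc))) NA_real_ else mean(vauc, na.rm = TRUE)
      curve <- rbind(curve, data.frame(epoch = epoch,
                                       train_loss = mean(losses),
                                       valid_mean_auc = vmean))
      if (!is.na(vmean) && vmean > best$valid_auc) {
        best <- list(valid_auc = vmean, params = params, epoch = epoch)
      }
      if (verbose) {
        message(sprintf("seed %d epoch %3d  loss %.4f  valid auc %.4f",
                        seed, epoch, mean(losses), vmean))
      }
    }
  }

  final <- if (cfg$model_selection == "best_valid" && best$epoch > 0) {
    list(params = best$params, epoch = best$epoch)
  } else {
    list(params = params, epoch = cfg$epochs)
  }
  tsc <- .hm_scores(final$params, pres, split$test_idx)
  tauc <- .auc_by_task(tsc, labels[split$test_idx, , drop = FALSE],
                       task_names)
  list(seed = seed,
       params = final$params,
       per_task_auc = tauc,
       mean_auc = mean(tauc, na.rm = TRUE),
       excluded_tasks = task_names[is.na(tauc)],
       selected_epoch = final$epoch,
       curve = curve)
}

#' Fit a fingerprint-hypergraph neural network
#'
#' End-to-end training: molecules are converted to substructure hypergraphs
#' (circular fingerprint environments linked by shared atoms), features are
#' one-hot over the folded bit vocabulary, and a GCN or GIN Inter-Encoder
#' with sum-pooling readout and a sigmoid head is trained with Adam on the
#' masked multitask binary cross-entropy. The dataset is split by
#' Bemis-Murcko scaffold (deterministic greedy 8:1:1 by default); one run is
#' executed per seed and test metrics are aggregated as mean and standard
#' deviation across runs. Within a run the test score is taken from the
#' epoch with the best validation mean ROC-AUC (`model_selection =
#' "best_valid"`) or from the last epoch.
#'
#' @param data an `hm_dataset` (see [read_dataset()], [make_dataset()]) or a
#'   CSV path understood by [read_dataset()].
#' @param backbone `"gcn"` or `"gin"`.
#' @param fp_length folded fingerprint length (default 2048).
#' @param max_radius fingerprint radius (default 2).
#' @param hidden_dim hidden width of the Inter-Encoder (default 128).
#' @param n_layers number of propagation layers (default 2).
#' @param epochs training epochs per run (default 100).
#' @param batch_size mini-batch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seeds integer vector, one training run per seed (default 1:3).
#' @param ratios scaffold-split fractions (default `c(0.8, 0.1, 0.1)`).
#' @param model_selection `"best_valid"` or `"last_epoch"`.
#' @param smiles_column,task_columns forwarded to [read_dataset()] when
#'   `data` is a path.
#' @param verbose print per-epoch progress.
#' @return an object of class `hypermol` with components `runs` (one per
#'   seed), `aggregate` (mean and s.d. of test mean ROC-AUC and per-task
#'   aggregates), `config` (the run manifest echoing every protocol
#'   setting), `split`, and `task_names`.
#' @seealso [evaluate_model()], [sensitivity_sweep()], [predict.hypermol()]
#' @export
hypermol <- function(data,
                     backbone = c("gcn", "gin"),
                     fp_length = 2048L,
                     max_radius = 2L,
                     hidden_dim = 128L,
                     n_layers = 2L,
                     epochs = 100L,
                     batch_size = 32L,
                     learning_rate = 1e-3,
                     seeds = c(1L, 2L, 3L),
                     ratios = c(0.8, 0.1, 0.1),
                     model_selection = c("best_valid", "last_epoch"),
                     smiles_column = "smiles",
                     task_columns = NULL,
                     verbose = FALSE) {
  backbone <- match.arg(backbone)
  model_selection <- match.arg(model_selection)
  if (is.character(data)) {
    data <- read_dataset(data, smiles_column = smiles_column,
                         task_columns = task_columns)
  }
  stopifnot(inherits(data, "hm_dataset"))
  if (epochs < 0 || batch_size < 1) stop("invalid epochs/batch_size")

  fpcfg <- fingerprint_config(fp_length, max_radius)
  cfg <- list(backbone = backbone, fp_length = fpcfg$fp_length,
              max_radius = fpcfg$max_radius, hidden_dim = as.integer(hidden_dim),
              n_layers = as.integer(n_layers), epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate, optimizer = "adam",
              seeds = as.integer(seeds), ratios = ratios,
              model_selection = model_selection,
              n_molecules = length(data$molecules),
              n_skipped = data$n_skipped,
              task_names = data$task_names)

  split <- scaffold_split(data, ratios)
  pres <- lapply(data$molecules, .hm_precompute, cfg = fpcfg)
  runs <- lapply(cfg$seeds, function(s) {
    .hm_train_run(pres, data$labels, split, cfg, s, data$task_names,
                  verbose = verbose)
  })

  mean_aucs <- vapply(runs, `[[`, 0, "mean_auc")
  per_task <- do.call(rbind, lapply(runs, `[[`, "per_task_auc"))
  aggregate <- list(
    mean_auc = mean(mean_aucs),
    sd_auc = stats::sd(mean_aucs),
    per_run_mean_auc = mean_aucs,
    per_task_mean = colMeans(per_task, na.rm = TRUE),
    per_task_sd = apply(per_task, 2, stats::sd, na.rm = TRUE))

  structure(list(runs = runs, aggregate = aggregate, config = cfg,
                 split = split, task_names = data$task_names,
                 fp_config = fpcfg, call = match.call()),
            class = "hypermol")
}

#' @export
print.hypermol <- function(x, ...) {
  cat("Fingerprint-hypergraph neural network (", toupper(x$config$backbone),
      " Inter-Encoder)\n", sep = "")
  cat(sprintf("  %d molecules, %d task(s); scaffold split %d/%d/%d\n",
              x$config$n_molecules, length(x$task_names),
              length(x$split$train_idx), length(x$split$valid_idx),
              length(x$split$test_idx)))
  cat(sprintf("  fp_length %d, radius %d; %d epochs x %d run(s)\n",
              x$config$fp_length, x$config$max_radius, x$config$epochs,
              length(x$runs)))
  cat(sprintf("  test mean ROC-AUC: %.4f +/- %.4f\n",
              x$aggregate$mean_auc,
              ifelse(is.na(x$aggregate$sd_auc), 0, x$aggregate$sd_auc)))
  invisible(x)
}

#' @export
summary.hypermol <- function(object, ...) {
  structure(list(fit = object), class = "summary.hypermol")
}

#' @export
print.summary.hypermol <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nProtocol manifest:\n")
  cfg <- fit$config
  for (nm in c("backbone", "fp_length", "max_radius", "hidden_dim",
               "n_layers", "epochs", "batch_size", "learning_rate",
               "optimizer", "model_selection")) {
    cat(sprintf("  %-15s %s\n", nm, paste(cfg[[nm]], collapse = ", ")))
  }
  cat(sprintf("  %-15s %s\n", "seeds", paste(cfg$seeds, collapse = ", ")))
  cat(sprintf("  %-15s %s\n", "ratios", paste(cfg$ratios, collapse = ":")))
  cat("\nPer-run test metrics:\n")
  for (r in fit$runs) {
    cat(sprintf("  seed %d: mean ROC-AUC %.4f (epoch %d)\n",
                r$seed, r$mean_auc, r$selected_epoch))
    if (length(r$excluded_tasks) > 0) {
      cat("    excluded single-class task(s): ",
          paste(r$excluded_tasks, collapse = ", "), "\n", sep = "")
    }
  }
  cat("\nPer-task aggregate (mean +/- s.d. across runs):\n")
  pt <- fit$aggregate
  for (k in seq_along(fit$task_names)) {
    cat(sprintf("  %s: %.4f +/- %.4f\n", fit$task_names[k],
                pt$per_task_mean[k],
                ifelse(is.na(pt$per_task_sd[k]), 0, pt$per_task_sd[k])))
  }
  invisible(x)
}

#' Model parameters of a fit
#'
#' @param object a `hypermol` fit.
#' @param run which run's parameters (default: the run with the best test
#'   mean ROC-AUC).
#' @param ... unused.
#' @return the nested parameter list (layer weights and head).
#' @export
coef.hypermol <- function(object, run = NULL, ...) {
  if (is.null(run)) run <- which.max(vapply(object$runs, `[[`, 0, "mean_auc"))
  object$runs[[run]]$params
}

#' Predict per-task probabilities for new molecules
#'
#' Scores are averaged over the per-seed models of the fit.
#'
#' @param object a `hypermol` fit.
#' @param newdata an `hm_dataset`, a character vector of SMILES, or a CSV
#'   path.
#' @param ... unused.
#' @return matrix of probabilities, molecules x tasks.
#' @export
predict.hypermol <- function(object, newdata, ...) {
  if (is.character(newdata) && length(newdata) == 1 &&
      file.exists(newdata)) {
    newdata <- read_dataset(newdata)
  }
  mols <- if (inherits(newdata, "hm_dataset")) {
    newdata$molecules
  } else if (is.character(newdata)) {
    lapply(newdata, parse_smiles)
  } else {
    stop("newdata must be an hm_dataset, SMILES vector or CSV path")
  }
  pres <- lapply(mols, .hm_precompute, cfg = object$fp_config)
  acc <- NULL
  for (r in object$runs) {
    sc <- .hm_scores(r$params, pres, seq_along(pres))
    acc <- if (is.null(acc)) sc else acc + sc
  }
  out <- acc / length(object$runs)
  colnames(out) <- object$task_names
  out
}

#' Plot training curves
#'
#' Validation mean ROC-AUC per epoch, one line per seeded run.
#'
#' @param x a `hypermol` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.hypermol <- function(x, ...) {
  curves <- lapply(x$runs, function(r) r$curve$valid_mean_auc)
  if (all(lengths(curves) == 0)) {
    stop("no training curve recorded (epochs = 0)")
  }
  Y <- do.call(cbind, curves)
  graphics::matplot(seq_len(nrow(Y)), Y, type = "l", lty = 1,
                    xlab = "epoch", ylab = "validation mean ROC-AUC",
                    main = "hypermol training curves", ...)
  graphics::legend("bottomright", legend = paste("seed", x$config$seeds),
                   lty = 1, col = seq_along(x$runs), bty = "n")
  invisible(x)
}

#' Fingerprint length/radius sensitivity sweep
#'
#' Re-fits the model for every combination of the requested fingerprint
#' lengths and radii and collects the aggregate test metrics.
#'
#' @param data dataset (or CSV path) as in [hypermol()].
#' @param lengths integer vector of fingerprint lengths
#'   (e.g. `c(1024, 2048, 4096)`).
#' @param radii integer vector of radii (e.g. `2:4`).
#' @param ... further arguments forwarded to [hypermol()].
#' @return data frame with one row per (length, radius): aggregate mean and
#'   s.d. of test mean ROC-AUC across runs.
#' @export
sensitivity_sweep <- function(data, lengths, radii, ...) {
  if (length(lengths) == 0 || length(radii) == 0) {
    stop("sensitivity_sweep() needs non-empty length and radius grids")
  }
  if (is.character(data)) data <- read_dataset(data)
  grid <- expand.grid(fp_length = as.integer(lengths),
                      max_radius = as.integer(radii))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    fit <- hypermol(data, fp_length = grid$fp_length[k],
                    max_radius = grid$max_radius[k], ...)
    data.frame(fp_length = grid$fp_length[k],
               max_radius = grid$max_radius[k],
               mean_auc = fit$aggregate$mean_auc,
               sd_auc = fit$aggregate$sd_auc)
  })
  do.call(rbind, rows)
}

#' Save / load a fitted model
#'
#' Checkpoints are single RDS files carrying a format version and the full
#' config echo alongside the parameters.
#'
#' @param fit a `hypermol` fit.
#' @param path file path.
#' @return `load_hypermol()` returns the fit; `save_hypermol()` the path.
#' @export
save_hypermol <- function(fit, path) {
  stopifnot(inherits(fit, "hypermol"))
  saveRDS(list(format = "hypermol-checkpoint", version = 1L,
               config = fit$config, fit = fit), path)
  invisible(path)
}

#' @rdname save_hypermol
#' @export
load_hypermol <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "hypermol-checkpoint")) {
    stop("not a hypermol checkpoint: ", path)
  }
  x$fit
}

#' Write run metrics, curves and log for a fit
#'
#' @param fit a `hypermol` fit.
#' @param dir output directory (created if needed); writes `metrics.json`,
#'   `curves.csv` and `run.log`.
#' @export
write_run_metrics <- function(fit, dir) {
  stopifnot(inherits(fit, "hypermol"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- list(
    config = fit$config,
    runs = lapply(fit$runs, function(r) {
      list(seed = r$seed, mean_auc = r$mean_auc,
           per_task_auc = as.list(r$per_task_auc),
           selected_epoch = r$selected_epoch,
           excluded_tasks = r$excluded_tasks)
    }),
    aggregate = list(mean_auc = fit$aggregate$mean_auc,
                     sd_auc = fit$aggregate$sd_auc))
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  curves <- do.call(rbind, lapply(fit$runs, function(r) {
    if (nrow(r$curve) == 0) return(NULL)
    cbind(seed = r$seed, r$curve)
  }))
  if (!is.null(curves)) {
    utils::write.csv(curves, file.path(dir, "curves.csv"), row.names = FALSE)
  }
  log_lines <- c(
    sprintf("molecules: %d (skipped unparsable rows: %d)",
            fit$config$n_molecules, fit$config$n_skipped),
    sprintf("split: %d/%d/%d", length(fit$split$train_idx),
            length(fit$split$valid_idx), length(fit$split$test_idx)),
    unlist(lapply(fit$runs, function(r) {
      if (length(r$excluded_tasks) > 0) {
        sprintf("seed %d: excluded single-class task(s): %s", r$seed,
                paste(r$excluded_tasks, collapse = ", "))
      } else {
        sprintf("seed %d: all tasks evaluable", r$seed)
      }
    })))
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}
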