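## Training -------------------------------------------------------------------

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-2; the grid in
#'   [grid_search_dme()] spans 1e-2, 1e-3, 1e-4).
#' @param hidden_units Hidden layer width; 0 for the linear model.
#' @param quadrature_order Gauss-Hermite order for the marginal likelihood
#'   (default 20).
#' @param patience Early-stopping patience in epochs (default 5): training
#'   stops when the held-out objective has failed to beat the running best
#'   by more than `tol` for `patience` consecutive epochs.
#' @param max_epochs Hard cap on epochs (default 100).
#' @param split_fractions Train/validation/test fractions over genes
#'   (default `c(0.8, 0.1, 0.1)`; must sum to 1).
#' @param dropout_rate Hidden-layer dropout rate (default 0.5).
#' @param sigma_init Initial random-effect standard deviation (default 0.5).
#' @param tol Minimal improvement counted by early stopping (default 1e-6).
#' @param average_epochs When positive and no validation split is used,
#'   the returned parameters are the element-wise (Polyak-Ruppert) average
#'   of the iterates over the final `average_epochs` epochs instead of the
#'   raw endpoint.  A constant-learning-rate Adam trajectory hovers around
#'   the optimum with noise proportional to the learning rate; tail
#'   averaging removes most of that hover variance in parameter-recovery
#'   runs.  Default 0 (off).
#' @param polish Linear models only: after the stochastic phase, refine
#'   the (low-dimensional) parameter vector by full-batch BFGS on the
#'   training objective, starting from the Adam endpoint.  A stochastic
#'   optimizer with a constant rate stops in a hover distribution around
#'   the optimum; the deterministic refinement converges to the optimum
#'   itself, which matters when reading point estimates (e.g. `sigma`) off
#'   a fitted model.  Default FALSE.
#' @param seed Seed governing the gene split, weight initialization, epoch
#'   shuffles and dropout masks; identical seeds give identical runs.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-2, hidden_units = 0L,
                         quadrature_order = 20L, patience = 5L,
                         max_epochs = 100L,
                         split_fractions = c(0.8, 0.1, 0.1),
                         dropout_rate = 0.5, sigma_init = 0.5,
                         tol = 1e-6, average_epochs = 0L, polish = FALSE,
                         seed = 1L) {
  if (abs(sum(split_fractions) - 1) > 1e-8)
    stop_uneecon("`split_fractions` must sum to 1")
  if (patience < 1) stop_uneecon("`patience` must be >= 1")
  if (quadrature_order < 2) stop_uneecon("`quadrature_order` must be >= 2")
  structure(list(learning_rate = learning_rate,
                 hidden_units = as.integer(hidden_units),
                 quadrature_order = as.integer(quadrature_order),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 split_fractions = split_fractions,
                 dropout_rate = dropout_rate, sigma_init = sigma_init,
                 tol = tol, average_epochs = as.integer(average_epochs),
                 polish = isTRUE(polish), seed = as.integer(seed)),
            class = "train_config")
}

#' Split genes into train/validation/test sets
#'
#' Genes are permuted under the seed and assigned to splits by the given
#' fractions (train gets the remainder after rounding).
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Seed for the permutation.
#' @return List with `train`, `validation`, `test` character vectors.
#' @export
split_genes <- function(gene_ids, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_uneecon("`fractions` must sum to 1")
  n <- length(gene_ids)
  perm <- with_seed_or_not(seed, sample(gene_ids, n))
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1L) stop_uneecon("training split is empty (%d genes total)", n)
  list(train = perm[seq_len(n_train)],
       validation = if (n_val) perm[n_train + seq_len(n_val)] else character(),
       test = if (n_test) perm[n_train + n_val + seq_len(n_test)] else character())
}

adam_init <- function(shapes) {
  list(m = lapply(shapes, function(s) s * 0),
       v = lapply(shapes, function(s) s * 0), t = 0L)
}

adam_step <- function(state, values, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    values[[nm]] <- values[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, values = values)
}

trainable_values <- function(params) {
  v <- list(W_output = params$W_output, b_output = params$b_output,
            log_sigma = log(params$sigma))
  if (params$hidden_units > 0L) {
    v$W_hidden <- params$W_hidden
    v$B_hidden <- params$B_hidden
  }
  v
}

set_trainable_values <- function(params, values) {
  params$W_output <- values$W_output
  params$b_output <- values$b_output
  params$sigma <- exp(values$log_sigma)
  if (params$hidden_units > 0L) {
    params$W_hidden <- values$W_hidden
    params$B_hidden <- values$B_hidden
  }
  params
}

## Full-batch BFGS refinement of a linear model from the Adam endpoint,
## using the analytic gradients.  Deterministic.
polish_linear <- function(batches, params, order) {
  p <- length(params$W_output)
  unpack <- function(theta) {
    prm <- params
    prm$W_output <- theta[seq_len(p)]
    prm$b_output <- theta[p + 1L]
    prm$sigma <- exp(theta[p + 2L])
    prm
  }
  fn <- function(theta) {
    prm <- unpack(theta)
    sum(vapply(batches, function(b)
      gene_nll_grad(b, prm, order, mode = "infer")$nll, 0))
  }
  gr <- function(theta) {
    prm <- unpack(theta)
    g <- Reduce(function(a, b) Map(`+`, a, b),
                lapply(batches, function(b)
                  gene_nll_grad(b, prm, order, mode = "infer")$grads))
    c(g$W_output, g$b_output, g$log_sigma)
  }
  start <- c(params$W_output, params$b_output, log(params$sigma))
  opt <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  unpack(opt$par)
}

dataset_nll <- function(batches, params, order) {
  if (!length(batches)) return(NA_real_)
  -sum(vapply(batches, gene_log_marginal_likelihood, 0,
              params = params, order = order))
}

#' Train the deep mixed-effects model
#'
#' Minimizes the summed per-gene negative log marginal likelihood by Adam
#' (`beta = (0.9, 0.999)`, `eps = 1e-8`), one minibatch per gene, gene
#' order reshuffled every epoch.  `sigma` is optimized jointly with the
#' network weights on the log scale.  Continuous features are standardized
#' on the training split and the standardizer is stored for scoring.
#' After each epoch the objective is evaluated on the validation split
#' (without dropout); training stops early after `patience` epochs without
#' improvement and the best-epoch parameters are restored.
#'
#' @param batches Named list of [gene_batch()]es with occurrence data.
#' @param config A [train_config()].
#' @param feature_kinds Optional per-column kinds for
#'   [standardize_features()].
#' @return A `dme_fit`: `params` (best-epoch [dme_params()]),
#'   `standardizer`, `history` (per-epoch train/validation objective),
#'   `split`, `best_epoch`, `config`.
#' @export
train_dme <- function(batches, config = train_config(),
                      feature_kinds = NULL) {
  stopifnot(inherits(config, "train_config"))
  if (!length(batches)) stop_uneecon("no gene batches supplied")
  for (b in batches)
    if (is.null(b$Y)) stop_uneecon("gene %s has no occurrence indicators",
                                   b$gene_id)
  gene_ids <- vapply(batches, `[[`, "", "gene_id")
  names(batches) <- gene_ids

  withr::with_seed(config$seed, {
    split <- split_genes(gene_ids, config$split_fractions, seed = NULL)
    train_X <- do.call(rbind, lapply(batches[split$train], `[[`, "X"))
    stdz <- standardize_features(train_X, feature_kinds)$standardizer
    std_batches <- lapply(batches, function(b) {
      b$X <- apply_standardizer(stdz, b$X); b
    })
    params <- dme_params(n_features = ncol(train_X),
                         hidden_units = config$hidden_units,
                         sigma = config$sigma_init,
                         dropout_rate = config$dropout_rate,
                         feature_names = colnames(train_X), seed = NULL)
    values <- trainable_values(params)
    state <- adam_init(values)
    monitor <- if (length(split$validation)) "validation" else "train"
    best <- Inf; best_values <- values; best_epoch <- 0L; wait <- 0L
    history <- NULL
    avg_k <- if (monitor == "train") config$average_epochs %||% 0L else 0L
    tail_values <- list()

    for (epoch in seq_len(config$max_epochs)) {
      for (g in sample(split$train)) {
        params <- set_trainable_values(params, values)
        gr <- gene_nll_grad(std_batches[[g]], params,
                            order = config$quadrature_order, mode = "train")
        if (!is.finite(gr$nll))
          stop_uneecon("non-finite objective on gene %s at epoch %d", g, epoch)
        upd <- adam_step(state, values, gr$grads, config$learning_rate)
        state <- upd$state; values <- upd$values
      }
      params <- set_trainable_values(params, values)
      train_nll <- dataset_nll(std_batches[split$train], params,
                               config$quadrature_order)
      val_nll <- dataset_nll(std_batches[split$validation], params,
                             config$quadrature_order)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_nll = train_nll,
                                  val_nll = val_nll))
      if (avg_k > 0L) {
        tail_values[[length(tail_values) + 1L]] <- values
        if (length(tail_values) > avg_k) tail_values[[1L]] <- NULL
      }
      obj <- if (monitor == "validation") val_nll else train_nll
      if (is.finite(obj) && obj < best - config$tol) {
        best <- obj; best_values <- values; best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    ## With a validation split, restore the best-validation epoch (early
    ## stopping as regularizer).  Without one, the plateau test only decides
    ## when to stop: the optimizer's endpoint is the estimate, since picking
    ## the min-train-objective epoch among converged epochs would select
    ## minibatch oscillation noise.
    if (monitor == "validation") {
      params <- set_trainable_values(params, best_values)
    } else {
      if (avg_k > 0L && length(tail_values)) {
        values <- Reduce(function(a, b) Map(`+`, a, b), tail_values)
        values <- lapply(values, `/`, length(tail_values))
      }
      params <- set_trainable_values(params, values)
      best_epoch <- nrow(history)
    }
    if (isTRUE(config$polish)) {
      if (params$hidden_units > 0L)
        stop_uneecon("`polish` is supported for linear models only (hidden_units = 0)")
      params <- polish_linear(std_batches[split$train], params,
                              config$quadrature_order)
    }
  })
  structure(list(params = params, standardizer = stdz, history = history,
                 split = split, best_epoch = best_epoch, config = config),
            class = "dme_fit")
}

#' @export
print.dme_fit <- function(x, ...) {
  cat(sprintf(
    "dme_fit: %s, sigma = %.4f, best epoch %d/%d (train %d / val %d / test %d genes)\n",
    if (x$params$hidden_units > 0L)
      sprintf("%d hidden units", x$params$hidden_units) else "linear",
    x$params$sigma, x$best_epoch, nrow(x$history),
    length(x$split$train), length(x$split$validation), length(x$split$test)))
  invisible(x)
}

#' Grid search over learning rate and hidden-layer width
#'
#' Trains one model per grid cell (all cells share the seed, hence the gene
#' split) and selects the cell with the lowest held-out objective.
#' Selection uses the validation split by default; `selection = "test"`
#' reproduces selection on the test split instead (at the cost of
#' conflating selection with evaluation).  Ties break toward fewer hidden
#' units, then smaller learning rate.  A cell whose training fails is
#' recorded in the report and skipped.
#'
#' @param batches Named list of [gene_batch()]es.
#' @param config Base [train_config()]; `learning_rate` and `hidden_units`
#'   are overridden per cell.
#' @param grid List with `learning_rate` and `hidden_units` vectors
#'   (defaults: 1e-2/1e-3/1e-4 and 64/128/256/512/0).
#' @param selection `"validation"` (default) or `"test"`.
#' @return List with `fit` (best `dme_fit`), `best` (its grid row), and
#'   `report` (one row per cell: hyperparameters, objective, error).
#' @export
grid_search_dme <- function(batches, config = train_config(),
                            grid = list(learning_rate = c(1e-2, 1e-3, 1e-4),
                                        hidden_units = c(64L, 128L, 256L, 512L, 0L)),
                            selection = c("validation", "test"),
                            feature_kinds = NULL) {
  selection <- match.arg(selection)
  if (!length(grid$learning_rate) || is.null(grid$hidden_units))
    stop_uneecon("`grid` must supply `learning_rate` and `hidden_units`")
  cells <- expand.grid(learning_rate = grid$learning_rate,
                       hidden_units = grid$hidden_units)
  fits <- vector("list", nrow(cells))
  report <- cells
  report$objective <- NA_real_
  report$error <- NA_character_
  for (i in seq_len(nrow(cells))) {
    cfg <- config
    cfg$learning_rate <- cells$learning_rate[i]
    cfg$hidden_units <- as.integer(cells$hidden_units[i])
    res <- tryCatch({
      fit <- train_dme(batches, cfg, feature_kinds = feature_kinds)
      obj <- if (selection == "validation") {
        min(fit$history$val_nll, na.rm = TRUE)
      } else {
        std <- lapply(batches[fit$split$test], function(b) {
          b$X <- apply_standardizer(fit$standardizer, b$X); b
        })
        dataset_nll(std, fit$params, cfg$quadrature_order)
      }
      list(fit = fit, obj = obj)
    }, error = function(e) list(fit = NULL, obj = NA_real_,
                                err = conditionMessage(e)))
    fits[[i]] <- res$fit
    report$objective[i] <- res$obj
    if (!is.null(res$err)) report$error[i] <- res$err
  }
  ok <- which(is.finite(report$objective))
  if (!length(ok)) stop_uneecon("every grid cell failed to train")
  ord <- ok[order(report$objective[ok], report$hidden_units[ok],
                  report$learning_rate[ok])]
  best <- ord[1L]
  list(fit = fits[[best]], best = report[best, , drop = FALSE], report = report)
}
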