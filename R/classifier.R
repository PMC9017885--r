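#' Assemble the dynamics feature vector for a variant site
#'
#' The four features used by the pathogenicity classifier:
#' \describe{
#'   \item{`dfi_i`}{DFI of the variant site.}
#'   \item{`pct_dci_ji`}{how strongly the functional (active-site) residues
#'     are coupled to the variant site: %DCI of the functional residues with
#'     the variant site as the perturbed set, averaged over the functional
#'     residues and ranked within the full per-residue distribution.}
#'   \item{`dci_asym`}{coupling asymmetry between the variant site and the
#'     functional set: the site's DCI given the functional set minus the
#'     functional residues' mean DCI given the site.}
#'   \item{`avg_dfi_7A`}{mean DFI over all residues within `radius`
#'     (default 7 Angstrom) of the site, the site itself included.}
#' }
#'
#' @param chain a [calpha_chain()].
#' @param A a [perturbation_matrix()] for the chain.
#' @param functional a [functional_sites()].
#' @param site author residue id of the variant.
#' @param radius neighbourhood radius in Angstrom (default 7).
#' @return named numeric vector `c(dfi_i, pct_dci_ji, dci_asym, avg_dfi_7A)`.
#' @export
assemble_features <- function(chain, A, functional, site, radius = 7) {
  ids <- chain$residue_ids
  if (!inherits(functional, "functional_sites")) {
    functional <- functional_sites(functional)
  }
  sidx <- chain_index(chain, site)
  fidx <- chain_index(chain, functional$residue_ids)
  prof_dfi <- dfi(A, ids)
  # coupling of every residue to the variant site as perturbed set
  to_site <- dci(A, as.character(site), ids)
  pct_dci_ji <- mean(to_site$ranks[fidx])
  # site's coupling to the functional set vs the functional set's to the site
  from_func <- dci(A, functional, ids)
  dci_asym <- from_func$values[sidx] - mean(to_site$values[fidx])
  nb <- chain_index(chain, neighborhood(chain, site, radius))
  c(dfi_i = unname(prof_dfi$values[sidx]),
    pct_dci_ji = pct_dci_ji,
    dci_asym = unname(dci_asym),
    avg_dfi_7A = mean(prof_dfi$values[nb]))
}

#' Feature table for a set of variant sites
#'
#' Vectorised [assemble_features()] producing the classifier's input schema.
#'
#' @inheritParams assemble_features
#' @param sites vector of author residue ids.
#' @param labels optional 0/1 pathogenicity labels, appended as
#'   `disease` column.
#' @param protein_id identifier copied into the `pdb_id` column.
#' @return data.frame with columns `pdb_id`, `residue_id`, `dfi_i`,
#'   `pct_dci_ji`, `dci_asym`, `avg_dfi_7A` (+ `disease`).
#' @export
feature_table <- function(chain, A, functional, sites, labels = NULL,
                          protein_id = "synthetic", radius = 7) {
  F <- t(vapply(sites, function(s)
    assemble_features(chain, A, functional, s, radius), numeric(4L)))
  out <- data.frame(pdb_id = protein_id, residue_id = as.character(sites),
                    F, row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(labels)) out$disease <- as.integer(labels)
  out
}

#' Confusion-matrix evaluation of a binary classifier
#'
#' Thresholds the scores, forms the confusion counts, and computes accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, and
#' the area under the ROC curve by trapezoidal integration over all score
#' thresholds.
#'
#' @param scores predicted probabilities (or any monotone scores).
#' @param truth 0/1 labels.
#' @param threshold classification threshold (default 0.5, `score >=
#'   threshold` predicts positive).
#' @return list with `tp`, `tn`, `fp`, `fn`, `accuracy`, `precision`,
#'   `recall`, `auc`.
#' @export
evaluate_binary <- function(scores, truth, threshold = 0.5) {
  if (length(scores) != length(truth)) stop("length mismatch")
  truth <- as.integer(truth)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & truth == 1L); tn <- sum(pred == 0L & truth == 0L)
  fp <- sum(pred == 1L & truth == 0L); fn <- sum(pred == 0L & truth == 1L)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = (tp + tn) / length(truth),
       precision = if (tp + fp > 0) tp / (tp + fp) else NaN,
       recall = if (tp + fn > 0) tp / (tp + fn) else NaN,
       auc = roc_auc(scores, truth))
}

#' Area under the ROC curve (trapezoidal)
#'
#' Sweeps the decision threshold over all observed score values, traces the
#' (false positive rate, true positive rate) curve, and integrates it with
#' the trapezoid rule. Tied scores contribute a single ROC vertex, so ties
#' are handled exactly (equivalent to the rank/Mann-Whitney statistic).
#'
#' @param scores numeric scores, higher = more positive.
#' @param truth 0/1 labels.
#' @return AUC in `[0, 1]`; `NaN` with a warning when only one class is
#'   present.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  P <- sum(truth == 1L); N <- sum(truth == 0L)
  if (P == 0L || N == 0L) {
    warning("AUC undefined: only one class present")
    return(NaN)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # cumulative counts at each distinct-score cut
  cut <- c(which(diff(s) != 0), length(s))
  tpr <- c(0, cumsum(y)[cut] / P)
  fpr <- c(0, cumsum(1L - y)[cut] / N)
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

#' Configuration of the feed-forward pathogenicity classifier
#'
#' Defaults follow the reference architecture: two hidden layers of 80
#' rectified-linear units joined by 50% dropout, a sigmoid output unit,
#' cross-entropy loss minimised by gradient descent with momentum at
#' learning rate 0.001 for 1000 epochs. Hidden weights are initialised
#' uniformly on +/- 1/sqrt(fan_in); the output layer uses Xavier-uniform.
#'
#' @param hidden integer vector of hidden-layer widths.
#' @param dropout dropout probability on hidden activations during training.
#' @param learning_rate,epochs,momentum optimiser settings.
#' @param batch_size minibatch size; `NULL` (default) = full batch.
#' @param seed integer seed for weight initialisation and dropout masks.
#' @return object of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(80L, 80L), dropout = 0.5,
                       learning_rate = 0.001, epochs = 1000L,
                       momentum = 0.9, batch_size = NULL, seed = NULL) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout in [0, 1)")
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 momentum = momentum, batch_size = batch_size, seed = seed),
            class = "mlp_config")
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

init_mlp <- function(n_in, config) {
  sizes <- c(n_in, config$hidden, 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    lim <- if (l == L) sqrt(6 / (fan_in + fan_out)) else 1 / sqrt(fan_in)
    W[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    b[[l]] <- stats::runif(fan_out, -lim, lim)
  }
  list(W = W, b = b)
}

mlp_forward <- function(params, X, keep = 1, masks = NULL) {
  L <- length(params$W)
  a <- list(X)
  for (l in seq_len(L)) {
    z <- sweep(a[[l]] %*% params$W[[l]], 2L, params$b[[l]], `+`)
    h <- if (l < L) relu(z) else sigmoid(z)
    if (l < L) {
      if (!is.null(masks)) h <- h * masks[[l]]        # training: dropout mask
      else if (keep < 1) h <- h * keep                # evaluation: weight scaling
    }
    a[[l + 1L]] <- h
  }
  a
}

#' Train the feed-forward pathogenicity classifier
#'
#' Fits the multilayer perceptron described in [mlp_config()] to a feature
#' matrix and binary labels by full-batch (or minibatch) gradient descent
#' with momentum on the cross-entropy loss. Dropout is applied to the hidden
#' activations during training only; prediction scales the retained
#' activations by the keep probability.
#'
#' Features are used raw by default (three of the four dynamics features are
#' already ratio or percentile quantities); set `standardize = TRUE` to
#' z-score columns using training-set statistics (stored in the model and
#' re-applied at prediction time).
#'
#' @param X numeric feature matrix (rows = variants) or data.frame of
#'   numeric columns.
#' @param y 0/1 labels.
#' @param config an [mlp_config()].
#' @param standardize z-score the feature columns (default FALSE).
#' @return object of class `prs_mlp` with the trained weights, the config,
#'   feature names, and the training-loss trace.
#' @export
mlp_fit <- function(X, y, config = mlp_config(), standardize = FALSE) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  scaling <- NULL
  if (standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    X <- scale(X, center = mu, scale = sdv)
    scaling <- list(center = mu, scale = sdv)
  }
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y length mismatch")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (!is.null(config$seed)) set.seed(config$seed)
  params <- init_mlp(ncol(X), config)
  L <- length(params$W)
  vel <- list(W = lapply(params$W, function(w) w * 0),
              b = lapply(params$b, function(b) b * 0))
  keep <- 1 - config$dropout
  n <- nrow(X)
  bs <- if (is.null(config$batch_size)) n else min(config$batch_size, n)
  loss_trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    idx <- if (bs < n) sample.int(n, bs) else seq_len(n)
    Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
    masks <- if (config$dropout > 0) {
      lapply(config$hidden, function(h)
        matrix(stats::rbinom(length(idx) * h, 1L, keep), length(idx), h))
    }
    a <- mlp_forward(params, Xb, masks = masks)
    p <- a[[L + 1L]][, 1L]
    eps <- 1e-12
    loss_trace[ep] <- -mean(yb * log(p + eps) + (1 - yb) * log(1 - p + eps))
    delta <- matrix((p - yb) / length(yb), ncol = 1L)   # dL/dz at output
    for (l in rev(seq_len(L))) {
      gW <- crossprod(a[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(params$W[[l]])) * (a[[l]] > 0)
        if (!is.null(masks)) delta <- delta * masks[[l - 1L]]
      }
      vel$W[[l]] <- config$momentum * vel$W[[l]] - config$learning_rate * gW
      vel$b[[l]] <- config$momentum * vel$b[[l]] - config$learning_rate * gb
      params$W[[l]] <- params$W[[l]] + vel$W[[l]]
      params$b[[l]] <- params$b[[l]] + vel$b[[l]]
    }
  }
  structure(list(params = params, config = config, scaling = scaling,
                 feature_names = colnames(X), loss = loss_trace),
            class = "prs_mlp")
}

#' @export
print.prs_mlp <- function(x, ...) {
  cat(sprintf("feed-forward classifier: %s -> %s -> 1 (dropout %.0f%%), final loss %.4f\n",
              length(x$feature_names %||% x$params$W[[1L]][, 1L]),
              paste(x$config$hidden, collapse = " -> "),
              100 * x$config$dropout, utils::tail(x$loss, 1L)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict pathogenicity probabilities
#'
#' @param object a fitted `prs_mlp`.
#' @param newdata feature matrix or data.frame.
#' @param ... unused.
#' @return vector of probabilities in (0, 1).
#' @export
predict.prs_mlp <- function(object, newdata, ...) {
  X <- as.matrix(newdata); storage.mode(X) <- "double"
  if (!is.null(object$scaling)) {
    X <- scale(X, center = object$scaling$center,
               scale = object$scaling$scale)
  }
  keep <- 1 - object$config$dropout
  a <- mlp_forward(object$params, X, keep = keep)
  a[[length(a)]][, 1L]
}

#' Repeated random-split cross-validation of the classifier
#'
#' Each repeat draws a fresh plain-random (unstratified) 90/10
#' train/test split, trains the network from a fresh weight initialisation,
#' and evaluates on the held-out 10%. A split whose training part lacks one
#' of the classes is redrawn with a warning.
#'
#' @param features numeric feature matrix or data.frame.
#' @param labels 0/1 labels.
#' @param config an [mlp_config()]; its `seed` seeds the whole procedure.
#' @param n_repeats number of random splits (default 10).
#' @param test_fraction held-out fraction (default 0.1).
#' @param standardize passed to [mlp_fit()].
#' @return object of class `prs_cv`: data.frame `metrics` (one row per
#'   repeat: accuracy, precision, recall, auc) plus `mean` and `sd` rows
#'   accessible via `summary()`.
#' @export
cross_validate <- function(features, labels, config = mlp_config(),
                           n_repeats = 10L, test_fraction = 0.1,
                           standardize = FALSE) {
  X <- as.matrix(features); y <- as.integer(labels)
  n <- nrow(X)
  if (n < 20L || length(unique(y)) < 2L) {
    stop("need at least 20 records with both classes present")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n_test <- max(1L, round(test_fraction * n))
  rows <- vector("list", n_repeats)
  for (rep in seq_len(n_repeats)) {
    repeat {
      test <- sample.int(n, n_test)
      if (length(unique(y[-test])) == 2L) break
      warning("class absent from a training split; resampling")
    }
    fit_cfg <- config; fit_cfg$seed <- NULL  # stream already seeded
    fit <- mlp_fit(X[-test, , drop = FALSE], y[-test], fit_cfg,
                   standardize = standardize)
    p <- predict(fit, X[test, , drop = FALSE])
    ev <- evaluate_binary(p, y[test])
    rows[[rep]] <- data.frame(repeat_id = rep, accuracy = ev$accuracy,
                              precision = ev$precision, recall = ev$recall,
                              auc = ev$auc)
  }
  metrics <- do.call(rbind, rows)
  structure(list(metrics = metrics, config = config), class = "prs_cv")
}

#' @export
print.prs_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("cross-validation over %d random 90/10 splits\n", nrow(m)))
  for (col in c("accuracy", "precision", "recall", "auc")) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", col,
                mean(m[[col]], na.rm = TRUE), stats::sd(m[[col]], na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.prs_cv <- function(object, ...) {
  m <- object$metrics[, c("accuracy", "precision", "recall", "auc")]
  rbind(mean = colMeans(m, na.rm = TRUE),
        sd = apply(m, 2L, stats::sd, na.rm = TRUE))
}
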