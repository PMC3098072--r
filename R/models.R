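# Classifier backends (support-vector machine, feed-forward neural network),
# per-protein prediction assembly, and model serialization.

default_hyperparameters <- function(backend) {
  switch(backend,
    svm = list(kernel = "radial", cost = 10, gamma = 0.01, tune = FALSE,
               tune_cost = c(1, 10, 100), tune_gamma = c(0.01, 0.1)),
    ann = list(hidden = 10L, learning_rate = 0.01, max_epochs = 100L,
               patience = 5L, validation_fraction = 0.2))
}

default_threshold <- function(backend) switch(backend, svm = 0, ann = 0.5)

# Score sweep range per backend: ANN outputs lie in [0,1]; SVM decision
# values are signed margins swept over [-1, 1].
threshold_range <- function(backend) {
  switch(backend, svm = c(-1, 1), ann = c(0, 1))
}

#' Train a classifier on an encoded pattern dataset
#'
#' Fits either a support-vector machine (via libsvm, RBF kernel by default)
#' or a single-hidden-layer feed-forward neural network trained by online
#' error back-propagation on a sum-of-squares error with learning rate 0.01.
#' SVM scores are signed decision margins (positive class above 0); ANN
#' scores are logistic outputs in [0, 1].  Training is deterministic given
#' \code{seed} and the hyperparameters.
#'
#' @param dataset a \code{pattern_dataset} (see \code{\link{build_dataset}})
#'   containing both classes.
#' @param encoding "binary" or "pssm".
#' @param backend "svm" or "ann".
#' @param profiles named list of \code{pssm_profile} objects (required for
#'   \code{encoding = "pssm"}).
#' @param hyperparameters named list overriding the backend defaults.  SVM:
#'   \code{kernel}, \code{cost}, \code{gamma}, and \code{tune} (when TRUE, a
#'   small cost x gamma grid is selected by internal 3-fold cross-validation
#'   on the training data).  ANN: \code{hidden}, \code{learning_rate},
#'   \code{max_epochs}, \code{patience}, \code{validation_fraction}.
#' @param seed integer seed (mandatory).
#' @param threshold decision threshold stored on the model; defaults to 0
#'   (svm) or 0.5 (ann).  Usually set afterwards from a cross-validated
#'   threshold sweep via \code{\link{set_threshold}}.
#' @return object of class \code{gtp_model}.
#' @seealso \code{\link{score_model}}, \code{\link{five_fold_cv}}, \code{\link{predict_protein}}
#' @export
train_model <- function(dataset, encoding = c("binary", "pssm"),
                        backend = c("svm", "ann"), profiles = NULL,
                        hyperparameters = list(), seed, threshold = NULL) {
  encoding <- match.arg(encoding)
  backend <- match.arg(backend)
  stopifnot(inherits(dataset, "pattern_dataset"))
  x <- encode_patterns(dataset, encoding, profiles)
  y <- as_binary_labels(attr(x, "labels"))
  train_model_xy(x, y, backend, hyperparameters, seed,
                 meta = list(technique = dataset$technique,
                             encoding = encoding,
                             L = unique(dataset$patterns$L),
                             k = unique(dataset$patterns$k),
                             regime = dataset$regime,
                             n_pos = dataset$n_pos, n_neg = dataset$n_neg),
                 threshold = threshold)
}

# Core fit on a plain feature matrix + 0/1 labels; used by train_model and
# by cross-validation.
train_model_xy <- function(x, y, backend, hyperparameters, seed, meta,
                           threshold = NULL) {
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class; both classes are required")
  }
  hp <- utils::modifyList(default_hyperparameters(backend), hyperparameters)
  fit <- switch(backend,
    svm = fit_svm(x, y, hp, seed),
    ann = fit_mlp(x, y, hp, seed))
  structure(list(backend = backend,
                 technique = meta$technique,
                 encoding = meta$encoding,
                 L = meta$L, k = meta$k,
                 alphabet = .AA21,
                 normalization = "logistic",
                 hyperparameters = fit$hp,
                 fit = fit$fit,
                 threshold = if (is.null(threshold)) default_threshold(backend)
                             else threshold,
                 seed = as.integer(seed),
                 counts = c(n_pos = sum(y == 1L), n_neg = sum(y == 0L)),
                 regime = meta$regime),
            class = "gtp_model")
}

fit_svm <- function(x, y, hp, seed) {
  yf <- factor(ifelse(y == 1L, "positive", "negative"),
               levels = c("positive", "negative"))
  if (isTRUE(hp$tune)) {
    grid <- expand.grid(cost = hp$tune_cost, gamma = hp$tune_gamma)
    folds <- with_seed(seed, make_stratified_folds(y, 3L))
    mcc_of <- function(cost, gamma) {
      s <- numeric(length(y))
      for (f in 1:3) {
        te <- folds == f
        fit <- e1071::svm(x[!te, , drop = FALSE], yf[!te], scale = FALSE,
                          kernel = hp$kernel, cost = cost, gamma = gamma)
        s[te] <- svm_scores(fit, x[te, , drop = FALSE])
      }
      metrics_at_threshold(s, y, 0)$mcc
    }
    perf <- mapply(mcc_of, grid$cost, grid$gamma)
    best <- which.max(perf)
    hp$cost <- grid$cost[best]
    hp$gamma <- grid$gamma[best]
  }
  fit <- e1071::svm(x, yf, scale = FALSE, kernel = hp$kernel,
                    cost = hp$cost, gamma = hp$gamma)
  list(fit = fit, hp = hp[c("kernel", "cost", "gamma")])
}

svm_scores <- function(fit, x) {
  if (nrow(x) == 0L) return(numeric(0))
  p <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  # libsvm's decision value is positive for the class named first in the
  # column label; orient so that "positive" scores high
  s <- if (identical(colnames(dv), "negative/positive")) -dv[, 1] else dv[, 1]
  unname(s)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Single-hidden-layer perceptron trained by online back-propagation with a
# sum-of-squares error.  Held-out SSE (a seeded validation split) decides
# when to stop: training halts when the best validation SSE has not improved
# for `patience` consecutive epochs, and the best weights are kept.
fit_mlp <- function(x, y, hp, seed) {
  n <- nrow(x); d <- ncol(x); h <- as.integer(hp$hidden)
  lr <- hp$learning_rate
  res <- with_seed(seed, {
    W1 <- matrix(stats::runif((d + 1L) * h, -0.5, 0.5), d + 1L, h)
    W2 <- matrix(stats::runif(h + 1L, -0.5, 0.5), h + 1L, 1L)
    n_val <- max(1L, round(hp$validation_fraction * n))
    val <- sample.int(n, n_val)
    tr <- setdiff(seq_len(n), val)
    if (length(tr) == 0L) { tr <- val }  # degenerate tiny input
    xv <- cbind(1, x[val, , drop = FALSE]); yv <- y[val]
    best <- list(W1 = W1, W2 = W2, sse = Inf)
    stale <- 0L
    for (epoch in seq_len(hp$max_epochs)) {
      for (i in sample(tr)) {
        a0 <- c(1, x[i, ])
        z1 <- sigmoid(drop(a0 %*% W1))
        a1 <- c(1, z1)
        out <- sigmoid(drop(a1 %*% W2))
        err <- out - y[i]
        delta2 <- err * out * (1 - out)
        delta1 <- (W2[-1, 1] * delta2) * z1 * (1 - z1)
        W2 <- W2 - lr * delta2 * a1
        W1 <- W1 - lr * outer(a0, delta1)
      }
      pv <- sigmoid(cbind(1, sigmoid(xv %*% W1)) %*% W2)
      sse <- sum((pv - yv)^2)
      if (sse < best$sse - 1e-9) {
        best <- list(W1 = W1, W2 = W2, sse = sse)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= hp$patience) break
      }
    }
    best
  })
  list(fit = list(W1 = res$W1, W2 = res$W2),
       hp = hp[c("hidden", "learning_rate", "max_epochs", "patience",
                 "validation_fraction")])
}

mlp_scores <- function(fit, x) {
  if (nrow(x) == 0L) return(numeric(0))
  unname(drop(sigmoid(cbind(1, sigmoid(cbind(1, x) %*% fit$W1)) %*% fit$W2)))
}

#' Score feature vectors with a trained model
#'
#' @param model a \code{gtp_model}.
#' @param x numeric matrix (rows = patterns, \code{L * 21} columns) or a
#'   single vector of that length.
#' @return numeric score per row: signed SVM margin or ANN output in [0,1].
#'   Calls are obtained by thresholding at \code{model$threshold}
#'   (score >= threshold is positive).
#' @export
score_model <- function(model, x) {
  stopifnot(inherits(model, "gtp_model"))
  if (is.null(dim(x))) {
    if (length(x) == 0L) return(numeric(0))
    x <- matrix(x, nrow = 1L)
  }
  if (nrow(x) == 0L) return(numeric(0))
  want <- model$L * 21L
  if (ncol(x) != want) {
    stop("feature dimension mismatch: model expects ", want,
         " values (L = ", model$L, " x 21), got ", ncol(x))
  }
  switch(model$backend,
    svm = svm_scores(model$fit, x),
    ann = mlp_scores(model$fit, x))
}

#' Set the decision threshold of a trained model
#'
#' @param model a \code{gtp_model}.
#' @param threshold new threshold (ANN: in [0,1]; SVM: in [-1,1]).
#' @return the model with \code{threshold} replaced.
#' @export
set_threshold <- function(model, threshold) {
  stopifnot(inherits(model, "gtp_model"), is.numeric(threshold),
            length(threshold) == 1L)
  rng <- threshold_range(model$backend)
  if (threshold < rng[1] || threshold > rng[2]) {
    stop("threshold ", threshold, " outside the ", model$backend,
         " sweep range [", rng[1], ", ", rng[2], "]")
  }
  model$threshold <- threshold
  model
}

#' @export
print.gtp_model <- function(x, ...) {
  cat(sprintf("<gtp_model> %s/%s/%s L=%d k=%d threshold=%.3g (%d pos / %d neg)\n",
              x$backend, x$technique, x$encoding, x$L, x$k, x$threshold,
              x$counts[["n_pos"]], x$counts[["n_neg"]]))
  invisible(x)
}

#' Predict GTP-interacting residues for one protein
#'
#' Generates all windows of each supplied model's technique over the chain,
#' scores them, thresholds at each model's stored decision threshold, and
#' assembles residue-level calls.  The combined per-residue call is by
#' default the union: a residue is positive when called by the
#' single-residue model or covered by any positive dipeptide/tripeptide
#' call.  With \code{combine = "majority"}, a residue must be supported by
#' more than half of the supplied models.
#'
#' @param sequence amino-acid string (20 standard letters).
#' @param models named list with any of elements \code{srt}, \code{dpt},
#'   \code{tpt}, each a \code{gtp_model} of the matching technique.
#' @param profile \code{pssm_profile} for the chain; required when any
#'   model uses PSSM encoding.
#' @param chain_id identifier used in the output.
#' @param combine "union" (default) or "majority".
#' @return object of class \code{residue_prediction}; see
#'   \code{\link{as.data.frame.residue_prediction}} for the tabular form.
#' @export
predict_protein <- function(sequence, models, profile = NULL,
                            chain_id = "query", combine = c("union", "majority")) {
  combine <- match.arg(combine)
  stopifnot(is.list(models), length(models) > 0L)
  names(models) <- tolower(names(models))
  bad <- setdiff(names(models), c("srt", "dpt", "tpt"))
  if (length(bad)) stop("unknown model slot(s): ", paste(bad, collapse = ", "))
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  chain <- labeled_chain(chain_id, sequence, integer(n))

  track <- function(slot) {
    model <- models[[slot]]
    if (is.null(model)) return(NULL)
    stopifnot(inherits(model, "gtp_model"))
    if (tolower(model$technique) != slot) {
      stop("model in slot '", slot, "' was trained for technique ",
           model$technique)
    }
    pats <- extract_patterns(chain, model$technique, L = model$L)
    if (model$encoding == "pssm") {
      if (is.null(profile)) {
        stop("model '", slot, "' uses PSSM encoding but no profile was supplied",
             " for chain '", chain_id, "'")
      }
      if (nrow(profile$matrix) != n) {
        stop("profile has ", nrow(profile$matrix), " rows but chain '",
             chain_id, "' has ", n, " residues")
      }
    }
    x <- encode_patterns(pats, model$encoding,
                         profiles = stats::setNames(list(profile), chain_id))
    s <- score_model(model, x)
    data.frame(start = pats$center_start, score = s,
               call = as.integer(s >= model$threshold))
  }

  srt <- track("srt"); dpt <- track("dpt"); tpt <- track("tpt")

  # residue-level implied call per technique: positive if any positive
  # k-mer call covers the residue; NA when the technique is absent
  implied <- function(tr, k) {
    if (is.null(tr)) return(NULL)
    v <- integer(n)
    for (s in tr$start[tr$call == 1L]) v[s:(s + k - 1L)] <- 1L
    v
  }
  tracks <- Filter(Negate(is.null),
                   list(srt = implied(srt, 1L), dpt = implied(dpt, 2L),
                        tpt = implied(tpt, 3L)))
  votes <- Reduce(`+`, tracks)
  combined <- if (combine == "union") as.integer(votes > 0L)
              else as.integer(votes > length(tracks) / 2)

  structure(list(chain_id = chain_id, sequence = sequence,
                 srt = srt, dpt = dpt, tpt = tpt,
                 combined = combined, combine = combine),
            class = "residue_prediction")
}

#' Tabulate a residue prediction
#'
#' One row per residue: position, residue letter, per-technique score and
#' call (dipeptide/tripeptide values are attached to the k-mer's first
#' residue; trailing positions that start no k-mer are NA), and the
#' combined call.
#'
#' @param x a \code{residue_prediction}.
#' @param ... ignored.
#' @return data frame with N rows.
#' @export
as.data.frame.residue_prediction <- function(x, ...) {
  n <- nchar(x$sequence)
  pad_track <- function(tr) {
    if (is.null(tr)) return(list(score = rep(NA_real_, n),
                                 call = rep(NA_integer_, n)))
    score <- rep(NA_real_, n); call <- rep(NA_integer_, n)
    score[tr$start] <- tr$score; call[tr$start] <- tr$call
    list(score = score, call = call)
  }
  s <- pad_track(x$srt); d <- pad_track(x$dpt); t <- pad_track(x$tpt)
  data.frame(position = seq_len(n),
             residue = strsplit(x$sequence, "", fixed = TRUE)[[1]],
             srt_score = s$score, srt_call = s$call,
             dpt_score = d$score, dpt_call = d$call,
             tpt_score = t$score, tpt_call = t$call,
             combined_call = x$combined)
}

#' @export
print.residue_prediction <- function(x, ...) {
  cat(sprintf("<residue_prediction> %s: %d residues, %d called interacting (%s)\n",
              x$chain_id, nchar(x$sequence), sum(x$combined), x$combine))
  invisible(x)
}

#' Save / load a trained model
#'
#' A model directory holds a JSON manifest (backend, technique, encoding,
#' window length, threshold, hyperparameters, alphabet order, normalization)
#' next to the serialized weights.  \code{load_model} refuses manifests that
#' disagree with the stored weights' configuration.
#'
#' @param model a \code{gtp_model}.
#' @param dir directory to create/populate.
#' @return \code{save_model}: invisibly, \code{dir}; \code{load_model}: the
#'   \code{gtp_model}.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "gtp_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- model[c("backend", "technique", "encoding", "L", "k",
                      "alphabet", "normalization", "hyperparameters",
                      "threshold", "seed", "regime")]
  manifest$counts <- as.list(model$counts)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  model_path <- file.path(dir, "model.rds")
  stopifnot(file.exists(manifest_path), file.exists(model_path))
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  model <- readRDS(model_path)
  stopifnot(inherits(model, "gtp_model"))
  same <- function(field) identical(as.character(manifest[[field]]),
                                    as.character(model[[field]]))
  for (field in c("backend", "technique", "encoding")) {
    if (!same(field)) {
      stop("model manifest disagrees with stored weights on '", field, "'")
    }
  }
  if (!identical(as.integer(manifest$L), as.integer(model$L)) ||
      !identical(manifest$alphabet, model$alphabet)) {
    stop("model manifest disagrees with stored weights on window/alphabet")
  }
  model$threshold <- manifest$threshold
  model
}
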