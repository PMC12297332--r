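# Downstream evaluation protocol ----------------------------------------------
#
# Frozen-backbone adaptation: an L2-penalised logistic probe on standardised
# full embeddings (standardisation fit on the training set only), 2-D
# projections by PCA or UMAP (cosine metric, deterministic seeding) probed
# with an unscaled logistic model and KNN, transport of frozen fits across
# datasets, and the rule that drops classes every model finds trivial
# (minimum AUC across models >= 0.95).

#' Evaluation protocol settings
#'
#' @param max_iterations Maximum solver iterations for the probes
#'   (default 20000).
#' @param standardize Standardise full embeddings to zero mean / unit variance
#'   with parameters estimated on the training set only (default TRUE; 2-D
#'   projections are never rescaled).
#' @param knn_k Neighbours for the KNN probe (default 5).
#' @param projection_dim Projection dimension (default 2).
#' @param umap_metric Distance metric for UMAP (default "cosine").
#' @param pca_precomponents Principal components kept before UMAP in the
#'   sensitivity variant (default 100).
#' @param trivial_auc_threshold Classes where every model reaches at least
#'   this AUC are dropped as trivial (default 0.95, strict less-than keeps).
#' @return An object of class `eval_protocol`.
#' @export
eval_protocol <- function(max_iterations = 20000L, standardize = TRUE,
                          knn_k = 5L, projection_dim = 2L,
                          umap_metric = c("cosine", "euclidean"),
                          pca_precomponents = 100L,
                          trivial_auc_threshold = 0.95) {
  stopifnot(max_iterations >= 1, knn_k >= 1, projection_dim >= 1,
            trivial_auc_threshold > 0, trivial_auc_threshold <= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 standardize = isTRUE(standardize), knn_k = as.integer(knn_k),
                 projection_dim = as.integer(projection_dim),
                 umap_metric = match.arg(umap_metric),
                 pca_precomponents = as.integer(pca_precomponents),
                 trivial_auc_threshold = trivial_auc_threshold),
            class = "eval_protocol")
}

#' Area under the ROC curve
#'
#' @param labels Binary labels (0/1, logical, or 2-level factor).
#' @param scores Numeric scores, larger meaning more positive.
#' @return AUC in `[0, 1]`, or `NA` (with attribute `"single_class"`) when
#'   only one class is present.
#' @export
auc_score <- function(labels, scores) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) < 2L) {
    return(structure(NA_real_, single_class = TRUE))
  }
  as.numeric(pROC::auc(pROC::roc(y, as.numeric(scores), quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Cosine affinity of two vectors
#'
#' `a . b / (||a|| ||b||)`, in `[-1, 1]`. The UMAP metric uses one minus this
#' value as its distance.
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_affinity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine affinity undefined for zero vectors",
                               call. = FALSE)
  sum(a * b) / (na * nb)
}

# Standardiser fit on training data only (constant columns get unit scale).
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mean = mu, sd = sd)
}
apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, `/`)
}

# The probes mirror a penalised logistic fit with unit inverse-regularisation
# strength: ridge penalty lambda = 1 / n_train in glmnet's parameterisation.
probe_lambda <- function(n) 1 / n

#' Fit a linear probe on frozen embeddings
#'
#' An L2-penalised logistic model (ridge, penalty equivalent to unit inverse
#' regularisation strength) on standardised embeddings; standardisation
#' parameters are estimated on the training set only. With more than two
#' classes a single multinomial model is fitted and per-class one-vs-rest
#' scores are derived from its predicted probabilities. A binary probe on
#' `d`-dimensional embeddings has exactly `d + 1` parameters.
#'
#' @param train `n x d` embedding matrix.
#' @param labels Vector of length `n`; 2 levels gives a binary probe, more a
#'   multinomial one.
#' @param protocol An [eval_protocol()].
#' @param target Label name used in error messages.
#' @return An object of class `linear_probe`.
#' @export
fit_linear_probe <- function(train, labels, protocol = eval_protocol(),
                             target = "target") {
  stopifnot(is.matrix(train), nrow(train) == length(labels))
  y <- factor(labels)
  if (nlevels(y) < 2L) {
    stop(sprintf("target '%s' has a single class in the training set", target),
         call. = FALSE)
  }
  scaler <- if (protocol$standardize) fit_scaler(train) else NULL
  x <- if (is.null(scaler)) train else apply_scaler(scaler, train)
  fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
  fit <- glmnet::glmnet(x, y, family = fam, alpha = 0,
                        lambda = probe_lambda(nrow(x)), standardize = FALSE,
                        maxit = 50 * protocol$max_iterations, thresh = 1e-9)
  structure(list(fit = fit, scaler = scaler, levels = levels(y),
                 family = fam, d = ncol(train), target = target),
            class = "linear_probe")
}

#' Predicted class probabilities from a linear probe
#'
#' @param probe A [fit_linear_probe()] result.
#' @param newdata `m x d` embedding matrix.
#' @return Binary probe: numeric vector of probabilities for the second
#'   (positive) level. Multinomial probe: `m x K` matrix of class
#'   probabilities.
#' @export
predict_probe <- function(probe, newdata) {
  stopifnot(inherits(probe, "linear_probe"))
  if (ncol(newdata) != probe$d) {
    stop(sprintf("embedding dimension mismatch: probe fit on %d, data has %d",
                 probe$d, ncol(newdata)), call. = FALSE)
  }
  x <- if (is.null(probe$scaler)) newdata else apply_scaler(probe$scaler, newdata)
  pr <- stats::predict(probe$fit, newx = x, type = "response")
  if (probe$family == "binomial") as.numeric(pr) else pr[, , 1]
}

#' Parameter count of a linear probe
#'
#' One weight per embedding dimension plus an intercept, per fitted decision
#' function: `d + 1` for a binary probe, `K (d + 1)` for a K-class
#' multinomial probe.
#'
#' @param probe A `linear_probe`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(probe) {
  stopifnot(inherits(probe, "linear_probe"))
  per <- probe$d + 1L
  if (probe$family == "binomial") per else length(probe$levels) * per
}

# --- 2-D projections ---------------------------------------------------------

run_umap_python <- function(train, test = NULL, metric = "cosine", seed = 0L,
                            n_components = 2L) {
  py <- Sys.which("python")
  if (py == "") stop("UMAP requires a `python` with umap-learn on the PATH",
                     call. = FALSE)
  td <- tempfile("umap")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  tr_path <- file.path(td, "train.csv")
  utils::write.table(train, tr_path, sep = ",", row.names = FALSE, col.names = FALSE)
  te_path <- "NONE"
  if (!is.null(test)) {
    te_path <- file.path(td, "test.csv")
    utils::write.table(test, te_path, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  script <- file.path(td, "run_umap.py")
  writeLines(c(
    "import sys, warnings",
    "warnings.filterwarnings('ignore')",
    "import numpy as np, umap",
    "train = np.loadtxt(sys.argv[1], delimiter=',', ndmin=2)",
    "m = umap.UMAP(n_components=int(sys.argv[4]), metric=sys.argv[2],",
    "              random_state=int(sys.argv[3]), n_jobs=1)",
    "emb = m.fit_transform(train)",
    "np.savetxt(sys.argv[5], emb, delimiter=',')",
    "if sys.argv[6] != 'NONE':",
    "    test = np.loadtxt(sys.argv[6], delimiter=',', ndmin=2)",
    "    np.savetxt(sys.argv[7], m.transform(test), delimiter=',')"
  ), script)
  out_tr <- file.path(td, "emb_train.csv")
  out_te <- file.path(td, "emb_test.csv")
  status <- system2(py, c(script, tr_path, metric, seed, n_components,
                          out_tr, te_path, out_te),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(out_tr)) {
    stop("UMAP subprocess failed", call. = FALSE)
  }
  res <- list(train = as.matrix(utils::read.table(out_tr, sep = ",")))
  if (!is.null(test)) res$test <- as.matrix(utils::read.table(out_te, sep = ","))
  res
}

#' Fit a 2-D projection on training embeddings
#'
#' `"pca"` keeps the first two principal components (centred, unscaled).
#' `"umap"` runs UMAP with the protocol's metric, fixed `random_state`, and
#' single-threaded layout so results are deterministic. `"pca100_umap"` first
#' reduces to the leading principal components (default 100) and runs UMAP in
#' that space -- the sensitivity variant that removes the effect of differing
#' raw dimensionalities. The fit uses training rows only; test rows are mapped
#' through the frozen transform by [predict_projection()].
#'
#' @param train `n x d` embedding matrix (n >= 10).
#' @param method `"pca"`, `"umap"`, or `"pca100_umap"`.
#' @param protocol An [eval_protocol()]; supplies the UMAP metric and the PCA
#'   pre-component count. The metric is ignored (with a warning) for PCA.
#' @param metric Overrides the protocol metric when given.
#' @param seed Integer seed for UMAP.
#' @return An object of class `projection_fit` carrying `train_coords`.
#' @export
fit_projection <- function(train, method = c("pca", "umap", "pca100_umap"),
                           protocol = eval_protocol(), metric = NULL,
                           seed = 0L) {
  stopifnot(is.matrix(train), nrow(train) >= 10)
  method <- match.arg(method)
  metric_given <- !is.null(metric)
  if (is.null(metric)) metric <- protocol$umap_metric
  k <- protocol$projection_dim
  obj <- list(method = method, metric = metric, seed = as.integer(seed), dim = ncol(train))
  if (method == "pca") {
    if (metric_given && metric != "euclidean") {
      warning("PCA ignores the distance metric", call. = FALSE)
    }
    pc <- stats::prcomp(train, center = TRUE, scale. = FALSE, rank. = k)
    obj$center <- pc$center
    obj$rotation <- pc$rotation
    obj$sdev <- pc$sdev[seq_len(k)]
    obj$train_coords <- pc$x[, seq_len(k), drop = FALSE]
  } else {
    pre <- NULL
    tr <- train
    if (method == "pca100_umap") {
      npc <- min(protocol$pca_precomponents, ncol(train), nrow(train) - 1L)
      pc <- stats::prcomp(train, center = TRUE, scale. = FALSE, rank. = npc)
      pre <- list(center = pc$center, rotation = pc$rotation)
      tr <- pc$x[, seq_len(npc), drop = FALSE]
    }
    obj$pre <- pre
    obj$train_ref <- tr     # UMAP refits deterministically from these rows
    um <- run_umap_python(tr, metric = metric, seed = seed, n_components = k)
    obj$train_coords <- um$train
  }
  structure(obj, class = "projection_fit")
}

#' Map new embeddings through a fitted projection
#'
#' PCA applies the frozen centring and rotation. UMAP re-runs the fit on the
#' stored training rows with the stored seed (deterministic) and transforms
#' the new rows through that model; no refitting on the new data occurs.
#'
#' @param fit A [fit_projection()] result.
#' @param newdata `m x d` embedding matrix.
#' @return `m x 2` coordinate matrix.
#' @export
predict_projection <- function(fit, newdata) {
  stopifnot(inherits(fit, "projection_fit"))
  if (ncol(newdata) != fit$dim) {
    stop(sprintf("dimension mismatch: projection fit on %d, data has %d",
                 fit$dim, ncol(newdata)), call. = FALSE)
  }
  if (fit$method == "pca") {
    return(sweep(newdata, 2, fit$center) %*% fit$rotation)
  }
  x <- newdata
  if (!is.null(fit$pre)) {
    x <- sweep(x, 2, fit$pre$center) %*% fit$pre$rotation
  }
  run_umap_python(fit$train_ref, test = x, metric = fit$metric,
                  seed = fit$seed)$test
}

#' Probe a 2-D projection with logistic regression and KNN
#'
#' The logistic probe is a single binary ridge model per target fitted on the
#' raw (unrescaled) 2-D coordinates; the KNN probe averages the labels of the
#' `k` nearest training points. Both are evaluated on the test coordinates.
#'
#' @param train_coords,test_coords `n x 2` / `m x 2` coordinate matrices.
#' @param train_labels,test_labels Binary labels.
#' @param protocol An [eval_protocol()].
#' @return List with `auc` (named vector for logistic and knn), `scores`
#'   (per-classifier test scores for bootstrapping), and `single_class_test`
#'   flagging a test set lacking one of the classes.
#' @export
probe_2d <- function(train_coords, test_coords, train_labels, test_labels,
                     protocol = eval_protocol()) {
  ytr <- factor(train_labels)
  stopifnot(nlevels(ytr) == 2L)
  pos <- levels(ytr)[2]
  fit <- glmnet::glmnet(train_coords, ytr, family = "binomial", alpha = 0,
                        lambda = probe_lambda(nrow(train_coords)),
                        standardize = FALSE, maxit = 50 * protocol$max_iterations,
                        thresh = 1e-9)
  s_lr <- as.numeric(stats::predict(fit, newx = test_coords, type = "response"))
  kn <- class::knn(train_coords, test_coords, cl = ytr,
                   k = protocol$knn_k, prob = TRUE)
  pwin <- attr(kn, "prob")
  s_knn <- ifelse(kn == pos, pwin, 1 - pwin)
  single <- length(unique(test_labels)) < 2L
  list(auc = c(logistic = auc_score(test_labels, s_lr),
               knn = auc_score(test_labels, s_knn)),
       scores = list(logistic = s_lr, knn = s_knn),
       single_class_test = single)
}

#' Evaluate frozen fits on an external dataset
#'
#' Applies a probe (and optionally a projection) fitted on dataset A to the
#' embeddings of dataset B without any refitting: the standardiser, the
#' projection, and the classifier all stay frozen.
#'
#' @param probe A `linear_probe` fitted on dataset A.
#' @param embeddings Dataset-B embedding matrix.
#' @param labels Dataset-B labels for the probe's target.
#' @param projection Optional `projection_fit` from dataset A applied before
#'   the probe (the probe must then have been fitted on A's coordinates).
#' @return List with `auc` and `scores`.
#' @export
transport_evaluate <- function(probe, embeddings, labels, projection = NULL) {
  x <- embeddings
  if (!is.null(projection)) x <- predict_projection(projection, x)
  scores <- predict_probe(probe, x)
  if (is.matrix(scores)) {
    auc <- vapply(seq_along(probe$levels), function(k) {
      auc_score(as.integer(factor(labels, levels = probe$levels)) == k, scores[, k])
    }, numeric(1))
    names(auc) <- probe$levels
  } else {
    auc <- auc_score(labels, scores)
  }
  list(auc = auc, scores = scores)
}

#' Drop classes that every model finds trivial
#'
#' A class is kept iff the minimum AUC across models is strictly below the
#' threshold; classes at exactly the threshold are dropped. Dropped classes
#' are meant to remain in evaluation sets as negative examples.
#'
#' @param auc_table Numeric matrix, classes in rows, models in columns.
#' @param threshold AUC threshold (default 0.95).
#' @return Character vector of kept class names.
#' @export
select_nontrivial_classes <- function(auc_table, threshold = 0.95) {
  stopifnot(is.matrix(auc_table), !is.null(rownames(auc_table)),
            !anyNA(auc_table))
  keep <- apply(auc_table, 1, min) < threshold
  rownames(auc_table)[keep]
}
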