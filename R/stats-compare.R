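# Statistical model comparison -------------------------------------------------
#
# Robust model ranking on a shared test set: the test set is bootstrapped 100
# times, per-model AUCs are computed on identical resample index sets (so the
# comparison is paired), medians are reported, and the best and second-best
# models are compared with a two-sided Wilcoxon signed-rank test across the
# paired bootstrap AUCs; p < alpha is a win, otherwise a tie. Wins and ties
# are tallied per target, never aggregated across targets.

#' Paired bootstrap AUCs for several models
#'
#' Each resample is drawn with replacement at full test-set size and is shared
#' by every model. Resamples containing a single class are redrawn (the redraw
#' count is recorded); after 1,000 failed attempts an error is raised.
#'
#' @param scores Numeric matrix `n x n_models` (or vector for one model) of
#'   test scores, larger meaning more positive.
#' @param labels Binary labels of length `n`; both classes must be present.
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @return Object of class `bootstrap_aucs`: matrix `n_boot x n_models` of
#'   AUCs with attributes `seed` and `redraws`.
#' @export
bootstrap_auc <- function(scores, labels, n_boot = 100L, seed = 1L) {
  if (is.vector(scores)) scores <- matrix(scores, ncol = 1)
  stopifnot(nrow(scores) == length(labels), n_boot >= 1)
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) < 2L) {
    stop("both classes must be present in the full test set", call. = FALSE)
  }
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("model_", seq_len(ncol(scores)))
  }
  n <- length(y)
  out <- matrix(NA_real_, n_boot, ncol(scores),
                dimnames = list(NULL, colnames(scores)))
  redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      attempts <- 0L
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2L) break
        attempts <- attempts + 1L
        redraws <- redraws + 1L
        if (attempts >= 1000L) {
          stop("could not draw a two-class bootstrap resample in 1,000 attempts",
               call. = FALSE)
        }
      }
      for (m in seq_len(ncol(scores))) {
        out[b, m] <- auc_score(y[idx], scores[idx, m])
      }
    }
  })
  structure(out, seed = as.integer(seed), redraws = redraws,
            class = c("bootstrap_aucs", "matrix", "array"))
}

#' Median bootstrap AUC per model
#' @param boot A [bootstrap_auc()] result.
#' @return Named numeric vector of medians.
#' @export
median_auc <- function(boot) {
  apply(unclass(boot), 2, stats::median)
}

# Paired two-sided signed-rank p-value with the classic zero policy: exact
# zero differences are discarded; if none remain the methods are
# indistinguishable and p = 1.
signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  suppressWarnings(stats::wilcox.test(d, alternative = "two.sided")$p.value)
}

#' Compare the best and second-best models
#'
#' Models are ranked by median bootstrap AUC; the top two are compared with a
#' two-sided Wilcoxon signed-rank test over their paired bootstrap AUCs. The
#' verdict is a win for the best model when `p < alpha`, otherwise a tie.
#' Because the test is paired on shared resamples, permuting model order
#' never changes any p-value.
#'
#' @param boot A [bootstrap_auc()] result with >= 2 models.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `comparison_result`: best, second, their median
#'   AUCs, `p_value`, and `verdict` ("win"/"tie").
#' @export
compare_best_vs_second <- function(boot, alpha = 0.05) {
  m <- unclass(boot)
  stopifnot(ncol(m) >= 2)
  med <- apply(m, 2, stats::median)
  ord <- order(med, decreasing = TRUE)
  best <- colnames(m)[ord[1]]; second <- colnames(m)[ord[2]]
  p <- signed_rank_p(m[, best], m[, second])
  structure(list(best = best, second = second,
                 median_best = med[[best]], median_second = med[[second]],
                 p_value = p, alpha = alpha,
                 verdict = if (p < alpha) "win" else "tie"),
            class = "comparison_result")
}

#' @exportS3Method base::print
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (median AUC %.4f) vs %s (%.4f): p = %.3g -> %s\n",
              x$best, x$median_best, x$second, x$median_second,
              x$p_value, x$verdict))
  invisible(x)
}

#' Tally wins and ties across targets
#'
#' One comparison per target; no p-values are aggregated. A win counts for
#' the winning model; a tie counts for both models involved.
#'
#' @param results List of `comparison_result`s (one per target).
#' @return data.frame with model, wins, ties.
#' @export
tally_wins <- function(results) {
  stopifnot(all(vapply(results, inherits, logical(1), "comparison_result")))
  models <- unique(unlist(lapply(results, function(r) c(r$best, r$second))))
  wins <- stats::setNames(integer(length(models)), models)
  ties <- wins
  for (r in results) {
    if (r$verdict == "win") {
      wins[r$best] <- wins[r$best] + 1L
    } else {
      ties[r$best] <- ties[r$best] + 1L
      ties[r$second] <- ties[r$second] + 1L
    }
  }
  data.frame(model = models, wins = as.integer(wins), ties = as.integer(ties),
             row.names = NULL)
}
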