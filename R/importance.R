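# HRV-branch feature importance: gradient-based attributions (integrated
# gradients against a training-mean baseline) with a permutation-importance
# fallback that works for any classifier head.

#' Descriptors reported in the group-comparison tables
#'
#' The 15 descriptors printed in the statistical comparison tables; the
#' importance table is reported over this roster by default.
#' @return character vector of length 15.
#' @export
table_feature_roster <- function() {
  c("mean_rr", "sdnn", "lf_hf", "sd1_sd2", "poincare_area_s", "sampen",
    "dfa_alpha1", "hf", "lf", "vlf", "rmssd", "sdsd", "sd2", "sd1", "pnn50")
}

# gradient of the class-c logit wrt the standardized HRV input; the fusion
# is a concatenation, so the RR branch does not enter this gradient
hrv_branch_grad <- function(model, Hs, class_idx) {
  p <- model$params
  Ht <- t(Hs)                      # features x samples
  z1 <- p$Wh1 %*% Ht + p$bh1
  a1 <- relu(z1)
  z2 <- p$Wh2 %*% a1 + p$bh2
  rr_dim <- model$cfg$fusion_dim - model$cfg$mlp_neurons[2]
  wo_hrv <- p$Wo[, (rr_dim + 1):model$cfg$fusion_dim, drop = FALSE]
  n <- nrow(Hs)
  G <- matrix(0, n, ncol(Hs))
  for (i in seq_len(n)) {
    d2 <- wo_hrv[class_idx[i], ] * (z2[, i] > 0)
    d1 <- crossprod(p$Wh2, d2)[, 1] * (z1[, i] > 0)
    G[i, ] <- as.numeric(crossprod(p$Wh1, d1))
  }
  G
}

#' HRV feature importance
#'
#' `method = "gradient_attribution"`: integrated gradients of the
#' predicted-class logit with respect to the standardized HRV inputs,
#' integrated from the training-mean baseline (the origin in standardized
#' space) in `steps` interpolation steps; per-feature importance is the
#' mean absolute attribution. `method = "permutation"`: accuracy drop when
#' a feature column is permuted (averaged over `repeats` shuffles), which
#' also covers SVM-head models.
#'
#' Importances are nonnegative and normalized to sum 1 over the reported
#' feature set (by default the descriptors of the group-comparison
#' tables, [table_feature_roster()]).
#'
#' @param model a trained `multimodal_model`.
#' @param samples list with `X`, `H`, `y` as in [train_model()].
#' @param method attribution method.
#' @param features features to report (subset of the HRV columns).
#' @param steps integration steps for the gradient method.
#' @param repeats shuffles per feature for the permutation method.
#' @param seed seed for the permutation method.
#' @return data.frame of class `ImportanceTable` (`feature`, `importance`),
#'   sorted decreasing; `method` recorded as an attribute.
#' @export
feature_importance <- function(model, samples,
                               method = c("gradient_attribution", "permutation"),
                               features = table_feature_roster(),
                               steps = 20L, repeats = 3L, seed = 1L) {
  method <- match.arg(method)
  if (!isTRUE(model$trained)) stop("model is not trained")
  cn <- colnames(samples$H)
  if (is.null(cn)) cn <- hrv_feature_names()
  if (method == "gradient_attribution") {
    Hs <- apply_scaler(model$scaler, samples$H)
    kept <- colnames(Hs)
    if (is.null(kept)) kept <- cn[!(cn %in% model$scaler$dropped)]
    pred <- predict(model, samples$X, samples$H)
    cls <- match(as.character(pred$labels), model$class_levels)
    acc_grad <- matrix(0, nrow(Hs), ncol(Hs))
    for (a in (seq_len(steps) - 0.5) / steps) {
      acc_grad <- acc_grad + hrv_branch_grad(model, Hs * a, cls)
    }
    attrib <- Hs * acc_grad / steps  # baseline is the origin (training mean)
    raw <- colMeans(abs(attrib))
    names(raw) <- kept
  } else {
    set.seed(as.integer(seed))
    base_acc <- mean(predict(model, samples$X, samples$H)$labels == samples$y)
    raw <- vapply(seq_along(cn), function(j) {
      drop <- 0
      for (r in seq_len(repeats)) {
        Hp <- samples$H
        Hp[, j] <- sample(Hp[, j])
        drop <- drop + base_acc -
          mean(predict(model, samples$X, Hp)$labels == samples$y)
      }
      max(drop / repeats, 0)
    }, numeric(1))
    names(raw) <- cn
  }
  features <- features[features %in% names(raw)]
  imp <- raw[features]
  imp[!is.finite(imp)] <- 0
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  out <- data.frame(feature = names(imp), importance = as.numeric(imp))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  attr(out, "method") <- method
  class(out) <- c("ImportanceTable", "data.frame")
  out
}
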