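# The three multimodal classifiers: a shared 1D-CNN RR-sequence encoder and
# an HRV multilayer perceptron fused by concatenation into a 96-dimensional
# representation, classified by a softmax layer (variant A), by a linear
# one-vs-rest SVM on the trained backbone's embeddings (variant B), or with
# an LSTM replacing the flatten/projection stage before the SVM (variant C).
# Training is end-to-end with Adam and categorical cross-entropy under
# strict subject-wise partitioning.

CLASS_LEVELS <- c("MetS", "C", "M")

#' Encoder configuration (defaults follow the study architecture)
#'
#' @param conv_filters filters in the two convolutional blocks.
#' @param kernel_sizes kernel sizes of the two blocks.
#' @param pool_size max-pooling size.
#' @param conv_dropout dropout rate in the convolutional blocks.
#' @param rr_embedding_dim RR-branch embedding width.
#' @param mlp_neurons HRV-branch dense layer widths.
#' @param mlp_dropout dropout rate in the MLP layers.
#' @param hrv_embedding_dim HRV-branch embedding width.
#' @param lstm_units LSTM hidden units (variant C).
#' @param seq_len RR sequence length.
#' @param hrv_input_dim HRV feature dimension.
#' @param svm_cost linear-SVM regularization constant for SVM heads.
#' @return object of class `EncoderConfig`; the fusion dimension is
#'   `rr_embedding_dim + hrv_embedding_dim` (96 by default).
#' @export
encoder_config <- function(conv_filters = c(64L, 128L),
                           kernel_sizes = c(5L, 3L), pool_size = 2L,
                           conv_dropout = 0.2, rr_embedding_dim = 64L,
                           mlp_neurons = c(64L, 32L), mlp_dropout = 0.3,
                           hrv_embedding_dim = 32L, lstm_units = 64L,
                           seq_len = 256L, hrv_input_dim = 32L,
                           svm_cost = 1.0) {
  structure(list(conv_filters = conv_filters, kernel_sizes = kernel_sizes,
                 pool_size = pool_size, conv_dropout = conv_dropout,
                 rr_embedding_dim = rr_embedding_dim,
                 mlp_neurons = mlp_neurons, mlp_dropout = mlp_dropout,
                 hrv_embedding_dim = hrv_embedding_dim,
                 lstm_units = lstm_units, seq_len = seq_len,
                 hrv_input_dim = hrv_input_dim, svm_cost = svm_cost,
                 fusion_dim = rr_embedding_dim + hrv_embedding_dim),
            class = "EncoderConfig")
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 32).
#' @param max_epochs maximum epochs (default 100).
#' @param patience early-stopping patience on validation loss (default 10);
#'   best-validation weights are restored.
#' @param seed seed controlling shuffling, initialization and dropout.
#' @return object of class `TrainConfig`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 100L, patience = 10L, seed = 42L) {
  if (learning_rate <= 0 || batch_size < 1) stop("invalid training config")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 seed = as.integer(seed)), class = "TrainConfig")
}

conv_out_len <- function(L, cfg) {
  l1 <- (L - cfg$kernel_sizes[1] + 1L) %/% cfg$pool_size
  (l1 - cfg$kernel_sizes[2] + 1L) %/% cfg$pool_size
}

#' Build a multimodal model
#'
#' Variant `"A"`: CNN-MLP with softmax head, trained end to end.
#' Variant `"B"`: same backbone; after training the softmax head is
#' replaced by a linear one-vs-rest SVM on the fused embeddings.
#' Variant `"C"`: the convolutional feature maps feed a unidirectional
#' LSTM whose final hidden state is the RR embedding; SVM head.
#'
#' @param cfg an [encoder_config()].
#' @param variant `"A"`, `"B"` or `"C"`.
#' @param seed initialization seed.
#' @return object of class `multimodal_model` (untrained).
#' @export
build_model <- function(cfg = encoder_config(), variant = c("A", "B", "C"),
                        seed = 42L) {
  variant <- match.arg(variant)
  set.seed(as.integer(seed))
  k1 <- cfg$kernel_sizes[1]; k2 <- cfg$kernel_sizes[2]
  f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]
  Lf <- conv_out_len(cfg$seq_len, cfg)
  p <- list(
    K1 = he_init(f1, k1, k1), b1 = numeric(f1),
    g1 = rep(1, f1), be1 = numeric(f1),
    K2 = he_init(f2, k2 * f1, k2 * f1), b2 = numeric(f2),
    g2 = rep(1, f2), be2 = numeric(f2),
    Wh1 = he_init(cfg$mlp_neurons[1], cfg$hrv_input_dim, cfg$hrv_input_dim),
    bh1 = numeric(cfg$mlp_neurons[1]),
    Wh2 = he_init(cfg$mlp_neurons[2], cfg$mlp_neurons[1], cfg$mlp_neurons[1]),
    bh2 = numeric(cfg$mlp_neurons[2]),
    # zero-initialized readout: initial predictions are exactly uniform
    Wo = matrix(0, 3L, cfg$fusion_dim), bo = numeric(3L))
  if (variant %in% c("A", "B")) {
    p$Wrr <- he_init(cfg$rr_embedding_dim, Lf * f2, Lf * f2)
    p$brr <- numeric(cfg$rr_embedding_dim)
  } else {
    l <- lstm_init(f2, cfg$lstm_units)
    p$Wx <- l$Wx; p$Wh <- l$Wh; p$bl <- l$b
  }
  structure(list(variant = variant, cfg = cfg, params = p,
                 bn1 = list(mean = numeric(f1), var = rep(1, f1)),
                 bn2 = list(mean = numeric(f2), var = rep(1, f2)),
                 class_levels = CLASS_LEVELS,
                 scaler = NULL, seq_center = 0, seq_scale = 1,
                 svm_head = NULL, trained = FALSE, curves = NULL),
            class = "multimodal_model")
}

#' Number of trainable parameters
#' @param model a `multimodal_model`.
#' @return integer count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, integer(1)))

# forward pass; X: matrix n x seq_len (raw ms), H: matrix n x hrv_dim
# (already standardized). Internally channel-major: activations are
# (features x batch). Returns logits (3 x B), fused embedding (96 x B)
# and the cache for backprop.
mm_forward <- function(model, X, H, train = FALSE) {
  cfg <- model$cfg; p <- model$params
  B <- nrow(X)
  Xs <- (X - model$seq_center) / model$seq_scale
  A0 <- array(t(Xs), c(1L, cfg$seq_len, B))
  cache <- list(B = B)

  c1 <- conv1d_forward(A0, p$K1, p$b1, cfg$kernel_sizes[1])
  bn1 <- bn_forward(c1$Z, p$g1, p$be1, model$bn1, train)
  if (train) model$bn1 <- bn1$state
  r1 <- relu(bn1$Y)
  a1 <- array(r1, c(cfg$conv_filters[1], c1$Lo, B))
  pl1 <- pool2_forward(a1)
  dr1 <- dropout_forward(pl1$Y, cfg$conv_dropout, train)

  c2 <- conv1d_forward(dr1$Y, p$K2, p$b2, cfg$kernel_sizes[2])
  bn2 <- bn_forward(c2$Z, p$g2, p$be2, model$bn2, train)
  if (train) model$bn2 <- bn2$state
  r2 <- relu(bn2$Y)
  a2 <- array(r2, c(cfg$conv_filters[2], c2$Lo, B))
  pl2 <- pool2_forward(a2)
  dr2 <- dropout_forward(pl2$Y, cfg$conv_dropout, train)

  if (model$variant %in% c("A", "B")) {
    flat <- matrix(dr2$Y, pl2$Lo * cfg$conv_filters[2], B)
    drr <- dense_forward(flat, p$Wrr, p$brr)
    z_rr <- relu(drr$Z)
    cache$drr <- drr
  } else {
    ls <- lstm_forward(dr2$Y, p$Wx, p$Wh, p$bl, cfg$lstm_units)
    z_rr <- ls$h
    cache$lstm <- ls
  }

  Ht <- t(H)
  dh1 <- dense_forward(Ht, p$Wh1, p$bh1)
  rh1 <- relu(dh1$Z)
  dph1 <- dropout_forward(rh1, cfg$mlp_dropout, train)
  dh2 <- dense_forward(dph1$Y, p$Wh2, p$bh2)
  z_hrv <- relu(dh2$Z)
  dph2 <- dropout_forward(z_hrv, cfg$mlp_dropout, train)

  z_fusion <- rbind(z_rr, dph2$Y)
  dout <- dense_forward(z_fusion, p$Wo, p$bo)

  cache <- c(cache, list(c1 = c1, bn1 = bn1, pl1 = pl1,
                         dr1 = dr1, c2 = c2, bn2 = bn2, pl2 = pl2, dr2 = dr2,
                         dh1 = dh1, dph1 = dph1, dh2 = dh2, dph2 = dph2,
                         z_rr = z_rr, dout = dout))
  list(logits = dout$Z, z_fusion = z_fusion, cache = cache, model = model)
}

mm_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg; p <- model$params
  B <- cache$B
  g <- list()
  bo_back <- dense_backward(dlogits, cache$dout, p$Wo)
  g$Wo <- bo_back$dW; g$bo <- bo_back$db
  dz <- bo_back$dX
  rr_dim <- if (model$variant %in% c("A", "B")) cfg$rr_embedding_dim else cfg$lstm_units
  dz_rr <- dz[seq_len(rr_dim), , drop = FALSE]
  dz_hrv <- dz[(rr_dim + 1):nrow(dz), , drop = FALSE]

  # HRV branch
  dz_hrv <- dropout_backward(dz_hrv, cache$dph2)
  dz_hrv <- drelu(dz_hrv, cache$dh2$Z)
  bh2 <- dense_backward(dz_hrv, cache$dh2, p$Wh2)
  g$Wh2 <- bh2$dW; g$bh2 <- bh2$db
  d1 <- dropout_backward(bh2$dX, cache$dph1)
  d1 <- drelu(d1, cache$dh1$Z)
  bh1 <- dense_backward(d1, cache$dh1, p$Wh1)
  g$Wh1 <- bh1$dW; g$bh1 <- bh1$db

  # RR branch
  if (model$variant %in% c("A", "B")) {
    dz_rr <- drelu(dz_rr, cache$drr$Z)
    brr <- dense_backward(dz_rr, cache$drr, p$Wrr)
    g$Wrr <- brr$dW; g$brr <- brr$db
    dpool2 <- array(brr$dX, c(cfg$conv_filters[2], cache$pl2$Lo, B))
  } else {
    lb <- lstm_backward(dz_rr, cache$lstm, p$Wx, p$Wh, cfg$lstm_units)
    g$Wx <- lb$dWx; g$Wh <- lb$dWh; g$bl <- lb$db
    dpool2 <- lb$dX
  }
  dpool2 <- dropout_backward(dpool2, cache$dr2)
  da2 <- pool2_backward(dpool2, cache$pl2)
  dr2m <- matrix(da2, cfg$conv_filters[2], cache$c2$Lo * B)
  dr2m <- drelu(dr2m, cache$bn2$Y)
  bb2 <- bn_backward(dr2m, cache$bn2, p$g2)
  g$g2 <- bb2$dgamma; g$be2 <- bb2$dbeta
  cb2 <- conv1d_backward(bb2$dZ, cache$c2, p$K2, cfg$kernel_sizes[2])
  g$K2 <- cb2$dW; g$b2 <- cb2$db

  dpool1 <- dropout_backward(cb2$dX, cache$dr1)
  da1 <- pool2_backward(dpool1, cache$pl1)
  dr1m <- matrix(da1, cfg$conv_filters[1], cache$c1$Lo * B)
  dr1m <- drelu(dr1m, cache$bn1$Y)
  bb1 <- bn_backward(dr1m, cache$bn1, p$g1)
  g$g1 <- bb1$dgamma; g$be1 <- bb1$dbeta
  cb1 <- conv1d_backward(bb1$dZ, cache$c1, p$K1, cfg$kernel_sizes[1])
  g$K1 <- cb1$dW; g$b1 <- cb1$db
  g
}

one_hot <- function(y, levels = CLASS_LEVELS) {
  # classes x batch
  Y <- matrix(0, length(levels), length(y))
  Y[cbind(match(as.character(y), levels), seq_along(y))] <- 1
  Y
}

#' Subject-wise train/validation/test split
#'
#' Partitions at the subject level (all stages of a subject share the
#' partition), stratified by group where counts allow: `test_frac` of each
#' group's subjects to the test set, then `val_frac` of the remaining
#' development subjects to internal validation.
#'
#' @param subjects data.frame with `subject_id` and `group` (one row per
#'   subject; a per-sample table is collapsed automatically).
#' @param test_frac fraction of subjects held out for testing (default 0.2).
#' @param val_frac fraction of development subjects for validation
#'   (default 0.1).
#' @param seed split seed.
#' @return object of class `SplitAssignment`: data.frame `subject_id`,
#'   `group`, `partition` (train/val/test).
#' @export
subject_wise_split <- function(subjects, test_frac = 0.2, val_frac = 0.1,
                               seed = 42L) {
  if (test_frac <= 0 || test_frac >= 1 || val_frac < 0 || val_frac >= 1)
    stop("fractions must lie in (0, 1)")
  subjects <- unique(subjects[, c("subject_id", "group")])
  set.seed(as.integer(seed))
  out <- NULL
  for (g in unique(subjects$group)) {
    ids <- subjects$subject_id[subjects$group == g]
    if (length(ids) < 3)
      warning("group ", g, " has fewer than 3 subjects; stratification degenerate")
    ids <- sample(ids)
    n_test <- max(1L, round(length(ids) * test_frac))
    dev <- ids[-seq_len(n_test)]
    n_val <- max(1L, round(length(dev) * val_frac))
    part <- c(rep("test", n_test), rep("val", n_val),
              rep("train", length(dev) - n_val))
    out <- rbind(out, data.frame(subject_id = ids, group = g,
                                 partition = part))
  }
  rownames(out) <- NULL
  class(out) <- c("SplitAssignment", "data.frame")
  out
}

partition_of <- function(split, subject_ids) {
  split$partition[match(subject_ids, split$subject_id)]
}

#' Train a multimodal model
#'
#' End-to-end supervised training with Adam and categorical cross-entropy.
#' The HRV z-score scaler and the RR-sequence normalization statistics are
#' fitted on the training partition only and stored on the model, so
#' validation/test rows never influence preprocessing. Per-epoch
#' train/validation loss and accuracy are recorded; early stopping
#' monitors validation loss and the best-validation weights are restored.
#' For SVM-head variants (B, C) the backbone is trained with a temporary
#' softmax head and the SVM is fitted on the fused training embeddings
#' afterwards.
#'
#' @param model a [build_model()] result.
#' @param samples list with `X` (n x 256 RR sequences, ms), `H` (n x 32 raw
#'   HRV features), `y` (labels), `subject_id`.
#' @param split a [subject_wise_split()] assignment.
#' @param cfg a [train_config()].
#' @return the trained model, with `curves` (per-epoch metrics) attached.
#' @export
train_model <- function(model, samples, split, cfg = train_config()) {
  part <- partition_of(split, samples$subject_id)
  tr <- which(part == "train"); va <- which(part == "val")
  if (length(tr) == 0) stop("empty training partition")
  set.seed(cfg$seed)

  model$scaler <- fit_scaler(samples$H[tr, , drop = FALSE])
  H_all <- apply_scaler(model$scaler, samples$H)
  if (ncol(H_all) != model$cfg$hrv_input_dim) {
    model$cfg$hrv_input_dim <- ncol(H_all)
    model$params$Wh1 <- he_init(model$cfg$mlp_neurons[1], ncol(H_all), ncol(H_all))
  }
  model$seq_center <- mean(samples$X[tr, ])
  model$seq_scale <- stats::sd(samples$X[tr, ])
  if (!is.finite(model$seq_scale) || model$seq_scale < 1e-12)
    model$seq_scale <- 1
  Y <- one_hot(samples$y)

  opt <- adam_init(model$params)
  best <- list(val = Inf, params = model$params, bn1 = model$bn1,
               bn2 = model$bn2, epoch = 0L)
  curves <- NULL
  wait <- 0L
  eval_part <- function(idx) {
    if (length(idx) == 0) return(c(NA_real_, NA_real_))
    fw <- mm_forward(model, samples$X[idx, , drop = FALSE],
                     H_all[idx, , drop = FALSE], train = FALSE)
    sc <- softmax_ce(fw$logits, Y[, idx, drop = FALSE])
    c(sc$loss, mean(max.col(t(sc$P)) == match(samples$y[idx], model$class_levels)))
  }
  for (ep in seq_len(cfg$max_epochs)) {
    idx <- sample(tr)
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    ep_loss <- 0; ep_correct <- 0
    for (b in batches) {
      fw <- mm_forward(model, samples$X[b, , drop = FALSE],
                       H_all[b, , drop = FALSE], train = TRUE)
      model <- fw$model  # updated batch-norm running stats
      sc <- softmax_ce(fw$logits, Y[, b, drop = FALSE])
      grads <- mm_backward(model, fw$cache, sc$dZ)
      st <- adam_step(model$params, grads, opt, lr = cfg$learning_rate)
      model$params <- st$params; opt <- st$state
      ep_loss <- ep_loss + sc$loss * length(b)
      ep_correct <- ep_correct +
        sum(max.col(t(sc$P)) == match(samples$y[b], model$class_levels))
    }
    vm <- eval_part(va)
    curves <- rbind(curves, data.frame(
      epoch = ep, train_loss = ep_loss / length(tr),
      train_acc = ep_correct / length(tr),
      val_loss = vm[1], val_acc = vm[2]))
    if (length(va) > 0 && is.finite(vm[1])) {
      if (vm[1] < best$val - 1e-6) {
        best <- list(val = vm[1], params = model$params, bn1 = model$bn1,
                     bn2 = model$bn2, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  }
  if (is.finite(best$val)) {
    model$params <- best$params; model$bn1 <- best$bn1; model$bn2 <- best$bn2
  }
  model$curves <- curves
  model$trained <- TRUE
  if (model$variant %in% c("B", "C")) {
    emb <- extract_embeddings(model, samples$X[tr, , drop = FALSE],
                              samples$H[tr, , drop = FALSE])
    model$svm_head <- fit_svm_head(emb, samples$y[tr],
                                   cost = model$cfg$svm_cost)
  }
  model
}

#' Extract fused 96-dimensional embeddings
#'
#' Deterministic inference-mode forward pass returning the late-fusion
#' representation `z_fusion = [z_RR, z_HRV]` for each sample.
#'
#' @param model a trained `multimodal_model`.
#' @param X n x 256 RR sequence matrix (ms).
#' @param H n x 32 raw HRV feature matrix (the model's stored scaler is
#'   applied).
#' @return n x 96 matrix.
#' @export
extract_embeddings <- function(model, X, H) {
  if (!isTRUE(model$trained)) stop("model is not trained")
  Hs <- apply_scaler(model$scaler, H)
  t(mm_forward(model, X, Hs, train = FALSE)$z_fusion)
}

#' Fit a linear one-vs-rest SVM head with Platt-style calibration
#'
#' Three binary linear SVMs (each class against the rest); prediction is
#' the argmax of the decision values. A logistic (Platt) calibration is
#' fitted on the training decision values of each class so the head can
#' emit continuous class scores for ROC analysis.
#'
#' @param embeddings n x d matrix of fused embeddings.
#' @param labels class labels.
#' @param cost SVM regularization constant (default 1).
#' @return object of class `svm_head`.
#' @export
fit_svm_head <- function(embeddings, labels, cost = 1.0) {
  labels <- factor(as.character(labels), levels = CLASS_LEVELS)
  present <- levels(droplevels(labels))
  if (length(present) < 2) stop("need at least 2 classes to fit the SVM head")
  machines <- lapply(CLASS_LEVELS, function(cl) {
    if (!cl %in% present) return(NULL)
    y <- factor(ifelse(labels == cl, "yes", "rest"), levels = c("yes", "rest"))
    fit <- e1071::svm(x = embeddings, y = y, kernel = "linear", cost = cost,
                      scale = FALSE)
    dv <- as.numeric(attr(stats::predict(fit, embeddings,
                                         decision.values = TRUE),
                          "decision.values"))
    flip <- mean(dv[y == "yes"]) < mean(dv[y == "rest"])
    if (flip) dv <- -dv
    # Platt-style sigmoid on training decision values
    platt <- suppressWarnings(
      stats::glm((y == "yes") ~ dv, family = stats::binomial()))
    list(fit = fit, flip = flip, platt = stats::coef(platt))
  })
  names(machines) <- CLASS_LEVELS
  structure(list(machines = machines, cost = cost), class = "svm_head")
}

svm_head_scores <- function(head, embeddings) {
  sc <- sapply(CLASS_LEVELS, function(cl) {
    m <- head$machines[[cl]]
    if (is.null(m)) return(rep(-Inf, nrow(embeddings)))
    dv <- as.numeric(attr(stats::predict(m$fit, embeddings,
                                         decision.values = TRUE),
                          "decision.values"))
    if (m$flip) dv <- -dv
    dv
  })
  sc <- matrix(sc, nrow = nrow(embeddings),
               dimnames = list(NULL, CLASS_LEVELS))
  prob <- sapply(CLASS_LEVELS, function(cl) {
    m <- head$machines[[cl]]
    if (is.null(m)) return(rep(0, nrow(embeddings)))
    eta <- m$platt[1] + m$platt[2] * sc[, cl]
    1 / (1 + exp(-eta))
  })
  prob <- matrix(prob, nrow = nrow(embeddings),
                 dimnames = list(NULL, CLASS_LEVELS))
  rs <- rowSums(prob)
  prob[rs > 0, ] <- prob[rs > 0, ] / rs[rs > 0]
  list(decision = sc, prob = prob)
}

#' Predict labels and per-class scores
#'
#' Softmax variants return calibrated probabilities directly; SVM-head
#' variants return the argmax of the one-vs-rest decision values with
#' Platt-calibrated, renormalized probability surrogates.
#'
#' @param object a trained `multimodal_model`.
#' @param X n x 256 RR sequence matrix.
#' @param H n x 32 raw HRV feature matrix.
#' @param ... unused.
#' @return list with `labels` (factor) and `scores` (n x 3 matrix; rows of
#'   softmax scores sum to 1).
#' @export
predict.multimodal_model <- function(object, X, H, ...) {
  if (!isTRUE(object$trained)) stop("model is not trained")
  Hs <- apply_scaler(object$scaler, H)
  fw <- mm_forward(object, X, Hs, train = FALSE)
  if (object$variant == "A" || is.null(object$svm_head)) {
    P <- t(softmax_cols(fw$logits))
    colnames(P) <- object$class_levels
    lab <- object$class_levels[max.col(P)]
    return(list(labels = factor(lab, levels = object$class_levels),
                scores = P))
  }
  sh <- svm_head_scores(object$svm_head, t(fw$z_fusion))
  lab <- CLASS_LEVELS[max.col(sh$decision)]
  list(labels = factor(lab, levels = CLASS_LEVELS), scores = sh$prob)
}

#' Derive the SVM-headed variant from a trained softmax backbone
#'
#' Model B shares Model A's multimodal encoder: after supervised training
#' of the CNN-MLP backbone, the softmax layer is replaced by a linear
#' one-vs-rest SVM fitted on the fused training embeddings. This converts
#' a trained variant-A model accordingly (the backbone weights are reused
#' unchanged).
#'
#' @param model a trained variant-A `multimodal_model`.
#' @param samples the sample list used for training.
#' @param split the `SplitAssignment` used for training (the SVM head is
#'   fitted on the training partition only).
#' @return a variant-B `multimodal_model`.
#' @export
as_svm_model <- function(model, samples, split) {
  if (!isTRUE(model$trained)) stop("model is not trained")
  if (model$variant != "A") stop("expected a variant-A backbone")
  tr <- which(partition_of(split, samples$subject_id) == "train")
  model$variant <- "B"
  emb <- extract_embeddings(model, samples$X[tr, , drop = FALSE],
                            samples$H[tr, , drop = FALSE])
  model$svm_head <- fit_svm_head(emb, samples$y[tr], cost = model$cfg$svm_cost)
  model
}
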