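# Model unit tests run on a reduced encoder (short sequences, few filters)
# so that training steps take seconds; the architecture code paths are the
# same as at full scale.

tiny_cfg <- function(dropout = TRUE) {
  encoder_config(conv_filters = c(4L, 6L), kernel_sizes = c(5L, 3L),
                 rr_embedding_dim = 8L, mlp_neurons = c(8L, 6L),
                 hrv_embedding_dim = 6L, lstm_units = 8L, seq_len = 64L,
                 hrv_input_dim = 5L,
                 conv_dropout = if (dropout) 0.2 else 0,
                 mlp_dropout = if (dropout) 0.3 else 0)
}

toy_samples <- function(n_per_group = 6L, stages = 2L, seq_len = 64L,
                        hrv_dim = 5L, sep = 3, seed = 1L) {
  set.seed(seed)
  groups <- c("MetS", "C", "M")
  shift <- c(MetS = -sep, C = 0, M = sep)
  X <- NULL; H <- NULL; y <- c(); sid <- c(); stage <- c()
  for (g in groups) for (s in seq_len(n_per_group)) {
    id <- paste0(g, s)
    base <- stats::rnorm(1, shift[g], 0.5)
    for (st in seq_len(stages)) {
      X <- rbind(X, 900 + 60 * base + stats::rnorm(seq_len, 0, 20))
      H <- rbind(H, base + stats::rnorm(hrv_dim, 0, 0.5))
      y <- c(y, g); sid <- c(sid, id); stage <- c(stage, st)
    }
  }
  colnames(H) <- paste0("f", seq_len(hrv_dim))
  list(X = X, H = H, y = factor(y, levels = groups), subject_id = sid,
       stage = stage)
}

trained_tiny <- local({
  cache <- NULL
  function(variant = "A") {
    if (!is.null(cache[[variant]])) return(cache[[variant]])
    smp <- toy_samples()
    split <- subject_wise_split(data.frame(subject_id = smp$subject_id,
                                           group = as.character(smp$y)),
                                seed = 2)
    m <- build_model(tiny_cfg(), variant = variant, seed = 2)
    m <- train_model(m, smp, split,
                     train_config(max_epochs = 80, patience = 80, batch_size = 8L, seed = 2))
    cache[[variant]] <<- list(model = m, smp = smp, split = split)
    cache[[variant]]
  }
})

test_that("subject-wise split keeps subjects intact, disjoint and near the 80/20 target", {
  subj <- data.frame(
    subject_id = c(paste0("MetS", 1:15), paste0("C", 1:10), paste0("M", 1:15)),
    group = rep(c("MetS", "C", "M"), c(15, 10, 15)))
  sp <- subject_wise_split(subj, seed = 3)
  expect_equal(sum(sp$partition == "test"), 8L)
  expect_length(intersect(sp$subject_id[sp$partition == "train"],
                          sp$subject_id[sp$partition == "test"]), 0)
  # every partition stratified by group
  expect_true(all(table(sp$group[sp$partition == "test"]) >= 1))

  # all stage-samples of one subject land in one partition
  samples <- subj[rep(1:40, each = 5), ]
  part <- sp$partition[match(samples$subject_id, sp$subject_id)]
  expect_true(all(tapply(part, samples$subject_id,
                         function(p) length(unique(p)) == 1L)))

  # deterministic for a fixed seed
  expect_identical(sp, subject_wise_split(subj, seed = 3))
  expect_error(subject_wise_split(subj, test_frac = 1.2), "fractions")
})

test_that("analytic backpropagation matches finite differences for both encoder types", {
  cfg <- tiny_cfg(dropout = FALSE)
  smp <- toy_samples()
  Y <- hrvogtt:::one_hot(smp$y[1:8])
  X <- smp$X[1:8, ]; H <- smp$H[1:8, ]
  for (variant in c("A", "C")) {
    m <- build_model(cfg, variant = variant, seed = 5)
    m$seq_center <- mean(X); m$seq_scale <- sd(X)
    loss_of <- function(model) {
      fw <- hrvogtt:::mm_forward(model, X, H, train = TRUE)
      hrvogtt:::softmax_ce(fw$logits, Y)$loss
    }
    fw <- hrvogtt:::mm_forward(m, X, H, train = TRUE)
    grads <- hrvogtt:::mm_backward(m, fw$cache,
                                   hrvogtt:::softmax_ce(fw$logits, Y)$dZ)
    set.seed(6)
    for (nm in names(grads)) {
      idx <- sample(length(grads[[nm]]), min(4, length(grads[[nm]])))
      for (i in idx) {
        eps <- 1e-5
        mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
        mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
        fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
        expect_lt(abs(grads[[nm]][i] - fd) / max(1e-2, abs(fd)), 1e-3,
                  label = sprintf("%s grad %s[%d]", variant, nm, i))
      }
    }
  }
})

test_that("softmax outputs are valid distributions and consistent with predicted labels", {
  tt <- trained_tiny("A")
  pr <- predict(tt$model, tt$smp$X, tt$smp$H)
  expect_true(all(abs(rowSums(pr$scores) - 1) < 1e-6))
  expect_true(all(pr$scores >= 0))
  expect_identical(as.character(pr$labels),
                   colnames(pr$scores)[max.col(pr$scores)])
  # robust to an all-zero input
  z <- predict(tt$model, matrix(0, 1, 64), matrix(0, 1, 5))
  expect_true(all(is.finite(z$scores)))
})

test_that("training learns separable toy data, records curves, and starts near chance loss", {
  tt <- trained_tiny("A")
  m <- tt$model
  expect_equal(nrow(m$curves), 80L)
  expect_true(all(c("train_loss", "val_loss", "train_acc", "val_acc") %in%
                    names(m$curves)))
  # inference-mode accuracy on the training partition (the in-training
  # accuracy column is depressed by active dropout on a net this small)
  tr <- which(hrvogtt:::partition_of(tt$split, tt$smp$subject_id) == "train")
  pr <- predict(m, tt$smp$X[tr, ], tt$smp$H[tr, ])
  expect_gt(mean(pr$labels == tt$smp$y[tr]), 0.9)
  expect_lt(abs(m$curves$train_loss[1] - log(3)), 0.2)
})

test_that("training is deterministic for a fixed seed", {
  smp <- toy_samples()
  split <- subject_wise_split(data.frame(subject_id = smp$subject_id,
                                         group = as.character(smp$y)), seed = 4)
  tc <- train_config(max_epochs = 3, seed = 9)
  m1 <- train_model(build_model(tiny_cfg(), "A", seed = 9), smp, split, tc)
  m2 <- train_model(build_model(tiny_cfg(), "A", seed = 9), smp, split, tc)
  expect_identical(m1$curves$val_loss, m2$curves$val_loss)
  expect_identical(m1$params$Wo, m2$params$Wo)
})

test_that("fused embeddings have the configured fusion width and are batch invariant", {
  for (variant in c("A", "C")) {
    tt <- trained_tiny(variant)
    emb <- extract_embeddings(tt$model, tt$smp$X, tt$smp$H)
    expect_equal(dim(emb), c(nrow(tt$smp$X), tiny_cfg()$fusion_dim))
    # duplicate sample gives identical rows; batch composition irrelevant
    one <- extract_embeddings(tt$model, tt$smp$X[c(1, 1), ],
                              tt$smp$H[c(1, 1), ])
    expect_equal(one[1, ], one[2, ], tolerance = 1e-12)
    expect_equal(unname(one[1, ]), unname(emb[1, ]), tolerance = 1e-12)
  }
  # the default configuration fuses at 96 dimensions
  expect_equal(encoder_config()$fusion_dim, 96L)
  m <- build_model(encoder_config(), "A", seed = 1)
  expect_equal(nrow(m$params$Wo) * 0 + ncol(m$params$Wo), 96L)
})

test_that("variant C carries the recurrent layer; A and B the flatten projection", {
  mA <- build_model(tiny_cfg(), "A", seed = 1)
  mC <- build_model(tiny_cfg(), "C", seed = 1)
  expect_true(all(c("Wx", "Wh", "bl") %in% names(mC$params)))
  expect_false("Wx" %in% names(mA$params))
  expect_true("Wrr" %in% names(mA$params))
})

test_that("the SVM head separates separable embeddings and is symmetric under relabeling", {
  set.seed(31)
  centers <- rbind(c(0, 9), c(8, -5), c(-8, -5))
  emb <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(20, centers[k, 1]), rnorm(20, centers[k, 2]))))
  lab <- factor(rep(c("MetS", "C", "M"), each = 20),
                levels = c("MetS", "C", "M"))
  head <- fit_svm_head(emb, lab)
  sc <- hrvogtt:::svm_head_scores(head, emb)
  pred <- c("MetS", "C", "M")[max.col(sc$decision)]
  expect_equal(mean(pred == as.character(lab)), 1.0)
  expect_true(all(abs(rowSums(sc$prob) - 1) < 1e-9))

  # duplicating every training point leaves decisions unchanged
  head2 <- fit_svm_head(rbind(emb, emb), factor(c(lab, lab),
                                                levels = levels(lab)))
  sc2 <- hrvogtt:::svm_head_scores(head2, emb)
  expect_equal(max.col(sc2$decision), max.col(sc$decision))

  # consistent label swap permutes predictions consistently
  perm <- c(MetS = "M", C = "MetS", M = "C")
  head3 <- fit_svm_head(emb, factor(perm[as.character(lab)],
                                    levels = c("MetS", "C", "M")))
  sc3 <- hrvogtt:::svm_head_scores(head3, emb)
  pred3 <- c("MetS", "C", "M")[max.col(sc3$decision)]
  expect_identical(pred3, unname(perm[pred]))

  expect_error(fit_svm_head(emb, factor(rep("C", 60),
                                        levels = c("MetS", "C", "M"))),
               "2 classes")
})

test_that("preprocessing is fitted on the training partition only (leakage guard)", {
  smp <- toy_samples()
  split <- subject_wise_split(data.frame(subject_id = smp$subject_id,
                                         group = as.character(smp$y)), seed = 7)
  te <- which(hrvogtt:::partition_of(split, smp$subject_id) == "test")
  tc <- train_config(max_epochs = 2, seed = 7)
  m1 <- train_model(build_model(tiny_cfg(), "A", seed = 7), smp, split, tc)
  smp2 <- smp
  smp2$H[te[1], ] <- smp2$H[te[1], ] + 1e4   # perturb a test row
  smp2$X[te[1], ] <- smp2$X[te[1], ] + 1e4
  m2 <- train_model(build_model(tiny_cfg(), "A", seed = 7), smp2, split, tc)
  expect_identical(m1$scaler$center, m2$scaler$center)
  expect_identical(m1$scaler$scale, m2$scaler$scale)
  expect_identical(m1$seq_center, m2$seq_center)
  # no subject is shared between partitions
  expect_length(intersect(split$subject_id[split$partition == "test"],
                          split$subject_id[split$partition != "test"]), 0)
})

test_that("variant B reuses the trained A backbone and stays close to it on toy data", {
  tt <- trained_tiny("A")
  mB <- as_svm_model(tt$model, tt$smp, tt$split)
  expect_equal(mB$variant, "B")
  expect_identical(mB$params, tt$model$params)
  prA <- predict(tt$model, tt$smp$X, tt$smp$H)
  prB <- predict(mB, tt$smp$X, tt$smp$H)
  expect_gte(mean(prA$labels == prB$labels), 0.7)
})
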