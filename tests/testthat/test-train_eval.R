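test_that("BCE loss matches closed forms and is monotone in the true class", {
  # uninformative prediction: each of C classes contributes ln 2
  for (C in c(2, 5, 6)) {
    probs <- matrix(0.5, 1, C)
    y <- matrix(0, 1, C); y[1, 1] <- 1
    expect_equal(bce_loss(probs, y), C * log(2))
  }

  # near-perfect prediction: loss near 0
  y <- matrix(c(1, 0, 0), 1, 3)
  expect_lt(bce_loss(matrix(c(1, 0, 0), 1, 3), y), 1e-5)

  # raising the true-class probability with others fixed lowers the loss
  l1 <- bce_loss(matrix(c(0.4, 0.3, 0.3), 1, 3), y)
  l2 <- bce_loss(matrix(c(0.7, 0.3, 0.3), 1, 3), y)
  expect_lt(l2, l1)

  expect_error(bce_loss(matrix(0.5, 2, 3), matrix(0, 2, 2)), "shapes differ")
  expect_error(bce_loss(matrix(NaN, 1, 2), matrix(0, 1, 2)), "NaN")
})

test_that("loss is invariant to sample order within a batch", {
  set.seed(30)
  probs <- matrix(runif(24), 8, 3)
  y <- one_hot_encode(sample(0:2, 8, TRUE), 3)
  ord <- sample(8)
  expect_equal(bce_loss(probs, y), bce_loss(probs[ord, ], y[ord, ]))
})

test_that("one-hot encoding has a single 1 per row at the label", {
  y <- one_hot_encode(c(0, 2, 1), 4)
  expect_equal(rowSums(y), rep(1, 3))
  expect_equal(which(y[2, ] == 1), 3L)
})

test_that("flips are involutions and rotation by zero is the identity", {
  img <- random_image(16, 12, seed = 31)
  expect_identical(flip_horizontal(flip_horizontal(img)), img)
  expect_identical(flip_vertical(flip_vertical(img)), img)
  expect_identical(rotate_reflect(img, 0), img)
  # reflection padding keeps values inside the original gamut
  rot <- rotate_reflect(img, 13.7)
  expect_true(all(rot >= min(img) - 1e-12 & rot <= max(img) + 1e-12))
})

test_that("augmentation is deterministic given its seed", {
  img <- random_image(32, 32, seed = 32)
  a1 <- augment_fundus(img, seed = 99)
  a2 <- augment_fundus(img, seed = 99)
  expect_identical(a1, a2)
  a3 <- augment_fundus(img, seed = 100)
  expect_false(identical(a1, a3))
})

test_that("model forward produces normalized grading scores", {
  cfg <- micro_config()
  model <- init_model(cfg, n_classes = 5, seed = 2)
  fw <- model_forward(model, random_image(8, 8, seed = 33))
  expect_length(fw$logits, 5)
  expect_equal(sum(fw$probs), 1, tolerance = 1e-6)
  expect_true(fw$predicted %in% 0:4)
})

test_that("analytic gradients match central finite differences", {
  cfg <- micro_config()
  model <- init_model(cfg, n_classes = 3, seed = 42)
  img <- random_image(8, 8, seed = 9)
  loss_fn <- function(m) drgrader:::forward_batch(m, list(img), 1L)$loss
  fw <- drgrader:::forward_batch(model, list(img), 1L, keep_cache = TRUE)
  grads <- drgrader:::batch_gradients(model, fw)
  h <- 1e-5
  check_leaf <- function(get, set, g) {
    v <- get(model$params)
    set.seed(sum(dim(as.matrix(v))))
    idx <- sample(length(v), min(6, length(v)))
    for (i in idx) {
      mp <- model; mm <- model
      vp <- v; vp[i] <- vp[i] + h; mp$params <- set(mp$params, vp)
      vm <- v; vm[i] <- vm[i] - h; mm$params <- set(mm$params, vm)
      num <- (loss_fn(mp) - loss_fn(mm)) / (2 * h)
      # relative where the gradient is sizeable, absolute where tiny
      expect_lt(abs(num - g[i]) / max(abs(num), abs(g[i]), 1e-4), 1e-3)
    }
  }
  check_leaf(function(p) p$E, function(p, v) { p$E[] <- v; p },
             as.vector(grads$E))
  check_leaf(function(p) p$E_pos, function(p, v) { p$E_pos[] <- v; p },
             as.vector(grads$E_pos))
  check_leaf(function(p) p$m, function(p, v) { p$m[] <- v; p },
             as.vector(grads$m))
  for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "b1", "W2", "b2",
               "ln1_g", "ln1_b")) {
    check_leaf(function(p) p$layers[[1]][[nm]],
               function(p, v) { p$layers[[1]][[nm]][] <- v; p },
               as.vector(grads$layers[[1]][[nm]]))
  }
})

make_micro_data <- function(n_per_class = 4, seed = 0) {
  # 8x8 "images" whose mean brightness encodes the class
  set.seed(seed)
  images <- list(); labels <- integer()
  for (g in 0:2) {
    for (i in seq_len(n_per_class)) {
      images[[length(images) + 1L]] <-
        array(pmin(pmax(g / 3 + runif(8 * 8 * 3, 0, 0.2), 0), 1), c(8, 8, 3))
      labels <- c(labels, g)
    }
  }
  list(images = images, labels = labels)
}

test_that("zero learning rates leave every parameter bit-identical", {
  data <- list(train = make_micro_data(), val = make_micro_data(seed = 1))
  cfg <- micro_config()
  tr <- train_grader(data, cfg,
                     train_config(epochs = 1, batch_size = 4,
                                  lr_backbone = 0, lr_classifier = 0,
                                  weight_decay = 0, seed = 3),
                     n_classes = 3)
  ref <- init_model(cfg, n_classes = 3, seed = 3)
  expect_identical(tr$final_model$params, ref$params)
})

test_that("the two parameter groups step at their own learning rates", {
  data <- list(train = make_micro_data(), val = list(images = list(),
                                                     labels = integer()))
  cfg <- micro_config()
  run <- function(lr_bb, lr_cl) {
    train_grader(data, cfg,
                 train_config(epochs = 1, batch_size = 12,
                              lr_backbone = lr_bb, lr_classifier = lr_cl,
                              momentum = 0, weight_decay = 0, seed = 3),
                 n_classes = 3)$final_model$params
  }
  ref <- init_model(cfg, n_classes = 3, seed = 3)$params
  p_cl_only <- run(0, 1e-2)
  # classifier moved, backbone untouched
  expect_false(identical(p_cl_only$m, ref$m))
  expect_identical(p_cl_only$E, ref$E)
  expect_identical(p_cl_only$layers, ref$layers)
  # classifier step size scales linearly with its learning rate
  p1 <- run(0, 1e-2)
  p2 <- run(0, 2e-2)
  d1 <- p1$m - ref$m; d2 <- p2$m - ref$m
  expect_equal(d2, 2 * d1, tolerance = 1e-8)
})

test_that("training declines the loss and memorizes a tiny separable set", {
  data <- list(train = make_micro_data(6, seed = 5),
               val = make_micro_data(2, seed = 6))
  tr <- train_grader(data, micro_config(),
                     train_config(epochs = 8, batch_size = 6, seed = 0),
                     n_classes = 3)
  expect_lt(tr$log$train_loss[nrow(tr$log)], tr$log$train_loss[1])
  ev <- suppressWarnings(
    evaluate_grader(tr$best_model, data$train$images, data$train$labels))
  # memorization sanity: most mass on the diagonal
  expect_gt(sum(diag(unclass(ev$cm))) / length(data$train$labels), 0.5)
})

test_that("training rejects degenerate datasets", {
  empty <- list(train = list(images = list(), labels = integer()),
                val = list(images = list(), labels = integer()))
  expect_error(train_grader(empty, micro_config(), train_config()),
               "empty training set")
  one_class <- list(train = list(images = list(random_image(8)),
                                 labels = 0L),
                    val = list(images = list(), labels = integer()))
  expect_error(train_grader(one_class, micro_config(), train_config()),
               "at least 2 classes")
})

test_that("evaluation is deterministic and rejects mismatched class counts", {
  data <- make_micro_data(2, seed = 7)
  model <- init_model(micro_config(), n_classes = 3, seed = 1)
  e1 <- suppressWarnings(evaluate_grader(model, data$images, data$labels))
  e2 <- suppressWarnings(evaluate_grader(model, data$images, data$labels))
  expect_identical(e1$cm, e2$cm)
  expect_identical(e1$probs, e2$probs)
  expect_error(evaluate_grader(model, data$images, rep(5L, length(data$labels))),
               "exceeds model class count")
})

test_that("binarization collapses grades to screening labels", {
  expect_equal(binarize_labels(c(0, 1, 4, 0, 5)), c(0L, 1L, 1L, 0L, 1L))
})
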