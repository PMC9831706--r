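# shared fixtures and independent oracles

# tiny encoder config for desk-scale forward/backward tests
micro_config <- function(...) {
  args <- utils::modifyList(
    list(n_layers = 1L, d_model = 8L, n_heads = 2L, ffn_dim = 16L,
         patch_size = 4L, image_size = 8L),
    list(...))
  do.call(encoder_config, args)
}

random_image <- function(h = 8, w = h, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

# random feature map as positions matrix + object
random_fmap <- function(h, w, d, seed = 1) {
  set.seed(seed)
  feature_map_from_positions(matrix(rnorm(h * w * d), h * w, d), h, w)
}

# naive-loop CSRA oracle: literal per-class, per-position evaluation of the
# score/feature/logit chain, no shared computation with the implementation
naive_csra_logits <- function(fmap, m, temps, lambda) {
  X <- as_positions(fmap)
  n <- nrow(X); C <- nrow(m)
  logits <- numeric(C)
  for (i in seq_len(C)) {
    per_head <- numeric(length(temps))
    for (t in seq_along(temps)) {
      Tt <- temps[t]
      u <- numeric(n)
      for (j in seq_len(n)) u[j] <- sum(X[j, ] * m[i, ])
      if (is.infinite(Tt)) {
        s <- as.numeric(u == max(u)); s <- s / sum(s)
      } else {
        e <- exp(Tt * u - max(Tt * u)); s <- e / sum(e)
      }
      a <- numeric(ncol(X))
      for (j in seq_len(n)) a <- a + s[j] * X[j, ]
      g <- colSums(X) / n
      f <- g + lambda * a
      per_head[t] <- sum(m[i, ] * f)
    }
    logits[i] <- mean(per_head)
  }
  logits
}

# O(n^2) pair-counting AUC oracle
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# brute-force Youden search over every midpoint threshold
brute_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  best <- -Inf
  for (th in cand) {
    sens <- mean(scores[labels == 1] > th)
    spec <- mean(scores[labels == 0] <= th)
    best <- max(best, sens + spec - 1)
  }
  best
}

idrid_cm_path <- function() {
  system.file("extdata", "idrid_confusion.csv", package = "drgrader")
}
ddr_cm_path <- function() {
  system.file("extdata", "ddr_confusion.csv", package = "drgrader")
}
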