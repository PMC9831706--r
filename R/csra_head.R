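#' CSRA head parameters
#'
#' Class-specific residual attention pooling: each class i owns a classifier
#' vector m_i that both scores spatial positions (temperature-softmax
#' attention) and produces the final logit. The residual weight lambda mixes
#' the class-specific attention feature into global average pooling.
#'
#' @param m C x d matrix of per-class classifier vectors.
#' @param lambda residual weight (default 0.3).
#' @param n_heads number of CSRA heads in {1, 2, 4, 6} (default 2); the
#'   per-head temperatures follow [multi_head_temperatures()].
#' @param temperatures optional explicit temperature vector overriding the
#'   schedule; `Inf` is the max-pooling sentinel.
#' @return list of class `csra_head_params`.
#' @export
csra_head_params <- function(m, lambda = 0.3, n_heads = 2L,
                             temperatures = NULL) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("at least 2 classes are required", call. = FALSE)
  if (is.null(temperatures)) temperatures <- multi_head_temperatures(n_heads)
  if (any(temperatures <= 0)) {
    stop("every temperature must be positive (Inf = max pooling)",
         call. = FALSE)
  }
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  structure(list(m = m, lambda = lambda, n_heads = length(temperatures),
                 temperatures = temperatures),
            class = "csra_head_params")
}

#' Temperature schedule for multi-head CSRA
#'
#' Fixed schedule indexed by head count: 1 head uses T = 1; with more heads
#' the temperatures increase and the last head is the max-pooling limit
#' (T = Inf), following the convention of the residual-attention method the
#' head derives from.
#'
#' @param n_heads head count, one of 1, 2, 4, 6.
#' @return numeric vector of temperatures (last entry `Inf` for n_heads > 1).
#' @export
multi_head_temperatures <- function(n_heads) {
  switch(as.character(n_heads),
         "1" = 1,
         "2" = c(1, Inf),
         "4" = c(1, 2, 4, Inf),
         "6" = c(1, 2, 3, 4, 5, Inf),
         stop(sprintf("unsupported CSRA head count %s (use 1, 2, 4 or 6)",
                      n_heads), call. = FALSE))
}

#' Spatial class-attention scores
#'
#' For class vector `m_i` and temperature T, the score of position j is
#' `exp(T x_j' m_i) / sum_k exp(T x_k' m_i)` — a temperature-controlled
#' softmax over spatial positions, computed with max subtraction so large
#' logits cannot overflow. `T = Inf` returns the indicator of the argmax
#' position (max pooling limit; ties split evenly).
#'
#' @param fmap `feature_map` (or d x h x w array).
#' @param m_i length-d class vector.
#' @param temperature positive scalar or `Inf`.
#' @return length-hw score vector, non-negative, summing to 1.
#' @export
csra_scores <- function(fmap, m_i, temperature) {
  X <- as_positions(fmap)
  stopifnot_finite(X, "feature map")
  if (length(m_i) != ncol(X)) {
    stop(sprintf("class vector length %d does not match feature dimension %d",
                 length(m_i), ncol(X)), call. = FALSE)
  }
  u <- as.vector(X %*% m_i)
  if (is.infinite(temperature)) {
    s <- as.numeric(u == max(u))
    return(s / sum(s))
  }
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  softmax_vec(temperature * u)
}

#' Class-specific residual attention feature
#'
#' `f_i = g + lambda * a_i`, where `g` is the unweighted spatial mean of the
#' position vectors and `a_i` their attention-score-weighted sum.
#'
#' @inheritParams csra_scores
#' @param lambda residual weight.
#' @return length-d class feature vector.
#' @export
csra_feature <- function(fmap, m_i, temperature, lambda) {
  X <- as_positions(fmap)
  s <- csra_scores(fmap, m_i, temperature)
  g <- colMeans(X)
  a <- as.vector(t(X) %*% s)
  g + lambda * a
}

#' CSRA logits and probabilities for all classes
#'
#' Logit i is `m_i' f_i`; with several heads, each head computes logits at
#' its own temperature and the heads are averaged. Because `m_i' g` is the
#' mean of the per-position logits `u_j = x_j' m_i` and `m_i' a_i` their
#' score-weighted mean, the whole head reduces to operations on the
#' hw x C matrix `U = X m'`, which is how it is computed.
#'
#' @param fmap `feature_map` (or d x h x w array).
#' @param params `csra_head_params`.
#' @return list of class `grading_scores` with `logits` (length C),
#'   `probs` (softmax of logits, summing to 1), and `predicted`
#'   (0-based argmax class).
#' @export
csra_logits <- function(fmap, params) {
  X <- as_positions(fmap)
  if (ncol(X) != ncol(params$m)) {
    stop(sprintf("feature dimension %d does not match classifier dimension %d",
                 ncol(X), ncol(params$m)), call. = FALSE)
  }
  U <- X %*% t(params$m)                       # hw x C per-position logits
  base <- colMeans(U)                          # = m_i' g
  att <- rowMeans(vapply(params$temperatures, function(Tt) {
    if (is.infinite(Tt)) {
      apply(U, 2L, max)
    } else {
      S <- apply(U, 2L, function(u) softmax_vec(Tt * u))
      colSums(S * U)                           # = m_i' a_i
    }
  }, numeric(ncol(U))))
  logits <- base + params$lambda * att
  probs <- softmax_vec(logits)
  structure(list(logits = logits, probs = probs,
                 predicted = which.max(logits) - 1L),
            class = "grading_scores")
}

# --- training-time forward/backward on the U = X m' parameterisation ------

# forward returning cache; X is hw x d positions
csra_forward_cache <- function(X, params) {
  U <- X %*% t(params$m)
  n <- nrow(U)
  heads <- lapply(params$temperatures, function(Tt) {
    if (is.infinite(Tt)) {
      kstar <- apply(U, 2L, which.max)
      list(inf = TRUE, kstar = kstar, att = U[cbind(kstar, seq_len(ncol(U)))])
    } else {
      S <- apply(U, 2L, function(u) softmax_vec(Tt * u))
      list(inf = FALSE, S = S, att = colSums(S * U), Tt = Tt)
    }
  })
  att <- rowMeans(vapply(heads, `[[`, numeric(ncol(U)), "att"))
  logits <- colMeans(U) + params$lambda * att
  list(logits = logits, U = U, heads = heads, n = n)
}

# backward: dlogits length C -> list(dX hw x d, dm C x d)
csra_backward <- function(dlogits, cache, X, params) {
  U <- cache$U
  n <- cache$n
  C <- ncol(U)
  H <- length(cache$heads)
  dU <- matrix(rep(dlogits / n, each = n), n, C)   # through the g term
  scale <- params$lambda / H
  for (hd in cache$heads) {
    if (hd$inf) {
      idx <- cbind(hd$kstar, seq_len(C))
      dU[idx] <- dU[idx] + scale * dlogits
    } else {
      # d(s'u)/du_k = s_k (1 + T (u_k - s'u))
      W <- hd$S * (1 + hd$Tt * sweep(U, 2L, hd$att, `-`))
      dU <- dU + sweep(W, 2L, scale * dlogits, `*`)
    }
  }
  list(dX = dU %*% params$m, dm = t(dU) %*% X)
}
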