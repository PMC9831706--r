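#' Split an image into flattened patches
#'
#' Reshapes an H x W x C image into an N x (P^2 C) matrix of flattened
#' square tiles, N = HW/P^2, in row-major tile order (left-to-right then
#' top-to-bottom). Each row is the row-major flattening of one P x P x C
#' tile with channels interleaved last (pixel-major).
#'
#' @param image H x W x C numeric array (or H x W matrix, taken as C = 1),
#'   values in `[0, 1]`.
#' @param patch_size patch side length P; H and W must be multiples of P.
#' @return list of class `patch_grid` with fields `patches` (N x P^2C
#'   matrix), `patch_size`, `grid_h`, `grid_w`, `channels`.
#' @export
patchify <- function(image, patch_size) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  if (length(d) != 3L || d[1] < 1L || d[2] < 1L) {
    stop("image must be a non-empty H x W x C array", call. = FALSE)
  }
  H <- d[1]; W <- d[2]; C <- d[3]
  P <- as.integer(patch_size)
  if (P < 1L || H %% P != 0L || W %% P != 0L) {
    stop(sprintf(
      "image sides must be positive multiples of the patch size: H=%d, W=%d, P=%d",
      H, W, P), call. = FALSE)
  }
  gh <- H %/% P; gw <- W %/% P
  N <- gh * gw
  patches <- matrix(0, N, P * P * C)
  idx <- 0L
  for (ti in seq_len(gh)) {
    rr <- ((ti - 1L) * P + 1L):(ti * P)
    for (tj in seq_len(gw)) {
      cc <- ((tj - 1L) * P + 1L):(tj * P)
      idx <- idx + 1L
      tile <- image[rr, cc, , drop = FALSE]
      # row-major within the tile: iterate rows slowest? we flatten as
      # (row, col, channel) with channel fastest, col next, row slowest
      patches[idx, ] <- as.vector(aperm(tile, c(3L, 2L, 1L)))
    }
  }
  structure(list(patches = patches, patch_size = P, grid_h = gh, grid_w = gw,
                 channels = C),
            class = "patch_grid")
}

#' Reassemble an image from a patch grid
#'
#' Exact inverse of [patchify()].
#'
#' @param grid `patch_grid` object.
#' @return H x W x C array.
#' @export
unpatchify <- function(grid) {
  P <- grid$patch_size; gh <- grid$grid_h; gw <- grid$grid_w
  C <- grid$channels
  H <- gh * P; W <- gw * P
  image <- array(0, c(H, W, C))
  idx <- 0L
  for (ti in seq_len(gh)) {
    rr <- ((ti - 1L) * P + 1L):(ti * P)
    for (tj in seq_len(gw)) {
      cc <- ((tj - 1L) * P + 1L):(tj * P)
      idx <- idx + 1L
      tile <- array(grid$patches[idx, ], c(C, P, P))
      image[rr, cc, ] <- aperm(tile, c(3L, 2L, 1L))
    }
  }
  image
}

#' Embed patches into the token sequence
#'
#' Projects each flattened patch with the linear map `E`, prepends the
#' learnable class token, and adds the positional embedding table:
#' token 0 is `x_class + E_pos[0]`, token j is `x_p^j E + E_pos[j]`.
#'
#' @param grid `patch_grid` (or plain N x P^2C matrix).
#' @param E (P^2 C) x D projection matrix.
#' @param E_pos (N+1) x D positional embedding.
#' @param x_class length-D class-token vector.
#' @return (N+1) x D token matrix; row 1 is the class token.
#' @export
patch_embed <- function(grid, E, E_pos, x_class) {
  X <- if (inherits(grid, "patch_grid")) grid$patches else grid
  if (ncol(X) != nrow(E)) {
    stop(sprintf("projection E has %d rows but patches have length %d",
                 nrow(E), ncol(X)), call. = FALSE)
  }
  N <- nrow(X); D <- ncol(E)
  if (!all(dim(E_pos) == c(N + 1L, D))) {
    stop(sprintf("positional embedding must be (N+1) x D = %d x %d, got %d x %d",
                 N + 1L, D, nrow(E_pos), ncol(E_pos)), call. = FALSE)
  }
  if (length(x_class) != D) {
    stop(sprintf("class token must have length D = %d, got %d",
                 D, length(x_class)), call. = FALSE)
  }
  rbind(matrix(x_class, 1L, D), X %*% E) + E_pos
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V`, softmax applied row-wise with
#' max-subtraction stabilization. Each output row is a convex combination
#' of the rows of V.
#'
#' @param Q n_q x d_k query matrix.
#' @param K n_kv x d_k key matrix.
#' @param V n_kv x d_v value matrix.
#' @param d_k key dimension used in the scale factor; defaults to `ncol(K)`.
#' @return list with `output` (n_q x d_v) and `weights` (n_q x n_kv,
#'   rows summing to 1).
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K)) {
  if (ncol(Q) != ncol(K)) {
    stop(sprintf("Q and K must share the key dimension: %d vs %d",
                 ncol(Q), ncol(K)), call. = FALSE)
  }
  if (nrow(K) != nrow(V)) {
    stop(sprintf("K and V must have equal row counts: %d vs %d",
                 nrow(K), nrow(V)), call. = FALSE)
  }
  S <- Q %*% t(K) / sqrt(d_k)
  W <- softmax_rows(S)
  list(output = W %*% V, weights = W)
}

#' Multi-head attention
#'
#' Projects queries, keys, and values with per-head weight matrices, runs
#' scaled dot-product attention in each head, concatenates the head outputs,
#' and projects with `W_O`.
#'
#' @param Q,K,V n x d_model input matrices.
#' @param weights list with fields `W_Q`, `W_K`, `W_V` (each a list of h
#'   d_model x d_k / d_v matrices) and `W_O` ((h d_v) x d_model).
#' @return n x d_model output matrix.
#' @export
multi_head_attention <- function(Q, K, V, weights) {
  h <- length(weights$W_Q)
  if (h < 1L) stop("at least one head is required", call. = FALSE)
  heads <- vector("list", h)
  for (i in seq_len(h)) {
    Wq <- weights$W_Q[[i]]; Wk <- weights$W_K[[i]]; Wv <- weights$W_V[[i]]
    if (nrow(Wq) != ncol(Q) || nrow(Wk) != ncol(K) || nrow(Wv) != ncol(V)) {
      stop(sprintf("head %d projection shape mismatch with input d_model=%d",
                   i, ncol(Q)), call. = FALSE)
    }
    heads[[i]] <- scaled_dot_attention(Q %*% Wq, K %*% Wk, V %*% Wv,
                                       d_k = ncol(Wk))$output
  }
  concat <- do.call(cbind, heads)
  if (ncol(concat) != nrow(weights$W_O)) {
    stop(sprintf("W_O expects %d input columns, heads concatenate to %d",
                 nrow(weights$W_O), ncol(concat)), call. = FALSE)
  }
  concat %*% weights$W_O
}

#' Encoder configuration
#'
#' Defaults follow the transformer convention the architecture derives from:
#' a stack of identical post-norm encoder layers, each a multi-head
#' self-attention sublayer then a position-wise feed-forward sublayer, both
#' wrapped as `LN(x + Sublayer(x))`.
#'
#' @param n_layers encoder depth (default 6).
#' @param d_model token dimension D (default 512).
#' @param n_heads attention heads h (default 8); `d_k = d_v = D/h`.
#' @param ffn_dim feed-forward hidden width (default 2048).
#' @param patch_size patch side P (default 16).
#' @param image_size input side length (default 512).
#' @param dropout dropout rate (default 0; nonzero values are not used by
#'   the reference training recipe).
#' @param use_layer_norm logical; disabling is only for algebraic tests of
#'   the residual path.
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 6L, d_model = 512L, n_heads = 8L,
                           ffn_dim = 2048L, patch_size = 16L,
                           image_size = 512L, dropout = 0,
                           use_layer_norm = TRUE) {
  if (d_model %% n_heads != 0L) {
    stop(sprintf("d_model=%d must be divisible by n_heads=%d",
                 d_model, n_heads), call. = FALSE)
  }
  structure(list(n_layers = as.integer(n_layers),
                 d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads),
                 d_k = as.integer(d_model %/% n_heads),
                 d_v = as.integer(d_model %/% n_heads),
                 ffn_dim = as.integer(ffn_dim),
                 patch_size = as.integer(patch_size),
                 image_size = as.integer(image_size),
                 dropout = dropout,
                 use_layer_norm = isTRUE(use_layer_norm)),
            class = "encoder_config")
}

#' Small desk-scale encoder preset
#'
#' 64 x 64 input, 8 x 8 patches, 2 layers, D = 128 — the configuration used
#' throughout the package's synthetic-data experiments.
#'
#' @param ... overrides passed to [encoder_config()].
#' @export
tiny_encoder_config <- function(...) {
  args <- utils::modifyList(
    list(n_layers = 2L, d_model = 128L, n_heads = 4L, ffn_dim = 256L,
         patch_size = 8L, image_size = 64L),
    list(...))
  do.call(encoder_config, args)
}

# layer norm over the last (feature) dimension of a token matrix,
# per row; returns value plus cache for backprop
layer_norm_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  sd_ <- sqrt(v + eps)
  xhat <- xc / sd_
  list(out = sweep(xhat, 2L, gamma, `*`) + rep(beta, each = nrow(X)),
       xhat = xhat, sd = sd_)
}

layer_norm_backward <- function(dY, cache, gamma) {
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) / cache$sd
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# combined-projection self-attention forward used inside the encoder;
# Wq/Wk/Wv/Wo are D x D with heads as contiguous column blocks
self_attention_forward <- function(Z, lw, config) {
  h <- config$n_heads; dk <- config$d_k
  Q <- Z %*% lw$Wq; K <- Z %*% lw$Wk; V <- Z %*% lw$Wv
  n <- nrow(Z)
  O <- matrix(0, n, config$d_model)
  P_list <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
    P <- softmax_rows(S)
    P_list[[i]] <- P
    O[, cols] <- P %*% V[, cols, drop = FALSE]
  }
  out <- O %*% lw$Wo
  list(out = out, Q = Q, K = K, V = V, O = O, P_list = P_list)
}

self_attention_backward <- function(dOut, cache, Z, lw, config) {
  h <- config$n_heads; dk <- config$d_k
  dWo <- t(cache$O) %*% dOut
  dO <- dOut %*% t(lw$Wo)
  dQ <- matrix(0, nrow(Z), config$d_model)
  dK <- dQ; dV <- dQ
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    P <- cache$P_list[[i]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dP <- dOh %*% t(Vh)
    dV[, cols] <- t(P) %*% dOh
    dS <- P * (dP - rowSums(dP * P))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dk)
    dK[, cols] <- t(dS) %*% cache$Q[, cols, drop = FALSE] / sqrt(dk)
  }
  dZ <- dQ %*% t(lw$Wq) + dK %*% t(lw$Wk) + dV %*% t(lw$Wv)
  list(dZ = dZ,
       dWq = t(Z) %*% dQ, dWk = t(Z) %*% dK, dWv = t(Z) %*% dV, dWo = dWo)
}

# one encoder layer forward with cache
encoder_layer_forward <- function(Z, lw, config) {
  att <- self_attention_forward(Z, lw, config)
  R1 <- Z + att$out
  if (config$use_layer_norm) {
    ln1 <- layer_norm_forward(R1, lw$ln1_g, lw$ln1_b)
    Z1 <- ln1$out
  } else {
    ln1 <- NULL; Z1 <- R1
  }
  Hpre <- Z1 %*% lw$W1 + rep(lw$b1, each = nrow(Z1))
  Hact <- pmax(Hpre, 0)
  Ffn <- Hact %*% lw$W2 + rep(lw$b2, each = nrow(Z1))
  R2 <- Z1 + Ffn
  if (config$use_layer_norm) {
    ln2 <- layer_norm_forward(R2, lw$ln2_g, lw$ln2_b)
    Z2 <- ln2$out
  } else {
    ln2 <- NULL; Z2 <- R2
  }
  list(out = Z2, att = att, ln1 = ln1, ln2 = ln2, Z = Z, Z1 = Z1,
       Hpre = Hpre, Hact = Hact)
}

encoder_layer_backward <- function(dZ2, cache, lw, config) {
  g <- list()
  if (config$use_layer_norm) {
    lb2 <- layer_norm_backward(dZ2, cache$ln2, lw$ln2_g)
    dR2 <- lb2$dX; g$ln2_g <- lb2$dgamma; g$ln2_b <- lb2$dbeta
  } else {
    dR2 <- dZ2; g$ln2_g <- 0 * lw$ln2_g; g$ln2_b <- 0 * lw$ln2_b
  }
  dFfn <- dR2
  g$W2 <- t(cache$Hact) %*% dFfn
  g$b2 <- colSums(dFfn)
  dHact <- dFfn %*% t(lw$W2)
  dHpre <- dHact * (cache$Hpre > 0)
  g$W1 <- t(cache$Z1) %*% dHpre
  g$b1 <- colSums(dHpre)
  dZ1 <- dR2 + dHpre %*% t(lw$W1)
  if (config$use_layer_norm) {
    lb1 <- layer_norm_backward(dZ1, cache$ln1, lw$ln1_g)
    dR1 <- lb1$dX; g$ln1_g <- lb1$dgamma; g$ln1_b <- lb1$dbeta
  } else {
    dR1 <- dZ1; g$ln1_g <- 0 * lw$ln1_g; g$ln1_b <- 0 * lw$ln1_b
  }
  ab <- self_attention_backward(dR1, cache$att, cache$Z, lw, config)
  g$Wq <- ab$dWq; g$Wk <- ab$dWk; g$Wv <- ab$dWv; g$Wo <- ab$dWo
  list(dZ = dR1 + ab$dZ, grads = g)
}

#' Run the transformer encoder stack
#'
#' Applies `n_layers` identical blocks of multi-head self-attention and
#' position-wise feed-forward sublayers, each wrapped with a residual
#' connection and post-layer-normalization; output shape equals input shape.
#'
#' @param tokens (N+1) x D token matrix.
#' @param layers list of per-layer weight lists (fields `Wq`, `Wk`, `Wv`,
#'   `Wo`, `W1`, `b1`, `W2`, `b2`, `ln1_g`, `ln1_b`, `ln2_g`, `ln2_b`), as
#'   produced by [init_vit_params()].
#' @param config `encoder_config`.
#' @param keep_cache logical; when `TRUE` the per-layer forward caches are
#'   attached (used by the training backward pass).
#' @return token matrix of the same shape (with attribute `cache` when
#'   requested).
#' @export
encoder_forward <- function(tokens, layers, config, keep_cache = FALSE) {
  Z <- tokens
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  for (l in seq_along(layers)) {
    fc <- encoder_layer_forward(Z, layers[[l]], config)
    Z <- fc$out
    if (!all(is.finite(Z))) {
      stop(sprintf("non-finite activations after encoder layer %d", l),
           call. = FALSE)
    }
    if (keep_cache) caches[[l]] <- fc
  }
  if (keep_cache) attr(Z, "cache") <- caches
  Z
}

#' Reshape encoder tokens into a spatial feature map
#'
#' Drops the class token, arranges the N patch tokens on their
#' sqrt(N) x sqrt(N) grid in row-major patch order, and (optionally)
#' linearly projects the token dimension D to `target_d`.
#'
#' @param tokens (N+1) x D token matrix (row 1 = class token).
#' @param target_d output feature dimension; default D (no projection).
#' @param W_proj optional D x target_d projection matrix; required when
#'   `target_d != D` unless supplied by the model parameters.
#' @return object of class `feature_map`: list with `x` (d x h x w array),
#'   `h`, `w`, `d`, and `positions` (the hw x d matrix of position vectors
#'   x_j in row-major order).
#' @export
tokens_to_feature_map <- function(tokens, target_d = ncol(tokens),
                                  W_proj = NULL) {
  N <- nrow(tokens) - 1L
  side <- as.integer(round(sqrt(N)))
  if (side * side != N) {
    stop(sprintf("token count N=%d is not a perfect square; cannot form a grid",
                 N), call. = FALSE)
  }
  X <- tokens[-1L, , drop = FALSE]
  D <- ncol(X)
  if (target_d != D) {
    if (is.null(W_proj)) {
      stop(sprintf("projection matrix required to map D=%d to target_d=%d",
                   D, target_d), call. = FALSE)
    }
    X <- X %*% W_proj
  }
  feature_map_from_positions(X, side, side)
}

#' Build a feature map from a position-vector matrix
#'
#' @param positions hw x d matrix; row j is the position vector x_j in
#'   row-major spatial order.
#' @param h,w grid height and width.
#' @return `feature_map` object.
#' @export
feature_map_from_positions <- function(positions, h, w) {
  stopifnot(nrow(positions) == h * w)
  d <- ncol(positions)
  x <- array(t(positions), c(d, w, h))  # fill cols fastest: position index row-major
  x <- aperm(x, c(1L, 3L, 2L))
  structure(list(x = x, d = d, h = h, w = w, positions = positions),
            class = "feature_map")
}

#' Coerce a feature map (or d x h x w array) to its position matrix
#'
#' @param fmap `feature_map` or d x h x w array.
#' @return hw x d matrix of position vectors in row-major spatial order.
#' @export
as_positions <- function(fmap) {
  if (inherits(fmap, "feature_map")) return(fmap$positions)
  d <- dim(fmap)
  stopifnot(length(d) == 3L)
  m <- matrix(0, d[2] * d[3], d[1])
  k <- 0L
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    k <- k + 1L
    m[k, ] <- fmap[, i, j]
  }
  m
}
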