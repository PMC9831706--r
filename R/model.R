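#' Initialize a ViT + CSRA grading model
#'
#' Builds the full two-block model: the patch-embedding/transformer feature
#' extraction block and the class-specific residual attention grading head.
#' Weight matrices use Xavier/Glorot scaling (sd = sqrt(2/(fan_in +
#' fan_out))), LayerNorm gains start at 1 and all biases at 0; the
#' positional table and class token use a small-variance N(0, 0.02^2) draw.
#'
#' @param config `encoder_config`.
#' @param n_classes number of grades C (2, 5 or 6).
#' @param lambda CSRA residual weight (default 0.3).
#' @param n_csra_heads CSRA head count in {1, 2, 4, 6} (default 2).
#' @param seed integer seed for the weight draw.
#' @return list of class `dr_model` with fields `config`, `n_classes`,
#'   `lambda`, `temperatures`, `params`.
#' @export
init_model <- function(config, n_classes, lambda = 0.3, n_csra_heads = 2L,
                       seed = 0L) {
  P <- config$patch_size
  D <- config$d_model
  ppc <- P * P * 3L
  N <- (config$image_size %/% P)^2
  temps <- multi_head_temperatures(n_csra_heads)
  params <- with_seed(seed, {
    xavier <- function(r, c) {
      matrix(stats::rnorm(r * c, 0, sqrt(2 / (r + c))), r, c)
    }
    rmat <- function(r, c, sd = 0.02) matrix(stats::rnorm(r * c, 0, sd), r, c)
    layers <- lapply(seq_len(config$n_layers), function(l) {
      list(Wq = xavier(D, D), Wk = xavier(D, D), Wv = xavier(D, D),
           Wo = xavier(D, D),
           W1 = xavier(D, config$ffn_dim), b1 = numeric(config$ffn_dim),
           W2 = xavier(config$ffn_dim, D), b2 = numeric(D),
           ln1_g = rep(1, D), ln1_b = numeric(D),
           ln2_g = rep(1, D), ln2_b = numeric(D))
    })
    list(E = xavier(ppc, D), E_pos = rmat(N + 1L, D),
         x_class = stats::rnorm(D, 0, 0.02), layers = layers,
         m = xavier(n_classes, D))
  })
  structure(list(config = config, n_classes = as.integer(n_classes),
                 lambda = lambda, temperatures = temps, params = params),
            class = "dr_model")
}

#' Forward pass of the grading model
#'
#' Patchifies the image, embeds it into the token sequence, runs the
#' encoder stack, reshapes the patch tokens to a spatial feature map, and
#' applies the CSRA head.
#'
#' @param model `dr_model`.
#' @param image H x W x 3 array matching `model$config$image_size`.
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return `grading_scores` (see [csra_logits()]); with `keep_cache`,
#'   a `cache` field is attached.
#' @export
model_forward <- function(model, image, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  # center pixel intensities before embedding (inputs arrive in [0, 1])
  grid <- patchify((image - 0.5) / 0.5, cfg$patch_size)
  Z0 <- patch_embed(grid, p$E, p$E_pos, p$x_class)
  Z <- encoder_forward(Z0, p$layers, cfg, keep_cache = keep_cache)
  X <- Z[-1L, , drop = FALSE]
  head_params <- csra_head_params(p$m, lambda = model$lambda,
                                  temperatures = model$temperatures)
  if (keep_cache) {
    cc <- csra_forward_cache(X, head_params)
    logits <- cc$logits
    cache <- list(patches = grid$patches, enc = attr(Z, "cache"), X = X,
                  csra = cc, head_params = head_params)
  } else {
    side <- as.integer(sqrt(nrow(X)))
    fmap <- feature_map_from_positions(X, side, side)
    sc <- csra_logits(fmap, head_params)
    logits <- sc$logits
    cache <- NULL
  }
  out <- list(logits = logits, probs = softmax_vec(logits),
              sigmoid = 1 / (1 + exp(-logits)),
              predicted = which.max(logits) - 1L)
  if (keep_cache) out$cache <- cache
  structure(out, class = "grading_scores")
}

# backward pass: dlogits (length C) -> gradient list shaped like params
model_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  cb <- csra_backward(dlogits, cache$csra, cache$X, cache$head_params)
  dZ <- rbind(0, cb$dX)
  glayers <- vector("list", length(p$layers))
  for (l in rev(seq_along(p$layers))) {
    lb <- encoder_layer_backward(dZ, cache$enc[[l]], p$layers[[l]], cfg)
    dZ <- lb$dZ
    glayers[[l]] <- lb$grads
  }
  # embed: Z0 = rbind(x_class, Xp E) + E_pos
  dE_pos <- dZ
  dx_class <- dZ[1L, ]
  dE <- t(cache$patches) %*% dZ[-1L, , drop = FALSE]
  list(E = dE, E_pos = dE_pos, x_class = dx_class, layers = glayers,
       m = cb$dm)
}

# elementwise binary operation over a params-shaped nested list
params_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- params_map2(a[[nm]], b[[nm]], f)
    if (is.null(names(a))) {
      for (i in seq_along(a)) out[[i]] <- params_map2(a[[i]], b[[i]], f)
    }
    out
  } else {
    f(a, b)
  }
}

params_zero <- function(p) params_map2(p, p, function(a, b) a * 0)

# is this leaf part of the classifier parameter group?
# (the CSRA classifier matrix m is the only classifier-group leaf)

#' Save a model checkpoint
#'
#' Serializes the model (weights plus an embedded config block) to a single
#' file; the write is atomic.
#'
#' @param model `dr_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  atomic_write(path, function(p) saveRDS(model, p))
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return `dr_model`.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dr_model")) {
    stop(sprintf("%s is not a drgrader checkpoint", path), call. = FALSE)
  }
  model
}

#' Read a model/training configuration from YAML
#'
#' Recognized keys mirror [encoder_config()], [init_model()] and
#' [train_config()] arguments under `model:` and `train:` blocks.
#'
#' @param path YAML file.
#' @return list with `model_config` (`encoder_config`), `n_classes`,
#'   `lambda`, `n_csra_heads`, and `train` (`train_config`).
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  mc <- y$model %||% list()
  enc_args <- mc[intersect(names(mc),
                           c("n_layers", "d_model", "n_heads", "ffn_dim",
                             "patch_size", "image_size", "dropout"))]
  cfg <- do.call(encoder_config, enc_args)
  tr <- do.call(train_config, y$train %||% list())
  list(model_config = cfg,
       n_classes = mc$n_classes %||% 6L,
       lambda = mc$lambda %||% 0.3,
       n_csra_heads = mc$n_csra_heads %||% 2L,
       train = tr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
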