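#' Lesion specification for one synthetic fundus image
#'
#' Lesion content is cumulative in grade, mirroring clinical phenomenology:
#' grade 0 renders a lesion-free retina (disc, fovea, vessels only);
#' grade 1 adds dark-red dot lesions (microaneurysms / dot hemorrhages);
#' grade 2 adds yellow-white punctate hard exudates; grade 3 adds white
#' cotton-wool soft-exudate blobs; grade 4 adds neovascular tufts near the
#' disc and a large hemorrhage; grade 5 overlays an exposure or blur
#' artifact on content of a random lower grade (ungradable image quality).
#'
#' @param grade integer 0-5.
#' @param seed integer seed; every stochastic choice of the renderer derives
#'   from it.
#' @param n_microaneurysms,n_hard_exudates,n_soft_exudates length-2 integer
#'   ranges (min, max) for the per-image lesion counts.
#' @return list of class `lesion_spec`.
#' @export
lesion_spec <- function(grade, seed = 0L,
                        n_microaneurysms = c(4L, 10L),
                        n_hard_exudates = c(6L, 14L),
                        n_soft_exudates = c(2L, 5L)) {
  grade <- as.integer(grade)
  if (grade < 0L || grade > 5L) stop("grade must be in 0..5", call. = FALSE)
  content <- if (grade == 5L) NA_integer_ else grade  # drawn at render time
  structure(list(grade = grade, seed = as.integer(seed),
                 content_grade = content,
                 n_microaneurysms = if (grade >= 1L && grade <= 4L) n_microaneurysms else c(0L, 0L),
                 n_hard_exudates = if (grade >= 2L && grade <= 4L) n_hard_exudates else c(0L, 0L),
                 n_soft_exudates = if (grade >= 3L && grade <= 4L) n_soft_exudates else c(0L, 0L),
                 neovascular = grade == 4L,
                 artifact = grade == 5L),
            class = "lesion_spec")
}

# alpha-composite a soft mask with a flat colour onto an image
paint <- function(img, soft, color, alpha = 1) {
  a <- soft * alpha
  for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - a) + color[ch] * a
  img
}

soft_disc <- function(rr, cc, cy, cx, radius, edge = 1) {
  d <- sqrt((rr - cy)^2 + (cc - cx)^2)
  pmin(pmax((radius - d) / edge, 0), 1)
}

# stamp a polyline (vessel) by compositing small discs along its path;
# returns list(img, mask)
draw_walk <- function(img, mask, rr, cc, y, x, angle, n_steps, width0,
                      width1, color, wobble, alpha = 0.9) {
  H <- dim(img)[1]
  for (t in seq_len(n_steps)) {
    angle <- angle + stats::rnorm(1, 0, wobble)
    y <- y + sin(angle); x <- x + cos(angle)
    w <- width0 + (width1 - width0) * t / n_steps
    s <- soft_disc(rr, cc, y, x, w, edge = 0.8)
    img <- paint(img, s, color, alpha)
    mask <- mask | (s > 0.25)
  }
  list(img = img, mask = mask, y = y, x = x, angle = angle)
}

#' Render one synthetic fundus image
#'
#' Renders a circular retinal field on a black background with one bright
#' optic disc, one dark fovea, branching vessel polylines, and then the
#' lesion content dictated by the spec, with per-lesion jittered position,
#' size and colour. Deterministic given `spec$seed`. Alongside the pixels,
#' per-lesion-type binary masks are returned so tests can target geometry
#' rather than absolute colours.
#'
#' @param spec `lesion_spec`.
#' @param size image side length (>= 64).
#' @return list of class `fundus_image` with `pixels` (size x size x 3 in
#'   `[0, 1]`), `grade`, `id`, and `masks` (named list of logical matrices:
#'   `vessel`, `microaneurysm`, `hard_exudate`, `soft_exudate`,
#'   `neovascular`, `artifact`).
#' @export
generate_fundus <- function(spec, size = 64L) {
  if (size < 64L) {
    stop(sprintf("image size %d too small; minimum is 64", size),
         call. = FALSE)
  }
  s <- as.integer(size)
  with_seed(spec$seed, {
    eff <- if (spec$artifact) {
      lesion_spec(sample(0:4, 1), seed = spec$seed)  # random content grade
    } else {
      spec
    }
    rr <- matrix(seq_len(s), s, s)
    cc <- matrix(seq_len(s), s, s, byrow = TRUE)
    ctr <- (s + 1) / 2
    R <- 0.47 * s
    dist <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
    field <- soft_disc(rr, cc, ctr, ctr, R, edge = 1.5)
    shade <- 1 - 0.35 * pmin(dist / R, 1)^2
    base <- c(0.62, 0.32, 0.10) + stats::runif(3, -0.04, 0.04)
    img <- array(0, c(s, s, 3))
    for (ch in 1:3) img[, , ch] <- base[ch] * shade * field
    masks <- list(vessel = matrix(FALSE, s, s),
                  microaneurysm = matrix(FALSE, s, s),
                  hard_exudate = matrix(FALSE, s, s),
                  soft_exudate = matrix(FALSE, s, s),
                  neovascular = matrix(FALSE, s, s),
                  artifact = matrix(FALSE, s, s))

    # optic disc on a random side, fovea opposite
    side_sign <- sample(c(-1, 1), 1)
    disc_y <- ctr + stats::runif(1, -0.05, 0.05) * s
    disc_x <- ctr + side_sign * (0.28 + stats::runif(1, -0.03, 0.03)) * s
    disc_r <- (0.07 + stats::runif(1, -0.01, 0.01)) * s
    img <- paint(img, soft_disc(rr, cc, disc_y, disc_x, disc_r,
                                edge = 0.25 * disc_r) * field,
                 c(0.97, 0.88, 0.55), 0.95)
    fov_x <- ctr - side_sign * 0.18 * s
    fov <- exp(-((rr - ctr)^2 + (cc - fov_x)^2) / (2 * (0.055 * s)^2))
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.45 * fov)

    # vessels: random walks out of the disc
    vessel_col <- c(0.30, 0.07, 0.04)
    n_vessels <- 5L
    for (v in seq_len(n_vessels)) {
      ang <- stats::runif(1, 0, 2 * pi)
      dw <- draw_walk(img, masks$vessel, rr, cc, disc_y, disc_x, ang,
                      n_steps = round(0.55 * s), width0 = 0.022 * s,
                      width1 = 0.008 * s, color = vessel_col, wobble = 0.22)
      img <- dw$img; masks$vessel <- dw$mask
    }

    rand_pos <- function(max_r = 0.8) {
      repeat {
        a <- stats::runif(1, 0, 2 * pi)
        d <- sqrt(stats::runif(1)) * max_r * R
        y <- ctr + d * sin(a); x <- ctr + d * cos(a)
        if (sqrt((y - disc_y)^2 + (x - disc_x)^2) > 1.4 * disc_r) {
          return(c(y, x))
        }
      }
    }
    draw_dots <- function(img, mask, n, rad, rad_jit, color, alpha,
                          edge_frac = 0.5) {
      for (i in seq_len(n)) {
        p <- rand_pos()
        r0 <- rad * stats::runif(1, 1 - rad_jit, 1 + rad_jit)
        col <- pmin(pmax(color + stats::runif(3, -0.03, 0.03), 0), 1)
        sdisc <- soft_disc(rr, cc, p[1], p[2], r0, edge = edge_frac * r0)
        img <- paint(img, sdisc, col, alpha)
        mask <- mask | (sdisc > 0.25)
      }
      list(img = img, mask = mask)
    }

    if (eff$n_microaneurysms[2] > 0) {
      n <- sample(eff$n_microaneurysms[1]:eff$n_microaneurysms[2], 1)
      d <- draw_dots(img, masks$microaneurysm, n, 0.016 * s, 0.35,
                     c(0.25, 0.05, 0.03), 0.9)
      img <- d$img; masks$microaneurysm <- d$mask
    }
    if (eff$n_hard_exudates[2] > 0) {
      n <- sample(eff$n_hard_exudates[1]:eff$n_hard_exudates[2], 1)
      d <- draw_dots(img, masks$hard_exudate, n, 0.013 * s, 0.35,
                     c(0.95, 0.85, 0.25), 0.9)
      img <- d$img; masks$hard_exudate <- d$mask
    }
    if (eff$n_soft_exudates[2] > 0) {
      n <- sample(eff$n_soft_exudates[1]:eff$n_soft_exudates[2], 1)
      d <- draw_dots(img, masks$soft_exudate, n, 0.05 * s, 0.3,
                     c(0.92, 0.92, 0.85), 0.65, edge_frac = 0.9)
      img <- d$img; masks$soft_exudate <- d$mask
    }
    if (eff$neovascular) {
      # dense tuft of short wiggly vessels at the disc margin
      for (tft in 1:6) {
        ang <- stats::runif(1, 0, 2 * pi)
        dw <- draw_walk(img, masks$neovascular, rr, cc,
                        disc_y + stats::rnorm(1, 0, 0.02 * s),
                        disc_x + stats::rnorm(1, 0, 0.02 * s),
                        ang, n_steps = round(0.15 * s),
                        width0 = 0.016 * s, width1 = 0.008 * s,
                        color = c(0.28, 0.05, 0.03), wobble = 0.6)
        img <- dw$img; masks$neovascular <- dw$mask
      }
      p <- rand_pos(0.6)
      hem <- soft_disc(rr, cc, p[1], p[2], 0.10 * s, edge = 0.04 * s)
      img <- paint(img, hem, c(0.22, 0.04, 0.03), 0.9)
      masks$neovascular <- masks$neovascular | (hem > 0.25)
    }
    if (spec$artifact) {
      if (stats::runif(1) < 0.5) {
        # overexposure flare from a random border point
        a <- stats::runif(1, 0, 2 * pi)
        fy <- ctr + R * sin(a); fx <- ctr + R * cos(a)
        flare <- exp(-((rr - fy)^2 + (cc - fx)^2) / (2 * (0.35 * s)^2))
        for (ch in 1:3) img[, , ch] <- img[, , ch] + 0.75 * flare
      } else {
        # severe defocus with global darkening
        for (ch in 1:3) {
          img[, , ch] <- EBImage::gblur(img[, , ch], sigma = 0.035 * s)
        }
        img <- img * stats::runif(1, 0.55, 0.75)
      }
      masks$artifact <- field > 0.5
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(pixels = img, grade = spec$grade,
                   id = sprintf("g%d_s%09d", spec$grade, spec$seed),
                   masks = masks, spec = spec),
              class = "fundus_image")
  })
}

#' Pixel-statistics colour features of a fundus image
#'
#' Simple per-image features (fractions of the retinal field occupied by
#' dark-red, yellow, and bright-white pixels, plus mean brightness) used to
#' verify that generated grades are separable by trivial statistics — i.e.
#' that the synthetic set is learnable at all.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @return named numeric vector.
#' @export
fundus_color_features <- function(image) {
  R <- image[, , 1]; G <- image[, , 2]; B <- image[, , 3]
  bright <- (R + G + B) / 3
  field <- bright > 0.05
  nf <- max(sum(field), 1L)
  dark_red <- field & R > 0.12 & R < 0.45 & G < 0.35 * R
  yellow <- field & R > 0.7 & G > 0.55 & B < 0.45
  white <- field & R > 0.65 & G > 0.6 & B > 0.35
  c(dark_red_frac = sum(dark_red) / nf,
    yellow_frac = sum(yellow) / nf,
    white_frac = sum(white) / nf,
    mean_brightness = mean(bright[field]))
}

#' Generate a synthetic graded fundus dataset on disk
#'
#' Writes `n_per_class` PNG images per grade, a `labels.csv`
#' (`image,label,split`), optional per-lesion-type mask PNGs, and a YAML
#' manifest recording every spec. Images are split 60/20/20 into
#' train/validation/test, stratified by grade. Fully deterministic given
#' `seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param n_per_class images per grade (>= 1).
#' @param size image side length.
#' @param seed master seed.
#' @param n_classes 6 (grades 0-5) or 5 (grades 0-4).
#' @param write_masks also write lesion masks as PNGs.
#' @param imbalance mimic the heavy class skew of real screening sets
#'   (grade proportions roughly 46/5/33/2/7/8 percent) instead of balanced
#'   counts; `n_per_class` then sets the mean class size.
#' @return data.frame index (`image`, `label`, `split`), invisibly.
#' @export
generate_dataset <- function(out_dir, n_per_class = 50L, size = 64L,
                             seed = 0L, n_classes = 6L, write_masks = FALSE,
                             imbalance = FALSE) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  if (!n_classes %in% c(5L, 6L)) stop("n_classes must be 5 or 6", call. = FALSE)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory %s", out_dir), call. = FALSE)
  }
  if (write_masks) {
    dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  }
  grades <- 0:(n_classes - 1L)
  counts <- if (imbalance) {
    props <- c(0.46, 0.05, 0.33, 0.02, 0.07, 0.08)[seq_len(n_classes)]
    pmax(1L, round(n_per_class * n_classes * props / sum(props)))
  } else {
    rep(as.integer(n_per_class), n_classes)
  }
  rows <- list()
  manifest <- list()
  for (gi in seq_along(grades)) {
    g <- grades[gi]
    n <- counts[gi]
    n_tr <- round(0.6 * n); n_va <- round(0.2 * n)
    splits <- c(rep("train", n_tr), rep("val", n_va),
                rep("test", n - n_tr - n_va))
    for (i in seq_len(n)) {
      img_seed <- (as.numeric(seed) * 100003 + g * 7919 + i * 13) %%
        .Machine$integer.max
      spec <- lesion_spec(g, seed = as.integer(img_seed))
      fi <- generate_fundus(spec, size = size)
      name <- sprintf("%s_%03d.png", fi$id, i)
      atomic_write(file.path(out_dir, "images", name), function(p) {
        png::writePNG(fi$pixels, p)
      })
      if (write_masks) {
        mk <- array(0, c(size, size, 3))
        mk[, , 1] <- fi$masks$microaneurysm | fi$masks$neovascular
        mk[, , 2] <- fi$masks$hard_exudate | fi$masks$soft_exudate
        mk[, , 3] <- fi$masks$vessel | fi$masks$artifact
        atomic_write(file.path(out_dir, "masks", name), function(p) {
          png::writePNG(mk, p)
        })
      }
      rows[[length(rows) + 1L]] <- data.frame(
        image = file.path("images", name), label = g, split = splits[i])
      manifest[[length(manifest) + 1L]] <- list(
        image = name, grade = g, seed = as.integer(img_seed),
        split = splits[i])
    }
  }
  index <- do.call(rbind, rows)
  atomic_write(file.path(out_dir, "labels.csv"), function(p) {
    utils::write.csv(index, p, row.names = FALSE)
  })
  atomic_write(file.path(out_dir, "manifest.yaml"), function(p) {
    yaml::write_yaml(list(seed = seed, size = size, n_classes = n_classes,
                          images = manifest), p)
  })
  invisible(index)
}
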