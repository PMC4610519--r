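# Seeded synthetic farrowing-pen scenes: multiplicative illumination fields
# with lamp on/off step events, a textured elliptical animal ("sow") that
# may move or stay motionless, smaller blobs ("piglets"), locally shuffled
# background texture ("straw"), and additive sensor noise. Every frame
# carries its ground-truth illumination, reflectance and foreground masks,
# so every pipeline stage is testable without external data.
#
# Conventions: the illumination field carries the intensity scale (gray
# levels, base ~90) and the reflectance field is dimensionless around 1
# (background ~1.0, animal ~2.0), so image = clip(illum * refl + noise).

# smoothed seeded white noise, standardized to sd 1
.smooth_noise <- function(M, N, corr_len) {
  z <- matrix(stats::rnorm(M * N), M, N)
  if (corr_len > 0) {
    h <- ceiling(3 * corr_len)
    taps <- stats::dnorm(-h:h, sd = corr_len)
    taps <- taps / sum(taps)
    z <- .conv_sep(.conv_sep(z, taps, 1L, 1L, "symmetric"),
                   taps, 2L, 1L, "symmetric")
  }
  z / stats::sd(z)
}

.ellipse_mask <- function(M, N, center, axes, angle_deg) {
  th <- angle_deg * pi / 180
  r <- matrix(seq_len(M), M, N) - center[1]
  c_ <- matrix(seq_len(N), M, N, byrow = TRUE) - center[2]
  # x = columns, y = -rows (y up); express each point in the ellipse frame
  # (rotation by -angle), so a positive angle tilts the major axis CCW
  x <- c_ * cos(th) + (-r) * sin(th)
  y <- -c_ * sin(th) + (-r) * cos(th)
  (x / axes[2])^2 + (y / axes[1])^2 <= 1
}

.illum_base <- function(M, N, field, base_level) {
  type <- field$type %||% "ramp"
  amp <- field$amplitude %||% 0.25
  switch(type,
    uniform = matrix(base_level, M, N),
    ramp = base_level *
      (1 + amp * matrix(seq(-1, 1, length.out = N), M, N, byrow = TRUE)),
    spot = {
      rc <- c(M, N) / 2
      s <- 0.35 * min(M, N)
      r <- matrix(seq_len(M), M, N) - rc[1]
      c_ <- matrix(seq_len(N), M, N, byrow = TRUE) - rc[2]
      base_level * (1 - amp + 2 * amp * exp(-(r^2 + c_^2) / (2 * s^2)))
    },
    stop(sprintf("unknown illumination field type '%s'", type)))
}

#' Synthetic-scene specification
#'
#' Defaults describe the emulated recording conditions: a 256x256 pen view
#' under a lateral illumination ramp (base level 90 gray values, +/-25%),
#' 64 warm-up frames without animals followed by 60 frames with a sow and
#' three piglets, a lamp switched off (gain 0.5) at animal-frame 20 and
#' back on (gain 2.0, restoring the base) at frame 40, 5% of background
#' straw patches re-shuffled per frame, and additive sensor noise of 2 gray
#' values. The sow's reflectance texture amplitude (0.25) is more than
#' three times the background's (0.08), reflecting a light-coated animal on
#' darker bedding.
#'
#' @param size image size `c(M, N)` in pixels.
#' @param n_warmup number of initial frames without foreground objects.
#' @param n_frames number of frames with the animal present.
#' @param illumination_field `list(type, amplitude)` with type `"uniform"`,
#'   `"ramp"` or `"spot"`.
#' @param base_level illumination base in gray values.
#' @param lamp_events list of `list(frame, gain)`: at animal-segment frame
#'   `frame` the cumulative illumination gain is multiplied by `gain`
#'   (gain persists until the next event). `NULL` for no events.
#' @param animal `list(center_start, center_end, axes, angle, base,
#'   texture_amp, texture_corr)`; the centre moves linearly between the two
#'   endpoints over the animal segment (equal endpoints = motionless).
#' @param piglets list of `list(center, radius, base)` small blobs (may be
#'   `NULL`).
#' @param straw_dynamics fraction of 16x16 background patches re-shuffled
#'   per frame.
#' @param noise_sigma additive Gaussian noise, gray values.
#' @param seed integer; fixes the generated sequence exactly.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(size = c(256L, 256L), n_warmup = 64L, n_frames = 60L,
                       illumination_field = list(type = "ramp", amplitude = 0.25),
                       base_level = 90,
                       lamp_events = list(list(frame = 20L, gain = 0.5),
                                          list(frame = 40L, gain = 2.0)),
                       animal = list(center_start = c(140, 80),
                                     center_end = c(120, 176),
                                     axes = c(32, 58), angle = 25,
                                     base = 2.0, texture_amp = 0.25,
                                     texture_corr = 3),
                       piglets = list(list(center = c(60, 70), radius = 7, base = 1.45),
                                      list(center = c(200, 120), radius = 7, base = 1.45),
                                      list(center = c(70, 200), radius = 6, base = 1.5)),
                       straw_dynamics = 0.05, noise_sigma = 2, seed = 1L) {
  stopifnot(length(size) == 2, all(size >= 16))
  if (!is.null(lamp_events))
    for (ev in lamp_events)
      if (ev$gain <= 0) stop("lamp event gains must be > 0")
  structure(list(size = as.integer(size), n_warmup = as.integer(n_warmup),
                 n_frames = as.integer(n_frames),
                 illumination_field = illumination_field,
                 base_level = base_level, lamp_events = lamp_events,
                 animal = animal, piglets = piglets,
                 straw_dynamics = straw_dynamics,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "scene_spec")
}

# swap a random subset of background patches between random positions,
# leaving foreground pixels untouched
.shuffle_patches <- function(refl, frac, patch = 16L, protect = NULL) {
  if (frac <= 0) return(refl)
  M <- nrow(refl); N <- ncol(refl)
  pr <- seq(1L, M - patch + 1L, by = patch)
  pc <- seq(1L, N - patch + 1L, by = patch)
  cells <- expand.grid(r = pr, c = pc)
  ok <- vapply(seq_len(nrow(cells)), function(i) {
    rr <- cells$r[i]:(cells$r[i] + patch - 1L)
    cc <- cells$c[i]:(cells$c[i] + patch - 1L)
    is.null(protect) || !any(protect[rr, cc])
  }, logical(1))
  cells <- cells[ok, , drop = FALSE]
  n_swap <- floor(frac * nrow(cells) / 2)
  if (n_swap < 1) return(refl)
  pick <- sample(nrow(cells), 2L * n_swap)
  for (s in seq_len(n_swap)) {
    i <- pick[2L * s - 1L]; j <- pick[2L * s]
    ri <- cells$r[i]:(cells$r[i] + patch - 1L)
    ci <- cells$c[i]:(cells$c[i] + patch - 1L)
    rj <- cells$r[j]:(cells$r[j] + patch - 1L)
    cj <- cells$c[j]:(cells$c[j] + patch - 1L)
    tmp <- refl[ri, ci]
    refl[ri, ci] <- refl[rj, cj]
    refl[rj, cj] <- tmp
  }
  refl
}

# integer-shift a matrix, mirror-filling the vacated band
.shift_int <- function(x, dr, dc) {
  M <- nrow(x); N <- ncol(x)
  x[.edge_index(seq_len(M) - dr, M, "symmetric"),
    .edge_index(seq_len(N) - dc, N, "symmetric")]
}

#' Generate a synthetic scene
#'
#' Produces a clean reference frame (no foreground), `n_warmup` empty
#' frames, and `n_frames` frames with the animal, all with ground truth.
#' The full sequence is a deterministic function of `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return object of class `scene`: `list(reference, warmup, frames, spec)`
#'   where `reference` and each element of `warmup`/`frames` is a
#'   `scene_frame`: `list(image, true_illum, true_refl, animal_mask,
#'   piglet_mask, event_flag)`. `image = clip(true_illum * true_refl +
#'   noise, 0, 255)`; animal and piglet masks are disjoint; `event_flag`
#'   marks frames whose lamp state differs from the reference frame's
#'   (cumulative gain != 1).
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, .generate_scene_impl(spec))
}

.generate_scene_impl <- function(spec) {
  M <- spec$size[1]; N <- spec$size[2]
  illum0 <- .illum_base(M, N, spec$illumination_field, spec$base_level)
  refl_bg <- pmax(1 + 0.08 * .smooth_noise(M, N, 2.5), 0.05)
  an <- spec$animal
  tex_animal <- if (!is.null(an))
    an$base + an$texture_amp * .smooth_noise(M, N, an$texture_corr) else NULL
  tex_piglet <- if (!is.null(spec$piglets))
    lapply(spec$piglets, function(p)
      p$base + 0.2 * .smooth_noise(M, N, 2)) else NULL

  gain_at <- function(frame_idx) {       # cumulative lamp gain, animal segment
    g <- 1
    if (!is.null(spec$lamp_events))
      for (ev in spec$lamp_events) if (frame_idx >= ev$frame) g <- g * ev$gain
    g
  }

  make_frame <- function(refl, illum, event_flag, amask, pmask) {
    noise <- if (spec$noise_sigma > 0)
      matrix(stats::rnorm(M * N, sd = spec$noise_sigma), M, N) else 0
    img <- .clip255(illum * refl + noise)
    list(image = img, true_illum = illum, true_refl = refl,
         animal_mask = amask, piglet_mask = pmask,
         event_flag = event_flag)
  }
  empty <- matrix(FALSE, M, N)

  reference <- make_frame(refl_bg, illum0, FALSE, empty, empty)

  warmup <- vector("list", spec$n_warmup)
  refl_t <- refl_bg
  if (spec$n_warmup > 0) {
    for (i in seq_len(spec$n_warmup)) {
      refl_t <- .shuffle_patches(refl_t, spec$straw_dynamics)
      warmup[[i]] <- make_frame(refl_t, illum0, FALSE, empty, empty)
    }
  }

  frames <- vector("list", spec$n_frames)
  for (i in seq_len(spec$n_frames)) {
    amask <- empty
    refl <- refl_t
    if (!is.null(an)) {
      ctr <- if (spec$n_frames > 1) {
        an$center_start + (i - 1) / (spec$n_frames - 1) *
          (an$center_end - an$center_start)
      } else an$center_start
      amask <- .ellipse_mask(M, N, ctr, an$axes, an$angle)
      dr <- round(ctr[1] - an$center_start[1])
      dc <- round(ctr[2] - an$center_start[2])
      tex <- .shift_int(tex_animal, dr, dc)
      refl[amask] <- tex[amask]
    }
    pmask <- empty
    if (!is.null(spec$piglets)) {
      for (pi in seq_along(spec$piglets)) {
        p <- spec$piglets[[pi]]
        pm <- .ellipse_mask(M, N, p$center, c(p$radius, p$radius), 0) & !amask
        refl[pm] <- tex_piglet[[pi]][pm]
        pmask <- pmask | pm
      }
    }
    refl_t <- .shuffle_patches(refl_t, spec$straw_dynamics,
                               protect = amask | pmask)
    g <- gain_at(i)
    # event = the illumination state differs from the reference frame's
    frames[[i]] <- make_frame(refl, illum0 * g, g != 1, amask, pmask)
  }
  structure(list(reference = reference, warmup = warmup, frames = frames,
                 spec = spec), class = "scene")
}

#' Write a scene to disk
#'
#' Frames as 8-bit grayscale PNGs (`frame_0001.png`, ...), ground truth
#' (illumination, reflectance, masks) under `truth/`, and a JSON manifest.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "scene"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  all_frames <- c(list(scene$reference), scene$warmup, scene$frames)
  labels <- c("reference",
              sprintf("warmup_%04d", seq_along(scene$warmup)),
              sprintf("frame_%04d", seq_along(scene$frames)))
  for (i in seq_along(all_frames)) {
    fr <- all_frames[[i]]
    EBImage::writeImage(EBImage::Image(t(fr$image) / 255),
                        file.path(dir, paste0(labels[i], ".png")))
    EBImage::writeImage(EBImage::Image(t(fr$animal_mask * 1)),
                        file.path(dir, "truth", paste0(labels[i], "_animal.png")))
  }
  manifest <- list(n_warmup = scene$spec$n_warmup,
                   n_frames = scene$spec$n_frames,
                   size = scene$spec$size, seed = scene$spec$seed,
                   event_frames = which(vapply(scene$frames,
                                               `[[`, logical(1), "event_flag")))
  jsonlite::write_json(manifest, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
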