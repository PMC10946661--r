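# Synthetic dish-image generator: circular Petri dish densely packed with
# convex grain shapes, four pigment-class colour palettes (tan-yellow /
# purple-blue / gray-black / dark purple-black), a hulled/hulless appearance
# shift, exact ground-truth masks, and 9 replicate images per accession
# produced by re-randomizing grain placement.

#' AccessionSpec: generative parameters for one synthetic accession
#'
#' Palette parameters (HSV means and spreads) are a deterministic function
#' of (pigment label, hull status, accession seed).
#'
#' @slot accession_id character.
#' @slot pigment_label one of \code{NP/A/M/AM}.
#' @slot hulled logical.
#' @slot palette list with \code{h, s, v} means and \code{h_sd, s_sd, v_sd}
#'   spreads (HSV, all channels on [0, 1]).
#' @slot grain_count_range integer interval within [100, 160].
#' @slot grain_geometry list: \code{axis_frac_mean}/\code{axis_frac_sd}
#'   (grain semi-major axis as a fraction of the dish radius) and
#'   \code{aspect_mean}/\code{aspect_sd} (semi-minor / semi-major ratio).
#' @slot seed integer accession-level seed.
#' @export
setClass("AccessionSpec", representation(
  accession_id = "character", pigment_label = "character",
  hulled = "logical", palette = "list",
  grain_count_range = "integer", grain_geometry = "list",
  seed = "integer"))

setValidity("AccessionSpec", function(object) {
  if (!object@pigment_label %in% pigmentLevels())
    return("pigment_label outside {NP, A, M, AM}")
  r <- object@grain_count_range
  if (length(r) != 2 || r[1] > r[2]) return("bad grain_count_range")
  if (r[1] < 100 || r[2] > 160)
    return("grain_count_range must lie within [100, 160]")
  TRUE
})

# class palettes in HSV. NP tan-yellow (high value, low-mid saturation);
# A purple-blue; M gray-black (low saturation + value); AM = A-like hue at
# M-like value range. "hard" narrows the A-vs-AM and M-vs-AM gaps to mimic
# the confusion structure of real accessions.
paletteTable <- function(mode = c("default", "hard")) {
  mode <- match.arg(mode)
  base <- list(
    NP = c(h = 0.115, s = 0.40, v = 0.83),
    A  = c(h = 0.700, s = 0.62, v = 0.50),
    M  = c(h = 0.090, s = 0.10, v = 0.22),
    AM = c(h = 0.720, s = 0.52, v = 0.17))
  spread <- list(
    NP = c(h = 0.015, s = 0.05, v = 0.040),
    A  = c(h = 0.025, s = 0.07, v = 0.050),
    M  = c(h = 0.050, s = 0.04, v = 0.040),
    AM = c(h = 0.025, s = 0.07, v = 0.035))
  if (mode == "hard") {
    base$A[c("s", "v")]  <- c(0.45, 0.36)
    base$AM[c("s", "v")] <- c(0.30, 0.22)
    base$M[c("s", "v")]  <- c(0.16, 0.25)
    spread$A["v"] <- 0.07; spread$AM["v"] <- 0.06; spread$M["v"] <- 0.06
  }
  list(base = base, spread = spread)
}

#' Create a synthetic accession specification
#'
#' Identical arguments yield byte-identical specs. The palette is the class
#' base palette, shifted for hull status (hulled grains: higher value, lower
#' saturation) and jittered deterministically by the accession seed.
#'
#' @param pigment_label one of \code{NP/A/M/AM}.
#' @param hulled logical.
#' @param seed integer accession seed.
#' @param mode \code{"default"} (well-separated palettes) or \code{"hard"}
#'   (narrowed A/AM and M/AM gaps).
#' @param grain_count_range integer interval, within [100, 160].
#' @param accession_id optional id; derived from the arguments if missing.
#' @return an \code{\linkS4class{AccessionSpec}}.
#' @examples
#' spec <- makeAccession("AM", hulled = FALSE, seed = 7)
#' spec@palette$v
#' @export
makeAccession <- function(pigment_label, hulled, seed,
                          mode = c("default", "hard"),
                          grain_count_range = c(105L, 140L),
                          accession_id = NULL) {
  mode <- match.arg(mode)
  stopifnot(pigment_label %in% pigmentLevels(), is.logical(hulled))
  tab <- paletteTable(mode)
  b <- tab$base[[pigment_label]]
  sp <- tab$spread[[pigment_label]]
  if (hulled) {
    b["v"] <- b["v"] + 0.06
    b["s"] <- max(b["s"] - 0.05, 0.02)
  }
  jit <- withSeed(seed, runif(3, -1, 1)) * c(0.008, 0.02, 0.02)
  pal <- list(h = unname(clamp(b["h"] + jit[1])),
              s = unname(clamp(b["s"] + jit[2], 0.01, 1)),
              v = unname(clamp(b["v"] + jit[3], 0.02, 1)),
              h_sd = unname(sp["h"]), s_sd = unname(sp["s"]),
              v_sd = unname(sp["v"]))
  if (is.null(accession_id))
    accession_id <- sprintf("%s_%s_s%d", pigment_label,
                            if (hulled) "H" else "h", as.integer(seed))
  new("AccessionSpec",
      accession_id = accession_id, pigment_label = pigment_label,
      hulled = hulled, palette = pal,
      grain_count_range = as.integer(grain_count_range),
      grain_geometry = list(axis_frac_mean = 0.085, axis_frac_sd = 0.006,
                            aspect_mean = 0.62, aspect_sd = 0.04),
      seed = as.integer(seed))
}

setMethod("show", "AccessionSpec", function(object) {
  cat("AccessionSpec", object@accession_id, ":", object@pigment_label,
      if (object@hulled) "(hulled)" else "(hulless)", "\n")
  cat(sprintf("  palette HSV ~ (%.3f, %.2f, %.2f)\n",
              object@palette$h, object@palette$s, object@palette$v))
})

#' Rendering configuration for synthetic dish images
#'
#' @param image_size square image side in pixels (>= 64).
#' @param dish_radius_fraction dish radius relative to the image side; must
#'   keep the dish fully inside the frame (<= 0.5).
#' @param background_color,dish_color RGB triples in [0, 1].
#' @param noise_sigma per-pixel Gaussian noise standard deviation.
#' @param lighting_amplitude per-grain linear lighting-gradient amplitude.
#' @param replicates_per_accession replicate images per accession
#'   (default 9).
#' @param max_overlap maximum painted pairwise overlap fraction when
#'   placing a grain.
#' @param grain_count_override optional fixed grain count (e.g. 0 renders an
#'   empty dish for segmentation diagnostics), bypassing the spec range.
#' @param format \code{"png"} (lossless, default).
#' @return a list of class \code{RenderConfig}.
#' @examples
#' cfg <- renderConfig(image_size = 96)
#' @export
renderConfig <- function(image_size = 256L, dish_radius_fraction = 0.46,
                         background_color = c(0.91, 0.90, 0.88),
                         dish_color = c(0.97, 0.97, 0.955),
                         noise_sigma = 0.015, lighting_amplitude = 0.12,
                         replicates_per_accession = 9L, max_overlap = 0.15,
                         grain_count_override = NULL, format = "png") {
  stopifnot(image_size >= 64, dish_radius_fraction > 0,
            dish_radius_fraction <= 0.5,
            length(background_color) == 3, replicates_per_accession >= 1)
  structure(list(image_size = as.integer(image_size),
                 dish_radius_fraction = dish_radius_fraction,
                 background_color = background_color,
                 dish_color = dish_color, noise_sigma = noise_sigma,
                 lighting_amplitude = lighting_amplitude,
                 replicates_per_accession =
                   as.integer(replicates_per_accession),
                 max_overlap = max_overlap,
                 grain_count_override = grain_count_override,
                 format = format),
            class = "RenderConfig")
}

# vectorized HSV -> RGB, all channels in [0, 1]
hsv2rgbMat <- function(h, s, v) {
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Render one replicate image of an accession
#'
#' Grains are filled ellipses packed on a jittered hexagonal lattice inside
#' the dish circle, with per-grain palette colours, a per-grain lighting
#' gradient and per-pixel Gaussian noise. The returned mask marks exactly
#' the painted grain pixels. Different replicate seeds permute grain
#' placement but not the accession palette.
#'
#' @param spec an \code{\linkS4class{AccessionSpec}}.
#' @param config a \code{\link{renderConfig}}.
#' @param replicate_seed integer seed for this replicate.
#' @return list with \code{image} (H x W x 3 array), \code{mask} (H x W
#'   integer matrix, 1 = grain) and \code{label} (the spec's pigment label).
#' @examples
#' out <- renderReplicate(makeAccession("A", FALSE, 1),
#'                        renderConfig(image_size = 96), 1)
#' sum(out$mask)
#' @export
renderReplicate <- function(spec, config, replicate_seed) {
  stopifnot(is(spec, "AccessionSpec"), inherits(config, "RenderConfig"))
  withSeed(replicate_seed, {
    size <- config$image_size
    rDish <- config$dish_radius_fraction * size
    cen <- (size + 1) / 2
    geo <- spec@grain_geometry
    aMean <- geo$axis_frac_mean * rDish
    bMean <- aMean * geo$aspect_mean

    n <- if (!is.null(config$grain_count_override))
      as.integer(config$grain_count_override)
    else {
      rg <- spec@grain_count_range
      if (rg[1] == rg[2]) rg[1] else sample(rg[1]:rg[2], 1)
    }

    # canvas: background, then dish disc
    img <- array(rep(config$background_color, each = size * size),
                 c(size, size, 3))
    px <- matrix(rep(seq_len(size), each = size), size)   # col index
    py <- matrix(rep(seq_len(size), size), size)          # row index
    inDish <- (px - cen)^2 + (py - cen)^2 <= rDish^2
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[inDish] <- config$dish_color[ch]
      img[, , ch] <- pl
    }
    mask <- matrix(0L, size, size)

    if (n > 0) {
      # jittered hex lattice of candidate centres inside the dish
      dx <- 2 * aMean * 1.02
      dy <- 2 * bMean * 1.05
      rows <- seq(cen - rDish + bMean, cen + rDish - bMean, by = dy)
      cand <- do.call(rbind, lapply(seq_along(rows), function(i) {
        off <- if (i %% 2 == 0) dx / 2 else 0
        xs <- seq(cen - rDish + aMean + off, cen + rDish - aMean, by = dx)
        cbind(xs, rows[i])
      }))
      keep <- (cand[, 1] - cen)^2 + (cand[, 2] - cen)^2 <=
        (rDish - 0.9 * bMean)^2
      cand <- cand[keep, , drop = FALSE]
      if (n > nrow(cand))
        stop("impossible packing: ", n, " grains requested but only ",
             nrow(cand), " lattice sites fit in the dish")
      cand <- cand[sample(nrow(cand), n), , drop = FALSE]

      pal <- spec@palette
      occupied <- matrix(FALSE, size, size)
      for (g in seq_len(n)) {
        a <- max(clamp(rnorm(1, aMean, geo$axis_frac_sd * rDish),
                       0.8 * aMean, 1.2 * aMean), 1.5)
        b <- max(a * clamp(rnorm(1, geo$aspect_mean, geo$aspect_sd),
                           0.45, 0.85), 1.2)
        col <- hsv2rgbMat(clamp(rnorm(1, pal$h, pal$h_sd)) ,
                          clamp(rnorm(1, pal$s, pal$s_sd), 0, 1),
                          clamp(rnorm(1, pal$v, pal$v_sd), 0.01, 1))
        best <- NULL
        for (attempt in 1:30) {
          gx <- cand[g, 1] + runif(1, -0.18, 0.18) * dx
          gy <- cand[g, 2] + runif(1, -0.18, 0.18) * dy
          th <- runif(1, -pi / 12, pi / 12)
          # bounding box, clipped to frame
          r0 <- max(1L, floor(gy - a)); r1 <- min(size, ceiling(gy + a))
          c0 <- max(1L, floor(gx - a)); c1 <- min(size, ceiling(gx + a))
          lr <- r0:r1; lc <- c0:c1
          ddy <- matrix(rep(lr - gy, length(lc)), length(lr))
          ddx <- matrix(rep(lc - gx, each = length(lr)), length(lr))
          u <- (ddx * cos(th) + ddy * sin(th)) / a
          w <- (-ddx * sin(th) + ddy * cos(th)) / b
          inside <- u * u + w * w <= 1
          # keep grains inside the dish circle
          inside <- inside &
            (ddx + gx - cen)^2 + (ddy + gy - cen)^2 <= rDish^2
          if (!any(inside)) next
          ov <- sum(occupied[lr, lc][inside]) / sum(inside)
          if (is.null(best) || ov < best$ov)
            best <- list(ov = ov, lr = lr, lc = lc, inside = inside,
                         u = u)
          if (ov <= config$max_overlap) break
        }
        # a grain that cannot be placed without excessive overlap means the
        # requested count does not fit: fail explicitly
        if (is.null(best) || best$ov > 0.35)
          stop("impossible packing: grain ", g,
               " cannot be placed with bounded overlap")
        lr <- best$lr; lc <- best$lc; inside <- best$inside
        shade <- 1 + config$lighting_amplitude * best$u[inside] / 2
        for (ch in 1:3) {
          pl <- img[lr, lc, ch]
          pl[inside] <- clamp(col[ch] * shade)
          img[lr, lc, ch] <- pl
        }
        occ <- occupied[lr, lc]; occ[inside] <- TRUE
        occupied[lr, lc] <- occ
      }
      mask[occupied] <- 1L
    }

    if (config$noise_sigma > 0)
      img <- clamp(img + array(rnorm(length(img), 0, config$noise_sigma),
                               dim(img)))
    list(image = img, mask = mask, label = spec@pigment_label)
  })
}

#' Generate a complete synthetic dataset
#'
#' Creates accessions for the requested per-class counts, renders
#' \code{replicates_per_accession} replicate images each (re-randomized
#' grain placement per replicate), writes images and ground-truth masks as
#' PNG under \code{dir}, and writes + returns the manifest. The whole
#' dataset is a pure function of (arguments, seed).
#'
#' @param classCounts named integer vector with (a subset of) names
#'   \code{NP, A, M, AM}: accessions per pigment class.
#' @param config a \code{\link{renderConfig}}.
#' @param seed integer global seed.
#' @param dir output directory.
#' @param hulledFraction fraction of accessions per class flagged hulled
#'   (apportioned by largest remainder).
#' @param mode palette mode passed to \code{\link{makeAccession}}.
#' @return a \code{\linkS4class{GrainManifest}}; the same table is written
#'   to \code{dir/manifest.csv}.
#' @examples
#' \donttest{
#' m <- generateDataset(c(NP = 1), renderConfig(image_size = 96),
#'                      seed = 1, dir = tempfile())
#' nImages(m)
#' }
#' @export
generateDataset <- function(classCounts, config = renderConfig(), seed = 1,
                            dir = tempfile("grainset"),
                            hulledFraction = 0.73,
                            mode = c("default", "hard")) {
  mode <- match.arg(mode)
  classCounts <- classCounts[classCounts > 0]
  stopifnot(all(names(classCounts) %in% pigmentLevels()))
  if (length(classCounts) == 0 || sum(classCounts) == 0)
    stop("zero accessions requested")
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)

  recs <- list()
  for (lab in names(classCounts)) {
    nAcc <- as.integer(classCounts[[lab]])
    nHulled <- largestRemainder(nAcc, c(hulledFraction,
                                        1 - hulledFraction))[1]
    for (i in seq_len(nAcc)) {
      id <- sprintf("%s_%03d", lab, i)
      hulled <- i <= nHulled
      spec <- makeAccession(lab, hulled,
                            seed = stageSeed(seed, paste0("acc_", id)),
                            mode = mode, accession_id = id)
      imgDir <- file.path(dir, "images", id)
      mskDir <- file.path(dir, "masks", id)
      dir.create(imgDir, showWarnings = FALSE)
      dir.create(mskDir, showWarnings = FALSE)
      for (r in seq_len(config$replicates_per_accession)) {
        out <- renderReplicate(spec, config,
                               stageSeed(seed, sprintf("%s_rep%02d", id, r)))
        ip <- file.path(imgDir, sprintf("%02d.png", r))
        mp <- file.path(mskDir, sprintf("%02d.png", r))
        writeImageRGB(out$image, ip)
        writeMask(out$mask, mp)
        recs[[length(recs) + 1L]] <- data.frame(
          accession_id = id, pigment_label = lab, hulled = hulled,
          replicate = r, image_path = ip, mask_path = mp,
          split = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- GrainManifest(do.call(rbind, recs))
  saveManifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}
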