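#' Synthetic multi-view object sets
#'
#' Generates an ordered collection of grayscale images: `n_objects` distinct
#' base shapes, each rendered as `n_views` smooth parametric transforms
#' (in-plane rotation in fixed angular steps, plus mild per-view scale and
#' shear jitter). Views of one object are therefore strongly pixel-correlated
#' with each other and much less so with views of other objects, emulating a
#' multi-view object library (e.g. turntable photographs of household objects)
#' without shipping any image data.
#'
#' Base shapes are drawn from four shape families (star polygons, compound
#' ellipse blobs, wobbled annuli, and bar crosses), cycled across objects, with
#' per-object shape parameters and a per-object radial shading profile drawn
#' from the seeded generator. Because a rigid rotation leaves the radial mass
#' and shading profile of a centred shape unchanged, views of the same object
#' share their radial structure exactly, which is what gives the generated
#' sets their within-object correlation block structure.
#'
#' @param n_objects number of distinct objects (>= 1).
#' @param n_views number of views per object (>= 1).
#' @param size image side in pixels (square retina); must be >= 32.
#' @param seed integer seed; identical arguments and seed give bit-identical
#'   pixels.
#' @param view_step angular spacing of successive views, degrees. The default
#'   of 40 degrees gives 9 views spanning 320 degrees.
#' @param scale_jitter,shear_jitter half-width of the uniform per-view scale
#'   and shear perturbations (dimensionless).
#' @return A `stimulus_set`: list with `images` (list of `size` x `size`
#'   matrices in `[0,1]`, ordered object-major), `labels` (data.frame with
#'   zero-based `object_id` and `view_id`), `n_objects`, `n_views`, `size`.
#' @examples
#' s <- generate_synthetic_objects(2, 3, size = 64, seed = 1)
#' s$labels
#' @export
generate_synthetic_objects <- function(n_objects, n_views, size = 256L,
                                       seed = 1L, view_step = 40,
                                       scale_jitter = 0.03,
                                       shear_jitter = 0.05) {
  stopifnot(n_objects >= 1, n_views >= 1)
  if (size < 32)
    stop("'size' must be at least 32 pixels to render shapes")
  set.seed(as.integer(seed))

  objects <- lapply(seq_len(n_objects), function(o) {
    family <- ((o - 1L) %% 4L) + 1L
    # The radial shading profile and overall size are the rotation-invariant
    # signature of an object (pixel correlation across rotated views is
    # carried by the rotation-invariant image component). Spread them across
    # objects with low-discrepancy (golden-ratio) sequences so that any two
    # objects -- even among hundreds -- have distinct radial profiles.
    g1 <- (o * 0.6180339887) %% 1
    g2 <- (o * 0.7548776662) %% 1
    g3 <- (o * 0.5698402910) %% 1
    list(
      family   = family,
      r0       = size * (0.22 + 0.16 * g3),
      # star / annulus wobble (kept mild so rotated views overlap strongly)
      k        = sample(3:8, 1),
      amp      = stats::runif(1, 0.08, 0.2),
      phase    = stats::runif(1, 0, 2 * pi),
      # annulus inner radius fraction
      rin      = stats::runif(1, 0.30, 0.55),
      # compound blob: ellipse offsets and axes (fractions of r0)
      blobs    = {
        m <- sample(2:4, 1)
        cbind(dx = stats::runif(m, -0.35, 0.35),
              dy = stats::runif(m, -0.35, 0.35),
              ax = stats::runif(m, 0.45, 0.8),
              ay = stats::runif(m, 0.45, 0.8),
              th = stats::runif(m, 0, pi))
      },
      # cross arms
      arm_w    = stats::runif(2, 0.18, 0.32),
      arm_rot  = stats::runif(1, 0, pi / 2),
      # radial shading profile: frequency and phase spread across objects
      shade_f  = 1.5 + 3 * g1,
      shade_ph = 2 * pi * g2,
      base_val = stats::runif(1, 0.7, 0.95)
    )
  })
  # per-(object, view) jitters, drawn up-front so rendering order is irrelevant
  jit_scale <- matrix(stats::runif(n_objects * n_views, 1 - scale_jitter,
                                   1 + scale_jitter), n_objects, n_views)
  jit_shear <- matrix(stats::runif(n_objects * n_views, -shear_jitter,
                                   shear_jitter), n_objects, n_views)

  images <- vector("list", n_objects * n_views)
  labels <- data.frame(object_id = integer(0), view_id = integer(0))
  i <- 0L
  for (o in seq_len(n_objects)) {
    for (v in seq_len(n_views)) {
      i <- i + 1L
      ang <- (v - 1L) * view_step * pi / 180
      images[[i]] <- render_object_view(objects[[o]], size, ang,
                                        jit_scale[o, v], jit_shear[o, v])
      labels <- rbind(labels,
                      data.frame(object_id = o - 1L, view_id = v - 1L))
    }
  }
  new_stimulus_set(images, labels, n_objects, n_views, size)
}

new_stimulus_set <- function(images, labels, n_objects, n_views, size) {
  structure(list(images = images, labels = labels, n_objects = n_objects,
                 n_views = n_views, size = as.integer(size)),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set: %d objects x %d views, %dx%d px>\n",
              x$n_objects, x$n_views, x$size, x$size))
  invisible(x)
}

# Render one view of one parametric object. `ang` rotates the shape, then a
# mild scale/shear is applied; pixels are classified by the inverse transform.
render_object_view <- function(obj, size, ang, scl, shr) {
  ctr <- (size + 1) / 2
  xs <- matrix(rep(seq_len(size) - ctr, each = size), size, size)   # column = x
  ys <- matrix(rep(seq_len(size) - ctr, times = size), size, size)  # row = y
  # inverse view transform: unshear, unscale, unrotate
  u0 <- xs - shr * ys
  v0 <- ys
  u0 <- u0 / scl; v0 <- v0 / scl
  ca <- cos(-ang); sa <- sin(-ang)
  u <- ca * u0 - sa * v0
  v <- sa * u0 + ca * v0
  rho <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)

  inside <- switch(obj$family,
    { # 1: star polygon r(phi)
      rb <- obj$r0 * (1 + obj$amp * cos(obj$k * phi + obj$phase))
      rho <= rb
    },
    { # 2: union of ellipses
      acc <- matrix(FALSE, size, size)
      for (b in seq_len(nrow(obj$blobs))) {
        p <- obj$blobs[b, ]
        du <- u - p["dx"] * obj$r0
        dv <- v - p["dy"] * obj$r0
        ct <- cos(p["th"]); st <- sin(p["th"])
        eu <- ct * du + st * dv
        ev <- -st * du + ct * dv
        acc <- acc | ((eu / (p["ax"] * obj$r0))^2 +
                      (ev / (p["ay"] * obj$r0))^2 <= 1)
      }
      acc
    },
    { # 3: wobbled annulus
      rb <- obj$r0 * (1 + 0.6 * obj$amp * cos(obj$k * phi + obj$phase))
      (rho <= rb) & (rho >= obj$rin * rb)
    },
    { # 4: solid disc with protruding bar arms (disc dominates, so views
      # of the object still overlap strongly under rotation)
      ct <- cos(obj$arm_rot); st <- sin(obj$arm_rot)
      bu <- ct * u + st * v
      bv <- -st * u + ct * v
      (rho <= 0.85 * obj$r0) |
        (abs(bu) <= obj$arm_w[1] * obj$r0 & abs(bv) <= obj$r0) |
        (abs(bv) <= obj$arm_w[2] * obj$r0 & abs(bu) <= obj$r0)
    })

  # radial shading, rigid under rotation; foreground strictly positive
  shade <- obj$base_val *
    (0.55 + 0.45 * cos(2 * pi * obj$shade_f * rho / obj$r0 + obj$shade_ph))
  img <- matrix(0, size, size)
  img[inside] <- pmax(shade[inside], 0.05)
  img
}

#' Write a stimulus set to a directory as PNG images plus a manifest
#'
#' The manifest (`manifest.csv` with columns `object_id`, `view_id`,
#' `filename`) is the layout that [load_image_directory()] reads back by
#' default.
#'
#' @param set a `stimulus_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stimulus_set <- function(set, dir) {
  stopifnot(inherits(set, "stimulus_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- sprintf("obj%03d_view%02d.png",
                set$labels$object_id, set$labels$view_id)
  for (i in seq_along(set$images))
    png::writePNG(set$images[[i]], file.path(dir, fn[i]))
  manifest <- cbind(set$labels, filename = fn)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a multi-view image directory as a stimulus set
#'
#' Reads per-object view images, converts to grayscale luminance, resizes
#' preserving aspect ratio, centre-pads onto a black `size` x `size` canvas,
#' and rescales into `[0,1]`. Three directory layouts are supported:
#' \describe{
#'   \item{`manifest`}{a `manifest.csv` with columns `object_id`, `view_id`,
#'     `filename` (written by [write_stimulus_set()]).}
#'   \item{`flat`}{filenames matching `obj<k>_view<v>.<ext>`.}
#'   \item{`subdirs`}{one subdirectory per object containing its view images
#'     in lexicographic order (ALOI-style).}
#' }
#' PNG and JPEG are read with EBImage; plain PGM (P2/P5) is read directly.
#' An error naming the offending object is raised if objects do not all have
#' the same number of views.
#'
#' @param path directory to read.
#' @param size output image side in pixels.
#' @param layout naming convention, see Details.
#' @return a `stimulus_set`.
#' @export
load_image_directory <- function(path, size = 256L,
                                 layout = c("manifest", "flat", "subdirs")) {
  layout <- match.arg(layout)
  if (layout == "manifest" &&
      !file.exists(file.path(path, "manifest.csv")))
    layout <- "flat"
  if (layout == "manifest") {
    man <- utils::read.csv(file.path(path, "manifest.csv"))
    files <- file.path(path, man$filename)
    obj <- man$object_id; view <- man$view_id
  } else if (layout == "flat") {
    files <- list.files(path, pattern = "\\.(png|jpe?g|pgm)$",
                        ignore.case = TRUE)
    m <- regmatches(files, regexec("obj(\\d+)_view(\\d+)", files))
    ok <- lengths(m) == 3
    if (!any(ok)) stop("no files matching 'obj<k>_view<v>.<ext>' in ", path)
    files <- files[ok]; m <- m[ok]
    obj <- as.integer(vapply(m, `[`, "", 2))
    view <- as.integer(vapply(m, `[`, "", 3))
    files <- file.path(path, files)
  } else {
    dirs <- list.dirs(path, recursive = FALSE)
    if (!length(dirs)) stop("no object subdirectories in ", path)
    files <- character(0); obj <- integer(0); view <- integer(0)
    for (d in seq_along(dirs)) {
      fs <- sort(list.files(dirs[d], pattern = "\\.(png|jpe?g|pgm)$",
                            ignore.case = TRUE, full.names = TRUE))
      files <- c(files, fs)
      obj <- c(obj, rep(d - 1L, length(fs)))
      view <- c(view, seq_along(fs) - 1L)
    }
  }

  ord <- order(obj, view)
  files <- files[ord]; obj <- obj[ord]; view <- view[ord]
  counts <- table(obj)
  if (length(unique(counts)) != 1L) {
    bad <- names(counts)[counts != stats::median(counts)][1]
    stop("object ", bad, " has ", counts[[bad]],
         " views; all objects must have the same number of views")
  }
  # renumber objects densely from 0
  obj <- match(obj, sort(unique(obj))) - 1L
  images <- lapply(files, read_gray_image, size = size)
  new_stimulus_set(images,
                   data.frame(object_id = obj, view_id = view),
                   n_objects = length(counts),
                   n_views = unname(counts[1]), size = size)
}

# grayscale read + aspect-preserving resize + centre pad, values in [0,1]
read_gray_image <- function(file, size) {
  if (grepl("\\.pgm$", file, ignore.case = TRUE)) {
    g <- read_pgm(file)
  } else {
    img <- EBImage::readImage(file)
    d <- dim(img)
    a <- EBImage::imageData(img)
    if (length(d) == 3 && d[3] >= 3) {
      # Rec. 709 luminance
      g <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
    } else if (length(d) == 3) {
      g <- a[, , 1]
    } else g <- a
    g <- t(g)  # EBImage stores x,y; internal convention is row = y
  }
  g[g < 0] <- 0; g[g > 1] <- 1
  h <- nrow(g); w <- ncol(g)
  s <- size / max(h, w)
  nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
  if (nh != h || nw != w) {
    r <- EBImage::resize(EBImage::Image(t(g)), w = nw, h = nh)
    g <- t(EBImage::imageData(r))
    g[g < 0] <- 0; g[g > 1] <- 1
  }
  out <- matrix(0, size, size)
  r0 <- floor((size - nh) / 2); c0 <- floor((size - nw) / 2)
  out[r0 + seq_len(nh), c0 + seq_len(nw)] <- g
  out
}

# Plain PGM (P2 ascii / P5 binary) reader; no installed R package reads PGM.
read_pgm <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  toks <- integer(0)
  while (length(toks) < 3) {
    ln <- readLines(con, n = 1)
    ln <- sub("#.*", "", ln)
    toks <- c(toks, as.integer(strsplit(trimws(ln), "\\s+")[[1]]))
  }
  w <- toks[1]; h <- toks[2]; maxv <- toks[3]
  if (identical(magic, "P5")) {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else if (identical(magic, "P2")) {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else stop("unsupported PGM magic: ", magic)
  matrix(vals / maxv, nrow = h, ncol = w, byrow = TRUE)
}
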