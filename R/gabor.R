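#' Build a V1-like Gabor filter bank
#'
#' Constructs the filter bank that converts a grayscale retina into a
#' 32-channel input representation: `n_frequencies` spatial frequencies
#' (wavelength halving, i.e. frequency doubling, at each step) times four
#' orientations, with each signed filter response later split into rectified
#' positive (P) and negative (N) channels, emulating V1 simple cells of
#' opposite contrast polarity.
#'
#' Kernels are even-symmetric (cosine phase) Gabors with an elliptical
#' Gaussian envelope elongated along the preferred bar orientation
#' (`sigma = sigma_factor * wavelength`, aspect ratio `aspect`). Each kernel
#' is made exactly zero-sum by subtracting a scaled copy of its envelope, so
#' a uniform image produces zero response everywhere. Orientation 0 prefers
#' vertical gratings (luminance varying along x).
#'
#' Each channel is normalised by the peak response of its kernel to a
#' full-contrast grating of matched wavelength and orientation (pixel values
#' `0.5 + 0.5*cos`), computed once at bank construction, so filtering is
#' image-independent and responses land in `[0,1]`.
#'
#' @param base_wavelength wavelength in pixels of the lowest-frequency
#'   (largest) filter.
#' @param n_frequencies number of frequency bands (each doubling the last).
#' @param orientations preferred orientations in degrees.
#' @param size retina side in pixels (kernel FFTs are precomputed at this
#'   size).
#' @param sigma_factor Gaussian envelope sigma as a fraction of wavelength.
#' @param aspect envelope elongation along the bar axis.
#' @return a `gabor_bank` with 2 * `n_frequencies` * `length(orientations)`
#'   channels.
#' @export
gabor_bank <- function(base_wavelength = 32, n_frequencies = 4,
                       orientations = c(0, 45, 90, 135), size = 256L,
                       sigma_factor = 0.5, aspect = 1.5) {
  stopifnot(n_frequencies >= 1)
  wavelengths <- base_wavelength / 2^(seq_len(n_frequencies) - 1)
  if (min(wavelengths) < 2)
    stop("highest-frequency wavelength ", min(wavelengths),
         " px is below the 2 px sampling limit")

  kernels <- list(); meta <- NULL
  for (f in seq_len(n_frequencies)) {
    for (oi in seq_along(orientations)) {
      k <- gabor_kernel(wavelengths[f], orientations[oi],
                        sigma_factor, aspect)
      kernels[[length(kernels) + 1L]] <- k
      meta <- rbind(meta, data.frame(
        frequency = f - 1L, wavelength = wavelengths[f],
        orientation = orientations[oi],
        norm = grating_response(k, wavelengths[f], orientations[oi])))
    }
  }
  # FFT workspace: zero-padded linear convolution at a fixed retina size.
  # Kernels are packed in pairs (k1 + i*k2) so one inverse FFT yields two
  # real convolutions (Re and Im parts); pairs share a frequency band and
  # hence a kernel size.
  kmax <- max(vapply(kernels, nrow, 1L))
  pad <- next_fast_size(size + kmax - 1L)
  kfft <- lapply(seq_len(ceiling(length(kernels) / 2)), function(p) {
    k1 <- kernels[[2 * p - 1]]
    k2 <- if (2 * p <= length(kernels)) kernels[[2 * p]]
          else matrix(0, nrow(k1), ncol(k1))
    z <- matrix(0i, pad, pad)
    z[seq_len(nrow(k1)), seq_len(ncol(k1))] <-
      k1 + (0 + 1i) * k2
    stats::fft(z)
  })
  structure(list(kernels = kernels, meta = meta, size = as.integer(size),
                 pad = pad, kfft = kfft,
                 n_frequencies = n_frequencies,
                 orientations = orientations,
                 base_wavelength = base_wavelength,
                 n_channels = 2L * length(kernels)),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf(
    "<gabor_bank: %d frequencies x %d orientations x P/N = %d channels, %d px retina>\n",
    x$n_frequencies, length(x$orientations), x$n_channels, x$size))
  invisible(x)
}

# even-symmetric Gabor, exactly zero-sum (envelope-weighted DC correction)
gabor_kernel <- function(wavelength, orientation, sigma_factor, aspect) {
  sigma <- sigma_factor * wavelength
  hs <- max(3L, ceiling(2.5 * sigma))
  xs <- matrix(rep(-hs:hs, each = 2 * hs + 1), 2 * hs + 1)   # column = x
  ys <- matrix(rep(-hs:hs, times = 2 * hs + 1), 2 * hs + 1)  # row = y
  th <- orientation * pi / 180
  u <- xs * cos(th) + ys * sin(th)   # across the bars
  v <- -xs * sin(th) + ys * cos(th)  # along the bars
  env <- exp(-(u^2 + (v / aspect)^2) / (2 * sigma^2))
  k <- env * cos(2 * pi * u / wavelength)
  k - env * (sum(k) / sum(env))
}

# peak response of a kernel to a matched full-contrast grating in [0,1]
grating_response <- function(k, wavelength, orientation) {
  hs <- (nrow(k) - 1) / 2
  xs <- matrix(rep(-hs:hs, each = 2 * hs + 1), 2 * hs + 1)
  ys <- matrix(rep(-hs:hs, times = 2 * hs + 1), 2 * hs + 1)
  th <- orientation * pi / 180
  u <- xs * cos(th) + ys * sin(th)
  ph <- 2 * pi * u / wavelength
  # grating 0.5 + 0.5*cos(ph - phase): amplitude over phase of sum(k * grating)
  0.5 * sqrt(sum(k * cos(ph))^2 + sum(k * sin(ph))^2)
}

# smallest 5-smooth integer >= n (keeps stats::fft fast)
next_fast_size <- function(n) {
  repeat {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(as.integer(n))
    n <- n + 1
  }
}

#' Filter an image through a Gabor bank
#'
#' Convolves (zero-padded) the image with every kernel, splits each signed
#' response into rectified positive and negative channels, and rescales by
#' the bank's per-channel grating normalisation constants. Channel layout is
#' frequency-major: for frequency f and orientation o, the P channel is at
#' index `((f * n_orient) + o) * 2 + 1` and N at the following index
#' (1-based, f and o zero-based).
#'
#' @param image a `size` x `size` matrix in `[0,1]` (row = y, column = x),
#'   or a `stimulus_set` image.
#' @param bank a [gabor_bank()] built at the same size.
#' @param rectify if `FALSE`, return the signed normalised responses (half as
#'   many channels, no rectification or clipping) — mainly for diagnostics
#'   and testing linearity.
#' @return a `size` x `size` x `n_channels` array of responses in `[0,1]`
#'   (class `filtered_input`), or signed responses if `rectify = FALSE`.
#' @export
filter_image <- function(image, bank, rectify = TRUE) {
  stopifnot(inherits(bank, "gabor_bank"))
  if (!is.matrix(image) || nrow(image) != bank$size ||
      ncol(image) != bank$size)
    stop("image must be a ", bank$size, "x", bank$size,
         " matrix matching the bank's retina size")
  pad <- bank$pad
  z <- matrix(0, pad, pad)
  z[seq_len(bank$size), seq_len(bank$size)] <- image
  fimg <- stats::fft(z)

  nk <- length(bank$kernels)
  nc <- if (rectify) 2L * nk else nk
  out <- array(0, c(bank$size, bank$size, nc))
  for (p in seq_len(ceiling(nk / 2))) {
    conv <- stats::fft(fimg * bank$kfft[[p]], inverse = TRUE) / pad^2
    for (half in 1:2) {
      i <- 2L * p - 2L + half
      if (i > nk) next
      hs <- (nrow(bank$kernels[[i]]) - 1L) / 2L
      cr <- conv[hs + seq_len(bank$size), hs + seq_len(bank$size)]
      resp <- (if (half == 1) Re(cr) else Im(cr)) / bank$meta$norm[i]
      if (rectify) {
        out[, , 2L * i - 1L] <- pmin(pmax(resp, 0), 1)
        out[, , 2L * i] <- pmin(pmax(-resp, 0), 1)
      } else {
        out[, , i] <- resp
      }
    }
  }
  if (rectify) class(out) <- c("filtered_input", class(out))
  out
}

#' Filter every image of a stimulus set, with compact caching
#'
#' Precomputes the 32-channel input representation for every stimulus once
#' (inputs are static across training epochs). With `storage = "byte"`
#' responses are stored 8-bit quantised (resolution 1/255 on the `[0,1]` rate
#' scale), cutting memory ~8-fold for large sets; `"double"` keeps full
#' precision.
#'
#' @param set a `stimulus_set`.
#' @param bank a [gabor_bank()].
#' @param storage `"byte"` or `"double"`.
#' @param verbose print progress.
#' @return a `filtered_set`; elements are retrieved with [filtered_input_of()]
#'   as flat numeric vectors of length `size^2 * n_channels` (channel-major
#'   blocks of column-major `size` x `size` planes).
#' @export
filter_stimulus_set <- function(set, bank, storage = c("byte", "double"),
                                verbose = FALSE) {
  storage <- match.arg(storage)
  stopifnot(inherits(set, "stimulus_set"))
  n <- length(set$images)
  data <- vector("list", n)
  for (i in seq_len(n)) {
    fi <- as.numeric(filter_image(set$images[[i]], bank))
    data[[i]] <- if (storage == "byte")
      as.raw(round(fi * 255)) else fi
    if (verbose && i %% 25 == 0)
      message("filtered ", i, "/", n, " stimuli")
  }
  structure(list(data = data, storage = storage, labels = set$labels,
                 n_objects = set$n_objects, n_views = set$n_views,
                 size = set$size, n_channels = bank$n_channels),
            class = "filtered_set")
}

#' Retrieve one filtered stimulus as a numeric vector
#' @param fs a `filtered_set`.
#' @param i stimulus index (object-major order).
#' @return numeric vector of non-negative rates in `[0,1]`.
#' @export
filtered_input_of <- function(fs, i) {
  if (fs$storage == "byte") as.integer(fs$data[[i]]) / 255
  else fs$data[[i]]
}

#' @export
print.filtered_set <- function(x, ...) {
  cat(sprintf("<filtered_set: %d stimuli, %dx%dx%d, %s storage>\n",
              length(x$data), x$size, x$size, x$n_channels, x$storage))
  invisible(x)
}
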