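# Gabor kernel synthesis and feature extraction.
#
# Each filter is a Gaussian envelope times a *sine* carrier,
#   g(x, y) = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * sin(2 pi x' / lambda + psi)
# with x' = x cos(theta) + y sin(theta), y' = -x sin(theta) + y cos(theta),
# sampled on an m x m grid centred at the origin. The sine carrier (rather
# than the cosine most library Gabor routines default to) makes odd-size,
# psi = 0 kernels zero-sum and antisymmetric, so kernels are synthesized from
# the formula directly instead of delegating to a library routine.

# parameter domains searched by the optimizer: (m, sigma, theta, lambda, gamma, psi)
gabor_domain <- list(
  lower = c(m = 1,  sigma = 1, theta = 0,  lambda = 1,  gamma = 0, psi = 0),
  upper = c(m = 20, sigma = 5, theta = pi, lambda = 10, gamma = 1, psi = 2 * pi)
)

#' Gabor filter parameters
#'
#' Bundles and validates the six parameters of one filter: square window side
#' `m` (pixels, integer, 1-20), Gaussian envelope scale `sigma` (pixels,
#' 1-5), orientation `theta` (radians, 0-pi), carrier wavelength `lambda`
#' (pixels per cycle, 1-10), envelope aspect ratio `gamma` (0-1), and carrier
#' phase `psi` (radians, 0-2pi).
#'
#' @param m,sigma,theta,lambda,gamma,psi filter parameters (see above).
#' @return object of class `gabor_params`.
#' @export
gabor_params <- function(m, sigma, theta, lambda, gamma, psi) {
  m <- as.integer(m)
  vals <- c(m = m, sigma = sigma, theta = theta, lambda = lambda,
            gamma = gamma, psi = psi)
  if (any(!is.finite(vals))) stop("non-finite Gabor parameter")
  lo <- gabor_domain$lower; hi <- gabor_domain$upper
  bad <- names(vals)[vals < lo | vals > hi]
  if (length(bad)) {
    stop("Gabor parameter(s) out of domain: ", paste(bad, collapse = ", "))
  }
  structure(list(m = m, sigma = sigma, theta = theta, lambda = lambda,
                 gamma = gamma, psi = psi),
            class = "gabor_params")
}

#' Gabor filter bank
#'
#' An ordered set of filters; the feature vector follows this order.
#'
#' @param ... `gabor_params` objects, or a single list of them.
#' @return object of class `gabor_bank`.
#' @export
gabor_bank <- function(...) {
  filters <- list(...)
  if (length(filters) == 1L && !inherits(filters[[1L]], "gabor_params")) {
    filters <- filters[[1L]]
  }
  if (length(filters) < 1L) stop("a bank needs at least one filter")
  ok <- vapply(filters, inherits, logical(1), "gabor_params")
  if (!all(ok)) stop("all bank entries must be gabor_params objects")
  structure(list(filters = filters), class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat("Gabor filter bank:", length(x$filters), "filters\n")
  df <- as.data.frame(t(vapply(x$filters, function(p) {
    unlist(p)
  }, numeric(6))))
  print(format(df, digits = 5), row.names = TRUE)
  invisible(x)
}

# symmetric sample offsets: integers for odd m, half-integers for even m
kernel_offsets <- function(m) seq_len(m) - (m + 1) / 2

#' Synthesize a Gabor kernel
#'
#' Samples the filter formula on an `m x m` grid centred at the origin. The
#' first matrix index (rows) is the x coordinate, the second (columns) is y.
#'
#' @param p a `gabor_params` object.
#' @return object of class `gabor_kernel` with elements `weights` (`m x m`
#'   matrix) and `params`.
#' @export
gabor_kernel <- function(p) {
  stopifnot(inherits(p, "gabor_params"))
  d <- kernel_offsets(p$m)
  X <- matrix(d, p$m, p$m)                # x varies down rows
  Y <- matrix(d, p$m, p$m, byrow = TRUE)  # y varies across columns
  xp <- X * cos(p$theta) + Y * sin(p$theta)
  yp <- -X * sin(p$theta) + Y * cos(p$theta)
  w <- exp(-(xp^2 + p$gamma^2 * yp^2) / (2 * p$sigma^2)) *
    sin(2 * pi * xp / p$lambda + p$psi)
  structure(list(weights = w, params = p), class = "gabor_kernel")
}

#' Convolve an image with a Gabor kernel
#'
#' True 2-D convolution (kernel flipped relative to correlation) with
#' same-size output and replicate border padding, so a zero-sum kernel gives
#' an exactly-zero response on a constant image.
#'
#' @param img numeric matrix.
#' @param kernel a `gabor_kernel`, `gabor_params`, or plain weight matrix.
#' @return numeric matrix with the dimensions of `img`.
#' @export
gabor_convolve <- function(img, kernel) {
  stopifnot(is.matrix(img))
  if (inherits(kernel, "gabor_params")) kernel <- gabor_kernel(kernel)
  w <- if (inherits(kernel, "gabor_kernel")) kernel$weights else kernel
  stopifnot(is.matrix(w))
  conv2_replicate(img, w)
}

#' Mean and standard deviation of a response map
#'
#' The summary statistics that enter the feature vector: the mean over all
#' `M x N` response values and the population (divisor `MN`, not `MN - 1`)
#' standard deviation.
#'
#' @param r numeric matrix (filter response).
#' @return named numeric vector `c(mu, sigma)`.
#' @export
response_stats <- function(r) {
  stopifnot(is.matrix(r) || is.numeric(r), length(r) > 0)
  mu <- mean(r)
  c(mu = mu, sigma = sqrt(mean((r - mu)^2)))
}

#' Extract the Gabor feature vector of an image
#'
#' Convolves the image with every filter in the bank and concatenates the
#' response statistics as `[mu1, sigma1, ..., muNf, sigmaNf]` in bank order.
#'
#' @param img numeric matrix (cropped grayscale ROI).
#' @param bank a `gabor_bank`.
#' @return named numeric vector of length `2 * Nf`.
#' @export
extract_features <- function(img, bank) {
  stopifnot(is.matrix(img), inherits(bank, "gabor_bank"))
  nf <- length(bank$filters)
  out <- numeric(2L * nf)
  for (j in seq_len(nf)) {
    st <- response_stats(gabor_convolve(img, bank$filters[[j]]))
    out[2L * j - 1L] <- st[["mu"]]
    out[2L * j] <- st[["sigma"]]
  }
  names(out) <- paste0(rep(c("mu", "sigma"), nf), rep(seq_len(nf), each = 2L))
  out
}

#' Write / read a filter bank as JSON
#'
#' Serialization format: `{"filters": [{"m": ..., "sigma": ..., "theta": ...,
#' "lambda": ..., "gamma": ..., "psi": ...}, ...]}`. Loading revalidates all
#' parameter domains.
#'
#' @param bank a `gabor_bank`.
#' @param path file path.
#' @param metadata optional named list stored alongside the filters (e.g.
#'   run seed and final fitness).
#' @return `read_bank` returns a `gabor_bank` with any metadata attached as
#'   the `"metadata"` attribute; `write_bank` returns `path` invisibly.
#' @export
write_bank <- function(bank, path, metadata = NULL) {
  stopifnot(inherits(bank, "gabor_bank"))
  obj <- list(filters = lapply(bank$filters, function(p) {
    list(m = p$m, sigma = p$sigma, theta = p$theta, lambda = p$lambda,
         gamma = p$gamma, psi = p$psi)
  }))
  if (!is.null(metadata)) obj$metadata <- metadata
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$filters) || !length(obj$filters)) {
    stop("no filters found in ", path)
  }
  bank <- gabor_bank(lapply(obj$filters, function(f) {
    gabor_params(f$m, f$sigma, f$theta, f$lambda, f$gamma, f$psi)
  }))
  if (!is.null(obj$metadata)) attr(bank, "metadata") <- obj$metadata
  bank
}
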