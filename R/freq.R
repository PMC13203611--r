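# Frequency-domain decomposition of B-mode frames.
#
# Free fluid reads mostly from the low-frequency image content (overall
# echo-intensity distribution and region continuity), while boundary
# sharpness and parenchymal texture live in the high frequencies. This
# decomposition reproduces that visualisation: an ideal radial mask in
# the 2-D Fourier domain (or a Gaussian-blur approximation), with the
# high-pass part defined as the exact complement so that low + high
# reconstructs the input bit for bit.

#' Split an image into low- and high-frequency components
#'
#' @param image single-channel matrix.
#' @param cutoff low-pass cut-off as a fraction of the Nyquist frequency
#'   (radial ideal mask), default 0.1.
#' @param method `"fourier"` (ideal radial mask) or `"gaussian"`
#'   (blur-based approximation; `cutoff` maps to the blur bandwidth).
#' @return `list(low, high)` with `low + high == image` exactly.
#' @export
#' @examples
#' img <- matrix(runif(64 * 64), 64)
#' fd <- freq_decompose(img)
#' max(abs(fd$low + fd$high - img)) < 1e-9
freq_decompose <- function(image, cutoff = 0.1,
                           method = c("fourier", "gaussian")) {
  method <- match.arg(method)
  if (length(dim(image)) != 2L)
    stop("freq_decompose expects a single-channel image matrix")
  H <- nrow(image); W <- ncol(image)
  if (method == "fourier") {
    fy <- c(seq(0, floor(H / 2)), seq(-ceiling(H / 2) + 1, -1)) / (H / 2)
    fx <- c(seq(0, floor(W / 2)), seq(-ceiling(W / 2) + 1, -1)) / (W / 2)
    rad <- sqrt(outer(fy^2, fx^2, "+"))
    mask <- rad <= cutoff
    F <- stats::fft(image)
    low <- Re(stats::fft(F * mask, inverse = TRUE)) / (H * W)
  } else {
    low <- blur_mat(image, sigma = 1 / (pi * max(cutoff, 1e-3)))
  }
  list(low = low, high = image - low)
}

#' Split a feature map into high- and low-frequency channel groups
#'
#' The low-frequency group takes `round(alpha * C)` channels (ties up)
#' and is downsampled by 2 x 2 average pooling; the high-frequency group
#' keeps the remaining channels at full resolution. The two channel
#' counts always sum to `C`.
#'
#' @param x feature map array (H, W, C) with even H and W.
#' @param alpha_in fraction of channels routed to the low-frequency
#'   group, in \[0, 1\].
#' @return `list(high, low)`; either part is `NULL` when its channel
#'   count is zero.
#' @export
#' @examples
#' x <- array(rnorm(8 * 8 * 64), c(8, 8, 64))
#' sp <- split_channels(x, 0.5)
#' dim(sp$high)[3] + dim(sp$low)[3]  # 64
split_channels <- function(x, alpha_in) {
  if (!is.numeric(alpha_in) || alpha_in < 0 || alpha_in > 1)
    stop("alpha_in must lie in [0, 1]")
  d <- dim(x)
  if (length(d) != 3L) stop("expected an (H, W, C) array")
  C <- d[3]
  cl <- low_channels(C, alpha_in)
  ch <- C - cl
  if ((cl == 0L || ch == 0L) && alpha_in > 0 && alpha_in < 1)
    stop("channel count too small for the requested split: C = ", C)
  pool2 <- function(a) {
    H <- dim(a)[1]; W <- dim(a)[2]
    0.25 * (a[seq(1, H, 2), seq(1, W, 2), , drop = FALSE] +
            a[seq(2, H, 2), seq(1, W, 2), , drop = FALSE] +
            a[seq(1, H, 2), seq(2, W, 2), , drop = FALSE] +
            a[seq(2, H, 2), seq(2, W, 2), , drop = FALSE])
  }
  list(high = if (ch > 0L) x[, , seq_len(ch), drop = FALSE],
       low = if (cl > 0L) pool2(x[, , ch + seq_len(cl), drop = FALSE]))
}
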