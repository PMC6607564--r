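# Empirical mode decomposition by envelope sifting: cubic-spline envelopes
# through local maxima/minima (with mirror extension at the ends), Cauchy-type
# stopping, decomposition until the residual is monotone.

find_extrema <- function(x) {
  d <- diff(x)
  # collapse plateaus so strict sign changes are detectable
  s <- sign(d)
  nz <- which(s != 0)
  maxima <- integer(0); minima <- integer(0)
  if (length(nz) >= 2) {
    ch <- which(s[nz][-1] != s[nz][-length(nz)])
    idx <- nz[ch] + 1L
    up <- s[nz][ch] > 0
    maxima <- idx[up]
    minima <- idx[!up]
  }
  list(maxima = maxima, minima = minima)
}

# spline envelope through (idx, x[idx]) with 2-point mirror extension
spline_envelope <- function(x, idx) {
  n <- length(x)
  k <- min(2L, length(idx))
  left_p <- 2 - rev(idx[seq_len(k)])
  right_p <- 2 * n - rev(rev(idx)[seq_len(k)])
  px <- c(left_p, idx, right_p)
  py <- c(x[rev(idx[seq_len(k)])], x[idx], x[rev(rev(idx)[seq_len(k)])])
  keep <- !duplicated(px)
  stats::spline(px[keep], py[keep], xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by standard
#' sifting: at each step the mean of the cubic-spline envelopes through the
#' local maxima and minima is subtracted until the Cauchy criterion
#' `sum((h_prev - h)^2) / sum(h_prev^2) < stop_threshold` is met. Extraction
#' stops when the residual has fewer than two maxima or two minima (i.e. is
#' monotone) or `max_imfs` is reached. The IMFs plus residual reconstruct
#' the input exactly.
#'
#' @param x numeric signal
#' @param max_imfs maximum number of IMFs to extract
#' @param stop_threshold Cauchy stopping threshold for sifting
#' @param max_siftings cap on sifting iterations per IMF
#' @return object of class `imf_set`: `imfs` (matrix, one IMF per row;
#'   zero rows if the input has too few extrema), `residual`, and
#'   `diagnostics` (per-IMF sifting iterations and final stop metric)
#' @export
emd <- function(x, max_imfs = 12, stop_threshold = 0.05, max_siftings = 60) {
  n <- length(x)
  imfs <- list()
  diag <- list()
  res <- x
  while (length(imfs) < max_imfs) {
    ex <- find_extrema(res)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) break
    h <- res
    iters <- 0L
    sd_metric <- Inf
    repeat {
      ex_h <- find_extrema(h)
      if (length(ex_h$maxima) < 2 || length(ex_h$minima) < 2) break
      upper <- spline_envelope(h, ex_h$maxima)
      lower <- spline_envelope(h, ex_h$minima)
      h_new <- h - (upper + lower) / 2
      sd_metric <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      iters <- iters + 1L
      if (sd_metric < stop_threshold || iters >= max_siftings) break
    }
    imfs[[length(imfs) + 1L]] <- h
    diag[[length(diag) + 1L]] <- list(siftings = iters, stop_metric = sd_metric)
    res <- res - h
  }
  structure(
    list(
      imfs = if (length(imfs)) do.call(rbind, imfs) else matrix(0, 0, n),
      residual = res,
      diagnostics = diag
    ),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs of length %d + residual\n",
              nrow(x$imfs), length(x$residual)))
  invisible(x)
}
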