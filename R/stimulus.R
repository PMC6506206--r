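#' Generate a blocked white-noise checkerboard stimulus
#'
#' Builds the spatiotemporal white-noise stimulus used to drive model LGN
#' cells: square frames of `n_px` x `n_px` pixels, each pixel drawn
#' independently from four contrast levels spanning black to white, presented
#' in blocks of `block_frames` frames separated by uniform-gray gaps. With the
#' defaults (18 blocks of 250 frames at 16 ms, 1 s gray between blocks) the
#' stimulus lasts 89 s.
#'
#' @param n_blocks Number of white-noise blocks (>= 1).
#' @param frame_ms Frame duration in ms.
#' @param n_px Pixels per side of the square frame.
#' @param levels Contrast levels in `[-1, 1]`; exactly four unless
#'   `strict_levels = FALSE`.
#' @param block_frames Frames per block.
#' @param gray_gap_s Zero-contrast gap between blocks, seconds.
#' @param strict_levels Enforce the four-level design.
#' @param seed Optional integer seed; a fixed seed reproduces the frame array
#'   exactly.
#'
#' @return An object of class `wn_stimulus`: a list with `frames` (array
#'   `n_frames x n_px x n_px`), `frame_onset_s`, `frame_ms`, `levels`,
#'   `block_frames`, `gray_gap_s`, `n_blocks` and `duration_s`.
#' @export
#' @examples
#' stim <- wn_stimulus(n_blocks = 2, seed = 1)
#' stim$duration_s
wn_stimulus <- function(n_blocks = 18, frame_ms = 16, n_px = 16,
                        levels = c(-1, -1 / 3, 1 / 3, 1),
                        block_frames = 250, gray_gap_s = 1,
                        strict_levels = TRUE, seed = NULL) {
  if (n_blocks < 1) abort("`n_blocks` must be >= 1.")
  if (frame_ms <= 0) abort("`frame_ms` must be positive.")
  if (strict_levels && length(levels) != 4L) {
    abort("`levels` must contain exactly 4 contrast values (set `strict_levels = FALSE` to override).")
  }
  if (any(abs(levels) > 1)) abort("contrast `levels` must lie in [-1, 1].")
  seed_if(seed)
  n_frames <- n_blocks * block_frames
  frames <- array(
    sample(levels, n_frames * n_px * n_px, replace = TRUE),
    dim = c(n_frames, n_px, n_px)
  )
  block_dur <- block_frames * frame_ms / 1000
  block_start <- (seq_len(n_blocks) - 1) * (block_dur + gray_gap_s)
  frame_onset_s <- rep(block_start, each = block_frames) +
    rep((seq_len(block_frames) - 1) * frame_ms / 1000, times = n_blocks)
  structure(
    list(
      frames = frames, frame_onset_s = frame_onset_s, frame_ms = frame_ms,
      n_px = n_px, levels = sort(levels), block_frames = block_frames,
      gray_gap_s = gray_gap_s, n_blocks = n_blocks,
      duration_s = n_blocks * block_dur + (n_blocks - 1) * gray_gap_s
    ),
    class = "wn_stimulus"
  )
}

#' @export
print.wn_stimulus <- function(x, ...) {
  cat(sprintf(
    "<wn_stimulus> %d frames (%d blocks x %d), %g ms/frame, %dx%d px, %.3g s total\n",
    dim(x$frames)[1], x$n_blocks, x$block_frames, x$frame_ms, x$n_px, x$n_px,
    x$duration_s
  ))
  invisible(x)
}

#' @export
tidy.wn_stimulus <- function(x, ...) {
  n <- dim(x$frames)[1]
  tibble::tibble(
    frame = seq_len(n),
    onset_s = x$frame_onset_s,
    mean_contrast = apply(x$frames, 1, mean)
  )
}

# index of the frame on screen at time t (seconds); NA during gray gaps
frame_index_at <- function(stim, t) {
  i <- findInterval(t, stim$frame_onset_s)
  on <- i >= 1 & t < (stim$frame_onset_s[pmax(i, 1)] + stim$frame_ms / 1000)
  i[!on] <- NA_integer_
  i
}
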