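#' Build the period-normalized cycle matrix
#'
#' Each interior beat (first and last detections dropped as potentially
#' truncated) is cut as `[R - 0.3 RRAvg, R + 0.7 RRAvg]` -- a 30/70 split
#' that keeps the full T wave inside the cycle at neonatal heart rates --
#' and linearly resampled to `M` samples. Columns of the result are the
#' resampled cycles, on the physical (de-normalized) amplitude scale.
#'
#' @param segment an [ecg_segment].
#' @param ann a `qrs_annotation` for the segment.
#' @param M resampled cycle length (samples).
#' @return object of class `cycle_matrix`: list with `X` (M x N matrix),
#'   `r_index` (source R sample per column), `M`, `rravg` (s), `fs`.
#' @export
build_cycle_matrix <- function(segment, ann, M = 256) {
  stopifnot(inherits(ann, "qrs_annotation"))
  x <- if (inherits(segment, "ecg_segment")) physical_samples(segment) else as.numeric(segment)
  fs <- ann$fs
  r <- ann$beats$r
  if (length(r) < 4)
    ecgph_stop("need at least 4 beats to form cycles", "ecgph_insufficient_cycles")
  r <- r[-c(1, length(r))]
  rravg <- ann$rravg
  n <- length(x)
  phase <- (seq_len(M) - 1) / M  # [0, 1) of one RRAvg
  off <- (phase - 0.3) * rravg * fs
  keep <- r + off[1] >= 1 & r + off[M] <= n
  r <- r[keep]
  if (length(r) < 3)
    ecgph_stop("fewer than 3 usable cycles", "ecgph_insufficient_cycles")
  # linear interpolation of all cycles at once
  xo <- outer(off, r, "+")          # M x N sample positions
  i0 <- pmin.int(floor(xo), n - 1)
  frac <- xo - i0
  X <- x[i0] * (1 - frac) + x[i0 + 1L] * frac
  dim(X) <- dim(xo)
  structure(list(X = X, r_index = r, M = M, rravg = rravg, fs = fs),
            class = "cycle_matrix")
}

#' Extract the representative cycle by PCA
#'
#' Cycles (columns) are treated as repeated observations of one underlying
#' beat. The representative is the mean cycle plus the rank-1 reconstruction
#' along the leading eigenvector of the across-cycle covariance, averaged
#' over cycles; the eigenvector sign is fixed by positive correlation with
#' the mean cycle. The fraction of variance carried by the retained
#' component is reported. A degenerate matrix whose columns are all equal
#' returns that column with variance fraction 1.
#'
#' The production path uses the singular value decomposition of the centred
#' matrix (numerically equivalent to the eigen-decomposition of the
#' covariance, and cheaper when cycles are few).
#'
#' @param cmat a [build_cycle_matrix()] result.
#' @return object of class `representative_cycle`: list with `waveform`
#'   (M samples), `variance_fraction`, `n_cycles`, `M`, `rravg`.
#' @export
extract_representative <- function(cmat) {
  stopifnot(inherits(cmat, "cycle_matrix"))
  X <- cmat$X
  M <- nrow(X); N <- ncol(X)
  m <- rowMeans(X)
  Xc <- X - m
  total_var <- sum(Xc^2) / (N - 1)
  out <- function(wave, vf)
    structure(list(waveform = wave, variance_fraction = vf, n_cycles = N,
                   M = M, rravg = cmat$rravg),
              class = "representative_cycle")
  if (total_var < 1e-24 * max(1, sum(m^2))) return(out(X[, 1], 1))
  sv <- svd(Xc, nu = 1, nv = 1)
  u <- sv$u[, 1]
  if (sum(u * m) < 0) u <- -u
  scores <- as.numeric(crossprod(Xc, u))
  wave <- m + u * mean(scores)
  out(wave, sv$d[1]^2 / sum(sv$d^2))
}

#' @export
print.representative_cycle <- function(x, ...) {
  cat(sprintf("<representative_cycle: M = %d from %d cycles, leading component %.1f%% of variance, RRAvg %.3f s>\n",
              x$M, x$n_cycles, 100 * x$variance_fraction, x$rravg))
  invisible(x)
}

#' Export a representative cycle
#'
#' Writes the waveform as CSV (`phase,amplitude`) and, alongside it, a JSON
#' sidecar with the extraction metadata.
#'
#' @param cycle a `representative_cycle`.
#' @param path CSV output path; metadata goes to `<path>.json`.
#' @export
write_cycle <- function(cycle, path) {
  df <- data.frame(phase = (seq_len(cycle$M) - 1) / cycle$M,
                   amplitude = cycle$waveform)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(variance_fraction = cycle$variance_fraction,
                            n_cycles = cycle$n_cycles, M = cycle$M,
                            rravg = cycle$rravg),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# phase <-> seconds helpers: phase i covers t_rel = ((i-1)/M - 0.3) * rravg
cycle_time <- function(cycle) ((seq_len(cycle$M) - 1) / cycle$M - 0.3) * cycle$rravg
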