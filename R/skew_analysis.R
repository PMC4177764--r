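#' Windowed and cumulative GC skew
#'
#' Per-window skew is (G - C)/(G + C) over sliding windows (wrapping the
#' junction on circular genomes); windows with no G or C get skew 0. The
#' cumulative profile is the per-base running sum of +1 for G, -1 for C and 0
#' otherwise, computed independently of the windowing so extremum positions
#' are resolution-independent.
#'
#' @param seq Nucleotide string, or a `GenomeRecord`.
#' @param window Window size in nt.
#' @param step Step between window starts in nt.
#' @param circular Wrap windows around the junction (taken from the record's
#'   topology when `seq` is a `GenomeRecord`).
#' On circular genomes the extremum positions (`min_pos`, `max_pos`) are
#' taken from the detrended cumulative curve (the running sum minus its
#' linear drift), because when the genome-wide G and C totals differ the
#' plain cumulative extrema depend on the arbitrary coordinate start; after
#' detrending they are equivariant under genome rotation. The plain
#' cumulative profile is reported unchanged for plotting.
#'
#' @return list of class `SkewProfile`: `positions` (window centres), `skew`,
#'   `cumulative` (length = genome length), `detrended`, `min_pos`,
#'   `max_pos`, `window`, `step`, `circular`.
#' @export
gc_skew <- function(seq, window = 1000L, step = 500L, circular = TRUE) {
  if (inherits(seq, "GenomeRecord")) {
    circular <- seq$topology == "circular"
    seq <- seq$sequence
  }
  if (window <= 0L || step <= 0L) stop("window and step must be positive")
  L <- nchar(seq)
  if (window > L) stop("window larger than sequence")
  base <- strsplit(toupper(seq), "")[[1]]
  inc <- ifelse(base == "G", 1L, ifelse(base == "C", -1L, 0L))
  cumulative <- cumsum(inc)

  isG <- as.integer(base == "G")
  isC <- as.integer(base == "C")
  if (circular) { isG2 <- c(isG, isG); isC2 <- c(isC, isC) } else { isG2 <- isG; isC2 <- isC }
  cg <- c(0L, cumsum(isG2)); cc <- c(0L, cumsum(isC2))
  win_starts <- seq(1L, if (circular) L else L - window + 1L, by = step)
  g <- cg[win_starts + window] - cg[win_starts]
  c_ <- cc[win_starts + window] - cc[win_starts]
  skew <- ifelse(g + c_ == 0, 0, (g - c_) / (g + c_))
  centres <- ((win_starts + (window - 1L) %/% 2L - 1L) %% L) + 1L

  extremum_curve <- if (circular) {
    cumulative - seq_len(L) * cumulative[L] / L
  } else {
    cumulative
  }
  structure(list(
    positions = centres, skew = skew, cumulative = cumulative,
    detrended = extremum_curve,
    min_pos = which.min(extremum_curve), max_pos = which.max(extremum_curve),
    window = window, step = step, circular = circular
  ), class = "SkewProfile")
}

#' Predict replication origin and terminus from cumulative GC skew
#'
#' On two-replichore genomes the leading strands are G-rich, so the
#' cumulative skew decreases along the arc replicated leftward of the origin
#' and increases toward the terminus: the global minimum marks the origin and
#' the global maximum the terminus (the GenSkew convention). The assignment
#' can be flipped since some genomes are annotated the other way around.
#' Ties are broken by the smallest position.
#'
#' @param profile A `SkewProfile` from [gc_skew()] on a circular genome.
#' @param origin_at `"min"` (default) or `"max"`.
#' @return list with `origin`, `terminus` (1-based nt positions, NA when
#'   there is no signal) and `status` (`"ok"` or `"no_signal"`).
#' @export
predict_ori_ter <- function(profile, origin_at = c("min", "max")) {
  origin_at <- match.arg(origin_at)
  curve <- profile$detrended %||% profile$cumulative
  if (isTRUE(all.equal(max(curve), min(curve)))) {
    return(list(origin = NA_integer_, terminus = NA_integer_, status = "no_signal"))
  }
  mn <- profile$min_pos  # first occurrence = smallest position
  mx <- profile$max_pos
  if (origin_at == "min") list(origin = mn, terminus = mx, status = "ok")
  else list(origin = mx, terminus = mn, status = "ok")
}
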