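#' Read a genetic map in the standard text dialects
#'
#' Accepts the common three-column dialect (position bp, rate cM/Mb,
#' cumulative cM) and the four-column dialect with a leading chromosome
#' column; a header line is detected and skipped automatically. Positions
#' must be strictly increasing and all entries non-negative.
#'
#' @param path path to the map file.
#' @return A \code{RecombMap}.
#' @export
readRecombMap <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("format error: empty genetic map file")
  fields <- strsplit(trimws(lines), "[ \t,]+")
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L || !ncols %in% c(3L, 4L))
    stop("format error: genetic map must have 3 or 4 columns throughout")
  first <- suppressWarnings(as.numeric(fields[[1]]))
  start <- if (anyNA(first[(ncols - 2L):ncols])) 2L else 1L
  if (start > length(fields)) stop("format error: no data rows in genetic map")
  mat <- do.call(rbind, lapply(fields[start:length(fields)], function(f) {
    v <- suppressWarnings(as.numeric(f[(ncols - 2L):ncols]))
    if (anyNA(v)) stop("format error: non-numeric entry in genetic map")
    v
  }))
  pos <- mat[, 1]; rate <- mat[, 2]; cm <- mat[, 3]
  if (any(diff(pos) <= 0)) stop("format error: map positions must be strictly increasing")
  if (any(rate < 0) || any(cm < 0) || any(pos < 0))
    stop("format error: negative entries in genetic map")
  if (any(diff(cm) < 0)) stop("format error: cumulative cM must be non-decreasing")
  new("RecombMap", pos = pos, rateCMMb = rate, cm = cm)
}

#' Uniform-rate recombination map
#'
#' @param ratePerBp per-bp per-generation recombination rate (1e-8
#'   corresponds to 1 cM/Mb).
#' @param length sequence length in bp.
#' @return A two-knot \code{RecombMap} spanning [0, length].
#' @export
uniformRecombMap <- function(ratePerBp, length) {
  stopifnot(ratePerBp >= 0, length > 0)
  new("RecombMap",
      pos = c(0, length),
      rateCMMb = c(ratePerBp * 1e8, ratePerBp * 1e8),
      cm = c(0, length * ratePerBp * 100))
}

#' Bundled desk-scale variable-rate map
#'
#' A deterministic variable-rate map used as the desk-scale default: knots
#' every 500 kb with rates cycling through a fixed pattern between 0.4 and
#' 2.8 cM/Mb (mean ~1.24 cM/Mb, comparable to the chromosome-1 average),
#' emulating the hot/cold rate structure of a real genetic map without
#' shipping one.
#'
#' @param length sequence length in bp.
#' @return A \code{RecombMap} spanning [0, length].
#' @export
deskRecombMap <- function(length = 1e7) {
  stopifnot(length > 0)
  pattern <- c(0.8, 1.6, 0.4, 2.8, 1.0, 0.6, 2.2, 1.2, 0.5, 1.3)
  knot <- 5e5
  nInt <- max(1L, ceiling(length / knot))
  rates <- rep_len(pattern, nInt)
  pos <- c(0, pmin(seq_len(nInt) * knot, length))
  pos <- unique(pos)
  rates <- rates[seq_len(length(pos) - 1L)]
  cm <- c(0, cumsum(diff(pos) / 1e6 * rates))
  new("RecombMap", pos = pos, rateCMMb = c(rates, rates[length(rates)]), cm = cm)
}

#' Genetic position (cM) of physical positions
#'
#' Linear interpolation between map knots; positions beyond the last knot
#' extrapolate at the final rate, positions before the first knot at the
#' first rate.
#'
#' @param map a \code{RecombMap}.
#' @param posBp physical positions in bp.
#' @return Genetic positions in cM.
#' @export
mapCM <- function(map, posBp) {
  validObject(map)
  p <- map@pos; cm <- map@cm
  out <- numeric(length(posBp))
  if (length(p) == 1L) {
    out <- cm[1] + (posBp - p[1]) / 1e6 * map@rateCMMb[1]
    return(out)
  }
  inside <- posBp >= p[1] & posBp <= p[length(p)]
  if (any(inside))
    out[inside] <- stats::approx(p, cm, xout = posBp[inside], ties = "ordered")$y
  lo <- posBp < p[1]
  if (any(lo)) out[lo] <- cm[1] - (p[1] - posBp[lo]) / 1e6 * map@rateCMMb[1]
  hi <- posBp > p[length(p)]
  if (any(hi))
    out[hi] <- cm[length(cm)] +
      (posBp[hi] - p[length(p)]) / 1e6 * map@rateCMMb[length(map@rateCMMb)]
  out
}

# Per-interval per-bp rates covering [0, L], derived from the cumulative cM
# column so that simulation rates and cM interpolation are consistent.
mapToIntervals <- function(map, L) {
  p <- map@pos; cm <- map@cm
  r <- if (length(p) > 1L) diff(cm) / 100 / diff(p) else numeric(0)
  firstRate <- map@rateCMMb[1] * 1e-8
  lastRate <- map@rateCMMb[length(map@rateCMMb)] * 1e-8
  pos <- p; rates <- r
  if (pos[1] > 0) { pos <- c(0, pos); rates <- c(firstRate, rates) }
  if (pos[length(pos)] < L) { pos <- c(pos, L); rates <- c(rates, lastRate) }
  idx <- which(pos < L)
  pos <- c(pos[idx], L)
  rates <- rates[seq_len(length(pos) - 1L)]
  list(positions = pos, rates = rates)
}

#' Write a genetic map in the three-column dialect
#'
#' @param map a \code{RecombMap}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRecombMap <- function(map, path) {
  validObject(map)
  df <- data.frame(position = map@pos, rate_cM_Mb = map@rateCMMb, map_cM = map@cm)
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
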