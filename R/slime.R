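#' Slime lattice field
#'
#' The slime laid down by cells lives on a square lattice with constant
#' `spacing`; site `(r, c)` sits at coordinates `(x = c * spacing,
#' y = r * spacing)`. The field stores a dense rectangular window of sites;
#' any site outside the stored window reads as 0 (virgin substrate), and the
#' window grows as cells travel. Slime never decays and never diffuses, so
#' every site is monotone non-decreasing over a run, bounded by `S_max`.
#'
#' @param values Numeric matrix of slime amounts; row `i`, column `j` holds
#'   site `(r_min + i - 1, c_min + j - 1)`.
#' @param r_min,c_min Lattice indices of the first row/column of `values`.
#' @param spacing Lattice constant.
#' @param S_max Per-site cap.
#' @return An object of class `slime_field`.
#' @export
slime_field <- function(values, r_min = 0L, c_min = 0L, spacing = 1,
                        S_max = 1000) {
  values <- as.matrix(values)
  if (any(values < 0)) abort("slime amounts must be non-negative")
  if (any(values > S_max)) abort("slime amounts must not exceed `S_max`")
  structure(list(values = values, r_min = as.integer(r_min),
                 c_min = as.integer(c_min), spacing = spacing, S_max = S_max),
            class = "slime_field")
}

#' @export
print.slime_field <- function(x, ...) {
  cat(sprintf("<slime_field> %d x %d sites, spacing %g, total slime %g\n",
              nrow(x$values), ncol(x$values), x$spacing, sum(x$values)))
  invisible(x)
}

#' Read slime under given coordinates
#'
#' Returns the slime amount at the lattice site nearest each `(x, y)`;
#' untouched sites read as 0.
#'
#' @param slime A [slime_field()].
#' @param x,y Coordinates (vectorized).
#' @return Numeric vector of slime amounts.
#' @export
slime_at <- function(slime, x, y) {
  r <- round(y / slime$spacing)
  c <- round(x / slime$spacing)
  i <- r - slime$r_min + 1
  j <- c - slime$c_min + 1
  ok <- i >= 1 & j >= 1 & i <= nrow(slime$values) & j <= ncol(slime$values)
  out <- numeric(length(i))
  out[ok] <- slime$values[cbind(i[ok], j[ok])]
  out
}

#' @rdname slime_at
#' @export
slime_total <- function(slime) sum(slime$values)

# grow the stored window (zero padding) to cover lattice rows/cols ranges
grow_slime_field <- function(slime, r_range, c_range) {
  r0 <- min(slime$r_min, r_range[1])
  r1 <- max(slime$r_min + nrow(slime$values) - 1L, r_range[2])
  c0 <- min(slime$c_min, c_range[1])
  c1 <- max(slime$c_min + ncol(slime$values) - 1L, c_range[2])
  if (r0 == slime$r_min && c0 == slime$c_min &&
      r1 == slime$r_min + nrow(slime$values) - 1L &&
      c1 == slime$c_min + ncol(slime$values) - 1L) return(slime)
  nv <- matrix(0, nrow = r1 - r0 + 1L, ncol = c1 - c0 + 1L)
  ir <- (slime$r_min - r0 + 1L):(slime$r_min - r0 + nrow(slime$values))
  ic <- (slime$c_min - c0 + 1L):(slime$c_min - c0 + ncol(slime$values))
  nv[ir, ic] <- slime$values
  slime$values <- nv
  slime$r_min <- as.integer(r0)
  slime$c_min <- as.integer(c0)
  slime
}

#' Lay a pre-existing slime band
#'
#' Raises every lattice site inside a vertical strip `x` in `[xlim[1],
#' xlim[2]]` to at least `level` (existing higher values are kept). Used to
#' reproduce the band-crossing experiment in which advancing fingers meet a
#' strip of saturated slime laid normal to their direction of growth. Because
#' the lattice is materialized lazily, the strip is filled over a finite `y`
#' extent: by default the row range already stored in the field, which covers
#' the colony and everywhere cells have been.
#'
#' @param slime A [slime_field()].
#' @param xlim Length-2 numeric, the x-interval of the band.
#' @param level Slime amount, at most `S_max`.
#' @param ylim Optional length-2 numeric restricting/extending the filled rows.
#' @return The updated `slime_field`.
#' @export
make_slime_band <- function(slime, xlim, level, ylim = NULL) {
  if (level < 0) abort("band `level` must be non-negative")
  if (level > slime$S_max) abort("band `level` must not exceed `S_max`")
  if (length(xlim) != 2 || xlim[1] > xlim[2]) abort("`xlim` must be an ordered interval")
  if (level == 0) return(slime)
  cr <- c(ceiling(xlim[1] / slime$spacing), floor(xlim[2] / slime$spacing))
  if (cr[1] > cr[2]) return(slime)   # no site centre falls in the strip
  if (is.null(ylim)) {
    rr <- c(slime$r_min, slime$r_min + nrow(slime$values) - 1L)
  } else {
    rr <- c(ceiling(ylim[1] / slime$spacing), floor(ylim[2] / slime$spacing))
  }
  slime <- grow_slime_field(slime, rr, cr)
  i <- (rr[1]:rr[2]) - slime$r_min + 1L
  j <- (cr[1]:cr[2]) - slime$c_min + 1L
  slime$values[i, j] <- pmax(slime$values[i, j], level)
  slime
}

#' @export
tidy.slime_field <- function(x, drop_zero = TRUE, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  out <- tibble(
    r = rep(x$r_min + seq_len(nr) - 1L, times = nc),
    c = rep(x$c_min + seq_len(nc) - 1L, each = nr),
    value = as.vector(x$values))
  out$x <- out$c * x$spacing
  out$y <- out$r * x$spacing
  if (drop_zero) out <- out[out$value > 0, , drop = FALSE]
  out[, c("r", "c", "x", "y", "value")]
}
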