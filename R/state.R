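#' Per-cell state
#'
#' Positions are an `n x 2` matrix of cell-centre coordinates, headings are
#' angles in `[0, 2*pi)`, and `freeloader` flags the cells that cannot sense
#' the light (they still move, tug, and secrete slime).
#'
#' @param positions `n x 2` numeric matrix.
#' @param headings Numeric vector of length `n` (wrapped into `[0, 2*pi)`).
#' @param freeloader Logical vector of length `n`; default all sighted.
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(positions, headings = NULL, freeloader = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2) abort("`positions` must have two columns (x, y)")
  if (!all(is.finite(positions))) abort("`positions` must be finite")
  n <- nrow(positions)
  if (is.null(headings)) headings <- numeric(n)
  if (is.null(freeloader)) freeloader <- logical(n)
  if (length(headings) != n || length(freeloader) != n)
    abort("`headings` and `freeloader` must have one entry per cell")
  structure(list(positions = unname(positions),
                 headings = as.numeric(headings) %% (2 * pi),
                 freeloader = as.logical(freeloader)),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state> %d cells (%d freeloaders)\n",
              nrow(x$positions), sum(x$freeloader)))
  invisible(x)
}

#' @export
tidy.cell_state <- function(x, ...) {
  tibble(cell_id = seq_len(nrow(x$positions)),
         x = x$positions[, 1], y = x$positions[, 2],
         heading = x$headings, freeloader = x$freeloader)
}
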