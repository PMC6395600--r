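#' Regular analysis grid of square cells
#'
#' Builds the lattice of square cells on which all analysis operates. Cells are
#' indexed 0-based by `(row, col)` with row 0 the northernmost row; centroids
#' sit at `(col + 0.5, row + 0.5) * cell_size_km` in planar km (the `y_km`
#' coordinate therefore increases southwards from the northern grid edge).
#' An optional mask restricts the grid to an irregular study region; masked-out
#' cells carry no covariates and never appear in the `cells` table.
#'
#' @param n_rows,n_cols Positive lattice dimensions.
#' @param cell_size_km Cell side length in km (typically 5 or 10).
#' @param mask Optional logical `n_rows x n_cols` matrix, `TRUE` for cells
#'   inside the study region. `NULL` keeps the full rectangle.
#' @return An object of class `sdm_grid`: a list with the dimensions, cell
#'   size, mask, and a data frame `cells` with columns `cell_id`, `row`,
#'   `col`, `x_km`, `y_km` for the unmasked cells. `cell_id` is the 1-based
#'   row-major index over the full rectangle, so ids are stable under masking.
#' @examples
#' g <- sdm_grid(4, 4, cell_size_km = 5)
#' nrow(g$cells)  # 16
#' @export
sdm_grid <- function(n_rows, n_cols, cell_size_km = 5, mask = NULL) {
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be positive")
  if (is.null(mask)) {
    mask <- matrix(TRUE, n_rows, n_cols)
  } else {
    if (!is.logical(mask) || !all(dim(mask) == c(n_rows, n_cols)))
      stop("mask must be a logical n_rows x n_cols matrix")
  }
  rows <- rep(seq_len(n_rows) - 1L, each = n_cols)
  cols <- rep(seq_len(n_cols) - 1L, times = n_rows)
  keep <- as.vector(t(mask))
  cells <- data.frame(
    cell_id = seq_along(rows)[keep],
    row = rows[keep],
    col = cols[keep],
    x_km = (cols[keep] + 0.5) * cell_size_km,
    y_km = (rows[keep] + 0.5) * cell_size_km
  )
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size_km = cell_size_km, mask = mask, cells = cells),
    class = "sdm_grid"
  )
}

#' @export
print.sdm_grid <- function(x, ...) {
  cat(sprintf("sdm_grid: %d x %d cells of %g km (%d inside study region)\n",
              x$n_rows, x$n_cols, x$cell_size_km, nrow(x$cells)))
  invisible(x)
}

#' Number of cells inside the study region
#' @param grid An [sdm_grid()].
#' @return Integer count of unmasked cells.
#' @export
n_cells <- function(grid) nrow(grid$cells)

#' Synthetic country-like study-region mask
#'
#' Deterministically carves an irregular, mostly contiguous region of exactly
#' `target_cells` cells out of an `n_rows x n_cols` rectangle by thresholding a
#' smoothed random field. This is a synthetic stand-in for a national
#' territory outline (the defaults give 987 cells of a 33 x 30 lattice, the
#' cell count of the mainland-Portugal 10 x 10 km grid); it makes no attempt
#' at real geography.
#'
#' @param n_rows,n_cols Lattice dimensions.
#' @param target_cells Number of cells the mask must keep.
#' @param seed Integer seed controlling the region shape.
#' @return Logical matrix usable as the `mask` argument of [sdm_grid()].
#' @export
synthetic_region_mask <- function(n_rows = 33, n_cols = 30,
                                  target_cells = 987, seed = 2941) {
  if (target_cells > n_rows * n_cols)
    stop("target_cells exceeds the lattice size")
  set.seed(seed)
  f <- smooth_noise(n_rows, n_cols, range_cells = 6)
  # bias towards a single blob centred on the lattice so the region is compact
  rr <- (row(f) - (n_rows + 1) / 2) / n_rows
  cc <- (col(f) - (n_cols + 1) / 2) / n_cols
  score <- f - 4 * (rr^2 + cc^2)
  thr <- sort(score, decreasing = TRUE)[target_cells]
  score >= thr
}

#' Regular knight's-move cell selection
#'
#' Selects a deterministic, regularly spaced subset of grid cells: the closure
#' of repeated chess-knight moves from a starting corner, which is the lattice
#' `{(row, col) : (2 row + col) mod 5 == offset}` and covers ~1/5 of the
#' cells. Used to pick survey cells spread evenly over a study region.
#'
#' @param grid An [sdm_grid()].
#' @param start_corner One of `"NW"`, `"NE"`, `"SW"`, `"SE"`; the offset is
#'   chosen so the unmasked cell nearest that corner is selected.
#' @param offset Optional explicit offset in `0:4`, overriding `start_corner`.
#' @return Integer vector of selected `cell_id`s.
#' @examples
#' g <- sdm_grid(3, 3)
#' knight_move_select(g)  # 2 of 9 cells
#' @export
knight_move_select <- function(grid, start_corner = "NW", offset = NULL) {
  cells <- grid$cells
  if (nrow(cells) == 0L) stop("grid has no cells inside the study region")
  if (is.null(offset)) {
    corner <- match.arg(start_corner, c("NW", "NE", "SW", "SE"))
    ord <- switch(corner,
      NW = order(cells$row, cells$col),
      NE = order(cells$row, -cells$col),
      SW = order(-cells$row, cells$col),
      SE = order(-cells$row, -cells$col)
    )
    anchor <- cells[ord[1L], ]
    offset <- (2L * anchor$row + anchor$col) %% 5L
  }
  sel <- (2L * cells$row + cells$col) %% 5L == offset %% 5L
  cells$cell_id[sel]
}

#' Refine a grid by subdividing each cell
#'
#' Splits every cell into `factor^2` subcells (e.g. 10 km cells into four
#' 5 km quadrants). The mask is expanded so subcells inherit their parent's
#' membership.
#'
#' @param grid An [sdm_grid()].
#' @param factor Integer subdivision factor (default 2).
#' @return An `sdm_grid` with `factor`-times finer cells.
#' @export
refine_grid <- function(grid, factor = 2L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  mask <- grid$mask[rep(seq_len(grid$n_rows), each = factor),
                    rep(seq_len(grid$n_cols), each = factor), drop = FALSE]
  sdm_grid(grid$n_rows * factor, grid$n_cols * factor,
           grid$cell_size_km / factor, mask)
}

#' Subcell ids of a parent cell in a refined grid
#'
#' @param grid Coarse [sdm_grid()].
#' @param fine Refined grid from [refine_grid()].
#' @param cell_id Parent `cell_id` on `grid`.
#' @param factor Subdivision factor used in [refine_grid()].
#' @return Integer `cell_id`s of the (unmasked) subcells on `fine`.
#' @export
subcell_ids <- function(grid, fine, cell_id, factor = 2L) {
  i <- match(cell_id, grid$cells$cell_id)
  if (is.na(i)) stop("cell_id not in grid")
  r <- grid$cells$row[i]; c <- grid$cells$col[i]
  sub <- expand.grid(row = factor * r + seq_len(factor) - 1L,
                     col = factor * c + seq_len(factor) - 1L)
  ids <- sub$row * fine$n_cols + sub$col + 1L
  ids[ids %in% fine$cells$cell_id]
}
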