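#' Construct a two-dimensional pooling layout
#'
#' Plants are potted in `n_blocks` complete grids of `n_rows` by `n_cols`.
#' Leaf segments from every plant in a row are pooled into that row's DNA
#' sample, and likewise along columns, so each plant contributes to exactly
#' one row pool and one column pool of its block. A block therefore screens
#' `n_rows * n_cols` plants in `n_rows + n_cols` sequencing libraries.
#'
#' Plant identifiers are synthesised deterministically as
#' `"B{block}R{row}C{col}"` (block-major, then row-major), so the same
#' dimensions always produce the same layout.
#'
#' @param n_blocks,n_rows,n_cols positive integers.
#' @return An object of class `grid_layout`: a list with the dimensions and
#'   a `plants` data frame (plant_id, block, row, col).
#' @examples
#' ly <- build_layout(1, 16, 16)
#' count_plants(ly)  # 256
#' count_pools(ly)   # 32
#' @export
build_layout <- function(n_blocks, n_rows, n_cols) {
  dims <- c(n_blocks = n_blocks, n_rows = n_rows, n_cols = n_cols)
  if (any(dims < 1) || any(dims != as.integer(dims))) {
    .stopf("all layout dimensions must be positive integers (got %s)",
           paste(dims, collapse = ", "))
  }
  g <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows),
                   block = seq_len(n_blocks))
  plants <- data.frame(
    plant_id = sprintf("B%dR%dC%d", g$block, g$row, g$col),
    block = g$block, row = g$row, col = g$col,
    stringsAsFactors = FALSE
  )
  plants <- plants[order(plants$block, plants$row, plants$col), ]
  rownames(plants) <- NULL
  structure(list(n_blocks = as.integer(n_blocks),
                 n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 plants = plants),
            class = "grid_layout")
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("2D pooling layout: %d block(s) of %d x %d\n",
              x$n_blocks, x$n_rows, x$n_cols))
  cat(sprintf("  %d plants, %d pools (%d per block)\n",
              count_plants(x), count_pools(x), x$n_rows + x$n_cols))
  invisible(x)
}

#' Number of pools in a layout
#'
#' Each block contributes `n_rows` row pools and `n_cols` column pools.
#'
#' @param layout a [grid_layout][build_layout].
#' @return integer count, `n_blocks * (n_rows + n_cols)`.
#' @export
count_pools <- function(layout) {
  stopifnot(inherits(layout, "grid_layout"))
  layout$n_blocks * (layout$n_rows + layout$n_cols)
}

#' Number of plants in a layout
#'
#' @inheritParams count_pools
#' @return integer count, `n_blocks * n_rows * n_cols`.
#' @export
count_plants <- function(layout) {
  stopifnot(inherits(layout, "grid_layout"))
  layout$n_blocks * layout$n_rows * layout$n_cols
}

#' Pool identifier
#'
#' @param block block number (1-based).
#' @param axis `"row"` or `"column"`.
#' @param index row or column number within the block (1-based).
#' @return character pool id of the canonical form `"B{block}_{R|C}{index}"`.
#' @export
pool_id <- function(block, axis, index) {
  axis <- match.arg(axis, c("row", "column"), several.ok = TRUE)
  if (length(axis) == 1L && length(block) > 1L) axis <- rep(axis, length(block))
  sprintf("B%d_%s%02d", block, ifelse(axis == "row", "R", "C"), index)
}

#' @noRd
.parse_pool_id <- function(pool) {
  m <- regmatches(pool, regexec("^B([0-9]+)_([RC])([0-9]+)$", pool))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) .stopf("malformed pool id: %s", pool[bad][1])
  data.frame(
    pool_id = pool,
    block = as.integer(vapply(m, `[`, "", 2L)),
    axis = ifelse(vapply(m, `[`, "", 3L) == "R", "row", "column"),
    index = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' The two pools a plant contributes to
#'
#' @inheritParams count_pools
#' @param plant_id a plant identifier present in the layout.
#' @return character vector of length 2: the plant's row pool and column pool.
#' @export
pools_for_plant <- function(layout, plant_id) {
  stopifnot(inherits(layout, "grid_layout"))
  p <- layout$plants[layout$plants$plant_id == plant_id, ]
  if (nrow(p) != 1L) .stopf("unknown plant: %s", plant_id)
  c(pool_id(p$block, "row", p$row), pool_id(p$block, "column", p$col))
}

#' Plant at a row/column intersection
#'
#' @inheritParams count_pools
#' @param block,row,col grid coordinates.
#' @return plant identifier.
#' @export
plant_at <- function(layout, block, row, col) {
  stopifnot(inherits(layout, "grid_layout"))
  p <- layout$plants
  hit <- p$block == block & p$row == row & p$col == col
  if (!any(hit)) .stopf("no plant at block %d row %d col %d", block, row, col)
  p$plant_id[hit]
}

#' Plants contributing to a pool
#'
#' @inheritParams count_pools
#' @param pool a pool id (see [pool_id()]).
#' @return character vector of member plant ids (length `n_cols` for a row
#'   pool, `n_rows` for a column pool).
#' @export
pool_members <- function(layout, pool) {
  stopifnot(inherits(layout, "grid_layout"))
  pd <- .parse_pool_id(pool)
  p <- layout$plants
  if (pd$axis == "row") {
    p$plant_id[p$block == pd$block & p$row == pd$index]
  } else {
    p$plant_id[p$block == pd$block & p$col == pd$index]
  }
}

#' All pool ids of a layout
#'
#' @inheritParams count_pools
#' @return character vector of pool ids, blocks ordered first, rows before
#'   columns within a block.
#' @export
layout_pools <- function(layout) {
  stopifnot(inherits(layout, "grid_layout"))
  unlist(lapply(seq_len(layout$n_blocks), function(b) {
    c(pool_id(rep(b, layout$n_rows), "row", seq_len(layout$n_rows)),
      pool_id(rep(b, layout$n_cols), "column", seq_len(layout$n_cols)))
  }))
}

#' Express a layout as a sample sheet
#'
#' The sample sheet is the TSV interchange format mapping sequencing
#' libraries (pool ids) to their block, axis and index; see
#' [read_sample_sheet()].
#'
#' @inheritParams count_pools
#' @return data frame with columns pool_id, block, axis, index.
#' @export
layout_sample_sheet <- function(layout) {
  .parse_pool_id(layout_pools(layout))
}
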