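#' Neutral fractal landscape of resource-rich and resource-poor cells
#'
#' Generates a continuous fractal surface on a square (2^k + 1) grid by
#' diamond-square midpoint displacement, with the displacement standard
#' deviation shrinking by `2^(-H)` per subdivision level (`H` is the Hurst
#' parameter: higher `H` gives larger, smoother habitat patches), then labels
#' the cells whose surface value exceeds the empirical `(1 - p)`-quantile as
#' resource rich.  Quantile thresholding hits the requested rich proportion
#' exactly: the rich-cell count is `round(p * n_cells^2)` for every surface.
#'
#' The default grid (257 x 257) covers 3 km^2, giving a cell size of
#' `sqrt(3e6)/257` = 6.74 m.  Movement across the landscape wraps toroidally;
#' displacement bookkeeping uses unwrapped coordinates.
#'
#' @param n_cells grid side; must be 2^k + 1 (default 257).
#' @param hurst Hurst parameter in (0, 1).
#' @param p_rich target proportion of resource-rich cells in \[0, 1\].
#' @param seed optional integer seed for the surface.
#' @param cell_size_m cell edge length in metres (default sized to 3 km^2).
#' @return An object of class `landscape`: the 0/1 grid (1 = rich; rows index
#'   x, columns y), cell size, side length, and the generation parameters.
#' @export
fractal_landscape <- function(n_cells = 257, hurst = 0.5, p_rich = 0.5,
                              seed = NULL,
                              cell_size_m = sqrt(3e6) / n_cells) {
  k <- log2(n_cells - 1)
  if (n_cells < 3 || abs(k - round(k)) > 1e-9) {
    stop("n_cells must be 2^k + 1 for midpoint displacement (e.g. 129, 257); got ",
         n_cells)
  }
  if (hurst <= 0 || hurst >= 1) stop("hurst must lie in (0, 1)")
  if (p_rich < 0 || p_rich > 1) stop("p_rich must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  surface <- diamond_square(n_cells, hurst)
  grid <- threshold_surface(surface, p_rich)
  structure(list(grid = grid, n_cells = as.integer(n_cells),
                 cell_size_m = cell_size_m,
                 side_m = n_cells * cell_size_m,
                 hurst = hurst, p_rich = p_rich, seed = seed,
                 surface = surface),
            class = "landscape")
}

# diamond-square midpoint displacement on an n x n grid (n = 2^k + 1);
# boundary midpoints average their 3 available neighbours
diamond_square <- function(n, hurst) {
  g <- matrix(0, n, n)
  g[c(1, n), c(1, n)] <- stats::rnorm(4)
  step <- n - 1L
  scale <- 1
  while (step > 1L) {
    half <- step %/% 2L
    scale <- scale * 2^(-hurst)
    # diamond step: centres of the current squares
    ci <- seq(half + 1L, n, by = step)
    lo <- ci - half; hi <- ci + half
    g[ci, ci] <- (g[lo, lo] + g[hi, lo] + g[lo, hi] + g[hi, hi]) / 4 +
      stats::rnorm(length(ci)^2) * scale
    # square step: edge midpoints, two sublattices
    sq_fill <- function(rows, cols) {
      pts <- expand.grid(r = rows, c = cols)
      s <- numeric(nrow(pts)); cnt <- numeric(nrow(pts))
      for (off in list(c(-half, 0L), c(half, 0L), c(0L, -half), c(0L, half))) {
        rr <- pts$r + off[1]; cc <- pts$c + off[2]
        ok <- rr >= 1L & rr <= n & cc >= 1L & cc <= n
        rr[!ok] <- 1L; cc[!ok] <- 1L
        v <- g[cbind(rr, cc)]
        v[!ok] <- 0
        s <- s + v; cnt <- cnt + ok
      }
      g[cbind(pts$r, pts$c)] <<- s / cnt + stats::rnorm(nrow(pts)) * scale
    }
    sq_fill(seq(half + 1L, n, by = step), seq(1L, n, by = step))
    sq_fill(seq(1L, n, by = step), seq(half + 1L, n, by = step))
    step <- half
  }
  g
}

# label the top round(p * n^2) surface values rich (1), the rest poor (0)
threshold_surface <- function(surface, p_rich) {
  n2 <- length(surface)
  m <- round(p_rich * n2)
  grid <- matrix(0L, nrow(surface), ncol(surface))
  if (m > 0L) {
    ord <- order(as.vector(surface), decreasing = TRUE)
    grid[ord[seq_len(m)]] <- 1L
  }
  grid
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d cells (%.2f m), side %.0f m, H = %.2f, rich %d/%d cells (p = %.3f)\n",
              x$n_cells, x$n_cells, x$cell_size_m, x$side_m, x$hurst,
              sum(x$grid), length(x$grid), x$p_rich))
  invisible(x)
}

#' Habitat class at a coordinate
#'
#' Cell lookup with toroidal wrapping of the coordinates (positions beyond
#' the landscape edge wrap around).
#'
#' @param landscape a [fractal_landscape()].
#' @param x_m,y_m coordinates in metres (vectorized).
#' @return character vector, `"rich"` or `"poor"`.
#' @export
habitat_at <- function(landscape, x_m, y_m) {
  stopifnot(inherits(landscape, "landscape"))
  n <- landscape$n_cells
  ix <- floor(x_m / landscape$cell_size_m) %% n
  iy <- floor(y_m / landscape$cell_size_m) %% n
  ifelse(landscape$grid[cbind(ix + 1, iy + 1)] == 1L, "rich", "poor")
}

#' Same-class join-count clumping statistic
#'
#' The proportion of rook-adjacent cell pairs (with toroidal wrapping) whose
#' two cells share a habitat class.  At fixed `p_rich`, the statistic
#' increases with the Hurst parameter as patches become larger and smoother —
#' the test oracle for the clumping control.
#'
#' @param landscape a [fractal_landscape()].
#' @return proportion in \[0, 1\].
#' @export
clumping <- function(landscape) {
  stopifnot(inherits(landscape, "landscape"))
  g <- landscape$grid
  n <- nrow(g)
  right <- g[, c(2:n, 1)]
  down <- g[c(2:n, 1), ]
  mean(c(g == right, g == down))
}

#' Write / read a landscape
#'
#' The grid is written as a headerless CSV of 0/1 cells (rows = x index) with
#' a JSON sidecar (`<path>.json`) holding the Hurst parameter, rich
#' proportion, seed and cell size.
#'
#' @param landscape a [fractal_landscape()].
#' @param path CSV file path.
#' @return `write_landscape` returns `path` invisibly; `read_landscape`
#'   returns a `landscape` object (without the continuous surface).
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "landscape"))
  utils::write.table(landscape$grid, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- landscape[c("n_cells", "cell_size_m", "side_m", "hurst", "p_rich", "seed")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  grid <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(grid) <- NULL
  storage.mode(grid) <- "integer"
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(grid = grid, n_cells = as.integer(meta$n_cells),
                 cell_size_m = meta$cell_size_m, side_m = meta$side_m,
                 hurst = meta$hurst, p_rich = meta$p_rich,
                 seed = meta$seed, surface = NULL),
            class = "landscape")
}
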