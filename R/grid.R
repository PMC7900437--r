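#' Build an electrode-array grid
#'
#' Constructs the geometry of a rectangular high-density mapping array:
#' electrode coordinates, the 8-neighborhood relation (4 orthogonal and 4
#' oblique links) restricted to active sites, and the array periphery
#' (active electrodes with fewer than 8 active neighbors).
#'
#' @param n_rows,n_cols Lattice dimensions (rows x columns), each >= 1.
#' @param spacing_mm Inter-electrode distance in mm (> 0). Orthogonal
#'   neighbors are `spacing_mm` apart, oblique neighbors
#'   `spacing_mm * sqrt(2)`.
#' @param active_mask Logical matrix `n_rows x n_cols`; `TRUE` marks a
#'   physical electrode. Default: all sites active.
#' @param region Region label(s) for the electrodes: a single string
#'   (applied to all) or a character matrix matching the lattice.
#'
#' @return An object of class `electrode_grid`: a list with elements
#'   `n_rows`, `n_cols`, `spacing_mm`, `active` (logical matrix), `id`
#'   (integer matrix, `NA` at inactive sites), `electrodes` (data frame
#'   `electrode, row, col, x_mm, y_mm, region`), `neighbors` (data frame
#'   `from, to, relation, dist_mm`, one row per unordered pair, `from < to`),
#'   `degree` (active-neighbor count per electrode) and `periphery`
#'   (electrode ids on the array edge).
#'
#' @details Coordinates are electrode-centered, x increasing with column
#'   (rightward) and y increasing upward (row 1 is the top row), in mm.
#'
#' @examples
#' g <- build_grid(3, 3, 2.5)
#' nrow(g$neighbors)   # 20 pairs: 12 orthogonal + 8 oblique
#' g$periphery         # all but the center electrode
#' @export
build_grid <- function(n_rows, n_cols, spacing_mm,
                       active_mask = NULL, region = "A") {
  stopifnot(n_rows >= 1, n_cols >= 1, spacing_mm > 0)
  if (is.null(active_mask)) {
    active_mask <- matrix(TRUE, n_rows, n_cols)
  }
  active_mask <- as.matrix(active_mask)
  if (!identical(dim(active_mask), c(as.integer(n_rows), as.integer(n_cols))))
    stop("active_mask dimensions must be n_rows x n_cols")
  mode(active_mask) <- "logical"
  n_active <- sum(active_mask)
  if (n_active < 1L) stop("invalid grid: no active electrodes")

  # ids assigned row-major over active sites
  id <- matrix(NA_integer_, n_rows, n_cols)
  idx <- which(t(active_mask))   # row-major order
  ord <- cbind(row = ((idx - 1L) %/% n_cols) + 1L,
               col = ((idx - 1L) %% n_cols) + 1L)
  id[ord] <- seq_len(n_active)

  if (is.matrix(region)) {
    reg <- region[ord]
  } else {
    reg <- rep(as.character(region), length.out = n_active)
  }
  electrodes <- data.frame(
    electrode = seq_len(n_active),
    row = ord[, "row"], col = ord[, "col"],
    x_mm = (ord[, "col"] - 1) * spacing_mm,
    y_mm = (n_rows - ord[, "row"]) * spacing_mm,
    region = reg,
    stringsAsFactors = FALSE
  )

  # 8-neighborhood among active sites; enumerate each unordered pair once
  offs <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  rel  <- c("orthogonal", "orthogonal", "oblique", "oblique")
  from <- integer(0); to <- integer(0); relation <- character(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- ord[, "row"] + offs[k, 1L]
    c2 <- ord[, "col"] + offs[k, 2L]
    ok <- r2 >= 1L & r2 <= n_rows & c2 >= 1L & c2 <= n_cols
    ok[ok] <- active_mask[cbind(r2[ok], c2[ok])]
    if (!any(ok)) next
    from <- c(from, electrodes$electrode[ok])
    to <- c(to, id[cbind(r2[ok], c2[ok])])
    relation <- c(relation, rep(rel[k], sum(ok)))
  }
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  o <- order(from, to)
  neighbors <- data.frame(
    from = from[o], to = to[o], relation = relation[o],
    dist_mm = ifelse(relation[o] == "orthogonal",
                     spacing_mm, spacing_mm * sqrt(2)),
    stringsAsFactors = FALSE
  )

  degree <- tabulate(c(neighbors$from, neighbors$to), nbins = n_active)
  grid <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    spacing_mm = spacing_mm, active = active_mask, id = id,
    electrodes = electrodes, neighbors = neighbors,
    degree = degree, periphery = which(degree < 8L),
    n_electrodes = n_active
  )
  class(grid) <- "electrode_grid"
  grid
}

#' Default 249-electrode mapping array
#'
#' A 16 x 16 lattice at 2.5 mm spacing with 7 corner sites masked, matching
#' the 249-electrode count of the high-density epicardial array while keeping
#' the exact physical layout (which is hardware-specific) configurable.
#'
#' @param region Region label for all electrodes (e.g. `"RA"`, `"LA"`).
#' @param spacing_mm Inter-electrode distance in mm.
#' @return An [build_grid()] `electrode_grid` with 249 active electrodes.
#' @export
default_af_grid <- function(region = "RA", spacing_mm = 2.5) {
  mask <- matrix(TRUE, 16, 16)
  # one corner site clipped at three corners, a 2x2 block at the fourth
  mask[1, 1] <- mask[1, 16] <- mask[16, 16] <- FALSE
  mask[16, 1] <- mask[16, 2] <- mask[15, 1] <- mask[15, 2] <- FALSE
  build_grid(16, 16, spacing_mm, mask, region = region)
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf(
    "<electrode_grid> %d x %d lattice, %.3g mm spacing, %d active electrodes\n",
    x$n_rows, x$n_cols, x$spacing_mm, x$n_electrodes))
  cat(sprintf("  %d neighbor pairs (%d orthogonal, %d oblique), %d on periphery\n",
              nrow(x$neighbors),
              sum(x$neighbors$relation == "orthogonal"),
              sum(x$neighbors$relation == "oblique"),
              length(x$periphery)))
  invisible(x)
}

#' Is an electrode on the array periphery?
#' @param grid An `electrode_grid`.
#' @param electrode Integer electrode id(s).
#' @return Logical vector.
#' @export
is_periphery <- function(grid, electrode) electrode %in% grid$periphery

#' Write / read grid geometry as JSON
#'
#' @param grid An `electrode_grid`.
#' @param path File path (JSON).
#' @return `read_grid` returns an `electrode_grid` rebuilt from the stored
#'   lattice description; `write_grid` returns `path` invisibly.
#' @export
write_grid <- function(grid, path) {
  regions <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  regions[cbind(grid$electrodes$row, grid$electrodes$col)] <-
    grid$electrodes$region
  jsonlite::write_json(
    list(n_rows = grid$n_rows, n_cols = grid$n_cols,
         spacing_mm = grid$spacing_mm,
         mask = grid$active, regions = regions),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$spacing_mm) || is.null(j$mask))
    stop("grid JSON must contain spacing_mm and mask")
  mask <- matrix(as.logical(j$mask), j$n_rows, j$n_cols)
  reg <- if (!is.null(j$regions)) {
    m <- matrix(as.character(j$regions), j$n_rows, j$n_cols)
    m[is.na(m)] <- "A"
    m
  } else "A"
  build_grid(j$n_rows, j$n_cols, j$spacing_mm, mask, region = reg)
}
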