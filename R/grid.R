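#' Space--time grid for simulation and analysis
#'
#' Regular grid on a flat cortical patch. Space is centred on the origin
#' (`x = 0` lies on a grid node); time starts at `t = 0`. One spatial
#' dimension (`ny = 1`) or two are supported.
#'
#' @param dx Spatial step (mm).
#' @param dt Temporal step (s).
#' @param nx,ny Number of spatial samples (set `ny = 1` for 1-D).
#' @param nt Number of temporal samples.
#' @return An object of class `st_grid` with coordinate vectors `x`, `y`,
#'   `t`.
#' @export
#' @examples
#' g <- st_grid(dx = 0.25, dt = 0.25, nx = 128, nt = 256)
st_grid <- function(dx, dt, nx, nt, ny = 1) {
  if (dx <= 0 || dt <= 0) stop("st_grid: dx and dt must be positive", call. = FALSE)
  if (nx < 2 || nt < 2 || ny < 1) stop("st_grid: grid too small", call. = FALSE)
  structure(list(dx = dx, dt = dt, nx = as.integer(nx), ny = as.integer(ny),
                 nt = as.integer(nt),
                 x = (seq_len(nx) - 1 - nx %/% 2) * dx,
                 y = (seq_len(ny) - 1 - ny %/% 2) * dx,
                 t = (seq_len(nt) - 1) * dt),
            class = "st_grid")
}

#' @export
print.st_grid <- function(x, ...) {
  cat(sprintf("<st_grid> %d x %d x %d (x, y, t), dx = %g mm, dt = %g s, extent %g mm x %g mm x %g s\n",
              x$nx, x$ny, x$nt, x$dx, x$dt, x$nx * x$dx, x$ny * x$dx,
              x$nt * x$dt))
  invisible(x)
}

# FFT sample frequencies (cycles per unit), standard wrap-around ordering.
fft_freq <- function(n, d) {
  i <- 0:(n - 1)
  ifelse(i < (n + 1) %/% 2, i, i - n) / (n * d)
}

# Angular frequency grids matching fft() ordering
grid_omega <- function(grid) 2 * pi * fft_freq(grid$nt, grid$dt)
grid_kx <- function(grid) 2 * pi * fft_freq(grid$nx, grid$dx)
grid_ky <- function(grid) 2 * pi * fft_freq(grid$ny, grid$dx)

# index of the spatial origin (x = 0, y = 0)
grid_origin <- function(grid) c(ix = grid$nx %/% 2 + 1L, iy = grid$ny %/% 2 + 1L)

#' Tagged field on a space--time grid
#'
#' Thin wrapper pairing an array of values with its grid, the physical
#' quantity it represents and its units. Simulation inputs and outputs are
#' passed around as fields.
#'
#' @param values Numeric array, dimension `c(nx, nt)` (1-D grid) or
#'   `c(nx, ny, nt)`.
#' @param grid An [st_grid()].
#' @param quantity One of `"z"` (neural drive), `"F"` (inflow), `"xi"`
#'   (blood mass), `"P"` (pressure), `"Q"` (dHb), `"y"` (BOLD), `"v"`
#'   (velocity component).
#' @param units Units tag, free text.
#' @return An object of class `hw_field`.
#' @export
hw_field <- function(values, grid, quantity = c("z", "F", "xi", "P", "Q", "y", "v"),
                     units = "") {
  quantity <- match.arg(quantity)
  values <- field_array(values, grid)
  if (!all(is.finite(values)))
    stop("hw_field: values must all be finite", call. = FALSE)
  structure(list(values = values, grid = grid, quantity = quantity,
                 units = units),
            class = "hw_field")
}

# coerce to the canonical array shape for a grid: (nx, nt) or (nx, ny, nt)
field_array <- function(values, grid) {
  want <- if (grid$ny == 1L) c(grid$nx, grid$nt) else c(grid$nx, grid$ny, grid$nt)
  d <- dim(values)
  if (is.null(d)) stop("field values must be a matrix or array", call. = FALSE)
  if (length(d) == 3 && grid$ny == 1L && d[2] == 1) {
    values <- array(values, c(d[1], d[3]))
    d <- dim(values)
  }
  if (!identical(as.integer(d), as.integer(want)))
    stop(sprintf("field shape (%s) does not match grid (%s)",
                 paste(d, collapse = "x"), paste(want, collapse = "x")),
         call. = FALSE)
  values
}

#' @export
print.hw_field <- function(x, ...) {
  cat(sprintf("<hw_field '%s'%s> %s; range [%.3g, %.3g]\n", x$quantity,
              if (nzchar(x$units)) paste0(" (", x$units, ")") else "",
              paste(dim(x$values), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

field_values <- function(f) if (inherits(f, "hw_field")) f$values else f
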