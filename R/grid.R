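#' Discretized water-column habitat
#'
#' Builds a uniform grid on the water column \eqn{X = [0, depth\_max]} together
#' with trapezoidal quadrature weights normalized so that they integrate the
#' constant function 1 to exactly 1. The habitat thus carries the *uniform
#' probability measure* \eqn{\mu}; all strategy densities in the package are
#' densities with respect to \eqn{\mu}, so the uniform strategy is the constant
#' vector 1.
#'
#' @param depth_max bottom of the water column in meters (> 0); the surface is
#'   at depth 0.
#' @param n_nodes number of grid nodes (integer >= 2), endpoints included.
#'
#' @return An object of class `habitat_grid`: a list with elements
#'   `depth_max`, `n_nodes`, `depths` (node positions, meters) and `weights`
#'   (quadrature weights, summing to 1).
#'
#' @examples
#' g <- habitat_grid(100, 300)
#' sum(g$weights)          # exactly 1
#' inner_product(g$depths, rep(1, 300), g)  # ~ 50, mean depth
#' @export
habitat_grid <- function(depth_max = 100, n_nodes = 300) {
  if (!is.numeric(depth_max) || length(depth_max) != 1 || !is.finite(depth_max) ||
      depth_max <= 0) {
    stop("`depth_max` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n_nodes) || length(n_nodes) != 1 || !is.finite(n_nodes) ||
      n_nodes < 2 || n_nodes != round(n_nodes)) {
    stop("`n_nodes` must be a single integer >= 2", call. = FALSE)
  }
  n <- as.integer(n_nodes)
  depths <- seq(0, depth_max, length.out = n)
  # trapezoid weights h*(1/2, 1, ..., 1, 1/2) normalized by depth_max so that
  # <1,1> = 1: interior weight 1/(n-1), endpoints 1/(2(n-1))
  w <- rep(1 / (n - 1), n)
  w[c(1L, n)] <- 1 / (2 * (n - 1))
  structure(
    list(depth_max = depth_max, n_nodes = n, depths = depths, weights = w),
    class = "habitat_grid"
  )
}

#' @export
print.habitat_grid <- function(x, ...) {
  cat(sprintf("habitat_grid: [0, %g] m, %d nodes, trapezoid weights (sum %.15g)\n",
              x$depth_max, x$n_nodes, sum(x$weights)))
  invisible(x)
}

#' Inner product against the habitat probability measure
#'
#' Quadrature form of \eqn{\langle f, g\rangle = \int_X f g \, d\mu}:
#' \eqn{\sum_j w_j f_j g_j}. Symmetric and bilinear. This is the inner product
#' every encounter-rate and fitness term in the model is built from.
#'
#' @param f,g numeric vectors on the grid nodes.
#' @param grid a [habitat_grid()].
#' @return a scalar.
#' @export
inner_product <- function(f, g, grid) {
  stopifnot(inherits(grid, "habitat_grid"))
  if (length(f) != grid$n_nodes || length(g) != grid$n_nodes) {
    stop("`f` and `g` must have length grid$n_nodes", call. = FALSE)
  }
  sum(grid$weights * f * g)
}

#' Test whether a vector is a probability density on the grid
#'
#' A strategy density must be nonnegative and integrate to 1 against \eqn{\mu}.
#'
#' @param sigma numeric vector on the grid.
#' @param grid a [habitat_grid()].
#' @param tol tolerance for both the negativity and normalization checks.
#' @return a list with `ok` (logical), `min_value` (most negative entry, 0 if
#'   none), and `mass_error` (integral minus 1).
#' @export
is_probability_density <- function(sigma, grid, tol = 1e-8) {
  stopifnot(inherits(grid, "habitat_grid"), length(sigma) == grid$n_nodes)
  mn <- min(sigma)
  mass_err <- inner_product(sigma, rep(1, grid$n_nodes), grid) - 1
  list(
    ok = (mn >= -tol) && (abs(mass_err) <= tol),
    min_value = min(mn, 0),
    mass_error = mass_err
  )
}

#' Serialize a grid to JSON
#'
#' @param grid a [habitat_grid()].
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
grid_to_json <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "habitat_grid"))
  x <- list(depth_max = grid$depth_max, n_nodes = grid$n_nodes,
            depths = grid$depths, weights = grid$weights)
  if (is.null(path)) {
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
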