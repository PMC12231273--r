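#' Rotation matrix from extrinsic ZYZ Euler angles
#'
#' R = R(Z, phi) R(Y, theta) R(Z, chi): starting from the laboratory frame,
#' rotate about Z by chi, then about Y by theta, then about Z by phi. The
#' columns of R are the molecule-fixed basis vectors expressed in the
#' laboratory frame; v_lab = R v_mol.
#'
#' @param chi,theta,phi Euler angles in radians.
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
euler_to_rotation <- function(chi, theta, phi) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rz(phi) %*% ry(theta) %*% rz(chi)
}

#' External field direction in the molecule-fixed frame
#'
#' With the laboratory field along Z, the molecule-fixed components of the
#' unit field direction are (-sin(theta) cos(chi), sin(theta) sin(chi),
#' cos(theta)); this is independent of the third Euler angle phi.
#'
#' @param chi,theta Euler angles in radians.
#' @return Unit 3-vector.
#' @export
field_direction_mol <- function(chi, theta) {
  c(-sin(theta) * cos(chi), sin(theta) * sin(chi), cos(theta))
}

#' Available orientation-grid sizes
#'
#' The catalog contains the 32 Lebedev quadrature rules with 6 to 5810
#' points (algebraic design orders 3 to 131).
#'
#' @return Integer vector of point counts.
#' @export
orientation_grid_sizes <- function() {
  c(6L, 14L, 26L, 38L, 50L, 74L, 86L, 110L, 146L, 170L, 194L, 230L, 266L,
    302L, 350L, 434L, 590L, 770L, 974L, 1202L, 1454L, 1730L, 2030L, 2354L,
    2702L, 3074L, 3470L, 3890L, 4334L, 4802L, 5294L, 5810L)
}

.lebedev_orders <- c(3L, 5L, 7L, 9L, 11L, 13L, 15L, 17L, 19L, 21L, 23L, 25L,
                     27L, 29L, 31L, 35L, 41L, 47L, 53L, 59L, 65L, 71L, 77L,
                     83L, 89L, 95L, 101L, 107L, 113L, 119L, 125L, 131L)

# cache of loaded grids for the lifetime of the session
.lebedev_cache <- new.env(parent = emptyenv())

#' Lebedev quadrature grid on the unit sphere
#'
#' Loads one of the 32 embedded Lebedev-Laikov rules and expands its
#' octahedral-symmetry orbits into explicit points. Weights are stored
#' normalized to sum 1, i.e. a weighted sum over points approximates the
#' uniform average over the sphere (the 1/4pi of the continuous average is
#' absorbed). A rule of design order p integrates all spherical harmonics
#' of degree <= p exactly.
#'
#' @param n Number of grid points; one of [orientation_grid_sizes()].
#' @return Object of class `orientation_grid`: `directions` (n x 3 matrix
#'   of unit vectors), `weights` (sum 1), `order` (design order), `n`.
#' @examples
#' g <- lebedev_grid(26)
#' sum(g$weights)           # 1
#' @export
lebedev_grid <- function(n) {
  sizes <- orientation_grid_sizes()
  n <- as.integer(n)
  if (length(n) != 1 || is.na(n) || !n %in% sizes) {
    stop("no grid with ", n, " points; available sizes: ",
         paste(sizes, collapse = ", "))
  }
  key <- as.character(n)
  if (!is.null(.lebedev_cache[[key]])) return(.lebedev_cache[[key]])
  fn <- system.file("extdata", "lebedev",
                    sprintf("lebedev_%04d.txt", n), package = "paranmr")
  if (fn == "") stop("embedded Lebedev table for n = ", n, " not found")
  tab <- utils::read.table(fn, comment.char = "#",
                           col.names = c("type", "a", "b", "w"))
  pts <- do.call(rbind, lapply(seq_len(nrow(tab)), function(k) {
    expand_lebedev_orbit(tab$type[k], tab$a[k], tab$b[k])
  }))
  w <- rep(tab$w, vapply(tab$type, orbit_size, integer(1)))
  grid <- structure(
    list(directions = pts, weights = w,
         order = .lebedev_orders[match(n, sizes)], n = n),
    class = "orientation_grid")
  validate_orientation_grid(grid)
  .lebedev_cache[[key]] <- grid
  grid
}

orbit_size <- function(type) {
  c(6L, 12L, 8L, 24L, 24L, 48L)[type]
}

# Octahedral-symmetry orbits of the Lebedev construction:
#   1: (1,0,0)        vertices of the octahedron            (6 points)
#   2: (a,a,0)/|.|    edge midpoints, a = 1/sqrt(2)         (12 points)
#   3: (a,a,a)/|.|    cube vertices, a = 1/sqrt(3)          (8 points)
#   4: (a,a,b)        b = sqrt(1 - 2 a^2)                   (24 points)
#   5: (a,b,0)        b = sqrt(1 - a^2)                     (24 points)
#   6: (a,b,c)        c = sqrt(1 - a^2 - b^2)               (48 points)
expand_lebedev_orbit <- function(type, a, b) {
  signs2 <- as.matrix(expand.grid(s1 = c(1, -1), s2 = c(1, -1)))
  signs3 <- as.matrix(expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1)))
  if (type == 1) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else if (type == 2) {
    a <- sqrt(0.5)
    do.call(rbind, lapply(1:3, function(zero_pos) {
      idx <- setdiff(1:3, zero_pos)
      t(apply(signs2, 1, function(s) {
        v <- numeric(3); v[idx] <- a * s; v
      }))
    }))
  } else if (type == 3) {
    a <- 1 / sqrt(3)
    t(apply(signs3, 1, function(s) a * s))
  } else if (type == 4) {
    b <- sqrt(max(0, 1 - 2 * a^2))
    do.call(rbind, lapply(1:3, function(b_pos) {
      idx <- setdiff(1:3, b_pos)
      t(apply(signs3, 1, function(s) {
        v <- numeric(3)
        v[idx] <- a * s[1:2]; v[b_pos] <- b * s[3]
        v
      }))
    }))
  } else if (type == 5) {
    b <- sqrt(max(0, 1 - a^2))
    do.call(rbind, lapply(1:3, function(zero_pos) {
      idx <- setdiff(1:3, zero_pos)
      rbind(
        t(apply(signs2, 1, function(s) {
          v <- numeric(3); v[idx] <- c(a, b) * s; v
        })),
        t(apply(signs2, 1, function(s) {
          v <- numeric(3); v[idx] <- c(b, a) * s; v
        })))
    }))
  } else if (type == 6) {
    cc <- sqrt(max(0, 1 - a^2 - b^2))
    perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                   c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    do.call(rbind, lapply(seq_len(nrow(perms)), function(p) {
      base <- c(a, b, cc)[perms[p, ]]
      t(apply(signs3, 1, function(s) base * s))
    }))
  } else {
    stop("unknown Lebedev orbit type ", type)
  }
}

validate_orientation_grid <- function(grid) {
  nrm <- sqrt(rowSums(grid$directions^2))
  if (max(abs(nrm - 1)) > 1e-12) stop("grid directions are not unit vectors")
  if (abs(sum(grid$weights) - 1) > 1e-12) stop("grid weights do not sum to 1")
  # the 74-, 230- and 266-point rules carry a few small negative weights;
  # that is a property of the published rules, not a data error
  if (any(abs(grid$weights) > 1)) stop("grid weights out of range")
  invisible(grid)
}

#' @export
print.orientation_grid <- function(x, ...) {
  cat("<orientation_grid>", x$n, "points, design order", x$order, "\n")
  invisible(x)
}

#' Average of a function of direction over the unit sphere
#'
#' Quadrature approximation sum_i w_i f(u_i) to the uniform orientational
#' average, exact for integrands that are spherical polynomials up to the
#' grid's design order.
#'
#' @param f Function taking a unit 3-vector, returning a scalar.
#' @param grid An [orientation_grid][lebedev_grid].
#' @return Real scalar.
#' @examples
#' orientational_average(function(u) u[3]^2, lebedev_grid(26))  # 1/3
#' @export
orientational_average <- function(f, grid) {
  stopifnot(inherits(grid, "orientation_grid"))
  vals <- vapply(seq_len(grid$n),
                 function(i) f(grid$directions[i, ]), numeric(1))
  sum(grid$weights * vals)
}
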