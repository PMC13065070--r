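# Compositional primitives for 24-hour time-use data: closure, subcomposition,
# multiplicative zero replacement, compositional (geometric) mean, and
# isometric log-ratio transforms built from pivot (sequential binary
# partition) bases.  All operations treat a composition as a named vector of
# non-negative minutes per behaviour set, closed to 1440 min/day; matrix
# inputs (one composition per row) are supported throughout.

#' Minutes in a 24-hour day
#'
#' The fixed total every behaviour composition is closed to.
#' @export
DAY_MINUTES <- 1440

as_comp_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
}

#' Close a composition to a fixed total
#'
#' Rescales non-negative parts so they sum to `total` (1440 minutes by
#' default), the linear adjustment used when reporting compositional means of
#' daily time use.
#'
#' @param x Named numeric vector of parts, or a matrix with one composition
#'   per row (columns = parts).
#' @param total Positive total to close to, in minutes. Default 1440.
#' @return Object of the same shape as `x` with rows summing to `total`.
#' @examples
#' closure(c(sleep = 1, media = 1, domestic = 1), total = 1440)
#' @export
closure <- function(x, total = DAY_MINUTES) {
  stopifnot(is.numeric(total), length(total) == 1, total > 0)
  m <- as_comp_matrix(x)
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("parts must be finite and non-negative")
  }
  s <- rowSums(m)
  if (any(s <= 0)) {
    stop("degenerate input: all-zero composition cannot be closed")
  }
  out <- m * (total / s)
  if (is.matrix(x)) out else stats::setNames(drop(out), names(x))
}

#' Multiplicative replacement of zero parts
#'
#' Zeros are replaced with a small positive value (`impute` minutes, which
#' must be below the 10-minute diary slot resolution) and the remaining
#' non-zero parts are scaled down proportionally so the day still sums to
#' `total`.  Ratios among the originally non-zero parts are preserved
#' exactly.
#'
#' @param x Composition (vector or matrix of rows) already closed to `total`.
#' @param impute Minutes substituted for each zero part; must lie in (0, 10).
#' @param total Closed total, default 1440.
#' @return Strictly positive composition summing to `total`.
#' @examples
#' replace_zeros(c(sleep = 900, pa = 0, media = 200, school = 50,
#'                 hobbies = 60, domestic = 230), impute = 5)
#' @export
replace_zeros <- function(x, impute = 5, total = DAY_MINUTES) {
  if (!is.numeric(impute) || length(impute) != 1 || impute <= 0 || impute >= 10) {
    stop("impute must be a single value in (0, 10) minutes")
  }
  m <- as_comp_matrix(x)
  if (any(!is.finite(m)) || any(m < 0)) stop("parts must be finite and non-negative")
  s <- rowSums(m)
  if (any(abs(s - total) > 1e-6)) {
    stop("input must be closed to ", total, " before zero replacement")
  }
  if (any(rowSums(m > 0) == 0)) stop("all-zero composition")
  z <- m == 0
  nz <- rowSums(z)
  scale <- (total - impute * nz) / total
  out <- m * scale
  out[z] <- impute
  if (is.matrix(x)) out else stats::setNames(drop(out), names(x))
}

#' Compositional (geometric) mean
#'
#' Part-wise geometric mean of a sample of strictly positive compositions,
#' linearly adjusted (closed) to `total` minutes.
#'
#' @param x Matrix of compositions, one per row, strictly positive.
#' @param total Closed total, default 1440.
#' @return Named vector: the closed geometric-mean composition.
#' @export
compositional_mean <- function(x, total = DAY_MINUTES) {
  m <- as_comp_matrix(x)
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("compositional mean requires strictly positive parts; replace zeros first")
  }
  g <- exp(colMeans(log(m)))
  closure(stats::setNames(g, colnames(m)), total = total)
}

#' Subcomposition
#'
#' Restricts a composition to a subset of parts and re-closes to `total`.
#' Used to drop physical activity and school from weekend days.
#'
#' @param x Named composition vector, or matrix with named columns.
#' @param keep Character vector of part names to retain.
#' @param total Closed total, default 1440.
#' @return Composition over `keep`, summing to `total`.
#' @export
subcomposition <- function(x, keep, total = DAY_MINUTES) {
  if (length(keep) == 0) stop("keep must name at least one part")
  nm <- if (is.matrix(x)) colnames(x) else names(x)
  if (is.null(nm) || !all(keep %in% nm)) {
    stop("keep must be a subset of the composition's part names")
  }
  sub <- if (is.matrix(x)) x[, keep, drop = FALSE] else x[keep]
  closure(sub, total = total)
}

#' Part percentages of the day
#'
#' Each part expressed as a percentage of the closed day, rounded for
#' reporting.
#'
#' @param x Composition closed to `total`.
#' @param digits Rounding digits; default 0 (nearest integer percent).
#' @param total Closed total, default 1440.
#' @return Named numeric vector of percentages.
#' @examples
#' part_percentages(c(sleep = 897, pa = 23, media = 143, school = 50,
#'                    hobbies = 61, domestic = 266))
#' @export
part_percentages <- function(x, digits = 0, total = DAY_MINUTES) {
  round(100 * x / total, digits)
}

# ---- ILR bases and transforms ------------------------------------------

#' Pivot (sequential binary partition) ILR basis
#'
#' Builds the orthonormal D x (D-1) contrast matrix of pivot coordinates:
#' coordinate j contrasts the j-th part of `pivot_order` against all later
#' parts, with normalising constant sqrt((D-j)/(D-j+1)).  Each coordinate
#' thus represents one behaviour relative to the remaining behaviours.
#'
#' @param parts Character vector of part names (length D >= 2), or a single
#'   integer D (parts are then named part1..partD).
#' @param pivot_order Permutation of `1:D` (or of the part names) giving the
#'   pivot sequence; default is the given part order.
#' @return An object of class `ilr_basis`: list with the contrast matrix `V`
#'   (rows in the original part order), `parts`, and `pivot_order`.
#' @examples
#' b <- pivot_basis(c("sleep", "pa", "media", "school", "hobbies", "domestic"))
#' crossprod(b$V)  # identity
#' @export
pivot_basis <- function(parts, pivot_order = NULL) {
  if (is.numeric(parts) && length(parts) == 1) {
    parts <- paste0("part", seq_len(parts))
  }
  D <- length(parts)
  if (D < 2) stop("an ILR basis needs at least two parts")
  if (anyDuplicated(parts)) stop("part names must be unique")
  if (is.null(pivot_order)) pivot_order <- seq_len(D)
  if (is.character(pivot_order)) pivot_order <- match(pivot_order, parts)
  if (length(pivot_order) != D || anyNA(pivot_order) ||
      !setequal(pivot_order, seq_len(D))) {
    stop("pivot_order must be a permutation of the parts")
  }
  V <- matrix(0, nrow = D, ncol = D - 1,
              dimnames = list(parts, paste0("ilr_", seq_len(D - 1))))
  for (j in seq_len(D - 1)) {
    r <- D - j
    a <- sqrt(r / (r + 1))
    V[pivot_order[j], j] <- a
    V[pivot_order[(j + 1):D], j] <- -a / r
  }
  structure(list(V = V, parts = parts, pivot_order = pivot_order),
            class = "ilr_basis")
}

#' @export
print.ilr_basis <- function(x, ...) {
  cat("Pivot ILR basis on", length(x$parts), "parts:",
      paste(x$parts[x$pivot_order], collapse = " | "), "\n")
  print(round(x$V, 4))
  invisible(x)
}

check_basis <- function(basis) {
  if (!inherits(basis, "ilr_basis")) stop("basis must be an ilr_basis object")
  basis
}

#' Isometric log-ratio transform
#'
#' Maps a strictly positive D-part composition to D-1 real coordinates,
#' `z = V' log(x)`.  Scale-invariant: `ilr(x)` equals `ilr(closure(x))`.
#'
#' @param x Named composition vector or matrix of rows; strictly positive.
#' @param basis An [pivot_basis()] object whose parts match `x`.
#' @return Numeric vector of D-1 coordinates, or matrix with one row per
#'   composition.
#' @export
ilr <- function(x, basis) {
  check_basis(basis)
  m <- as_comp_matrix(x)
  nm <- colnames(m)
  if (!is.null(nm)) {
    if (!setequal(nm, basis$parts)) {
      stop("composition parts do not match the basis parts")
    }
    m <- m[, basis$parts, drop = FALSE]
  } else if (ncol(m) != length(basis$parts)) {
    stop("composition has ", ncol(m), " parts; basis expects ",
         length(basis$parts))
  }
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("ilr requires strictly positive parts; replace zeros first")
  }
  z <- log(m) %*% basis$V
  if (is.matrix(x)) z else stats::setNames(drop(z), colnames(basis$V))
}

#' Inverse isometric log-ratio transform
#'
#' Maps D-1 ILR coordinates back to the simplex and closes to `total`
#' minutes; `ilr_inverse(ilr(x), basis)` recovers `closure(x)`.
#'
#' @param z Coordinate vector (length D-1) or matrix of coordinate rows.
#' @param basis An [pivot_basis()] object.
#' @param total Closed total, default 1440.
#' @return Named composition vector, or matrix with one row per input row.
#' @export
ilr_inverse <- function(z, basis, total = DAY_MINUTES) {
  check_basis(basis)
  zm <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  if (ncol(zm) != ncol(basis$V)) {
    stop("coordinate length ", ncol(zm), " does not match basis dimension ",
         ncol(basis$V))
  }
  if (any(!is.finite(zm))) stop("coordinates must be finite")
  lx <- zm %*% t(basis$V)
  # guard against overflow for extreme coordinates: closure is invariant to
  # a per-row shift of the log scale
  lx <- lx - apply(lx, 1, max)
  comp <- exp(lx)
  if (any(!is.finite(comp))) stop("coordinates overflow the simplex")
  colnames(comp) <- basis$parts
  out <- closure(comp, total = total)
  if (is.matrix(z)) out else stats::setNames(drop(out), basis$parts)
}
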