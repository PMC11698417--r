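# Per-class truncated signed distance supervision and the entropy-based
# adaptive weight map.

#' Boundary pixels of one class
#'
#' A pixel belongs to the boundary of class `k` when it carries label `k` and
#' has at least one 4-neighbor inside the image with a different label.
#' Image borders alone do not create boundary pixels.
#'
#' @param mask `H x W` integer label matrix (values `0 .. K-1`).
#' @param k Class index (0-based).
#' @return Two-column matrix of 1-based `(row, col)` coordinates (possibly
#'   zero rows when the class is absent or fills the image).
#' @export
boundary_pixels <- function(mask, k) {
  inside <- mask == k
  if (!any(inside)) return(matrix(integer(0), 0, 2,
                                  dimnames = list(NULL, c("row", "col"))))
  H <- nrow(mask); W <- ncol(mask)
  differs <- matrix(FALSE, H, W)
  if (H > 1) {
    differs[-H, ] <- differs[-H, ] | (mask[-H, ] != mask[-1, ])
    differs[-1, ] <- differs[-1, ] | (mask[-1, ] != mask[-H, ])
  }
  if (W > 1) {
    differs[, -W] <- differs[, -W] | (mask[, -W] != mask[, -1])
    differs[, -1] <- differs[, -1] | (mask[, -1] != mask[, -W])
  }
  idx <- which(inside & differs, arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  idx
}

#' Truncated signed distance to a class boundary
#'
#' Computes `d(x) = -min(dist(x, boundary), tau)` inside the class region and
#' `+min(dist(x, boundary), tau)` outside, with `dist` the exact Euclidean
#' distance to the nearest boundary pixel.  When the class has no boundary
#' pixels the map is the constant `+tau` (class absent) or `-tau` (class
#' fills the image).
#'
#' @inheritParams boundary_pixels
#' @param tau Truncation distance in pixels (> 0); the default 5 matches the
#'   threshold used throughout the package.
#' @return `H x W` numeric matrix.
#' @export
signed_distance <- function(mask, k, tau = 5) {
  if (tau <= 0) stop("tau must be > 0")
  bp <- boundary_pixels(mask, k)
  inside <- mask == k
  if (nrow(bp) == 0) {
    return(matrix(if (any(inside)) -tau else tau, nrow(mask), ncol(mask)))
  }
  sites <- matrix(0, nrow(mask), ncol(mask))
  sites[bp] <- 1
  d <- .edt(sites)
  d <- pmin(d, tau)
  d[inside] <- -d[inside]
  d
}

#' Normalize a signed-distance map to the unit interval around zero
#'
#' Divides by the maximum absolute value over the whole image; an all-zero
#' input returns all zeros.
#'
#' @param sd Numeric matrix (finite).
#' @return Matrix of the same shape with values in `[-1, 1]`.
#' @export
normalize_sd <- function(sd) {
  m <- max(abs(sd))
  if (m == 0) return(sd * 0)
  sd / m
}

#' Per-class normalized TSDF stack
#'
#' Stacks [signed_distance()] followed by [normalize_sd()] for every class
#' `0 .. K-1`.
#'
#' @inheritParams signed_distance
#' @param K Number of classes; all mask values must be `< K`.
#' @return `H x W x K` numeric array with values in `[-1, 1]` (class `k` in
#'   slice `k + 1`).
#' @export
tsdf_stack <- function(mask, K, tau = 5) {
  if (any(mask >= K)) stop("mask contains values >= K")
  out <- array(0, c(nrow(mask), ncol(mask), K))
  for (k in seq_len(K) - 1L) {
    out[, , k + 1L] <- normalize_sd(signed_distance(mask, k, tau))
  }
  out
}

#' Largest and second-largest channel values per pixel
#'
#' @param stack `H x W x K` array (`K >= 2`), typically a TSDF stack or the
#'   boundary branch's prediction.
#' @return List with `dmax1` and `dmax2` (`H x W` matrices); ties resolve to
#'   the lowest class index so `dmax1 = dmax2` where two channels tie.
#' @export
top2 <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] < 2) stop("stack must be H x W x K with K >= 2")
  K <- d[3]
  m <- matrix(stack, d[1] * d[2], K)
  k1 <- max.col(m, ties.method = "first")
  dmax1 <- m[cbind(seq_len(nrow(m)), k1)]
  m[cbind(seq_len(nrow(m)), k1)] <- -Inf
  dmax2 <- do.call(pmax, lapply(seq_len(K), function(k) m[, k]))
  list(dmax1 = matrix(dmax1, d[1], d[2]), dmax2 = matrix(dmax2, d[1], d[2]))
}

#' Adaptive entropy weight map
#'
#' Converts the two largest TSDF channel values into a two-way softmax
#' probability and returns the base-2 information entropy: the weight is 1
#' exactly where the two values tie (boundaries and ambiguous regions) and
#' decreases monotonically as their gap grows.
#'
#' @param dmax1,dmax2 Matrices from [top2()] (`dmax1 >= dmax2` elementwise).
#' @return Matrix of weights in `(0, 1]`.
#' @export
entropy_weight <- function(dmax1, dmax2) {
  p1 <- 1 / (1 + exp(-(dmax1 - dmax2)))
  p2 <- 1 - p1
  h <- -(p1 * log(pmax(p1, .Machine$double.xmin)) +
           p2 * log(pmax(p2, .Machine$double.xmin))) / log(2)
  pmin(h, 1)
}

#' Weight map for a TSDF stack
#'
#' Convenience wrapper: [top2()] then [entropy_weight()].
#'
#' @inheritParams top2
#' @return `H x W` weight matrix in `(0, 1]`.
#' @export
tsdf_weight_map <- function(stack) {
  t2 <- top2(stack)
  entropy_weight(t2$dmax1, t2$dmax2)
}
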