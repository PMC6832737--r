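## Binary-image primitives: connected-component labeling (4- or
## 8-connectivity, run-based union-find) and separable box dilation.
## Implemented here because no installed package labels plain matrices under
## a configurable connectivity (EBImage::bwlabel is 4-connected only); the
## EBImage implementation serves as an independent oracle in the test suite.

#' Label connected components of a binary mask
#'
#' @param mask Logical (or 0/1) matrix; `TRUE` pixels are foreground.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return Integer matrix of the same shape: 0 for background, 1..K for the
#'   K components (labels in column-major discovery order).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  m <- mask > 0
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  if (!any(m)) return(lab)

  # vertical runs of foreground within each column
  prev <- rbind(FALSE, m[-h, , drop = FALSE])
  nxt <- rbind(m[-1, , drop = FALSE], FALSE)
  starts <- which(m & !prev)         # linear indices, column-major
  ends <- which(m & !nxt)
  nr <- length(starts)
  run_col <- ((starts - 1L) %/% h) + 1L
  run_s <- ((starts - 1L) %% h) + 1L
  run_e <- ((ends - 1L) %% h) + 1L

  parent <- seq_len(nr)
  uf_find <- function(i) {            # path-halving find on `parent`
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  tol <- if (connectivity == 8L) 1L else 0L
  runs_by_col <- split(seq_len(nr), run_col)
  cols_present <- as.integer(names(runs_by_col))
  for (ci in seq_along(cols_present)[-1]) {
    if (cols_present[ci] - cols_present[ci - 1L] != 1L) next
    left <- runs_by_col[[ci - 1L]]; right <- runs_by_col[[ci]]
    ls <- run_s[left]; le <- run_e[left]
    for (j in right) {
      lo <- findInterval(run_s[j] - tol - 0.5, le) + 1L
      hi <- findInterval(run_e[j] + tol + 0.5, ls)
      if (hi >= lo) for (i in lo:hi) {
        a <- uf_find(left[i]); b <- uf_find(j)
        if (a != b) parent[b] <- a
      }
    }
  }
  root <- vapply(seq_len(nr), uf_find, integer(1))
  comp <- match(root, unique(root[order(starts)]))
  # paint runs
  lens <- run_e - run_s + 1L
  idx <- sequence(lens) - 1L + rep(starts, lens)
  lab[idx] <- rep(comp, lens)
  lab
}

# running-window OR along rows: out[i,] = any(mask[(i-a)..(i+b),])
window_or_rows <- function(m, a, b) {
  h <- nrow(m)
  cs <- apply(m, 2, cumsum)
  if (h == 1L) cs <- matrix(cs, 1L)
  cs0 <- rbind(0, cs)
  hi <- pmin(seq_len(h) + b, h)
  lo <- pmax(seq_len(h) - a - 1L, 0L)
  (cs0[hi + 1L, , drop = FALSE] - cs0[lo + 1L, , drop = FALSE]) > 0
}

#' Dilate a binary mask with a square structuring element
#'
#' Square k x k box dilation, computed separably with running-window sums.
#' For even k the element is anchored to cover offsets `-(k/2 - 1) .. k/2`
#' in each axis (an even box has no centre pixel); for odd k it is centred.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param size Side length k of the square element, pixels (>= 1).
#' @return Logical matrix of the same shape.
#' @export
dilate_square <- function(mask, size = 10L) {
  stopifnot(is.matrix(mask))
  size <- as.integer(size)
  if (size < 1L) stop("size must be >= 1")
  a <- size %/% 2L
  b <- (size - 1L) %/% 2L
  m <- mask > 0
  t(window_or_rows(t(window_or_rows(m, a, b)), a, b))
}
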