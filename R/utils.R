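#' Label connected components of a binary mask
#'
#' Connected-component labelling for 2D or 3D logical masks via an adjacency
#' graph (8-connectivity in 2D, 26-connectivity in 3D by default; pass
#' `connectivity = 4` / `6` for face-only adjacency).
#'
#' @param mask logical matrix or 3D array
#' @param connectivity 8 or 4 (2D); 26 or 6 (3D)
#' @return Integer array of the same shape: 0 = background, components
#'   labelled 1..k in decreasing size order (ties broken by first voxel).
#' @export
labelComponents <- function(mask, connectivity = if (length(dim(mask)) == 2L) 8L else 26L) {
  d <- dim(mask)
  if (is.null(d)) stop("'mask' must be a matrix or 3D array")
  two_d <- length(d) == 2L
  if (two_d) d <- c(d, 1L)
  storage.mode(mask) <- "logical"
  idx <- which(mask)
  lab <- array(0L, dim(mask))
  if (length(idx) == 0L) return(lab)

  full <- if (two_d) connectivity %in% c(8L, 26L) else connectivity %in% c(26L, 8L)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1,
                                dk = if (two_d) 0L else -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  if (!full) offs <- offs[rowSums(abs(offs)) == 1L, , drop = FALSE]
  # one of each +/- pair is enough for an undirected graph
  keep <- offs[, 1L] > 0L | (offs[, 1L] == 0L & offs[, 2L] > 0L) |
    (offs[, 1L] == 0L & offs[, 2L] == 0L & offs[, 3L] > 0L)
  offs <- offs[keep, , drop = FALSE]

  rank <- integer(prod(d))
  rank[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    ni <- co[, 1L] + offs[r, 1L]
    nj <- co[, 2L] + offs[r, 2L]
    nk <- co[, 3L] + offs[r, 3L]
    ok <- ni >= 1L & ni <= d[1L] & nj >= 1L & nj <= d[2L] & nk >= 1L & nk <= d[3L]
    nlin <- (nk[ok] - 1L) * d[1L] * d[2L] + (nj[ok] - 1L) * d[1L] + ni[ok]
    nr <- rank[nlin]
    src <- rank[idx[ok]][nr > 0L]
    edges[[r]] <- rbind(src, nr[nr > 0L])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(em) && ncol(em) > 0L)
    g <- igraph::add_edges(g, as.vector(em))
  memb <- igraph::components(g)$membership
  # relabel in decreasing size order
  sizes <- tabulate(memb)
  ord <- order(sizes, decreasing = TRUE)
  relab <- integer(length(sizes))
  relab[ord] <- seq_along(ord)
  lab[idx] <- relab[memb]
  lab
}

#' Remove small connected components
#'
#' @param mask logical matrix or 3D array
#' @param minPixels components with fewer connected pixels than this are
#'   deleted (strict: a component of exactly `minPixels` is kept)
#' @param connectivity passed to [labelComponents()]
#' @return logical array of the same shape
#' @export
removeSmallComponents <- function(mask, minPixels,
                                  connectivity = if (length(dim(mask)) == 2L) 8L else 26L) {
  lab <- labelComponents(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minPixels)
  array(lab %in% keep, dim(mask))
}

# Windowed box sum of a matrix via 2D cumulative sums (zero-padded borders).
boxSum <- function(x, window) {
  stopifnot(window %% 2L == 1L)
  h <- (window - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  cs <- apply(apply(x, 2L, cumsum), 1L, cumsum)  # transposed double cumsum
  cs <- t(cs)
  # pad with a leading zero row/col for clean differencing
  P <- matrix(0, nr + 1L, nc + 1L)
  P[-1L, -1L] <- cs
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  P[r2 + 1L, c2 + 1L, drop = FALSE] - P[r1, c2 + 1L, drop = FALSE] -
    P[r2 + 1L, c1, drop = FALSE] + P[r1, c1, drop = FALSE]
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# cm^2 x mm -> uL (1 cm^2 x 1 mm = 100 mm^3 = 100 uL)
cm2mm_to_ul <- function(area_cm2, step_mm) 100 * area_cm2 * step_mm

# um/px -> cm^2 per pixel
pixelAreaCm2 <- function(pixelSizeUm) (pixelSizeUm * 1e-4)^2
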