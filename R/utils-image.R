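#' Otsu threshold of a numeric sample
#'
#' Classical histogram-based Otsu threshold: the cut maximising the
#' between-class variance of the two resulting classes.  Used to separate
#' hematoxylin-dark nuclei from eosin-stained tissue and tissue from the
#' near-white slide background.
#'
#' @param x numeric vector of luminance values (any range; binned internally).
#' @param n_bins number of histogram bins.
#' @return the threshold value; values `<= threshold` form the dark class.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0) {
    stop("otsu_threshold: degenerate input (constant or empty)")
  }
  rng <- range(x)
  h <- tabulate(
    pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins)),
    nbins = n_bins
  )
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[n_bins]
  # between-class variance for every candidate cut
  bcv <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv)
  rng[1] + k / n_bins * diff(rng)
}

#' Luminance class decomposition of an H&E image
#'
#' H&E luminance is (up to) trimodal: dark nuclei, mid-bright eosin tissue
#' and a near-white background.  A single Otsu split lands between the
#' nuclei and everything else when nuclei are present, so the
#' tissue/background cut is found by a second Otsu pass restricted to the
#' non-nuclear class.  When no distinctly dark class exists the first split
#' already is the tissue/background cut.
#'
#' @param values numeric vector or matrix of luminance values (0-255).
#' @return list with `thr_dark` (nuclei cut, `NA` if no dark class),
#'   `thr_bg` (tissue/background cut), and class means `mu_nuclei`,
#'   `mu_tissue`, `mu_bg`.
#' @export
luminance_classes <- function(values) {
  v <- as.numeric(values)
  t1 <- otsu_threshold(v)
  lo <- v[v <= t1]
  hi <- v[v > t1]
  if (length(lo) && length(hi) && mean(lo) < 0.6 * mean(hi)) {
    # dark nuclear class present; split the bright remainder again
    thr_dark <- t1
    thr_bg <- if (diff(range(hi)) > 0) otsu_threshold(hi) else t1
    tis <- hi[hi <= thr_bg]
    bg <- hi[hi > thr_bg]
    list(
      thr_dark = thr_dark, thr_bg = thr_bg,
      mu_nuclei = mean(lo),
      mu_tissue = if (length(tis)) mean(tis) else NA_real_,
      mu_bg = if (length(bg)) mean(bg) else NA_real_
    )
  } else {
    list(
      thr_dark = NA_real_, thr_bg = t1,
      mu_nuclei = NA_real_,
      mu_tissue = if (length(lo)) mean(lo) else NA_real_,
      mu_bg = if (length(hi)) mean(hi) else NA_real_
    )
  }
}

# integer (dy, dx) offsets of a filled disk of pixel radius r
disk_offsets <- function(r) {
  r <- max(0L, as.integer(round(r)))
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2 + 1e-9, , drop = FALSE]
}

shift_matrix <- function(m, dy, dx, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dy):min(nr, nr + dy)
  cs <- max(1, 1 + dx):min(nc, nc + dx)
  out[rs, cs] <- m[rs - dy, cs - dx]
  out
}

binary_dilate <- function(mask, r) {
  off <- disk_offsets(r)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_matrix(mask, off$dy[i], off$dx[i])
  }
  out
}

binary_erode <- function(mask, r) !binary_dilate(!mask, r)

# closing bridges gaps narrower than ~2r while leaving wider tears intact
binary_close <- function(mask, r) {
  if (r <= 0) return(mask)
  binary_erode(binary_dilate(mask, r), r)
}

#' Label 4-connected components of a binary mask
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 outside the mask, components
#'   numbered in decreasing size order (1 = largest).
#' @export
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  id_of <- integer(length(mask))
  id_of[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  right <- idx[co < ncol(mask) & mask[pmin(idx + nr, length(mask))]]
  down <- idx[r < nr & mask[idx + 1L]]
  edges <- rbind(
    cbind(id_of[right], id_of[right + nr]),
    cbind(id_of[down], id_of[down + 1L])
  )
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  relabel <- integer(length(sizes))
  relabel[order(sizes, decreasing = TRUE)] <- seq_along(sizes)
  lab[idx] <- relabel[memb]
  lab
}

# run-length style extraction of maximal TRUE runs; returns matrix [start, end]
flag_runs <- function(flag) {
  if (!length(flag) || !any(flag)) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  d <- diff(c(FALSE, flag, FALSE))
  cbind(start = which(d == 1L), end = which(d == -1L) - 1L)
}

# preserve caller's RNG state while running seeded generator code
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_field <- function(field, why) {
  stop(sprintf("invalid field '%s': %s", field, why), call. = FALSE)
}
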