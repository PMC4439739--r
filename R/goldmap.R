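#' Construct a micrograph annotation
#'
#' Bundles the manual annotations of one (or a pooled set of) electron
#' micrograph(s): immunogold particle positions, cristae-junction (CJ)
#' points and cristae-membrane polylines, all in the image plane. Pixel
#' coordinates are converted to nanometres with `scale`.
#'
#' @param particles Two-column matrix (or data frame) of gold-particle
#'   coordinates.
#' @param cj_points Two-column matrix of CJ coordinates.
#' @param cristae List of two-column matrices, each a polyline (>= 2
#'   vertices) tracing a cristae membrane.
#' @param scale Nanometres per pixel (> 0); applied when `units = "px"`.
#' @param units Units of the supplied coordinates, `"nm"` (default) or
#'   `"px"`.
#' @return A `micrograph_annotation` object with all coordinates in nm.
#' @export
micrograph_annotation <- function(particles, cj_points, cristae,
                                  scale = 1, units = c("nm", "px")) {
  units <- match.arg(units)
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  as_xy <- function(x, what) {
    m <- as.matrix(x)
    if (length(m) == 0) m <- matrix(numeric(0), ncol = 2)
    if (ncol(m) != 2) stop(what, " must have two coordinate columns", call. = FALSE)
    storage.mode(m) <- "double"
    unname(m)
  }
  particles <- as_xy(particles, "particles")
  cj_points <- as_xy(cj_points, "cj_points")
  cristae <- lapply(cristae, as_xy, what = "cristae polylines")
  if (any(vapply(cristae, nrow, integer(1)) < 2)) {
    stop("each cristae polyline needs at least 2 vertices", call. = FALSE)
  }
  if (units == "px") {
    particles <- particles * scale
    cj_points <- cj_points * scale
    cristae <- lapply(cristae, function(m) m * scale)
  }
  structure(list(scale = scale, particles = particles, cj_points = cj_points,
                 cristae = cristae),
            class = "micrograph_annotation")
}

#' Read a micrograph annotation from JSON
#'
#' Expected fields: `scale_nm_per_px`, `particles`, `cj_points`, `cristae`
#' (arrays of `[x, y]` pairs; `cristae` an array of such arrays) and
#' optionally `units` (`"nm"`, the default, or `"px"`).
#'
#' @param path JSON file path.
#' @return A [micrograph_annotation()].
#' @export
read_goldmap_annotation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_mat <- function(x) {
    if (is.null(x) || length(x) == 0) return(matrix(numeric(0), ncol = 2))
    if (is.list(x)) x <- do.call(rbind, x)
    as.matrix(x)
  }
  cristae <- j$cristae
  if (is.array(cristae) && length(dim(cristae)) == 3) {
    # equal-length polylines simplify to one 3-d array; split back per polyline
    cristae <- lapply(seq_len(dim(cristae)[1]), function(i) cristae[i, , ])
  } else if (is.data.frame(cristae) || is.matrix(cristae)) {
    cristae <- list(cristae)
  }
  micrograph_annotation(
    particles = to_mat(j$particles),
    cj_points = to_mat(j$cj_points),
    cristae = lapply(cristae, to_mat),
    scale = j$scale_nm_per_px %||% 1,
    units = j$units %||% "nm"
  )
}

#' Distance from each gold particle to its nearest cristae junction
#'
#' Straight-line Euclidean distance in the micrograph plane, in nm; output
#' order matches particle order.
#'
#' @param annotation A [micrograph_annotation()] with at least one particle
#'   and one CJ point.
#' @return Numeric vector of distances (nm).
#' @export
nearest_cj_distance <- function(annotation) {
  stopifnot(inherits(annotation, "micrograph_annotation"))
  p <- annotation$particles
  cj <- annotation$cj_points
  if (nrow(cj) == 0) stop("no cristae-junction points annotated", call. = FALSE)
  if (nrow(p) == 0) stop("no gold particles annotated", call. = FALSE)
  nearest_point_distance(p, cj)
}

nearest_point_distance <- function(p, q) {
  d2 <- outer(p[, 1], q[, 1], "-")^2 + outer(p[, 2], q[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Fraction-per-bin histogram of CJ distances
#'
#' Half-open bins `[0, w)`, `[w, 2w)`, ... of width `w = bin_width`; the
#' last bin (the one containing the maximum distance) is open-ended.
#' Fractions are counts over the number of particles and sum to 1.
#'
#' @param distances Non-empty numeric vector of distances (nm, >= 0).
#' @param bin_width Bin width in nm (default 50).
#' @return A `distance_histogram` object: list with `bin_width`,
#'   `bin_edges` (left edges, last bin extends to `Inf`), `counts`,
#'   `fractions`, `n_particles`.
#' @examples
#' h <- distance_histogram(c(10, 60, 110, 140))
#' h$fractions  # 0.25 0.25 0.50
#' @export
distance_histogram <- function(distances, bin_width = 50) {
  if (length(distances) == 0) stop("no distances supplied", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  if (any(distances < 0)) stop("distances must be non-negative", call. = FALSE)
  n_bins <- floor(max(distances) / bin_width) + 1L
  bin <- pmin(floor(distances / bin_width) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  structure(
    list(bin_width = bin_width,
         bin_edges = (seq_len(n_bins) - 1) * bin_width,
         counts = counts,
         fractions = counts / length(distances),
         n_particles = length(distances)),
    class = "distance_histogram"
  )
}

#' Monte-Carlo test of gold-particle enrichment near cristae junctions
#'
#' Tests whether the observed particles sit closer to CJs than expected if
#' the label were spread uniformly along the annotated cristae membranes —
#' the natural null for a membrane-associated protein with no CJ
#' preference. Each null draw places the same number of particles uniformly
#' by arc length along the cristae polylines and recomputes the summary
#' statistic; the one-sided p-value for the CJ-proximity (small-distance)
#' alternative is `(1 + #{null <= observed}) / (1 + n_draws)`.
#'
#' @param annotation A [micrograph_annotation()] with particles, CJ points
#'   and non-degenerate cristae polylines.
#' @param statistic Function reducing a vector of nearest-CJ distances to
#'   one number (default `mean`); smaller values must indicate stronger CJ
#'   proximity.
#' @param n_draws Number of null draws (default 9999).
#' @param seed Optional integer; fixing it makes the test deterministic.
#' @return List with `observed`, `p_value`, `null_quantile` (fraction of
#'   null draws below the observed statistic), `null_stats` and `n_draws`.
#' @export
enrichment_test <- function(annotation, statistic = mean, n_draws = 9999,
                            seed = NULL) {
  stopifnot(inherits(annotation, "micrograph_annotation"))
  if (length(annotation$cristae) == 0) {
    stop("cristae polylines are required to define the null support", call. = FALSE)
  }
  lens <- vapply(annotation$cristae, polyline_length, numeric(1))
  if (sum(lens) <= 0) stop("total cristae polyline length is zero", call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  obs <- statistic(nearest_cj_distance(annotation))
  n <- nrow(annotation$particles)
  null_stats <- vapply(seq_len(n_draws), function(i) {
    pts <- sample_on_paths(annotation$cristae, n)
    statistic(nearest_point_distance(pts, annotation$cj_points))
  }, numeric(1))
  list(observed = obs,
       p_value = (1 + sum(null_stats <= obs)) / (1 + n_draws),
       null_quantile = mean(null_stats < obs),
       null_stats = null_stats,
       n_draws = n_draws)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- polyline helpers -------------------------------------------------------

polyline_length <- function(path) {
  sum(sqrt(rowSums(diff(path)^2)))
}

# point on a polyline at arc length s (clamped to [0, L])
point_at_arc <- function(path, s) {
  seg <- diff(path)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(seg))
  t <- ifelse(seg_len[i] > 0, (s - cum[i]) / seg_len[i], 0)
  path[i, , drop = FALSE] + seg[i, , drop = FALSE] * t
}

# n points uniform by arc length over a list of polylines
sample_on_paths <- function(paths, n) {
  lens <- vapply(paths, polyline_length, numeric(1))
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  which_path <- sample.int(length(paths), n, replace = TRUE, prob = lens)
  s <- runif(n) * lens[which_path]
  out <- matrix(NA_real_, n, 2)
  for (p in unique(which_path)) {
    sel <- which_path == p
    out[sel, ] <- point_at_arc(paths[[p]], s[sel])
  }
  out
}

# reflect an arc coordinate into [0, L] (triangle fold)
reflect_arc <- function(s, L) {
  s <- abs(s) %% (2 * L)
  ifelse(s > L, 2 * L - s, s)
}
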