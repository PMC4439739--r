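#' Score bait-prey interactions against a multi-bait background
#'
#' CompPASS-style scoring. For prey `j` across a panel of `k` baits, with
#' `X[i, j]` the APSM of prey `j` in bait `i` and `p[i, j]` the number of
#' technical replicates detecting it:
#'
#' * `f_j` — number of baits in which the prey was detected,
#' * `x_bar_j`, `sigma_j` — mean and sample standard deviation of the full
#'   column, zeros included,
#' * `omega_j = max(1, sigma_j / x_bar_j)` — variability weight, so preys
#'   whose abundance varies strongly across the panel score higher,
#' * `WD[i, j] = sqrt( X[i, j] * ((k / f_j) * omega_j) ^ p[i, j] )`,
#' * `Z[i, j] = (X[i, j] - x_bar_j) / sigma_j` (0 where `sigma_j` = 0),
#' * `NWD = WD / q`, where `q` is the `normalization_percentile`-th
#'   percentile of all positive WD scores, so that NWD = 1 marks the chosen
#'   high quantile of the score distribution.
#'
#' One row is emitted per detected (bait, prey) pair; pairs with zero APSM
#' produce no row. Output row order is bait then prey, lexicographic, so the
#' result is invariant to the ordering of the input table.
#'
#' @param table A [stats_table()] with at least two baits and one detection.
#' @param normalization_percentile Percentile of positive WD scores mapped to
#'   NWD = 1 (default 98).
#'
#' @return A tibble with columns `bait`, `prey`, `X`, `f`, `p`, `omega`, `Z`,
#'   `WD`, `NWD` and `cell_line`.
#' @examples
#' X <- matrix(0, 4, 1, dimnames = list(paste0("B", 1:4), "P"))
#' X[1, 1] <- 9
#' P <- (X > 0) * 2L
#' score_interactions(stats_table(X, P))$WD  # 24
#' @export
score_interactions <- function(table, normalization_percentile = 98) {
  stopifnot(inherits(table, "stats_table"))
  X <- table$apsm
  P <- table$detections
  k <- nrow(X)
  if (k < 2) {
    stop("scoring needs a stats table with k >= 2 baits (background model undefined)",
         call. = FALSE)
  }
  if (!any(X > 0)) stop("stats table has no detections to score", call. = FALSE)
  if (normalization_percentile <= 0 || normalization_percentile >= 100) {
    stop("normalization_percentile must lie in (0, 100)", call. = FALSE)
  }

  col_mean <- colMeans(X)
  col_sd <- apply(X, 2, sd)
  f <- colSums(X > 0)
  omega <- ifelse(col_mean > 0, pmax(1, col_sd / col_mean), 1)

  idx <- which(X > 0, arr.ind = TRUE)
  j <- idx[, 2]
  x <- X[idx]
  p <- P[idx]
  wd <- sqrt(x * ((k / f[j]) * omega[j])^p)
  z <- ifelse(col_sd[j] > 0, (x - col_mean[j]) / col_sd[j], 0)
  q <- quantile(wd[wd > 0], normalization_percentile / 100, names = FALSE, type = 7)

  out <- tibble::tibble(
    bait = rownames(X)[idx[, 1]],
    prey = colnames(X)[j],
    X = unname(x),
    f = unname(as.integer(f[j])),
    p = unname(as.integer(p)),
    omega = unname(omega[j]),
    Z = unname(z),
    WD = unname(wd),
    NWD = unname(wd / q),
    cell_line = table$cell_line
  )
  dplyr::arrange(out, .data$bait, .data$prey)
}

#' Filter scored interactions to high-confidence interacting proteins
#'
#' A scored pair is a high-confidence interacting protein (HCIP) when its
#' NWD score strictly exceeds `nwd_threshold`, its APSM is at least
#' `min_apsm`, and (if a membership list is supplied) the prey is on the
#' list. This mirrors the usual HCIP definition: NWD > 1, restriction to
#' mitochondrial proteins via MitoCarta, and a minimum of 2 APSM for panels
#' where low single-spectrum identifications are untrusted.
#'
#' @param scores Tibble from [score_interactions()].
#' @param nwd_threshold Strict lower bound on NWD (default 1).
#' @param min_apsm Minimum APSM, inclusive (default 0; use 2 to require two
#'   or more average spectral matches).
#' @param membership Optional character vector of allowed prey identifiers
#'   (e.g. from [read_membership()]); `NULL` disables the filter.
#' @param keep_all If `TRUE`, return all rows with the `is_hcip` flag set;
#'   if `FALSE` (default), return only the retained rows (input order
#'   preserved), still carrying `is_hcip = TRUE`.
#'
#' @return A tibble like `scores` with an added logical column `is_hcip`.
#' @export
filter_hcips <- function(scores, nwd_threshold = 1, min_apsm = 0,
                         membership = NULL, keep_all = FALSE) {
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) == 0) {
    scores$is_hcip <- logical(0)
    return(scores)
  }
  keep <- scores$NWD > nwd_threshold & scores$X >= min_apsm
  if (!is.null(membership)) keep <- keep & scores$prey %in% membership
  scores$is_hcip <- keep
  if (keep_all) scores else scores[keep, , drop = FALSE]
}
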