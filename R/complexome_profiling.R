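#' Calibrate BN-PAGE gel slices to molecular mass
#'
#' A blue-native PAGE lane cut into `n_slices` pieces is calibrated by
#' assigning each slice an equal span in log10 molecular mass between
#' `mass_top` (slice 1, the highest masses) and `mass_bottom` (the last
#' slice). Defaults mirror a 20-slice lane spanning roughly 1 MDa down to
#' 60 kDa.
#'
#' @param n_slices Number of gel slices (>= 2; default 20).
#' @param mass_top Mass at the top edge of slice 1, kDa (default 1000).
#' @param mass_bottom Mass at the bottom edge of the last slice, kDa
#'   (default 60).
#' @return A `fraction_calibration` object with the log10-mass slice edges
#'   (decreasing) and centres.
#' @export
calibrate_fractions <- function(n_slices = 20, mass_top = 1000, mass_bottom = 60) {
  if (n_slices < 2) stop("n_slices must be >= 2", call. = FALSE)
  if (mass_top <= 0 || mass_bottom <= 0) stop("masses must be positive", call. = FALSE)
  if (mass_top <= mass_bottom) stop("mass_top must exceed mass_bottom", call. = FALSE)
  edges <- seq(log10(mass_top), log10(mass_bottom), length.out = n_slices + 1)
  structure(
    list(n_slices = as.integer(n_slices), mass_top = mass_top,
         mass_bottom = mass_bottom, log10_edges = edges,
         log10_centers = (edges[-1] + edges[-(n_slices + 1)]) / 2,
         step = (log10(mass_top) - log10(mass_bottom)) / n_slices),
    class = "fraction_calibration"
  )
}

#' Map a molecular mass to its gel slice
#'
#' Each slice covers the half-open mass interval from its upper edge
#' (inclusive) down to its lower edge (exclusive). Masses above `mass_top`
#' clamp to slice 1 and masses at or below `mass_bottom` clamp to the last
#' slice; the returned vector carries a logical `clamped` attribute marking
#' out-of-range inputs.
#'
#' @param cal A [calibrate_fractions()] object.
#' @param mass Numeric vector of masses in kDa (positive).
#' @return Integer slice indices (1-based) with attribute `clamped`.
#' @examples
#' cal <- calibrate_fractions()
#' mass_to_slice(cal, c(1000, 700, 10))  # 1, 3, 20 (clamped)
#' @export
mass_to_slice <- function(cal, mass) {
  stopifnot(inherits(cal, "fraction_calibration"))
  if (any(mass <= 0)) stop("mass must be positive", call. = FALSE)
  pos <- (log10(cal$mass_top) - log10(mass)) / cal$step
  slice <- floor(pos) + 1L
  clamped <- mass > cal$mass_top | mass <= cal$mass_bottom
  slice[mass > cal$mass_top] <- 1L
  slice[slice > cal$n_slices | mass <= cal$mass_bottom] <- cal$n_slices
  slice[slice < 1L] <- 1L
  structure(as.integer(slice), clamped = clamped)
}

#' Per-fraction heavy:light ratios for each protein
#'
#' For every protein and gel slice the heavy:light ratio is the quotient of
#' the summed heavy and summed light peptide intensities in that slice
#' (`method = "sum"`, the default), or the median of the individual peptide
#' ratios (`method = "median"`). Cells where both channels are absent are
#' missing; cells with heavy signal but zero light are capped at `cap` and
#' flagged, so downstream log-ratio means stay finite.
#'
#' @param quants Data frame of peptide-level quantifications with columns
#'   `peptide`, `protein`, `fraction` (1-based slice index),
#'   `heavy_intensity`, `light_intensity` (both >= 0).
#' @param cal A [calibrate_fractions()] object; fractions must lie within
#'   its range.
#' @param method `"sum"` or `"median"`.
#' @param cap Ratio assigned to heavy-only cells (default 100); the
#'   symmetric floor `1/cap` is applied when taking log ratios.
#' @return A `complexome_profile`: list with `ratios` (protein x slice
#'   matrix, `NA` where unquantified), `capped` (logical matrix),
#'   `total_ratio` (named vector, summed-over-all-fractions H:L per
#'   protein), `proteins`, `calibration`, `cap`, `method`.
#' @export
protein_fraction_ratios <- function(quants, cal = calibrate_fractions(),
                                    method = c("sum", "median"), cap = 100) {
  method <- match.arg(method)
  quants <- validate_quants(quants, cal)
  proteins <- unique(quants$protein)

  ratios <- matrix(NA_real_, length(proteins), cal$n_slices,
                   dimnames = list(proteins, NULL))
  capped <- matrix(FALSE, length(proteins), cal$n_slices,
                   dimnames = list(proteins, NULL))

  if (method == "sum") {
    cell <- quants |>
      dplyr::group_by(.data$protein, .data$fraction) |>
      dplyr::summarise(h = sum(.data$heavy_intensity),
                       l = sum(.data$light_intensity), .groups = "drop")
  } else {
    cell <- quants |>
      dplyr::group_by(.data$protein, .data$peptide, .data$fraction) |>
      dplyr::summarise(h = sum(.data$heavy_intensity),
                       l = sum(.data$light_intensity), .groups = "drop") |>
      dplyr::filter(.data$h > 0 | .data$l > 0) |>
      dplyr::mutate(pep_ratio = ifelse(.data$l > 0, .data$h / .data$l, cap)) |>
      dplyr::group_by(.data$protein, .data$fraction) |>
      dplyr::summarise(h = sum(.data$h), l = sum(.data$l),
                       med = median(.data$pep_ratio), .groups = "drop")
  }
  cell <- dplyr::filter(cell, .data$h > 0 | .data$l > 0)
  ij <- cbind(match(cell$protein, proteins), cell$fraction)
  if (method == "sum") {
    ratios[ij] <- ifelse(cell$l > 0, cell$h / cell$l, cap)
  } else {
    ratios[ij] <- pmin(cell$med, cap)
  }
  capped[ij] <- cell$l == 0

  totals <- quants |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(h = sum(.data$heavy_intensity),
                     l = sum(.data$light_intensity), .groups = "drop") |>
    dplyr::filter(.data$h > 0 | .data$l > 0)
  total_ratio <- setNames(rep(NA_real_, length(proteins)), proteins)
  total_ratio[totals$protein] <- ifelse(totals$l > 0, totals$h / totals$l, cap)

  structure(list(ratios = ratios, capped = capped, total_ratio = total_ratio,
                 proteins = proteins, calibration = cal, cap = cap,
                 method = method),
            class = "complexome_profile")
}

validate_quants <- function(quants, cal) {
  quants <- tibble::as_tibble(quants)
  req <- c("peptide", "protein", "fraction", "heavy_intensity", "light_intensity")
  miss <- setdiff(req, names(quants))
  if (length(miss)) {
    stop("quants is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(quants) == 0) stop("quants is empty", call. = FALSE)
  if (any(quants$heavy_intensity < 0) || any(quants$light_intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (any(quants$fraction < 1 | quants$fraction > cal$n_slices)) {
    stop("fraction indices outside the calibration range", call. = FALSE)
  }
  quants$fraction <- as.integer(quants$fraction)
  quants
}

#' Total-abundance heavy:light ratios across all fractions
#'
#' Sums each peptide's heavy and light intensities over all gel slices and
#' reports the per-peptide ratio distribution together with the
#' protein-level quotient of summed intensities — the overall change in a
#' protein's abundance irrespective of its migration.
#'
#' @inheritParams protein_fraction_ratios
#' @return A list with tibbles `per_peptide` (`protein`, `peptide`,
#'   `heavy_total`, `light_total`, `ratio`, `capped`) and `per_protein`
#'   (`protein`, `heavy_total`, `light_total`, `ratio`, `capped`).
#' @export
total_abundance_ratios <- function(quants, cap = 100) {
  quants <- tibble::as_tibble(quants)
  if (nrow(quants) == 0) stop("quants is empty", call. = FALSE)
  per_peptide <- quants |>
    dplyr::group_by(.data$protein, .data$peptide) |>
    dplyr::summarise(heavy_total = sum(.data$heavy_intensity),
                     light_total = sum(.data$light_intensity), .groups = "drop") |>
    dplyr::mutate(ratio = ifelse(.data$light_total > 0,
                                 .data$heavy_total / .data$light_total,
                                 ifelse(.data$heavy_total > 0, cap, NA_real_)),
                  capped = .data$light_total == 0 & .data$heavy_total > 0)
  per_protein <- quants |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(heavy_total = sum(.data$heavy_intensity),
                     light_total = sum(.data$light_intensity), .groups = "drop") |>
    dplyr::mutate(ratio = ifelse(.data$light_total > 0,
                                 .data$heavy_total / .data$light_total,
                                 ifelse(.data$heavy_total > 0, cap, NA_real_)),
                  capped = .data$light_total == 0 & .data$heavy_total > 0)
  list(per_peptide = per_peptide, per_protein = per_protein)
}

#' Detect complex-disassembly shifts from a complexome profile
#'
#' Compares each protein's mean log2 heavy:light ratio in two mass windows:
#' around the mature complex (`mature_mass`, default 700 kDa) and around a
#' putative sub-complex (`sub_mass`, default 500 kDa). Windows span
#' `window` slices either side of the slice containing the window mass;
#' slices belonging to the mature window are excluded from the sub-complex
#' window so the two means come from disjoint fractions. Ratios are clipped
#' to `[1/cap, cap]` before logging.
#'
#' Calls, in order of precedence:
#' * `subcomplex_shift` — mature mean < `-delta` and sub-complex mean >
#'   `+delta`: the protein leaves the mature complex and accumulates in the
#'   smaller species (disassembly intermediate).
#' * `degraded` — total-abundance log2 ratio < `-delta` without sub-complex
#'   accumulation: the protein is lost outright.
#' * `depleted` — mature mean < `-delta` only.
#' * `no_change` otherwise; `insufficient_data` when either window holds no
#'   quantified value.
#'
#' @param profile A [protein_fraction_ratios()] `complexome_profile`.
#' @param mature_mass,sub_mass Window centres in kDa.
#' @param delta Call threshold on |log2 ratio| (default `log2(1.5)`).
#' @param window Half-width of each window in slices (default 1).
#' @return Tibble with columns `protein`, `mature_log2`, `sub_log2`,
#'   `total_log2`, `call`.
#' @export
detect_shift <- function(profile, mature_mass = 700, sub_mass = 500,
                         delta = log2(1.5), window = 1) {
  stopifnot(inherits(profile, "complexome_profile"))
  cal <- profile$calibration
  mature_slices <- window_slices(cal, mature_mass, window)
  sub_slices <- setdiff(window_slices(cal, sub_mass, window), mature_slices)
  if (length(sub_slices) == 0) {
    stop("sub-complex window is empty after removing mature-window slices",
         call. = FALSE)
  }
  cap <- profile$cap
  log2_clip <- function(r) log2(pmin(pmax(r, 1 / cap), cap))

  res <- lapply(profile$proteins, function(pr) {
    row <- profile$ratios[pr, ]
    m_vals <- row[mature_slices]
    s_vals <- row[sub_slices]
    m_ok <- !is.na(m_vals)
    s_ok <- !is.na(s_vals)
    total <- profile$total_ratio[[pr]]
    total_log2 <- if (is.na(total)) NA_real_ else log2_clip(total)
    if (!any(m_ok) || !any(s_ok)) {
      return(tibble::tibble(protein = pr, mature_log2 = NA_real_,
                            sub_log2 = NA_real_, total_log2 = total_log2,
                            call = "insufficient_data"))
    }
    m <- mean(log2_clip(m_vals[m_ok]))
    s <- mean(log2_clip(s_vals[s_ok]))
    call <- if (m < -delta && s > delta) {
      "subcomplex_shift"
    } else if (!is.na(total_log2) && total_log2 < -delta && s <= delta) {
      "degraded"
    } else if (m < -delta) {
      "depleted"
    } else {
      "no_change"
    }
    tibble::tibble(protein = pr, mature_log2 = m, sub_log2 = s,
                   total_log2 = total_log2, call = call)
  })
  dplyr::bind_rows(res)
}

window_slices <- function(cal, mass, window) {
  center <- as.integer(mass_to_slice(cal, mass))
  seq(max(1L, center - window), min(cal$n_slices, center + window))
}

#' Plot a complexome profile heatmap
#'
#' Protein rows by gel-slice columns, coloured by log2 heavy:light ratio on
#' a diverging scale centred at ratio 1: green below 1 (loss in the heavy
#' channel), red above 1 (accumulation), grey for unquantified cells. Row
#' order follows the profile's protein order.
#'
#' @param profile A `complexome_profile`.
#' @param path Optional output file (e.g. `.png` or `.svg`); when `NULL`
#'   the plot object is returned without writing.
#' @param width,height Device size in inches when writing.
#' @return The ggplot object, invisibly when written to `path`.
#' @export
render_heatmap <- function(profile, path = NULL, width = 7, height = 4) {
  stopifnot(inherits(profile, "complexome_profile"))
  cap <- profile$cap
  df <- tibble::as_tibble(expand.grid(
    protein = profile$proteins, fraction = seq_len(profile$calibration$n_slices),
    stringsAsFactors = FALSE))
  df$ratio <- profile$ratios[cbind(match(df$protein, profile$proteins), df$fraction)]
  df$log2_ratio <- log2(pmin(pmax(df$ratio, 1 / cap), cap))
  df$protein <- factor(df$protein, levels = rev(profile$proteins))
  lim <- max(abs(df$log2_ratio), 1, na.rm = TRUE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$protein,
                                        fill = .data$log2_ratio)) +
    ggplot2::geom_tile(color = "grey90") +
    ggplot2::scale_fill_gradient2(low = "#1a9850", mid = "white",
                                  high = "#d73027", midpoint = 0,
                                  limits = c(-lim, lim),
                                  na.value = "grey70",
                                  name = "log2 H:L") +
    ggplot2::scale_x_continuous(breaks = pretty(seq_len(profile$calibration$n_slices)),
                                expand = c(0, 0)) +
    ggplot2::labs(x = "gel slice (high → low mass)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Read / write peptide quantification tables
#'
#' Tab-separated, UTF-8, `#` comments; columns `peptide`, `protein`,
#' `fraction`, `heavy_intensity`, `light_intensity`. `col_map` renames
#' foreign column headers (e.g. evidence-style exports) onto the expected
#' names, as `c(expected = "actual", ...)`.
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping expected column
#'   names to the names used in the file.
#' @return A tibble of peptide quantifications.
#' @export
read_peptide_quants <- function(path, col_map = NULL) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!is.null(col_map)) {
    for (want in names(col_map)) {
      have <- col_map[[want]]
      if (!have %in% names(df)) {
        stop("mapped column not found in file: ", have, call. = FALSE)
      }
      names(df)[names(df) == have] <- want
    }
  }
  req <- c("peptide", "protein", "fraction", "heavy_intensity", "light_intensity")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("peptide quant file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df[, req]
}

#' @param quants Tibble of peptide quantifications.
#' @rdname read_peptide_quants
#' @export
write_peptide_quants <- function(quants, path) {
  readr::write_tsv(tibble::as_tibble(quants), path, progress = FALSE)
  invisible(path)
}
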