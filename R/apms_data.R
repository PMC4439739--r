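#' Assemble per-protein APSM counts from peptide-spectrum matches
#'
#' Converts the peptide-level spectral counts of a single AP-MS run into
#' per-protein counts, apportioning peptides whose sequence matches more than
#' one protein. Two allocation policies are available:
#'
#' * `"proportional"` (default): each shared peptide's count is split across
#'   its matched proteins in proportion to their unique-peptide evidence
#'   (equal split when no matched protein has unique evidence). Total
#'   spectral counts are conserved.
#' * `"parsimony"`: each shared peptide's count is assigned entirely to the
#'   matched protein with the most unique evidence (lexicographically first
#'   on ties); shared peptides whose matched proteins all lack unique
#'   evidence are dropped.
#'
#' Proteins ending with zero allocated counts are omitted from the result.
#'
#' @param psms A data frame of peptide-spectrum match records with columns
#'   `peptide`, `protein` (either a list column of character vectors or a
#'   `";"`-separated string for peptides matching several proteins),
#'   `spectral_count` (non-negative), `bait` and `replicate`. All rows must
#'   share one bait and one replicate.
#' @param policy Shared-peptide allocation policy, `"proportional"` or
#'   `"parsimony"`.
#' @param cell_line Label for the cell line the run was acquired in.
#'
#' @return A `bait_run` object: a list with elements `bait`, `replicate`,
#'   `cell_line` and `counts` (a named numeric vector of per-protein counts,
#'   sorted by protein identifier).
#' @examples
#' psms <- tibble::tibble(
#'   peptide = c("PEPA", "PEPB", "PEPS"),
#'   protein = c("A", "B", "A;B"),
#'   spectral_count = c(6, 6, 4),
#'   bait = "MIC60", replicate = "r1"
#' )
#' assemble_apsm(psms)$counts  # A and B each get 6 + 2
#' @export
assemble_apsm <- function(psms, policy = c("proportional", "parsimony"),
                          cell_line = "unknown") {
  policy <- match.arg(policy)
  psms <- tibble::as_tibble(psms)
  if (nrow(psms) == 0) {
    return(new_bait_run(NA_character_, NA_character_, cell_line, numeric(0)))
  }
  required <- c("peptide", "protein", "spectral_count", "bait", "replicate")
  miss <- setdiff(required, names(psms))
  if (length(miss)) {
    stop("psms is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(psms$spectral_count < 0)) {
    stop("spectral_count must be non-negative", call. = FALSE)
  }
  if (length(unique(psms$bait)) != 1L || length(unique(psms$replicate)) != 1L) {
    stop("all PSM records must share one bait and one replicate", call. = FALSE)
  }
  prots <- if (is.list(psms$protein)) {
    lapply(psms$protein, as.character)
  } else {
    strsplit(as.character(psms$protein), ";", fixed = TRUE)
  }
  if (any(lengths(prots) == 0)) {
    stop("each PSM must match at least one protein", call. = FALSE)
  }

  all_prot <- sort(unique(unlist(prots)))
  unique_ev <- setNames(numeric(length(all_prot)), all_prot)
  is_unique <- lengths(prots) == 1L
  for (i in which(is_unique)) {
    p <- prots[[i]]
    unique_ev[[p]] <- unique_ev[[p]] + psms$spectral_count[i]
  }
  alloc <- unique_ev
  for (i in which(!is_unique)) {
    pp <- prots[[i]]
    cnt <- psms$spectral_count[i]
    w <- unique_ev[pp]
    if (policy == "proportional") {
      if (sum(w) == 0) w[] <- 1
      alloc[pp] <- alloc[pp] + cnt * w / sum(w)
    } else {
      if (all(w == 0)) next
      winner <- pp[order(-w, pp)][1L]
      alloc[[winner]] <- alloc[[winner]] + cnt
    }
  }
  alloc <- alloc[alloc > 0]
  new_bait_run(as.character(psms$bait[1]), as.character(psms$replicate[1]),
               cell_line, alloc)
}

new_bait_run <- function(bait, replicate, cell_line, counts) {
  structure(
    list(bait = bait, replicate = replicate, cell_line = cell_line,
         counts = if (length(counts)) counts[order(names(counts))] else counts),
    class = "bait_run"
  )
}

#' Merge technical replicate runs of one bait
#'
#' Averages per-protein counts over a bait's technical replicates and records
#' in how many replicates each prey was detected. The divisor is the number
#' of replicates acquired, not the number detecting a prey, so absence in a
#' replicate drags the average down.
#'
#' @param runs A list of [assemble_apsm()] `bait_run` objects sharing one bait.
#'
#' @return A `bait_summary` object: a list with elements `bait`, `cell_line`,
#'   `n_replicates`, `apsm` (named numeric, the replicate-averaged counts) and
#'   `detections` (named integer, replicates with count > 0).
#' @examples
#' r1 <- assemble_apsm(tibble::tibble(peptide = "P", protein = "MIC19",
#'   spectral_count = 8, bait = "MIC60", replicate = "r1"))
#' r2 <- assemble_apsm(tibble::tibble(peptide = "P", protein = "MIC19",
#'   spectral_count = 10, bait = "MIC60", replicate = "r2"))
#' merge_replicates(list(r1, r2))$apsm  # MIC19: 9
#' @export
merge_replicates <- function(runs) {
  if (length(runs) == 0) stop("at least one replicate run is required", call. = FALSE)
  baits <- unique(vapply(runs, function(r) as.character(r$bait), character(1)))
  if (length(baits) != 1L) stop("all runs must share one bait", call. = FALSE)
  reps <- vapply(runs, function(r) as.character(r$replicate), character(1))
  if (anyDuplicated(reps)) stop("replicate identifiers must be unique within a bait", call. = FALSE)
  preys <- sort(unique(unlist(lapply(runs, function(r) names(r$counts)))))
  n_rep <- length(runs)
  m <- matrix(0, nrow = length(preys), ncol = n_rep, dimnames = list(preys, NULL))
  for (j in seq_len(n_rep)) {
    cnt <- runs[[j]]$counts
    m[names(cnt), j] <- cnt
  }
  structure(
    list(bait = baits, cell_line = runs[[1]]$cell_line, n_replicates = n_rep,
         apsm = rowSums(m) / n_rep,
         detections = setNames(as.integer(rowSums(m > 0)), preys)),
    class = "bait_summary"
  )
}

#' Construct a CompPASS background stats table
#'
#' A stats table is the panel of many baits' AP-MS results that serves as the
#' background model for interaction scoring: a bait-by-prey matrix of average
#' peptide spectral matches (APSM) together with a parallel matrix of
#' replicate detection counts.
#'
#' @param apsm Numeric matrix of APSM values, baits in rows, preys in
#'   columns; dimnames required.
#' @param detections Integer matrix of the same shape: in how many technical
#'   replicates each (bait, prey) pair was detected. Must be positive exactly
#'   where `apsm` is positive.
#' @param cell_line Label for the cell line the panel was acquired in.
#'
#' @return A `stats_table` object.
#' @export
stats_table <- function(apsm, detections, cell_line = "unknown") {
  apsm <- as.matrix(apsm)
  detections <- as.matrix(detections)
  if (!identical(dim(apsm), dim(detections))) {
    stop("apsm and detections must have identical dimensions", call. = FALSE)
  }
  if (nrow(apsm) > 0 && (is.null(rownames(apsm)) || is.null(colnames(apsm)))) {
    stop("apsm must carry bait row names and prey column names", call. = FALSE)
  }
  dimnames(detections) <- dimnames(apsm)
  if (any(apsm < 0)) stop("APSM values must be non-negative", call. = FALSE)
  if (any(detections < 0)) stop("replicate detections must be non-negative", call. = FALSE)
  if (!all((apsm > 0) == (detections >= 1))) {
    stop("APSM must be positive exactly where a prey was detected in >= 1 replicate",
         call. = FALSE)
  }
  structure(list(apsm = apsm, detections = detections, cell_line = cell_line),
            class = "stats_table")
}

#' Assemble a stats table from per-bait replicate summaries
#'
#' @param summaries List of [merge_replicates()] `bait_summary` objects, one
#'   per bait.
#' @param cell_line Label; defaults to the first summary's.
#' @return A [stats_table()] object whose baits are the summaries' baits (in
#'   input order) and whose preys are the sorted union of all detected preys.
#' @export
stats_table_from_summaries <- function(summaries, cell_line = NULL) {
  if (length(summaries) == 0) stop("no bait summaries supplied", call. = FALSE)
  baits <- vapply(summaries, function(s) s$bait, character(1))
  if (anyDuplicated(baits)) stop("duplicate baits in summaries", call. = FALSE)
  preys <- sort(unique(unlist(lapply(summaries, function(s) names(s$apsm)))))
  X <- matrix(0, length(baits), length(preys), dimnames = list(baits, preys))
  P <- matrix(0L, length(baits), length(preys), dimnames = list(baits, preys))
  for (i in seq_along(summaries)) {
    s <- summaries[[i]]
    X[i, names(s$apsm)] <- s$apsm
    P[i, names(s$detections)] <- s$detections
  }
  if (is.null(cell_line)) cell_line <- summaries[[1]]$cell_line
  stats_table(X, P, cell_line)
}

#' @export
print.stats_table <- function(x, ...) {
  cat(sprintf("<stats_table> %d baits x %d preys (cell line: %s)\n",
              nrow(x$apsm), ncol(x$apsm), x$cell_line))
  invisible(x)
}

#' Read / write a stats table
#'
#' Stats tables are stored as UTF-8 tab-separated text with `#` comment
#' lines. Data columns are `bait`, `prey`, `apsm`, `replicates`, one row per
#' detected (bait, prey) pair, sorted by bait then prey. Metadata comment
#' lines of the form `#% key<TAB>value...` preserve the cell line and the
#' full bait/prey ordering so that write-then-read is the identity even for
#' baits with no detected preys.
#'
#' @param path File path.
#' @return `read_stats_table()` returns a [stats_table()];
#'   `write_stats_table()` returns `path` invisibly.
#' @export
read_stats_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#%", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    parts <- strsplit(sub("^#%\\s*", "", ml), "\t", fixed = TRUE)[[1]]
    meta[[parts[1]]] <- parts[-1]
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) == 0) stop("stats table file has no header line", call. = FALSE)
  df <- suppressWarnings(  # column presence is validated below with a clearer error
    readr::read_tsv(I(paste(body, collapse = "\n")),
                    col_types = readr::cols(
                      bait = readr::col_character(),
                      prey = readr::col_character(),
                      apsm = readr::col_double(),
                      replicates = readr::col_integer(),
                      .default = readr::col_guess()
                    ), progress = FALSE))
  for (col in c("bait", "prey", "apsm", "replicates")) {
    if (!col %in% names(df)) {
      stop("stats table file is missing required column: ", col, call. = FALSE)
    }
  }
  if (nrow(df) > 0 && (any(df$apsm < 0) || any(df$replicates < 0))) {
    stop("negative counts in stats table file", call. = FALSE)
  }
  baits <- if (!is.null(meta$baits)) meta$baits else sort(unique(df$bait))
  preys <- if (!is.null(meta$preys)) meta$preys else sort(unique(df$prey))
  cell_line <- if (!is.null(meta$cell_line)) meta$cell_line else "unknown"
  X <- matrix(0, length(baits), length(preys), dimnames = list(baits, preys))
  P <- matrix(0L, length(baits), length(preys), dimnames = list(baits, preys))
  if (nrow(df) > 0) {
    if (!all(df$bait %in% baits) || !all(df$prey %in% preys)) {
      stop("stats table rows reference baits/preys absent from metadata", call. = FALSE)
    }
    X[cbind(df$bait, df$prey)] <- df$apsm
    P[cbind(df$bait, df$prey)] <- df$replicates
  }
  stats_table(X, P, cell_line)
}

#' @param table A [stats_table()] object.
#' @rdname read_stats_table
#' @export
write_stats_table <- function(table, path) {
  stopifnot(inherits(table, "stats_table"))
  idx <- which(table$apsm > 0, arr.ind = TRUE)
  df <- tibble::tibble(
    bait = rownames(table$apsm)[idx[, 1]],
    prey = colnames(table$apsm)[idx[, 2]],
    apsm = table$apsm[idx],
    replicates = as.integer(table$detections[idx])
  )
  df <- dplyr::arrange(df, .data$bait, .data$prey)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "# micoskit stats table",
    paste0("#% cell_line\t", table$cell_line),
    paste0("#% baits\t", paste(rownames(table$apsm), collapse = "\t")),
    paste0("#% preys\t", paste(colnames(table$apsm), collapse = "\t"))
  ), con)
  writeLines(readr::format_tsv(df), con, sep = "")
  invisible(path)
}

#' Read a membership list (e.g. MitoCarta)
#'
#' One protein identifier per line; blank lines and `#` comments ignored;
#' duplicates collapsed.
#'
#' @param path File path.
#' @return Character vector of unique identifiers.
#' @export
read_membership <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8"))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}
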