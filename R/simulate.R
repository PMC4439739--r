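#' Configuration for the AP-MS stats-table simulator
#'
#' Describes a panel of unrelated baits with a background of promiscuous
#' preys plus planted true interactions. Background prey detection
#' frequencies are drawn from a Beta distribution and background APSMs from
#' an overdispersed (negative-binomial) count model, mimicking the heavy
#' tail of spectral counts. Planted pairs receive an APSM boosted by
#' `multiplier` over the background mean and are detected in each replicate
#' with probability `reproducibility`.
#'
#' @param k_baits Number of baits in the panel (>= 2).
#' @param n_background_preys Number of background prey proteins.
#' @param freq_shape1,freq_shape2 Beta parameters for per-prey, per-replicate
#'   detection probability (defaults give a mean frequency of ~0.11).
#' @param apsm_mu,apsm_size Negative-binomial mean and dispersion for
#'   background spectral counts (counts are shifted by 1 so detected preys
#'   have at least one spectrum).
#' @param planted Data frame with columns `bait`, `prey`, `multiplier`
#'   (> 1) and optionally `reproducibility` (default 1); `NULL` for none.
#' @param n_replicates Technical replicates per bait (default 2).
#' @param cell_line Label stored in the generated table.
#' @return An `apms_sim_config` object.
#' @export
apms_sim_config <- function(k_baits = 50, n_background_preys = 500,
                            freq_shape1 = 1.2, freq_shape2 = 10,
                            apsm_mu = 4, apsm_size = 2,
                            planted = NULL, n_replicates = 2,
                            cell_line = "sim") {
  if (k_baits < 2) stop("k_baits must be >= 2", call. = FALSE)
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    if (!all(c("bait", "prey", "multiplier") %in% names(planted))) {
      stop("planted needs columns bait, prey, multiplier", call. = FALSE)
    }
    if (!"reproducibility" %in% names(planted)) planted$reproducibility <- 1
    if (any(planted$multiplier <= 1)) stop("multipliers must exceed 1", call. = FALSE)
    if (any(planted$reproducibility < 0 | planted$reproducibility > 1)) {
      stop("reproducibility must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(k_baits = as.integer(k_baits),
                 n_background_preys = as.integer(n_background_preys),
                 freq_shape1 = freq_shape1, freq_shape2 = freq_shape2,
                 apsm_mu = apsm_mu, apsm_size = apsm_size,
                 planted = planted, n_replicates = as.integer(n_replicates),
                 cell_line = cell_line),
            class = "apms_sim_config")
}

#' Simulate an AP-MS stats table with known ground truth
#'
#' Background: each (bait, prey, replicate) cell is detected independently
#' with the prey's frequency probability; detected cells draw a
#' `1 + NegBin(mu - 1, size)` spectral count. APSM is the mean count over
#' the replicates acquired and `detections` counts the replicates with
#' signal. Planted pairs are superimposed with a
#' `multiplier x apsm_mu` Poisson count per detected replicate. Identical
#' seeds give identical tables.
#'
#' @param config An [apms_sim_config()].
#' @param seed Optional integer seed.
#' @return List with `table` (a [stats_table()]), `truth` (tibble of
#'   planted `bait`, `prey` pairs) and `background_pairs` (tibble of all
#'   detected background pairs, for false-positive accounting).
#' @export
simulate_apms <- function(config = apms_sim_config(), seed = NULL) {
  stopifnot(inherits(config, "apms_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  k <- config$k_baits
  n_prey <- config$n_background_preys
  n_rep <- config$n_replicates
  baits <- sprintf("BAIT%03d", seq_len(k))
  bg_preys <- sprintf("PREY%04d", seq_len(n_prey))

  freq <- rbeta(n_prey, config$freq_shape1, config$freq_shape2)
  # per-replicate detection and counts, background
  X <- matrix(0, k, n_prey, dimnames = list(baits, bg_preys))
  P <- matrix(0L, k, n_prey, dimnames = list(baits, bg_preys))
  mu_shift <- max(config$apsm_mu - 1, 0.1)
  for (r in seq_len(n_rep)) {
    det <- matrix(rbinom(k * n_prey, 1, rep(freq, each = k)), k, n_prey)
    cnt <- matrix(1 + rnbinom(k * n_prey, mu = mu_shift, size = config$apsm_size),
                  k, n_prey)
    X <- X + det * cnt
    P <- P + det
  }
  X <- X / n_rep
  storage.mode(P) <- "integer"

  planted <- config$planted
  if (!is.null(planted) && nrow(planted) > 0) {
    extra <- setdiff(unique(planted$prey), bg_preys)
    if (length(extra)) {
      X <- cbind(X, matrix(0, k, length(extra), dimnames = list(baits, extra)))
      P <- cbind(P, matrix(0L, k, length(extra), dimnames = list(baits, extra)))
    }
    if (!all(planted$bait %in% baits)) {
      stop("planted baits must be among the simulated baits", call. = FALSE)
    }
    for (i in seq_len(nrow(planted))) {
      b <- planted$bait[i]; pr <- planted$prey[i]
      det <- rbinom(n_rep, 1, planted$reproducibility[i])
      cnt <- pmax(1, rpois(n_rep, planted$multiplier[i] * config$apsm_mu)) * det
      X[b, pr] <- X[b, pr] + sum(cnt) / n_rep
      P[b, pr] <- min(n_rep, P[b, pr] + sum(det))
    }
    truth <- planted[, c("bait", "prey")]
  } else {
    truth <- tibble::tibble(bait = character(), prey = character())
  }

  bg_idx <- which(X[, bg_preys, drop = FALSE] > 0, arr.ind = TRUE)
  background_pairs <- tibble::tibble(bait = baits[bg_idx[, 1]],
                                     prey = bg_preys[bg_idx[, 2]])
  background_pairs <- dplyr::anti_join(background_pairs, truth,
                                       by = c("bait", "prey"))

  list(table = stats_table(X, P, config$cell_line), truth = truth,
       background_pairs = background_pairs)
}

#' Configuration for the SILAC BN-PAGE complexome simulator
#'
#' Emulates a 1:1 heavy:light mix of knockdown (heavy) and control (light)
#' cells fractionated on a BN-PAGE lane: the light channel of every subunit
#' follows a Gaussian migration profile (in log10 mass) centred on its
#' complex's mass; the heavy channel is the light channel times a per-slice
#' effect — `mature_depletion` in the window around the complex mass,
#' `sub_accumulation` in the window around `sub_mass` (mature-window slices
#' excluded), and a global `degradation` factor — with independent
#' multiplicative lognormal noise on each channel.
#'
#' @param complex_mass Mass of the mature complex in kDa (default 700).
#' @param sub_mass Mass of the disassembly sub-complex (default 500).
#' @param effects Data frame with columns `protein` and (optionally)
#'   `mature_depletion`, `sub_accumulation`, `degradation` (all default 1 =
#'   unaffected). One simulated protein per row.
#' @param peptides_per_protein Peptides simulated per protein (default 5).
#' @param migration_sd_log10 Gaussian migration width in log10-mass units
#'   (default 0.03, so a complex spans roughly 1-2 of the default slices).
#' @param intensity_scale Peak light-channel intensity (arbitrary units).
#' @param noise_cv Coefficient of variation of the per-channel lognormal
#'   noise (default 0.2).
#' @param window Half-width in slices of the effect windows (default 1,
#'   matching [detect_shift()]).
#' @param calibration A [calibrate_fractions()] object.
#' @return A `complexome_sim_config` object.
#' @export
complexome_sim_config <- function(complex_mass = 700, sub_mass = 500,
                                  effects = tibble::tibble(protein = c("MIC60", "MIC19", "MIC25")),
                                  peptides_per_protein = 5,
                                  migration_sd_log10 = 0.03,
                                  intensity_scale = 1e6, noise_cv = 0.2,
                                  window = 1,
                                  calibration = calibrate_fractions()) {
  effects <- tibble::as_tibble(effects)
  if (!"protein" %in% names(effects)) stop("effects needs a protein column", call. = FALSE)
  for (col in c("mature_depletion", "sub_accumulation", "degradation")) {
    if (!col %in% names(effects)) effects[[col]] <- 1
    if (any(effects[[col]] < 0)) stop(col, " factors must be >= 0", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (complex_mass > calibration$mass_top || complex_mass <= calibration$mass_bottom ||
      sub_mass > calibration$mass_top || sub_mass <= calibration$mass_bottom) {
    stop("complex masses must lie within the calibration range", call. = FALSE)
  }
  structure(list(complex_mass = complex_mass, sub_mass = sub_mass,
                 effects = effects,
                 peptides_per_protein = as.integer(peptides_per_protein),
                 migration_sd_log10 = migration_sd_log10,
                 intensity_scale = intensity_scale, noise_cv = noise_cv,
                 window = as.integer(window), calibration = calibration),
            class = "complexome_sim_config")
}

#' Simulate SILAC BN-PAGE peptide quantifications with known shift labels
#'
#' @param config A [complexome_sim_config()].
#' @param seed Optional integer seed.
#' @return List with `quants` (peptide-level tibble readable by
#'   [protein_fraction_ratios()]) and `truth` (tibble of `protein`, the
#'   programmed factors and the expected [detect_shift()] `call`).
#' @export
simulate_complexome <- function(config = complexome_sim_config(), seed = NULL) {
  stopifnot(inherits(config, "complexome_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cal <- config$calibration
  centers <- cal$log10_centers
  mu <- log10(config$complex_mass)
  profile_shape <- exp(-0.5 * ((centers - mu) / config$migration_sd_log10)^2)

  mature_slices <- window_slices(cal, config$complex_mass, config$window)
  sub_slices <- setdiff(window_slices(cal, config$sub_mass, config$window),
                        mature_slices)

  sdlog <- sqrt(log(1 + config$noise_cv^2))
  meanlog <- -sdlog^2 / 2
  eff <- config$effects
  n_slice <- cal$n_slices

  rows <- vector("list", nrow(eff))
  for (i in seq_len(nrow(eff))) {
    e_slice <- rep(eff$degradation[i], n_slice)
    e_slice[mature_slices] <- e_slice[mature_slices] * eff$mature_depletion[i]
    e_slice[sub_slices] <- e_slice[sub_slices] * eff$sub_accumulation[i]
    n_pep <- config$peptides_per_protein
    pep_scale <- config$intensity_scale * rlnorm(n_pep, meanlog = 0, sdlog = 0.5)
    light_true <- outer(pep_scale, profile_shape)           # peptide x slice
    heavy_true <- sweep(light_true, 2, e_slice, `*`)
    light_obs <- light_true * rlnorm(length(light_true), meanlog, sdlog)
    heavy_obs <- heavy_true * rlnorm(length(heavy_true), meanlog, sdlog)
    rows[[i]] <- tibble::tibble(
      peptide = rep(sprintf("%s_pep%02d", eff$protein[i], seq_len(n_pep)),
                    times = n_slice),
      protein = eff$protein[i],
      fraction = rep(seq_len(n_slice), each = n_pep),
      heavy_intensity = as.vector(heavy_obs),
      light_intensity = as.vector(light_obs)
    )
  }
  quants <- dplyr::bind_rows(rows)

  delta <- log2(1.5)
  truth <- eff
  truth$expected_call <- vapply(seq_len(nrow(eff)), function(i) {
    m <- log2(eff$degradation[i] * eff$mature_depletion[i] + 1e-12)
    s <- log2(eff$degradation[i] * eff$sub_accumulation[i] + 1e-12)
    tot <- log2(eff$degradation[i] * eff$mature_depletion[i] + 1e-12)
    if (m < -delta && s > delta) "subcomplex_shift"
    else if (tot < -delta && s <= delta) "degraded"
    else if (m < -delta) "depleted"
    else "no_change"
  }, character(1))

  list(quants = quants, truth = truth)
}

#' Configuration for the immunogold micrograph simulator
#'
#' Places gold particles on annotated cristae membranes either uniformly by
#' arc length (`placement = "uniform"`, the pattern expected for a protein
#' spread along cristae) or concentrated near cristae junctions
#' (`placement = "cj_concentrated"`): a CJ is chosen at random and the
#' particle displaced along the membrane by a half-normal(`sigma`) arc
#' distance in a random direction, reflecting at the polyline ends.
#' Isotropic Gaussian `jitter` emulates localization error of the label.
#'
#' @param cristae List of two-column polyline matrices (nm).
#' @param cj_arcs Data frame with columns `path` (polyline index) and `s`
#'   (arc-length position, nm) giving the CJ positions on the membranes.
#' @param n_particles Number of particles to place (>= 0).
#' @param placement `"uniform"` or `"cj_concentrated"`.
#' @param sigma Half-normal scale in nm for `cj_concentrated` (default 30).
#' @param jitter Isotropic Gaussian SD in nm added to every particle
#'   (default 0).
#' @return A `gold_sim_config` object.
#' @export
gold_sim_config <- function(cristae = default_cristae_geometry(),
                            cj_arcs = default_cj_arcs(),
                            n_particles = 100,
                            placement = c("uniform", "cj_concentrated"),
                            sigma = 30, jitter = 0) {
  placement <- match.arg(placement)
  if (n_particles < 0) stop("n_particles must be >= 0", call. = FALSE)
  if (placement == "cj_concentrated" && sigma <= 0) {
    stop("sigma must be positive for cj_concentrated placement", call. = FALSE)
  }
  if (n_particles > 0 && length(cristae) == 0) {
    stop("cristae geometry required to place particles", call. = FALSE)
  }
  cj_arcs <- tibble::as_tibble(cj_arcs)
  if (!all(c("path", "s") %in% names(cj_arcs))) {
    stop("cj_arcs needs columns path and s", call. = FALSE)
  }
  structure(list(cristae = cristae, cj_arcs = cj_arcs,
                 n_particles = as.integer(n_particles), placement = placement,
                 sigma = sigma, jitter = jitter),
            class = "gold_sim_config")
}

#' Default simulated cristae geometry
#'
#' Four parallel straight cristae of 800 nm emanating from an inner
#' boundary membrane, 250 nm apart — a stylised mitochondrion cross
#' section.
#' @return List of polyline matrices (nm).
#' @export
default_cristae_geometry <- function() {
  lapply(0:3, function(i) {
    rbind(c(0, i * 250), c(800, i * 250))
  })
}

#' @rdname default_cristae_geometry
#' @export
default_cj_arcs <- function() {
  tibble::tibble(path = 1:4, s = 0)  # junction at the membrane origin of each crista
}

#' Simulate an immunogold micrograph annotation
#'
#' @param config A [gold_sim_config()].
#' @param seed Optional integer seed.
#' @return List with `annotation` (a [micrograph_annotation()]) and
#'   `labels` (tibble recording the placement mode of each particle).
#' @export
simulate_micrograph <- function(config = gold_sim_config(), seed = NULL) {
  stopifnot(inherits(config, "gold_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cristae <- config$cristae
  lens <- vapply(cristae, polyline_length, numeric(1))
  cj_points <- do.call(rbind, lapply(seq_len(nrow(config$cj_arcs)), function(i) {
    point_at_arc(cristae[[config$cj_arcs$path[i]]], config$cj_arcs$s[i])
  }))
  if (is.null(cj_points)) cj_points <- matrix(numeric(0), ncol = 2)

  n <- config$n_particles
  if (n == 0) {
    particles <- matrix(numeric(0), ncol = 2)
  } else if (config$placement == "uniform") {
    particles <- sample_on_paths(cristae, n)
  } else {
    which_cj <- sample.int(nrow(config$cj_arcs), n, replace = TRUE)
    d <- abs(rnorm(n, 0, config$sigma)) * sample(c(-1, 1), n, replace = TRUE)
    particles <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      pidx <- config$cj_arcs$path[which_cj[i]]
      s0 <- config$cj_arcs$s[which_cj[i]]
      s <- reflect_arc(s0 + d[i], lens[pidx])
      particles[i, ] <- point_at_arc(cristae[[pidx]], s)
    }
  }
  if (config$jitter > 0 && n > 0) {
    particles <- particles + matrix(rnorm(2 * n, 0, config$jitter), n, 2)
  }
  list(
    annotation = micrograph_annotation(particles, cj_points, cristae),
    labels = tibble::tibble(particle = seq_len(n), placement = config$placement)
  )
}
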