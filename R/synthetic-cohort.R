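#' Synthetic cohort configuration
#'
#' Defines the study-design constants of the synthetic multi-contrast
#' cohort: 18 patients with about 5 biopsies each, biopsy targets split
#' between enhancing core (ENH) and brain-around-tumor (BAT) and separated
#' by at least 1 cm, on grids with ~1.2 mm in-plane resolution and 3 mm
#' slice thickness. Class-conditional signal is carried by exactly three
#' contrasts: an rCBV mean shift in high-tumor tissue, an EPI+C
#' co-occurrence texture difference (class-dependent smoothing length of
#' the noise field), and a structured two-level blob pattern in T1+C confined to
#' high-tumor tissue. The other five contrasts are class-independent
#' noise.
#'
#' @param n_patients Number of patients.
#' @param volume_shape `(slices, rows, cols)` voxels.
#' @param n_biopsies_per_patient Biopsies sampled per patient.
#' @param enh_fraction Proportion of biopsies targeted at the ENH zone.
#' @param effect_rcbv Standardized mean shift of rCBV in high-tumor voxels
#'   (in units of `noise_sd`).
#' @param texture_scale_low,texture_scale_high Spatial correlation length
#'   (voxels) of the EPI+C noise field in low-/high-tumor tissue.
#' @param t1c_pattern_amplitude Amplitude (in units of `noise_sd`) of the
#'   two-level blob pattern mixed into T1+C in high-tumor voxels.
#' @param noise_sd Intensity noise scale for all contrasts.
#' @param min_spacing_mm Minimum pairwise biopsy separation (mm).
#' @param voxel_size_mm `(dz, dy, dx)` in mm.
#' @param bat_outer_mm Thickness of the BAT shell beyond the enhancing
#'   margin (mm); the spatial extent of BAT is not a fixed anatomical
#'   quantity, so it is exposed here rather than hard-coded.
#' @param tumor_mean_enh,tumor_mean_bat,tumor_mean_outside Mean percent
#'   tumor nuclei of the underlying field by zone.
#' @param tumor_sd,tumor_corr_len SD (percent points) and in-plane
#'   correlation length (voxels) of the smooth tumor-fraction field.
#' @param seed Integer random seed; the whole cohort is reproducible from
#'   `(config, seed)`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 18L,
                          volume_shape = c(12L, 64L, 64L),
                          n_biopsies_per_patient = 5L,
                          enh_fraction = 0.58,
                          effect_rcbv = 0.6,
                          texture_scale_low = 1.0,
                          texture_scale_high = 2.5,
                          t1c_pattern_amplitude = 0.3,
                          noise_sd = 1.0,
                          min_spacing_mm = 10,
                          voxel_size_mm = c(3, 1.2, 1.2),
                          bat_outer_mm = 14,
                          tumor_mean_enh = 85,
                          tumor_mean_bat = 70,
                          tumor_mean_outside = 20,
                          tumor_sd = 25,
                          tumor_corr_len = 9,
                          seed = 1L) {
  stopifnot(n_patients >= 1, n_biopsies_per_patient >= 1,
            enh_fraction >= 0, enh_fraction <= 1,
            min_spacing_mm >= 0, length(volume_shape) == 3,
            length(voxel_size_mm) == 3)
  if (volume_shape[2] < roi_size + 6 || volume_shape[3] < roi_size + 6)
    stop("volume_shape too small for an 8x8 ROI at radius-3 margin")
  structure(list(
    n_patients = as.integer(n_patients),
    volume_shape = as.integer(volume_shape),
    n_biopsies_per_patient = as.integer(n_biopsies_per_patient),
    enh_fraction = enh_fraction, effect_rcbv = effect_rcbv,
    texture_scale_low = texture_scale_low,
    texture_scale_high = texture_scale_high,
    t1c_pattern_amplitude = t1c_pattern_amplitude,
    noise_sd = noise_sd, min_spacing_mm = min_spacing_mm,
    voxel_size_mm = as.numeric(voxel_size_mm),
    bat_outer_mm = bat_outer_mm,
    tumor_mean_enh = tumor_mean_enh, tumor_mean_bat = tumor_mean_bat,
    tumor_mean_outside = tumor_mean_outside,
    tumor_sd = tumor_sd, tumor_corr_len = tumor_corr_len,
    seed = as.integer(seed)), class = "cohort_config")
}

# Per-patient derived seed: deterministic in (config$seed, patient_index)
# and kept below 2^31.
patient_seed <- function(config, patient_index) {
  as.integer((config$seed %% 1000003L) * 1009L + patient_index * 101L)
}

# Truncated, row-normalized Gaussian convolution matrix for 1D smoothing.
gauss_band <- function(n, sigma) {
  k <- outer(seq_len(n), seq_len(n),
             function(i, j) exp(-((i - j)^2) / (2 * sigma^2)))
  k[abs(row(k) - col(k)) > ceiling(4 * sigma)] <- 0
  k / rowSums(k)
}

# Per-slice 2D Gaussian smoothing of iid noise, renormalized to unit SD.
smooth_noise_slice <- function(nr, nc, sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma > 0) {
    z <- gauss_band(nr, sigma) %*% z %*% t(gauss_band(nc, sigma))
  }
  (z - mean(z)) / stats::sd(z)
}

# Mean SD over non-overlapping 8x8 blocks: the ROI-scale amplitude of a
# slice. Textured fields are divided by this so class membership cannot
# leak through the first-order ROI SD; only the spatial arrangement
# (co-occurrence, binary structure, spectrum) differs between classes.
local_block_sd <- function(m) {
  nb_r <- nrow(m) %/% roi_size; nb_c <- ncol(m) %/% roi_size
  s <- 0; n <- 0L
  for (i in seq_len(nb_r)) for (j in seq_len(nb_c)) {
    blk <- m[((i - 1) * roi_size + 1):(i * roi_size),
             ((j - 1) * roi_size + 1):(j * roi_size)]
    s <- s + stats::sd(blk); n <- n + 1L
  }
  s / n
}

unit_local_sd <- function(m) m / local_block_sd(m)

# Two-zone ellipsoidal geometry: normalized radius per voxel in physical mm.
zone_masks <- function(shape, voxel_size_mm, bat_outer_mm,
                       rz_mm = 12, rxy_mm = 18) {
  ctr <- (shape + 1) / 2
  dz <- (seq_len(shape[1]) - ctr[1]) * voxel_size_mm[1]
  dy <- (seq_len(shape[2]) - ctr[2]) * voxel_size_mm[2]
  dx <- (seq_len(shape[3]) - ctr[3]) * voxel_size_mm[3]
  rho <- sqrt(outer(outer((dz / rz_mm)^2, (dy / rxy_mm)^2, `+`),
                    (dx / rxy_mm)^2, `+`))
  rho_out <- (rxy_mm + bat_outer_mm) / rxy_mm
  list(enh = rho <= 1, bat = rho > 1 & rho <= rho_out)
}

#' Generate one synthetic patient
#'
#' Builds the ground-truth tumor-fraction field (a smoothed random field
#' over an ENH core with high mean fraction and a surrounding BAT shell
#' with lower mean) and the eight coregistered contrast volumes. Voxels
#' with tumor fraction >= 80 form the high-tumor class used to inject the
#' class-conditional signals. Deterministic given `(config$seed,
#' patient_index)`.
#'
#' @param config A [cohort_config()].
#' @param patient_index 1-based patient index (`<= n_patients`).
#' @return List with `volumes` (named list of eight `contrast_volume`s)
#'   and `field` (class `ground_truth_field` with `tumor_fraction`,
#'   `enh_mask`, `bat_mask`).
#' @export
generate_patient <- function(config, patient_index) {
  if (patient_index > config$n_patients)
    stop("patient_index exceeds n_patients")
  shape <- config$volume_shape
  set.seed(patient_seed(config, patient_index))
  zm <- zone_masks(shape, config$voxel_size_mm, config$bat_outer_mm)
  if (!any(zm$enh) || !any(zm$bat))
    stop("volume too small to contain the two-zone geometry")

  base <- array(config$tumor_mean_outside, shape)
  base[zm$bat] <- config$tumor_mean_bat
  base[zm$enh] <- config$tumor_mean_enh
  noise <- array(0, shape)
  for (s in seq_len(shape[1]))
    noise[s, , ] <- smooth_noise_slice(shape[2], shape[3],
                                       config$tumor_corr_len)
  tf <- pmin(pmax(base + config$tumor_sd * noise, 0), 100)
  high <- tf >= 80

  nz <- config$noise_sd
  iid <- function() array(stats::rnorm(prod(shape), sd = nz), shape)
  # smoothed noise volume, normalized to unit ROI-scale SD per slice
  smooth_vol <- function(sigma) {
    v <- array(0, shape)
    for (s in seq_len(shape[1]))
      v[s, , ] <- unit_local_sd(
        smooth_noise_slice(shape[2], shape[3], sigma)) * nz
    v
  }

  vols <- list()
  # T1+C: the high-tumor field mixes a two-level blob pattern (binarized
  # smoothed noise) into the noise, then is normalized to the same
  # ROI-scale SD as the plain-noise low-tumor field, so the class
  # difference is carried by local binary structure (flat runs and
  # edges), not by first-order statistics
  amp <- config$t1c_pattern_amplitude
  t1c <- array(0, shape)
  for (s in seq_len(shape[1])) {
    lo <- matrix(stats::rnorm(shape[2] * shape[3]), shape[2], shape[3])
    blob <- sign(smooth_noise_slice(shape[2], shape[3], 2))
    hi <- (matrix(stats::rnorm(shape[2] * shape[3]), shape[2], shape[3]) +
             amp * blob) / sqrt(1 + amp^2)
    sl <- ifelse(high[s, , ], unit_local_sd(hi), unit_local_sd(lo)) * nz
    t1c[s, , ] <- sl
  }
  vols[["T1+C"]] <- t1c
  vols[["T2W"]] <- iid()
  # rCBV: positive baseline (normalized maps sit above zero) plus a mean
  # shift of effect_rcbv noise-SD units in high-tumor voxels. The shift
  # is full strength in the enhancing core and attenuated in BAT, where
  # perfusion discriminates tumor content less sharply; this gives the
  # perfusion and texture channels complementary spatial domains.
  shift <- config$effect_rcbv * nz * high * ifelse(zm$enh, 1, 0.25)
  vols[["rCBV"]] <- iid() + 2 * nz + shift
  # EPI+C: smoothing length differs by class, most sharply in BAT (the
  # infiltrative margin, where cell-density texture is the discriminant);
  # in the enhancing core the high-class smoothing is intermediate. The
  # perfusion and texture channels therefore dominate opposite zones.
  sc_mid <- config$texture_scale_low +
    0.35 * (config$texture_scale_high - config$texture_scale_low)
  epi_low <- smooth_vol(config$texture_scale_low)
  epi_high <- smooth_vol(config$texture_scale_high)
  epi_mid <- smooth_vol(sc_mid)
  vols[["EPI+C"]] <- ifelse(high, ifelse(zm$enh, epi_mid, epi_high),
                            epi_low)
  for (cn in c("p", "q", "MD", "FA")) vols[[cn]] <- iid()

  volumes <- lapply(contrast_names(), function(cn)
    contrast_volume(cn, vols[[cn]], config$voxel_size_mm))
  names(volumes) <- contrast_names()
  field <- structure(list(tumor_fraction = tf, enh_mask = zm$enh,
                          bat_mask = zm$bat),
                     class = "ground_truth_field")
  list(volumes = volumes, field = field)
}

# Valid top-left corners (0-based) whose full 8x8 footprint lies inside
# the given zone mask on each slice, via integral images.
footprint_corners <- function(mask3d) {
  shape <- dim(mask3d)
  out <- NULL
  for (s in seq_len(shape[1])) {
    m <- mask3d[s, , ] * 1
    ii <- matrix(0, shape[2] + 1L, shape[3] + 1L)
    ii[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
    nr <- shape[2] - roi_size + 1L; nc <- shape[3] - roi_size + 1L
    if (nr < 1 || nc < 1) next
    r0 <- rep(seq_len(nr), times = nc); c0 <- rep(seq_len(nc), each = nr)
    s11 <- ii[cbind(r0 + roi_size, c0 + roi_size)]
    s01 <- ii[cbind(r0, c0 + roi_size)]
    s10 <- ii[cbind(r0 + roi_size, c0)]
    s00 <- ii[cbind(r0, c0)]
    full <- (s11 - s01 - s10 + s00) == roi_size^2
    if (any(full))
      out <- rbind(out, cbind(slice = s - 1L, row0 = r0[full] - 1L,
                              col0 = c0[full] - 1L))
  }
  out
}

site_center_mm <- function(slice, row0, col0, voxel_size_mm) {
  c(slice * voxel_size_mm[1],
    (row0 + (roi_size - 1) / 2) * voxel_size_mm[2],
    (col0 + (roi_size - 1) / 2) * voxel_size_mm[3])
}

#' Sample biopsy sites from a ground-truth field
#'
#' Pseudorandom site placement by rejection sampling (bounded at 10,000
#' draws): sites are split between ENH and BAT per `enh_fraction`, every
#' 8x8 footprint lies entirely inside its zone mask, and all pairwise
#' physical distances between ROI centers are at least `min_spacing_mm`.
#' Each site records the true percent tumor nuclei as the mean of the
#' tumor-fraction field over its footprint; the high/low label follows
#' from the 80% threshold on that ROI mean (histology labels whole
#' samples, not voxels).
#'
#' @param field A `ground_truth_field`.
#' @param config A [cohort_config()].
#' @param patient_id Identifier recorded on each site.
#' @param n_sites Number of sites (default `n_biopsies_per_patient`).
#' @return List of `biopsy_site`s.
#' @export
sample_biopsy_sites <- function(field, config, patient_id = "P01",
                                n_sites = config$n_biopsies_per_patient) {
  if (!any(field$enh_mask) || !any(field$bat_mask))
    stop("zone masks are empty")
  n_enh <- round(config$enh_fraction * n_sites)
  zones <- c(rep("ENH", n_enh), rep("BAT", n_sites - n_enh))
  cand <- list(ENH = footprint_corners(field$enh_mask),
               BAT = footprint_corners(field$bat_mask))
  for (z in unique(zones))
    if (is.null(cand[[z]]) || nrow(cand[[z]]) == 0)
      stop("no valid ", z, " footprint positions: volume too small")

  draws <- 0L
  repeat {
    placed <- list(); centers <- NULL; ok <- TRUE
    for (z in zones) {
      found <- FALSE
      while (draws < 10000L) {
        draws <- draws + 1L
        pick <- cand[[z]][sample.int(nrow(cand[[z]]), 1L), ]
        ctr <- site_center_mm(pick["slice"], pick["row0"], pick["col0"],
                              config$voxel_size_mm)
        if (is.null(centers) ||
            all(sqrt(colSums((t(centers) - ctr)^2)) >=
                config$min_spacing_mm)) {
          centers <- rbind(centers, ctr)
          placed[[length(placed) + 1L]] <- c(pick, zone = z)
          found <- TRUE
          break
        }
      }
      if (!found) { ok <- FALSE; break }
    }
    if (ok) break
    if (draws >= 10000L)
      stop("could not satisfy min_spacing_mm = ", config$min_spacing_mm,
           " after 10000 placement draws")
  }

  lapply(placed, function(p) {
    sl <- as.integer(p["slice"]); r0 <- as.integer(p["row0"])
    c0 <- as.integer(p["col0"])
    pct <- mean(field$tumor_fraction[sl + 1L, (r0 + 1L):(r0 + roi_size),
                                     (c0 + 1L):(c0 + roi_size)])
    biopsy_site(patient_id, sl, r0, c0, p[["zone"]], pct)
  })
}

#' Generate a full synthetic cohort
#'
#' Patients are generated independently (each deterministic in the config
#' seed and patient index); site sampling is seeded per patient. When
#' `n_sites_total` is given, biopsies are distributed as evenly as
#' possible with the remainder going to the first patients (e.g. 60 sites
#' across 11 patients gives five patients 6 and six patients 5).
#'
#' @param config A [cohort_config()].
#' @param n_patients Number of patients to generate (default from config).
#' @param n_sites_total Optional total biopsy count across the cohort.
#' @return List with `volumes` (per patient id, named list of contrasts),
#'   `fields`, `sites` (flat list of `biopsy_site`s) and `config`.
#' @export
generate_cohort <- function(config, n_patients = config$n_patients,
                            n_sites_total = NULL) {
  per <- rep(config$n_biopsies_per_patient, n_patients)
  if (!is.null(n_sites_total)) {
    per <- rep(n_sites_total %/% n_patients, n_patients)
    extra <- n_sites_total %% n_patients
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  }
  volumes <- list(); fields <- list(); sites <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%02d", i)
    pat <- generate_patient(config, i)
    volumes[[pid]] <- pat$volumes
    fields[[pid]] <- pat$field
    set.seed(patient_seed(config, i) + 7L)
    sites <- c(sites, sample_biopsy_sites(pat$field, config, pid, per[i]))
  }
  list(volumes = volumes, fields = fields, sites = sites, config = config)
}

#' Write a cohort to disk
#'
#' Contrast volumes as NIfTI (`<patient>_<contrast>.nii.gz`) and the
#' biopsy table as CSV.
#'
#' @param cohort From [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$volumes))
    for (cn in contrast_names())
      write_volume(cohort$volumes[[pid]][[cn]],
                   file.path(dir, paste0(pid, "_", cn, ".nii.gz")))
  write_sites(cohort$sites, file.path(dir, "sites.csv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `volumes` (per patient) and `sites`.
#' @export
read_cohort <- function(dir) {
  sites <- read_sites(file.path(dir, "sites.csv"))
  pids <- unique(vapply(sites, `[[`, "", "patient_id"))
  volumes <- lapply(pids, function(pid) {
    v <- lapply(contrast_names(), function(cn)
      read_volume(file.path(dir, paste0(pid, "_", cn, ".nii.gz")),
                  name = cn))
    names(v) <- contrast_names()
    v
  })
  names(volumes) <- pids
  list(volumes = volumes, sites = sites)
}
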