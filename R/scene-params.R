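# Parameterisation of synthetic synaptic-bouton scenes.
#
# All coordinates and lengths are nanometres; areas are nm^2 and volumes nm^3
# internally. Reporting functions convert to um^2 / um^3.

UM2 <- 1e6   # nm^2 per um^2
UM3 <- 1e9   # nm^3 per um^3

#' Synaptic-vesicle pool composition
#'
#' Fractions of the total vesicle complement falling in the perimeter bins
#' used throughout cortical bouton morphometry: p <= 10 nm (strict readily
#' releasable pool), 10 < p <= 20 nm (loose RRP criterion), 20 < p < 60 nm
#' (unnamed intermediate bin), 60 <= p <= 200 nm (recycling pool) and
#' p > 200 nm (resting pool), where p is the minimal distance from the vesicle
#' centre to the presynaptic density minus the vesicle radius.
#'
#' @param frac_p10,frac_p10_20,frac_20_60,frac_rp,frac_resting nonnegative
#'   fractions summing to 1.
#' @param docked_fraction fraction of the p10 vesicles flagged as docked
#'   (membrane-contacting, p = 0); in `[0, 1]`.
#' @return a `pool_spec` list.
#' @export
pool_spec <- function(frac_p10 = 0.004, frac_p10_20 = 0.006, frac_20_60 = 0.038,
                      frac_rp = 0.12, frac_resting = 0.832,
                      docked_fraction = 0.3) {
  f <- c(frac_p10 = frac_p10, frac_p10_20 = frac_p10_20, frac_20_60 = frac_20_60,
         frac_rp = frac_rp, frac_resting = frac_resting)
  if (any(f < 0)) stop("pool fractions must be nonnegative")
  if (abs(sum(f) - 1) > 1e-6) stop("pool fractions must sum to 1 (got ", sum(f), ")")
  if (docked_fraction < 0 || docked_fraction > 1)
    stop("docked_fraction must be in [0, 1]")
  structure(c(as.list(f), list(docked_fraction = docked_fraction)),
            class = "pool_spec")
}

#' Synaptic-cleft width specification
#'
#' @param lateral_width,central_width cleft widths in nm at the lateral edges
#'   and centre of the apposition zone (typically 15-25 nm, with a slight
#'   central broadening).
#' @param noise_sd per-measurement gaussian noise, nm.
#' @return a `cleft_spec` list.
#' @export
cleft_spec <- function(lateral_width = 17, central_width = 20, noise_sd = 1) {
  if (lateral_width <= 0 || central_width <= 0) stop("cleft widths must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(lateral_width = lateral_width, central_width = central_width,
                 noise_sd = noise_sd), class = "cleft_spec")
}

#' Parameters of a synthetic synaptic-bouton scene
#'
#' Targets are realised by the generator to within 2\% for areas and volumes
#' and exactly for integer counts.
#'
#' @param bouton_kind `"en_passant"` (swelling along a through-running axon)
#'   or `"end_terminal"`.
#' @param bouton_surface_area_target bouton membrane surface area, nm^2.
#' @param bouton_volume_target bouton volume, nm^3; together with the surface
#'   target this fixes the elongation of the bouton. `NULL` uses a default
#'   shape factor.
#' @param n_az number of active zones (1-3).
#' @param az_area_targets numeric vector (length `n_az`) of presynaptic-density
#'   patch areas, nm^2.
#' @param az_shape one of `"macular"`, `"perforated"`, `"horseshoe"`, `"ring"`
#'   (recycled across AZs if shorter than `n_az`).
#' @param total_sv total number of small clear synaptic vesicles.
#' @param pools [pool_spec()] pool composition.
#' @param sv_diameter_range vesicle diameter interval, nm (default 30-40).
#' @param n_dense_core number of large dense-core vesicles (diameter 70-90 nm).
#' @param n_mitochondria number of mitochondria.
#' @param mito_volume_fraction_target mitochondrial fraction of bouton volume.
#' @param cleft [cleft_spec()].
#' @param target_kind postsynaptic target: `"spine"`, `"shaft"` or
#'   `"astrocytic_process"`.
#' @param rng_seed integer seed; the scene is a deterministic function of the
#'   parameters including this seed.
#' @return a `scene_params` list.
#' @export
scene_params <- function(bouton_kind = c("en_passant", "end_terminal"),
                         bouton_surface_area_target = 6.09 * UM2,
                         bouton_volume_target = 0.63 * UM3,
                         n_az = 1L,
                         az_area_targets = 0.23 * UM2,
                         az_shape = "macular",
                         total_sv = 1519L,
                         pools = pool_spec(),
                         sv_diameter_range = c(30, 40),
                         n_dense_core = 3L,
                         n_mitochondria = 4L,
                         mito_volume_fraction_target = 0.15,
                         cleft = cleft_spec(),
                         target_kind = c("spine", "shaft", "astrocytic_process"),
                         rng_seed = 1L) {
  bouton_kind <- match.arg(bouton_kind)
  target_kind <- match.arg(target_kind)
  n_az <- as.integer(n_az)
  if (!n_az %in% 1:3) stop("n_az must be 1, 2 or 3")
  az_area_targets <- rep_len(as.numeric(az_area_targets), n_az)
  az_shape <- rep_len(as.character(az_shape), n_az)
  if (!all(az_shape %in% c("macular", "perforated", "horseshoe", "ring")))
    stop("unknown az_shape")
  if (bouton_surface_area_target <= 0 || any(az_area_targets <= 0))
    stop("area targets must be positive")
  if (!is.null(bouton_volume_target) && bouton_volume_target <= 0)
    stop("bouton_volume_target must be positive")
  if (total_sv < 0) stop("total_sv must be nonnegative")
  if (mito_volume_fraction_target < 0 || mito_volume_fraction_target >= 0.5)
    stop("mito_volume_fraction_target must be in [0, 0.5)")
  if (length(sv_diameter_range) != 2L || any(sv_diameter_range <= 0) ||
      diff(sv_diameter_range) < 0)
    stop("sv_diameter_range must be an increasing positive interval")
  stopifnot(inherits(pools, "pool_spec"), inherits(cleft, "cleft_spec"))
  structure(list(
    bouton_kind = bouton_kind,
    bouton_surface_area_target = bouton_surface_area_target,
    bouton_volume_target = bouton_volume_target,
    n_az = n_az, az_area_targets = az_area_targets, az_shape = az_shape,
    total_sv = as.integer(total_sv), pools = pools,
    sv_diameter_range = as.numeric(sv_diameter_range),
    n_dense_core = as.integer(n_dense_core),
    n_mitochondria = as.integer(n_mitochondria),
    mito_volume_fraction_target = mito_volume_fraction_target,
    cleft = cleft, target_kind = target_kind,
    rng_seed = as.integer(rng_seed)), class = "scene_params")
}

# Layer presets: representative published means for adult human temporal lobe
# neocortex (TLN) layer 4 and layer 5 excitatory boutons. Pool fractions are
# derived from the mean pool counts relative to the mean total vesicle number.
.tln_presets <- list(
  L4_TLN = list(surface = 2.50 * UM2, volume = 0.16 * UM3,
                preaz = 0.13 * UM2, psd = 0.13 * UM2,
                cleft_lateral = 14.11, cleft_central = 16.47,
                total_sv = 1820.64,
                p10 = 20.20, p20 = 48.59, rp = 382.10, resting = 1251.82,
                docked = 5.5, n_az_range = 1:3, n_az_typical = 1L,
                sd = list(surface = 1.78 * UM2, volume = 0.16 * UM3,
                          preaz = 0.07 * UM2, total_sv = 980.34)),
  L5_TLN = list(surface = 6.09 * UM2, volume = 0.63 * UM3,
                preaz = 0.23 * UM2, psd = 0.28 * UM2,
                cleft_lateral = 17.24, cleft_central = 19.05,
                total_sv = 1518.52,
                p10 = 5.42, p20 = 15.21, rp = 181.86, resting = 1264.05,
                docked = NA, n_az_range = 1:2, n_az_typical = 1L,
                sd = list(surface = 0.85 * UM2, volume = 0.17 * UM3,
                          preaz = 0.05 * UM2, total_sv = 303.18))
)

#' Scene parameters preset for a human temporal-lobe neocortex layer
#'
#' Returns [scene_params()] whose targets equal representative layer means for
#' human TLN excitatory boutons: bouton surface area and volume, presynaptic
#' density area, cleft widths, total vesicle number and the pool composition
#' (strict p10 RRP, loose p20 RRP, recycling 60-200 nm, resting > 200 nm, with
#' the unnamed 20-60 nm bin absorbing the remainder).
#'
#' Named pool bins are rounded to the nearest integer count and the
#' intermediate bin absorbs the rounding remainder, so realised integer counts
#' reproduce the preset means exactly.
#'
#' @param layer `"L4_TLN"` or `"L5_TLN"`.
#' @param rng_seed integer seed passed through to [scene_params()].
#' @return a `scene_params` object.
#' @export
scene_preset <- function(layer = c("L5_TLN", "L4_TLN"), rng_seed = 1L) {
  layer <- match.arg(layer)
  p <- .tln_presets[[layer]]
  total <- as.integer(round(p$total_sv))
  fr <- pool_fractions_from_counts(
    total_mean = p$total_sv, p10 = p$p10, p20 = p$p20,
    rp = p$rp, resting = p$resting)
  docked_fraction <- if (is.finite(p$docked)) min(1, p$docked / p$p10) else 0.3
  sp <- scene_params(
    bouton_kind = "en_passant",
    bouton_surface_area_target = p$surface,
    bouton_volume_target = p$volume,
    n_az = p$n_az_typical,
    az_area_targets = rep(p$preaz, p$n_az_typical),
    az_shape = "macular",
    total_sv = total,
    pools = do.call(pool_spec, c(fr, list(docked_fraction = docked_fraction))),
    n_mitochondria = 5L,
    cleft = cleft_spec(lateral_width = p$cleft_lateral,
                       central_width = p$cleft_central, noise_sd = 1),
    target_kind = "spine",
    rng_seed = rng_seed)
  attr(sp, "layer") <- layer
  attr(sp, "layer_means") <- p
  sp
}

pool_fractions_from_counts <- function(total_mean, p10, p20, rp, resting) {
  stopifnot(p20 >= p10, total_mean >= p20 + rp + resting)
  inter <- total_mean - p20 - rp - resting
  list(frac_p10 = p10 / total_mean,
       frac_p10_20 = (p20 - p10) / total_mean,
       frac_20_60 = inter / total_mean,
       frac_rp = rp / total_mean,
       frac_resting = resting / total_mean)
}

#' Integer pool-bin counts for a scene
#'
#' Named bins (p10, p10-20, recycling, resting) are rounded to the nearest
#' integer; the intermediate 20-60 nm bin absorbs the remainder so the bins
#' sum exactly to `total_sv`.
#' @param pools a [pool_spec()].
#' @param total_sv integer total.
#' @return named integer vector over the five bins.
#' @export
pool_counts_from_spec <- function(pools, total_sv) {
  total_sv <- as.integer(total_sv)
  if (total_sv == 0L)
    return(c(RRP_p10 = 0L, RRP_p10_20 = 0L, intermediate_20_60 = 0L,
             RP_60_200 = 0L, resting_gt200 = 0L))
  n_p10 <- as.integer(round(pools$frac_p10 * total_sv))
  n_p10_20 <- as.integer(round(pools$frac_p10_20 * total_sv))
  n_rp <- as.integer(round(pools$frac_rp * total_sv))
  n_rest <- as.integer(round(pools$frac_resting * total_sv))
  n_int <- total_sv - n_p10 - n_p10_20 - n_rp - n_rest
  if (n_int < 0L) stop("pool rounding infeasible: named bins exceed total_sv")
  c(RRP_p10 = n_p10, RRP_p10_20 = n_p10_20, intermediate_20_60 = n_int,
    RP_60_200 = n_rp, resting_gt200 = n_rest)
}
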