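#' Per-lesion uptake and burden metrics
#'
#' For each lesion: `suv_mean` and `suv_max` over its voxels, the molecular
#' tumor volume `mtv_ml` (voxel count x voxel volume, ml) and the
#' intensity-volume burden product `mtv_ml * suv_mean`, reported as TLG
#' (total lesion glycolysis) on the FDG tracer and TLC (total lesion
#' CXCR4-expression) on the CXCR4 tracer.
#'
#' @param lesion_set A `lesion_set` with at least one lesion.
#' @param pet SUV `scalar_volume` on the lesion grid.
#' @return Data frame: `label`, `n_voxels`, `volume_ml`, `suv_mean`,
#'   `suv_max`, `mtv_ml`, `tl_burden`.
#' @export
lesion_metrics <- function(lesion_set, pet) {
  stopifnot(inherits(lesion_set, "lesion_set"),
            inherits(pet, "scalar_volume"))
  if (!identical(dim(lesion_set$labels), dim(pet$values)))
    stop("PET volume is not on the lesion grid", call. = FALSE)
  if (any(vapply(lesion_set$voxels, length, integer(1)) == 0L))
    stop("empty lesion encountered", call. = FALSE)
  les <- lesion_set$lesions
  suv_mean <- vapply(lesion_set$voxels,
                     function(v) mean(pet$values[v]), numeric(1))
  suv_max <- vapply(lesion_set$voxels,
                    function(v) max(pet$values[v]), numeric(1))
  data.frame(label = les$label, n_voxels = les$n_voxels,
             volume_ml = les$volume_ml, suv_mean = suv_mean,
             suv_max = suv_max, mtv_ml = les$volume_ml,
             tl_burden = les$volume_ml * suv_mean)
}

#' Canonical bracket-notation feature name
#'
#' Patient-level features are keyed
#' `<metric>[<tracer> <site> <concordance>]`, e.g.
#' `SUVmean[FDG medullary concordant]`.
#'
#' @param metric,tracer,site,class Character scalars.
#' @return Character scalar.
#' @export
bracket_name <- function(metric, tracer, site, class) {
  sprintf("%s[%s %s %s]", metric, tracer, site, class)
}

#' Canonical patient-level imaging feature names
#'
#' The full bracket-notation feature set: for each tracer x site x
#' concordance stratum, SUVmean, SUVmax, MTV and the tracer's burden product
#' (TLG for FDG, TLC for CXCR4), plus per-tracer sDmax and the spleen
#' reference uptake.
#'
#' @param tracers Character vector of the two tracer tags.
#' @return Character vector of column names.
#' @export
canonical_feature_names <- function(tracers = c("FDG", "CXCR4")) {
  out <- character(0)
  for (tr in tracers) {
    burden <- if (tr == tracers[1]) "TLG" else "TLC"
    for (site in c("medullary", "extramedullary"))
      for (cls in c("concordant", "discordant"))
        out <- c(out, vapply(c("SUVmean", "SUVmax", "MTV", burden),
                             bracket_name, character(1),
                             tracer = tr, site = site, class = cls))
  }
  c(out, paste0("sDmax_", tracers), "spleen_SUVmean")
}

#' Aggregate lesion metrics to patient-level bracket features
#'
#' For each of the eight strata (2 tracers x medullary/extramedullary x
#' concordant/discordant): `SUVmean` is the voxel-pooled (volume-weighted)
#' mean over the stratum's lesions, i.e. the mean SUV over the union region;
#' `SUVmax` is the maximum; MTV and TLG/TLC are sums.  Empty strata yield
#' `NA` for the intensity metrics (SUVmean, SUVmax) and 0 for the burden
#' metrics (MTV, TLG/TLC): absence of burden is information, absence of
#' intensity is missingness.
#'
#' @param metrics_a,metrics_b Per-lesion metric tables from
#'   [lesion_metrics()] for the two tracers.
#' @param category_a,category_b Per-lesion categories from
#'   [adjudicate_concordance()].
#' @param site_a,site_b Per-lesion sites from [classify_site()].
#' @param tracers Tracer tags, default `c("FDG", "CXCR4")`.
#' @param pooled Use voxel-pooled SUVmean (default); `FALSE` averages the
#'   per-lesion means instead.
#' @return Named numeric vector over [canonical_feature_names()] minus the
#'   sDmax/spleen entries.
#' @export
aggregate_patient <- function(metrics_a, metrics_b, category_a, category_b,
                              site_a, site_b, tracers = c("FDG", "CXCR4"),
                              pooled = TRUE) {
  stopifnot(nrow(metrics_a) == length(category_a),
            nrow(metrics_a) == length(site_a),
            nrow(metrics_b) == length(category_b),
            nrow(metrics_b) == length(site_b))
  per_tracer <- list(list(m = metrics_a, cat = category_a, site = site_a),
                     list(m = metrics_b, cat = category_b, site = site_b))
  out <- numeric(0)
  for (k in 1:2) {
    tr <- tracers[k]
    burden <- if (k == 1L) "TLG" else "TLC"
    dat <- per_tracer[[k]]
    cls <- ifelse(dat$cat == "concordant", "concordant", "discordant")
    for (site in c("medullary", "extramedullary")) {
      for (cc in c("concordant", "discordant")) {
        sel <- dat$site == site & cls == cc
        m <- dat$m[sel, , drop = FALSE]
        if (nrow(m)) {
          suv_mean <- if (pooled)
            sum(m$suv_mean * m$n_voxels) / sum(m$n_voxels)
          else mean(m$suv_mean)
          vals <- c(suv_mean, max(m$suv_max), sum(m$mtv_ml), sum(m$tl_burden))
        } else {
          vals <- c(NA_real_, NA_real_, 0, 0)
        }
        names(vals) <- vapply(c("SUVmean", "SUVmax", "MTV", burden),
                              bracket_name, character(1),
                              tracer = tr, site = site, class = cc)
        out <- c(out, vals)
      }
    }
  }
  out
}

#' Body surface area (m^2)
#'
#' DuBois-DuBois by default:
#' `0.007184 * height_cm^0.725 * weight_kg^0.425`; Mosteller
#' (`sqrt(height_cm * weight_kg / 3600)`) as an alternative.
#'
#' @param height_cm,weight_kg Positive anthropometrics.
#' @param formula `"DuBois"` (default) or `"Mosteller"`.
#' @return BSA in m^2.
#' @export
body_surface_area <- function(height_cm, weight_kg,
                              formula = c("DuBois", "Mosteller")) {
  formula <- match.arg(formula)
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive", call. = FALSE)
  switch(formula,
         DuBois = 0.007184 * height_cm^0.725 * weight_kg^0.425,
         Mosteller = sqrt(height_cm * weight_kg / 3600))
}

#' Standardized maximum inter-lesion distance (sDmax)
#'
#' The largest pairwise Euclidean distance between lesion centroids (cm),
#' divided by body surface area (m^2): a dissemination metric in cm/m^2.
#' With fewer than two lesions the distance is undefined and `NA` is
#' returned.
#'
#' @param centroids_mm Numeric n x 3 matrix of lesion centroids in mm.
#' @param height_cm,weight_kg Anthropometrics for the BSA denominator.
#' @param bsa_formula Passed to [body_surface_area()].
#' @return sDmax in cm/m^2, or `NA` with fewer than 2 lesions.
#' @export
sdmax <- function(centroids_mm, height_cm, weight_kg,
                  bsa_formula = c("DuBois", "Mosteller")) {
  centroids_mm <- matrix(as.numeric(centroids_mm), ncol = 3)
  if (nrow(centroids_mm) < 2L) return(NA_real_)
  dmax_cm <- max(stats::dist(centroids_mm)) / 10
  dmax_cm / body_surface_area(height_cm, weight_kg, match.arg(bsa_formula))
}

#' Spleen reference uptake
#'
#' Mean SUV over spleen voxels after excluding every voxel belonging to any
#' lesion mask of either tracer.  `NA` (with a warning) when lesions cover
#' the whole spleen.
#'
#' @param pet SUV `scalar_volume`.
#' @param spleen_mask Binary `scalar_volume` on the PET grid.
#' @param lesion_masks List of binary `scalar_volume`s to exclude (may be
#'   empty).
#' @return Mean spleen SUV, or `NA`.
#' @export
spleen_reference <- function(pet, spleen_mask, lesion_masks = list()) {
  stopifnot(inherits(pet, "scalar_volume"))
  stop_if_grid_mismatch(pet, spleen_mask, "PET and spleen mask")
  keep <- spleen_mask$values > 0
  for (lm in lesion_masks) {
    stop_if_grid_mismatch(pet, lm, "PET and lesion mask")
    keep <- keep & !(lm$values > 0)
  }
  if (!any(keep)) {
    warning("spleen fully covered by lesions; reference uptake is NA")
    return(NA_real_)
  }
  mean(pet$values[keep])
}
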