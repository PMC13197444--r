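#' Label lesions as connected components of a binary mask
#'
#' Connected components are computed under 26-connectivity by default (all
#' voxels sharing a face, edge or corner are neighbors), the standard choice
#' for blob-like PET lesions; 6-connectivity (faces only) is available.
#' Labels are consecutive positive integers ordered by the first (smallest
#' linear index) voxel of each component, so labelling is deterministic.
#' Centroids are intensity-unweighted means of member voxel centers, in mm.
#'
#' @param mask Binary `scalar_volume`.
#' @param pet Optional SUV `scalar_volume` on the same grid (grid checked;
#'   values are not used here but by [lesion_metrics()]).
#' @param tracer Tracer tag carried through downstream tables
#'   (e.g. `"FDG"`, `"CXCR4"`).
#' @param connectivity 26 (default) or 6.
#' @return A `lesion_set`: list with `tracer`, `labels` (integer array, 0 =
#'   background), `lesions` (data frame: `label`, `n_voxels`, `volume_ml`,
#'   `centroid_x_mm`, `centroid_y_mm`, `centroid_z_mm`) and `voxels` (list of
#'   linear voxel index vectors, parallel to `lesions`).
#' @export
label_components <- function(mask, pet = NULL, tracer = "FDG",
                             connectivity = 26) {
  stopifnot(inherits(mask, "scalar_volume"))
  if (!all(mask$values %in% c(0, 1)))
    stop("`mask` must be binary", call. = FALSE)
  if (!is.null(pet)) stop_if_grid_mismatch(mask, pet, "mask and PET")
  if (!connectivity %in% c(6, 26))
    stop("`connectivity` must be 6 or 26", call. = FALSE)
  dm <- dim(mask$values)
  idx <- which(mask$values != 0)
  lab <- array(0L, dm)
  if (length(idx) == 0L) {
    return(new_lesion_set(tracer, lab, mask, integer(0), list()))
  }
  m <- length(idx)
  id_map <- integer(prod(dm))
  id_map[idx] <- seq_len(m)
  coords <- arrayInd(idx, dm)
  offs <- neighbor_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nc <- sweep(coords, 2, offs[r, ], "+")
    ok <- nc[, 1] >= 1 & nc[, 1] <= dm[1] &
      nc[, 2] >= 1 & nc[, 2] <= dm[2] &
      nc[, 3] >= 1 & nc[, 3] <= dm[3]
    if (!any(ok)) next
    lin <- (nc[ok, 3] - 1) * dm[1] * dm[2] + (nc[ok, 2] - 1) * dm[1] +
      nc[ok, 1]
    nid <- id_map[lin]
    keep <- nid > 0L
    from <- c(from, which(ok)[keep])
    to <- c(to, nid[keep])
  }
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)$membership
  # relabel components consecutively, ordered by first voxel occurrence
  first <- !duplicated(comp)
  relab <- integer(max(comp))
  relab[comp[first]] <- seq_len(sum(first))
  comp <- relab[comp]
  lab[idx] <- comp
  voxels <- split(idx, comp)
  new_lesion_set(tracer, lab, mask, seq_along(voxels), voxels)
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
    # keep one of each +/- pair: edges are undirected
    g[g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0))),
      , drop = FALSE]
  }
}

new_lesion_set <- function(tracer, labels, grid_vol, label_ids, voxels) {
  dm <- dim(labels)
  if (length(label_ids)) {
    n_vox <- vapply(voxels, length, integer(1))
    cents <- t(vapply(voxels, function(v) {
      colMeans(matrix(arrayInd(v, dm), ncol = 3))
    }, numeric(3)))
    cents <- sweep(sweep(cents - 1, 2, grid_vol$spacing_mm, "*"), 2,
                   grid_vol$origin_mm, "+")
    lesions <- data.frame(
      label = as.integer(label_ids),
      n_voxels = as.integer(n_vox),
      volume_ml = n_vox * prod(grid_vol$spacing_mm) / 1000,
      centroid_x_mm = cents[, 1], centroid_y_mm = cents[, 2],
      centroid_z_mm = cents[, 3]
    )
  } else {
    lesions <- data.frame(label = integer(0), n_voxels = integer(0),
                          volume_ml = numeric(0), centroid_x_mm = numeric(0),
                          centroid_y_mm = numeric(0), centroid_z_mm = numeric(0))
    voxels <- list()
  }
  structure(list(tracer = tracer, labels = labels,
                 spacing_mm = grid_vol$spacing_mm,
                 origin_mm = grid_vol$origin_mm,
                 lesions = lesions, voxels = voxels),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("<lesion_set> tracer %s: %d lesion(s), %d voxel(s)\n",
              x$tracer, nrow(x$lesions), sum(x$lesions$n_voxels)))
  invisible(x)
}

lesion_set_grid <- function(ls) {
  list(values = ls$labels, spacing_mm = ls$spacing_mm,
       origin_mm = ls$origin_mm)
}

stop_if_lesion_grid_mismatch <- function(a, b, what) {
  ok <- identical(dim(a$labels), dim(b$labels)) &&
    all(abs(a$spacing_mm - b$spacing_mm) <= 1e-6) &&
    all(abs(a$origin_mm - b$origin_mm) <= 1e-6)
  if (!ok) stop(sprintf("%s are not on the same grid", what), call. = FALSE)
  invisible(TRUE)
}

#' Threshold-based lesion segmentation
#'
#' Simple SUV-threshold segmentation inside a body mask: voxels with
#' SUV >= `suv_threshold`.  This is the built-in segmenter used when no
#' external lesion masks are supplied.
#'
#' @param pet SUV `scalar_volume`.
#' @param suv_threshold SUV cutoff.
#' @param body_mask Binary `scalar_volume` on the same grid.
#' @return Binary `scalar_volume`.
#' @export
threshold_segment <- function(pet, suv_threshold, body_mask) {
  stopifnot(inherits(pet, "scalar_volume"))
  stop_if_grid_mismatch(pet, body_mask, "PET and body mask")
  scalar_volume(array(as.numeric(pet$values >= suv_threshold &
                                   body_mask$values > 0), dim(pet$values)),
                pet$spacing_mm, pet$origin_mm, units = "binary")
}

#' Cross-tracer lesion overlap matrix
#'
#' All pairs of lesions (one from each tracer) with at least one shared
#' voxel, with exact intersection voxel counts.  Both lesion sets must live
#' on the same grid (masks are propagated to a common grid first when the
#' two PET grids differ).
#'
#' @param a,b `lesion_set` objects on the same grid.
#' @return Data frame `label_a`, `label_b`, `intersection_voxels`.
#' @export
overlap_matrix <- function(a, b) {
  stopifnot(inherits(a, "lesion_set"), inherits(b, "lesion_set"))
  stop_if_lesion_grid_mismatch(a, b, "lesion sets")
  sel <- a$labels > 0L & b$labels > 0L
  if (!any(sel))
    return(data.frame(label_a = integer(0), label_b = integer(0),
                      intersection_voxels = integer(0)))
  fa <- a$labels[sel]; fb <- b$labels[sel]
  tb <- table(fa, fb)
  df <- as.data.frame(tb, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, , drop = FALSE]
  out <- data.frame(label_a = as.integer(df$fa), label_b = as.integer(df$fb),
                    intersection_voxels = as.integer(df$Freq))
  out[order(out$label_a, out$label_b), , drop = FALSE]
}

#' Adjudicate cross-tracer lesion concordance
#'
#' A lesion is concordant when it participates in at least one cross-tracer
#' pair whose volumetric overlap fraction exceeds `threshold` (strict `>` by
#' default); otherwise it is a tracer-only (discordant) lesion.  The overlap
#' fraction of a pair is `intersection / denominator`, where the denominator
#' is the smaller of the two lesion volumes by default (symmetric and robust
#' when one tracer's lesion is much larger); `"a"`, `"b"` and `"union"` are
#' available alternatives.  Matching is many-to-many: concordance is a
#' per-lesion property and no one-to-one assignment is forced.  For cohort
#' counting, a concordant lesion and its partner(s) count as one lesion:
#' concordant units are the connected components of the qualifying-pair
#' graph, so `n_concordant_units + n_a_only + n_b_only` partitions the
#' total unique lesion count.
#'
#' @param pairs Output of [overlap_matrix()].
#' @param a,b The `lesion_set` objects the pairs refer to.
#' @param threshold Overlap fraction threshold in (0, 1); default 0.10.
#' @param denominator `"min"` (default), `"a"`, `"b"` or `"union"`.
#' @param strict Use strict `>` (default TRUE).
#' @return A `concordance_table`: list with `pairs` (with `overlap_fraction`
#'   and `qualifying`), `category_a`/`category_b` (per-label categories),
#'   `pair_group_a`/`pair_group_b` (concordant unit id per label, NA when
#'   not concordant), and `counts`.
#' @export
adjudicate_concordance <- function(pairs, a, b, threshold = 0.10,
                                   denominator = c("min", "a", "b", "union"),
                                   strict = TRUE) {
  denominator <- match.arg(denominator)
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  na <- nrow(a$lesions); nb <- nrow(b$lesions)
  vol_a <- a$lesions$n_voxels[match(pairs$label_a, a$lesions$label)]
  vol_b <- b$lesions$n_voxels[match(pairs$label_b, b$lesions$label)]
  denom <- switch(denominator,
                  min = pmin(vol_a, vol_b),
                  a = vol_a, b = vol_b,
                  union = vol_a + vol_b - pairs$intersection_voxels)
  frac <- if (nrow(pairs)) pairs$intersection_voxels / denom else numeric(0)
  qual <- if (strict) frac > threshold else frac >= threshold
  pairs$overlap_fraction <- frac
  pairs$qualifying <- qual
  conc_a <- sort(unique(pairs$label_a[qual]))
  conc_b <- sort(unique(pairs$label_b[qual]))
  cat_a <- ifelse(a$lesions$label %in% conc_a, "concordant",
                  paste0(a$tracer, "_only"))
  cat_b <- ifelse(b$lesions$label %in% conc_b, "concordant",
                  paste0(b$tracer, "_only"))
  # concordant units = connected components of the qualifying-pair graph
  group_a <- rep(NA_integer_, na); group_b <- rep(NA_integer_, nb)
  n_units <- 0L
  if (any(qual)) {
    qa <- pairs$label_a[qual]; qb <- pairs$label_b[qual]
    verts <- c(paste0("a", sort(unique(qa))), paste0("b", sort(unique(qb))))
    g <- igraph::graph_from_edgelist(cbind(paste0("a", qa), paste0("b", qb)),
                                     directed = FALSE)
    memb <- igraph::components(g)$membership
    n_units <- max(memb)
    for (lab in unique(qa))
      group_a[match(lab, a$lesions$label)] <- memb[[paste0("a", lab)]]
    for (lab in unique(qb))
      group_b[match(lab, b$lesions$label)] <- memb[[paste0("b", lab)]]
  }
  counts <- list(concordant_units = n_units,
                 a_only = sum(cat_a != "concordant"),
                 b_only = sum(cat_b != "concordant"))
  counts$total_unique <- counts$concordant_units + counts$a_only + counts$b_only
  structure(list(pairs = pairs, category_a = cat_a, category_b = cat_b,
                 pair_group_a = group_a, pair_group_b = group_b,
                 counts = counts, threshold = threshold,
                 denominator = denominator, strict = strict,
                 tracer_a = a$tracer, tracer_b = b$tracer),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf(
    "<concordance_table> %d concordant unit(s), %d %s-only, %d %s-only (threshold %s %.2g, denom %s)\n",
    x$counts$concordant_units, x$counts$a_only, x$tracer_a,
    x$counts$b_only, x$tracer_b, if (x$strict) ">" else ">=",
    x$threshold, x$denominator))
  invisible(x)
}

#' Classify lesion site: medullary vs. extramedullary
#'
#' A lesion is medullary when at least `threshold` (default 10%, inclusive
#' `>=`) of its voxels fall inside the bone mask, extramedullary otherwise.
#'
#' @param lesion_set A `lesion_set`.
#' @param bone_mask Binary `scalar_volume` on the lesion grid.
#' @param threshold Bone overlap fraction; default 0.10.
#' @param strict Use strict `>` instead of the default inclusive `>=`.
#' @return Character vector (`"medullary"`/`"extramedullary"`) per lesion.
#' @export
classify_site <- function(lesion_set, bone_mask, threshold = 0.10,
                          strict = FALSE) {
  stopifnot(inherits(lesion_set, "lesion_set"),
            inherits(bone_mask, "scalar_volume"))
  if (!identical(dim(lesion_set$labels), dim(bone_mask$values)))
    stop("bone mask is not on the lesion grid", call. = FALSE)
  unname(vapply(lesion_set$voxels, function(v) {
    frac <- sum(bone_mask$values[v] > 0) / length(v)
    med <- if (strict) frac > threshold else frac >= threshold
    if (med) "medullary" else "extramedullary"
  }, character(1)))
}

#' Flag splenic lesions
#'
#' A lesion is splenic when it shares at least one voxel with the spleen
#' mask; splenic lesions are excluded from the spleen reference uptake.
#'
#' @param lesion_set A `lesion_set`.
#' @param spleen_mask Binary `scalar_volume` on the lesion grid.
#' @return Logical vector per lesion.
#' @export
flag_spleen <- function(lesion_set, spleen_mask) {
  stopifnot(inherits(lesion_set, "lesion_set"))
  if (!identical(dim(lesion_set$labels), dim(spleen_mask$values)))
    stop("spleen mask is not on the lesion grid", call. = FALSE)
  unname(vapply(lesion_set$voxels, function(v) any(spleen_mask$values[v] > 0),
                logical(1)))
}
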