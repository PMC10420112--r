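#' Signed surface-to-surface deviation
#'
#' Samples the query surface uniformly by area, pairs every sample with
#' its exact nearest-facet point on the reference mesh, and signs the
#' distance by the reference facet normal (positive = outside the
#' reference, i.e. the plate standing off the bone). This is the
#' geometric-accuracy measure of the pipeline.
#'
#' @param query a `tri_mesh` or a [loft_surface()] result.
#' @param reference reference `tri_mesh` (e.g. the bone).
#' @param n_samples number of query samples (>= 100).
#' @param footprint_only crop the reference to the query's inflated
#'   bounding box before measuring (the plate footprint, not the whole
#'   bone).
#' @param seed RNG seed for the area-uniform sampling.
#' @param query_mesh_res resolution `c(nu, nv)` used when `query` is a
#'   parametric surface.
#' @return object of class `deviation_report`: `distances`, `median`,
#'   `median_abs`, `max_abs`, `percentiles` (5/25/75/95), `n_samples`,
#'   `footprint_only`, `reference`.
#' @export
surface_deviation <- function(query, reference, n_samples = 1000L,
                              footprint_only = TRUE, seed = 1L,
                              query_mesh_res = c(80L, 24L)) {
  if (n_samples < 100L) stop_pf("pf_parameter_error", "need n_samples >= 100")
  if (inherits(query, "plate_surface")) {
    query <- surface_to_mesh(query, query_mesh_res[1], query_mesh_res[2])
  }
  ref <- reference
  if (footprint_only) {
    lo <- apply(query$vertices, 2, min)
    hi <- apply(query$vertices, 2, max)
    pad <- 0.1 * max(hi - lo) + 5
    keep <- rep(TRUE, nrow(ref$faces))
    for (k in 1:3) {
      fv <- matrix(ref$vertices[ref$faces, k], ncol = 3)
      keep <- keep & rowSums(fv >= lo[k] - pad & fv <= hi[k] + pad) > 0
    }
    if (!any(keep)) {
      stop_pf("pf_geometry_error",
              "query footprint does not overlap the reference")
    }
    ref <- tri_mesh(ref$vertices, ref$faces[keep, , drop = FALSE],
                    provenance = ref$provenance, validate = TRUE)
  }
  smp <- sample_points_on_mesh(query, n_samples, seed = seed)
  cp <- closest_point_on_mesh(smp$points, ref)
  fn <- face_normals(ref)[cp$face, , drop = FALSE]
  sgn <- sign(rowSums((smp$points - cp$points) * fn))
  sgn[sgn == 0] <- 1
  d <- sgn * cp$dist
  structure(list(
    distances = d,
    median = stats::median(d),
    median_abs = stats::median(abs(d)),
    max_abs = max(abs(d)),
    percentiles = stats::quantile(d, c(0.05, 0.25, 0.75, 0.95)),
    n_samples = n_samples,
    footprint_only = footprint_only,
    reference = reference$provenance
  ), class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf(paste0("<deviation_report> n = %d vs '%s'%s\n",
                     "  median %+0.4f mm  |median| %.4f mm  max|d| %.4f mm\n",
                     "  p5 %+0.4f  p25 %+0.4f  p75 %+0.4f  p95 %+0.4f\n"),
              x$n_samples, x$reference,
              if (x$footprint_only) " (footprint only)" else "",
              x$median, x$median_abs, x$max_abs,
              x$percentiles[1], x$percentiles[2], x$percentiles[3],
              x$percentiles[4]))
  invisible(x)
}

#' @export
as.data.frame.deviation_report <- function(x, ...) {
  data.frame(distance_mm = x$distances)
}

# JSON-serializable summary (raw distances optional).
deviation_report_json <- function(report, raw = FALSE) {
  out <- list(median_mm = report$median,
              median_abs_mm = report$median_abs,
              max_abs_mm = report$max_abs,
              percentiles_mm = as.list(report$percentiles),
              n_samples = report$n_samples,
              footprint_only = report$footprint_only,
              reference = report$reference)
  if (raw) out$distances_mm <- report$distances
  out
}

#' Compare two deviation reports
#'
#' Relative change of the deviation maxima and medians of two reports
#' measured against the same reference (e.g. plate builds with 5 vs 9
#' sections).
#'
#' @param a,b [surface_deviation()] reports against the same reference.
#' @return list with `max_abs_change` and `median_change` (relative,
#'   e.g. -0.05 means 5% lower in `b`).
#' @export
compare_reports <- function(a, b) {
  if (!identical(a$reference, b$reference)) {
    stop_pf("pf_parameter_error",
            "reports measure different references ('%s' vs '%s')",
            a$reference, b$reference)
  }
  rel <- function(x, y, what) {
    if (x == 0) {
      if (y == 0) return(0)
      stop_pf("pf_undefined_ratio_error",
              "relative %s change undefined: baseline is 0", what)
    }
    (y - x) / x
  }
  list(max_abs_change = rel(a$max_abs, b$max_abs, "max"),
       median_change = if (a$median == 0 && b$median == 0) 0 else
         (b$median - a$median) / if (a$median != 0) a$median else NA_real_)
}
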