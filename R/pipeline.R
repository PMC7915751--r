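# End-to-end orchestration: render (or load) tiles per subject, segment and
# measure cells, estimate per-subject MitoTracker-low proportions, and run
# the cohort statistics.

#' Segment and measure every tile of a rendered subject
#'
#' @param rendered List of `render_tile()` results (or `mito_tile`s).
#' @param config A [seg_config()].
#' @param granularity Compute the granularity score per cell.
#' @return Data frame of cell records for the subject.
#' @export
measure_subject <- function(rendered, config = seg_config(),
                            granularity = FALSE) {
  recs <- lapply(rendered, function(r) {
    tile <- if (inherits(r, "mito_tile")) r else r$tile
    measure_cells(tile, segment_tile(tile, config), granularity = granularity)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Simulate and analyze a whole cohort
#'
#' Generates a synthetic cohort, renders and analyzes every subject's tiles
#' (simulate -> segment -> quantify -> subpop), joins the estimated
#' MitoTracker-low proportions onto the covariate table, and runs
#' [cohort_report()].
#'
#' @param cohort A [cohort_spec()].
#' @param scene A [scene_spec()]; its `seed` is combined with each subject.
#' @param n_tiles Tiles rendered per subject (protocol default 27; smaller
#'   values trade precision of the per-subject proportion for speed).
#' @param config A [seg_config()].
#' @param min_cells Per-subject cell floor for the density estimate.
#' @return List: `covariates` (with estimated `prop_low`), `subjects`
#'   (subpop results), `cells` (all cell records), `report`
#'   (cohort_report output).
#' @export
run_cohort_pipeline <- function(cohort = cohort_spec(), scene = scene_spec(),
                                n_tiles = 27L, config = seg_config(),
                                min_cells = 50L) {
  gen <- generate_cohort(cohort, n_tiles = n_tiles)
  cells <- do.call(rbind, lapply(gen$subjects, function(sub) {
    measure_subject(render_subject(scene, sub), config)
  }))
  subjects <- subpop_pipeline(cells, min_cells = min_cells)
  cov <- merge(gen$covariates, subjects[, c("patient_id", "prop_low")],
               by.x = "subject_id", by.y = "patient_id", all.x = TRUE)
  report <- cohort_report(cov)
  list(covariates = cov, subjects = subjects, cells = cells, report = report)
}
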