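#' Run the screening pipeline on a set of droplet wells
#'
#' End-to-end call -> quantify -> screen over a list of wells (or a droplet
#' CSV path). Wells failing the accepted-event QC are logged and excluded;
#' qualified results land in the screening report.
#'
#' @param wells list of [DropletWell-class], or a droplet CSV path.
#' @param cfg an [AssayConfig-class].
#' @param cutoffs a [ScreenCutoffs-class].
#' @param outDir output directory; created if missing. `NULL` skips writing.
#' @param sanger optional named list of [SangerOutcome-class] keyed by sample
#'   id (or a CSV path for [readSangerCSV()]).
#' @param layout optional plate-layout data.frame supplying gestational ages
#'   (`sample_id`, `gestational_age_weeks`).
#' @param minEvents QC threshold on accepted events.
#' @param quiet suppress per-well exclusion messages.
#' @return invisibly, a list with `report` (data.frame), `results`,
#'   `quants`, `excluded` (data.frame of excluded wells), and `paths`.
#' @examples
#' cfg <- AssayConfig(dropletsPerWell = 2000L)
#' wells <- list(
#'   simulateWell(SampleTruth(sampleId = "s1"), cfg, seed = 1, wellId = "A01"),
#'   simulateWell(blankTruth("s2"), cfg, seed = 2, wellId = "A02")
#' )
#' out <- runPipeline(wells, cfg, outDir = NULL, minEvents = 1000)
#' out$report
#' @export
runPipeline <- function(wells, cfg = AssayConfig(), cutoffs = ScreenCutoffs(),
                        outDir = NULL, sanger = NULL, layout = NULL,
                        minEvents = 10000, quiet = FALSE) {
  if (is.character(wells)) wells <- readDropletCSV(wells)
  if (is.character(sanger)) sanger <- readSangerCSV(sanger)
  excluded <- data.frame(well_id = character(), reason = character())
  results <- list()
  quants <- list()
  calls <- list()
  for (w in wells) {
    qc <- qcWell(w, minEvents)
    if (!qc$passed) {
      if (!quiet) message(sprintf("excluding well %s: %s", w@wellId, qc$reason))
      excluded <- rbind(excluded,
                        data.frame(well_id = w@wellId, reason = qc$reason))
      next
    }
    cl <- callWell(w, cfg, minEvents)
    q <- quantifyWell(cl, cfg)
    ga <- NA_real_
    if (!is.null(layout)) {
      i <- match(w@sampleId, layout$sample_id)
      if (!is.na(i)) ga <- layout$gestational_age_weeks[i]
    }
    st <- if (!is.null(sanger)) sanger[[w@sampleId]] else NULL
    res <- screenSample(q, cutoffs, secondTier = st, gestationalAgeWeeks = ga)
    calls[[length(calls) + 1L]] <- cl
    quants[[length(quants) + 1L]] <- q
    results[[length(results) + 1L]] <- res
  }
  if (length(results) == 0 && length(wells) > 0) {
    ddStop("all wells were excluded by QC", "ddQCError")
  }
  paths <- list()
  report <- NULL
  if (length(results)) {
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      callsTab <- do.call(rbind, calls)
      quantTab <- do.call(rbind, lapply(quants, function(q) {
        cbind(well_id = q@wellId, sample_id = q@sampleId, quantTable(q))
      }))
      paths$calls <- file.path(outDir, "calls.csv")
      paths$quant <- file.path(outDir, "quant.csv")
      paths$report <- file.path(outDir, "screen_report.tsv")
      utils::write.csv(callsTab, paths$calls, row.names = FALSE, quote = FALSE)
      utils::write.csv(quantTab, paths$quant, row.names = FALSE, quote = FALSE)
      report <- writeScreenReport(results, quants, paths$report)
    } else {
      report <- writeScreenReport(results, quants, tempfile(fileext = ".tsv"))
    }
  }
  invisible(list(
    report = report, results = results, quants = quants,
    excluded = excluded, paths = paths
  ))
}
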