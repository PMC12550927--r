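# Plain-text interchange: droplet amplitude CSV, call/quant CSV, screening
# report TSV, plate layout CSV, and the YAML pipeline configuration.
# Concentrations are serialized at full precision; display rounding happens
# only in the human-facing report.

.dropletCols <- c("well_id", "droplet_index", "ch1_amp", "ch2_amp",
                  "ch3_amp", "ch4_amp")

#' Write droplet wells to CSV
#'
#' One row per droplet: `well_id, droplet_index, ch1_amp..ch4_amp`. With
#' `writeTruth = TRUE` the simulator's occupancy labels go to a sibling file
#' `<path>.truth.csv` with matching columns.
#'
#' @param wells list of [DropletWell-class] (or a single well).
#' @param path output CSV path.
#' @param writeTruth also write truth labels when present.
#' @return invisibly, `path`.
#' @export
writeDropletCSV <- function(wells, path, writeTruth = FALSE) {
  if (is(wells, "DropletWell")) wells <- list(wells)
  tabs <- lapply(wells, function(w) {
    a <- amplitudes(w)
    data.frame(
      well_id = w@wellId, droplet_index = seq_len(nrow(a)),
      ch1_amp = a[, 1], ch2_amp = a[, 2], ch3_amp = a[, 3], ch4_amp = a[, 4]
    )
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  if (writeTruth) {
    tt <- lapply(wells, function(w) {
      l <- truthLabels(w)
      if (is.null(l)) return(NULL)
      data.frame(
        well_id = w@wellId, droplet_index = seq_len(nrow(l)),
        ch1 = l[, 1], ch2 = l[, 2], ch3 = l[, 3], ch4 = l[, 4]
      )
    })
    tt <- tt[!vapply(tt, is.null, logical(1))]
    if (length(tt)) {
      utils::write.csv(do.call(rbind, tt), paste0(path, ".truth.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}

#' Read droplet wells from CSV
#'
#' Inverse of [writeDropletCSV()]: rows are grouped by `well_id`; each
#' group's row count becomes the well's accepted event count.
#'
#' @param path CSV path.
#' @return list of [DropletWell-class], in order of first appearance.
#' @export
readDropletCSV <- function(path) {
  if (!file.exists(path)) {
    ddStop(sprintf("no such file: %s", path), "ddSchemaError")
  }
  tab <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) ddStop(sprintf("cannot parse %s: %s", path,
                                       conditionMessage(e)), "ddSchemaError")
  )
  if (nrow(tab) == 0) {
    ddStop(sprintf("empty droplet file: %s", path), "ddEmptyInputError")
  }
  missing <- setdiff(.dropletCols, names(tab))
  if (length(missing)) {
    ddStop(sprintf("droplet file %s is missing column(s): %s", path,
                   paste(missing, collapse = ", ")), "ddSchemaError")
  }
  ampCols <- paste0("ch", 1:4, "_amp")
  for (cc in ampCols) {
    if (!is.numeric(tab[[cc]])) {
      ddStop(sprintf("non-numeric amplitudes in column %s of %s", cc, path),
             "ddSchemaError")
    }
  }
  ids <- unique(tab$well_id)
  lapply(ids, function(id) {
    sub <- tab[tab$well_id == id, , drop = FALSE]
    DropletWell(
      amplitudes = as.matrix(sub[, ampCols]),
      sampleId = as.character(id), wellId = as.character(id)
    )
  })
}

#' Write a plate layout CSV
#'
#' Columns `sample_id, well_id, role, gestational_age_weeks`.
#'
#' @param layout data.frame with those columns.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePlateLayout <- function(layout, path) {
  need <- c("sample_id", "well_id", "role", "gestational_age_weeks")
  missing <- setdiff(need, names(layout))
  if (length(missing)) {
    ddStop(sprintf("layout is missing column(s): %s",
                   paste(missing, collapse = ", ")), "ddSchemaError")
  }
  utils::write.csv(layout[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read second-tier Sanger outcomes from CSV
#'
#' Columns `sample_id, assay_a, assay_b` (categorical levels as in
#' [SangerOutcome()]).
#'
#' @param path CSV path.
#' @return named list of [SangerOutcome-class], keyed by sample id.
#' @export
readSangerCSV <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay_a", "assay_b")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    ddStop(sprintf("Sanger file is missing column(s): %s",
                   paste(missing, collapse = ", ")), "ddSchemaError")
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    SangerOutcome(tab$assay_a[i], tab$assay_b[i])
  })
  names(out) <- tab$sample_id
  out
}

.configKeys <- c("assay", "cutoffs", "simulator", "outDir", "seed", "logLevel")
.assayKeys <- c(
  "dropletVolume", "dropletsPerWell", "wellVolume", "inputDnaVolume",
  "elutionVolume", "bloodPerPunch", "negMean", "negSd", "posMean", "posSd",
  "rainFraction", "falsePositiveRate", "runEffectSd"
)
.cutoffKeys <- c("rpp30MinBlood", "trecCutoffBlood", "minGestationalWeeks")

#' Read and validate a YAML pipeline configuration
#'
#' Top-level keys: `assay` (fields of [AssayConfig()]), `cutoffs` (fields of
#' [ScreenCutoffs()]), `simulator`, `outDir`, `seed`, `logLevel`. Unknown
#' keys at any level are rejected by name.
#'
#' @param path YAML file.
#' @return list with `assay` ([AssayConfig-class]), `cutoffs`
#'   ([ScreenCutoffs-class]), `simulator` (list), `outDir`, `seed`,
#'   `logLevel`.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  badTop <- setdiff(names(raw), .configKeys)
  if (length(badTop)) {
    ddStop(sprintf("unknown configuration key(s): %s",
                   paste(badTop, collapse = ", ")), "ddConfigError")
  }
  badAssay <- setdiff(names(raw$assay), .assayKeys)
  if (length(badAssay)) {
    ddStop(sprintf("unknown assay key(s): %s",
                   paste(badAssay, collapse = ", ")), "ddConfigError")
  }
  badCut <- setdiff(names(raw$cutoffs), .cutoffKeys)
  if (length(badCut)) {
    ddStop(sprintf("unknown cutoffs key(s): %s",
                   paste(badCut, collapse = ", ")), "ddConfigError")
  }
  assay <- do.call(AssayConfig, raw$assay %||% list())
  cutoffs <- do.call(ScreenCutoffs, raw$cutoffs %||% list())
  list(
    assay = assay, cutoffs = cutoffs,
    simulator = raw$simulator %||% list(),
    outDir = raw$outDir %||% ".",
    seed = raw$seed %||% NA_integer_,
    logLevel = raw$logLevel %||% "info"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the human-facing screening report
#'
#' Tab-separated, one row per specimen, with display rounding (blood
#' concentrations as integers; copy numbers as integer calls).
#'
#' @param results list of [ScreenResult-class].
#' @param quants matching list of [WellQuant-class] (for concentrations).
#' @param path output TSV path.
#' @return invisibly, the report data.frame.
#' @export
writeScreenReport <- function(results, quants, path) {
  rows <- mapply(function(r, q) {
    data.frame(
      sample_id = r@sampleId,
      qualified = r@qualified,
      trec_class = r@trecClass,
      sma_class = ifelse(is.na(r@smaClass), "NotClassified", r@smaClass),
      smn1_cn = r@smn1Cn, smn2_cn = r@smn2Cn,
      trec_blood = round(bloodConcentration(q, "TREC")),
      rpp30_blood = round(bloodConcentration(q, "RPP30")),
      needs_second_tier = r@needsSecondTier,
      flags = paste(r@flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }, results, quants, SIMPLIFY = FALSE)
  rep <- do.call(rbind, rows)
  utils::write.table(rep, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(rep)
}
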