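#' Accessors for ddScreen objects
#'
#' `acceptedEvents()` returns the accepted droplet count of a well (the
#' number of amplitude rows); `amplitudes()` the droplet-by-channel
#' fluorescence matrix; `truthLabels()` the simulator's template-occupancy
#' matrix (NULL for instrument data); `quantTable()` the per-target
#' quantification data.frame of a [WellQuant-class].
#'
#' @param x a [DropletWell-class] or [WellQuant-class] object.
#' @return see individual descriptions.
#' @name ddScreen-accessors
#' @examples
#' w <- simulateWell(SampleTruth(), AssayConfig(dropletsPerWell = 2000), seed = 1)
#' acceptedEvents(w)
#' dim(amplitudes(w))
NULL

#' @rdname ddScreen-accessors
#' @export
setGeneric("acceptedEvents", function(x) standardGeneric("acceptedEvents"))

#' @rdname ddScreen-accessors
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' @rdname ddScreen-accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @rdname ddScreen-accessors
#' @export
setGeneric("quantTable", function(x) standardGeneric("quantTable"))

#' @rdname ddScreen-accessors
#' @export
setMethod("acceptedEvents", "DropletWell", function(x) nrow(x@amplitudes))

#' @rdname ddScreen-accessors
#' @export
setMethod("amplitudes", "DropletWell", function(x) x@amplitudes)

#' @rdname ddScreen-accessors
#' @export
setMethod("truthLabels", "DropletWell", function(x) x@truthLabels)

#' @rdname ddScreen-accessors
#' @export
setMethod("quantTable", "WellQuant", function(x) x@quant)

setMethod("show", "DropletWell", function(object) {
  cat(
    "DropletWell", object@wellId, "(sample", paste0(object@sampleId, ","),
    "run", paste0(object@runId, ")\n")
  )
  cat(" accepted events:", nrow(object@amplitudes), "\n")
  cat(
    " truth labels:",
    if (is.null(object@truthLabels)) "absent" else "present", "\n"
  )
})

setMethod("show", "WellQuant", function(object) {
  cat("WellQuant for well", object@wellId, "\n")
  q <- object@quant
  q$lambda <- signif(q$lambda, 4)
  q$concReaction <- signif(q$concReaction, 5)
  q$concBlood <- round(q$concBlood)
  print(q[, c("target", "nPositive", "nNegative", "concReaction",
              "concBlood", "cnReported")], row.names = FALSE)
  if (length(object@flags)) cat(" flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult for", object@sampleId, "\n")
  cat(" qualified:", object@qualified, "\n")
  cat(" TREC:", object@trecClass, "| SMA:",
      ifelse(is.na(object@smaClass), "(not classified)", object@smaClass), "\n")
  cat(" SMN1 CN:", object@smn1Cn, "| SMN2 CN:", object@smn2Cn,
      "| second tier needed:", object@needsSecondTier, "\n")
  if (length(object@flags)) cat(" flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "AssayConfig", function(object) {
  cat("AssayConfig:", object@dropletsPerWell, "droplets x",
      object@dropletVolume, "nL;",
      "well", object@wellVolume, "uL; input", object@inputDnaVolume,
      "uL; elution", object@elutionVolume, "uL; blood/punch",
      object@bloodPerPunch, "uL\n")
  cat(" channels:", paste(names(sort(object@channelMap)), collapse = ", "), "\n")
  cat(" rain:", object@rainFraction, "| false positives:",
      object@falsePositiveRate, "| run effect sd:", object@runEffectSd, "\n")
})
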