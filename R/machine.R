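#' @include AllGenerics.R
NULL

# MU rate of the calibration anchor: protons/s at the calibration current,
# expressed in MU/s.
.calibrationMuRate <- function(model) {
    model@calibrationCurrent / model@elementaryCharge / model@protonsPerMu
}

#' Dose-per-MU constant at the spot peak
#'
#' The constant k (Gy per MU) converting a layer's MU rate into its spot
#' peak dose rate, derived once from the calibration anchor: at the
#' calibration current the machine delivers `calibrationSpdr` Gy/s while
#' delivering `calibrationCurrent / e / protonsPerMu` MU/s, so
#' k = calibrationSpdr / (MU rate at calibration). With the defaults
#' k is about 3.365e-3 Gy/MU.
#'
#' @param model a [MachineModel-class].
#' @return Gy per MU at the spot peak.
#' @export
dosePerMu <- function(model) {
    model@calibrationSpdr / .calibrationMuRate(model)
}

#' @rdname muRate
setMethod("muRate", "MachineModel", function(model) {
    model@minMuPerSpot / model@dwellTimeMinMu
})

#' @rdname spdrFromMinMu
setMethod("spdrFromMinMu", "MachineModel", function(model) {
    dosePerMu(model) * muRate(model)
})

#' @rdname currentFromMinMu
setMethod("currentFromMinMu", "MachineModel", function(model) {
    muRate(model) * model@protonsPerMu * model@elementaryCharge
})

#' @rdname minMuFromCurrent
setMethod("minMuFromCurrent", "MachineModel", function(model, current) {
    if (any(current <= 0)) stop("current must be positive")
    current / (model@elementaryCharge * model@protonsPerMu) *
        model@dwellTimeMinMu
})

#' @rdname dwellTime
setMethod("dwellTime", "MachineModel", function(model, spotMu) {
    if (any(!is.finite(spotMu))) stop("spot MU must be finite")
    # small relative tolerance so minimum-MU spots written out and re-read
    # through text round-trips stay deliverable
    if (any(spotMu < model@minMuPerSpot * (1 - 1e-9))) {
        stop(
            "undeliverable spot: MU weight below the minimum of ",
            model@minMuPerSpot, " MU per spot"
        )
    }
    spotMu / muRate(model)
})
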