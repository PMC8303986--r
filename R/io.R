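#' @include fixtures.R
#' @importFrom utils read.csv write.csv
NULL

#' Read and write spot-map CSV files
#'
#' The spot-map interchange format is a delimited text file with header
#' columns `field_id`, `x_mm`, `y_mm`, `mu` and one row per spot; row order
#' within a field is delivery order. An optional `gantry_angle` column
#' carries the per-field angle.
#'
#' @param file path to a CSV file.
#' @return `readSpotMaps` returns a list of [SpotMap-class] objects, one per
#'   field, in order of first appearance.
#' @export
readSpotMaps <- function(file) {
    df <- read.csv(file, stringsAsFactors = FALSE)
    need <- c("field_id", "x_mm", "y_mm", "mu")
    if (!all(need %in% names(df))) {
        stop(
            "spot-map file must have columns ",
            paste(need, collapse = ", ")
        )
    }
    ids <- unique(df$field_id)
    lapply(ids, function(id) {
        rows <- df[df$field_id == id, , drop = FALSE]
        ang <- if ("gantry_angle" %in% names(rows)) rows$gantry_angle[1L] else 0
        spotMap(rows$x_mm, rows$y_mm, rows$mu,
            fieldId = id, gantryAngle = ang
        )
    })
}

#' @param maps a [SpotMap-class] or list of them.
#' @rdname readSpotMaps
#' @export
writeSpotMaps <- function(maps, file) {
    if (is(maps, "SpotMap")) maps <- list(maps)
    df <- do.call(rbind, lapply(maps, function(m) {
        data.frame(
            field_id = m@fieldId,
            x_mm = m@spots$x, y_mm = m@spots$y, mu = m@spots$mu,
            gantry_angle = m@gantryAngle
        )
    }))
    write.csv(df, file, row.names = FALSE)
    invisible(file)
}

#' Read a machine model from a YAML or JSON config file
#'
#' Recognized keys (SI units unless noted): `protons_per_mu` (count),
#' `min_mu_per_spot` (MU), `dwell_time_min_mu` (s), `scan_speed` (mm/ms),
#' `calibration_current` (A), `calibration_spdr` (Gy/s). Missing keys take
#' the package defaults. A top-level `machine:` block is honored.
#'
#' @param file path to a `.yaml`/`.yml`/`.json` file.
#' @return A [MachineModel-class].
#' @export
readMachineConfig <- function(file) {
    cfg <- yaml::read_yaml(file)
    if (!is.null(cfg$machine)) cfg <- cfg$machine
    pick <- function(key, default) {
        if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
    }
    machineModel(
        protonsPerMu = pick("protons_per_mu", 5.17e6),
        minMuPerSpot = pick("min_mu_per_spot", 100),
        dwellTimeMinMu = pick("dwell_time_min_mu", 2e-3),
        scanSpeed = pick("scan_speed", 10),
        calibrationCurrent = pick("calibration_current", 640e-9),
        calibrationSpdr = pick("calibration_spdr", 2600)
    )
}

#' Export a grid volume
#'
#' `writeGridNifti` writes the 3D array as a NIfTI volume with the grid's
#' mm spacing in the header; `writeGridCsv` writes a flat table of voxel
#' indices (1-based, axis order x, y, z) and values.
#'
#' @param grid a [DoseGrid-class] or [DoseRateGrid-class].
#' @param file output path (`.nii` / `.nii.gz` for NIfTI).
#' @param omitUndefined for CSV: drop `NA` (undefined-metric) voxels
#'   (default TRUE).
#' @return the path, invisibly.
#' @export
writeGridNifti <- function(grid, file) {
    stopifnot(is(grid, "VoxelGrid"))
    img <- RNifti::asNifti(grid@values)
    RNifti::pixdim(img) <- grid@geometry@spacing
    RNifti::writeNifti(img, file)
    invisible(file)
}

#' @rdname writeGridNifti
#' @export
writeGridCsv <- function(grid, file, omitUndefined = TRUE) {
    stopifnot(is(grid, "VoxelGrid"))
    shape <- grid@geometry@shape
    idx <- arrayInd(seq_len(prod(shape)), shape)
    df <- data.frame(
        ix = idx[, 1L], iy = idx[, 2L], iz = idx[, 3L],
        value = as.vector(grid@values)
    )
    if (omitUndefined) df <- df[!is.na(df$value), , drop = FALSE]
    write.csv(df, file, row.names = FALSE)
    invisible(file)
}

#' Export a volume histogram as CSV
#'
#' Writes the cumulative curve as columns `bin_edge`,
#' `cumulative_fraction`.
#'
#' @param h a [VolumeHistogram-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeHistogramCsv <- function(h, file) {
    stopifnot(is(h, "VolumeHistogram"))
    write.csv(histCurve(h), file, row.names = FALSE)
    invisible(file)
}
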