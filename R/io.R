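#' Read and write spectra as JSON-lines
#'
#' One JSON object per line per spectrum: the metadata fields, the grid
#' parameters (`grid_start`, `grid_stop`, `n_channels`) and the intensity
#' array. `polarization_deg` is the angle in degrees or the string
#' `"conventional"`.
#'
#' @param x a [RamanSpectra-class].
#' @param path output file.
#' @return `writeSpectraJSONL`: invisibly, `path`; `readSpectraJSONL`: a
#'   [RamanSpectra-class].
#' @export
writeSpectraJSONL <- function(x, path) {
  g <- wavenumbers(x)
  con <- file(path, "w")
  on.exit(close(con))
  Y <- assay(x, "intensity")
  for (j in seq_len(ncol(x))) {
    rec <- list(patient_id = x$patient_id[j], sample_id = x$sample_id[j],
                tissue_class = x$tissue_class[j], component = x$component[j],
                point_id = x$point_id[j],
                polarization_deg = if (is.na(x$polarization_deg[j]))
                  "conventional" else x$polarization_deg[j],
                grid_start = g[1], grid_stop = g[length(g)],
                n_channels = length(g),
                intensity = Y[, j])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname writeSpectraJSONL
#' @export
readSpectraJSONL <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  r1 <- recs[[1]]
  grid <- wavenumberGrid(r1$grid_start, r1$grid_stop, r1$n_channels)
  Y <- vapply(recs, function(r) as.numeric(r$intensity),
              numeric(r1$n_channels))
  cd <- DataFrame(
    patient_id = vapply(recs, `[[`, character(1), "patient_id"),
    sample_id = vapply(recs, `[[`, character(1), "sample_id"),
    tissue_class = vapply(recs, `[[`, character(1), "tissue_class"),
    component = vapply(recs, `[[`, character(1), "component"),
    point_id = vapply(recs, function(r) as.integer(r$point_id), integer(1)),
    polarization_deg = vapply(recs, function(r)
      if (identical(r$polarization_deg, "conventional")) NA_real_
      else as.numeric(r$polarization_deg), numeric(1)))
  RamanSpectra(Y, grid, cd)
}

#' Read and write spectra as wide CSV
#'
#' The spectral matrix goes to `path` (first column `wavenumber`, one
#' column per spectrum); the per-spectrum metadata table goes to
#' `meta_path` (default `<path>.meta.csv`), keyed by the spectrum column
#' names.
#'
#' @inheritParams writeSpectraJSONL
#' @param meta_path metadata CSV path.
#' @return `writeSpectraCSV`: invisibly, `path`; `readSpectraCSV`: a
#'   [RamanSpectra-class].
#' @export
writeSpectraCSV <- function(x, path, meta_path = paste0(path, ".meta.csv")) {
  df <- data.frame(wavenumber = wavenumbers(x), assay(x, "intensity"),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  meta <- data.frame(spectrum = colnames(x),
                     as.data.frame(colData(x)[, .COLDATA_REQUIRED]))
  write.csv(meta, meta_path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectraCSV
#' @export
readSpectraCSV <- function(path, meta_path = paste0(path, ".meta.csv")) {
  df <- read.csv(path, check.names = FALSE)
  meta <- read.csv(meta_path)
  Y <- as.matrix(df[, -1, drop = FALSE])
  meta <- meta[match(colnames(Y), meta$spectrum), ]
  cd <- DataFrame(meta[, .COLDATA_REQUIRED])
  RamanSpectra(Y, df$wavenumber, cd)
}

#' Read and write an experiment configuration as YAML
#'
#' Serializes an [experimentConfig()] (grid and nested model configs
#' included) so every run can archive its resolved configuration.
#'
#' @param config an `"experimentConfig"`.
#' @param path YAML file path.
#' @return `writeExperimentConfig`: invisibly, `path`;
#'   `readExperimentConfig`: an `"experimentConfig"`.
#' @export
writeExperimentConfig <- function(config, path) {
  ser <- unclass(config)
  ser$synth$grid <- list(start = config$synth$grid[1],
                         stop = config$synth$grid[length(config$synth$grid)],
                         n_channels = length(config$synth$grid))
  ser$cnn2d <- unclass(ser$cnn2d)
  ser$cnn1d <- unclass(ser$cnn1d)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname writeExperimentConfig
#' @export
readExperimentConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$synth$grid <- wavenumberGrid(raw$synth$grid$start, raw$synth$grid$stop,
                                   raw$synth$grid$n_channels)
  raw$synth <- do.call(synthConfig, raw$synth[names(formals(synthConfig))[
    names(formals(synthConfig)) %in% names(raw$synth)]])
  for (nm in c("cnn2d", "cnn1d")) {
    cc <- raw[[nm]]
    keep <- names(formals(cnnConfig))[names(formals(cnnConfig)) %in% names(cc)]
    raw[[nm]] <- do.call(cnnConfig, cc[keep])
  }
  structure(raw, class = "experimentConfig")
}
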