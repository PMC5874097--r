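## NIfTI-1 and CSV/JSON interfaces. Volumes travel as NIfTI with spacing
## in the header; acquisition parameters travel as a JSON sidecar; tables
## as comma-separated UTF-8 CSV with a unit-naming comment line.

unitsHeader <- "# units: ktrans 1/min; ve, vp fraction; mvd vessels/field; time s; concentration mM"

writeTableCSV <- function(df, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(unitsHeader, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

readTableCSV <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write and read acquisition sidecars
#'
#' Acquisition parameters round-trip through a JSON sidecar so that a
#' dynamic series on disk is self-describing.
#'
#' @param acq an \code{\linkS4class{AcquisitionParams}}
#' @param path JSON file path
#' @return \code{readAcquisition} returns an \code{AcquisitionParams}
#' @export
writeAcquisition <- function(acq, path) {
  jsonlite::write_json(list(
    tr = acq@tr, te = acq@te, flip_angles_deg = acq@flipAngles,
    dynamic_flip_deg = acq@dynamicFlip, dt = acq@dt,
    n_dynamics = acq@nDynamics, n_baseline = acq@nBaseline,
    r1 = acq@r1, hct = acq@hct), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAcquisition
#' @export
readAcquisition <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  acquisitionParams(tr = j$tr, te = j$te, flipAngles = j$flip_angles_deg,
                    dynamicFlip = j$dynamic_flip_deg, dt = j$dt,
                    nDynamics = j$n_dynamics, nBaseline = j$n_baseline,
                    r1 = j$r1, hct = j$hct)
}

#' Read and write dynamic series
#'
#' The 4D signal travels as NIfTI-1; the acquisition parameters as a JSON
#' sidecar next to it. On read, the frame count is validated against the
#' sidecar.
#'
#' @param dyn a \code{\linkS4class{DynamicSeries}}
#' @param path NIfTI path (\code{.nii} or \code{.nii.gz})
#' @param sidecar JSON sidecar path; defaults to \code{path} with a
#'   \code{.json} extension
#' @return \code{readDynamicSeries} returns a \code{DynamicSeries}
#' @export
writeDynamicSeries <- function(dyn, path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  RNifti::writeNifti(RNifti::asNifti(dyn@signal), path)
  writeAcquisition(dyn@acq, sidecar)
  invisible(path)
}

#' @rdname writeDynamicSeries
#' @export
readDynamicSeries <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(path)) stop("dynamic series not found: ", path)
  if (!file.exists(sidecar)) stop("acquisition sidecar not found: ",
                                  sidecar)
  img <- RNifti::readNifti(path)
  acq <- readAcquisition(sidecar)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 4L)
    stop("malformed dynamic series: expected a 4D volume, got ",
         length(dim(arr)), "D")
  if (dim(arr)[4] != acq@nDynamics)
    stop(sprintf(
      "truncated series: %d frames on disk but sidecar declares %d",
      dim(arr)[4], acq@nDynamics))
  dynamicSeries(arr, acq)
}

#' Write and read parameter maps
#'
#' Each map (Ktrans, ve, vp, t0, rss) is one 3D NIfTI; the convergence and
#' ROI masks are integer NIfTIs.
#'
#' @param maps a \code{\linkS4class{ParameterMaps}}
#' @param dir output directory (created if missing)
#' @return \code{readParameterMaps} returns a \code{ParameterMaps}
#' @export
writeParameterMaps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("ktrans", "ve", "vp", "t0", "rss"))
    RNifti::writeNifti(RNifti::asNifti(slot(maps, nm)),
                       file.path(dir, paste0(nm, ".nii.gz")))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(maps@converged),
                                           dim(maps@converged))),
                     file.path(dir, "converged.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(maps@mask),
                                           dim(maps@mask))),
                     file.path(dir, "mask.nii.gz"))
  invisible(dir)
}

#' @rdname writeParameterMaps
#' @export
readParameterMaps <- function(dir) {
  rd <- function(nm) {
    img <- RNifti::readNifti(file.path(dir, paste0(nm, ".nii.gz")))
    array(as.numeric(img), dim(img))
  }
  mask <- rd("mask") > 0
  new("ParameterMaps", ktrans = rd("ktrans"), ve = rd("ve"),
      vp = rd("vp"), t0 = rd("t0"), rss = rd("rss"),
      converged = array(rd("converged") > 0, dim(mask)), mask = mask)
}

#' Read a subregion label volume
#'
#' @param path integer NIfTI with codes 0 (outside), 1 CNA, 2 PNA, 3 VTA
#' @return integer label array
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("label volume not found: ", path)
  img <- RNifti::readNifti(path)
  lab <- array(as.integer(round(as.numeric(img))), dim(img))
  if (!all(lab %in% 0:5))
    stop("malformed label volume: codes outside 0..5")
  lab
}

#' Write/read the arterial input function as CSV
#'
#' Two columns: \code{time_s} and \code{cp_mM}, plus a JSON sidecar with
#' the curve-shape quality metrics.
#'
#' @param aif an \code{\linkS4class{AIF}}
#' @param path CSV path
#' @return \code{readAIF} returns an \code{AIF}
#' @export
writeAIF <- function(aif, path) {
  utils::write.csv(data.frame(time_s = aif@times, cp_mM = aif@cp),
                   path, row.names = FALSE)
  jsonlite::write_json(as.list(aifQuality(aif)),
                       sub("\\.csv$", "_quality.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAIF
#' @export
readAIF <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "cp_mM") %in% names(df)))
    stop("malformed AIF CSV: expected columns time_s, cp_mM")
  aifCurve(df$cp_mM, df$time_s)
}

#' Read a microvessel-density table
#'
#' @param path CSV with at least columns \code{region} and \code{mvd}
#'   (optionally \code{tumor_id})
#' @return data.frame
#' @export
readMVD <- function(path) {
  if (!file.exists(path)) stop("MVD table not found: ", path)
  df <- readTableCSV(path)
  if (!all(c("region", "mvd") %in% names(df)))
    stop("malformed MVD CSV: expected columns region, mvd")
  df
}

#' Write a cohort summary table
#'
#' @param records summary data.frame (tumor_id, region, ktrans, ve, vp,
#'   mvd)
#' @param path CSV path
#' @export
writeSummary <- function(records, path) {
  writeTableCSV(records, path)
}

#' @rdname writeSummary
#' @export
readSummary <- function(path) {
  df <- readTableCSV(path)
  need <- c("tumor_id", "region", "ktrans", "ve", "vp", "mvd")
  if (!all(need %in% names(df)))
    stop("malformed summary CSV: expected columns ",
         paste(need, collapse = ", "))
  df
}

#' The bundled 15-tumor reference table
#'
#' Per-tumor, per-subregion pharmacokinetic parameters (Ktrans in /min,
#' ve and vp as fractions) and microvessel density (vessels per
#' high-power field, mean of five fields) for 15 ablated VX2 liver tumors,
#' in the three-subregion layout (CNA, PNA, VTA). This is the reference
#' dataset the statistical module reproduces and the source of the
#' phantom's default region statistics.
#'
#' @return data.frame with 45 rows and columns \code{tumor_id},
#'   \code{region}, \code{ktrans}, \code{ve}, \code{vp}, \code{mvd}
#' @examples
#' tab <- loadTable1Fixture()
#' nrow(tab)  # 45
#' @export
loadTable1Fixture <- function() {
  path <- system.file("extdata", "vx2_subregion_table.csv",
                      package = "dcequant", mustWork = TRUE)
  df <- readTableCSV(path)
  stopifnot(nrow(df) == 45L,
            identical(sort(unique(df$region)), c("CNA", "PNA", "VTA")))
  df
}
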