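#' Volume downsampling and snapshot output
#'
#' Full-resolution volumes are large; for visualisation-scale output fields
#' are reduced on a strided lattice.  The default stride of 6 retains the
#' visual structure of the full volume at 1/216 of the data.  Snapshots are
#' written as VTK legacy structured-points files (one scalar per file) with
#' a JSON sidecar, agents as CSV, time series as CSV.
#'
#' @name output_sampling
NULL

#' Strided volume reduction
#'
#' Splits the volume into stride-sized windows anchored at voxel (0, 0, 0)
#' and reduces each window: `"point"` picks the window-origin voxel,
#' `"mean"`/`"max"` aggregate the window.  Output dims are
#' `ceiling(dim / stride)`.
#'
#' @param field 3D array.
#' @param stride Integer stride >= 1, scalar or per-axis length 3.
#' @param reducer One of `"point"`, `"mean"`, `"max"`.
#' @return Reduced 3D array.
#' @export
#' @examples
#' sample_volume(array(1, c(12, 12, 12)), 6)  # 2 x 2 x 2, all 1
sample_volume <- function(field, stride = 6L,
                          reducer = c("point", "mean", "max")) {
  reducer <- match.arg(reducer)
  stride <- as.integer(rep(stride, length.out = 3L))
  if (any(stride < 1L)) stop("stride must be >= 1")
  d <- dim(field)
  if (is.null(d) || length(d) != 3L) stop("field must be a 3D array")
  if (reducer == "point") {
    return(field[seq(1L, d[1], by = stride[1]),
                 seq(1L, d[2], by = stride[2]),
                 seq(1L, d[3], by = stride[3]), drop = FALSE])
  }
  od <- as.integer(ceiling(d / stride))
  acc <- array(if (reducer == "max") -Inf else 0, od)
  cnt <- array(0L, od)
  ## accumulate over the (at most stride^3) within-window offsets
  for (k in 0:(stride[3] - 1L)) for (j in 0:(stride[2] - 1L))
    for (i in 0:(stride[1] - 1L)) {
      sub <- field[seq(1L + i, d[1], by = stride[1]),
                   seq(1L + j, d[2], by = stride[2]),
                   seq(1L + k, d[3], by = stride[3]), drop = FALSE]
      sd <- dim(sub)
      tgt <- list(seq_len(sd[1]), seq_len(sd[2]), seq_len(sd[3]))
      if (reducer == "mean") {
        acc[tgt[[1]], tgt[[2]], tgt[[3]]] <-
          acc[tgt[[1]], tgt[[2]], tgt[[3]], drop = FALSE] + sub
        cnt[tgt[[1]], tgt[[2]], tgt[[3]]] <-
          cnt[tgt[[1]], tgt[[2]], tgt[[3]], drop = FALSE] + 1L
      } else {
        acc[tgt[[1]], tgt[[2]], tgt[[3]]] <-
          pmax(acc[tgt[[1]], tgt[[2]], tgt[[3]], drop = FALSE], sub)
      }
    }
  if (reducer == "mean") acc <- acc / cnt
  acc
}

#' Write a 3D scalar field as a VTK legacy structured-points file
#'
#' ASCII "STRUCTURED_POINTS" dataset, x varying fastest, suitable for
#' ParaView/VisIt.
#'
#' @param field 3D array.
#' @param path Output path.
#' @param name Scalar name recorded in the file.
#' @param spacing Voxel spacing (um), scalar or length 3.
#' @return `path`, invisibly.
#' @export
write_vtk_volume <- function(field, path, name = "scalar", spacing = 15) {
  d <- dim(field)
  spacing <- rep(spacing, length.out = 3L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("%s volume", name),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", spacing[1], spacing[2], spacing[3]),
               sprintf("POINT_DATA %d", prod(d)),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(field), digits = 17, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' Read back a VTK legacy structured-points scalar volume
#' @param path Path written by [write_vtk_volume()].
#' @return 3D array.
#' @export
read_vtk_volume <- function(path) {
  lines <- readLines(path)
  dl <- grep("^DIMENSIONS", lines, value = TRUE)[1]
  d <- as.integer(strsplit(trimws(dl), "\\s+")[[1]][2:4])
  start <- grep("^LOOKUP_TABLE", lines)[1] + 1L
  vals <- as.numeric(lines[start:(start + prod(d) - 1L)])
  array(vals, d)
}

#' Write a world snapshot
#'
#' Writes each chemical field and the damage field as downsampled VTK
#' volumes, the agent table as CSV, and a JSON sidecar recording tick,
#' sampling spec and units.
#'
#' @param world A `vf_world`.
#' @param dir Output directory (created if needed).
#' @param stride Sampling stride (default 6).
#' @param reducer Sampling reducer (default `"point"`).
#' @return Named character vector of written paths, invisibly.
#' @export
write_snapshot <- function(world, dir, stride = 6L, reducer = "point") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- world$grid$patch_width * stride
  paths <- c()
  for (nm in names(world$chemicals)) {
    p <- file.path(dir, sprintf("chem_%s.vtk", nm))
    write_vtk_volume(sample_volume(world$chemicals[[nm]], stride, reducer),
                     p, nm, sp)
    paths[paste0("chem_", nm)] <- p
  }
  p <- file.path(dir, "damage.vtk")
  write_vtk_volume(sample_volume(world$damage, stride, reducer), p,
                   "damage", sp)
  paths["damage"] <- p
  p <- file.path(dir, "agents.csv")
  write_agents_csv(world, p)
  paths["agents"] <- p
  side <- list(tick = world$tick,
               time_min = world$tick * world$config$tick_minutes,
               stride = stride, reducer = reducer,
               patch_width_um = world$grid$patch_width,
               units = list(chemicals = "au", damage = "fraction"),
               grid = grid_dims(world$grid))
  p <- file.path(dir, "snapshot.json")
  jsonlite::write_json(side, p, auto_unbox = TRUE, pretty = TRUE)
  paths["sidecar"] <- p
  invisible(paths)
}

#' Write / read a run time series as CSV
#' @param series Data frame from [run()].
#' @param path CSV path.
#' @return `path` (writer) or the data frame (reader).
#' @export
write_timeseries <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
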