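#' Read a delimited x,y,z point table as a canopy cloud
#'
#' Accepts whitespace- or comma-separated tables with or without a header;
#' the first three numeric columns are taken as x, y, z in metres.
#'
#' @param path File path.
#' @param ground_elevation,normalized Passed to [canopy_cloud()].
#' @return A [canopy_cloud()].
#' @export
read_cloud_xyz <- function(path, ground_elevation = 0, normalized = TRUE) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  header <- !grepl("^[-0-9.eE+, \t]+$", first)
  df <- utils::read.table(path, header = header, sep = sep)
  num <- df[vapply(df, is.numeric, TRUE)]
  if (ncol(num) < 3) stop("need at least three numeric columns (x, y, z)")
  canopy_cloud(as.matrix(num[, 1:3]), ground_elevation, normalized)
}

#' Write a canopy cloud as a delimited x,y,z table
#'
#' @param cloud A [canopy_cloud()].
#' @param path Output path (CSV with header).
#' @export
write_cloud_xyz <- function(cloud, path) {
  stopifnot(inherits(cloud, "canopy_cloud"))
  utils::write.csv(as.data.frame(cloud$points), path, row.names = FALSE)
  invisible(path)
}

#' Write per-footprint canopy-entropy records
#'
#' @param entropies Named list of [canopy_entropy()] objects (names are
#'   footprint ids) or a data frame from `as.data.frame()`.
#' @param path Output CSV path.
#' @export
write_entropy_table <- function(entropies, path) {
  if (is.list(entropies) && !is.data.frame(entropies)) {
    df <- do.call(rbind, lapply(entropies, as.data.frame))
    df <- cbind(footprint_id = names(entropies), df)
  } else df <- entropies
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write wide RH-profile tables
#'
#' Wide format: one row per shot, columns `shot_id`, `rh0` ... `rh100`.
#'
#' @param profiles Named list of [rh_profile()] vectors (names are shot ids).
#' @param path File path.
#' @return `read_rh_table` returns a data frame.
#' @export
write_rh_table <- function(profiles, path) {
  df <- as.data.frame(do.call(rbind, profiles))
  df <- cbind(shot_id = names(profiles), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rh_table
#' @export
read_rh_table <- function(path) {
  utils::read.csv(path, check.names = TRUE)
}
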