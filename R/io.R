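# Readers and writers for the package's two CSV dialects.
#
# Individual-level: one row per participant with columns cluster_id,
# pair_id (optional), A, Y, then covariates named W* (individual-level) or
# E* (cluster-level, repeated within cluster). Cluster-level: one row per
# cluster with cluster_id, pair_id (optional), A, Yc, N, E* (and W*c means
# if available). Header row, UTF-8, '.' decimal.

#' Read an individual-level CRT CSV file
#'
#' @param path Path to a CSV file with columns `cluster_id`, `A`, `Y`,
#'   optional `pair_id`, and covariates named `W*`/`E*`.
#' @return A [crt_data] object (validated: constant cluster-level
#'   covariates and arm within cluster, binary `A` and `Y`).
#' @export
read_individual_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cluster_id", "A", "Y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(df),
                     c(required, "pair_id",
                       names(df)[startsWith(names(df), "W") |
                                   startsWith(names(df), "E")]))
  if (length(unknown)) {
    stop(path, ": unknown columns: ", paste(unknown, collapse = ", "))
  }
  bad_a <- which(!df$A %in% c(0, 1))
  if (length(bad_a)) {
    stop(path, ": non-binary A in row(s) ",
         paste(utils::head(bad_a, 5), collapse = ", "))
  }
  bad_y <- which(!df$Y %in% c(0, 1))
  if (length(bad_y)) {
    stop(path, ": non-binary Y in row(s) ",
         paste(utils::head(bad_y, 5), collapse = ", "))
  }
  data <- crt_data(df)
  v <- validate_crt(data)
  fatal <- grepl("not constant within clusters", v)
  if (any(fatal)) stop(path, ": ", paste(v[fatal], collapse = "; "))
  data
}

#' Read a cluster-level CRT CSV file
#'
#' For trials where only cluster-level aggregates are available. The
#' aggregated outcome `Yc` is a mean, so it need not correspond to an
#' integral event count.
#'
#' @param path Path to a CSV file with columns `cluster_id`, `A`, `Yc`
#'   (in \[0, 1\]), `N`, optional `pair_id`, and cluster covariates `E*`
#'   (and `W*c`).
#' @return A [crt_data] object with `cluster_only = TRUE`.
#' @export
read_cluster_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cluster_id", "A", "Yc", "N")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  crt_data_clusters(df)
}

#' Write CRT data to an individual-level CSV file
#'
#' Round-trips with [read_individual_csv()].
#'
#' @param data A [crt_data] object with individual-level records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_individual_csv <- function(data, path) {
  stopifnot(inherits(data, "crt_data"))
  if (data$cluster_only) {
    stop("no individual-level records; use write_cluster_csv()")
  }
  utils::write.csv(data$individuals, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write cluster-level aggregates to a CSV file
#'
#' @param data A [crt_data] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_csv <- function(data, path) {
  stopifnot(inherits(data, "crt_data"))
  utils::write.csv(data$clusters, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scatter of cluster size against cluster-level outcome by arm
#'
#' A quick look at informative cluster size: when outcome incidence varies
#' systematically with cluster size, cluster-level and individual-level
#' effects can diverge.
#'
#' @param x A [crt_data] object.
#' @param ... Further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.crt_data <- function(x, ...) {
  cl <- x$clusters
  graphics::plot(cl$N, cl$Yc, pch = ifelse(cl$A == 1, 19, 1),
                 xlab = "cluster size N", ylab = "cluster-level outcome Yc",
                 ...)
  graphics::legend("topright", legend = c("intervention", "control"),
                   pch = c(19, 1), bty = "n")
  invisible(x)
}
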