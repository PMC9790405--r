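#' Read and write trial data files
#'
#' Plain-text interchange for the package's data objects. Trial IPD
#' round-trip to CSV with header \code{x1..xK,z,y}; aggregate data to JSON
#' with keys \code{theta}, \code{sd}, \code{corr} and
#' \code{counts = \{yB, nB, yC, nC\}} (events and arm sizes for the active
#' and comparator arms); pseudo-populations to CSV with header
#' \code{x1..xK}.
#'
#' @param ipd,agg,pseudo object to write.
#' @param path file path.
#' @param em_idx optional effect-modifier indices attached on read.
#' @return The read functions return the corresponding object; the write
#'   functions return \code{path} invisibly.
#' @examples
#' cfg <- scenario_config(n_ac = 50)
#' ipd <- simulate_trial(cfg, cfg$mu_ac, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_trial_ipd(ipd, f)
#' identical(read_trial_ipd(f, em_idx = cfg$em_idx)$x, ipd$x)
#' @name popitc-io
NULL

#' @rdname popitc-io
#' @export
write_trial_ipd <- function(ipd, path) {
  stopifnot(inherits(ipd, "trial_ipd"))
  df <- data.frame(ipd$x, z = ipd$z, y = ipd$y, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname popitc-io
#' @export
read_trial_ipd <- function(path, em_idx = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("z", "y") %in% names(df)))
    stop("IPD file must contain `z` and `y` columns", call. = FALSE)
  xcols <- setdiff(names(df), c("z", "y"))
  trial_ipd(as.matrix(df[xcols]), df$z, df$y, em_idx = em_idx)
}

#' @rdname popitc-io
#' @export
write_aggregate_data <- function(agg, path) {
  stopifnot(inherits(agg, "aggregate_data"))
  obj <- list(theta = agg$theta, sd = agg$sd, corr = agg$corr,
              counts = list(yB = unname(agg$counts[1, 1]),
                            nB = unname(agg$n_active),
                            yC = unname(agg$counts[1, 2]),
                            nC = unname(agg$n_control)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname popitc-io
#' @export
read_aggregate_data <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cnt <- obj$counts
  counts <- matrix(c(cnt$yB, cnt$nB - cnt$yB, cnt$yC, cnt$nC - cnt$yC), 2, 2)
  aggregate_data(theta = obj$theta, sd = obj$sd,
                 corr = as.matrix(obj$corr), counts = counts)
}

#' @rdname popitc-io
#' @export
write_pseudo_population <- function(pseudo, path) {
  stopifnot(inherits(pseudo, "pseudo_population"))
  utils::write.csv(as.data.frame(pseudo$x_star), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname popitc-io
#' @export
read_pseudo_population <- function(path, em_idx = integer()) {
  df <- utils::read.csv(path)
  .pseudo_population(as.matrix(df), em_idx)
}
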