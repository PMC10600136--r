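# Plain-text I/O.  The canonical interchange formats are TSV matrices
# (frames x voxels, header row = voxel IDs) for time series and long-format
# TSV for adjacency data (one row per transition type and coefficient,
# with explicit s1/s2/class columns so state-relabelling stays auditable).

#' Read / write a frames-by-voxels matrix as TSV
#'
#' @param path file path.
#' @param m numeric matrix.
#' @return `read_hb_matrix` returns a numeric matrix with voxel IDs as
#'   column names.
#' @export
read_hb_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(dt)
  storage.mode(m) <- "double"
  m
}

#' @rdname read_hb_matrix
#' @export
write_hb_matrix <- function(m, path) {
  if (is.null(colnames(m))) colnames(m) <- paste0("v", seq_len(ncol(m)))
  data.table::fwrite(as.data.frame(m), path, sep = "\t")
  invisible(path)
}

#' Write adjacency data
#'
#' `write_suite_long` writes the long-format TSV of a suite;
#' `write_adjacency_csv` writes one coefficient as a 10 x 10 matrix CSV.
#'
#' @param suite an [adjacency_suite()].
#' @param path output file.
#' @param subject,breast label columns for the long format.
#' @param coefficient coefficient class for the matrix view.
#' @export
write_suite_long <- function(suite, path, subject = NA_character_,
                             breast = NA_character_) {
  data.table::fwrite(suite_long(suite, subject, breast), path, sep = "\t")
  invisible(path)
}

#' @rdname write_suite_long
#' @export
write_adjacency_csv <- function(suite, path, coefficient = "prob") {
  m <- as_adjacency_matrix(suite, coefficient)
  df <- data.frame(pre_state = 1:10, m)
  colnames(df) <- c("pre_state", paste0("post_", 1:10))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a long-format adjacency TSV back into suites
#'
#' @param path long-format TSV written by [write_suite_long()] (possibly
#'   several subjects/breasts concatenated).
#' @return named list of [adjacency_suite()]-like objects, one per
#'   (subject, breast) pair.
#' @export
read_suite_long <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("subject", "breast", "coefficient_class", "k", "value", "count")
  if (!all(need %in% names(dt)))
    stop("not a long-format adjacency table: ", path, call. = FALSE)
  split_by <- interaction(dt$subject, dt$breast, drop = TRUE)
  out <- lapply(split(dt, split_by), function(d) {
    cls <- unique(d$coefficient_class)
    coefs <- sapply(cls, function(cc) {
      v <- rep(NA_real_, 100L)
      sel <- d[d$coefficient_class == cc, ]
      v[sel$k] <- sel$value
      v
    })
    counts <- integer(100L)
    sel <- d[d$coefficient_class == cls[1L], ]
    counts[sel$k] <- sel$count
    structure(list(counts = counts, coefficients = coefs,
                   scheme = NA_character_, frame_rate = NA_real_,
                   subject = d$subject[1L], breast = d$breast[1L]),
              class = "adjacency_suite")
  })
  out
}
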